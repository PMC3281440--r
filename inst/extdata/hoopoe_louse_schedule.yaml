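# In vitro rearing calibration for the hoopoe chewing louse
# (35 C, 75-82% RH, feather diet). Durations in days.
stages:
- name: egg
  mean: 5.25
  sd: 0.97
  min: 4.0
  max: 7.0
- name: nymph1
  mean: 5.08
  sd: 0.85
  min: 4.0
  max: 7.0
- name: nymph2
  mean: 5.54
  sd: 0.84
  min: 4.0
  max: 7.0
- name: nymph3
  mean: 6.04
  sd: 1.89
  min: 5.0
  max: 7.0
adult_female_lifespan:
  mean: 15.0
  sd: 6.28
  min: 2.0
  max: 24.0
adult_male_lifespan:
  mean: 10.96
  sd: 3.92
  min: 1.0
  max: 21.0
eggs_per_female_day: 0.35
lifetime_eggs_per_female: 6.1
# adult sex ratio 1 male : 1.3 females
female_fraction: 0.5652173913043478
# protected in vitro rearing: no imposed immature mortality
stage_survival:
  egg: 1.0
  nymph1: 1.0
  nymph2: 1.0
  nymph3: 1.0
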