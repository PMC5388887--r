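# Default rat validation-cohort structure: VO around PND-33, first
# ovulation less than a day later, sacrifice at PND-37.
species: rat
n: 20
seed: 1
vo_age: {mean: 33.2, sd: 0.9, min: 25}
lag_vo_to_fo: {mean: 0.8, sd: 0.7, min: 0}
cycle_length_days: 4
p_long_cycle: 0
sacrifice: {rule: fixed, age_pnd: 37}
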