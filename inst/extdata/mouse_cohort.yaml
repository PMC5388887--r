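# Default mouse validation-cohort structure: VO around PND-32, first
# ovulation about a week later, sacrifice 0-8 days after first ovulation
# (inside the mouse retrospective dating window).
species: mouse
n: 17
seed: 1
vo_age: {mean: 31.8, sd: 1.8, min: 25}
lag_vo_to_fo: {mean: 6.8, sd: 2.3, min: 0}
cycle_length_days: 4
p_long_cycle: 0
sacrifice: {rule: fo_offset, min: 0, max: 8}
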