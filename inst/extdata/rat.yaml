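# Rat species parameterization for Pub-score staging.
# NOTE (non-normative bounds): only the small-follicle ceiling (< 275 um)
# is established for the rat here; the F1-F5 diameter bounds below are
# placeholders spanning the plausible preovulatory growth range and must
# be replaced with strain-appropriate values before diameter-based
# classification is used quantitatively in rats. Class labels and the
# class -> score mapping are normative.
species: rat
cycle_length_days: 4
max_regressing_generations: 2
max_score: 12
follicle_classes:
  - {label: SF, upper_um: 275, score: -5}
  - {label: F1, upper_um: 325, score: -5}
  - {label: F2, upper_um: 375, score: -4}
  - {label: F3, upper_um: 425, score: -3}
  - {label: F4, upper_um: 500, score: -2}
  - {label: F5, upper_um: .inf, score: -1}
cl_schedule:
  - day: 1
    luteinization: none
    mitoses: present
    apoptosis: absent
    vascular_pattern: false
    rupture_site: true
    fibrous_center: false
    companion_class: F1
    companion_classes: [SF, F1, F2]
    oocyte_location: ampulla_COC
  - day: 2
    luteinization: partial
    mitoses: abundant
    apoptosis: absent
    vascular_pattern: true
    rupture_site: false
    fibrous_center: false
    companion_class: F3
    companion_classes: [F2, F3]
    oocyte_location: isthmus_nude
  - day: 3
    luteinization: full
    mitoses: absent
    apoptosis: absent
    vascular_pattern: true
    rupture_site: false
    fibrous_center: false
    companion_class: F4
    companion_classes: [F4]
    oocyte_location: none
  - day: 4
    luteinization: full
    mitoses: absent
    apoptosis: absent
    vascular_pattern: true
    rupture_site: false
    fibrous_center: false
    companion_class: F5
    companion_classes: [F5]
    oocyte_location: none
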