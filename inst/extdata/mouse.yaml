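# Mouse species parameterization for Pub-score staging.
# Follicle class boundaries (upper diameter, micrometres) follow the
# published estrous-cycle follicle cohort measurements: SF < 250,
# F1 250-300, F2 301-350, F3 351-400, F4 > 400.
species: mouse
cycle_length_days: 4
max_regressing_generations: 1
max_score: 8
follicle_classes:
  - {label: SF, upper_um: 250, score: -5}
  - {label: F1, upper_um: 300, score: -4}
  - {label: F2, upper_um: 350, score: -3}
  - {label: F3, upper_um: 400, score: -2}
  - {label: F4, upper_um: .inf, score: -1}
# Current-cycle corpus luteum feature schedule, one row per day since
# ovulation. companion_class is the typical most-advanced follicle class;
# companion_classes lists all classes compatible with that day.
cl_schedule:
  - day: 1
    luteinization: none
    mitoses: present
    apoptosis: absent
    vascular_pattern: false
    rupture_site: true
    fibrous_center: false
    companion_class: F1
    companion_classes: [SF, F1]
    oocyte_location: ampulla_COC
  - day: 2
    luteinization: partial
    mitoses: abundant
    apoptosis: absent
    vascular_pattern: true
    rupture_site: false
    fibrous_center: false
    companion_class: F2
    companion_classes: [F2]
    oocyte_location: isthmus_nude
  - day: 3
    luteinization: full
    mitoses: absent
    apoptosis: absent
    vascular_pattern: true
    rupture_site: false
    fibrous_center: true
    companion_class: F3
    companion_classes: [F3]
    oocyte_location: uterotubal_junction
  - day: 4
    luteinization: full
    mitoses: absent
    apoptosis: abundant
    vascular_pattern: true
    rupture_site: false
    fibrous_center: false
    companion_class: F4
    companion_classes: [F4]
    oocyte_location: none
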