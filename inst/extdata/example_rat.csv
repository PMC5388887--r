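animal_id,species,age_pnd,vo_age_pnd,follicle_class,cl_generations,oocyte_location
rat_example,rat,40,34,F3,current:partial:abundant:absent:1:0:0:0;R1:full:absent:absent:0:0:0:1,isthmus_nude
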