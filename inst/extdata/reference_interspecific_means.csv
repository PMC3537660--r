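variable,units,species,mean_max,sem,n_cycles,n_individuals
mandibular_retraction_length,BL,Sicyopterus stimpsoni,0.019,0.001,95,4
mandibular_retraction_length,BL,Awaous guamensis,0.030,0.002,28,3
mandibular_retraction_length,BL,Lentipes concolor,0.044,0.002,33,3
hyoid_retraction_angle,deg,Sicyopterus stimpsoni,4.710,0.357,95,4
hyoid_retraction_angle,deg,Awaous guamensis,8.206,0.822,28,3
hyoid_retraction_angle,deg,Lentipes concolor,14.036,0.659,33,3
opercular_expansion_length,BL,Sicyopterus stimpsoni,0.007,0.001,95,4
opercular_expansion_length,BL,Awaous guamensis,0.035,0.002,28,3
opercular_expansion_length,BL,Lentipes concolor,0.044,0.001,33,3
premaxillary_protrusion_length,BL,Sicyopterus stimpsoni,0.031,0.000457,95,4
premaxillary_protrusion_length,BL,Awaous guamensis,0.016,0.001,28,3
premaxillary_protrusion_length,BL,Lentipes concolor,0.024,0.001,33,3
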