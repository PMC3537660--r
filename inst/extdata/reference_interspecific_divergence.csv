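variable,pair,divergence_angle_deg
mandibular_retraction_length,Awaous guamensis-Sicyopterus stimpsoni,5.77
mandibular_retraction_length,Lentipes concolor-Sicyopterus stimpsoni,13.03
hyoid_retraction_angle,Awaous guamensis-Sicyopterus stimpsoni,3.74
hyoid_retraction_angle,Lentipes concolor-Sicyopterus stimpsoni,2.98
opercular_expansion_length,Awaous guamensis-Sicyopterus stimpsoni,4.24
opercular_expansion_length,Lentipes concolor-Sicyopterus stimpsoni,3.03
premaxillary_protrusion_length,Awaous guamensis-Sicyopterus stimpsoni,45.31
premaxillary_protrusion_length,Lentipes concolor-Sicyopterus stimpsoni,46.93
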