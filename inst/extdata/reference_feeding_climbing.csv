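variable,units,feeding_mean_max,feeding_sem,climbing_mean_max,climbing_sem,feeding_n_cycles,climbing_n_cycles,divergence_angle_deg
cranial_elevation_angle,deg,5.824,0.234,7.173,1.858,96,36,7.56
premaxillary_protrusion_angle,deg,25.031,0.384,22.897,0.705,96,36,3.60
premaxillary_protrusion_length,BL,0.031,0.000457,0.035,0.001,96,36,4.23
hyoid_retraction_angle,deg,43.408,0.525,61.131,1.016,96,36,4.85
hyoid_retraction_length,BL,0.014,0.001,0.028,0.003,96,36,20.96
mandibular_retraction_length,BL,0.019,0.001,0.034,0.002,96,36,17.70
opercular_expansion_length,BL,0.171,0.001,0.132,0.008,96,36,3.65
oral_sucker_area,BL2,0.007,0.00009617,0.005,0.001,96,36,9.58
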