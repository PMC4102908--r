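species,treatment,mean_height,se_mean_height,height_growth,se_height_growth,mean_biomass,se_mean_biomass,biomass_growth,se_biomass_growth
Mallotus microcarpus,liberated,180.00,9.51,0.31,0.01,121.41,12.00,0.35,0.03
Mallotus microcarpus,control,184.82,9.27,0.41,0.02,93.56,13.79,0.28,0.04
Mallotus paniculatus,liberated,121.00,1.58,0.19,0.01,56.26,4.46,0.25,0.02
Mallotus paniculatus,control,139.13,2.07,0.28,0.01,41.12,2.26,0.17,0.01
Macaranga denticulata,liberated,133.14,3.13,0.16,0.01,68.57,3.79,0.25,0.02
Macaranga denticulata,control,153.65,2.72,0.26,0.00,54.97,2.87,0.16,0.01
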