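species,height,se_height,biomass,se_biomass,leaf_area,se_leaf_area,frac15,frac45,frac75,crown_volume,se_crown_volume,lw_ratio,se_lw_ratio,lad,se_lad,N_o,se_N_o,pmax_slope,se_pmax_slope,R_d,se_R_d,quantum_yield,se_quantum_yield
Mallotus microcarpus,1.26,0.07,52.70,8.48,0.29,0.02,0.23,0.48,0.29,0.04,0.00,1.18,0.03,6.72,0.27,94.28,1.25,0.17,0.05,1.04,0.02,0.03,0.00
Mallotus paniculatus,0.94,0.01,12.22,0.56,0.06,0.00,0.13,0.41,0.46,0.01,0.00,2.00,0.03,4.94,0.15,79.33,0.84,0.10,0.05,0.24,0.01,0.03,0.00
Macaranga denticulata,1.07,0.03,27.22,1.17,0.11,0.00,0.37,0.40,0.24,0.03,0.00,1.42,0.02,4.35,0.15,82.52,0.72,0.18,0.06,0.53,0.01,0.04,0.00
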