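organism,strain,wavelength_nm,kf,kf_sd,r_squared
E. coli,environmental,255,1.202,0.065,0.955
E. coli,environmental,260,1.120,0.047,0.949
E. coli,environmental,265,1.624,0.056,0.926
E. coli,environmental,270,1.030,0.024,0.917
E. coli,environmental,280,0.959,0.053,0.992
E. faecium,environmental,255,1.019,0.002,0.939
E. faecium,environmental,260,1.126,0.001,0.954
E. faecium,environmental,265,1.136,0.015,0.951
E. faecium,environmental,270,1.111,0.026,0.957
E. faecium,environmental,280,1.109,0.012,0.965
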