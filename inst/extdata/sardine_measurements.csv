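compound,feed_ppm,flux_value,flux_unit
1-penten-3-ol,0.100,6.58e-7,mol_m2_s
1-octen-3-ol,0.008,3.91e-8,mol_m2_s
2-nonanone,0.001,1.89e-8,mol_m2_s
heptanal,0.006,2.80e-8,mol_m2_s
"(E,Z)-2,6-nonadienal",0.044,4.65e-7,mol_m2_s
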