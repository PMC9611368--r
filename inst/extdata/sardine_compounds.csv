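name,family,mw_g_mol,antoine_A,antoine_B,antoine_C,antoine_dialect,t_min_K,t_max_K,gamma_inf,odour_threshold_mg_L,off_flavour,source
water,water,18.015,8.07131,1730.63,233.426,log10_mmHg_C,274.15,373.15,1,,FALSE,"classic Antoine correlation fitted to steam-table data, 1-100 C"
1-penten-3-ol,alcohol,86.13,6.281380,2432.76,0,CC2,273,390,60,,FALSE,"CC2 two-point fit: nbp 114.5 C and 9.93 mmHg at 25 C (handbook); gamma_inf interpolated from measured C5-alcohol Henry-law data"
1-octen-3-ol,alcohol,128.21,6.305666,2817.02,0,CC2,273,450,10000,,FALSE,"CC2 two-point fit: nbp 174 C and 0.54 mmHg at 25 C (handbook); gamma_inf log-midpoint of Henry/solubility-derived range 3e3-2e4"
heptanal,aldehyde,114.19,5.451403,2319.59,0,CC2,273,428,3200,0.60,TRUE,"CC2 two-point fit: nbp 152.8 C and 3.52 mmHg at 25 C (handbook); gamma_inf from Henry-law constant ~2.7e-4 atm m3/mol"
"(E,E)-2,4-heptadienal",aldehyde,110.15,6.665211,2997.77,0,CC2,273,452,1500,,FALSE,"CC2 two-point fit: nbp ~177 C and 0.306 mmHg at 25 C (supplier data); gamma_inf homologue estimate"
"(E,Z)-2,6-nonadienal",aldehyde,138.21,8.158042,3693.62,0,CC2,273,455,14000,0.70,TRUE,"CC2 two-point fit: 10 mmHg at 95 C and 0.044 mmHg at 25 C (supplier data); gamma_inf log-midpoint of Kow/solubility-derived range"
2-nonanone,ketone,142.24,5.412697,2532.90,0,CC2,273,470,25000,,FALSE,"CC2 two-point fit: nbp 195.3 C and 0.62 mmHg at 25 C (handbook); gamma_inf from ketone-homologue Henry-law scaling"
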