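phenotype,A,B,C,D
age_years,0.583,0.147,-0.226,-0.583
bmi_kg_m2,-1.683,0.184,1.016,0.828
whr_m_m,-1.042,0.208,0.833,0.625
bsa_m2,-1.449,0.58,0.725,0.362
fasting_cpeptide_pmol_l,-1.567,-1.665,2.348,1.035
fasting_hba1c_mmol_mol,-0.563,-0.225,-0.447,2.811
fasting_glucose_mmol_l,-0.324,-1.139,-0.228,2.842
fasting_insulin_pmol_l,-1.499,-1.243,2.595,0.964
fasting_hdl_mmol_l,1.447,-2.325,-0.439,-0.658
fasting_ldl_mmol_l,0.903,-1.997,-0.122,0.33
fasting_tg_mmol_l,-0.563,-1.667,0.583,1.292
fasting_alt_u_l,-0.609,-1.245,0.748,1.182
fasting_ast_u_l,0.066,-1.481,0.356,1.201
fasting_cholesterol_mmol_l,1.062,-3.009,-0.088,0.457
fasting_creatinine_umol_l,0.409,-3.183,0.262,0.312
fasting_ucpcr_nmol_mmol,-0.525,-0.594,1.25,-0.208
fasting_ucpep_nmol_l,-0.726,-0.128,1.406,-0.091
fasting_ucreatinine_mmol_l,-0.488,0.446,0.522,0.168
mmtt120_glucose_mmol_l,-0.719,-2.164,-0.24,3.094
mmtt120_insulin_pmol_l,-1.088,-1.215,2.36,0.111
mean_glucose_mmol_l,-0.672,-2.645,-0.257,2.927
mean_insulin_pmol_l,-1.249,-1.131,2.885,-0.202
basal_isr_pmol_min_m2,-1.491,-1.708,2.351,1.044
total_insulin_secretion_nmol_m2,-0.946,-1.793,2.403,-0.326
glucose_sensitivity_pmol_min_m2_l_mmol,-0.117,-0.388,1.569,-1.49
rate_sensitivity_pmol_m2_l_mmol,-0.263,-0.546,0.957,-0.419
potentiation_ratio,1.023,-0.76,-0.351,-0.819
stumvoll_index,1.734,1.292,-1.993,-1.224
matsuda_index,1.795,3.235,-1.35,-1.078
ogis_2h_ml_min_m2,0.909,4.778,-1.23,-1.582
basal_insulin_clearance_l_min_m2,1.373,0.065,-0.915,-0.539
insulin_clearance_l_min_m2,2,0.167,-1.722,-0.389
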