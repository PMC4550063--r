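patient_id,age,sex,smoker,diabetes,hyperlipidaemia,ecg_abnormal,pain_constricting,pain_exertional,pain_relieved_by_rest_or_gtn,baseline_meds,group,site,cdss_used,investigations_6m,meds_6m
fx_01,42,male,0,0,0,0,0,0,0,,before,site_a,0,,
fx_02,50,male,1,0,0,0,1,0,0,statin,before,site_b,0,functional_imaging,statin
fx_03,58,male,0,1,0,0,0,1,0,antiplatelet;statin,before,site_a,0,,antiplatelet;statin
fx_04,67,male,1,0,1,0,1,1,0,,before,site_b,0,invasive_angiography,antiplatelet;beta_blocker;statin
fx_05,42,male,0,0,0,0,0,0,1,,before,site_a,0,,
fx_06,50,male,1,0,0,0,1,0,1,statin,before,site_b,0,functional_imaging,statin
fx_07,58,male,0,1,0,0,0,1,1,antiplatelet;statin,before,site_a,0,,antiplatelet;statin
fx_08,67,male,1,0,1,0,1,1,1,,before,site_b,0,invasive_angiography,antiplatelet;beta_blocker;statin
fx_09,42,female,0,0,0,0,0,0,0,,after,site_a,1,,
fx_10,50,female,1,0,0,0,1,0,0,statin,after,site_b,1,functional_imaging,statin
fx_11,58,female,0,1,0,0,0,1,0,antiplatelet;statin,after,site_a,1,,antiplatelet;statin
fx_12,67,female,1,0,1,0,1,1,0,,after,site_b,1,invasive_angiography,antiplatelet;beta_blocker;statin
fx_13,42,female,0,0,0,0,0,0,1,,after,site_a,1,,
fx_14,50,female,1,0,0,0,1,0,1,statin,after,site_b,1,functional_imaging,statin
fx_15,58,female,0,1,0,0,0,1,1,antiplatelet;statin,after,site_a,1,,antiplatelet;statin
fx_16,67,female,1,0,1,0,1,1,1,,after,site_b,1,invasive_angiography,antiplatelet;beta_blocker;statin
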