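# Printed clinical comparison values for cefuroxime; same schema as the
# cefazolin file. Scenario rows carry simulated values only (no clinical
# comparator exists for the obese pregnant cefuroxime scenarios). Study 092
# adipose samples are microdialysis unbound ISF concentrations; study 01
# total adipose is the documented out-of-two-fold case.
study_code,drug,dose_mg,quantity,matrix,time_min,observed,dispersion_type,dispersion_value,predicted,predicted_p5,predicted_p95,printed_ratio,known_failure,note
01,cefuroxime,1500,auc,plasma_total,NA,NA,NA,NA,150.99,NA,NA,NA,FALSE,
01,cefuroxime,1500,conc,plasma_total,10,130.8,NA,NA,91.04,69.23,114.79,0.70,FALSE,
01,cefuroxime,1500,cl,plasma_total,NA,NA,NA,NA,11.36,NA,NA,NA,FALSE,
02,cefuroxime,750,auc,plasma_total,NA,60.8,NA,NA,75.79,NA,NA,1.25,FALSE,
02,cefuroxime,750,conc,plasma_total,9.6,51.48,NA,NA,52.19,41.15,63.31,1.01,FALSE,
02,cefuroxime,750,cl,plasma_total,NA,11.9,NA,NA,12.14,NA,NA,1.02,FALSE,
03,cefuroxime,1500,auc,plasma_total,NA,124,NA,NA,153.89,NA,NA,1.24,FALSE,
03,cefuroxime,1500,conc,plasma_total,16.8,56.35,NA,NA,65.21,53.63,78.74,1.16,FALSE,
03,cefuroxime,1500,cl,plasma_total,NA,12.09,NA,NA,10.99,NA,NA,0.91,FALSE,observed CL from Dose/AUC identity
04,cefuroxime,750,auc,plasma_total,NA,77,NA,NA,78.03,NA,NA,1.01,FALSE,
04,cefuroxime,750,conc,plasma_total,20,75.29,NA,NA,58.61,45.73,73.63,0.78,FALSE,
04,cefuroxime,750,cl,plasma_total,NA,9.74,NA,NA,11.48,NA,NA,1.18,FALSE,observed CL from Dose/AUC identity
05,cefuroxime,1500,auc,plasma_total,NA,137,NA,NA,157.20,NA,NA,1.15,FALSE,
05,cefuroxime,1500,conc,plasma_total,18,82.08,NA,NA,110.83,86.74,138.67,1.35,FALSE,
05,cefuroxime,1500,cl,plasma_total,NA,10.9,NA,NA,11.48,NA,NA,1.05,FALSE,observed CL from Dose/AUC identity
06,cefuroxime,750,auc,plasma_total,NA,42.0,NA,NA,61.09,NA,NA,1.45,FALSE,
06,cefuroxime,750,conc,plasma_total,7.8,43.56,NA,NA,45.29,37.65,53.94,1.04,FALSE,
06,cefuroxime,750,cl,plasma_total,NA,16.9,NA,NA,11.98,NA,NA,0.71,FALSE,
07,cefuroxime,750,auc,plasma_total,NA,46.7,NA,NA,63.33,NA,NA,1.36,FALSE,
07,cefuroxime,750,conc,plasma_total,9,43.83,NA,NA,39.73,33.94,46.55,0.91,FALSE,
07,cefuroxime,750,cl,plasma_total,NA,15.5,NA,NA,11.57,NA,NA,0.75,FALSE,
09,cefuroxime,1500,auc,plasma_total,NA,NA,NA,NA,121.51,NA,NA,NA,FALSE,
09,cefuroxime,1500,conc,plasma_total,30,55.2,NA,NA,56.02,42.21,71.86,1.01,FALSE,
09,cefuroxime,1500,cl,plasma_total,NA,NA,NA,NA,11.92,NA,NA,NA,FALSE,
091,cefuroxime,1500,auc,plasma_total,NA,NA,NA,NA,123.86,NA,NA,NA,FALSE,
091,cefuroxime,1500,conc,plasma_total,48,74.8,NA,NA,45.51,31.75,57.04,0.61,FALSE,
091,cefuroxime,1500,cl,plasma_total,NA,NA,NA,NA,11.57,NA,NA,NA,FALSE,
092,cefuroxime,1500,auc,plasma_total,NA,158.7,NA,NA,130.76,NA,NA,0.82,FALSE,
092,cefuroxime,1500,conc,plasma_total,30,64.25,NA,NA,48.13,39.02,57.18,0.75,FALSE,
092,cefuroxime,1500,cl,plasma_total,NA,8.39,NA,NA,12.33,NA,NA,1.47,FALSE,
scenario1,cefuroxime,750,auc,plasma_total,NA,NA,NA,NA,60.98,NA,NA,NA,FALSE,
scenario1,cefuroxime,750,conc,plasma_total,NA,NA,NA,NA,37.75,30.74,45.99,NA,FALSE,
scenario1,cefuroxime,750,cl,plasma_total,NA,NA,NA,NA,11.98,NA,NA,NA,FALSE,
scenario2,cefuroxime,1500,auc,plasma_total,NA,NA,NA,NA,121.97,NA,NA,NA,FALSE,
scenario2,cefuroxime,1500,conc,plasma_total,NA,NA,NA,NA,75.51,61.48,91.97,NA,FALSE,
scenario2,cefuroxime,1500,cl,plasma_total,NA,NA,NA,NA,11.98,NA,NA,NA,FALSE,
scenario3,cefuroxime,750,auc,plasma_total,NA,NA,NA,NA,57.40,NA,NA,NA,FALSE,
scenario3,cefuroxime,750,conc,plasma_total,NA,NA,NA,NA,31.76,25.84,38.35,NA,FALSE,
scenario3,cefuroxime,750,cl,plasma_total,NA,NA,NA,NA,12.85,NA,NA,NA,FALSE,
scenario4,cefuroxime,1500,auc,plasma_total,NA,NA,NA,NA,114.79,NA,NA,NA,FALSE,
scenario4,cefuroxime,1500,conc,plasma_total,NA,NA,NA,NA,63.52,51.67,76.70,NA,FALSE,
scenario4,cefuroxime,1500,cl,plasma_total,NA,NA,NA,NA,12.85,NA,NA,NA,FALSE,
01,cefuroxime,1500,adipose_conc,adipose_total,10,16.5,NA,NA,6.55,3.38,10.48,0.40,TRUE,outside the two-fold criterion
02,cefuroxime,750,adipose_conc,adipose_total,NA,NA,NA,NA,4.24,2.44,6.83,NA,FALSE,
03,cefuroxime,1500,adipose_conc,adipose_total,NA,NA,NA,NA,5.53,3.51,7.93,NA,FALSE,
04,cefuroxime,750,adipose_conc,adipose_total,NA,NA,NA,NA,3.19,1.87,4.60,NA,FALSE,
05,cefuroxime,1500,adipose_conc,adipose_total,NA,NA,NA,NA,6.36,3.84,9.10,NA,FALSE,
06,cefuroxime,750,adipose_conc,adipose_total,NA,NA,NA,NA,3.15,2.25,4.49,NA,FALSE,
07,cefuroxime,750,adipose_conc,adipose_total,NA,NA,NA,NA,2.88,2.16,3.80,NA,FALSE,
08,cefuroxime,1500,adipose_conc,adipose_total,NA,NA,NA,NA,5.72,4.35,7.32,NA,FALSE,
09,cefuroxime,1500,adipose_conc,adipose_total,NA,NA,NA,NA,6.14,3.75,10.81,NA,FALSE,
091,cefuroxime,1500,adipose_conc,adipose_total,NA,NA,NA,NA,6.88,3.86,10.45,NA,FALSE,
092,cefuroxime,1500,adipose_conc,adipose_isf_unbound,NA,36.06,NA,NA,33.74,29.62,37.84,0.94,FALSE,microdialysis unbound ISF
scenario1,cefuroxime,750,adipose_conc,adipose_total,NA,NA,NA,NA,2.72,1.82,4.05,NA,FALSE,
scenario2,cefuroxime,1500,adipose_conc,adipose_total,NA,NA,NA,NA,5.43,3.64,8.10,NA,FALSE,
scenario3,cefuroxime,750,adipose_conc,adipose_total,NA,NA,NA,NA,2.22,1.68,2.88,NA,FALSE,
scenario4,cefuroxime,1500,adipose_conc,adipose_total,NA,NA,NA,NA,4.44,3.36,5.75,NA,FALSE,
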