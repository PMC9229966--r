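# Printed clinical comparison values for cefazolin: observed and simulated
# AUC (mg/L*h), serum concentration (ug/mL) at the reported time point
# (time_min NA = Cmax / first reported point), clearance (L/h) and adipose
# tissue concentration (ug/g), with the printed predicted/observed ratio.
# known_failure marks the rows documented as outside the two-fold criterion.
# The study 002 observed AUC is printed as derived from Dose/Clearance but
# is not equal to 1000/3.8; both printed numbers are stored unresolved.
study_code,drug,dose_mg,quantity,matrix,time_min,observed,dispersion_type,dispersion_value,predicted,predicted_p5,predicted_p95,printed_ratio,known_failure,note
001,cefazolin,500,auc,plasma_total,NA,110,NA,NA,130.27,NA,NA,1.18,FALSE,
001,cefazolin,500,conc,plasma_total,10.8,73.24,NA,NA,66.26,51.82,82.85,0.90,FALSE,
001,cefazolin,500,cl,plasma_total,NA,4.04,NA,NA,3.91,NA,NA,0.97,FALSE,
002,cefazolin,1000,auc,plasma_total,NA,236.15,NA,NA,262.60,NA,NA,1.11,FALSE,printed as Dose/Clearance but inconsistent with 1000/3.8
002,cefazolin,1000,conc,plasma_total,4.4,188.6,NA,NA,152.72,128.60,179.57,0.81,FALSE,
002,cefazolin,1000,cl,plasma_total,NA,3.8,NA,NA,4.01,NA,NA,1.06,FALSE,
003,cefazolin,500,auc,plasma_total,NA,75.7,NA,NA,84.37,NA,NA,1.11,FALSE,
003,cefazolin,500,conc,plasma_total,9,60.07,NA,NA,57.38,45.56,73.06,0.96,FALSE,
003,cefazolin,500,cl,plasma_total,NA,7.3,NA,NA,6.22,NA,NA,0.85,FALSE,
004,cefazolin,2000,auc,plasma_total,NA,NA,NA,NA,362.97,NA,NA,NA,FALSE,observed AUC not reported
004,cefazolin,2000,conc,plasma_total,82,57.2,NA,NA,95.74,60.07,135.05,1.67,FALSE,
004,cefazolin,2000,cl,plasma_total,NA,NA,NA,NA,5.76,NA,NA,NA,FALSE,
005,cefazolin,1000,auc,plasma_total,NA,139.27,NA,NA,172.24,NA,NA,1.24,FALSE,observed AUC from Dose/Clearance identity
005,cefazolin,1000,conc,plasma_total,NA,82.53,NA,NA,105.60,86.73,126.67,1.28,FALSE,
005,cefazolin,1000,cl,plasma_total,NA,7.18,NA,NA,5.99,NA,NA,0.83,FALSE,
006,cefazolin,2000,auc,plasma_total,NA,NA,NA,NA,415.86,NA,NA,NA,FALSE,
006,cefazolin,2000,conc,plasma_total,16,159.96,NA,NA,131.55,110.07,155.41,0.82,FALSE,
006,cefazolin,2000,cl,plasma_total,NA,NA,NA,NA,5.04,NA,NA,NA,FALSE,
007,cefazolin,2000,auc,plasma_total,NA,234.3,NA,NA,307.48,NA,NA,1.31,FALSE,
007,cefazolin,2000,conc,plasma_total,NA,146.15,NA,NA,163.31,133.85,203.67,1.12,FALSE,
007,cefazolin,2000,cl,plasma_total,NA,8.4,NA,NA,6.17,NA,NA,0.73,FALSE,
008,cefazolin,3000,auc,plasma_total,NA,453.4,NA,NA,446.82,NA,NA,0.99,FALSE,
008,cefazolin,3000,conc,plasma_total,NA,223.74,NA,NA,249.68,199.69,301.13,1.12,FALSE,
008,cefazolin,3000,cl,plasma_total,NA,6.6,NA,NA,6.35,NA,NA,0.96,FALSE,
009,cefazolin,2000,auc,plasma_total,NA,NA,NA,NA,316.33,NA,NA,NA,FALSE,
009,cefazolin,2000,conc,plasma_total,24.5,100.7,NA,NA,116.01,84.16,161.83,1.15,FALSE,
009,cefazolin,2000,cl,plasma_total,NA,NA,NA,NA,6.53,NA,NA,NA,FALSE,
0091,cefazolin,2000,auc,plasma_total,NA,NA,NA,NA,294.52,NA,NA,NA,FALSE,
0091,cefazolin,2000,conc,plasma_total,12,155.45,NA,NA,115.28,85.84,153.94,0.74,FALSE,
0091,cefazolin,2000,cl,plasma_total,NA,NA,NA,NA,7.04,NA,NA,NA,FALSE,
001,cefazolin,500,adipose_conc,adipose_total,NA,NA,NA,NA,4.52,3.12,6.29,NA,FALSE,
002,cefazolin,1000,adipose_conc,adipose_total,NA,NA,NA,NA,7.62,5.17,10.84,NA,FALSE,
003,cefazolin,500,adipose_conc,adipose_total,NA,NA,NA,NA,4.01,2.56,5.72,NA,FALSE,
004,cefazolin,2000,adipose_conc,adipose_total,31.5,8.7,iqr,5.7-11.2,14.21,10.90,18.55,1.63,FALSE,observed is a median
005,cefazolin,1000,adipose_conc,adipose_total,NA,NA,NA,NA,6.88,4.47,10.11,NA,FALSE,
006,cefazolin,2000,adipose_conc,adipose_total,16,8.78,NA,NA,9.18,7.33,10.91,1.05,FALSE,
007,cefazolin,2000,adipose_conc,adipose_total,25,12.4,NA,NA,9.85,7.30,13.86,0.79,FALSE,
008,cefazolin,3000,adipose_conc,adipose_total,28,16.8,NA,NA,14.39,10.78,19.59,0.86,FALSE,
009,cefazolin,2000,adipose_conc,adipose_total,24.5,9.4,NA,NA,10.08,7.67,13.79,1.07,FALSE,
0091,cefazolin,2000,adipose_conc,adipose_total,12,18.36,sd,6.68,8.89,6.16,12.05,0.48,TRUE,outside the two-fold criterion
0091,cefazolin,2000,adipose_conc,adipose_total,60,21.73,sd,16.02,6.85,4.95,9.01,0.32,TRUE,outside the two-fold criterion
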