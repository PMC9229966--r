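# Cefuroxime compound file. The single basolateral uptake intrinsic
# clearance is carried in the OAT1 slot (no OAT3 component: absent
# transporters are 0, so the gestational OAT3 fold has no effect here).
# Log P is the experimental shake-flask value.
name: cefuroxime
molecular_weight: 424.39
log_p: -1.5
compound_type: monoprotic_acid
acid_pka: 3.15
blood_to_plasma: 0.56
fu_plasma: 0.67
kp_scalar: 1.0
adipose_clpd: 0.1
kp_overrides:
  lung: 0.43
  muscle: 0.25
  skin: 0.53
  kidney: 0.36
renal:
  clint_oat1_uptake: 9.62
  clint_oat3_uptake: 0.0
  clint_mrp4_efflux: 10.0
  clpd_basal: 0.0
  clpd_apical: 0.0
  fu_kidney_cell: 1.0
  fu_urine: 1.0
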