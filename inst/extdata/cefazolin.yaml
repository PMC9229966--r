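# Cefazolin compound file: physicochemical and kinetic constants for the
# whole-body PBPK model. Units: molecular_weight g/mol; adipose_clpd L/h;
# renal clint_* uL/min/1e6 cells; renal clpd_* mL/min/1e6 cells.
name: cefazolin
molecular_weight: 454.5
log_p: -0.58
compound_type: monoprotic_acid
acid_pka: 3.6
blood_to_plasma: 0.55
fu_plasma: 0.225
kp_scalar: 1.0
adipose_clpd: 0.1
kp_overrides:
  lung: 0.2
  muscle: 0.03
  skin: 0.09
  kidney: 0.21
renal:
  clint_oat1_uptake: 0.208
  clint_oat3_uptake: 7.28
  clint_mrp4_efflux: 41.43
  clpd_basal: 2.07e-8
  clpd_apical: 2.07e-8
  fu_kidney_cell: 1.0
  fu_urine: 1.0
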