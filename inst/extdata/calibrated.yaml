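# Calibrated baseline configuration.  Identical to the package defaults
# (defaultConfig()); listed explicitly here for the record.  See the
# methods vignette for how every free rate was chosen.
parameters:
  P_pathway_oc: 0.26
  lambda_C: 0.4
  Se_G: 0.54
  DEG: 0.001
  lambda_d: 0.5
  Pe_d: 0.1
  U_d: 0.04
  D_mot: 0.08
  beta2_GC: 0.008
cycle:
  MM: {G0G1: 5, S: 4, G2: 2, M: 1, rest: 16}
  OB: {G0G1: 4, S: 3, G2: 2, M: 1, rest: 1}
  OC: {G0G1: 5, S: 4, G2: 2, M: 1, rest: 17}
dosing:
  BHQ880: {reference: 30}
  GC: {reference: 1.0e-3}
  LDM: {reference: 1.35e-7}
options:
  beta_binding: labels
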