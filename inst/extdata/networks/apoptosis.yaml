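# Reduced intrinsic-apoptosis network: Bcl2-buffered MOMP switch.
#
# During the equilibration phase an enforced survival signal (surv = 1)
# drives BCL2 transcription and no death stimulus is present.  The
# dynamic phase withdraws the survival signal (surv = 0) and switches on
# a constant death stimulus (stress = 1) that produces an activator BH3
# protein.  Bcl2 sequesters the activator; once the Bcl2 buffer is
# titrated, free activator triggers cooperative release of mitochondrial
# cytochrome c and Smac, caspase activation and irreversible PARP
# cleavage.  Death is scored at >10% cleaved PARP.
#
# Units: hours; abundances in arbitrary concentration units consistent
# within this network (total PARP = 10000).
name: apoptosis
species:
  - {name: BCL2t,  initial: 0}       # BCL2 mRNA
  - {name: Bcl2,   initial: 0}       # free Bcl2 protein
  - {name: Act,    initial: 0}       # activator BH3 protein (death signal)
  - {name: Bcl2Act, initial: 0}      # Bcl2:activator complex
  - {name: CytoCm, initial: 1000}    # mitochondrial cytochrome c
  - {name: cCytoC, initial: 0}       # cytoplasmic cytochrome c
  - {name: Smacm,  initial: 1000}    # mitochondrial Smac
  - {name: cSmac,  initial: 0}       # cytoplasmic Smac
  - {name: Casp3,  initial: 0}       # active effector caspase
  - {name: PARP,   initial: 10000}   # intact PARP
  - {name: cPARP,  initial: 0}       # cleaved PARP
parameters:
  - {name: tr_bcl2, value: 1}        # BCL2 transcription rate (mutation target)
  - {name: b0,      value: 0.4}      # basal transcription weight
  - {name: b1,      value: 5.0}      # survival-signal transcription weight
  - {name: d_mrna,  value: 0.5}
  - {name: k_tl,    value: 1.0}      # translation
  - {name: d_bcl2,  value: 0.08}
  - {name: s_act,   value: 3.0}      # activator synthesis under stress
  - {name: d_act,   value: 0.01}
  - {name: k_on,    value: 20}       # Bcl2-activator association
  - {name: k_off,   value: 0.01}
  - {name: d_cplx,  value: 0.08}
  - {name: k_momp,  value: 10}       # cooperative MOMP release
  - {name: K_momp,  value: 1.5}
  - {name: n_momp,  value: 4}
  - {name: k_leak,  value: 0.01}     # basal (sub-threshold) permeability
  - {name: k_casp,  value: 2.0e-3}   # caspase activation by cCytoC
  - {name: K_smac,  value: 200}      # Smac-mediated de-repression
  - {name: d_casp,  value: 0.2}
  - {name: k_cleave, value: 0.05}    # PARP cleavage by caspase
  - {name: surv,    value: 1}        # phase switch: enforced survival signal
  - {name: stress,  value: 0}        # phase switch: death stimulus
inputs:
  - {name: momp_rate, expr: "k_momp * hill(Act, K_momp, n_momp) + k_leak * Act^2"}
rates:
  - {expr: "tr_bcl2 * (b0 + b1 * surv)",            stoich: {BCL2t: 1}}
  - {expr: "d_mrna * BCL2t",                        stoich: {BCL2t: -1}}
  - {expr: "k_tl * BCL2t",                          stoich: {Bcl2: 1}}
  - {expr: "d_bcl2 * Bcl2",                         stoich: {Bcl2: -1}}
  - {expr: "s_act * stress",                        stoich: {Act: 1}}
  - {expr: "d_act * Act",                           stoich: {Act: -1}}
  - {expr: "k_on * Bcl2 * Act",                     stoich: {Bcl2: -1, Act: -1, Bcl2Act: 1}}
  - {expr: "k_off * Bcl2Act",                       stoich: {Bcl2Act: -1, Bcl2: 1, Act: 1}}
  - {expr: "d_cplx * Bcl2Act",                      stoich: {Bcl2Act: -1}}
  - {expr: "momp_rate * CytoCm",                    stoich: {CytoCm: -1, cCytoC: 1}}
  - {expr: "momp_rate * Smacm",                     stoich: {Smacm: -1, cSmac: 1}}
  - {expr: "k_casp * cCytoC * cSmac / (cSmac + K_smac)", stoich: {Casp3: 1}}
  - {expr: "d_casp * Casp3",                        stoich: {Casp3: -1}}
  - {expr: "k_cleave * Casp3 * PARP",               stoich: {PARP: -1, cPARP: 1}}
phases:
  equilibration: {surv: 1, stress: 0}
  dynamic:       {surv: 0, stress: 1}
heterogeneity: [s_act, k_tl, d_bcl2, d_mrna, k_casp, k_cleave, d_casp]
conserved:
  - [PARP, cPARP]
  - [CytoCm, cCytoC]
  - [Smacm, cSmac]
readouts: [cSmac, cCytoC]
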