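# Reduced mammalian cell-cycle network: a mass-coupled CycB/Cdh1
# relaxation oscillator (Cdc20/IEP mitotic-exit arm) gated in G1 by a
# starter-kinase module in which p27 is titrated by CycD and CycE.
#
# Myc raises CycD and CycE synthesis (transcriptional capacity saturates
# at a five-fold equivalent).  Free CycE activity above a sharp threshold
# licenses Cdh1 inactivation; cells whose CycE cannot reach the threshold
# arrest in G1 with elevated p27.  Cks1-dependent SCF flux degrades p27
# (the CKS1B dosage hook).  Division fires when Cdh1 rises back through
# 0.1 at mitotic exit, halving the cell mass.
#
# Units: hours; mass and abundances in arbitrary units.
name: cellcycle
species:
  - {name: mass,   initial: 1}
  - {name: CycB,   initial: 0.04}
  - {name: Cdh1,   initial: 0.95}
  - {name: Cdc20T, initial: 0.1}
  - {name: Cdc20A, initial: 0.05}
  - {name: IEP,    initial: 0.1}
  - {name: CycD,   initial: 1.5}
  - {name: CycE,   initial: 1.4}
  - {name: p27,    initial: 0.3}
  - {name: CycA,   initial: 0.1}
parameters:
  - {name: tr_myc,      value: 1}      # MYC expression fold (mutation target)
  - {name: myc_cap,     value: 5}      # saturation of the MYC dose effect
  - {name: cks1b_act,   value: 1}      # Cks1/SCF activity fold (mutation target)
  - {name: mu,          value: 0.0705} # mass growth rate
  - {name: mass_max,    value: 8}      # growth ceiling
  - {name: ks_cycb,     value: 0.4}
  - {name: kd_cycb,     value: 0.4}
  - {name: kd_cycb_cdh1, value: 10}
  - {name: kd_cycb_cdc20, value: 10}
  - {name: ka_cdh1,     value: 60}
  - {name: ka_cdh1_cdc20, value: 400}
  - {name: ki_cdh1_cycb, value: 100}
  - {name: ki_cdh1_g1,  value: 24}
  - {name: w_cycd,      value: 0.115}  # CycD weight in the G1 Cdh1-off drive
  - {name: w_sk,        value: 1}      # starter-kinase weight
  - {name: K_sk,        value: 0.985}  # starter-kinase licensing threshold
  - {name: h_sk,        value: 130}    # threshold sharpness
  - {name: J_a,         value: 0.04}
  - {name: J_i,         value: 0.04}
  - {name: ks_cdc20,    value: 0.05}
  - {name: ks_cdc20_mx, value: 2}
  - {name: J_mx,        value: 0.9}
  - {name: kd_cdc20,    value: 1}
  - {name: ka_cdc20,    value: 10}
  - {name: ki_cdc20,    value: 5}
  - {name: J_a20,       value: 1.0e-3}
  - {name: J_i20,       value: 1.0e-3}
  - {name: ka_iep,      value: 1}
  - {name: ki_iep,      value: 0.2}
  - {name: ks_cycd,     value: 0.15}
  - {name: kd_cycd,     value: 0.1}
  - {name: ks_cyce,     value: 0.14}
  - {name: kd_cyce,     value: 0.3}
  - {name: e0,          value: 1}
  - {name: e1,          value: 2.0}    # MYC -> CycE coupling
  - {name: ks_p27,      value: 0.10}
  - {name: kd_p27,      value: 0.08}
  - {name: kd_p27_skp,  value: 0.45}   # Cks1/SCF-dependent p27 turnover
  - {name: K_skp,       value: 0.5}
  - {name: Kd_cycd_p27, value: 0.02}
  - {name: Kd_cyce_p27, value: 0.02}
  - {name: ka_cyca,     value: 2.4}
  - {name: kd_cyca,     value: 0.05}
  - {name: kd_cyca_cdc20, value: 2}
  - {name: kd_cyca_cdh1, value: 4}
inputs:
  - {name: f_myc,     expr: "min(tr_myc, myc_cap)"}
  - {name: pd,        expr: "bound_pair(CycD, p27, Kd_cycd_p27)"}
  - {name: p27_rem,   expr: "p27 - pd"}
  - {name: sk,        expr: "CycE - bound_pair(CycE, p27_rem, Kd_cyce_p27)"}
  - {name: cycd_free, expr: "CycD - pd"}
  - {name: mx,        expr: "mass * CycB"}
  - {name: sk_lic,    expr: "hill(sk, K_sk, h_sk)"}
rates:
  - {expr: "mu * mass * (1 - mass / mass_max)",     stoich: {mass: 1}}
  - {expr: "ks_cycb",                               stoich: {CycB: 1}}
  - {expr: "(kd_cycb + kd_cycb_cdh1 * Cdh1 + kd_cycb_cdc20 * Cdc20A) * CycB",
     stoich: {CycB: -1}}
  - {expr: "(ka_cdh1 + ka_cdh1_cdc20 * Cdc20A) * (1 - Cdh1) / (J_a + 1 - Cdh1)",
     stoich: {Cdh1: 1}}
  - {expr: "(ki_cdh1_cycb * mx + ki_cdh1_g1 * mass * (w_cycd * cycd_free + w_sk * sk_lic)) * Cdh1 / (J_i + Cdh1)",
     stoich: {Cdh1: -1}}
  - {expr: "ks_cdc20 + ks_cdc20_mx * hill(mx, J_mx, 4)", stoich: {Cdc20T: 1}}
  - {expr: "kd_cdc20 * Cdc20T",                     stoich: {Cdc20T: -1}}
  - {expr: "ka_cdc20 * IEP * (Cdc20T - Cdc20A) / (J_a20 + Cdc20T - Cdc20A)",
     stoich: {Cdc20A: 1}}
  - {expr: "ki_cdc20 * Cdc20A / (J_i20 + Cdc20A)",  stoich: {Cdc20A: -1}}
  - {expr: "kd_cdc20 * Cdc20A",                     stoich: {Cdc20A: -1}}
  - {expr: "ka_iep * mx * (1 - IEP)",               stoich: {IEP: 1}}
  - {expr: "ki_iep * IEP",                          stoich: {IEP: -1}}
  - {expr: "ks_cycd * f_myc",                       stoich: {CycD: 1}}
  - {expr: "kd_cycd * CycD",                        stoich: {CycD: -1}}
  - {expr: "ks_cyce * (e0 + e1 * f_myc)",           stoich: {CycE: 1}}
  - {expr: "kd_cyce * CycE",                        stoich: {CycE: -1}}
  - {expr: "ks_p27",                                stoich: {p27: 1}}
  - {expr: "(kd_p27 + kd_p27_skp * cks1b_act * hill(sk, K_skp, 4)) * p27",
     stoich: {p27: -1}}
  - {expr: "ka_cyca * (1 - Cdh1)",                  stoich: {CycA: 1}}
  - {expr: "(kd_cyca + kd_cyca_cdc20 * Cdc20A + kd_cyca_cdh1 * Cdh1) * CycA",
     stoich: {CycA: -1}}
events:
  division:
    root: "Cdh1 - 0.1"
    direction: up
    mass: mass
    reset: {mass: "mass / 2"}
heterogeneity: [ks_cycd, ks_cyce, ks_p27]
readouts: [Cdh1]
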