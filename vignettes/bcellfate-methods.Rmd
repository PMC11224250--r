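---
title: "Methods: mechanistic B-cell fate models and patient stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mechanistic B-cell fate models and patient stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the modelling decisions behind `bcellfate`: the
reference networks, their parameterisation, the simulation protocols,
the numerical choices, and the limits of what the synthetic studies can
show.  It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Scope and design stance

The package implements a pipeline with four layers: (i) a generic
ODE engine for declaratively specified reaction networks; (ii) three
reference networks (isolated apoptosis, isolated cell cycle, and a
composite multi-scale B-cell model); (iii) a personalisation layer that
converts tumour sequencing calls into multiplicative parameter changes
and stratifies patients from simulated 6-hour readouts; and (iv) a
survival layer plus a synthetic-cohort generator so that every stage is
testable without clinical data.

Networks are configuration, not code.  A YAML file declares species
with initial abundances, nonnegative parameters, algebraic helper
expressions, rate terms with stoichiometries, named phases (parameter
overrides such as the enforced survival signal of the equilibration
phase), fate events (root expressions with reset rules), the
heterogeneity subset, and conserved totals.  The engine validates that
every symbol resolves, compiles the definition into fast derivative,
root and reset functions, and hands them to a stiff-capable solver
(`deSolve::lsoda`/`lsodar`).  A fuller published topology can therefore
be loaded as an alternative to the reduced reference networks without
touching any R code.  The reduced networks below are original
constructions calibrated to reproduce the qualitative and quantitative
behaviours that the modelling study reports; they are not the published
194-equation network, whose role the config system is designed to host.

## The apoptosis network

The reference apoptosis module is a Bcl2-buffered
mitochondrial-outer-membrane-permeabilisation (MOMP) switch.

* Equilibration phase: an enforced survival signal (`surv = 1`) drives
  BCL2 transcription (`tr_bcl2 * (b0 + b1)`), building a Bcl2 protein
  stock; no death stimulus is present, so the phase has a true steady
  state found by `run_to_steady_state()` (largest relative derivative
  below `1e-7`).
* Dynamic phase: the survival signal is withdrawn and a constant death
  stimulus produces an activator BH3 protein at rate `s_act`.  Bcl2
  binds the activator tightly (`k_on = 20`); free activator above
  `K_momp` triggers cooperative (Hill 4) release of mitochondrial
  cytochrome c and Smac; released cCytoC activates caspase, Smac
  de-represses it (Michaelian factor), and caspase cleaves PARP
  irreversibly.  A small quadratic leak term (`k_leak * Act^2`)
  represents sub-threshold permeability; it supplies the graded
  cytoplasmic Smac/cytochrome-c readouts used for patient
  stratification while remaining far too weak to move death times.

Death-time structure.  While the Bcl2 synthesis flux exceeds the
activator flux, free activator stays pinned near zero; death happens
when the cumulative activator production exhausts the equilibration
stock plus the ongoing synthesis.  Because the dynamic-phase Bcl2 flux
scales with the BCL2 transcription fold, there is a genuine bifurcation:
folds above `s_act` divided by the basal Bcl2 flux (about 3.75 at the
reference parameters) never die.  With one extra gene copy counted as a
1.5-fold transcription change, five extra copies (fold 3.5) still die
within the 140-hour window and six (fold 4.0) survive it — the
saturating gene-dose behaviour.  The stock and flux parameters (`b1 = 5`,
`b0 = 0.4`, `s_act = 3`) were chosen so that the heterogeneous-population
mean death time rises by ≈1.3-fold at a 1.5-fold BCL2 dose; this is the
one deliberate quantitative calibration in the module, made once against
the printed wild-type/1.5-fold behaviour.

## The cell-cycle network

The mitotic core is a mass-coupled CycB/Cdh1 relaxation oscillator in
the style of the classic two-variable antagonism with a Cdc20/IEP
mitotic-exit arm: Cdh1 degrades CycB in G1; rising mass·CycB activates
Cdc20, which destroys CycB and re-activates Cdh1; division is scored
when Cdh1 rises back through 0.1 (the published division-trigger
convention) and the mass halves.  Growth is logistic
(`mu = 0.0705 /h`, ceiling `mass_max = 8`), giving a stable ~12-hour
limit cycle whose mass-at-division settles to three decimal places —
the equilibration criterion is exactly that: mass at division identical
to three decimals for five consecutive cycles.

The G1 gate is the package's main structural choice.  Free CycE
("starter kinase") is computed by tight-binding titration: p27 binds
CycD first, the remainder binds CycE.  The licensing function is a very
sharp Hill (`h_sk = 130`) in free CycE: cells above the threshold
travel at a speed set by mass growth and the CycD-weighted drive; cells
below it cannot inactivate Cdh1 even at the mass ceiling and arrest in
G1.  Three consequences, each matching a reported behaviour:

* The Myc dose effect on cycling speed is carried by the smooth
  CycD-weighted drive (`w_cycd`), tuned once so a 1.5-fold MYC dose
  shortens the settled single-cell cycle by ~8 minutes; the period
  effect saturates at a 5-fold equivalent because transcriptional
  capacity is capped (`myc_cap = 5`).
* Arrest is controlled by the CycE synthesis distribution: with
  lognormal cv 0.25 multipliers on the synthesis rates
  (`ks_cycd`, `ks_cyce`, `ks_p27`), a minority of cells (~8% at the
  threshold `K_sk = 0.985`) fall below the gate.  Arrested cells
  accumulate p27 (its SCF/Cks1-dependent degradation requires starter
  kinase), reproducing the elevated-p27 signature of arrested cells,
  and keep growing toward the mass ceiling.
* Rescue: raising MYC 1.5-fold lifts CycE by one third and frees p27
  from CycD; most arrested cells cross the gate, and because they
  arrive with banked mass they divide within a few hours of induction —
  the most rapidly dividing cells in the population at that moment.

Phase markers are conventions (the source modelling work does not
define them): G1 ends when Cdh1 falls through 0.1, the S/G2 boundary is
CycA rising through 2.0, division closes G2/M.  G1 dominates the cycle
and absorbs essentially all of the MYC effect; the absolute S and G2/M
durations are short in this reduced network and are not treated as
quantitative claims.

Population protocol.  Heterogeneous cells start from the common
wild-type baseline state (just after a division on the reference limit
cycle) and run for a 60-hour horizon — five nominal cycles, the arrest
horizon.  Arrest = no division in the window.  Cycle duration = the
mean of the last three inter-division intervals (at least three
divisions required), which discards the transient of the common start.
The MYC condition is simulated from the same start with the same
multipliers (paired), mirroring a lesion arising in an equilibrated
cell; rescue is scored by re-simulating the arrested cells from their
end state with the MYC fold applied.

## The multi-scale model

The composite network couples six NF-κB/differentiation species, the
cell-cycle module and the apoptosis module (27 species).  NEMO:IKK
activity — basal during equilibration, a saturating pulse decaying with
a 12-hour half-life and clamped to basal from 72 h in the dynamic
phase — drives nuclear NF-κB, which multiplies the transcription of
BCL2, MYC, CYCD and IRF4 through normalised induction factors.  Myc
protein (normalised to its basal level) feeds the cell-cycle CycD/CycE
synthesis; IRF4 promotes and BCL6 represses Blimp1, and Blimp1
represses MYC — the minimal differentiation switch, whose only
quantitative role is that BCL6 overexpression de-represses MYC mildly
(hence MYC+BCL6 double hits grow far less than MYC+BCL2).  The death
stimulus intensity in this tissue context (`s_act = 1.9`) is lower than
in the isolated-network study, placing wild-type death at ~48 h so that
survival and proliferation lesions express their effects within a
96-hour window.

Fate events follow the published thresholds: apoptosis at cleaved
PARP > 2500 (25% of the pool), division at Cdh1 rising through 0.1.
Death takes precedence if both fire together.  Lineage accounting
collapses daughters into the mother simulation: after the k-th division
the single simulation stands for 2^k cells (2 after the first, 4 after
the second), implemented as an event log of +weight jumps; a death
removes the lineage's entire current weight, encoding the observation
that B-cell fates are reliably inherited across generations.  The
bookkeeping is verified in the tests against a brute-force simulator
that actually spawns both daughters, with exact agreement.

Equilibration of the composite model uses the limit-cycle protocol
(mass criterion), since the cycling subsystem never reaches a fixed
point; the equilibrated state (just after a division) seeds every
founder and every patient simulation.  Patient equilibrations warm-start
from the unmutated baseline state, which shortens them without changing
the settled cycle.

## Patient personalisation and stratification

Sequencing input is cBioPortal-style: a mutation table (sample, HUGO
symbol, SNV_GOF/SNV_LOF, oncogenicity flag) and a copy-number table
(gene- or arm-level, copy states −2…+2).  Only oncogenic-flagged SNVs
and mappable genes are used; arm events expand through an editable
arm-membership table (1q carries MCL1 and CKS1B).  Copy gains of either
depth count as one extra copy (the all-lesions-equal assumption);
losses as one lost copy.  The gene→parameter map ships as an editable
CSV with a direction column (the sense of a *gain*) and a
network-membership column used only by the presence control; NF-κB
upstream genes are annotated as feeding both networks.  Gains map to
×1.5, losses to ×0.5, mirrored by direction, combined multiplicatively
per parameter (in canonically sorted order, so any permutation of the
same lesions yields bitwise-identical parameters).

Each patient model is equilibrated and run for 12 simulated hours.
Readouts are taken at exactly 6 h by linear interpolation: Cdh1
(pro-proliferative) and cytoplasmic Smac and cytochrome c
(anti-apoptotic).  Six hours is early enough that no cell has divided
or died (the code asserts this rather than defining a carry-forward
rule) and late enough that the induction transients have passed; the
driver mRNAs are strongly rank-correlated between 6, 9 and 12 h.  In
`single_cell` mode all patients share identical base parameters, so the
pipeline is fully deterministic; `mean_of_100` mode averages the
readouts over heterogeneous cells drawn once per cohort seed (common
random numbers across patients).  Cohort z-scores implement
"above/below the mean": PP ⇔ z(Cdh1) < 0, AA ⇔ z(cSmac) < 0 AND
z(cCytoC) < 0 (the conjunctive reading), groups AAPP / AA_or_PP /
Other.  Patients with no mappable lesion are retained; an all-identical
cohort degenerates to all-Other with a warning.

## Survival layer and synthetic cohorts

Kaplan–Meier estimation, the k-group log-rank test and univariable Cox
regression wrap the `survival` package (Efron ties, appropriate for
month-resolution data); the test suite checks them against independent
hand-tabulation oracles.  The four-category combination with a clinical
flag is: good metric + neither AA nor PP; good + at least one; poor +
not AAPP; poor + AAPP.  P-values are reported raw with the conventional
star coding.

The synthetic generator plants structure the pipeline should recover:
per-gene Bernoulli lesions at DLBCL-like frequencies (configuration
values, not claims), a MYD88→CD79B co-occurrence boost, decoy genes the
pipeline must drop, an arm-level 1q gain, exponential survival with
per-group hazard multipliers (default 2.5 / 1.5 / 1 — the scale, not
the value, of reported hazard ratios), uniform censoring thinned to the
requested rate, and clinical covariates independent of the planted
group by default.  Exponential survival keeps the recovery oracle
analytic; a dependence knob exists for sensitivity studies.

## Numerical choices

* Default tolerances `rtol = 1e-6`, `atol = 1e-9` for plain
  integration; population studies use `rtol = 1e-6`, `atol = 1e-8`.
  Tightening both ten-fold changes the reported readouts by well under
  0.1% (asserted in the tests).
* Events are located by the solver's own root finder on the trigger
  expressions, not by grid sampling; output grids only control
  reporting density.
* Negative abundances are not clipped during integration (rate laws
  are constructed to keep states nonnegative); only sub-tolerance
  negative excursions are zeroed in reported traces.
* The engine compiles each network once; parameters are swapped by
  reassignment into the compiled environment.  State arguments are
  forced before parameters are pushed, and parameters are re-pushed
  before every solver segment, so nested integrations of the same
  network object cannot interleave stale values.
* Problem sizes: the acceptance script uses 1000 heterogeneous cells
  for both the apoptosis and the cell-cycle populations; the test suite
  and the analysis drivers use 120–200 cells and 8–16 founders, sizes
  at which every qualitative assertion is stable under the fixed seeds.

## Known limitations

* The reduced networks reproduce the described couplings and readouts,
  not the literal published parameter set; absolute abundances are in
  arbitrary units and thresholds are meaningful only within a network.
* S and G2/M are compressed in the reduced cell-cycle model; phase
  claims beyond "G1 dominates and absorbs the MYC effect" should not be
  read quantitatively.
* Cohort stratification is relative (z-scores), so a patient's label
  depends on cohort composition — intended, but it means single-patient
  classification is undefined.
* The synthetic cohorts emulate lesion frequencies, co-occurrence and
  group-dependent hazards; they do not emulate mutational signatures,
  subclonality, panel-specific coverage, or covariate-outcome
  confounding, so passing the recovery tests shows pipeline
  correctness, not clinical validity.
* The heterogeneity model (independent lognormal multipliers on
  synthesis rates) is the standard distributed-parameter picture; its
  cv is a configuration knob and correlated extrinsic noise is not
  modelled.
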