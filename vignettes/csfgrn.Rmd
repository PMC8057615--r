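---
title: "Modelling the CSF1R-centered pro-inflammatory GRN: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the CSF1R-centered pro-inflammatory GRN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific and numerical choices behind
`csfgrn`: what the model is, how its parameters were calibrated, what the
synthetic-data generator emulates, and where the design was genuinely open.

## The system

Microglial cells mount a pro-inflammatory response to lipopolysaccharide
(LPS) that is organised around the colony stimulating factor 1 receptor
(CSF1R).  The network modelled here couples 11 components — CSF1 (ligand),
STAT1, STAT3, IRF8, PU.1, NFκB, C/EBPα (transcription factors), and IL6R,
TNFR1, CSF1R, CSF3R (receptors) — through 42 experimentally documented
regulations, 31 transcriptional and 11 post-translational, with exactly two
inhibitory links (IRF8 ⊣ STAT1 and LPS ⊣ C/EBPα).  Two of the regulations
summarise indirect routes (NFκB→STAT1 via IRF7; STAT1→STAT3 activation via
the LIF/OSM receptors); they are encoded as single direct edges with the
net sign because the intermediates are not model variables.  LPS is an
external dimensionless input, not a network component; 1 corresponds to
the experimental dose.

## Model structure and assumptions

* **State.** One mRNA variable per component (β-actin-relative units) plus
  inactive/active protein pools for the five post-translationally regulated
  components (STAT1, STAT3, NFκB, C/EBPα, CSF1R): 21 variables in total.
* **Transcription.** Basal synthesis plus additive saturating Hill terms
  for activating edges, times multiplicative Hill inhibition factors;
  first-order mRNA decay.  Saturating/Hill kinetics (rather than mass
  action) are required for the bistability the system exhibits.
* **Protein pools.** Synthesis proportional to mRNA, first-order decay of
  both forms, and activation/inactivation fluxes between the inactive and
  active form; the post-translational regulations enter only these fluxes.
  The active form is the transcriptionally competent species.
* **Protein proxy.** Components without an explicit protein pair act on
  their targets through 3000 × mRNA, using the genome-wide mean
  protein/mRNA ratio of ≈3000.  CSF1→CSF1R activation uses this proxy for
  CSF1 on CSF1R's inactive→active flux.
* **Inputs.** LPS activates STAT1 protein (linearly in the activation
  flux), activates NFκB transcription and represses C/EBPα transcription.
  Knockdown/overexpression is a multiplicative scale on a component's mRNA
  synthesis.

## Calibration of the default parameters

No complete kinetic parameterisation of this network is available as
machine-readable data, so the packaged defaults are the package's own
calibration.  The procedure had two stages:

1. **Analytic basal design.**  Basal mRNA targets on the β-actin-relative
   scale and per-edge basal occupancies were chosen, and rate constants
   were solved so that the basal state is an exact equilibrium.  mRNA
   degradation rates come from assumed half-lives, anchored by the two
   measured values (Irf8 4.1 h, Csf1 5.2 h — the two shortest in the
   network); protein half-lives are of order 10 h with synthesis set so
   total protein ≈ 3000 × mRNA.
2. **Behaviour-driven refinement.**  Individual rates and thresholds were
   then adjusted until the model reproduces the documented phenotypes:
   the qualitative LPS response classes (fast Stat1/Stat3 rise, delayed
   Csf1/Irf8/Tnfr1 rise, transient Nfkb rise, transient Il6r/Cebpa dip);
   irreversible bistability (stable basal and activated states at LPS = 0,
   a single activated state at LPS = 1, the activated branch persisting to
   LPS = 0); the washout behaviour (Irf8/Csf1 within 20% of the
   LPS-maintained arm 12 h after removal); the influence ranking (Stat1,
   Stat3, Cebpa strongest; Irf8, Csf1r among the weakest); and the
   knockdown phenotypes (50% Stat1 inhibition lowers all other components
   and preserves the bistability; 50% Irf8 inhibition changes nothing by
   more than 10%).

The resulting bifurcation structure: the basal branch ends in a saddle-node
at LPS ≈ 0.07; the activated branch is fold-free for LPS ≥ 0; continuing to
negative LPS (non-physical, used only inside continuation) the middle and
upper branches connect in a saddle-node at LPS ≈ −0.21.  To make that
continuation possible the linear LPS term in the STAT1 activation flux is
deliberately not clamped at zero.

Design choices that were genuinely open, and how they were resolved:

* Components without an active form get no protein ODEs — their regulatory
  activity is the 3000 × mRNA proxy.
* Hill exponents are small integers (1–6); the switch-forming edges
  (STAT1 auto-activation, STAT3→C/EBPα) use n = 4 with thresholds well
  above basal activity, which gives a deep basal basin together with a
  strongly separated activated state.
* Knockdown emulates siRNA by scaling mRNA synthesis (not degradation),
  with the scale found by bisection so the target settles at the stated
  residual fraction at the observation horizon — only the achieved percent
  inhibition is specified by the experiments being emulated.
* The influence statistic of the expression screen is the maximum absolute
  log2 ratio across readouts at 48 h over both fold directions (the
  reference experiments show per-readout bars without a summary
  statistic); folds default to 10 and 1/10 from the stated 5–10-fold
  range.
* The washout persistence criterion is a < 20% relative difference between
  arms ("did not differ statistically" in the emulated experiment).
* "Low" population initial condition = the basal state; "high" = the
  activated state of the unperturbed model; the bimodality threshold is
  the unperturbed unstable-state readout at that LPS, falling back to the
  midpoint of the stable states when no unstable state is found.
* Two measured LPS time-course figures disagree on the dose unit
  (1 μg/ml vs 1 μM); the model treats LPS as dimensionless with 1 ≡ the
  experimental dose, so the discrepancy is recorded, not resolved.

## Numerics

* **Integration.** lsoda (stiff-capable) with rtol 1e−8 / atol 1e−10 for
  simulations; protocol segment boundaries are exact restarts, never
  interpolated across.  Population ensembles and fitting use rtol 1e−6 /
  atol 1e−8 — halving tolerances changes 48 h readouts by far less than
  0.1%.  The right-hand side is evaluated in C from a flat packed
  description of the network, so a 48 h trajectory costs a few
  milliseconds.
* **Steady states.** Damped Newton with a central finite-difference
  Jacobian (step scaled to state magnitude); convergence when the
  magnitude-scaled residual max |f_i|/(1+|x_i|) < 1e−9; duplicate roots
  merged below 1e−4 relative distance; stability from Jacobian
  eigenvalues.  Numeric differentiation was preferred to hand-derived
  Jacobians to avoid derivation errors.
* **Continuation.** Pseudo-arclength with adaptive step (1e−6–0.05 in
  weighted arclength), tangent from the bordered Jacobian system, folds
  detected as sign changes of the LPS tangent component and located by
  interpolation.  Multi-start initial conditions are uniform in [0, 20]
  per variable, plus the basal and activated presets.
* **Fitting.** Levenberg–Marquardt (minpack.lm) on weighted residuals over
  log-parameters (rates are positive and span decades), with box bounds
  and random log-uniform restarts.  Weighting options: none, 1/sd², or
  1/mean² (relative error).  Identifiability is assessed by parameter
  recovery on synthetic data; weakly identifiable directions (e.g. the
  basal STAT1 synthesis rate under an LPS-step design) are reported by the
  recovery benchmark rather than hidden — the shipped recovery benchmark
  uses a five-parameter set (kdm_STAT1, ka_r1, kdm_IRF8, Ki_r15,
  kdm_CSF1) fitted to a combined basal + LPS-step design, mirroring the
  plus/minus-stimulus structure of the experiments this pipeline
  emulates; recovery experiments showed the set to be well identified
  from that design.

## The synthetic-data generator

`generate_qpcr()` emulates the statistical structure of qPCR time-course
experiments: a protocol preset (basal, LPS step, washout, or calibrated
knockdown), a sampling grid dense early and sparse late over 0–48 h, four
replicates per point, and multiplicative lognormal noise with cv 0.2 by
default (qPCR ratios are positive and approximately log-normal; the
generator is mean-unbiased).  β-actin is treated as an exact invariant
reference; Ct-level artefacts (amplification efficiency, plate effects)
are out of scope.  Every dataset ships with a truth record (true
parameters, noiseless trajectories), which is what makes the
parameter-recovery benchmark possible.  Passing tests on these data shows
the pipeline is self-consistent under the stated noise model — it does not
show that real measurements satisfy that model (real qPCR has
reference-gene noise, batch structure and occasional dropouts that are not
emulated).

## Problem sizes used in the shipped analyses

Population ensembles use 500 cells at 10/20/40% uniform variation with a
200 h settling dwell (steady-state scans) or a 48 h stimulation horizon
(time courses).  The continuation-vs-multistart agreement check samples 50
branch points and uses 6 random Newton starts plus the two presets per
LPS value.  The recovery benchmark runs 5 noise seeds with one random
restart each.

## Known limitations

* The parameters are a calibration to documented qualitative behaviour,
  not direct kinetic measurements; absolute concentrations and fold
  positions should be read as illustrative, and quantities reported by the
  acceptance script are properties of this calibration.
* Protein expression levels and activation states are modelled, not
  measured; the 3000× proxy is a genome-wide average applied uniformly.
* Only extrinsic (parameter) heterogeneity is modelled; there is no
  intrinsic molecular noise, cell division, or spatial coupling.
* The network structure is taken as given; components outside the 11-node
  scope that may quantitatively influence the real system are absent.
* Negative-LPS branches are a continuation device with no physical
  meaning.
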