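---
title: "A titration model of HSPA1A regulation in early- and late-passage hMSCs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A titration model of HSPA1A regulation in early- and late-passage hMSCs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(senhsr)
```

## The model

The heat-shock response of human mesenchymal stem cells (hMSCs) is modelled
as a delay differential-equation system over four interacting populations:
the stress-inducible chaperone HSPA1A (HSP70), the transcription factor
HSF1, the E3 ubiquitin ligase CHIP (STUB1), and a lumped misfolded-protein
pool (MFP). Five state variables are tracked: free HSPA1A `H`, the
HSPA1A.HSF1 complex `HF` (the inactive-HSF1 reservoir), free/active HSF1
`F`, misfolded protein `M`, and the CHIP pool `C`. Concentrations are
dimensionless, normalised so the prestress equilibrium has `H = 1`; time is
in minutes.

Seven processes define the rate laws:

1. **Misfolding**: MFP is generated at rate `k1`, multiplied by the stress
   factor `s` while the stress window is active.
2. **Refolding**: chaperone-catalysed refolding removes MFP at `k2·H·M`
   (H acts catalytically and is returned to the pool).
3. **Delayed synthesis**: HSPA1A is produced at `k·F(t−τ)/(Kd + F(t−τ))`, a
   saturating function of the active HSF1 level `τ` minutes earlier. The
   delay lumps transcription, export and translation; its default (180 min)
   reflects the observed ~3-h gap between transcript and protein peaks.
4. **MFP degradation**: CHIP-mediated turnover removes MFP at
   `k4·C·φ·M`.
5. **HSPA1A degradation**: CHIP-mediated turnover removes HSPA1A at
   `k5·C·(1−φ)·H`.
6. **HSF1 inactivation**: free HSPA1A sequesters active HSF1, `k6·H·F`.
7. **HSF1 release (titration)**: MFP competes HSPA1A off the complex,
   `k7·M·HF`, returning both an active HSF1 and a free chaperone.

Here `φ = a_chip·M/(a_chip·M + H)` is the fraction of CHIP activity
directed at misfolded clients, a quasi-steady-state competition with
affinity bias `a_chip > 1` for misfolded protein. This one-parameter
partition realises the key regulatory observation the model encodes: while
MFP is abundant, chaperone turnover is suppressed (the chaperone pool is
spared); once MFP is cleared but chaperone levels are still elevated,
turnover accelerates and restores the baseline. HSF1 is conserved
(`F + HF = F_tot`) exactly, by construction of the rate laws.

Design choices worth stating explicitly:

* Refolding treats `H` as a catalyst rather than forming an explicit
  H·M complex, keeping the four stated populations; the fitted `k2`
  absorbs the difference.
* The CHIP partition is quasi-steady-state (`φ`) rather than explicit
  CHIP·client complexes.
* Synthesis uses the simplest saturating (first-order Hill) form
  consistent with a maximal rate `k` and half-saturation `Kd`.
* The stress multiplier `s` acts on the misfolding rate `k1` only; it does
  not convert already-folded protein mass. This is the simpler of the two
  readings of "increasing the rate at which misfolded proteins were
  generated", and it keeps the prestress equilibrium independent of `s`.
* No HSF1 trimerisation/phosphorylation sub-states and no
  nuclear/cytoplasmic compartments are modelled.

## Numerical scheme

The delay system is integrated by a fixed-step RK4 method of steps
(compiled): the delayed `F` value is read from the stored solution history,
with cubic Hermite interpolation at off-node stage times, and the step is
chosen to divide the delay exactly. History before the start of a run is
the constant equilibrium state. An independent route through
`deSolve::dede()` (adaptive, with its own history interpolation) is kept in
the package and the test suite asserts agreement of the two integrators to
1e-4 relative on `H` over the full protocol. The default step is `h = 0.01` min — the stress phase is stiff (the
misfolded pool transiently dwarfs the chaperone pool, making the HSF1
release flux fast), and an explicit scheme needs a step well inside the
stability bound — with `h = 0.5` min sufficient inside the fitting loop
for moderate-stress scenarios.

**Equilibration.** The prestress state is found the way the experimental
ratio is imposed: CHIP relaxes towards `H / r_HC` (the measured
HSPA1A:CHIP abundance ratio) while the system is integrated to a stable
steady state, then a damped Newton iteration on the reduced steady-state
system polishes the root to machine precision. Stability is checked via
the eigenvalues of a numerically differenced Jacobian. After
equilibration, CHIP is frozen for the stress protocol.

**Stress protocol.** The standard in-silico experiment mirrors the in
vitro one: a 120-min stress (the 2-h 42 °C heat shock) followed by a 24-h
recovery, with the misfolding rate multiplied by `s` during the window.

## The calibrated baseline parameter set

No reference table of the fixed parameters or baseline fitted values is
available, so the package reconstructs them by calibrating once against
the quantitative behaviours the model is known to reproduce, in this
order of priority:

1. HSPA1A half-life of **100 min** after synthesis switch-off (`k5` is
   bisected to this target; the literature comparator is 99 min).
2. A period of proteotoxic stress of **10.3 h** for the early-passage
   (EP) model under the standard protocol (`s` is bisected to this
   target; `s` is a pure calibration constant with no independent
   measurement).
3. An LP/EP misfolded-protein AUC ratio of **~1.30** and the qualitative
   response shape: HSPA1A peaking a few hours into recovery, active HSF1
   plateauing within the stress window, dipping below baseline during
   recovery and then returning, and a weaker HSPA1A response in the
   senescent model.

The remaining structural constants were chosen once, inside those
constraints: total HSF1 `F_tot` is small relative to the chaperone pool
(HSF1 is a transcription factor, orders of magnitude less abundant than
HSP70), the prestress misfolded fraction `M_eq` is a few percent of `H`,
the HSPA1A:CHIP ratio `r_HC = 5`, and `a_chip` keeps CHIP's misfolded-client
bias strong but finite. Calibration searched the remaining rate constants
by Nelder-Mead on exactly these targets; the resulting defaults are stored
as the package's baseline parameter set (`hsr_params()`).

Two honest caveats from this reconstruction:

* Reproducing the suppressed senescent peak requires the misfolded pool to
  overshoot the chaperone pool by a large factor during stress, so the
  calibrated `s` is numerically large. Only the product `k1·s` (the stress
  misfolding flux) is mechanistically meaningful; `k1` itself is tiny in
  these normalised units.
* With every reported behaviour weighted, the calibrated model
  reproduces the EP stress period (10.30 h) and a ~25% LP/EP increase in
  misfolded-protein AUC, but the absolute LP stress period saturates
  near 11.1 h rather than the 12.7 h reference value. The cause is structural:
  the senescent model keeps HSPA1A elevated for longer (less CHIP), and
  the elevated chaperone accelerates late refolding-mediated clearance
  of misfolded protein, partially cancelling the slow-down from CHIP
  loss. The *direction* of the prediction — longer stress period and
  larger misfolded-protein burden in senescence — is robust across
  stress magnitudes and is what the test suite asserts as an invariant.

```{r model}
model <- hsr_model()
model
half_life(model)
```

```{r trajectory, fig.height = 4}
tr <- simulate(model, protocol = stress_protocol())
plot(tr)
```

## Senescence perturbation

The senescent (late-passage, LP) model applies the two measured
alterations to the fitted EP model: prestress CHIP is multiplied by
`2^-0.7799 = 0.5824` (immunofluorescence quantification of CHIP loss) and
the maximal synthesis rate `k` by `2^-0.4873 = 0.7134` (the mean log2
fold-change of 77 detected ribosomal proteins, a proxy for translational
capacity). CHIP is held at its scaled value — it is not re-titrated — and
the other species are re-relaxed to the LP model's own prestress steady
state before stress. Burden metrics (`mfp_burden()`) are computed per
condition against that condition's own baseline: the period of proteotoxic
stress is the time until MFP re-enters a `tol_fraction` band above its
prestress equilibrium (default 5%; no operational threshold is defined
by the source data, so this is a declared, configurable convention), and the MFP
burden is the trapezoidal area under the excursion above baseline.

```{r senescence}
res <- senescence_burden(model)
res$EP
res$LP
res$ratio
```

## Fitting

`hsr_fit()` optimises the six free parameters (`k`, `Kd`, `k2`, `k4`,
`k5`, `k7`) in log space — positivity for free, and the coarse stage
mirrors the order-of-magnitude structure of the original search — against
a relative HSPA1A time course. Every candidate is re-equilibrated so its
own prestress level is the normalisation (prestress `H = 1` is enforced
per candidate, never inherited), then scored by mean squared error against
the replicate-mean data; replicates are averaged before scoring because
the fitted data are mean immunofluorescence intensities. The local stage
is Nelder-Mead, chosen because re-equilibration makes finite-difference
gradients noisy; the mean-squared-error objective is this package's
choice.

Identifiability deserves emphasis: a single relative HSPA1A curve does
not determine six parameters. Near-exact compensations exist — scaling
`k7` and `Kd` together leaves the synthesis term almost unchanged; `k`
and `k5` trade off through the unobservable absolute equilibrium level;
the `k2`/`k4` split of misfolded-protein clearance is only weakly
curved — so joint six-parameter recovery from noisy data fails even at
generous tolerances, while the noiseless self-fit returns the truth
exactly and identifiable subsets (e.g. `free = c("k", "k2", "k5")`)
are recovered well within ±50%. Locally flat directions are detected
and reported on the fit object rather than hidden. Any point-estimate fit of this model shares the property; fitted values
should be read as one member of a plausible set, not a unique solution.

`hsf1_transcript_scale()` relates modelled active HSF1 to measured
transcript levels by the closed-form least-squares scalar
`α = Σ(F·mRNA)/Σ(F²)`, with its R².

## Synthetic data

The generators produce every input the pipeline consumes, with the
statistical structure the analyses assume — they emulate the *shape* of
the measured data, not its biology:

* **Time courses** (`synth_timecourse()`): baseline 1, a smooth
  gamma-shaped rise beginning during the 2-h stress, peak 4 h into
  recovery, exponential-like return; the LP variant is delayed by ~1 h
  with amplitude 63% of EP. Replicate noise is multiplicative lognormal
  (intensities are positive; the coefficient of variation is the natural
  noise scale for immunofluorescence). The default peak fold (2.0) is a
  typical induction for HSPA1A immunofluorescence (no reference value is
  available).
* **Fold-change tables** (`synth_foldchange_table()`): per-module true
  effects with additive Gaussian replicate noise (log2 fold-changes are
  signed and approximately normal), including a 77-protein "ribosome"
  subset whose default planted mean is −0.4873.
* **PPI graphs** (`synth_ppi_graph()`): planted partitions (5 blocks of
  30 by default, `p_in = 0.6`, `p_out = 0.02`) with weights uniform in
  the 0.90–1.00 high-confidence band.

What passing tests on these fixtures do *not* show: recovery of real
chaperome communities (real PPI graphs are heavier-tailed and noisier than
planted partitions), robustness to missing values or batch effects in real
proteomics tables, or correctness of the peak-fold assumption for real
IF data.

## Network and statistics conventions

* Community detection is weighted Louvain modularity maximisation at
  resolution 1.0 under a fixed seed. Community counts on real chaperome
  graphs depend on the interaction-database version and the modularity
  method's resolution, so the count is reported but never asserted. The highest-confidence
  band is taken as combined score ≥ 0.9.
* `module_response_test()` uses per-donor module means as the
  observational unit (replication is at the donor level, and per-protein units
  would pseudo-replicate); with a single tested group this is the
  one-sample t/F test, and its type-I error is verified by simulation.
* `subset_shift_test()` fits Gaussians by moment matching — the fitted
  maximum is the sample mean, with no binning artefacts — and tests by
  two-tailed Welch t test.
* `tagged_peptide_shift()` reports the Wilcoxon signed-rank test
  (zero-exclusion rule) as primary and the paired t test alongside,
  because the source figure caption and body text disagree on which was
  used.
* `recovery_time()` is the first post-stress time at which per-timepoint
  ANOVA versus the pooled prestress baseline stops rejecting (and stays
  non-rejecting), uncorrected across time points, mirroring per-timepoint
  testing; it right-censors at the last sampled time.

## Problem sizes and tolerances

Default integration tolerances: fixed step 0.1 min (0.5 min in fitting);
equilibration residual < 1e-9 with the CHIP-titration constraint enforced
to the same tolerance. The test suite runs the full stress protocol at
1-min output resolution, parameter recovery on 10 noisy synthetic
datasets, a 20-seed planted-partition benchmark (150 nodes each), and
1,000 null simulations for the type-I calibration; these sizes keep the
suite comfortably reproducible on a single CPU while leaving the
statistical assertions well-powered.

## Known limitations

* The model is deliberately minimal: no acquired thermotolerance, no
  repeated-stress protocols, no compartments, no explicit proteasome or
  autophagy arms (the source data showed no proteasomal loss in
  senescence).
* The parameter set is a calibrated reconstruction, not an independently
  measured one; absolute magnitudes of `s`, `k1` and the MFP excursion should be
  read as normalised quantities.
* Fitting six parameters to one observable is under-determined; the fit
  is a point estimate with flat directions flagged, not an uncertainty
  quantification.
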