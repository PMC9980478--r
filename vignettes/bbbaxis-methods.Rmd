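---
title: "Quantifying blood-brain-barrier integrity: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying blood-brain-barrier integrity: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bbbaxis)
```

# Scope

`bbbaxis` implements the quantitative machinery of a maternal-immune-activation
(MIA) study design in neonatal mice: MRI-based measurement of brain volume,
vessel volume and blood-brain-barrier (BBB) permeability, and curation plus
compartment analysis of untargeted LC-MS metabolomics from paired serum and
brain samples of four treatment groups (SPF control, LPS, *L. reuteri*,
LPS/*L. reuteri*). Because studies of this kind rarely deposit raw MRI or
metabolomics data, the package ships a synthetic-data module that generates
phantoms and feature tables with known ground truth, so every downstream
stage is testable end to end by parameter recovery.

# T1 relaxometry

## Model

A variable-repetition-time (VTR) saturation-recovery acquisition samples the
longitudinal recovery curve. Per voxel, the signal at repetition time $TR$ is

$$S(TR) = P_0\,\bigl(1 - e^{-TR/T_1}\bigr),$$

where $P_0$ is the equilibrium signal (proportional to proton density) and
$T_1$ the longitudinal relaxation time in seconds. `fit_t1_voxel()` solves
the two-parameter nonlinear least-squares problem per voxel with a bounded
Levenberg-Marquardt optimizer (`minpack.lm::nls.lm`). The default TR
schedule of the phantom generator is the nine-point protocol
0.281, 0.35, 0.5, 1, 1.5, 2, 3, 5, 10 s.

Numerical choices:

* **Initialization.** $P_0$ starts at the maximum observed signal. The $T_1$
  start is data-driven: the first TR at which the signal reaches 63.2% of
  the maximum (the $1 - e^{-1}$ point of the recovery), with the median TR
  as a second start; the lowest-SSE solution is kept. A single median-TR
  start can collapse to the lower bound for short $T_1$, which is why the
  multi-start exists.
* **Bounds and validity.** $T_1$ is constrained to $[1\,\mathrm{ms},
  20\,\mathrm{s}]$. A fit is invalid when the signal is non-positive or
  constant, the optimizer fails, $T_1$ lands on a bound, or the residual
  RMSE exceeds a configurable ceiling (disabled by default). Invalid voxels
  are excluded from every downstream mean.
* **Degenerate input.** All-zero or constant signal vectors return
  `valid = FALSE` rather than an error; fewer than three TR points or a
  non-increasing schedule are errors (the fit is under-determined).

## Achievable precision

With Gaussian noise of standard deviation $\sigma = P_0 / \mathrm{SNR}$
(SNR defined against the equilibrium signal), the Cramér-Rao bound for the
nine-point schedule gives a per-voxel relative $T_1$ standard error of about
$2/\mathrm{SNR}$ ($\approx$ 4% of $T_1$ at SNR 50 for $T_1$ between 0.8 and
2.2 s), i.e. a median absolute relative error of roughly 2.5-3% for an
unbiased, efficient estimator. The test suite asserts that the fitted maps
sit within 15% of this bound and are essentially unbiased; noiseless
signals invert to their generating parameters to better than $10^{-6}$
relative. This is the precision a single VTR acquisition can support;
averaging repeated acquisitions is the only way below it.

# Volumetry, vessel segmentation and the permeability index

Brain volume is the count of ROI voxels per slice times the in-plane pixel
area times the slice thickness (`roi_volume()`); masks are strict voxel
sets, with no partial-volume weighting. Vessels are segmented from the
time-of-flight (TOF) angiography stack by thresholding inside the brain
ROI (`segment_vessels()`); flowing blood is bright on TOF without contrast
agent. The threshold is configuration, not inference: the default adaptive
rule is mean + 3 SD of the within-ROI intensity, chosen because vessels
occupy a small intensity tail above parenchyma; an absolute threshold can
be supplied instead. A threshold above the stack maximum produces an empty
mask with a warning rather than an error, so parameter sweeps degrade
gracefully. `max_intensity_projection()` provides the standard per-pixel
maximum along one axis for visual inspection of the vascular tree.

BBB permeability is quantified from gadolinium contrast leakage:
accumulated contrast agent shortens $T_1$, so

$$\mathrm{index} = \frac{\Delta T_1}{V_\mathrm{vessel}}
  = \frac{\overline{T_1}^{\,\mathrm{baseline}} -
          \overline{T_1}^{\,\mathrm{post}}}{V_\mathrm{vessel}},$$

with means taken over the brain ROI and the vessel volume in mm³
normalizing for how much blood (and hence intravascular contrast) the brain
carries. Design choices, made where the measurement protocol leaves
freedom:

* **Replicate handling.** The post-contrast measurement is acquired twice;
  the two replicate maps are averaged voxel-wise before the ROI mean.
  Averaging is variance-minimizing and symmetric in the replicates; using
  only the second acquisition would discard half the data.
* **Jointly valid voxels.** Baseline and post-contrast validity masks can
  differ (independent fits). Both ROI means are computed over the voxels
  valid in the baseline map *and* every replicate, so $\Delta T_1$ is a
  difference of means over one common voxel set and cannot be biased by
  differential fit failures.
* **Units.** Seconds and mm³ internally; the command-line wrapper accepts
  milliseconds for $T_1$ bounds and converts.

Because $T_1$ depends only on the shape of the recovery versus TR, the
index is invariant under a global rescaling of all image intensities; the
suite checks this to $10^{-9}$ relative.

# The MRI phantom generator

`phantom_spec()` describes a digital phantom whose defaults follow a 9.4 T
neonatal-mouse protocol: a 128 × 96 in-plane matrix over a 25.6 × 19.2 mm
field of view (0.2 mm pixels), nine 1.5 mm slices, and the nine-point TR
schedule above. Tissue $T_1$ defaults to 1.8 s and blood to 2.2 s,
representative values for neonatal brain parenchyma and blood at 9.4 T.
The brain ROI is a centred in-plane ellipse through all slices; vessels are
straight cylinders along the slice axis with positions drawn uniformly
inside the ROI (shrunk so no cylinder clips the boundary), so each vessel's
volume is analytically $\pi r^2 h$ — this is what makes the volumetry
tests exact. Noise is additive Gaussian.

Contrast leakage uses the simplest monotone model consistent with a
whole-ROI $\Delta T_1$ readout: the post-contrast relaxation *rate* is
raised uniformly inside the ROI,

$$R_1^{\mathrm{post}} = R_1^{\mathrm{base}} + \kappa \cdot p,$$

with $p \ge 0$ the per-subject permeability parameter and $\kappa$
(default 0.5 s⁻¹ per unit) the leakage constant. $p = 0$ reproduces the
baseline exactly and $\Delta T_1$ increases strictly with $p$, which is all
the recovery tests claim. No published permeability-index values exist to
calibrate $\kappa$ against animal data, so only rank and recovery
properties — not absolute index values — are asserted anywhere.

What the phantom does **not** emulate: RARE echo trains and flip-angle
effects, k-space acquisition, Rician magnitude noise, motion, partial
volumes, or contrast-agent pharmacokinetics. Passing tests therefore show
that the estimators invert their own forward model at realistic noise
levels, not that they are robust to every artefact of real acquisitions.

# LC-MS feature curation

`curate()` applies five steps in a fixed order, with an audit report
recording each step's parameters, removed feature ids and reason:

1. **Solvent-blank filter** (raw areas): remove any feature whose raw peak
   area strictly exceeds 1E6 in *any* solvent blank ("over" is read as
   strict; an area of exactly 1E6 is retained).
2. **Internal-standard normalization**: divide every area in a sample by
   that sample's cholic-acid internal-standard area. The IS must be
   positive in every sample (violations are errors naming the sample), its
   own normalized area is 1 everywhere, and a second normalization is
   refused.
3. **Method-blank filter** (normalized areas): remove features whose
   summary area over study samples is ≤ the summary over method blanks.
   The summary is the **maximum** by default — the most conservative
   retention rule that still removes blank-dominated features (a feature
   survives if *any* study sample clearly exceeds *every* blank); a
   mean-vs-mean variant is available. The internal standard is exempt:
   after normalization it is identically 1 on both sides of the
   comparison, so the literal rule would always discard the normalization
   anchor.
4. **Pooled-QC %CV filter**: one pooled QC per treatment group, injected
   in replicate (three injections typical). Per feature and pool,
   %CV = 100 · sd/mean of the normalized areas using the sample (n − 1)
   standard deviation — conventional at n = 3. A feature is removed iff
   %CV strictly exceeds 10% in *any* pool: a feature unstable in any pool
   is analytically unreliable everywhere. All-zero features have %CV 0
   (not detected ≠ unstable); a zero mean with any non-zero injection is
   treated as unstable.
5. **Contaminant removal**: drop features flagged as known MS contaminants
   or polyether polymers. Flag ingestion only — spectral matching happens
   upstream.

Removal sets are disjoint (first reason wins) and conservation
(retained + Σ removed = input) is enforced by the report validator.
Running `curate()` on an already-curated table skips the raw-area steps
and removes nothing (idempotence). Because every post-normalization
quantity is a ratio to the IS, multiplying one sample's raw areas
(including its IS) by a constant changes nothing downstream of
normalization — the planted per-sample injection-scale factor in the
simulator exercises exactly this.

# Differential features, pools and BBB crossing

Per feature, a fixed-effects one-way ANOVA across the four treatment
groups is run on normalized areas (`stats::aov`; no log transform by
default, with a `log_transform` switch), and p-values are adjusted by
Benjamini-Hochberg step-up (`stats::p.adjust`). Degenerate features are
resolved before fitting: no variance at all gives p = 1; a group effect
with zero residual variance gives p = 0. Significance is *strict*
q < 0.05. Tukey's HSD (`stats::TukeyHSD`) serves per-feature post hoc
pairwise comparisons.

`pool_partition()` splits the serum and brain significant sets into
shared / serum-only / brain-only. On the study's printed pool sizes —
77 serum and 80 brain significant features with 20 shared — the partition
yields 57 serum-only and 60 brain-only. (Where source figure legends
disagree on 80 vs 88 brain features, 80 is adopted: the set arithmetic
20 + 60 = 80 is only consistent with 80.)

Presence calls proxy the original "noise and peak-shape cutoffs", which
cannot be re-derived from exported tables: a feature is detected in a
(group, compartment) cell iff its **raw** area is ≥ 3.0E4 (the raw-area
floor used when the feature list was built) in at least 50% of that cell's
study samples; both parameters are configurable, and raw areas are carried
through curation for exactly this purpose. A feature "newly crossed the
BBB" under treatment T when it is (i) present in control serum,
(ii) absent from control brain, (iii) present in the T brain, and
(iv) absent from the T serum. Condition (ii) is applied to both the LPS
and the *L. reuteri* contrast for symmetry (the crossing metabolites of
interest are those absent from every untreated brain pool); condition (iv)
is the stated exclusion of features still detectable on the blood side.
Raising the noise cutoff can never add a feature via condition (iii) —
the anti-monotonicity the property tests assert.

# The feature-table simulator

`feature_table_spec()` defaults mirror the 2-week study design: n = 3
study samples per treatment group and compartment, three solvent blanks,
three method blanks, three pooled-QC injections per treatment group, and
planted categories of 5 blank-high, 3 contaminant, 6 QC-unstable, 10
group-differential (log2 fold change 2 in the LPS group), 2 LPS-crossing
and 14 *L. reuteri*-crossing features among 400 total. Areas are
log-normal (median 5E5, log-sd 0.5 across features) with within-group
biological noise of log-sd 0.2 and a per-sample injection scale factor
(log-sd 0.1) that the internal standard tracks exactly — chosen as
plausible magnitudes for positive-mode LC-MS peak areas and
injection-to-injection drift. QC replicate multipliers are constructed so
the planted %CV (3% stable / 25% unstable) is *exact*, making the QC
filter's recovery test sharp rather than probabilistic. Crossing features
are planted as present (typical area) or absent (area 0) per cell;
"absent" cells fall below any sensible noise cutoff, so crossing-set
recovery is exact at default parameters. Setting `within_sdlog = 0` gives
the noiseless regime in which the differential-feature recovery is exact
as well.

All generators take explicit integer seeds and restore the caller's RNG
state; identical spec + seed reproduces outputs byte-identically.

# Pipeline and problem sizes

`run_pipeline()` executes simulate/load → curate → differential (serum and
brain) → pool partition → crossing (LPS and *L. reuteri*), and, when a
phantom is configured, simulate → baseline/post T1 maps → vessel
segmentation → permeability index, writing CSV/JSON/NIfTI artifacts and a
run report whose stage counts satisfy the conservation invariants.
Identical configuration and seed reproduce identical artifacts. A thin
command-line wrapper (`inst/cli/bbbaxis.R`) exposes the same stages as
subcommands; parameter defaults everywhere are the study's printed values
(1E6, 10%, 0.05, 3.0E4, the nine-TR schedule).

The test suite and the acceptance script run phantoms of 3-6 slices and
24-60 in-plane voxels (roughly 1,000-3,000 fitted voxels per map) and
feature tables of 30-400 features — sizes chosen so full parameter-recovery
experiments, including a six-subject permeability cohort, complete in
seconds to a couple of minutes while still exceeding a thousand voxels
where medians over voxels are asserted.

# Known limitations

* The phantom's noise is Gaussian, not Rician, and its anatomy is
  geometric; segmentation robustness claims are correspondingly limited.
* The permeability index inherits the whole-ROI design: it cannot localize
  leakage, and its absolute scale is arbitrary in the simulator.
* The presence rule is a proxy for chromatographic peak-shape review; with
  real data the cutoffs should be tuned against extracted-ion
  chromatograms.
* ANOVA on untransformed normalized areas follows the source analysis
  convention; heavy-tailed features may be better served by the log
  switch.
* With n = 3 per group, per-feature ANOVA has limited power and BH control
  is only asymptotically tight; the empirical-FDR property test uses
  larger simulated cohorts for that reason.
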