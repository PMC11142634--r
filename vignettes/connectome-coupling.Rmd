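---
title: "Cross-modal EEG-fMRI connectome coupling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-modal EEG-fMRI connectome coupling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossconn)
```

## The scientific problem

Electroencephalography and functional MRI see the same brain through very
different windows: EEG resolves fast electrophysiological dynamics, fMRI maps
slow hemodynamics at fine spatial resolution. Whole-brain functional
connectomes -- symmetric region-by-region matrices of pairwise statistical
dependence -- can be built from either modality, and in healthy adults the
two are moderately spatially correlated. Whether that cross-modal
correspondence survives, strengthens or breaks down in focal epilepsy matters
for any attempt to translate fMRI network findings into clinical EEG
practice. `crossconn` implements the full analysis chain needed to ask that
question: per-subject connectome construction in both modalities, the
cross-modal spatial correlation of group-averaged connectomes, and the
resampling machinery (label permutation, bootstrap-of-averages, subnetwork
restriction, contribution decomposition, network-based statistics) used to
compare patient groups -- left and right temporal lobe epilepsy -- against
controls.

Because real patient recordings cannot be redistributed, the package ships a
synthetic-cohort generator with controlled ground truth. Everything the
statistics modules claim is validated against that generator.

## Connectome construction

### fMRI

Region-level BOLD time series are cleaned in a fixed order:

1. **Nuisance regression** -- OLS residuals against an intercept, CSF and
   white-matter signals, six motion parameters and the global gray-matter
   signal.
2. **Band-pass filtering** at 0.009-0.08 Hz, a zero-phase (forward-backward)
   order-2 Butterworth filter. The contract is stated on gains, not
   coefficients: passband gain at 0.04 Hz is at least 0.9 and stopband gain
   at 0.2 Hz and at DC is at most 0.1, measured on 500-volume probe
   sinusoids at TR 2 s (these are asserted in the test suite). Series are
   demeaned before filtering, which removes DC exactly and avoids edge
   transients.
3. **Motion scrubbing** -- framewise displacement
   `fd[t] = sum|d trans| + 50 * sum|d rot|` (rotations as arc length on a
   50 mm sphere, the standard radius for this definition), volumes with
   `fd > 0.5` mm censored. Fewer than 10 surviving volumes is a
   subject-exclusion error.
4. **Pearson correlation** of the cleaned time courses, unthresholded,
   diagonal stored as zero.

Filtering precedes scrubbing because the filter needs contiguous samples;
the upstream description lists regression, filtering, then scrubbing, and we
follow that order. Zero-variance regions produce zeroed edges rather than
NaNs so matrices stay finite.

### EEG

Region-level source time series are segmented into epochs of one fMRI TR.
Two site-specific artifact policies exist: `sd4` (drop segments in which any
region leaves its whole-recording mean by more than 4 whole-recording SDs)
and `amp300` (drop segments leaving +/-300 microvolts; refuses unitless
data). Per segment, cross-spectra are estimated with Welch's method:
non-overlapping Hann sub-windows of `fs/2` samples, i.e. 2-Hz resolution.
Coherency `C = S_xy / sqrt(S_xx S_yy)` is converted to **corrected imaginary
coherency** (lagged coherence),

    ciCoh = sqrt( Im(C)^2 / (1 - Re(C)^2) ),

which is zero for purely real coherency of any magnitude -- exactly the
signature of instantaneous, volume-conduction-like mixing -- and is defined
as 0 where `Re(C)^2 = 1`. An ambiguity exists between this square-root form
and its square; the root form is used and isolated in one function
(`cicoh()`) so the alternative is a one-line switch.

Each bin is masked by the analytic null tail probability
`p = (1 - |C|^2)^((dof - 2)/2)` at `alpha = 0.05`, with `dof = 2 x` the
number of averaged sub-windows. **Why non-overlapping windows:** with
overlapped windows the recorded dof overstates the information content and
the analytic test becomes slightly anticonservative (we measured a null
rejection rate of 0.0535 at alpha = 0.05 with 50%-overlapped Hann windows,
versus 0.0506 without overlap). Since the package treats calibration of this
p-value as a contract -- the suite checks that white-noise segments at
dof = 8 reject at 0.05 within Monte-Carlo error -- the estimator uses
independent sub-windows, trading a little variance for exact calibration.

Masked ciCoh values are averaged over the 2-Hz bins of each canonical band
(delta 0.3-4, theta 4-8, alpha 8-12, beta 12-30, gamma 30-60 Hz; the FFT
coefficient at frequency `f` represents the bin `(f-2, f]` with center
`f-1`, so centers 1, 3, ..., 59 Hz partition cleanly into the five bands)
and then averaged across segments, zeros included; the final matrix is not
thresholded. Gamma keeps all bins up to 60 Hz with no notch exclusion, since
line noise is not modelled at source level.

## Group-level statistics

**Coupling.** The central statistic is the Pearson correlation across
upper-triangle edges between the group-mean EEG connectome of one band and
the group-mean fMRI connectome. Group differences in coupling are tested by
randomly switching group labels (sizes preserved), with the one-sided
add-one estimator `p = (1 + #{null >= obs}) / (1 + n_perm)`, which cannot
return zero.

**Split-half reliability.** A group is split in half; the correlation of the
two half-means measures within-modality consistency. Even groups smaller
than 16 are enumerated exactly (complementary splits counted once, e.g. 3
distinct splits at n = 4); larger groups use random splits; odd groups drop
one random subject per split.

**Contribution decomposition.** With z-scores normalized so `sum(z^2) = 1`,
the correlation is `r = sum(z_x z_y)` and `c_i = z_x z_y / r` is an exact
additive decomposition (`sum(c) = 1` to 1e-9, an identity the suite checks
on a thousand random pairs). Subnetwork analyses test both the coupling
restricted to intra-ICN edges (seven canonical intrinsic connectivity
networks) and the ICN-summed contribution share, each against label
permutation, at the Bonferroni threshold `alpha / (5 bands x 7 networks)`.

**Bootstrap-of-averages models.** To relate coupling to covariates, subjects
are resampled with replacement; each iteration yields one coupling value and
iteration-averaged covariates; OLS across iterations gives coefficients and
t-values. Model I compares controls vs lTLE, model II controls vs rTLE,
model III the two patient groups with epilepsy duration, hippocampal
sclerosis and interictal-discharge rate added. Significance compares the
observed t to a null built by permuting the target covariate across subjects
and rebuilding the whole bootstrap. The literature this follows is ambiguous
about whether the null uses 1,000 or 5,000 iterations; both depths are
exposed (`n_boot`, `n_perm_null`) with defaults of 1,000 each. Covariates
stay on natural scales (sex, site, group coded 0/1) so coefficients are
directly interpretable; constant covariates are excluded with a warning
rather than silently producing a singular fit.

**Network-based statistics.** Monomodal group differences are tested
edge-wise (OLS with age, sex, site as nuisance; fMRI Fisher z-transformed)
with one-sided first-level threshold `t > 2`, and corrected family-wise on
the extent (edge count) of connected suprathreshold components against the
permutation null of the maximal component size. Labels are permuted raw
(the classical scheme; Freedman-Lane residual permutation is a possible
extension, not implemented). Component finding is a hand-rolled union-find,
cross-checked in the tests against both an exhaustive label-propagation
oracle and an independent graph library. The six-model battery (fMRI + five
bands) uses the family threshold `0.05 / 6`.

**Thresholds.** `analysis_thresholds()` centralizes the battery's
multiple-testing arithmetic: `0.05 / 5 = 0.01` (bands),
`0.05 / 35 ~ 0.0014` (band x network grid), `0.05 / 6 ~ 0.0083` (NBS
models).

## The synthetic cohort generator

The generator's defaults encode the emulated study design: two sites
(TR 2.0 s, ~150 volumes, 1 kHz EEG vs TR 3.6 s, 350 volumes, 250 Hz EEG),
three groups totalling 17 controls, 16 lTLE and 17 rTLE subjects, 68
cortical regions, five EEG bands.

Coupling is induced at the edge-vector level rather than by matching full
joint dynamics: a shared latent topology `w_ij = exp(-lambda d_ij)` + noise
(distance decay `lambda = 0.02`/mm, so connectivity falls off with centroid
distance as in real connectomes) is mixed into each modality. fMRI edges are
`tanh(0.2 + 0.3 (z_L + noise))`; EEG band edges mix the shared latent with
an independent band latent at a calibrated weight and squash through
`plogis(-1.5 + 0.5 x)` into the ciCoh range. On the pre-squash scale group
averaging shrinks subject noise by `1/n`, so the weight achieving a target
group-mean coupling `rho` is `w = rho (1 + sd^2/n)` -- targets above ~0.95
under high noise are a calibration failure by design. The squashes are kept
gentle enough that the linear calibration survives them; the suite verifies
recovery within +/-0.05 for targets in [0, 0.7] at n = 16, R = 68.

Default coupling targets are 0.40 (controls and lTLE) and 0.55 (rTLE) in
delta-beta and 0.33 in gamma for all groups; the lTLE-beta coupling of
intra-default-mode-network edges is attenuated by a factor 0.75. These
targets are simulation choices consistent with the qualitative pattern the
analysis should resolve (moderate coupling ~0.3-0.4, a global rTLE increase,
a DMN-local lTLE-beta decrease), not measured values. The subject-level
noise SD of 0.6 was fixed once so that the generator meets its stated
contracts -- target recovery within +/-0.05 and the power to localize the
DMN x beta cell at the subnetwork Bonferroni threshold with ~16 subjects
per group. A consequence worth knowing: the resulting between-subject
variability of group-mean coupling is somewhat tighter than the bootstrap
confidence intervals real cohorts show, so passing the pattern-recovery
tests demonstrates correctness of the machinery, not field-realistic power.

Time-series mode exists to exercise the estimators, not to model physiology:
fMRI volumes are multivariate Gaussian draws matching the subject's target
correlation plus drift and a 0.12 Hz physiological component (removed by the
band-pass); motion is a smooth random walk with ~2% spike volumes so
scrubbing triggers; EEG is band-limited common drivers with a 90-degree lag
on designated region pairs (detected by ciCoh) on top of instantaneously
mixed background noise (suppressed by ciCoh). There is no hemodynamic
forward model, no sensor-space EEG, no leadfields.

The bundled 68-region atlas uses the standard cortical parcellation naming
but synthetic, approximate centroids and an approximate seven-network
assignment (the file is labelled accordingly); subject-specific parcellation
outputs are upstream of this package.

All randomness flows from one master seed per design; cohorts regenerate
bit-identically, and every resampling function takes an explicit seed.

## Numerical and design choices

- Edge vectorization is row-major over the upper triangle, (1,2), (1,3),
  ..., (R-1,R), defined once (`edge_index()`) and used everywhere; for
  R = 68 that is 2,278 edges, always derived from R.
- Connectome files are headerless TSV matrices with zero diagonal plus a
  JSON sidecar for modality/band/subject; matrices asymmetric beyond 1e-12
  are symmetrized as `(M + t(M))/2` with a warning, since 1e-15-level
  asymmetry is expected from upstream tools.
- Fisher z clips inputs at +/-(1 - 1e-7) with a warning instead of returning
  infinities.
- Missing clinical covariates are explicit `NA`, never 0; controls must have
  missing clinical fields.
- Permutation p-values use the add-one estimator throughout.
- One-sided directions are fixed a priori to the contrasts under study
  (rTLE > controls, lTLE < controls).

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on synthetic data at
deliberately modest sizes chosen as the smallest that still exercise each
property: full-scale cohorts (R = 68, n = 17/16/17, 5 bands) for coupling
calibration and pattern recovery (20 seeds, 2,000-5,000 permutations);
R = 15-20 cohorts with 500 permutations and 100-200 replicates for the
size/FWER calibrations; 6-region, 12-segment recordings for the ciCoh
suppression/detection checks; 10^4 segment-bins for the significance-mask
calibration.

## Limitations

- The generator validates the statistics, not the physiology: no real
  volume conduction, no spectral 1/f structure, no BOLD hemodynamics,
  no site-specific artifact spectra. Passing tests show the pipeline
  measures what it claims on data with known truth -- not that any clinical
  effect exists.
- Amplitude-envelope correlation, dynamic (time-resolved) coupling and
  graph-theoretic summaries are out of scope.
- The NBS implementation covers the extent statistic only.
- Voxel-level preprocessing (parcellation, realignment, coregistration,
  source reconstruction) is upstream; inputs are region-level series.
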