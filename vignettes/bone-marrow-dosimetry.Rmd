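---
title: "Image-based bone-marrow dosimetry for Lu-177 SPECT: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-based bone-marrow dosimetry for Lu-177 SPECT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(marrowdose)
```

## The problem

The bone marrow is the dose-limiting organ in Lu-177 radionuclide therapy of
neuroendocrine tumours, yet image-based marrow dosimetry is rarely done in
the clinic. The marrow signal in quantitative SPECT is weak: activity
concentrations in the vertebral cavities are low, so the reconstructed voxel
values are noisy, and the absorbed-dose (AD) estimate inherits that noise.
Practitioners delineate a handful of thoracic/lumbar vertebrae (T8--L5) as a
surrogate for the whole marrow, which raises three coupled questions this
package is built to study:

1. **Precision** -- how much does the AD estimate vary with the particular
   vertebrae chosen, and how quickly does averaging over more vertebrae
   stabilize it?
2. **Accuracy** -- how much signal is lost to partial-volume effects
   (spill-out) and to reconstruction bias near high-uptake organs
   (kidneys, spleen, liver), which sit directly beside T12--L2?
3. **Reconstruction settings** -- does the iteration x subset split of an
   OSEM reconstruction (at fixed total updates) change the dose?

Since patient data cannot ship with a package, every input is simulated:
the package generates digital phantoms, projects them with an analytic SPECT
model, adds Poisson noise at patient-like count levels, reconstructs,
quantifies, and doses -- end to end, deterministically seeded.

## The simulation chain

### Phantoms

* `build_body_phantom()` -- a stylized torso: elliptical soft-tissue body,
  two low-density lungs, liver, spleen, and two kidneys flanking the
  T12--L2 levels, plus a contiguous column of ten equal-sized cylindrical
  vertebral bodies (T8 cranially to L5 caudally; the intervertebral discs
  are below grid resolution). Each vertebra carries an interior *marrow
  VOI* -- a narrower, shorter cylinder graded from about 4 mL (T8) to about
  10 mL (L5), mirroring the limited marrow volume that can actually be
  delineated on low-dose CT inside a much larger vertebral body. Keeping
  the *bodies* identical and grading only the *VOIs* means recovery
  differences between vertebrae reflect their surroundings, not their
  shape.
* `build_lung_spine_phantom()` -- the sphere-insert accuracy phantom:
  elliptical body, two low-density lung regions, a bone-equivalent spinal
  rod, and spherical inserts (default 4/8/16 mL) at twice the background
  concentration (0.58 MBq/mL in the spheres). The rod and lungs differ
  from background only in attenuation, so at insert ratio 1 the activity
  map is uniform -- a useful degenerate case for testing.
* `build_calibration_cylinder()` -- a homogeneous cylinder with an exactly
  known total activity, used for the image calibration factor.

Organ uptake tables (`default_uptake()`) give homogeneous concentrations
per organ at 2, 24, 48 and 168 h after injection. The bundled values are
**synthetic** stand-ins shaped like a typical patient (kidney uptake several
times marrow; marrow a few times background, peaking near 24 h, with the
washout rate including physical decay); they are deliberately simple and
swappable. `marrow_only_uptake()` puts activity only in the marrow at 5:1
over a uniform background -- the control map that isolates reconstruction
bias from adjacent hot organs.

Attenuation uses NIST-derived linear coefficients at the 208 keV photopeak:
soft tissue 0.135, lung 0.040, bone 0.25 cm^-1, air 0.

### Projector

`forward_project()` implements an analytic attenuated parallel-beam
projector: for each of the (default 120, 60 in the bundled experiments)
views over 360 degrees the volume is rotated to the detector frame by
bilinear resampling, each depth slab is attenuated by the accumulated mu
toward the detector and convolved with a Gaussian collimator--detector
response whose width grows with distance, sigma(d) = sigma0 + slope x d
(defaults sigma0 = 2 mm, slope = 0.02, detector radius 250 mm -- around
7 mm sigma at the rotation centre, i.e. a medium-energy-collimator-like
16 mm FWHM). This is a photopeak-only approximation: no scatter windows,
no septal penetration, no detector dead time. Scatter-free projections are
a known simplification; what the model preserves is exactly the
phenomenology under study -- Poisson noise, partial-volume blur, and
spill-over between neighbouring structures.

Count levels are set by `scale_to_count_level()`: either a grand-total
budget (the three lung-spine noise levels eta_min/eta_med/eta_max, defaults
2e6/6e5/2e5 counts, spanning the factor ~10 a patient cohort spans) or by
matching the mean expected counts over detector bins whose rays intersect a
reference region -- the right kidney, the body-phantom normalization
(default 25 counts/bin). `sample_noise_realizations()` draws independent
Poisson realizations; realization `i` is seeded `base_seed + i` so any
single realization can be reproduced in isolation.

### Reconstruction

`reconstruct_osem()` is standard OSEM with the projector as system model
(attenuation and PSF inside the model, i.e. resolution recovery) and the
**exact matched adjoint** as back projector. The matched pair is a design
choice: it guarantees the EM monotonicity property (the Poisson
log-likelihood is non-decreasing under MLEM), which the test suite asserts
directly. Subsets partition the sorted views round-robin for maximal
angular spread; sensitivity images are computed per subset and voxels with
sensitivity below 1e-12 are frozen at zero; there is no post-filter.
"Updates" always means iterations x subsets, and `update_sweep()` serves a
whole sweep (e.g. 12--204 updates at 12 subsets) from one run by
snapshotting, which is what makes 60-realization sweeps affordable.

### Quantification

Calibration follows the ICF convention: `compute_icf()` divides the total
reconstructed counts in a large cylindrical VOI of the calibration phantom
by its known activity. Because the ICF is camera- *and*
reconstruction-specific, the experiment drivers recompute it per effective
exposure and per update number. `voi_concentration()`,
`recovery_coefficient()` (RC = C_R / (ICF x A_R)) and `voxel_recovery()`
(mean calibrated concentration over mean true concentration) then quantify
VOIs; all VOI voxels are used, with full-voxel (centre-in) membership and
no thresholding. `cov_stats()` computes the precision metric,
COV = sigma/mu x 100, with the sample (n-1) standard deviation -- the
denominator convention is a documented package choice.

### Dosimetry

Per region, concentration versus time is fitted with
`fit_biexp()`: f(t) = A1 e^(-lambda1 t) + A2 e^(-lambda2 t), nonlinear
least squares (Levenberg--Marquardt) with multi-start initialization (slow
rate from a log-linear fit to the last two points; fast-rate candidates
from the first two points and fixed multiples of the slow rate; amplitudes
by linear least squares at each rate pair; ties broken by residual norm
then by the smaller fast rate). A2 may be negative (uptake phase), but a
fit is only accepted if both rates are positive and f >= 0 on [0, Inf);
otherwise the fit falls back to a monoexponential restricted to the washout
phase (from the observed peak onward -- including an uptake-phase point
would flatten the rate and inflate the integral) and flags itself.
Concentrations are treated as not decay-corrected, so the fitted rates
include physical decay.

The time-integrated activity concentration is the closed form
A1/lambda1 + A2/lambda2 (cross-checked against adaptive quadrature to 0.1%
in the tests), and the absorbed dose attributes all measured VOI activity
to the red-marrow compartment:

    D [Gy] = TIA x 3.6e9 [decays/(MBq h)] x E_e [J] x AF / (VF x rho)

with volume fraction VF = 0.574 (proportion of the vertebral cavity
occupied by active red marrow, thoracic/lumbar average over sexes),
electron absorbed fraction AF = 0.645, marrow density
rho = 1.03e-3 kg/mL, and E_e = 2.37e-14 J per decay (~148 keV mean
electron + beta energy per Lu-177 decay, ICRP-107-style). The combining
formula is a package design decision -- the constants are standard but the
combination convention varies across groups; an alternative convention in
which the activity is shared with the whole cavity (VF cancelling) can be
had by setting `volume_fraction = 1` and rescaling, and all four constants
are arguments of `dosimetry_constants()`. Photon self- and cross-dose are
deliberately excluded (electron-only marrow self-dose). Doses are reported
in mGy per GBq injected (default 7.4 GBq per cycle).

### Precision analysis

`enumerate_combinations()` forms all unordered subsets of the available
lesion-free vertebrae for group sizes one to six (unordered subsets, not
contiguous runs -- the only reading consistent with 126 total combinations
for seven vertebrae, since sum_k C(7,k) for k = 1..6 = 126;
`count_total_combinations()` gives the closed form). For each combination
the member concentrations are **averaged first, then fitted** -- the order
matters and is fixed by the method description. `precision_by_group_size()`
tabulates mean dose and COV per group size; `compare_regions()` (paired t)
and `compare_recon_settings()` (per-group-size two-sample t with Bonferroni
correction at family level 0.01) run the statistical comparisons;
`ground_truth_restoration()` expresses an image-derived dose as a
percentage of the ground-truth dose.

## The synthetic patient ensemble

The combinatorial precision experiment needs per-vertebra time-activity
curves with realistic heterogeneity. `simulate_vertebra_series()` draws,
for each vertebra, a common uptake-washout curve
C (e^(-0.0095 t) - e^(-0.25 t)) -- peak near 24 h, effective washout
half-life ~73 h including physical decay -- scaled by a lognormal
per-vertebra factor (sdlog 0.30) and perturbed by a small lognormal
per-time-point jitter (sdlog 0.05). The amplitude default (0.043 MBq/mL)
puts the resulting mean marrow dose near 57 mGy/GBq, the level typical of
published Lu-177 DOTATATE cohorts. The lognormal vertebra factor lumps
together biological heterogeneity and single-vertebra measurement noise;
it is exchangeable across vertebrae by construction. What this generator
does *not* emulate: spatially correlated noise between neighbouring
vertebrae, metastatic infiltration, or vertebra-specific biases from
adjacent organs -- so the COV-versus-group-size results describe the
exchangeable-noise regime, and the spill-in bias is studied separately in
the imaging experiments where it belongs.

With exchangeable per-vertebra noise, subset means of size k drawn from n
vertebrae shrink like sqrt((n-k)/(k(n-1))) relative to single-vertebra
scatter, so the COV must fall steadily from k = 1 to k = 6 and the k = 6
group ends well below half the k = 1 value; the ensemble experiment
averages the per-draw COV over 20+ seeds and the tests assert exactly that
monotone decrease.

## Experiment drivers and problem sizes

Four drivers wire the stages together (`run_experiment()` dispatches on a
config list or YAML/JSON file and writes CSV/JSON bundles):

* `experiment_combination_precision()` -- 10 vertebrae, 20+ ensemble
  draws, all 847 combinations per draw.
* `experiment_lung_spine()` -- 64^3 grid at 4.5 mm, 60 views, three total
  count budgets, 20 Poisson realizations per level, one 17-iteration
  12-subset OSEM run per realization snapshotted at every iteration
  (updates 12..204), with an update-matched ICF per noise level.
* `experiment_xcat_spillin()` -- the body phantom at 64^3/5.5 mm, 60
  views, kidney-matched count level, 20 realizations each for the full
  map and the marrow-only map at 60 updates (5i12s), plus noise-free
  reconstructions at all four time points for the dose-restoration
  comparison of L3--L5 versus T12--L2.
* `experiment_subset_sensitivity()` -- noise-free body phantom at all four
  time points reconstructed both as 60i1s (MLEM) and 5i12s (OSEM), marrow
  curves from the vertebral VOIs, and the relative dose difference
  dAD = (AD_5i12s - AD_60i1s) / AD_5i12s.

These sizes are the package's chosen study conditions: large enough that
partial-volume, spill-in and noise phenomenology are clearly expressed,
small enough that the whole suite runs on a laptop core in tens of minutes.
Every stochastic step derives its seed from the experiment base seed with a
documented offset (noise realization i of level l uses
base_seed + (l-1) x n_realizations + i; ensemble draw s uses
base_seed + s); the fitting multi-starts use fixed deterministic grids and
consume no randomness.

## Numerical choices and degenerate inputs

* Rotation by bilinear gather; the adjoint is the bilinear scatter with
  identical weights -- an exact transpose. View-total conservation under
  rotation is approximate (interpolation), held to <1% in tests.
* The Gaussian response kernel is truncated at 2.5 sigma and normalized;
  edge truncation is *not* renormalized per-pixel, because only the
  untouched symmetric kernel keeps the blur operator self-adjoint.
* OSEM ratio bins with predicted counts below 1e-12 contribute zero;
  all-zero projection sets reconstruct to zero with a warning rather than
  an error; zero-sensitivity voxels are excluded, not divided by.
* COV with zero mean, t-tests with zero-variance differences, empty VOIs,
  non-divisor subset counts, all-zero time-activity series, and group
  sizes above six all fail loudly or flag themselves as degenerate.

## Known limitations

The projector is scatter-free and the anatomy parametric, so absolute
recoveries sit above what a Monte Carlo model of a real camera gives (the
bundled experiments see noise-free RC ~0.7--0.9 where measured-phantom
values are ~0.6--0.75); conclusions should be read as orderings and
trends, which is also how the experiments and tests are phrased. Marrow is
homogeneous within each vertebra; there are no lesions, no respiratory
motion, no patient-specific marrow volume fractions. Recovery coefficients
are computed but never *applied* as partial-volume corrections -- that
application is out of scope by design.
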