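# marrowdose

Simulation and analysis toolkit for **image-based bone-marrow dosimetry in
Lu-177 radionuclide therapy**, for medical physicists and dosimetry
methodologists who want to study — on fully synthetic, reproducible data —
how the precision and accuracy of a vertebra-based marrow absorbed-dose
estimate depend on:

* the **number of vertebrae** included in the estimate (all unique
  combinations of one to six of the available T8–L5 vertebrae),
* **image noise** (Poisson realizations at patient-like count levels) and
  the **OSEM update number**, via recovery coefficients of spherical
  inserts in a lung-spine phantom,
* **spill-in / reconstruction bias** from high-uptake organs (kidneys,
  spleen, liver) adjacent to the lower vertebrae, via a digital body
  phantom with and without organ uptake,
* the **iteration × subset split** of the reconstruction at fixed updates
  (60i1s versus 5i12s).

## The model at the core

The package simulates the whole quantitative-SPECT chain. Projections are
generated by an analytic attenuated parallel-beam projector with a
distance-dependent Gaussian collimator–detector response
σ(d) = σ₀ + slope·d; reconstruction is OSEM with the same system model and
its exact matched adjoint (so MLEM increases the Poisson likelihood
monotonically — asserted in the tests). Quantification follows the standard
calibration conventions:

* image calibration factor **ICF = C_cal / A_cal** (homogeneous cylinder),
* recovery coefficient **RC(v) = C_R(v) / (ICF · A_R(v))**,
* precision metric **COV = σ/μ · 100**.

Marrow absorbed doses come from biexponential time–activity fits
f(t) = A₁e^(−λ₁t) + A₂e^(−λ₂t) integrated analytically to infinity
(TIA = A₁/λ₁ + A₂/λ₂) and converted with red-marrow constants
(volume fraction 0.574, electron absorbed fraction 0.645, density
1.03×10⁻³ kg/mL, ~148 keV mean electron energy per decay):

    D [Gy] = TIA · 3.6×10⁹ · E_e · AF / (VF · ρ),      reported in mGy/GBq.

For a region set, concentrations are averaged across members per time point
first and fitted second; relative dose differences between reconstruction
settings use ΔAD = (AD_5i12s − AD_60i1s) / AD_5i12s.

See `vignettes/bone-marrow-dosimetry.Rmd` for the full account of the
models, parameters, numerical choices and limitations.

## Worked example

Precision of the marrow dose versus the number of vertebrae, on a synthetic
ensemble of ten exchangeable vertebral time–activity curves:

```r
library(marrowdose)

b <- experiment_combination_precision(n_vertebrae = 10, n_seeds = 25,
                                      base_seed = 1)
b$summary
#>   k n_combinations mean_dose mean_cov_percent
#> 1 1             10  56.43267        29.591210
#> 2 2             45  56.66485        19.076754
#> 3 3            120  56.79302        14.512568
#> 4 4            210  56.88987        11.623001
#> 5 5            252  56.95005         9.511397
#> 6 6            210  56.99897         7.799632
```

Reading: the mean marrow dose (~57 mGy/GBq at 7.4 GBq injected) barely
moves with the group size, but its **coefficient of variation across the
possible vertebra choices falls from ~30% with one vertebra to ~8% with
six** — averaging over more lesion-free vertebrae is nearly free precision.
The per-combination doses of the first draw are in `b$doses_first_seed`,
per-draw tables in `b$per_seed`.

Single pieces compose just as easily:

```r
s   <- simulate_vertebra_series(seed = 2)          # 10 vertebra TACs
fit <- fit_biexp(s$V1)                             # classed S3 model
coef(fit); predict(fit, 0:200)                     # the fitted curve
absorbed_dose(time_integrated_concentration(fit))  # dose_result, mGy/GBq
```

The imaging experiments (`experiment_lung_spine()`,
`experiment_xcat_spillin()`, `experiment_subset_sensitivity()`) run the
phantom → projector → noise → OSEM → quantify → dose chain; each takes a
few minutes on one core at the default 64³ problem sizes. All of them are
also reachable through `run_experiment()` with a config list or YAML/JSON
file.

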