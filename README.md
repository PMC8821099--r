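# dtialps

Glymphatic-function analysis with the DTI-ALPS index, on fully synthetic,
fully testable data.

The glymphatic system drains interstitial waste from the brain through
perivascular spaces. The **DTI-ALPS** ("analysis along the perivascular
space") method estimates its function from ordinary diffusion MRI: at the
level of the lateral-ventricle body the medullary veins — and with them the
perivascular spaces — run left–right (x), perpendicular to both the
projection fibers (inferior–superior, z) and the association fibers
(anterior–posterior, y). Water mobility *along x inside those fibers* is
therefore perivascular, and the index

```
ALPS = mean(Dxx_proj, Dxx_assoc) / mean(Dyy_proj, Dzz_assoc)
```

compares it with the fibers' ordinary radial diffusivity (Dij = diffusion
tensor element in the scanner frame; proj/assoc = one selected voxel in the
projection/association fiber). Isotropy gives 1; better presumed glymphatic
transport gives larger values. In the dialysis population this package
models, end-stage renal disease (ESRD) patients average 1.460 against 1.632
in healthy controls, and the index correlates with serum parathyroid
hormone (r = 0.357).

Patient scans from such studies are not shareable, so `dtialps` implements
the complete measurement chain over synthetic data with known ground truth:

* **Phantom** — a three-fiber periventricular voxel grid with calibrated
  diffusivity profiles (`build_phantom()`, `esrd_profile()`,
  `control_profile()`);
* **Scanner forward model** — Stejskal–Tanner signal with Rician noise and a
  shipped 32-direction b = 1000 s/mm² gradient table (`simulate_dwi()`,
  `default_protocol()`);
* **Tensor estimation** — log-linear least squares, exact on noise-free
  data, with principled handling of degenerate voxels (`fit_tensor()`,
  `eig_sorted()`, `axis_diffusivities()`);
* **ALPS core** — the voxel-selection rule (one voxel per fiber, maximum
  orientation, shared x index) and the index formula
  (`select_fiber_voxels()`, `compute_alps()`, `subject_alps()`);
* **Cohorts & statistics** — two-arm cohorts with clinical covariates
  coupled to perivascular diffusivity through a Gaussian copula, plus the
  study's t-test / chi-square / Pearson / Bonferroni battery
  (`simulate_cohort()`, `compare_groups()`, `correlate_clinical()`).

Everything is tibble-first and pipe-friendly; results have `tidy()`,
`glance()` and `autoplot()` methods. I/O speaks NIfTI-1 with FSL-dialect
`.bval`/`.bvec` files, ROI JSON and cohort CSV. A thin command-line front
end lives in `inst/cli/dtialps` (subcommands `simulate`, `fit`, `alps`,
`cohort`, `stats`, `run`).

## Worked example

One subject, end to end — build a control-profile phantom, scan it at
SNR 40, and measure:

```r
library(dtialps)

field <- build_phantom(default_geometry(), control_profile())
dwi   <- simulate_dwi(field, default_protocol(), snr = 40, seed = 11)
res   <- subject_alps(dwi, default_roi())
res
#> <alps_result> ALPS index = 1.6271
```

The measured 1.627 sits within noise of the profile's analytic value
`analytic_alps(control_profile())` = 1.632: the perivascular diffusivity
0.816 over the radial 0.50, in units of 10⁻³ mm²/s.

A full two-arm study (49 ESRD vs 38 controls, every subject imaged and
fitted) with the group comparison:

```r
cohort <- simulate_cohort(cohort_config(seed = 11, fidelity = "full"))
report <- compare_groups(cohort)
tidy(report) |>
  dplyr::filter(variable %in% c("alps", "dxx_proj", "age", "sex")) |>
  dplyr::select(variable, mean_a, mean_b, p.value, threshold, significant)
#> # A tibble: 4 × 6
#>   variable mean_a mean_b  p.value threshold significant
#>   <chr>     <dbl>  <dbl>    <dbl>     <dbl> <lgl>
#> 1 alps      1.61   1.44  3.05e-15   0.05    TRUE
#> 2 dxx_proj  0.814  0.721 6.15e-15   0.00556 TRUE
#> 3 age      61.3   60.2   5.01e- 1   0.05    FALSE
#> 4 sex      NA     NA     4.50e- 1   0.05    FALSE
```

Group `a` is the controls, `b` the ESRD arm. The ALPS difference is judged
at the plain two-tailed 0.05; the per-axis diffusivity rows carry the
Bonferroni-adjusted threshold 0.05/9 (displayed 0.0055) because nine such
comparisons are made. Age and sex are matched by construction, so their
p-values are unremarkable, as they should be. Within the ESRD arm,
`correlate_clinical()` returns the 17-variable correlation table; a single
cohort's ALPS–PTH r scatters around the calibrated 0.357 with a sampling SD
of about 0.13 at n = 49 (seed 11 gives r = 0.145, p = 0.32), which is why
calibration claims below average over many seeds.

`autoplot(cohort)` draws the group boxplot and
`plot_alps_scatter(cohort, "pth")` the correlation panel.

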