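# affrf

Orientation selectivity of visual receptive fields modelled as affine
Gaussian derivatives.

Neurons in the primary visual cortex respond selectively to the
orientation of visual stimuli, and recorded populations show a broad
spread in how sharp that selectivity is.  `affrf` implements a normative
model in which the receptive field of an `m`-th order simple cell is a
scale-normalized directional derivative of an anisotropic Gaussian,

    T_m(x) = sigma1^m * d^m/d(phi)^m  g(x; Sigma_phi),

with covariance eigenvalues `sigma1^2` (along the preferred orientation
`phi`) and `sigma2^2` (orthogonal), and a complex cell is the
quasi-quadrature energy of the first- and second-order responses.  The
whole theory is then driven by the elongation ratio `kappa = sigma2 /
sigma1` (eccentricity `epsilon = 1/kappa`): the orientation-tuning curve
of an order-`m` cell is

    r_m(theta) = |cos theta|^m / (cos^2 theta + kappa^2 sin^2 theta)^(m/2),

generalized to real exponents by `r_lambda = r_1^lambda` (complex cells
are `lambda = 3/2`), and tuning sharpness is summarized by the circular
resultant

    R = Int r(theta) e^(2 i theta) d(theta) / Int r(theta) d(theta),

with closed forms such as `|R|_2 = kappa / (kappa + 1)`.  The package is
aimed at computational neuroscientists who want to simulate resultant
histograms over populations with distributed elongation, estimate
`kappa` from measured tuning curves, or prototype the analysis of
pinwheel orientation maps with per-site eccentricity and homogeneity
measurements.

## What is in the package

* **Kernels** — `rf_shape()`, `make_covariance()`, `sample_spatial_rf()`,
  `sample_spatiotemporal_rf()`, and a numerical affine-covariance check
  (`check_affine_covariance()`).
* **Tuning** — closed-form curves (`tuning_closed_form()`), curves
  computed from kernels by frequency-maximized grating responses
  (`tuning_numeric()`), and the complex-cell energy model
  (`quasi_quadrature_response()`, `tuning_quadrature()`).
* **Resultant** — quadrature (`resultant_numeric()`) and closed forms
  with the `kappa < 1` branch continuation
  (`resultant_closed_form()`, `resultant_curve()`).
* **Population** — log-uniform elongation sampling and resultant
  histograms per cell class (`population_spec()`, `sample_kappa()`,
  `simulate_histograms()`, `combine_orders()`).
* **Fitting** — elongation estimation from tuning curves
  (`fit_tuning()`, `generate_synthetic_tuning()`, `resultant_of_fit()`).
* **Cortical maps** — synthetic pinwheel lattices and joint diagnostics
  (`generate_pinwheel_map()`, `orientation_homogeneity()`,
  `measure_map()`, `loop_winding()`).
* **I/O and CLI** — CSV readers/writers with JSON metadata sidecars and
  an `affrf` command-line front end (`affrf_cli()`,
  `inst/exec/affrf`) with subcommands `kernel`, `tuning`, `resultant`,
  `population`, `fit`, `cortmap`.

## Worked example

```r
library(affrf)

# Resultant of order-2 simple cells at increasing elongation
resultant_closed_form("simple", kappa = c(1, 2, 4, 8), order = 2)
#> [1] 0.5000000 0.6666667 0.8000000 0.8888889

# Estimate elongation from a noisy synthetic tuning curve
fit <- fit_tuning(generate_synthetic_tuning(3, 2, noise_sd = 0.02, seed = 1))
fit
#> tuning_fit: lambda = 1.9271, kappa = 3.1603 (eccentricity 0.3164), residual 2.403e-01
resultant_of_fit(fit)
#> [1] 0.7487783

# Population histogram of first-order cells, kappa log-uniform on [1/8, 8]
h <- simulate_histograms(population_spec(n_per_class = 10000))
h$simple1
#> rhistogram 'simple1': 10000 cells in 10 bins on [0, 1]
#> [0.0,0.1) [0.1,0.2) [0.2,0.3) [0.3,0.4) [0.4,0.5) [0.5,0.6) [0.6,0.7) [0.7,0.8)
#>       929      2109      1506      1350      1396      1645      1065         0
#> [0.8,0.9) [0.9,1.0)
#>         0         0
```

The order-2 resultants show tuning sharpening with elongation: an
isotropic field (`kappa = 1`) has `|R| = 0.5`, an 8-fold elongated one
`8/9`.  The fit recovers the generating parameters (`lambda = 2`,
`kappa = 3`) to within the noise level, and mapping the fitted curve to
the resultant scale gives its selectivity summary.  The first-order
population histogram is empty above 0.7: over `kappa <= 8` the
first-order model cannot exceed `|R| = 0.652`, which is the model's
explanation for the absence of very sharp first-order cells.

The same computations are available from a shell, e.g.

```sh
Rscript inst/exec/affrf resultant --model simple --order 2 --kappa 2
#> 0.666667
```

See `vignettes/orientation-selectivity.Rmd` for the model's assumptions,
parameter conventions, numerical choices and limitations.

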