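# tractlife

Small-area life expectancy estimation and spatial regression of health
disparities, for epidemiologists and health geographers working at the
census-tract scale.

Tract-level life expectancy at birth (e0) is a powerful disparity
metric, but tracts are small: death counts are thin, estimates are
noisy, and both the outcome and its social-determinant drivers are
spatially structured. `tractlife` implements the full analytic chain:

1. **Abridged life tables (adjusted Chiang II).** From deaths and
   person-years on the standard 19-interval schedule (<1, 1–4,
   five-year bins, 85+), with

   q_i = n_i·m_i / (1 + n_i·(1 − a_i)·m_i)

   for closed intervals, an exponential 85+ tail (L = l/m), and a
   closed-form variance of e0 that supports screening. Tracts with
   < 50 total deaths, < 5,000 person-years, or SE(e0) > 2 years are
   flagged for exclusion (strict inequalities; screening can be
   bypassed for sensitivity runs).

2. **Queen-contiguity spatial weights.** Built from GeoJSON polygons or
   GAL neighbor files (or synthetic lattices), row-standardized, with
   eigenvalue services for the likelihood.

3. **The spatial Durbin error model (SDEM)**, fitted by concentrated
   maximum likelihood:

   y = α + Xβ + WXθ + u,  u = λWu + ε,  ε ~ N(0, σ²I)

   Direct effects β, neighborhood (lagged) effects θ, total impacts
   β + θ; likelihood-ratio and AIC comparison against the plain spatial
   error model; VIF/correlation screening; global Moran's I on the
   whitened residuals.

4. **A seeded synthetic-data generator** (lattices, autocorrelated
   covariates, SDEM outcomes, Gompertz–Poisson mortality) so everything
   above is testable end to end without external data.

## Worked example

Generate a 30×30 synthetic study (true λ = 0.5, β = (1, −0.5),
θ = (0.3, 0), σ = 1) and run the full pipeline:

```r
library(tractlife)
d <- file.path(tempdir(), "demo")
make_fixture("recovery", d)
cfg <- study_config(
  mortality  = file.path(d, "mortality.csv"),
  population = file.path(d, "population.csv"),
  covariates = file.path(d, "covariates.csv"),
  gal        = file.path(d, "neighbors.gal"),
  outcome    = file.path(d, "outcome.csv"),
  outcome_mode = "file", seed = 7)
report <- run_study(cfg)
print(report)
```

```
Small-area life expectancy study
Tracts: 900 total, 900 retained, 0 removed; 900 analyzed
Spatial Durbin error model
n = 900, k = 5, lambda = 0.5185, sigma2 = 0.9116
logLik = -1255.014, AIC = 2524.029, pseudo-R2 = 0.596
         name     block estimate      se         z          p stars
1 (Intercept) intercept 80.92829 0.06611 1224.2227  0.000e+00   ***
2          x1    direct  1.05560 0.03650   28.9246 5.853e-184   ***
3          x2    direct -0.52579 0.03475  -15.1320  9.957e-52   ***
4      lag.x1       lag  0.25250 0.08952    2.8206  4.793e-03    **
5      lag.x2       lag -0.07585 0.09660   -0.7852  4.323e-01
Global Moran's I = 0.0035 (E[I] = -0.0011), p = 0.826 [permutation]
```

Reading the output: the estimated error autocorrelation λ̂ = 0.52 and
the coefficient estimates sit close to the generating values; `x1` has a
significant local effect (+1.06 years of life expectancy per standard
deviation) and a significant neighborhood effect (+0.25), so its total
impact is +1.31:

```r
impacts(report$fit)
#>   name    direct   indirect      total     direct_p indirect_p
#> 1   x1  1.055605  0.2525003  1.3081051 5.85287e-184 0.00479331
#> 2   x2 -0.525786 -0.0758459 -0.6016319  9.95698e-52 0.43234803
```

The residual Moran's I is non-significant (p = 0.83): after the spatial
error term, no spatial autocorrelation remains — the model is correctly
specified for these data. `write_report(report, "out/")` writes the life
expectancy table, a coefficient table with significance stars
(`"0.13***"`-style rendering), and a diagnostics JSON.

A thin command-line front-end is included:

```sh
Rscript inst/cli/lifespan.R simulate --fixture tiny --out study/
Rscript inst/cli/lifespan.R lifetable --mortality M.csv --population P.csv --out le.csv
Rscript inst/cli/lifespan.R run --config study.yaml --out out/ [--no-filters]
```

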