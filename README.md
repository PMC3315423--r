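# morphrel

Scanner-related reliability analysis for multicentre, test-retest brain
morphometry.

Automated morphometry — grey/white matter and CSF volumes, the global
sulcal index (GSI), per-sulcus surface area and geodesic depth — is
widely used in cross-sectional neuroimaging, but multicentre and
longitudinal designs add scanner- and session-related variance that can
swamp small group differences. Given a balanced crossed design (the
same subjects scanned twice at every centre), `morphrel` answers two
questions for each measure:

* **Are centres or visits significantly different?** A fixed-effects
  ANCOVA with a subject factor, centre, visit and their interaction,
  with cerebral hemisphere volume (and GSI, for sulcal measures) as
  covariates, tests each scanner effect with
  `F = (ΔSS/Δdf)/MSE`.
* **How reliable is the measure?** A crossed random-effects variance
  decomposition (subject, centre, visit, all interactions, residual)
  estimated by solving the expected-mean-squares equations, then

  ```
  R_factor = (V_total − V_factor) / V_total
  ```

  where `V_factor` sums the factor's variance component and every
  interaction containing it. `R = 1` means the factor contributes no
  variance, `R = 0` that it is the only source; values are graded
  poor / moderate / good / excellent at 0.50 / 0.70 / 0.90.

The package also provides bias-correction quality metrics on grey-level
volumes (within-mask coefficient of variation, WM/GM contrast from
histogram peaks, mask intersection), and synthetic generators — crossed
morphometry tables with known variance structure, and 3-D tissue
phantoms with noise and a multiplicative bias field — so the whole
pipeline is testable at desk scale. The audience is imaging scientists
planning or auditing multi-site structural MRI studies.

## Worked example

Simulate the default study conditions (13 subjects × 3 centres × 2
visits × 2 hemispheres) with known variance components, then recover
them and compute reliabilities:

```r
library(morphrel)

sim <- simulate_morphometry(
  components = c(subject = 9, centre = 1, visit = 0.25,
                 "subject:centre" = 0.5, residual = 1),
  seed = 42
)
view <- complete_design_view(sim$table, "gm_volume")

vc <- estimate_variance_components(view)
vc
#> Variance components (13 x 3 x 2 design, 2 replicate(s)/cell)
#>                  term df    sumsq   meansq variance_raw variance
#>               subject 12 1236.020 103.0016      8.31656  8.31656
#>                centre  2   68.975  34.4874      0.58119  0.58119
#>        subject:centre 24   87.346   3.6394      0.61348  0.61348
#>                 visit  1    6.220   6.2200      0.06212  0.06212
#>         subject:visit 12    8.988   0.7490     -0.07275  0.00000
#>          centre:visit  2    3.623   1.8113      0.02407  0.02407
#>  subject:centre:visit 24   28.452   1.1855      0.14638  0.14638
#>              residual 78   69.635   0.8928      0.89276  0.89276

reliability_pair(vc)
#> # A tibble: 2 × 5
#>   factor value grade     v_factor v_total
#>   <chr>  <dbl> <chr>        <dbl>   <dbl>
#> 1 centre 0.872 good         1.37     10.6
#> 2 visit  0.978 excellent    0.233    10.6
```

The estimated between-centre reliability (0.87, "good") and
between-visit reliability (0.98, "excellent") sit next to the analytic
truths implied by the generating components (0.872 and 0.979,
`sim$truth$reliability`). Note the negative raw `subject:visit`
estimate, reported as is and truncated to zero in the working column.

The ANCOVA on the same view flags the injected centre variance:

```r
f_test_effects(view, model_spec("gm_volume"))
#> ANCOVA for 'gm_volume' (adjusted SS, alpha = 0.05)
#>        effect df statistic       p significant
#>        centre  2    24.479 < 0.001        TRUE
#>         visit  1     4.415   0.037        TRUE
#>  centre:visit  2     1.286   0.280       FALSE
```

And the derived-measure utilities follow the standard conversions, e.g.
the fraction of cortex buried in sulci from a mean GSI:

```r
round(100 * buried_fraction(c(1.44, 1.66)))
#> [1] 59 62
```

`run_reliability_report()` chains all of this over a full study table
(per cohort: an effect-table CSV, global and sulcal reliability CSVs,
and a reproducibility manifest); `tidy()`, `glance()`, `autoplot()` and
`plot_reliability()` cover programmatic and graphical use. A thin CLI
(`inst/scripts/morphrel`) exposes `analyze`, `simulate` and
`image-metrics` verbs.

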