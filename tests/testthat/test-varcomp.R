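test_that("EMS estimates match the hand-solved oracle on a tiny fixture", {
  tbl <- crossed_table(3, 2, 2, 2, sd = c(
    subject = 2, centre = 1, visit = 0.5, sc = 0.3, sv = 0.2, cv = 0.1,
    scv = 0.1, e = 1
  ), seed = 7)
  vc <- estimate_variance_components(tbl)
  got <- setNames(vc$components$variance_raw, vc$components$term)
  oracle <- ems_oracle(tbl)
  expect_equal(got[names(oracle)], oracle, tolerance = 1e-10)
  # Same check without replicates (three-way confounded with residual).
  tbl1 <- crossed_table(3, 2, 2, 1, sd = c(
    subject = 2, centre = 1, visit = 0.5, sc = 0.3, sv = 0.2, cv = 0.1,
    scv = 0, e = 1
  ), seed = 8)
  vc1 <- estimate_variance_components(tbl1)
  got1 <- setNames(vc1$components$variance_raw, vc1$components$term)
  oracle1 <- ems_oracle(tbl1)
  expect_equal(got1[names(oracle1)], oracle1, tolerance = 1e-10)
  expect_false("subject:centre:visit" %in% names(got1))
})

test_that("noise-free subject-only data attributes all variance to subject", {
  tbl <- crossed_table(5, 3, 2, 2, sd = c(
    subject = 3, centre = 0, visit = 0, sc = 0, sv = 0, cv = 0, scv = 0, e = 0
  ), seed = 3)
  vc <- estimate_variance_components(tbl)
  comp <- setNames(vc$components$variance, vc$components$term)
  raw <- setNames(vc$components$variance_raw, vc$components$term)
  expect_gt(comp["subject"], 0)
  others <- setdiff(names(comp), "subject")
  expect_true(all(raw[others] <= 1e-10))
  expect_true(all(comp[others] == 0))
})

test_that("unbalanced and degenerate designs raise informative errors", {
  tbl <- crossed_table(3, 2, 2, 2)
  expect_error(
    estimate_variance_components(tbl[-1, ]),
    regexp = "REML",
    class = "morphrel_unbalanced_design_error"
  )
  one_centre <- tbl[tbl$centre == "A", ]
  expect_error(
    estimate_variance_components(one_centre),
    class = "morphrel_degenerate_design_error"
  )
})

test_that("reliability implements the variance-ratio identity and boundaries", {
  comps <- c(subject = 3, centre = 1, visit = 0, `subject:centre` = 0,
             `subject:visit` = 0, `centre:visit` = 0, residual = 1)
  r <- reliability(comps, "centre")
  expect_equal(r$value, 0.8, tolerance = 1e-15)
  expect_setequal(r$components_used,
                  c("centre", "subject:centre", "centre:visit"))
  # Factor contributes nothing -> exactly 1.
  expect_identical(
    reliability(c(subject = 2, residual = 1), "centre")$value, 1
  )
  # Factor is the only source -> exactly 0.
  expect_identical(
    reliability(c(centre = 2, `subject:centre` = 1), "centre")$value, 0
  )
  expect_error(reliability(c(subject = 0), "centre"),
               class = "morphrel_domain_error")
  # Identity reliability + V_f/V_t = 1 over random nonnegative mappings.
  set.seed(99)
  for (i in 1:50) {
    v <- stats::runif(8, 0, 10)
    names(v) <- c("subject", "centre", "visit", "subject:centre",
                  "subject:visit", "centre:visit", "subject:centre:visit",
                  "residual")
    for (fac in c("centre", "visit")) {
      r <- reliability(v, fac)
      expect_equal(r$value + r$v_factor / r$v_total, 1, tolerance = 1e-12)
      expect_gte(r$value, 0)
      expect_lte(r$value, 1)
    }
  }
})

test_that("three-way interaction counts toward both factors only when estimable", {
  comps <- c(subject = 1, `subject:centre:visit` = 2, residual = 1)
  expect_setequal(
    reliability(comps, "centre")$components_used, "subject:centre:visit"
  )
  expect_equal(reliability(comps, "centre")$value, 2 / 4, tolerance = 1e-15)
  expect_equal(reliability(comps, "visit")$value, 2 / 4, tolerance = 1e-15)
})

test_that("grades follow the poor/moderate/good/excellent cut points", {
  expect_equal(classify_reliability(0.92), "excellent")
  expect_equal(classify_reliability(0.13), "poor")
  expect_equal(
    classify_reliability(c(0, 0.4999, 0.5, 0.69, 0.7, 0.89, 0.9, 1)),
    c("poor", "poor", "moderate", "moderate", "good", "good",
      "excellent", "excellent")
  )
  expect_error(classify_reliability(1.2), class = "morphrel_domain_error")
  expect_error(classify_reliability(-0.1), class = "morphrel_domain_error")
})

test_that("components and reliabilities are invariant to shift and scale", {
  tbl <- crossed_table(6, 3, 2, 2, sd = c(
    subject = 3, centre = 1, visit = 0.5, sc = 0.5, sv = 0.2, cv = 0.1,
    scv = 0.2, e = 1
  ), seed = 17)
  vc <- estimate_variance_components(tbl)
  r0 <- reliability_pair(vc)$value
  shifted <- tbl
  shifted$value <- shifted$value + 1000
  vs <- estimate_variance_components(shifted)
  expect_equal(vs$components$variance, vc$components$variance,
               tolerance = 1e-10)
  scaled <- tbl
  scaled$value <- scaled$value * 3.7
  vsc <- estimate_variance_components(scaled)
  expect_equal(vsc$components$variance, vc$components$variance * 3.7^2,
               tolerance = 1e-10)
  expect_equal(reliability_pair(vsc)$value, r0, tolerance = 1e-10)
  expect_equal(reliability_pair(vs)$value, r0, tolerance = 1e-10)
})

test_that("method-of-moments agrees with REML on balanced data", {
  n_rep <- 40 # reduced; the 200-replicate check lives in the acceptance suite
  diffs <- matrix(NA_real_, n_rep, 2,
                  dimnames = list(NULL, c("centre", "subject")))
  for (r in seq_len(n_rep)) {
    sim <- simulate_morphometry(
      components = c(subject = 9, centre = 1, visit = 0.25,
                     `subject:centre` = 0.5, residual = 1),
      seed = 5000 + r
    )
    view <- complete_design_view(sim$table, "gm_volume")
    mom <- estimate_variance_components(view)
    momv <- setNames(mom$components$variance, mom$components$term)
    reml <- reml_oracle(view)
    diffs[r, "centre"] <- momv["centre"] - reml["centre"]
    diffs[r, "subject"] <- momv["subject"] - reml["subject"]
  }
  for (term in colnames(diffs)) {
    m <- mean(diffs[, term])
    se <- sd(diffs[, term]) / sqrt(n_rep)
    expect_lt(abs(m), max(4 * se, 0.15))
  }
})

test_that("per-sulcus summaries cover all labels and flag reduced/skipped sulci", {
  sim <- simulate_morphometry(
    n_subjects = 5, grand_mean = 800,
    components = c(subject = 900, centre = 100, residual = 100),
    measure = "sulcal_surface", n_sulci = 6, algorithm = "markovian",
    seed = 44
  )
  tbl <- tibble::as_tibble(sim$table)
  sm <- sulcal_reliability_summary(tbl, "sulcal_surface", "markovian")
  # 6 sulci x 2 hemispheres x 2 factors
  expect_equal(nrow(sm$per_sulcus), 6 * 2 * 2)
  expect_equal(sm$summary$n_sulci, c(12, 12))
  expect_length(sm$skipped, 0)
  # Mean reliability should sit near the analytic truth of the shared
  # generating components.
  truth <- sim$truth$reliability
  for (fac in c("centre", "visit")) {
    got <- sm$summary$mean_reliability[sm$summary$factor == fac]
    expect_lt(abs(got - truth$value[truth$factor == fac]), 0.25)
  }
  # One sulcus missing a subject entirely -> analyzed on reduced set, flagged.
  drop <- tbl$sulcus == "sulcus_01" & tbl$subject == "S01"
  sm2 <- sulcal_reliability_summary(tbl[!drop, ], "sulcal_surface", "markovian")
  flagged <- sm2$per_sulcus[sm2$per_sulcus$sulcus == "sulcus_01", ]
  expect_true(all(flagged$reduced_subjects))
  expect_true(all(flagged$n_subjects == 4))
  # A sulcus observed at a single centre only -> skipped.
  keep <- !(tbl$sulcus == "sulcus_02" & tbl$centre != "A")
  sm3 <- sulcal_reliability_summary(tbl[keep, ], "sulcal_surface", "markovian")
  expect_true(any(grepl("sulcus_02", sm3$skipped)))
})

test_that("covariate residualization removes covariate-driven variance", {
  sim <- simulate_morphometry(
    components = c(subject = 1, residual = 1),
    covariate = list(name = "hemisphere_volume", mean = 640, sd = 40,
                     beta = 0.5),
    seed = 77
  )
  view <- complete_design_view(sim$table, "gm_volume")
  raw_vc <- estimate_variance_components(view)
  adj_vc <- estimate_variance_components(view, covariates = "hemisphere_volume")
  raw_subj <- raw_vc$components$variance[raw_vc$components$term == "subject"]
  adj_subj <- adj_vc$components$variance[adj_vc$components$term == "subject"]
  # Covariate inflates apparent subject variance; adjustment removes it.
  expect_gt(raw_subj, adj_subj)
  expect_lt(abs(adj_subj - 1), 2.5)
  expect_equal(adj_vc$covariates, "hemisphere_volume")
})
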