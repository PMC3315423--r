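test_that("design matrix has the expected columns and centered covariates", {
  tbl <- crossed_table(2, 2, 2, 1, sd = c(
    subject = 1, centre = 0, visit = 0, sc = 0, sv = 0, cv = 0, scv = 0, e = 1
  ))
  dm <- build_design_matrix(tbl, model_spec("gm_volume"))
  expect_equal(dim(dm$X), c(8, 5)) # intercept + subject + centre + visit + c:v
  expect_setequal(
    unique(dm$term),
    c("(Intercept)", "subject", "centre", "visit", "centre:visit")
  )
  set.seed(2)
  tbl$hemisphere_volume <- rnorm(nrow(tbl), 640, 50)
  dm2 <- build_design_matrix(
    tbl, model_spec("gm_volume", covariates = "hemisphere_volume")
  )
  expect_equal(ncol(dm2$X), 6)
  cov_col <- dm2$X[, dm2$term == "hemisphere_volume"]
  expect_equal(mean(cov_col), 0, tolerance = 1e-12)
  # Constant covariate is collinear with the intercept.
  tbl$flat <- 5
  expect_error(
    build_design_matrix(tbl, model_spec("gm_volume", covariates = "flat")),
    class = "morphrel_aliasing_error"
  )
})

test_that("fit_ols matches an explicit normal-equations solve", {
  set.seed(11)
  X <- cbind(1, matrix(rnorm(20 * 4), 20, 4))
  y <- rnorm(20)
  fit <- fit_ols(X, y)
  beta_oracle <- ols_normal_equations(X, y)
  expect_equal(unname(fit$coefficients), as.numeric(beta_oracle),
               tolerance = 1e-8)
  expect_equal(fit$rss, sum((y - X %*% beta_oracle)^2), tolerance = 1e-8)
  # Exact linear combination -> zero residual SS.
  y_exact <- X %*% c(2, -1, 0.5, 3, 0)
  expect_lt(fit_ols(X, as.numeric(y_exact))$rss, 1e-18 * sum(y_exact^2))
  expect_error(fit_ols(X[1:3, ], y[1:3]),
               class = "morphrel_insufficient_data_error")
})

test_that("adjusted and sequential SS coincide on balanced no-covariate designs", {
  tbl <- crossed_table(6, 3, 2, 2, sd = c(
    subject = 3, centre = 1, visit = 0.5, sc = 0, sv = 0, cv = 0.2,
    scv = 0, e = 1
  ), seed = 9)
  adj <- tidy(f_test_effects(tbl, model_spec("gm_volume", ss_type = "adjusted")))
  seq_ <- tidy(f_test_effects(tbl, model_spec("gm_volume", ss_type = "sequential")))
  expect_equal(adj$sumsq, seq_$sumsq, tolerance = 1e-8)
  expect_equal(adj$p_value, seq_$p_value, tolerance = 1e-8)
})

test_that("sequential SS plus residual SS conserve total SS about the mean", {
  tbl <- crossed_table(5, 3, 2, 2, sd = c(
    subject = 2, centre = 1, visit = 0.3, sc = 0.4, sv = 0.1, cv = 0.2,
    scv = 0.1, e = 1
  ), seed = 13)
  spec <- model_spec("gm_volume", ss_type = "sequential")
  dm <- build_design_matrix(tbl, spec)
  full <- fit_ols(dm$X, dm$y)
  # Incremental SS over the full fitting order, computed term by term.
  order_terms <- c("(Intercept)", "subject", "centre", "visit", "centre:visit")
  rss_prev <- sum((dm$y - mean(dm$y))^2)
  ss_seq <- numeric(0)
  for (i in 2:length(order_terms)) {
    keep <- dm$term %in% order_terms[1:i]
    rss_i <- fit_ols(dm$X[, keep, drop = FALSE], dm$y)$rss
    ss_seq <- c(ss_seq, rss_prev - rss_i)
    rss_prev <- rss_i
  }
  total <- sum((dm$y - mean(dm$y))^2)
  expect_equal(sum(ss_seq) + full$rss, total, tolerance = 1e-8 * total)
})

test_that("effect F-tests agree with base anova and with car type-III", {
  tbl <- crossed_table(6, 3, 2, 2, sd = c(
    subject = 3, centre = 1, visit = 0.5, sc = 0, sv = 0, cv = 0.2,
    scv = 0, e = 1
  ), seed = 21)
  ours <- tidy(f_test_effects(tbl, model_spec("gm_volume")))
  df <- data.frame(
    value = tbl$value, subject = factor(tbl$subject),
    centre = factor(tbl$centre), visit = factor(tbl$visit)
  )
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op))
  lmfit <- stats::lm(value ~ subject + centre * visit, data = df)
  a3 <- car::Anova(lmfit, type = 3)
  for (eff in c("centre", "visit", "centre:visit")) {
    expect_equal(
      ours$statistic[ours$effect == eff],
      a3[eff, "F value"],
      tolerance = 1e-8
    )
  }
})

test_that("a large injected centre shift is detected; a null visit is not", {
  sim <- simulate_morphometry(
    components = c(subject = 9, residual = 1),
    fixed_centre_shifts = c(0, 8, -4),
    seed = 31
  )
  view <- complete_design_view(sim$table, "gm_volume")
  out <- tidy(f_test_effects(view, model_spec("gm_volume")))
  expect_lt(out$p_value[out$effect == "centre"], 0.001)
  expect_gt(out$p_value[out$effect == "visit"], 0.05)
})

test_that("degenerate responses raise saturated/degenerate errors", {
  tbl <- crossed_table(3, 2, 2, 2, sd = c(
    subject = 0, centre = 0, visit = 0, sc = 0, sv = 0, cv = 0, scv = 0, e = 0
  ))
  tbl$value <- 100
  expect_error(
    f_test_effects(tbl, model_spec("gm_volume")),
    class = "morphrel_saturated_error"
  )
})

test_that("type-I error of the centre test is near alpha under the null", {
  # Reduced-size calibration run; the full 2000-replicate check lives in
  # the acceptance suite.
  n_rep <- 300
  p <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    sim <- simulate_morphometry(
      n_subjects = 8, components = c(subject = 9, residual = 1),
      seed = 1000 + r
    )
    view <- complete_design_view(sim$table, "gm_volume")
    out <- tidy(f_test_effects(view, model_spec("gm_volume")))
    p[r] <- out$p_value[out$effect == "centre"]
  }
  rate <- mean(p < 0.05)
  expect_lt(abs(rate - 0.05), 0.035) # ~3 MC SDs at n = 300
})
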