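#' Specify the fixed-effects model for centre/visit testing
#'
#' The model always contains an intercept, a subject factor (absorbing
#' between-individual differences), centre, visit and the centre:visit
#' interaction; continuous covariates (cerebral hemisphere volume, and
#' additionally GSI for sulcal measures) enter additively after mean
#' centering.
#'
#' @param response Measure name the model is fitted to.
#' @param covariates Character vector of covariate column names
#'   (default none).
#' @param ss_type `"adjusted"` (drop-one sums of squares, each effect
#'   adjusted for every other term; the default) or `"sequential"`
#'   (incremental in the order subject, covariates, centre, visit,
#'   centre:visit). The two coincide for balanced designs without
#'   covariates.
#' @param alpha Significance level used to flag effects (default 0.05).
#' @param hemisphere `"replicate"` (hemisphere observations pooled as
#'   replicates within each subject x centre x visit cell, the default)
#'   or `"factor"` (a hemisphere main effect is added).
#' @return A list of class `morph_model_spec`.
#' @export
model_spec <- function(response, covariates = character(0),
                       ss_type = c("adjusted", "sequential"),
                       alpha = 0.05,
                       hemisphere = c("replicate", "factor")) {
  ss_type <- match.arg(ss_type)
  hemisphere <- match.arg(hemisphere)
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0, alpha < 1)
  structure(
    list(
      response = response, covariates = as.character(covariates),
      ss_type = ss_type, alpha = alpha, hemisphere = hemisphere
    ),
    class = "morph_model_spec"
  )
}

# Term labels in fitting order. Subject first so that sequential SS
# adjust the scanner effects for between-individual differences.
model_terms <- function(spec) {
  c(
    "subject",
    if (spec$hemisphere == "factor") "hemisphere",
    spec$covariates,
    "centre", "visit", "centre:visit"
  )
}

#' Build the design matrix for the fixed-effects model
#'
#' Encodes intercept, sum-to-zero (deviation) contrasts for subject,
#' centre, visit and the centre:visit interaction, plus mean-centered
#' covariate columns, and fails with an aliasing error if the encoding
#' is rank deficient. Deviation coding makes the drop-one sums of
#' squares well defined in the presence of the interaction (the
#' Type-III convention); on balanced designs without covariates they
#' coincide with the sequential sums of squares.
#'
#' @param data A complete-design view of one measure (rows of a
#'   morphometry table, one observation per row).
#' @param spec A [model_spec()].
#' @return A list with `X` (design matrix), `y` (response), `term`
#'   (character vector mapping columns to model terms) and `spec`.
#' @export
build_design_matrix <- function(data, spec) {
  tbl <- tibble::as_tibble(data)
  stopifnot(nrow(tbl) > 0)
  for (cov in spec$covariates) {
    if (!(cov %in% names(tbl))) {
      abort(paste0("covariate column not found: ", cov), class = "morphrel_schema_error")
    }
  }
  df <- data.frame(
    subject = factor(tbl$subject),
    centre = factor(tbl$centre),
    visit = factor(tbl$visit)
  )
  if (spec$hemisphere == "factor") df$hemisphere <- factor(tbl$hemisphere)
  for (cov in spec$covariates) {
    df[[cov]] <- tbl[[cov]] - mean(tbl[[cov]])
  }
  fml <- stats::reformulate(model_terms(spec))
  fac_cols <- names(df)[vapply(df, is.factor, TRUE)]
  X <- stats::model.matrix(
    fml, data = df,
    contrasts.arg = setNames(
      replicate(length(fac_cols), stats::contr.sum, simplify = FALSE), fac_cols
    )
  )
  term_of_col <- attr(X, "assign")
  labels <- c("(Intercept)", attr(stats::terms(fml, data = df), "term.labels"))
  term <- labels[term_of_col + 1L]
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    abort(
      paste0("design matrix is rank deficient; aliased column(s): ",
             paste(aliased, collapse = ", ")),
      class = "morphrel_aliasing_error"
    )
  }
  list(X = X, y = tbl$value, term = term, spec = spec)
}

#' Ordinary least squares fit
#'
#' QR-based least-squares solve returning coefficients, residual sum of
#' squares and residual degrees of freedom.
#'
#' @param X Full-rank numeric design matrix.
#' @param y Response vector, `length(y) == nrow(X)`.
#' @return A list with `coefficients`, `rss`, `df_residual`, `fitted`,
#'   `residuals`.
#' @export
fit_ols <- function(X, y) {
  stopifnot(is.matrix(X), length(y) == nrow(X))
  if (nrow(X) < ncol(X)) {
    abort("fewer observations than model columns", class = "morphrel_insufficient_data_error")
  }
  fit <- lm.fit(X, y)
  if (fit$rank < ncol(X)) {
    abort("design matrix is rank deficient", class = "morphrel_aliasing_error")
  }
  rss <- sum(fit$residuals^2)
  list(
    coefficients = fit$coefficients,
    rss = rss,
    df_residual = nrow(X) - ncol(X),
    fitted = fit$fitted.values,
    residuals = fit$residuals
  )
}

#' F-tests for centre, visit and their interaction
#'
#' Fits the fixed-effects ANCOVA (subject + covariates + centre + visit
#' + centre:visit) and tests each scanner-related effect with
#' `F = (dSS/ddf) / MSE`, where `MSE` is the full-model residual mean
#' square and `dSS` is either the drop-one sum of squares (each term
#' adjusted for all others, `ss_type = "adjusted"`) or the incremental
#' sum of squares in fitting order (`ss_type = "sequential"`). P-values
#' are reported unadjusted for multiple testing.
#'
#' @param data A complete-design view of one measure (e.g. from
#'   [complete_design_view()]), with covariate columns if the spec
#'   names any.
#' @param spec A [model_spec()]; a bare measure name is promoted to a
#'   covariate-free spec.
#' @return An object of class `morph_anova`: the effect table is
#'   available via [tidy()], fit summaries via [glance()].
#' @export
f_test_effects <- function(data, spec) {
  if (is.character(spec)) spec <- model_spec(spec)
  dm <- build_design_matrix(data, spec)
  full <- fit_ols(dm$X, dm$y)
  if (full$df_residual <= 0) {
    abort("saturated model: no residual degrees of freedom", class = "morphrel_saturated_error")
  }
  mse <- full$rss / full$df_residual
  if (mse <= .Machine$double.eps * max(1, mean(dm$y)^2)) {
    abort(
      "degenerate fit: residual mean square is zero (constant or exactly-fitted response)",
      class = "morphrel_saturated_error"
    )
  }
  effects <- c("centre", "visit", "centre:visit")
  rows <- purrr::map(effects, function(eff) {
    cols <- dm$term == eff
    ddf <- sum(cols)
    if (spec$ss_type == "adjusted") {
      reduced <- fit_ols(dm$X[, !cols, drop = FALSE], dm$y)
      dss <- reduced$rss - full$rss
    } else {
      order_terms <- c("(Intercept)", model_terms(spec))
      upto <- seq_len(match(eff, order_terms))
      with_term <- dm$term %in% order_terms[upto]
      without_term <- dm$term %in% order_terms[upto[-length(upto)]]
      dss <- fit_ols(dm$X[, without_term, drop = FALSE], dm$y)$rss -
        fit_ols(dm$X[, with_term, drop = FALSE], dm$y)$rss
    }
    dss <- max(dss, 0)
    Fstat <- (dss / ddf) / mse
    tibble::tibble(
      effect = eff, sumsq = dss, df = ddf, df_denom = full$df_residual,
      statistic = Fstat, p_value = pf(Fstat, ddf, full$df_residual, lower.tail = FALSE)
    )
  })
  tab <- dplyr::bind_rows(rows) |>
    dplyr::mutate(significant = .data$p_value < spec$alpha)
  structure(
    list(
      effects = tab, spec = spec, rss = full$rss,
      df_residual = full$df_residual, mse = mse,
      n_obs = length(dm$y),
      total_ss = sum((dm$y - mean(dm$y))^2)
    ),
    class = "morph_anova"
  )
}

#' @export
print.morph_anova <- function(x, ...) {
  cat(sprintf(
    "ANCOVA for '%s' (%s SS, alpha = %g)\n",
    x$spec$response, x$spec$ss_type, x$spec$alpha
  ))
  tab <- x$effects
  tab$p <- format_p_value(tab$p_value)
  print(as.data.frame(tab[c("effect", "df", "statistic", "p", "significant")]),
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' @rdname f_test_effects
#' @param x A `morph_anova` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.morph_anova <- function(x, ...) {
  x$effects
}

#' @rdname f_test_effects
#' @exportS3Method generics::glance
glance.morph_anova <- function(x, ...) {
  tibble::tibble(
    nobs = x$n_obs,
    df_residual = x$df_residual,
    rss = x$rss,
    sigma = sqrt(x$mse),
    r_squared = 1 - x$rss / x$total_ss
  )
}

#' Format p-values the way reliability reports print them
#'
#' Values below 0.001 are shown as `"< 0.001"`, others to three
#' decimals.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
format_p_value <- function(p) {
  ifelse(p < 0.001, "< 0.001", sprintf("%.3f", p))
}
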