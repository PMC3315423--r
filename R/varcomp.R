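#' Variance components of the crossed subject x centre x visit design
#'
#' Decomposes one measure's variability into components for subject,
#' centre, visit, their two-way interactions, the three-way interaction
#' (when within-cell replicates make it estimable) and residual, using
#' the method of moments for balanced designs: the classical ANOVA sums
#' of squares are computed for every term of the fully crossed random
#' model and the expected-mean-squares (EMS) linear system is solved for
#' the component variances. Raw solutions may be negative; they are
#' retained for transparency and clamped to zero in the working
#' estimates (`variance` column).
#'
#' When `hemisphere = "replicate"` (default) the left/right hemisphere
#' observations act as replicates within each subject x centre x visit
#' cell, so the three-way subject:centre:visit component is estimable.
#' With a single observation per cell the three-way interaction is
#' confounded with residual error and the combined term is reported as
#' `residual`.
#'
#' If `covariates` are named, values are first residualized against them
#' with a pooled least-squares fit (the grand mean is added back), so
#' the decomposition applies to covariate-adjusted values; this choice
#' is recorded in the object's metadata.
#'
#' @param data A complete-design view of one measure (e.g. from
#'   [complete_design_view()]); must be balanced.
#' @param covariates Optional character vector of covariate columns to
#'   residualize against before decomposition.
#' @param hemisphere `"replicate"` to pool hemispheres as within-cell
#'   replicates (default). Any other per-row replicate structure is
#'   taken as-is from the row multiplicity per cell.
#' @return An object of class `morph_varcomp`. Use [tidy()] for the
#'   component table and [glance()] for totals and reliabilities.
#' @export
estimate_variance_components <- function(data, covariates = NULL,
                                         hemisphere = "replicate") {
  tbl <- tibble::as_tibble(data)
  stopifnot(nrow(tbl) > 0)
  factors <- c("subject", "centre", "visit")
  levels_n <- vapply(factors, function(f) length(unique(tbl[[f]])), 1L)
  if (any(levels_n < 2)) {
    abort(
      paste0("factor(s) with a single level: ",
             paste(factors[levels_n < 2], collapse = ", ")),
      class = "morphrel_degenerate_design_error"
    )
  }
  cell_counts <- tbl |>
    dplyr::count(.data$subject, .data$centre, .data$visit)
  n_rep <- unique(cell_counts$n)
  if (length(n_rep) != 1 ||
      nrow(cell_counts) != prod(levels_n)) {
    abort(
      paste0(
        "unbalanced design: every subject x centre x visit cell must hold the ",
        "same number of observations; use a REML mixed model (e.g. lme4) for ",
        "unbalanced data"
      ),
      class = "morphrel_unbalanced_design_error"
    )
  }

  y <- tbl$value
  resid_meta <- NULL
  if (!is.null(covariates) && length(covariates) > 0) {
    for (cov in covariates) {
      if (!(cov %in% names(tbl))) {
        abort(paste0("covariate column not found: ", cov), class = "morphrel_schema_error")
      }
    }
    Z <- cbind(1, as.matrix(tbl[covariates]))
    fit <- lm.fit(Z, y)
    y <- fit$residuals + mean(tbl$value)
    resid_meta <- covariates
  }
  tbl$.y <- y

  comps <- ems_decompose(tbl, factors, levels_n, n_rep)

  structure(
    list(
      components = comps$table,
      n_levels = setNames(as.integer(levels_n), factors),
      n_replicates = n_rep,
      covariates = resid_meta,
      grand_mean = mean(y)
    ),
    class = "morph_varcomp"
  )
}

# Balanced ANOVA decomposition + EMS solve. Terms are all non-empty
# subsets of the factors; with n_rep == 1 the full interaction is the
# residual stratum (its variance confounded with error).
ems_decompose <- function(tbl, factors, levels_n, n_rep) {
  k <- length(factors)
  subsets <- purrr::map(seq_len(2^k - 1), function(i) {
    factors[bitwAnd(i, 2^(seq_len(k) - 1)) > 0]
  })
  term_label <- vapply(subsets, paste, "", collapse = ":")
  has_rep <- n_rep > 1
  # With replicates the full interaction is a real term; without, it is
  # the error stratum.
  full_idx <- which(lengths(subsets) == k)
  comp_subsets <- if (has_rep) subsets else subsets[-full_idx]
  comp_labels <- if (has_rep) term_label else term_label[-full_idx]

  mean_by <- function(fs) {
    if (length(fs) == 0) {
      return(mean(tbl$.y))
    }
    agg <- tbl |>
      dplyr::group_by(dplyr::across(dplyr::all_of(fs))) |>
      dplyr::summarise(.m = mean(.data$.y), .groups = "drop")
    agg
  }
  grand <- mean(tbl$.y)
  cell_means <- purrr::map(subsets, mean_by)

  # Inclusion-exclusion effect estimates per term, on the term's own
  # index grid; SS_T = n_rep * prod(levels not in T) * sum(effect^2).
  ss <- numeric(length(subsets))
  df <- numeric(length(subsets))
  for (ti in seq_along(subsets)) {
    T <- subsets[[ti]]
    grid <- cell_means[[ti]][T]
    eff <- rep(-0, nrow(grid))
    for (ui in c(0L, seq_along(subsets))) {
      U <- if (ui == 0L) character(0) else subsets[[ui]]
      if (!all(U %in% T)) next
      sign <- (-1)^(length(T) - length(U))
      if (length(U) == 0) {
        eff <- eff + sign * grand
      } else {
        m <- cell_means[[ui]]
        idx <- match(
          do.call(paste, c(grid[U], sep = "\r")),
          do.call(paste, c(m[U], sep = "\r"))
        )
        eff <- eff + sign * m$.m[idx]
      }
    }
    mult <- n_rep * prod(levels_n[setdiff(factors, T)])
    ss[ti] <- mult * sum(eff^2)
    df[ti] <- prod(levels_n[T] - 1)
  }
  ss_total <- sum((tbl$.y - grand)^2)
  ss_resid <- ss_total - sum(ss)
  df_resid <- prod(levels_n) * (n_rep - 1)
  if (!has_rep) {
    ss_resid <- ss[full_idx]
    df_resid <- df[full_idx]
    ss <- ss[-full_idx]
    df <- df[-full_idx]
  }
  ms <- ss / df
  ms_resid <- ss_resid / df_resid

  # EMS coefficient matrix: E(MS_T) = sigma2_e + sum over supersets U of
  # n_rep * prod(levels of factors outside U) * sigma2_U.
  p <- length(comp_subsets)
  M <- matrix(0, nrow = p + 1, ncol = p + 1,
              dimnames = list(c(comp_labels, "residual"), c(comp_labels, "residual")))
  for (ti in seq_len(p)) {
    for (ui in seq_len(p)) {
      if (all(comp_subsets[[ti]] %in% comp_subsets[[ui]])) {
        M[ti, ui] <- n_rep * prod(levels_n[setdiff(factors, comp_subsets[[ui]])])
      }
    }
    M[ti, p + 1] <- 1
  }
  M[p + 1, p + 1] <- 1
  raw <- solve(M, c(ms, ms_resid))

  list(table = tibble::tibble(
    term = c(comp_labels, "residual"),
    df = c(df, df_resid),
    sumsq = c(ss, ss_resid),
    meansq = c(ms, ms_resid),
    variance_raw = as.numeric(raw),
    variance = pmax(as.numeric(raw), 0)
  ))
}

#' @export
print.morph_varcomp <- function(x, ...) {
  cat(sprintf(
    "Variance components (%d x %d x %d design, %d replicate(s)/cell)\n",
    x$n_levels[1], x$n_levels[2], x$n_levels[3], x$n_replicates
  ))
  if (!is.null(x$covariates)) {
    cat("Values residualized against:", paste(x$covariates, collapse = ", "), "\n")
  }
  print(as.data.frame(x$components), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @rdname estimate_variance_components
#' @param x A `morph_varcomp` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.morph_varcomp <- function(x, ...) {
  x$components
}

#' @rdname estimate_variance_components
#' @exportS3Method generics::glance
glance.morph_varcomp <- function(x, ...) {
  tibble::tibble(
    v_total = sum(x$components$variance),
    n_terms = nrow(x$components),
    reliability_centre = reliability(x, "centre")$value,
    reliability_visit = reliability(x, "visit")$value
  )
}

#' Between-centre or between-visit reliability
#'
#' The reliability associated with a factor is the fraction of the total
#' variance not attributable to that factor:
#' `(V_total - V_factor) / V_total`, where `V_total` is the sum of all
#' (truncated) variance components and `V_factor` is the sum of the
#' factor's own component and every interaction component whose term
#' contains the factor (subject:factor, centre:visit, and the three-way
#' interaction when estimable). A value of 1 means the factor
#' contributes negligible variance; 0 means it is the only source.
#'
#' @param components Either a `morph_varcomp` object or a named numeric
#'   vector/list of nonnegative variances (names as in the component
#'   table, e.g. `c(subject = 3, centre = 1, residual = 1)`).
#' @param factor `"centre"` or `"visit"`.
#' @return A list of class `morph_reliability` with `factor`, `value`,
#'   `grade`, `components_used`, `v_factor`, `v_total`.
#' @export
reliability <- function(components, factor = c("centre", "visit")) {
  factor <- match.arg(factor)
  if (inherits(components, "morph_varcomp")) {
    vals <- setNames(components$components$variance, components$components$term)
  } else {
    vals <- unlist(components)
  }
  if (any(vals < 0)) {
    abort("variance components must be nonnegative", class = "morphrel_domain_error")
  }
  v_total <- sum(vals)
  if (v_total <= 0) {
    abort("total variance is zero; reliability undefined", class = "morphrel_domain_error")
  }
  used <- names(vals)[vapply(
    strsplit(names(vals), ":", fixed = TRUE),
    function(parts) factor %in% parts, TRUE
  )]
  v_factor <- sum(vals[used])
  value <- (v_total - v_factor) / v_total
  structure(
    list(
      factor = factor, value = value,
      grade = classify_reliability(value),
      components_used = used, v_factor = v_factor, v_total = v_total
    ),
    class = "morph_reliability"
  )
}

#' @export
print.morph_reliability <- function(x, ...) {
  cat(sprintf(
    "Between-%s reliability: %.2f (%s)\n", x$factor, x$value, x$grade
  ))
  invisible(x)
}

#' @rdname reliability
#' @param x A `morph_reliability` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.morph_reliability <- function(x, ...) {
  tibble::tibble(
    factor = x$factor, value = x$value, grade = x$grade,
    v_factor = x$v_factor, v_total = x$v_total
  )
}

#' Grade a reliability value
#'
#' Applies the conventional rule of thumb: values below 0.50 are poor,
#' 0.50 to below 0.70 moderate, 0.70 to below 0.90 good, and 0.90 and
#' above excellent. Intervals are left-closed so every value in `[0, 1]`
#' receives exactly one grade.
#'
#' @param value Numeric vector of reliabilities in `[0, 1]`.
#' @return Character vector of grades.
#' @export
classify_reliability <- function(value) {
  if (!is.numeric(value) || any(!is.finite(value)) ||
      any(value < 0) || any(value > 1)) {
    abort("reliability must lie in [0, 1]", class = "morphrel_domain_error")
  }
  cut_points <- c(0, 0.5, 0.7, 0.9, Inf)
  grades <- c("poor", "moderate", "good", "excellent")
  grades[findInterval(value, cut_points, left.open = FALSE)]
}

#' Reliability pair for one variance decomposition
#'
#' Convenience wrapper returning the between-centre and between-visit
#' reliabilities of a `morph_varcomp` as a two-row tibble.
#'
#' @param components A `morph_varcomp` object or named variance vector.
#' @return A tibble with columns `factor`, `value`, `grade`,
#'   `v_factor`, `v_total`.
#' @export
reliability_pair <- function(components) {
  dplyr::bind_rows(
    tidy(reliability(components, "centre")),
    tidy(reliability(components, "visit"))
  )
}

#' Per-sulcus reliabilities and across-sulcus averages
#'
#' Sulcal measures vary hugely between sulci, so reliability is
#' estimated independently per sulcus label and hemisphere (each
#' analyzed as a subject x centre x visit design with one observation
#' per cell), then summarised as the unweighted mean across sulci.
#' Sulci whose design cannot be validated (no complete subject, or a
#' single-level factor) are listed as skipped; sulci analyzed on a
#' reduced subject set (some subjects incomplete) are flagged.
#'
#' @param data A morphometry table containing sulcal records.
#' @param measure `"sulcal_surface"` or `"sulcal_depth"`.
#' @param algorithm Recognition algorithm to analyze (one of
#'   `"talairach"`, `"global"`, `"local"`, `"markovian"`).
#' @param covariates Optional covariate columns passed to
#'   [estimate_variance_components()].
#' @return A list of class `morph_sulcal_summary`: `per_sulcus` (one
#'   row per sulcus x hemisphere x factor), `summary` (mean reliability
#'   per factor), `skipped` (labels that failed validation).
#' @export
sulcal_reliability_summary <- function(data, measure, algorithm,
                                       covariates = NULL) {
  stopifnot(measure %in% SULCAL_MEASURES, algorithm %in% ALGORITHMS)
  tbl <- tibble::as_tibble(data) |>
    dplyr::filter(.data$measure == !!measure, .data$algorithm == !!algorithm)
  if (nrow(tbl) == 0) {
    abort(
      paste0("no records for measure '", measure, "' with algorithm '", algorithm, "'"),
      class = "morphrel_empty_summary_error"
    )
  }
  units <- tbl |> dplyr::distinct(.data$sulcus, .data$hemisphere)
  n_all_subjects <- length(unique(tbl$subject))
  skipped <- character(0)
  rows <- purrr::pmap(units, function(sulcus, hemisphere) {
    sub <- tbl[tbl$sulcus == sulcus & tbl$hemisphere == hemisphere, ]
    res <- tryCatch(
      {
        des <- validate_design(sub, measure, sulcus = sulcus)
        view <- sub[sub$subject %in% des$subjects, ]
        vc <- estimate_variance_components(view, covariates = covariates)
        pair <- reliability_pair(vc)
        pair$sulcus <- sulcus
        pair$hemisphere <- hemisphere
        pair$n_subjects <- des$n_subjects
        # Reduced relative to the full cohort of the table, whether the
        # subject had partial coverage or no record at all.
        pair$reduced_subjects <- des$n_subjects < n_all_subjects
        pair
      },
      error = function(e) NULL
    )
    if (is.null(res)) {
      skipped <<- c(skipped, paste0(sulcus, "/", hemisphere))
    }
    res
  })
  per_sulcus <- dplyr::bind_rows(rows)
  if (nrow(per_sulcus) == 0) {
    abort("no sulcus passed design validation", class = "morphrel_empty_summary_error")
  }
  per_sulcus <- per_sulcus |>
    dplyr::select(
      "sulcus", "hemisphere", "factor", "value", "grade",
      "n_subjects", "reduced_subjects"
    )
  summary <- per_sulcus |>
    dplyr::group_by(.data$factor) |>
    dplyr::summarise(
      mean_reliability = mean(.data$value),
      n_sulci = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(measure = !!measure, algorithm = !!algorithm, .before = 1)
  structure(
    list(per_sulcus = per_sulcus, summary = summary, skipped = skipped,
         measure = measure, algorithm = algorithm),
    class = "morph_sulcal_summary"
  )
}

#' @export
print.morph_sulcal_summary <- function(x, ...) {
  cat(sprintf("Sulcal reliability summary: %s / %s\n", x$measure, x$algorithm))
  print(as.data.frame(x$summary), row.names = FALSE, digits = 3)
  if (length(x$skipped) > 0) {
    cat("Skipped (failed validation):", paste(x$skipped, collapse = ", "), "\n")
  }
  invisible(x)
}
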