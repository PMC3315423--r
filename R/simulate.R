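VC_TERMS <- c(
  "subject", "centre", "visit",
  "subject:centre", "subject:visit", "centre:visit",
  "subject:centre:visit", "residual"
)

# Deterministic sub-stream seed per random term, so enlarging one part
# of the design leaves the other terms' draws unchanged.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + 97 * k) %% 2147483629)
}

normalize_components <- function(components) {
  components <- unlist(components)
  unknown <- setdiff(names(components), VC_TERMS)
  if (length(unknown) > 0) {
    abort(
      paste0("unknown variance component term(s): ", paste(unknown, collapse = ", ")),
      class = "morphrel_domain_error"
    )
  }
  if (any(components < 0)) {
    abort("variance components must be nonnegative", class = "morphrel_domain_error")
  }
  full <- setNames(numeric(length(VC_TERMS)), VC_TERMS)
  full[names(components)] <- components
  full
}

#' Analytic reliabilities implied by a set of variance components
#'
#' Applies the reliability definition directly to known (generating)
#' component variances: `(V_total - V_factor) / V_total`, with the
#' factor's own variance plus every interaction containing it counted
#' in `V_factor`.
#'
#' @param components Named nonnegative variances (terms as in
#'   [estimate_variance_components()]).
#' @return A tibble with one row per factor (`centre`, `visit`).
#' @export
analytic_reliability <- function(components) {
  reliability_pair(normalize_components(components))
}

#' Simulate a balanced crossed morphometry table
#'
#' Generates `value(s, c, v, h) = grand_mean + shift_c + A_s + B_c +
#' C_v + AB_sc + AC_sv + BC_cv + ABC_scv + e_scvh`, each random term
#' drawn independently Gaussian with its specified variance and shared
#' across the design as the crossed model requires (e.g. the centre
#' effect `B_c` is identical for every subject and visit at centre
#' `c`). Defaults mirror a multicentre test-retest study: 13 subjects
#' x 3 centres x 2 visits x 2 hemispheres (the 1.5 T-style group; use
#' 11 x 5 for a 3 T-style group).
#'
#' Optionally a subject-level covariate (e.g. cerebral hemisphere
#' volume) is generated and `beta * (covariate - mean)` added to the
#' response; and with `n_sulci` set, the same additive model is drawn
#' independently per sulcus label with per-sulcus grand means drawn
#' once (log-normal around `grand_mean`), emulating the large
#' between-sulcus size differences of real sulcal measures.
#'
#' @param n_subjects,n_centres,n_visits,n_hemispheres Design sizes
#'   (defaults 13, 3, 2, 2).
#' @param grand_mean Mean response in measure units (default 300, a
#'   typical hemisphere tissue volume in cm^3).
#' @param components Named nonnegative variances for the random terms
#'   (`subject`, `centre`, `visit`, `subject:centre`, `subject:visit`,
#'   `centre:visit`, `subject:centre:visit`, `residual`); omitted terms
#'   are zero.
#' @param fixed_centre_shifts Optional numeric vector (length
#'   `n_centres`) of systematic per-centre offsets, for injecting a
#'   fixed centre effect.
#' @param fixed_visit_shifts Optional numeric vector (length
#'   `n_visits`) of systematic per-visit offsets.
#' @param covariate Optional list `list(name=, mean=, sd=, beta=)`
#'   describing a subject x hemisphere covariate and its slope.
#' @param measure Measure label for the records (default
#'   `"gm_volume"`; with `n_sulci` set, a sulcal measure).
#' @param n_sulci Optional number of sulcus labels for sulcal
#'   simulation.
#' @param sulcus_log_sd SD of the log-normal per-sulcus grand-mean
#'   multipliers (default 0.4).
#' @param algorithm Algorithm label for sulcal records.
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A list with `table` (a validated `morph_table`) and `truth`
#'   (generating components, fixed shifts, analytic reliabilities and
#'   the per-level random draws).
#' @export
simulate_morphometry <- function(n_subjects = 13, n_centres = 3,
                                 n_visits = 2, n_hemispheres = 2,
                                 grand_mean = 300,
                                 components = c(subject = 9, residual = 1),
                                 fixed_centre_shifts = NULL,
                                 fixed_visit_shifts = NULL,
                                 covariate = NULL,
                                 measure = "gm_volume",
                                 n_sulci = NULL,
                                 sulcus_log_sd = 0.4,
                                 algorithm = "global",
                                 seed = 1L) {
  stopifnot(
    n_subjects >= 1, n_centres >= 1, n_visits >= 1, n_hemispheres >= 1,
    measure %in% MEASURES
  )
  comp <- normalize_components(components)
  if (!is.null(fixed_centre_shifts)) stopifnot(length(fixed_centre_shifts) == n_centres)
  if (!is.null(fixed_visit_shifts)) stopifnot(length(fixed_visit_shifts) == n_visits)

  subjects <- sprintf("S%02d", seq_len(n_subjects))
  centres <- LETTERS[seq_len(n_centres)]
  visits <- seq_len(n_visits)
  hemis <- HEMISPHERES[seq_len(min(n_hemispheres, 2))]
  if (n_hemispheres > 2) hemis <- HEMISPHERES # at most left/right supported
  sulci <- if (!is.null(n_sulci)) sprintf("sulcus_%02d", seq_len(n_sulci)) else NA_character_

  draw_term <- function(k, n, sigma2) {
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
      add = TRUE
    )
    set.seed(derive_seed(seed, k))
    if (sigma2 > 0) rnorm(n, 0, sqrt(sigma2)) else numeric(n)
  }

  one_block <- function(block_idx, block_mean, sulcus_label) {
    off <- block_idx * 20L
    A <- setNames(draw_term(off + 1L, n_subjects, comp["subject"]), subjects)
    B <- setNames(draw_term(off + 2L, n_centres, comp["centre"]), centres)
    C <- setNames(draw_term(off + 3L, n_visits, comp["visit"]), as.character(visits))
    grid_sc <- expand.grid(subject = subjects, centre = centres,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid_sv <- expand.grid(subject = subjects, visit = visits,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid_cv <- expand.grid(centre = centres, visit = visits,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid_scv <- expand.grid(subject = subjects, centre = centres, visit = visits,
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    AB <- draw_term(off + 4L, nrow(grid_sc), comp["subject:centre"])
    AC <- draw_term(off + 5L, nrow(grid_sv), comp["subject:visit"])
    BC <- draw_term(off + 6L, nrow(grid_cv), comp["centre:visit"])
    ABC <- draw_term(off + 7L, nrow(grid_scv), comp["subject:centre:visit"])

    rows <- expand.grid(
      hemisphere = hemis, visit = visits, centre = centres, subject = subjects,
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    key <- function(...) do.call(paste, c(list(...), sep = "\r"))
    e <- draw_term(off + 8L, nrow(rows), comp["residual"])
    value <- block_mean +
      A[rows$subject] + B[rows$centre] + C[as.character(rows$visit)] +
      AB[match(key(rows$subject, rows$centre), key(grid_sc$subject, grid_sc$centre))] +
      AC[match(key(rows$subject, rows$visit), key(grid_sv$subject, grid_sv$visit))] +
      BC[match(key(rows$centre, rows$visit), key(grid_cv$centre, grid_cv$visit))] +
      ABC[match(key(rows$subject, rows$centre, rows$visit),
                key(grid_scv$subject, grid_scv$centre, grid_scv$visit))] +
      e
    if (!is.null(fixed_centre_shifts)) {
      value <- value + fixed_centre_shifts[match(rows$centre, centres)]
    }
    if (!is.null(fixed_visit_shifts)) {
      value <- value + fixed_visit_shifts[match(rows$visit, visits)]
    }
    tbl <- tibble::tibble(
      subject = rows$subject, centre = rows$centre,
      visit = as.integer(rows$visit), hemisphere = rows$hemisphere,
      measure = measure,
      sulcus = sulcus_label,
      algorithm = if (is.na(sulcus_label)) NA_character_ else algorithm,
      value = as.numeric(value)
    )
    list(table = tbl, draws = list(subject = A, centre = B, visit = C))
  }

  if (is.null(n_sulci)) {
    blocks <- list(one_block(0L, grand_mean, NA_character_))
    sulcus_means <- NULL
  } else {
    if (!(measure %in% SULCAL_MEASURES)) {
      abort("n_sulci requires a sulcal measure", class = "morphrel_domain_error")
    }
    mult <- {
      old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
      set.seed(derive_seed(seed, 999983L))
      m <- exp(rnorm(length(sulci), 0, sulcus_log_sd))
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      m
    }
    sulcus_means <- setNames(grand_mean * mult, sulci)
    blocks <- purrr::imap(sulci, function(s, i) one_block(i, sulcus_means[[s]], s))
  }
  tab <- dplyr::bind_rows(purrr::map(blocks, "table"))

  cov_truth <- NULL
  if (!is.null(covariate)) {
    stopifnot(all(c("name", "mean", "sd", "beta") %in% names(covariate)))
    grid_sh <- expand.grid(subject = subjects, hemisphere = hemis,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    cov_vals <- covariate$mean + draw_term(499979L, nrow(grid_sh), covariate$sd^2)
    idx <- match(
      paste(tab$subject, tab$hemisphere, sep = "\r"),
      paste(grid_sh$subject, grid_sh$hemisphere, sep = "\r")
    )
    tab[[covariate$name]] <- cov_vals[idx]
    tab$value <- tab$value + covariate$beta * (cov_vals[idx] - covariate$mean)
    cov_truth <- covariate
  }

  list(
    table = morphometry_table(tab, max_visits = n_visits),
    truth = list(
      components = comp,
      grand_mean = grand_mean,
      fixed_centre_shifts = fixed_centre_shifts,
      fixed_visit_shifts = fixed_visit_shifts,
      covariate = cov_truth,
      sulcus_means = sulcus_means,
      reliability = if (sum(comp) > 0) {
        analytic_reliability(comp)
      } else {
        # Fully degenerate generator: no variance, reliability undefined.
        tibble::tibble(
          factor = c("centre", "visit"), value = NA_real_,
          grade = NA_character_, v_factor = 0, v_total = 0
        )
      },
      draws = blocks[[1]]$draws,
      seed = seed
    )
  )
}

#' Simulate a 3-D tissue phantom with noise and bias field
#'
#' Builds a deterministic concentric-ellipsoid geometry (WM core, GM
#' shell, CSF outer shell, zero background), assigns each tissue its
#' mean grey level, multiplies by a smooth bias field `1 + alpha * g(x)`
#' with `g` in `[-1, 1]`, and adds Gaussian noise. With
#' `bias_amplitude = 0` the phantom is bias-free; with zero noise each
#' tissue is perfectly uniform.
#'
#' Two field shapes are available: `"cosine"`, a separable product of
#' slowly varying per-axis cosine profiles (low-frequency, zero-mean
#' modulation at the default one cycle per axis), and `"radial"`,
#' increasing from the centre outwards (a surface-coil-like
#' inhomogeneity that inflates outer tissues more than the core).
#'
#' @param shape Integer extents of the volume (default `c(64, 64, 64)`).
#' @param tissue_means Named grey levels, `c(wm=, gm=, csf=)`; for a
#'   T1-like phantom `wm > gm > csf` (default 150, 100, 40).
#' @param noise_sd Global noise SD, or a named per-tissue vector.
#' @param bias_amplitude Bias amplitude `alpha >= 0` (default 0).
#' @param bias_profile `"cosine"` (default) or `"radial"`.
#' @param bias_scale Spatial frequency of the cosine profile in cycles
#'   across each axis (default 1, one full cycle).
#' @param radii Named fractional ellipsoid radii (of the half-extent)
#'   for the tissue boundaries, default `c(wm=0.55, gm=0.75, csf=0.92)`;
#'   must be increasing.
#' @param seed Integer seed for the noise draw.
#' @return A list with `volume` (3-D array), `masks` (named list of
#'   logical arrays), and `truth` (tissue means, noise, analytic
#'   noiseless contrast `wm/gm`, voxel counts, bias parameters).
#' @export
simulate_phantom <- function(shape = c(64, 64, 64),
                             tissue_means = c(wm = 150, gm = 100, csf = 40),
                             noise_sd = 0,
                             bias_amplitude = 0,
                             bias_profile = c("cosine", "radial"),
                             bias_scale = 1,
                             radii = c(wm = 0.55, gm = 0.75, csf = 0.92),
                             seed = 1L) {
  bias_profile <- match.arg(bias_profile)
  stopifnot(
    length(shape) == 3, all(shape >= 4),
    all(c("wm", "gm", "csf") %in% names(tissue_means)),
    all(tissue_means > 0),
    all(c("wm", "gm", "csf") %in% names(radii)),
    bias_amplitude >= 0
  )
  if (!(radii["wm"] < radii["gm"] && radii["gm"] < radii["csf"] && radii["csf"] <= 1)) {
    abort("radii must satisfy wm < gm < csf <= 1", class = "morphrel_geometry_error")
  }
  ax <- purrr::map(shape, function(n) {
    c_n <- (n + 1) / 2
    ((seq_len(n) - c_n) / ((n - 1) / 2)) # in [-1, 1]
  })
  rr <- sqrt(
    outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  )
  masks <- list(
    wm = rr <= radii["wm"],
    gm = rr > radii["wm"] & rr <= radii["gm"],
    csf = rr > radii["gm"] & rr <= radii["csf"]
  )
  counts <- vapply(masks, sum, 1L)
  if (any(counts == 0)) {
    abort(
      paste0("empty tissue region(s): ",
             paste(names(counts)[counts == 0], collapse = ", ")),
      class = "morphrel_geometry_error"
    )
  }

  vol <- array(0, dim = shape)
  for (t in c("wm", "gm", "csf")) vol[masks[[t]]] <- tissue_means[[t]]

  if (bias_amplitude > 0) {
    g <- switch(bias_profile,
      cosine = {
        prof <- purrr::map(shape, function(n) {
          u <- (seq_len(n) - 1) / (n - 1)
          cos(2 * pi * bias_scale * (u - 0.5))
        })
        outer(outer(prof[[1]], prof[[2]]), prof[[3]])
      },
      radial = {
        r_max <- max(rr[masks$wm | masks$gm | masks$csf])
        2 * pmin(rr / r_max, 1) - 1
      }
    )
    vol <- vol * (1 + bias_amplitude * g)
  }

  if (any(noise_sd > 0)) {
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    set.seed(derive_seed(seed, 424243L))
    for (t in c("wm", "gm", "csf")) {
      sdv <- if (length(noise_sd) > 1) noise_sd[[t]] else noise_sd
      if (sdv > 0) {
        vol[masks[[t]]] <- vol[masks[[t]]] + rnorm(counts[[t]], 0, sdv)
      }
    }
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }

  list(
    volume = vol,
    masks = masks,
    truth = list(
      tissue_means = tissue_means,
      noise_sd = noise_sd,
      contrast_noiseless = unname(tissue_means["wm"] / tissue_means["gm"]),
      voxel_counts = counts,
      bias_amplitude = bias_amplitude,
      bias_profile = bias_profile,
      seed = seed
    )
  )
}
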