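#' Configuration for a full reliability analysis run
#'
#' Assembles (and validates against the input data at run time) the
#' configuration for [run_reliability_report()]. Defaults follow the
#' standard analysis of a multicentre test-retest morphometry study:
#' cerebral hemisphere volume as covariate for the global measures, and
#' hemisphere volume plus GSI for sulcal measures; drop-one (adjusted)
#' sums of squares; alpha 0.05; covariate-adjusted variance
#' decomposition.
#'
#' @param input Path to a morphometry CSV/TSV, or a data frame.
#' @param measures Global measures to analyze (default: all global
#'   measures present in the input).
#' @param sulcal_measures,algorithms Sulcal measures / recognition
#'   algorithms to summarise (defaults: those present).
#' @param covariates Named list mapping each measure to its covariate
#'   measures. Defaults: `hemisphere_volume` for tissue volumes and
#'   GSI; `hemisphere_volume` + `gsi` for sulcal measures; none for
#'   `hemisphere_volume` itself.
#' @param group Optional column name splitting the data into
#'   independently analyzed groups (e.g. field-strength cohorts).
#' @param ss_type,alpha Passed to [model_spec()].
#' @param adjust_varcomp Residualize values against the measure's
#'   covariates before variance decomposition (default TRUE).
#' @param derive_hemisphere Derive `hemisphere_volume` from the tissue
#'   volumes when absent (default TRUE).
#' @param out_dir Output directory for the report bundle.
#' @return A list of class `morph_pipeline_config`.
#' @export
pipeline_config <- function(input,
                            measures = NULL,
                            sulcal_measures = NULL,
                            algorithms = NULL,
                            covariates = NULL,
                            group = NULL,
                            ss_type = "adjusted",
                            alpha = 0.05,
                            adjust_varcomp = TRUE,
                            derive_hemisphere = TRUE,
                            out_dir = "morphrel-report") {
  structure(
    list(
      input = input, measures = measures,
      sulcal_measures = sulcal_measures, algorithms = algorithms,
      covariates = covariates, group = group,
      ss_type = ss_type, alpha = alpha,
      adjust_varcomp = adjust_varcomp,
      derive_hemisphere = derive_hemisphere,
      out_dir = out_dir
    ),
    class = "morph_pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path Path to a YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @return A `morph_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(
      paste0("unknown config key(s): ", paste(unknown, collapse = ", ")),
      class = "morphrel_config_error"
    )
  }
  do.call(pipeline_config, raw)
}

default_covariates <- function(measure) {
  switch(measure,
    hemisphere_volume = character(0),
    sulcal_surface = c("hemisphere_volume", "gsi"),
    sulcal_depth = c("hemisphere_volume", "gsi"),
    "hemisphere_volume"
  )
}

# Join covariate measures (themselves rows of the table) onto an
# analysis view as columns keyed by subject/centre/visit/hemisphere.
attach_covariates <- function(view, full_tbl, covariates) {
  for (cov in covariates) {
    if (cov %in% names(view)) next
    if (!(cov %in% MEASURES)) {
      abort(paste0("covariate '", cov, "' is neither a column nor a measure"),
            class = "morphrel_config_error")
    }
    cov_vals <- full_tbl |>
      dplyr::filter(.data$measure == cov) |>
      dplyr::select("subject", "centre", "visit", "hemisphere", "value") |>
      dplyr::rename(!!cov := "value")
    if (nrow(cov_vals) == 0) {
      abort(paste0("covariate measure '", cov, "' absent from input"),
            class = "morphrel_config_error")
    }
    view <- dplyr::left_join(
      view, cov_vals,
      by = c("subject", "centre", "visit", "hemisphere")
    )
    if (anyNA(view[[cov]])) {
      abort(paste0("covariate '", cov, "' missing for some analysis rows"),
            class = "morphrel_config_error")
    }
  }
  view
}

analyze_group <- function(tbl, config) {
  present <- unique(tbl$measure)
  measures <- config$measures %||% setdiff(intersect(MEASURES, present), SULCAL_MEASURES)
  missing <- setdiff(measures, present)
  if (length(missing) > 0) {
    abort(
      paste0("configured measure(s) absent from input: ", paste(missing, collapse = ", ")),
      class = "morphrel_config_error"
    )
  }
  sulcal <- config$sulcal_measures %||% intersect(SULCAL_MEASURES, present)
  algos <- config$algorithms %||%
    sort(unique(tbl$algorithm[tbl$measure %in% SULCAL_MEASURES]))

  effect_rows <- list()
  rel_rows <- list()
  for (m in measures) {
    covs <- config$covariates[[m]]
    if (is.null(covs)) {
      # Defaults apply only where the covariate measure is available;
      # explicitly configured covariates must be present (checked in
      # attach_covariates).
      covs <- intersect(default_covariates(m), c(present, names(tbl)))
    }
    covs <- setdiff(covs, m)
    view <- complete_design_view(tbl, m)
    view <- attach_covariates(view, tbl, covs)
    fit <- f_test_effects(view, model_spec(m, covariates = covs,
                                           ss_type = config$ss_type,
                                           alpha = config$alpha))
    effect_rows[[m]] <- tidy(fit) |> dplyr::mutate(measure = m, .before = 1)
    vc <- estimate_variance_components(
      view,
      covariates = if (isTRUE(config$adjust_varcomp)) covs else NULL
    )
    rel_rows[[m]] <- reliability_pair(vc) |> dplyr::mutate(measure = m, .before = 1)
  }
  sulcal_rows <- list()
  for (m in sulcal) {
    for (alg in algos) {
      sm <- sulcal_reliability_summary(tbl, m, alg)
      sulcal_rows[[paste(m, alg)]] <- sm$summary
    }
  }
  list(
    effects = dplyr::bind_rows(effect_rows),
    reliability = dplyr::bind_rows(rel_rows),
    sulcal = dplyr::bind_rows(sulcal_rows)
  )
}

format_effects_csv <- function(effects) {
  effects |>
    dplyr::mutate(p = format_p_value(.data$p_value)) |>
    dplyr::select("measure", "effect", "p") |>
    tidyr::pivot_wider(names_from = "effect", values_from = "p") |>
    dplyr::rename(centre_x_visit = "centre:visit")
}

format_reliability_csv <- function(rel) {
  rel |>
    dplyr::mutate(value = sprintf("%.2f", .data$value)) |>
    dplyr::select("measure", "factor", "value") |>
    tidyr::pivot_wider(names_from = "factor", values_from = "value") |>
    dplyr::rename(between_centre = "centre", between_visit = "visit") |>
    dplyr::select("measure", "between_visit", "between_centre")
}

format_sulcal_csv <- function(sulcal) {
  sulcal |>
    dplyr::mutate(value = sprintf("%.2f", .data$mean_reliability)) |>
    dplyr::select("measure", "algorithm", "factor", "value") |>
    tidyr::pivot_wider(names_from = "factor", values_from = "value") |>
    dplyr::rename(between_centre = "centre", between_visit = "visit") |>
    dplyr::select("measure", "algorithm", "between_visit", "between_centre")
}

#' Run the full reliability analysis and write a report bundle
#'
#' Loads and validates the input table, optionally derives the cerebral
#' hemisphere volume, and — per group, if a grouping column is
#' configured — writes: `effects_<group>.csv` (centre/visit/interaction
#' p-values per measure, formatted with "< 0.001" below 0.001),
#' `reliability_global_<group>.csv` (between-visit and between-centre
#' reliabilities to two decimals), `reliability_sulcal_<group>.csv`
#' (per-algorithm across-sulcus means) when sulcal records exist, and a
#' `manifest.json` capturing the configuration, package version and an
#' MD5 digest of the input for reproducibility. Identical input and
#' configuration produce byte-identical CSVs.
#'
#' On failure, any partial outputs are moved to a `quarantine/`
#' subdirectory and the error is re-signalled with the failing stage
#' name.
#'
#' @param config A [pipeline_config()], or a path to a YAML config.
#' @return Invisibly, a list with the per-group result tibbles and the
#'   written file paths.
#' @export
run_reliability_report <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "morph_pipeline_config"))
  stage <- "load"
  staging <- file.path(tempfile("morphrel-report-"))
  dir.create(staging, recursive = TRUE)
  written <- character(0)
  result <- tryCatch(
    {
      if (is.character(config$input)) {
        input_digest <- unname(tools::md5sum(config$input))
        tbl <- read_morphometry_table(config$input)
      } else {
        tmp <- tempfile(fileext = ".csv")
        tbl <- morphometry_table(config$input)
        write_morphometry_table(tbl, tmp)
        input_digest <- unname(tools::md5sum(tmp))
        unlink(tmp)
      }
      stage <- "analyze"
      groups <- if (is.null(config$group)) {
        list(all = tbl)
      } else {
        if (!(config$group %in% names(tbl))) {
          abort(paste0("grouping column not found: ", config$group),
                class = "morphrel_config_error")
        }
        split(tbl, tbl[[config$group]])
      }
      results <- purrr::imap(groups, function(g_tbl, g_name) {
        g_tbl <- tibble::as_tibble(g_tbl)
        if (isTRUE(config$derive_hemisphere) &&
            !("hemisphere_volume" %in% g_tbl$measure) &&
            all(c("gm_volume", "wm_volume", "csf_volume") %in% g_tbl$measure)) {
          g_tbl <- derive_hemisphere_volume(g_tbl)
        }
        analyze_group(g_tbl, config)
      })
      stage <- "write"
      for (g in names(results)) {
        res <- results[[g]]
        f1 <- file.path(staging, paste0("effects_", g, ".csv"))
        readr::write_csv(format_effects_csv(res$effects), f1, progress = FALSE)
        f2 <- file.path(staging, paste0("reliability_global_", g, ".csv"))
        readr::write_csv(format_reliability_csv(res$reliability), f2, progress = FALSE)
        written <- c(written, f1, f2)
        if (nrow(res$sulcal) > 0) {
          f3 <- file.path(staging, paste0("reliability_sulcal_", g, ".csv"))
          readr::write_csv(format_sulcal_csv(res$sulcal), f3, progress = FALSE)
          written <- c(written, f3)
        }
      }
      manifest <- list(
        package = "morphrel",
        version = as.character(packageVersion("morphrel")),
        input_md5 = input_digest,
        groups = names(results),
        config = config[setdiff(names(config), "input")]
      )
      fm <- file.path(staging, "manifest.json")
      jsonlite::write_json(manifest, fm, auto_unbox = TRUE, pretty = TRUE)
      written <- c(written, fm)
      list(results = results, files = written)
    },
    error = function(e) {
      if (length(list.files(staging)) > 0) {
        qdir <- file.path(config$out_dir, "quarantine")
        dir.create(qdir, recursive = TRUE, showWarnings = FALSE)
        file.copy(list.files(staging, full.names = TRUE), qdir, overwrite = TRUE)
      }
      abort(
        paste0("pipeline failed at stage '", stage, "': ", conditionMessage(e)),
        class = "morphrel_pipeline_error", parent = e
      )
    }
  )
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  final <- file.path(config$out_dir, basename(result$files))
  file.copy(result$files, final, overwrite = TRUE)
  unlink(staging, recursive = TRUE)
  invisible(list(results = result$results, files = final))
}
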