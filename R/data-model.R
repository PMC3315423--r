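#' Assemble and validate a morphometry table
#'
#' A morphometry table is a long-format tibble with one row per
#' subject x centre x visit x hemisphere x measure observation
#' (optionally x sulcus x recognition algorithm for sulcal measures).
#' `morphometry_table()` checks record invariants and key uniqueness and
#' returns a validated tibble of class `morph_table`.
#'
#' Invariants enforced per record:
#' * `value` is finite and strictly positive (volumes, surfaces, depths
#'   and the global sulcal index are all positive quantities);
#' * `hemisphere` is `"left"` or `"right"`;
#' * `visit` is an integer in `1..max_visits`;
#' * `sulcus` and `algorithm` are present if and only if the measure is
#'   sulcal (`sulcal_surface`, `sulcal_depth`);
#' * no two rows share the full key
#'   (subject, centre, visit, hemisphere, measure, sulcus, algorithm).
#'
#' @param data A data frame with columns `subject`, `centre`, `visit`,
#'   `hemisphere`, `measure`, `value` and optionally `sulcus`,
#'   `algorithm` plus covariate columns. Empty strings in `sulcus` /
#'   `algorithm` are treated as missing.
#' @param max_visits Largest admissible visit index (default 2).
#' @return A tibble of class `morph_table` with canonical column order.
#' @export
morphometry_table <- function(data, max_visits = 2L) {
  required <- c("subject", "centre", "visit", "hemisphere", "measure", "value")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(
      paste0("missing required column(s): ", paste(missing_cols, collapse = ", ")),
      class = "morphrel_schema_error"
    )
  }
  tbl <- tibble::as_tibble(data)
  if (!("sulcus" %in% names(tbl))) tbl$sulcus <- NA_character_
  if (!("algorithm" %in% names(tbl))) tbl$algorithm <- NA_character_
  tbl <- tbl |>
    dplyr::mutate(
      subject    = as.character(.data$subject),
      centre     = as.character(.data$centre),
      hemisphere = as.character(.data$hemisphere),
      measure    = as.character(.data$measure),
      sulcus     = dplyr::na_if(as.character(.data$sulcus), ""),
      algorithm  = dplyr::na_if(as.character(.data$algorithm), "")
    )

  if (!is.numeric(tbl$value)) {
    bad <- which(is.na(suppressWarnings(as.numeric(tbl$value))))
    abort(
      paste0("non-numeric value(s) at row(s): ", paste(head(bad, 10), collapse = ", ")),
      class = "morphrel_parse_error"
    )
  }
  visit_num <- suppressWarnings(as.numeric(tbl$visit))
  problems <- character(0)
  note <- function(rows, what) {
    if (length(rows) > 0) {
      problems <<- c(problems, paste0(
        what, " at row(s): ", paste(head(rows, 10), collapse = ", ")
      ))
    }
  }
  note(which(!is.finite(tbl$value)), "non-finite value")
  note(which(is.finite(tbl$value) & tbl$value <= 0), "non-positive value")
  note(which(!(tbl$hemisphere %in% HEMISPHERES)), "hemisphere not 'left'/'right'")
  note(which(!(tbl$measure %in% MEASURES)), "unknown measure")
  note(
    which(is.na(visit_num) | visit_num != round(visit_num) |
      visit_num < 1 | visit_num > max_visits),
    sprintf("visit not an integer in 1..%d", max_visits)
  )
  is_sulcal <- tbl$measure %in% SULCAL_MEASURES
  note(
    which(is_sulcal & (is.na(tbl$sulcus) | is.na(tbl$algorithm))),
    "sulcal measure lacking sulcus/algorithm"
  )
  note(
    which(!is_sulcal & (!is.na(tbl$sulcus) | !is.na(tbl$algorithm))),
    "non-sulcal measure carrying sulcus/algorithm"
  )
  note(
    which(!is.na(tbl$algorithm) & !(tbl$algorithm %in% ALGORITHMS)),
    paste0("algorithm not one of ", paste(ALGORITHMS, collapse = "/"))
  )
  if (length(problems) > 0) {
    abort(
      paste0("invalid morphometry records:\n  ", paste(problems, collapse = "\n  ")),
      class = "morphrel_validation_error"
    )
  }
  tbl$visit <- as.integer(visit_num)

  key_cols <- c("subject", "centre", "visit", "hemisphere", "measure", "sulcus", "algorithm")
  dup <- duplicated(tbl[key_cols])
  if (any(dup)) {
    k <- tbl[which(dup)[1], key_cols]
    abort(
      paste0(
        "duplicate key: ",
        paste(sprintf("%s=%s", key_cols, vapply(k, as.character, "")), collapse = ", ")
      ),
      class = "morphrel_validation_error"
    )
  }
  extra <- setdiff(names(tbl), c(key_cols, "value"))
  tbl <- tbl[c(key_cols[1:5], "sulcus", "algorithm", "value", extra)]
  class(tbl) <- c("morph_table", class(tbl))
  tbl
}

#' Read a morphometry table from delimited text
#'
#' Reads a CSV/TSV file and validates it with [morphometry_table()].
#' The expected default columns are
#' `subject,centre,visit,hemisphere,measure,sulcus,algorithm,value`;
#' other layouts are accommodated via `schema`, a named list/vector
#' mapping canonical names to the file's column names, e.g.
#' `schema = c(subject = "participant_id", value = "vol_cm3")`.
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema Optional mapping from canonical column names to the
#'   file's column names.
#' @param delim Field delimiter; guessed from the file extension when
#'   `NULL` (".tsv"/".txt" read as tab, everything else as comma).
#' @param max_visits Passed on to [morphometry_table()].
#' @return A validated `morph_table` tibble.
#' @export
read_morphometry_table <- function(path, schema = NULL, delim = NULL,
                                   max_visits = 2L) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "morphrel_io_error")
  }
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(
    path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE, show_col_types = FALSE
  )
  if (!is.null(schema)) {
    schema <- unlist(schema)
    absent <- setdiff(unname(schema), names(raw))
    if (length(absent) > 0) {
      abort(
        paste0("schema maps to missing column(s): ", paste(absent, collapse = ", ")),
        class = "morphrel_schema_error"
      )
    }
    names(raw)[match(unname(schema), names(raw))] <- names(schema)
  }
  if (!("value" %in% names(raw))) {
    abort("missing required column(s): value", class = "morphrel_schema_error")
  }
  val <- suppressWarnings(as.numeric(raw$value))
  bad <- which(is.na(val) | is.nan(val))
  if (length(bad) > 0) {
    abort(
      paste0(
        "value not a finite number at data row(s): ",
        paste(head(bad, 10), collapse = ", ")
      ),
      class = "morphrel_parse_error"
    )
  }
  raw$value <- val
  num_extra <- setdiff(
    names(raw),
    c("subject", "centre", "visit", "hemisphere", "measure", "sulcus", "algorithm", "value")
  )
  for (col in num_extra) {
    shot <- suppressWarnings(as.numeric(raw[[col]]))
    if (!anyNA(shot)) raw[[col]] <- shot
  }
  morphometry_table(raw, max_visits = max_visits)
}

#' Write a morphometry table to CSV
#'
#' Inverse of [read_morphometry_table()]: writes the canonical
#' comma-delimited layout with empty strings for inapplicable
#' sulcus/algorithm fields, so that a read-back reproduces the records.
#'
#' @param data A morphometry table (validated or validatable).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_morphometry_table <- function(data, path) {
  out <- tibble::as_tibble(data)
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Summarise and check the crossed design for one measure
#'
#' Checks that each subject is observed in every centre x visit x
#' hemisphere cell (x sulcus x algorithm for sulcal measures) for the
#' given measure. Subjects with incomplete coverage are reported in
#' `excluded_subjects` and omitted from the completed design, mirroring
#' the listwise exclusion applied to participants lacking repeated scans
#' at all centres.
#'
#' @param data A morphometry table.
#' @param measure Measure to check (single string).
#' @param sulcus,algorithm Optional filters for sulcal measures.
#' @return A list of class `morph_design` with elements `n_subjects`,
#'   `n_centres`, `n_visits`, `n_hemispheres`, `complete`,
#'   `excluded_subjects` and `subjects` (the retained labels).
#' @export
validate_design <- function(data, measure, sulcus = NULL, algorithm = NULL) {
  stopifnot(is.character(measure), length(measure) == 1)
  m <- measure
  sub <- dplyr::filter(tibble::as_tibble(data), .data$measure == m)
  if (!is.null(sulcus)) sub <- dplyr::filter(sub, .data$sulcus == !!sulcus)
  if (!is.null(algorithm)) sub <- dplyr::filter(sub, .data$algorithm == !!algorithm)
  if (nrow(sub) == 0) {
    abort(
      paste0("no records for measure '", m, "'"),
      class = "morphrel_empty_design_error"
    )
  }
  centres <- sort(unique(sub$centre))
  visits <- sort(unique(sub$visit))
  hemis <- sort(unique(sub$hemisphere))
  n_cells <- length(centres) * length(visits) * length(hemis)
  coverage <- sub |>
    dplyr::distinct(.data$subject, .data$centre, .data$visit, .data$hemisphere) |>
    dplyr::count(.data$subject)
  complete_subj <- coverage$subject[coverage$n == n_cells]
  excluded <- sort(setdiff(unique(sub$subject), complete_subj))
  if (length(complete_subj) == 0) {
    abort(
      paste0("no subject has complete ", length(centres), "x", length(visits),
             "x", length(hemis), " coverage for measure '", m, "'"),
      class = "morphrel_empty_design_error"
    )
  }
  structure(
    list(
      n_subjects = length(complete_subj),
      n_centres = length(centres),
      n_visits = length(visits),
      n_hemispheres = length(hemis),
      complete = TRUE,
      excluded_subjects = excluded,
      subjects = sort(complete_subj),
      centres = centres, visits = visits, hemispheres = hemis
    ),
    class = "morph_design"
  )
}

#' @export
print.morph_design <- function(x, ...) {
  cat(sprintf(
    "Crossed design: %d subjects x %d centres x %d visits x %d hemispheres\n",
    x$n_subjects, x$n_centres, x$n_visits, x$n_hemispheres
  ))
  if (length(x$excluded_subjects) > 0) {
    cat("Excluded (incomplete):", paste(x$excluded_subjects, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Restrict a table to the complete crossed design for a measure
#'
#' Convenience wrapper: applies [validate_design()] and returns only the
#' rows of the measure belonging to subjects with full coverage.
#'
#' @inheritParams validate_design
#' @return A tibble restricted to complete subjects, with the design
#'   summary attached as attribute `"design"`.
#' @export
complete_design_view <- function(data, measure, sulcus = NULL, algorithm = NULL) {
  des <- validate_design(data, measure, sulcus = sulcus, algorithm = algorithm)
  m <- measure
  out <- dplyr::filter(
    tibble::as_tibble(data),
    .data$measure == m, .data$subject %in% des$subjects
  )
  if (!is.null(sulcus)) out <- dplyr::filter(out, .data$sulcus == !!sulcus)
  if (!is.null(algorithm)) out <- dplyr::filter(out, .data$algorithm == !!algorithm)
  attr(out, "design") <- des
  out
}

#' Derive cerebral hemisphere volume from tissue volumes
#'
#' Adds `hemisphere_volume = gm_volume + wm_volume + csf_volume` per
#' (subject, centre, visit, hemisphere), the standard whole-hemisphere
#' volume obtained by summing the three segmented tissue classes.
#' Existing `hemisphere_volume` rows are replaced, making the operation
#' idempotent; all input records are preserved unchanged.
#'
#' @param data A morphometry table containing `gm_volume`, `wm_volume`
#'   and `csf_volume` rows for every key.
#' @return The table with `hemisphere_volume` rows appended.
#' @export
derive_hemisphere_volume <- function(data) {
  tbl <- tibble::as_tibble(data) |>
    dplyr::filter(.data$measure != "hemisphere_volume")
  vols <- dplyr::filter(tbl, .data$measure %in% c("gm_volume", "wm_volume", "csf_volume"))
  if (nrow(vols) == 0) {
    abort("no gm/wm/csf volume records present", class = "morphrel_incomplete_triplet_error")
  }
  wide <- vols |>
    dplyr::select("subject", "centre", "visit", "hemisphere", "measure", "value") |>
    tidyr::pivot_wider(names_from = "measure", values_from = "value")
  for (col in c("gm_volume", "wm_volume", "csf_volume")) {
    if (!(col %in% names(wide))) wide[[col]] <- NA_real_
  }
  bad <- wide |>
    dplyr::filter(is.na(.data$gm_volume) | is.na(.data$wm_volume) | is.na(.data$csf_volume))
  if (nrow(bad) > 0) {
    k <- bad[1, c("subject", "centre", "visit", "hemisphere")]
    abort(
      paste0(
        "gm/wm/csf triplet incomplete for key: ",
        paste(sprintf("%s=%s", names(k), vapply(k, as.character, "")), collapse = ", ")
      ),
      class = "morphrel_incomplete_triplet_error"
    )
  }
  derived <- wide |>
    dplyr::transmute(
      .data$subject, .data$centre, .data$visit, .data$hemisphere,
      measure = "hemisphere_volume",
      sulcus = NA_character_, algorithm = NA_character_,
      value = .data$gm_volume + .data$wm_volume + .data$csf_volume
    )
  out <- dplyr::bind_rows(tbl, derived)
  morphometry_table(out, max_visits = max(out$visit))
}

#' Fraction of the cortex buried in sulci
#'
#' Converts a global sulcal index (GSI, the ratio of folded to outer
#' cortical surface area) into the fraction of the whole cortical
#' surface that lies buried inside sulci: `gsi / (1 + gsi)`.
#'
#' @param gsi Positive numeric vector of global sulcal index values.
#' @return Numeric vector of fractions in (0, 1).
#' @examples
#' buried_fraction(1.44) # ~0.59: 59% of cortex buried
#' @export
buried_fraction <- function(gsi) {
  if (!is.numeric(gsi) || any(!is.finite(gsi)) || any(gsi <= 0)) {
    abort("gsi must be a finite positive number", class = "morphrel_domain_error")
  }
  gsi / (1 + gsi)
}
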