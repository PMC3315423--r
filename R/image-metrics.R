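#' Read a grey-level volume or binary mask from NIfTI
#'
#' Thin wrappers over `RNifti`. Masks treat any nonzero voxel as TRUE.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return `read_volume()`: a 3-D numeric array (with NIfTI metadata
#'   retained); `read_mask()`: a 3-D logical array.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3) {
    abort("expected a 3-D volume", class = "morphrel_shape_error")
  }
  img
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  img <- read_volume(path)
  array(as.vector(img) != 0, dim = dim(img))
}

check_same_shape <- function(a, b, what = "arrays") {
  if (!identical(dim(a), dim(b))) {
    abort(
      paste0(
        "shape mismatch between ", what, ": ",
        paste(dim(a), collapse = "x"), " vs ", paste(dim(b), collapse = "x")
      ),
      class = "morphrel_shape_error"
    )
  }
}

#' Intersect two tissue masks
#'
#' Voxelwise logical AND. Defining each tissue mask as the intersection
#' of the masks produced by two segmentation methods avoids biasing the
#' comparison towards either method.
#'
#' @param a,b Logical arrays of identical shape.
#' @return Logical array, TRUE where both masks are TRUE.
#' @export
intersect_masks <- function(a, b) {
  check_same_shape(a, b, "masks")
  a & b
}

#' Coefficient of variation of grey levels within a mask
#'
#' Standard deviation divided by mean of the grey levels over the
#' masked voxels. Lower values indicate narrower within-tissue intensity
#' distributions, i.e. better bias-field correction. The population
#' (1/N) standard deviation is used by default; masks of interest
#' contain thousands of voxels, where the distinction is immaterial,
#' but the sample (1/(N-1)) form is available via `sd_type`.
#'
#' @param volume 3-D numeric array of grey levels.
#' @param mask Logical array of the same shape.
#' @param min_voxels Minimum mask size required (default 10).
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return Nonnegative scalar.
#' @export
coefficient_of_variation <- function(volume, mask, min_voxels = 10,
                                     sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  check_same_shape(volume, mask, "volume and mask")
  v <- as.vector(volume)[as.vector(mask)]
  if (length(v) < min_voxels) {
    abort(
      sprintf("mask holds %d voxel(s); at least %d required", length(v), min_voxels),
      class = "morphrel_insufficient_mask_error"
    )
  }
  mu <- mean(v)
  if (mu <= 0) {
    abort("mean grey level within mask is not positive", class = "morphrel_domain_error")
  }
  n <- length(v)
  s2 <- var(v) * (if (sd_type == "population") (n - 1) / n else 1)
  sqrt(s2) / mu
}

#' Modal grey level within a mask
#'
#' Estimates the peak (mode) of the within-mask grey-level distribution
#' by histogramming over the mask's central percentile range, optionally
#' smoothing the counts with a moving average, and returning the center
#' of the maximal bin. Ties are broken toward the lower grey level.
#'
#' @param volume 3-D numeric array of grey levels.
#' @param mask Logical array of the same shape.
#' @param bins Number of histogram bins (default 128).
#' @param smooth Moving-average window in bins (odd integer, default 3;
#'   1 disables smoothing).
#' @param clip Percentile range used for the histogram support
#'   (default `c(0.01, 0.99)`), clipping outlier voxels.
#' @param min_voxels Minimum mask size required (default 10).
#' @return Scalar grey level at the distribution peak. If all masked
#'   values are identical, that value is returned.
#' @export
detect_peak <- function(volume, mask, bins = 128, smooth = 3,
                        clip = c(0.01, 0.99), min_voxels = 10) {
  check_same_shape(volume, mask, "volume and mask")
  v <- as.vector(volume)[as.vector(mask)]
  if (length(v) < min_voxels) {
    abort(
      sprintf("mask holds %d voxel(s); at least %d required", length(v), min_voxels),
      class = "morphrel_insufficient_mask_error"
    )
  }
  rng <- unname(quantile(v, clip, names = FALSE))
  if (diff(rng) <= 0) {
    return(rng[1])
  }
  edges <- seq(rng[1], rng[2], length.out = bins + 1)
  counts <- tabulate(
    findInterval(pmin(pmax(v, rng[1]), rng[2]), edges,
                 rightmost.closed = TRUE, all.inside = TRUE),
    nbins = bins
  )
  if (smooth > 1) {
    w <- rep(1 / smooth, smooth)
    counts <- as.numeric(stats::filter(counts, w, sides = 2))
    counts[is.na(counts)] <- 0
  }
  peak_bin <- which.max(counts) # which.max takes the first (lowest) tie
  (edges[peak_bin] + edges[peak_bin + 1]) / 2
}

#' White/grey matter contrast
#'
#' Ratio of the modal grey level within the white-matter mask to that
#' within the grey-matter mask, each estimated with [detect_peak()].
#' Higher values indicate a better-separated WM/GM intensity
#' distribution, hence more effective bias correction; on T1-weighted
#' images WM is brighter than GM so the ratio exceeds 1.
#'
#' @param volume 3-D numeric array of grey levels.
#' @param wm_mask,gm_mask Logical arrays of the same shape as `volume`.
#' @param ... Passed on to [detect_peak()] (bins, smooth, clip).
#' @return Positive scalar ratio.
#' @export
wm_gm_contrast <- function(volume, wm_mask, gm_mask, ...) {
  wm_peak <- detect_peak(volume, wm_mask, ...)
  gm_peak <- detect_peak(volume, gm_mask, ...)
  if (gm_peak <= 0) {
    abort("grey-matter peak is not positive", class = "morphrel_domain_error")
  }
  wm_peak / gm_peak
}

#' Bias-correction quality metrics for one volume
#'
#' Computes the within-mask coefficient of variation for each supplied
#' tissue mask and the WM/GM contrast, returned as a tidy tibble (one
#' row per metric). Metrics are computed over the full masks as given;
#' to follow the whole-cerebrum convention, supply masks covering both
#' hemispheres.
#'
#' @param volume 3-D numeric array (bias-corrected T1 grey levels).
#' @param masks Named list of logical arrays, e.g.
#'   `list(wm = ..., gm = ..., csf = ...)`.
#' @param ... Passed on to [detect_peak()] for the contrast.
#' @return A tibble with columns `metric`, `tissue`, `value`.
#' @export
image_quality_metrics <- function(volume, masks, ...) {
  stopifnot(is.list(masks), !is.null(names(masks)))
  cov_rows <- purrr::imap(masks, function(m, tissue) {
    tibble::tibble(
      metric = "cov", tissue = tissue,
      value = coefficient_of_variation(volume, m)
    )
  })
  out <- dplyr::bind_rows(cov_rows)
  if (all(c("wm", "gm") %in% names(masks))) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      metric = "wm_gm_contrast", tissue = "wm/gm",
      value = wm_gm_contrast(volume, masks$wm, masks$gm, ...)
    ))
  }
  out
}
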