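#' Rim expansion parameters
#'
#' The unified droplet mask is expanded by a fixed pixel radius so it
#' captures the droplet surface, where perilipin fluorescence concentrates.
#' The default (3 px at 120 nm/px, i.e. 360 nm) matches iterated 3x3 binary
#' dilation; a Euclidean-disk alternative is offered for isotropic physical
#' expansion.
#'
#' @param dilation_px non-negative integer expansion radius (default 3).
#' @param pixel_size_nm physical pixel size, used to derive `dilation_nm`.
#' @param metric `"chebyshev"` (iterated 3x3 dilation, default) or
#'   `"euclidean"` (pixels within Euclidean distance `dilation_px`).
#' @return A list of class `rim_params` with derived `dilation_nm`.
#' @export
rim_params <- function(dilation_px = 3L, pixel_size_nm = 120,
                       metric = c("chebyshev", "euclidean")) {
  dilation_px <- as.integer(dilation_px)
  if (dilation_px < 0L) stop("dilation_px must be >= 0")
  structure(list(dilation_px = dilation_px,
                 dilation_nm = dilation_px * pixel_size_nm,
                 metric = match.arg(metric)),
            class = "rim_params")
}

#' Dilate a binary mask
#'
#' `chebyshev` performs `r` iterations of 8-connected (3x3) dilation,
#' equivalent to a single `(2r+1) x (2r+1)` box dilation; `euclidean` adds
#' every pixel within Euclidean distance `r` of the mask. `r = 0` is the
#' identity; the output always contains the input.
#'
#' @param mask logical matrix.
#' @param dilation_px expansion radius `r`, or a [rim_params()] object.
#' @param metric distance metric (ignored when `dilation_px` is a
#'   `rim_params`).
#' @return Logical matrix.
#' @export
dilate_mask <- function(mask, dilation_px = 3L,
                        metric = c("chebyshev", "euclidean")) {
  if (inherits(dilation_px, "rim_params")) {
    metric <- dilation_px$metric
    dilation_px <- dilation_px$dilation_px
  } else metric <- match.arg(metric)
  r <- as.integer(dilation_px)
  if (r == 0L || !any(mask)) return(mask | FALSE)
  num <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  out <- if (metric == "chebyshev") {
    EBImage::dilate(num, EBImage::makeBrush(2L * r + 1L, "box")) > 0
  } else {
    d <- EBImage::distmap(1 - num, metric = "euclidean")
    mask | (d <= r)
  }
  matrix(out, nrow(mask), ncol(mask))
}

erode_mask <- function(mask, r) {
  if (r == 0L || !any(mask)) return(mask | FALSE)
  num <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  matrix(EBImage::erode(num, EBImage::makeBrush(2L * r + 1L, "box")) > 0,
         nrow(mask), ncol(mask))
}

#' Unify droplet masks into one object mask
#'
#' Pixelwise union; droplets are quantified as a single pooled object, not as
#' instances.
#'
#' @param masks list of logical matrices with identical dimensions.
#' @return Logical matrix.
#' @export
unify_mask <- function(masks) {
  if (!is.list(masks) || length(masks) == 0) stop("masks must be a non-empty list")
  d <- dim(masks[[1]])
  for (m in masks) {
    if (!all(dim(m) == d)) stop("mask dimensions differ")
  }
  Reduce(`|`, masks)
}

#' Droplet-associated vs cytoplasmic mean fluorescence
#'
#' Applies the rim-expanded droplet mask to the protein channel:
#' `mean_ld` is the mean intensity over (mask intersect ROI) and `mean_cyto`
#' the mean over the ROI with the mask subtracted, computed as a
#' sum-and-area subtraction so it is a true pixel mean of the cytoplasmic
#' region. Degenerate compartments (empty mask, or mask filling the ROI)
#' yield `NA`, never zero, so downstream regressions are not biased.
#'
#' @param protein a [micrograph] of the protein channel.
#' @param rim_mask logical matrix, the rim-expanded droplet mask.
#' @param roi a [region_of_interest()] delineating the tissue.
#' @param rim_only if `TRUE`, measure the rim shell alone (expanded minus
#'   eroded mask) rather than the filled expanded mask. Off by default.
#' @param erosion_px erosion radius for the `rim_only` variant.
#' @return One-row `data.frame`: `subject_id`, `genotype_label`, `time_hr`,
#'   `mean_ld`, `mean_cyto`, `area_ld_px`, `area_roi_px`.
#' @export
compartment_means <- function(protein, rim_mask, roi, rim_only = FALSE,
                              erosion_px = 3L) {
  stopifnot(inherits(protein, "micrograph"), inherits(roi, "roi"))
  px <- protein$pixels
  if (!all(dim(rim_mask) == dim(px)) || !all(dim(roi$mask) == dim(px))) {
    stop("mask/ROI dimensions do not match the image")
  }
  meas <- if (rim_only) rim_mask & !erode_mask(rim_mask, 2L * erosion_px) else rim_mask
  ld <- meas & roi$mask
  n_ld <- sum(ld)
  n_roi <- sum(roi$mask)
  sum_ld <- sum(px[ld])
  sum_roi <- sum(px[roi$mask])
  mean_ld <- if (n_ld > 0) sum_ld / n_ld else NA_real_
  mean_cyto <- if (n_roi > n_ld) (sum_roi - sum_ld) / (n_roi - n_ld) else NA_real_
  data.frame(subject_id = protein$subject_id,
             genotype_label = protein$genotype_label,
             time_hr = protein$time_hr,
             mean_ld = mean_ld, mean_cyto = mean_cyto,
             area_ld_px = n_ld, area_roi_px = n_roi,
             stringsAsFactors = FALSE)
}

#' Fraction of tissue area covered by droplets
#'
#' Uses the undilated droplet mask.
#'
#' @param droplet_mask logical matrix.
#' @param roi a [region_of_interest()].
#' @return Scalar in `[0, 1]`.
#' @export
area_fraction <- function(droplet_mask, roi) {
  stopifnot(inherits(roi, "roi"))
  if (!all(dim(droplet_mask) == dim(roi$mask))) stop("dimensions differ")
  n_roi <- sum(roi$mask)
  if (n_roi == 0) stop("ROI is empty")
  sum(droplet_mask & roi$mask) / n_roi
}
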