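as_pixels <- function(x) if (inherits(x, "micrograph")) x$pixels else x

# Orthogonal regression of y on x on standardized intensities (reduced major
# axis): slope = sign(cov) * sd(y)/sd(x). Unlike raw total least squares this
# is equivariant under per-channel intensity rescaling, so the linked
# threshold pair rescales with the channels.
tls_fit <- function(x, y) {
  sxy <- stats::cov(x, y)
  slope <- (if (sxy < 0) -1 else 1) * stats::sd(y) / stats::sd(x)
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

#' Costes automatic threshold for a two-channel image pair
#'
#' Fits the orthogonal (reduced major axis) regression of channel 2 on
#' channel 1 over the ROI,
#' then walks a linked threshold pair down the sorted distinct channel-1
#' intensities, starting from the maximum: at each candidate `T1` the Pearson
#' correlation of the pixel pairs below threshold in both channels
#' (`ch1 < T1` and `ch2 < slope * T1 + intercept`) is evaluated, and the
#' search stops at the largest `T1` for which that correlation is `<= 0`.
#' The below-threshold pixels are then statistically uncorrelated, and
#' everything above threshold is counted as genuine signal by the Manders
#' coefficients.
#'
#' @param ch1,ch2 [micrograph]s (or matrices) of the two channels.
#' @param roi a [region_of_interest()]; at least 50 pixels.
#' @return A list of class `coloc_result`: `slope`, `intercept`,
#'   `threshold_ch1`, `threshold_ch2` (`= slope * threshold_ch1 +
#'   intercept`), `pearson_below` (correlation at the stopping point),
#'   `converged`, `n_pixels`.
#' @export
costes_threshold <- function(ch1, ch2, roi) {
  stopifnot(inherits(roi, "roi"))
  p1 <- as_pixels(ch1); p2 <- as_pixels(ch2)
  if (!all(dim(p1) == dim(p2)) || !all(dim(p1) == dim(roi$mask))) {
    stop("channels and ROI must be congruent")
  }
  x <- p1[roi$mask]; y <- p2[roi$mask]
  if (length(x) < 50) stop("ROI must contain at least 50 pixels")
  if (stats::var(x) == 0) stop("degenerate input: channel 1 is constant within the ROI")
  if (stats::var(y) == 0) stop("degenerate input: channel 2 is constant within the ROI")
  fit <- tls_fit(x, y)
  cand <- sort(unique(x), decreasing = TRUE)
  res <- list(slope = fit$slope, intercept = fit$intercept,
              threshold_ch1 = min(cand), pearson_below = NA_real_,
              converged = FALSE, n_pixels = length(x))
  for (t1 in cand) {
    below <- x < t1 & y < fit$slope * t1 + fit$intercept
    if (sum(below) < 10) {               # too few pairs: r undefined, stop
      res$threshold_ch1 <- t1
      break
    }
    xb <- x[below]; yb <- y[below]
    if (stats::var(xb) == 0 || stats::var(yb) == 0) {
      res$threshold_ch1 <- t1
      break
    }
    r <- stats::cor(xb, yb)
    if (r <= 0) {
      res$threshold_ch1 <- t1
      res$pearson_below <- r
      res$converged <- TRUE
      break
    }
  }
  res$threshold_ch2 <- res$slope * res$threshold_ch1 + res$intercept
  structure(res, class = "coloc_result")
}

#' Thresholded Manders colocalization coefficients
#'
#' `tM1` is the fraction of channel-1 intensity found on pixels where
#' channel 2 exceeds its threshold; `tM2` symmetrically. Sums run over the
#' ROI only. A zero denominator yields `NA` (flagged missing, never 0).
#'
#' @param ch1,ch2 [micrograph]s or matrices.
#' @param threshold_ch1,threshold_ch2 per-channel thresholds (e.g. from
#'   [costes_threshold()]); 0 disables thresholding.
#' @param roi a [region_of_interest()].
#' @return A list with `tM1` and `tM2` in `[0, 1]` (or `NA`).
#' @export
manders_coefficients <- function(ch1, ch2, threshold_ch1, threshold_ch2, roi) {
  stopifnot(inherits(roi, "roi"))
  p1 <- as_pixels(ch1)[roi$mask]
  p2 <- as_pixels(ch2)[roi$mask]
  s1 <- sum(p1); s2 <- sum(p2)
  tM1 <- if (s1 > 0) sum(p1[p2 > threshold_ch2]) / s1 else NA_real_
  tM2 <- if (s2 > 0) sum(p2[p1 > threshold_ch1]) / s2 else NA_real_
  list(tM1 = tM1, tM2 = tM2)
}

#' Full colocalization analysis of one image pair
#'
#' Costes automatic thresholding followed by thresholded Manders
#' coefficients, returned as one tidy row.
#'
#' @inheritParams costes_threshold
#' @return One-row `data.frame` with the regression, thresholds, `tM1`,
#'   `tM2`, `pearson_below`, `converged`, and `n_pixels`.
#' @export
coloc_analysis <- function(ch1, ch2, roi) {
  ct <- costes_threshold(ch1, ch2, roi)
  tm <- manders_coefficients(ch1, ch2, ct$threshold_ch1, ct$threshold_ch2, roi)
  meta <- if (inherits(ch1, "micrograph")) ch1 else NULL
  data.frame(subject_id = if (is.null(meta)) NA_character_ else meta$subject_id,
             time_hr = if (is.null(meta)) NA_real_ else meta$time_hr,
             slope = ct$slope, intercept = ct$intercept,
             threshold_ch1 = ct$threshold_ch1,
             threshold_ch2 = ct$threshold_ch2,
             tM1 = tm$tM1, tM2 = tm$tM2,
             pearson_below = ct$pearson_below,
             converged = ct$converged, n_pixels = ct$n_pixels,
             stringsAsFactors = FALSE)
}
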