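#' Raw integrated density over a region
#'
#' The sum of pixel intensities over the ROI — the whole-organ fluorescence
#' readout (as opposed to the mean gray value, the region average).
#'
#' @param image a [micrograph].
#' @param roi a [region_of_interest()].
#' @return Scalar sum.
#' @export
raw_integrated_density <- function(image, roi) {
  stopifnot(inherits(roi, "roi"))
  px <- as_pixels(image)
  if (!all(dim(px) == dim(roi$mask))) stop("image/ROI dimensions differ")
  if (!any(roi$mask)) stop("ROI is empty")
  sum(px[roi$mask])
}

#' Mean gray value over a region
#'
#' Brightfield opacity proxy: the mean intensity of the intestine region in
#' the brightfield image estimates the amount of lipid consumed.
#'
#' @inheritParams raw_integrated_density
#' @return Scalar mean.
#' @export
opacity_mean_gray <- function(image, roi) {
  raw_integrated_density(image, roi) / sum(roi$mask)
}

#' Quantify a whole-mount image series
#'
#' Computes the raw integrated density of every image over the ROI and
#' returns one tidy row per subject.
#'
#' @param images list of [micrograph]s.
#' @param roi a shared [region_of_interest()].
#' @return `data.frame` with `subject_id`, `genotype_label`, `time_hr`,
#'   `raw_integrated_density`.
#' @export
quantify_wholemount <- function(images, roi) {
  do.call(rbind, lapply(images, function(mg) {
    data.frame(subject_id = mg$subject_id,
               genotype_label = mg$genotype_label,
               time_hr = mg$time_hr,
               raw_integrated_density = raw_integrated_density(mg, roi),
               stringsAsFactors = FALSE)
  }))
}

#' Sibling autofluorescence correction
#'
#' Subtracts, at each time-point, the mean wild-type (non-reporter) value
#' from every measurement at that time-point. Wild-type corrected values
#' therefore average exactly zero per time-point; reporter corrected values
#' may be negative (noise around zero is preserved, not clipped).
#'
#' @param points `data.frame` with `genotype_label`, `time_hr`, and
#'   `raw_integrated_density` columns.
#' @param wt_label genotype label identifying wild-type siblings.
#' @return `points` with a `corrected_value` column added.
#' @export
autofluorescence_correct <- function(points, wt_label = "wild_type") {
  stopifnot(all(c("genotype_label", "time_hr", "raw_integrated_density")
                %in% names(points)))
  is_wt <- points$genotype_label == wt_label
  rep_t <- unique(points$time_hr[!is_wt])
  wt_t <- unique(points$time_hr[is_wt])
  missing_t <- setdiff(rep_t, wt_t)
  if (length(missing_t)) {
    stop("no wild-type measurements at time-point(s): ",
         paste(sort(missing_t), collapse = ", "))
  }
  wt_n <- table(points$time_hr[is_wt])
  if (any(wt_n < 3)) {
    warning("fewer than 3 wild-type fish at time-point(s): ",
            paste(names(wt_n)[wt_n < 3], collapse = ", "))
  }
  wt_mean <- tapply(points$raw_integrated_density[is_wt],
                    points$time_hr[is_wt], mean)
  points$corrected_value <- points$raw_integrated_density -
    as.numeric(wt_mean[as.character(points$time_hr)])
  points
}

#' Windowed least-squares fit with correlation coefficient
#'
#' Ordinary least squares of `y` on `x` restricted to `x` inside `window`,
#' reporting the signed Pearson correlation coefficient R of the in-window
#' pairs (not R^2). Pairs with missing values are dropped.
#'
#' @param x,y numeric vectors (typically time in hours and a fluorescence
#'   measurement).
#' @param window `c(t_min, t_max)` inclusive fitting window; `NULL` uses all
#'   points.
#' @return A list of class `regression_fit`: `slope`, `intercept`, `r`, `n`,
#'   `window`.
#' @export
linear_fit <- function(x, y, window = NULL) {
  keep <- is.finite(x) & is.finite(y)
  if (!is.null(window)) keep <- keep & x >= window[1] & x <= window[2]
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 in-window complete pairs")
  if (stats::var(x) == 0) stop("degenerate input: zero variance in x")
  fit <- stats::lm(y ~ x)
  r <- if (stats::var(y) == 0) 0 else stats::cor(x, y)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r = r, n = length(x),
                 window = if (is.null(window)) range(x) else window),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<fit> y = %.4gx + %.4g, R = %.4f, n = %d, window [%g, %g] hr\n",
              x$slope, x$intercept, x$r, x$n, x$window[1], x$window[2]))
  invisible(x)
}

#' Normalize measurements by their genotype-group mean
#'
#' Divides every value by the overall mean of all individual data points of
#' its genotype (pooled across compartments and time-points), so trajectories
#' of reporters with very different absolute brightness can be overlaid. The
#' post-normalization pooled mean of each group is exactly 1.
#'
#' @param points `data.frame` with a `genotype_label` column.
#' @param value_cols columns to normalize jointly (pooled for the group
#'   mean).
#' @return `points` with the value columns normalized; group means are
#'   attached as attribute `group_means`.
#' @export
normalize_by_group_mean <- function(points,
                                    value_cols = c("mean_ld", "mean_cyto")) {
  stopifnot("genotype_label" %in% names(points),
            all(value_cols %in% names(points)))
  groups <- split(seq_len(nrow(points)), points$genotype_label)
  means <- vapply(groups, function(i) {
    v <- unlist(points[i, value_cols], use.names = FALSE)
    v <- v[is.finite(v)]
    if (length(v) == 0) stop("a genotype group has no finite values")
    mean(v)
  }, numeric(1))
  if (any(means == 0)) {
    stop("zero group mean for genotype(s): ",
         paste(names(means)[means == 0], collapse = ", "))
  }
  for (g in names(groups)) {
    i <- groups[[g]]
    points[i, value_cols] <- points[i, value_cols] / means[[g]]
  }
  attr(points, "group_means") <- means
  points
}

#' LOWESS smoothing of a time series
#'
#' Locally weighted linear regression with tricube weights and bisquare
#' robustness iterations, evaluated at the observed `x`. Intended for
#' visualization only; fits and tests use the raw values.
#'
#' @param x,y numeric vectors, at least 5 points.
#' @param frac smoothing span in `(0, 1]` (default 0.35).
#' @param n_iter robustness iterations (default 2).
#' @return Numeric vector of smoothed values aligned with the input order.
#' @export
lowess_smooth <- function(x, y, frac = 0.35, n_iter = 2L) {
  keep <- is.finite(x) & is.finite(y)
  if (sum(keep) < 5) stop("need at least 5 finite points")
  if (frac <= 0 || frac > 1) stop("frac must be in (0, 1]")
  o <- order(x[keep])
  sm <- stats::lowess(x[keep][o], y[keep][o], f = frac, iter = n_iter)
  out <- rep(NA_real_, length(x))
  tmp <- numeric(sum(keep))
  tmp[o] <- sm$y
  out[keep] <- tmp
  out
}
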