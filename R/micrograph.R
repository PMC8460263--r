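#' Single-channel micrograph with acquisition metadata
#'
#' Constructs the basic image container used throughout the pipeline: a
#' rectangular grid of non-negative intensities together with the physical
#' pixel size, the quantization bit depth, and the experimental annotations
#' (time since meal onset, channel role, genotype, subject) that the
#' downstream statistics key on.
#'
#' Coordinate convention: matrices are indexed `[row, col]`; when pixels are
#' addressed by continuous coordinates (polygon ROIs), `x` is the 0-based
#' column index and `y` the 0-based row index, with pixel centers at integer
#' coordinates. Images are strictly 2D; confocal stacks must be supplied one
#' plane at a time.
#'
#' @param pixels numeric matrix of intensities, all `>= 0` and
#'   `<= 2^bit_depth - 1`.
#' @param pixel_size_nm physical edge length of one pixel in nanometres
#'   (default 120, i.e. three pixels = 360 nm).
#' @param bit_depth integer quantization depth of the detector (default 12).
#' @param time_hr hours since meal onset, or `NA` when not applicable.
#' @param channel_role one of `"lipid_dye"`, `"protein"`, `"brightfield"`.
#' @param genotype_label free-text genotype (e.g. `"reporter"`,
#'   `"wild_type"`).
#' @param subject_id free-text subject identifier.
#' @return An object of class `micrograph`.
#' @export
micrograph <- function(pixels, pixel_size_nm = 120, bit_depth = 12,
                       time_hr = NA_real_, channel_role = "lipid_dye",
                       genotype_label = "reporter", subject_id = "s1") {
  if (!is.matrix(pixels) || length(pixels) == 0L) {
    stop("`pixels` must be a non-empty matrix")
  }
  storage.mode(pixels) <- "double"
  if (anyNA(pixels) || any(pixels < 0)) {
    stop("intensities must be finite and >= 0")
  }
  if (!is.numeric(pixel_size_nm) || pixel_size_nm <= 0) {
    stop("`pixel_size_nm` must be > 0")
  }
  bit_depth <- as.integer(bit_depth)
  if (bit_depth < 1L || any(pixels > 2^bit_depth - 1)) {
    stop("intensities exceed 2^bit_depth - 1")
  }
  channel_role <- match.arg(channel_role,
                            c("lipid_dye", "protein", "brightfield"))
  structure(
    list(pixels = pixels, pixel_size_nm = pixel_size_nm,
         bit_depth = bit_depth, time_hr = as.numeric(time_hr),
         channel_role = channel_role,
         genotype_label = as.character(genotype_label),
         subject_id = as.character(subject_id)),
    class = "micrograph")
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("<micrograph> %d x %d px, %g nm/px, %d-bit, channel=%s\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_nm, x$bit_depth,
              x$channel_role))
  cat(sprintf("  subject=%s genotype=%s t=%s hr, intensity range [%g, %g]\n",
              x$subject_id, x$genotype_label,
              ifelse(is.na(x$time_hr), "NA", format(x$time_hr)),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.micrograph <- function(x) dim(x$pixels)

#' Read a grayscale TIFF as a micrograph
#'
#' Intensities are preserved bit-exactly (integer samples are read as stored,
#' without rescaling to `[0, 1]`). Multi-page files are indexed with `page`;
#' RGB input is refused unless a channel to extract is named.
#'
#' @param path TIFF file path.
#' @param page page index for multi-page files (default 1).
#' @param channel for RGB input, which plane (1-3) to extract; `NULL`
#'   (default) makes RGB input an error.
#' @inheritParams micrograph
#' @return A [micrograph].
#' @export
read_micrograph <- function(path, page = 1L, channel = NULL,
                            pixel_size_nm = 120, bit_depth = 12,
                            time_hr = NA_real_, channel_role = "lipid_dye",
                            genotype_label = "reporter", subject_id = "s1") {
  if (!file.exists(path)) stop("cannot read micrograph: no such file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) {
                      stop("cannot decode TIFF at ", path, ": ",
                           conditionMessage(e))
                    })
  if (page < 1L || page > length(pages)) {
    stop("page ", page, " out of range for ", path,
         " (", length(pages), " pages)")
  }
  px <- pages[[page]]
  if (length(dim(px)) == 3L) {
    if (is.null(channel)) {
      stop("RGB TIFF at ", path,
           " requires `channel` to select a plane (1-", dim(px)[3], ")")
    }
    px <- px[, , channel]
  }
  micrograph(px, pixel_size_nm = pixel_size_nm, bit_depth = bit_depth,
             time_hr = time_hr, channel_role = channel_role,
             genotype_label = genotype_label, subject_id = subject_id)
}

#' Write a micrograph to a 16-bit grayscale TIFF
#'
#' Samples are stored as 16-bit integers so any image quantized to
#' `bit_depth <= 16` round-trips pixel-identically through
#' [read_micrograph()].
#'
#' @param mg a [micrograph].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_micrograph <- function(mg, path) {
  stopifnot(inherits(mg, "micrograph"))
  px <- round(mg$pixels)
  if (any(px > 65535)) stop("intensities exceed 16-bit storage range")
  tiff::writeTIFF(px / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Tissue region of interest
#'
#' A binary mask congruent with the micrograph it restricts; `TRUE` marks
#' pixels inside the tissue.
#'
#' @param mask logical matrix.
#' @param allow_empty permit an all-`FALSE` mask (only meaningful for
#'   intermediate set algebra; measurement functions require a non-empty ROI).
#' @return An object of class `roi`.
#' @export
region_of_interest <- function(mask, allow_empty = FALSE) {
  if (!is.matrix(mask)) stop("`mask` must be a matrix")
  mask <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  if (anyNA(mask)) stop("ROI mask must not contain NA")
  if (!allow_empty && !any(mask)) {
    stop("ROI mask is empty (no TRUE pixel)")
  }
  structure(list(mask = mask), class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> %d x %d px, %d inside (%.1f%%)\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask),
              100 * mean(x$mask)))
  invisible(x)
}

#' Full-frame region of interest
#' @param shape `c(nrow, ncol)` grid dimensions.
#' @return An [region_of_interest()] covering every pixel.
#' @export
full_roi <- function(shape) {
  region_of_interest(matrix(TRUE, shape[1], shape[2]))
}

#' Rasterize a polygon to a binary mask
#'
#' Even-odd (ray crossing) fill evaluated at pixel centers. Vertices are in
#' the package coordinate frame: `x` = 0-based column, `y` = 0-based row,
#' pixel centers at integer coordinates.
#'
#' @param vertices two-column matrix or data.frame of `(x, y)` polygon
#'   vertices, in order; the polygon is closed implicitly.
#' @param shape `c(nrow, ncol)` of the target grid.
#' @return Logical matrix of dimension `shape`.
#' @export
rasterize_polygon <- function(vertices, shape) {
  v <- as.matrix(vertices)[, 1:2, drop = FALSE]
  storage.mode(v) <- "double"
  if (nrow(v) < 3L) stop("polygon needs at least 3 vertices")
  nr <- shape[1]; nc <- shape[2]
  px <- rep(0:(nc - 1L), each = nr)   # x = column index of each pixel center
  py <- rep(0:(nr - 1L), times = nc)  # y = row index
  inside <- rep(FALSE, nr * nc)
  n <- nrow(v)
  j <- n
  for (i in seq_len(n)) {
    x1 <- v[j, 1]; y1 <- v[j, 2]; x2 <- v[i, 1]; y2 <- v[i, 2]
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xc <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      inside <- xor(inside, crosses & (px < xc))
    }
    j <- i
  }
  matrix(inside, nr, nc)
}

#' Read a region of interest from disk
#'
#' Accepts either a binary-mask TIFF (any non-zero sample is inside) or a CSV
#' polygon with columns `x,y`, rasterized to `shape` with even-odd fill at
#' pixel centers.
#'
#' @param path path to a `.tif`/`.tiff` mask or `.csv` vertex list.
#' @param shape `c(nrow, ncol)` dimensions the ROI must match.
#' @return An [region_of_interest()].
#' @export
read_roi <- function(path, shape) {
  if (!file.exists(path)) stop("cannot read ROI: no such file: ", path)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    v <- utils::read.csv(path)
    if (!all(c("x", "y") %in% names(v))) {
      stop("polygon CSV must have columns x,y: ", path)
    }
    mask <- rasterize_polygon(v[, c("x", "y")], shape)
  } else {
    px <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(px)) == 3L) px <- px[, , 1]
    if (!all(dim(px) == shape)) {
      stop("ROI dimensions ", paste(dim(px), collapse = "x"),
           " do not match expected ", paste(shape, collapse = "x"))
    }
    mask <- px > 0
  }
  if (!all(dim(mask) == shape)) {
    stop("ROI dimensions do not match expected shape")
  }
  region_of_interest(mask)
}

#' Write a binary mask as a TIFF
#' @param mask logical matrix (or an `roi`).
#' @param path output path.
#' @export
write_mask <- function(mask, path) {
  if (inherits(mask, "roi")) mask <- mask$mask
  tiff::writeTIFF(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path,
                  bits.per.sample = 8L, compression = "none")
  invisible(path)
}

#' Assemble a tidy measurement table
#'
#' Long-format rows of `{subject_id, genotype_label, time_hr, metric, value}`,
#' the orientation every downstream statistic and the exported CSVs use.
#' Duplicate `(subject, time, metric)` keys and non-finite values (other than
#' explicitly missing ones) are rejected.
#'
#' @param subject_id,genotype_label,time_hr,metric,value vectors, recycled to
#'   a common length.
#' @return A `data.frame` in long orientation.
#' @export
measurement_table <- function(subject_id, genotype_label, time_hr, metric,
                              value) {
  df <- data.frame(subject_id = as.character(subject_id),
                   genotype_label = as.character(genotype_label),
                   time_hr = as.numeric(time_hr),
                   metric = as.character(metric),
                   value = as.numeric(value),
                   stringsAsFactors = FALSE)
  validate_measurement_table(df)
  df
}

#' Validate a measurement table
#' @param df a long-format measurement `data.frame`.
#' @return `df`, invisibly, or an error.
#' @export
validate_measurement_table <- function(df) {
  need <- c("subject_id", "genotype_label", "time_hr", "metric", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("measurement table lacks columns: ",
                         paste(miss, collapse = ", "))
  key <- paste(df$subject_id, df$time_hr, df$metric, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (subject, time, metric) keys in measurement table")
  }
  bad <- !is.na(df$value) & !is.finite(df$value)
  if (any(bad)) stop("non-finite values in measurement table")
  invisible(df)
}
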