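#' Feature bank configuration for pixel classification
#'
#' Scales and feature kinds of the multi-scale Gaussian feature bank used by
#' the droplet pixel classifier. Defaults follow the common
#' interactive-segmentation recipe: intensity (smoothing) features at
#' sigma 1.6-5.0 px and edge/texture features at sigma 0.07-5.0 px.
#'
#' @param intensity_sigmas_px ascending Gaussian scales (px) for smoothed
#'   intensity.
#' @param edge_texture_sigmas_px ascending scales (px) for gradient,
#'   Laplacian, Hessian and structure-tensor features.
#' @param kinds subset of `c("gaussian", "gradient", "log", "hessian",
#'   "structure")`.
#' @return A list of class `feature_bank_config`.
#' @export
feature_bank_config <- function(intensity_sigmas_px = c(1.6, 2.3, 3.5, 5.0),
                                edge_texture_sigmas_px =
                                  c(0.07, 0.7, 1.6, 3.5, 5.0),
                                kinds = c("gaussian", "gradient", "log",
                                          "hessian", "structure")) {
  if (length(kinds) == 0) stop("at least one feature kind must be enabled")
  kinds <- match.arg(kinds, several.ok = TRUE)
  for (s in list(intensity_sigmas_px, edge_texture_sigmas_px)) {
    if (length(s) && (any(s <= 0) || is.unsorted(s))) {
      stop("sigma lists must be positive and sorted ascending")
    }
  }
  structure(list(intensity_sigmas_px = intensity_sigmas_px,
                 edge_texture_sigmas_px = edge_texture_sigmas_px,
                 kinds = kinds),
            class = "feature_bank_config")
}

# Sampled Gaussian (and derivative) kernels. Derivatives at sub-pixel sigma
# degenerate numerically, so below sigma 0.5 the finite-difference stencils
# are used instead; smoothing kernels are always the normalized sampled
# Gaussian.
gauss_kernel <- function(sigma, order = 0L) {
  if (order > 0L && sigma < 0.5) {
    return(if (order == 1L) c(0.5, 0, -0.5) else c(1, -2, 1))
  }
  r <- max(1L, ceiling(4 * sigma))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (order == 0L) return(g)
  if (order == 1L) {
    return(-x * g / sum(x^2 * g))     # unit response to a unit ramp
  }
  k <- (x^2 - sigma^2) / sigma^4 * g  # second derivative
  k - mean(k)                         # zero response to constants
}

# Band matrix for 1D convolution with symmetric (reflective) padding.
conv_matrix <- function(n, k) {
  r <- (length(k) - 1L) %/% 2L
  idx <- c(r:1, 1:n, n:(n - r + 1L))       # symmetric reflection indices
  a <- matrix(0, n, n + 2L * r)
  for (u in seq_along(k)) {
    a[cbind(seq_len(n), seq_len(n) + u - 1L)] <- k[u]
  }
  # fold the padded columns back onto the n true columns
  m <- matrix(0, n, n)
  for (j in seq_len(n + 2L * r)) m[, idx[j]] <- m[, idx[j]] + a[, j]
  m
}

# Separable convolution: kernel kr along rows (vertical), kc along columns.
conv_sep <- function(img, kr, kc) {
  out <- img
  if (length(kr) > 1L) out <- conv_matrix(nrow(img), kr) %*% out
  if (length(kc) > 1L) out <- out %*% t(conv_matrix(ncol(img), kc))
  out
}

gauss_deriv <- function(img, sigma, ox, oy) {
  # ox, oy: derivative orders along columns (x) and rows (y)
  conv_sep(img, gauss_kernel(sigma, oy), gauss_kernel(sigma, ox))
}

hessian_eigen <- function(hxx, hxy, hyy) {
  tr2 <- (hxx + hyy) / 2
  disc <- sqrt(((hxx - hyy) / 2)^2 + hxy^2)
  list(hi = tr2 + disc, lo = tr2 - disc)
}

#' Multi-scale per-pixel feature bank
#'
#' Computes one feature plane per (kind, sigma) pair using separable Gaussian
#' (derivative) convolution with reflective boundary handling:
#' smoothed intensity; gradient magnitude; Laplacian of Gaussian; the two
#' Hessian eigenvalues; and the two structure-tensor eigenvalues (gradient
#' outer products integrated at the same scale).
#'
#' @param image a [micrograph] or numeric matrix.
#' @param config a [feature_bank_config()].
#' @return A 3D array `nrow x ncol x n_features` with named feature planes;
#'   the configuration is attached as attribute `config`.
#' @export
compute_feature_bank <- function(image, config = feature_bank_config()) {
  img <- if (inherits(image, "micrograph")) image$pixels else image
  if (!is.matrix(img) || length(img) == 0) stop("image must be a non-empty matrix")
  smax <- max(c(config$intensity_sigmas_px, config$edge_texture_sigmas_px))
  if (smax >= min(dim(img)) / 4) {
    stop("largest sigma must be < min(image dimensions)/4")
  }
  planes <- list()
  if ("gaussian" %in% config$kinds) {
    for (s in config$intensity_sigmas_px) {
      planes[[sprintf("gaussian_s%.2f", s)]] <- gauss_deriv(img, s, 0L, 0L)
    }
  }
  for (s in config$edge_texture_sigmas_px) {
    gx <- gauss_deriv(img, s, 1L, 0L)
    gy <- gauss_deriv(img, s, 0L, 1L)
    if ("gradient" %in% config$kinds) {
      planes[[sprintf("gradmag_s%.2f", s)]] <- sqrt(gx^2 + gy^2)
    }
    if (any(c("log", "hessian") %in% config$kinds)) {
      hxx <- gauss_deriv(img, s, 2L, 0L)
      hyy <- gauss_deriv(img, s, 0L, 2L)
      hxy <- gauss_deriv(img, s, 1L, 1L)
      if ("log" %in% config$kinds) {
        planes[[sprintf("log_s%.2f", s)]] <- hxx + hyy
      }
      if ("hessian" %in% config$kinds) {
        he <- hessian_eigen(hxx, hxy, hyy)
        planes[[sprintf("hessian_hi_s%.2f", s)]] <- he$hi
        planes[[sprintf("hessian_lo_s%.2f", s)]] <- he$lo
      }
    }
    if ("structure" %in% config$kinds) {
      sxx <- gauss_deriv(gx * gx, s, 0L, 0L)
      syy <- gauss_deriv(gy * gy, s, 0L, 0L)
      sxy <- gauss_deriv(gx * gy, s, 0L, 0L)
      se <- hessian_eigen(sxx, sxy, syy)
      planes[[sprintf("structure_hi_s%.2f", s)]] <- se$hi
      planes[[sprintf("structure_lo_s%.2f", s)]] <- se$lo
    }
  }
  if (!all(vapply(planes, function(p) all(is.finite(p)), logical(1)))) {
    stop("non-finite feature values")
  }
  bank <- array(unlist(planes, use.names = FALSE),
                dim = c(nrow(img), ncol(img), length(planes)),
                dimnames = list(NULL, NULL, names(planes)))
  attr(bank, "config") <- config
  bank
}

# Flatten a feature bank to a pixels x features matrix.
bank_matrix <- function(bank) {
  d <- dim(bank)
  m <- matrix(bank, d[1] * d[2], d[3])
  colnames(m) <- dimnames(bank)[[3]]
  m
}
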