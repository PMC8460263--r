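#' Train the droplet pixel classifier
#'
#' Fits a probability random forest on sparsely labeled pixels of one or more
#' feature banks, mirroring interactive pixel-classification training: the
#' user paints a few droplet and background strokes, the model generalizes to
#' all pixels. A stratified hold-out split reports generalization accuracy.
#'
#' @param features a feature bank from [compute_feature_bank()], or a list of
#'   banks (one per training image, all under the same configuration).
#' @param labels a matrix (or list of matrices) congruent with the image(s),
#'   with entries `"droplet"`, `"background"`, or `NA` for unlabeled pixels.
#' @param seed RNG seed controlling the hold-out split and forest growth.
#' @param num_trees trees in the forest.
#' @param holdout_frac fraction of labeled pixels held out per class.
#' @return An object of class `pixel_classifier`: the forest, the feature
#'   configuration, label counts, hold-out accuracy, and the seed.
#' @export
train_pixel_classifier <- function(features, labels, seed = 1L,
                                   num_trees = 100L, holdout_frac = 0.2) {
  if (!is.list(features) || is.array(features)) features <- list(features)
  if (!is.list(labels)) labels <- list(labels)
  stopifnot(length(features) == length(labels))
  config <- attr(features[[1]], "config")
  if (is.null(config)) stop("features must come from compute_feature_bank()")
  xs <- list(); ys <- list()
  for (i in seq_along(features)) {
    lab <- as.vector(labels[[i]])
    keep <- !is.na(lab)
    bad <- setdiff(unique(lab[keep]), c("droplet", "background"))
    if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "))
    xs[[i]] <- bank_matrix(features[[i]])[keep, , drop = FALSE]
    ys[[i]] <- lab[keep]
  }
  x <- do.call(rbind, xs)
  y <- factor(unlist(ys), levels = c("background", "droplet"))
  counts <- table(y)
  if (any(counts < 50)) {
    stop("need >= 50 labeled pixels per class (got background=",
         counts[["background"]], ", droplet=", counts[["droplet"]], ")")
  }
  local_seed(seed, {
    hold <- unlist(lapply(levels(y), function(cl) {
      idx <- which(y == cl)
      sample(idx, max(1L, round(holdout_frac * length(idx))))
    }))
    train <- setdiff(seq_along(y), hold)
    df <- data.frame(x, check.names = FALSE)
    df$.class <- y
    fit <- ranger::ranger(
      dependent.variable.name = ".class", data = df[train, ],
      num.trees = num_trees, probability = TRUE, seed = seed,
      num.threads = 1L)
    pred <- stats::predict(fit, df[hold, ], num.threads = 1L)$predictions
    acc <- mean((pred[, "droplet"] >= 0.5) == (y[hold] == "droplet"))
    structure(list(forest = fit, config = config,
                   label_counts = as.list(counts),
                   holdout_accuracy = acc, num_trees = num_trees,
                   seed = as.integer(seed)),
              class = "pixel_classifier")
  })
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat(sprintf(
    "<pixel_classifier> %d trees, %d features, hold-out accuracy %.3f\n",
    x$num_trees, length(x$forest$forest$independent.variable.names),
    x$holdout_accuracy))
  invisible(x)
}

#' Droplet probability map for an image
#'
#' Computes the model's feature bank on the image and returns the per-pixel
#' probability of the droplet class.
#'
#' @param model a [train_pixel_classifier()] fit.
#' @param image a [micrograph] or matrix.
#' @return Numeric matrix in `[0, 1]`, congruent with the image.
#' @export
predict_probability <- function(model, image) {
  if (!inherits(model, "pixel_classifier")) stop("model is not a trained pixel_classifier")
  bank <- compute_feature_bank(image, model$config)
  m <- bank_matrix(bank)
  pred <- stats::predict(model$forest, data.frame(m, check.names = FALSE),
                         num.threads = 1L)$predictions
  matrix(pred[, "droplet"], dim(bank)[1], dim(bank)[2])
}

# 8-connected labeling: 4-connected pass, then merge labels touching
# diagonally (union-find over label ids).
label_components8 <- function(mask) {
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nl <- max(lab)
  if (nl < 2L) return(lab)
  parent <- seq_len(nl)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1])))   # up-right
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(nl), find, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- dense[lab[lab > 0L]]
  out
}

#' Threshold a probability map into a droplet mask
#'
#' Pixels at or above `threshold` are droplet candidates; 8-connected
#' components smaller than `min_object_px` are removed as speckle.
#'
#' @param probability_map matrix in `[0, 1]`.
#' @param threshold scalar in `(0, 1)`.
#' @param min_object_px minimum component size kept (default 4).
#' @return Logical droplet mask.
#' @export
binarize <- function(probability_map, threshold = 0.5, min_object_px = 4L) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  mask <- probability_map >= threshold
  if (min_object_px > 1L && any(mask)) {
    lab <- label_components8(mask)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_object_px)
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  }
  mask
}

#' Segment droplets in a dye-channel image
#'
#' The full classification chain: probability map, threshold, small-object
#' removal.
#'
#' @inheritParams predict_probability
#' @inheritParams binarize
#' @return A list of class `segmentation_result` with `probability_map`,
#'   `threshold`, and `droplet_mask`.
#' @export
segment_image <- function(model, image, threshold = 0.5, min_object_px = 4L) {
  pm <- predict_probability(model, image)
  structure(list(probability_map = pm, threshold = threshold,
                 droplet_mask = binarize(pm, threshold, min_object_px)),
            class = "segmentation_result")
}

#' Save / load a trained pixel classifier
#'
#' The serialized model embeds its feature configuration; a reloaded model
#' produces bit-identical probability maps.
#'
#' @param model a `pixel_classifier`.
#' @param path file path (`.rds`).
#' @return `save_classifier` returns `path` invisibly; `load_classifier`
#'   returns the model.
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "pixel_classifier"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "pixel_classifier")) stop("not a pixel_classifier file")
  model
}

#' Intersection over union of two masks
#' @param a,b logical matrices of equal dimension.
#' @return IoU in `[0, 1]`; 1 when both masks are empty.
#' @export
mask_iou <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
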