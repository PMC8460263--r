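# Shared fixtures built in code. The trained classifier is cached for the
# test run because several files exercise the same separable two-intensity
# study conditions.

.fixture_env <- new.env(parent = emptyenv())

fixture_scene <- function(seed = 7, time_hr = 6, kind = "plin2_like", ...) {
  make_droplet_scene(scene_params(seed = seed, ...),
                     protein_schedule(kind), time_hr)
}

# Sparse truth-derived labels, as an annotator would paint them.
truth_labels <- function(scene, n_per_class = 400, seed = 1) {
  set.seed(seed)
  lab <- matrix(NA_character_, nrow(scene$dye$pixels), ncol(scene$dye$pixels))
  dr <- which(scene$truth$droplet_mask)
  bg <- which(!scene$truth$droplet_mask & scene$truth$roi$mask)
  lab[sample(dr, min(n_per_class, length(dr)))] <- "droplet"
  lab[sample(bg, min(n_per_class, length(bg)))] <- "background"
  lab
}

fixture_classifier <- function() {
  if (!is.null(.fixture_env$model)) return(.fixture_env$model)
  scenes <- list(fixture_scene(seed = 101, time_hr = 2),
                 fixture_scene(seed = 102, time_hr = 20))
  banks <- lapply(scenes, function(s) compute_feature_bank(s$dye))
  labs <- lapply(seq_along(scenes),
                 function(i) truth_labels(scenes[[i]], seed = 100 + i))
  .fixture_env$model <- train_pixel_classifier(banks, labs, seed = 5)
  .fixture_env$model
}
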