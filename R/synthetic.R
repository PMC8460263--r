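#' @title Synthetic two-channel droplet scenes with ground truth
#' @description Generators that emulate the statistical structure of confocal
#'   micrographs of intestinal enterocytes after a high-fat meal: bright
#'   lipid-dye puncta (droplets) over diffuse cytoplasmic and luminal signal,
#'   and a protein channel that mixes a droplet-rim component with a diffuse
#'   cytoplasmic component whose weights change over 0-30 h. Every scene
#'   records its noiseless ground truth so downstream stages can be tested
#'   for parameter recovery without any acquired data.
#' @name synthetic
NULL

# Run code under a fixed RNG seed, restoring the caller's RNG state after.
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Scene generation parameters
#'
#' Intensity levels are mean photon counts before quantization; droplet cores
#' must be brighter than the cytoplasm (they are segmented as the "brighter
#' puncta"). Defaults give a 4x core-to-cytoplasm contrast at 12-bit depth.
#'
#' @param image_size `c(nrow, ncol)` in pixels.
#' @param pixel_size_nm physical pixel size (nm).
#' @param n_droplets number of droplets to place.
#' @param radius_range_px `c(min, max)` droplet radius in pixels; radii must
#'   be at least 2 px.
#' @param rim_width_px thickness of the rim shell (annulus just inside the
#'   droplet boundary) carrying the rim protein component.
#' @param droplet_core_dye_intensity,cytoplasm_dye_intensity,lumen_dye_intensity
#'   mean dye-channel photon counts for the droplet interior, the enterocyte
#'   cytoplasm, and the intestinal lumen.
#' @param background_level offset outside the tissue ROI.
#' @param read_noise_sd Gaussian read-noise standard deviation (counts).
#' @param poisson_noise apply photon (Poisson) noise.
#' @param bit_depth quantization depth.
#' @param lumen_fraction fraction of the ROI height occupied by the central
#'   lumen band (no droplets are placed there).
#' @param seed RNG seed for placement and noise.
#' @return A list of class `scene_params`.
#' @export
scene_params <- function(image_size = c(128, 128), pixel_size_nm = 120,
                         n_droplets = 25, radius_range_px = c(3, 7),
                         rim_width_px = 2,
                         droplet_core_dye_intensity = 480,
                         cytoplasm_dye_intensity = 120,
                         lumen_dye_intensity = 250,
                         background_level = 20,
                         read_noise_sd = 3, poisson_noise = TRUE,
                         bit_depth = 12, lumen_fraction = 0.15, seed = 1L) {
  if (droplet_core_dye_intensity <= cytoplasm_dye_intensity ||
      cytoplasm_dye_intensity < 0) {
    stop("droplet cores must be brighter than the cytoplasm (core > cyto >= 0)")
  }
  if (radius_range_px[1] < 2) stop("droplet radii must be >= 2 px")
  if (read_noise_sd < 0) stop("read_noise_sd must be >= 0")
  structure(list(
    image_size = as.integer(image_size), pixel_size_nm = pixel_size_nm,
    n_droplets = as.integer(n_droplets),
    radius_range_px = as.numeric(radius_range_px),
    rim_width_px = as.numeric(rim_width_px),
    droplet_core_dye_intensity = droplet_core_dye_intensity,
    cytoplasm_dye_intensity = cytoplasm_dye_intensity,
    lumen_dye_intensity = lumen_dye_intensity,
    background_level = background_level,
    read_noise_sd = read_noise_sd, poisson_noise = poisson_noise,
    bit_depth = as.integer(bit_depth), lumen_fraction = lumen_fraction,
    seed = as.integer(seed)), class = "scene_params")
}

ramp_up <- function(t, onset, tau) {
  ifelse(t > onset, 1 - exp(-(t - onset) / tau), 0)
}
decay_after <- function(t, start, tau) {
  exp(-pmax(t - start, 0) / tau)
}

#' Time schedules for the protein channel
#'
#' Parametric rim and cytoplasm intensity trajectories over hours post-meal,
#' piecewise-smooth (delayed saturating rise times exponential decline):
#'
#' * `plin3_like` - protein present in the cytoplasm before the meal
#'   (`cyto(0) > 0`), rim signal peaking at the first imaging time and
#'   declining towards a plateau afterwards, flat at late times.
#' * `plin2_like` - no rim signal at `t = 0`, a delayed rise (detection from
#'   about 2-3 h), peak near `t_fall`, then a late decline.
#' * `overexpressed_like` - rim signal rising from the first sampled time
#'   (no expression delay), late decline.
#'
#' @param kind one of `"plin3_like"`, `"plin2_like"`, `"overexpressed_like"`.
#' @param rim_amplitude,rim_base peak-scale and plateau rim intensities
#'   (counts).
#' @param onset_hr delay before the rim component starts rising.
#' @param rise_tau_hr,decline_tau_hr rise and decline time constants (h).
#' @param decline_onset_hr time at which the decline factor engages.
#' @param cyto_base,cyto_amplitude cytoplasmic baseline and rise amplitude.
#' @return A list of class `protein_schedule` with functions
#'   `rim_intensity(t)` and `cyto_intensity(t)`.
#' @export
protein_schedule <- function(kind = c("plin3_like", "plin2_like",
                                      "overexpressed_like"),
                             rim_amplitude = NULL, rim_base = NULL,
                             onset_hr = NULL, rise_tau_hr = NULL,
                             decline_onset_hr = NULL, decline_tau_hr = NULL,
                             cyto_base = NULL, cyto_amplitude = NULL) {
  kind <- match.arg(kind)
  d <- switch(kind,
    plin3_like = list(rim_amplitude = 260, rim_base = 180, onset_hr = 0,
                      rise_tau_hr = 0.3, decline_onset_hr = 0.75,
                      decline_tau_hr = 2, cyto_base = 150,
                      cyto_amplitude = 0, cyto_tau_hr = 1),
    plin2_like = list(rim_amplitude = 420, rim_base = 0, onset_hr = 2,
                      rise_tau_hr = 2.5, decline_onset_hr = 10,
                      decline_tau_hr = 10, cyto_base = 30,
                      cyto_amplitude = 50, cyto_tau_hr = 3),
    overexpressed_like = list(rim_amplitude = 380, rim_base = 0, onset_hr = 0,
                              rise_tau_hr = 2, decline_onset_hr = 12,
                              decline_tau_hr = 12, cyto_base = 40,
                              cyto_amplitude = 30, cyto_tau_hr = 3))
  ov <- list(rim_amplitude = rim_amplitude, rim_base = rim_base,
             onset_hr = onset_hr, rise_tau_hr = rise_tau_hr,
             decline_onset_hr = decline_onset_hr,
             decline_tau_hr = decline_tau_hr, cyto_base = cyto_base,
             cyto_amplitude = cyto_amplitude)
  for (nm in names(ov)) if (!is.null(ov[[nm]])) d[[nm]] <- ov[[nm]]
  p <- d
  rim_fn <- function(t) {
    p$rim_base + p$rim_amplitude *
      ramp_up(t, p$onset_hr, p$rise_tau_hr) *
      decay_after(t, p$decline_onset_hr, p$decline_tau_hr)
  }
  cyto_fn <- function(t) {
    p$cyto_base + p$cyto_amplitude * ramp_up(t, 1, p$cyto_tau_hr)
  }
  structure(list(kind = kind, params = p, rim_intensity = rim_fn,
                 cyto_intensity = cyto_fn),
            class = "protein_schedule")
}

disk_mask <- function(shape, cx, cy, r_in, r_out) {
  # pixels with r_in < distance(center) <= r_out; r_in <= 0 gives the full disk
  nr <- shape[1]; nc <- shape[2]
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  d2 <- (rows - cy)^2 + (cols - cx)^2
  d2 <= r_out^2 & (r_in <= 0 | d2 > r_in^2)
}

#' Render one two-channel droplet scene
#'
#' The dye channel is piecewise constant by compartment (background outside
#' the ROI; lumen band, cytoplasm, and droplet cores inside). The protein
#' channel carries `cyto_intensity(t)` everywhere inside the ROI plus
#' `rim_intensity(t)` on each droplet's rim shell. Both channels then pass
#' through the Poisson + Gaussian noise model and quantization of
#' [apply_noise()]. Droplets are non-overlapping disks placed uniformly at
#' random in the ROI outside the lumen band.
#'
#' @param params a [scene_params()].
#' @param schedule a [protein_schedule()].
#' @param time_hr hours post-meal for this scene.
#' @param roi optional [region_of_interest()]; default spans the full frame.
#' @param subject_id subject label attached to both channels.
#' @return A list with `dye` and `protein` ([micrograph]s) and `truth`, a
#'   list recording droplet centers/radii, the droplet and rim-shell masks,
#'   the noiseless rim and cytoplasm protein means, and the noise settings.
#' @export
make_droplet_scene <- function(params, schedule, time_hr, roi = NULL,
                               subject_id = "scene1") {
  stopifnot(inherits(params, "scene_params"),
            inherits(schedule, "protein_schedule"))
  nr <- params$image_size[1]; nc <- params$image_size[2]
  if (is.null(roi)) roi <- full_roi(c(nr, nc))
  if (!all(dim(roi$mask) == c(nr, nc))) stop("ROI does not match image size")
  roi_px <- sum(roi$mask)
  exp_area <- params$n_droplets * pi * mean(params$radius_range_px)^2
  if (exp_area >= 0.3 * roi_px) {
    stop(sprintf(
      "infeasible droplet placement: expected droplet area %.0f px >= 30%% of ROI (%d px)",
      exp_area, roi_px))
  }
  lumen_rows <- integer(0)
  if (params$lumen_fraction > 0) {
    h <- round(params$lumen_fraction * nr)
    mid <- nr %/% 2
    lumen_rows <- seq(max(1, mid - h %/% 2), min(nr, mid + ceiling(h / 2) - 1))
  }
  lumen <- matrix(FALSE, nr, nc)
  lumen[lumen_rows, ] <- roi$mask[lumen_rows, ]

  local_seed(params$seed, {
    centers <- matrix(numeric(0), 0, 2)  # (cx = col, cy = row)
    radii <- numeric(0)
    droplet <- matrix(FALSE, nr, nc)
    rim <- matrix(FALSE, nr, nc)
    tries <- 0L; max_tries <- 400L * max(params$n_droplets, 1L)
    while (length(radii) < params$n_droplets) {
      if (tries >= max_tries) {
        stop(sprintf(
          "infeasible droplet placement after %d tries (%d of %d placed, density %.2f)",
          tries, length(radii), params$n_droplets, exp_area / roi_px))
      }
      tries <- tries + 1L
      r <- stats::runif(1, params$radius_range_px[1], params$radius_range_px[2])
      cy <- stats::runif(1, r + 1, nr - r)
      cx <- stats::runif(1, r + 1, nc - r)
      if (nrow(centers) > 0) {
        if (any(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2) <
                radii + r + 1)) next
      }
      dsk <- disk_mask(c(nr, nc), cx, cy, -1, r)
      if (!all(roi$mask[dsk]) || any(lumen[dsk])) next
      centers <- rbind(centers, c(cx, cy))
      radii <- c(radii, r)
      droplet <- droplet | dsk
      rim <- rim | disk_mask(c(nr, nc), cx, cy, r - params$rim_width_px, r)
    }

    dye_clean <- matrix(params$background_level, nr, nc)
    dye_clean[roi$mask] <- params$cytoplasm_dye_intensity
    dye_clean[lumen] <- params$lumen_dye_intensity
    dye_clean[droplet] <- params$droplet_core_dye_intensity

    rim_t <- schedule$rim_intensity(time_hr)
    cyto_t <- schedule$cyto_intensity(time_hr)
    prot_clean <- matrix(params$background_level, nr, nc)
    prot_clean[roi$mask] <- cyto_t
    prot_clean[rim] <- cyto_t + rim_t

    mk <- function(px, role) {
      micrograph(pmin(px, 2^params$bit_depth - 1),
                 pixel_size_nm = params$pixel_size_nm,
                 bit_depth = params$bit_depth, time_hr = time_hr,
                 channel_role = role, genotype_label = schedule$kind,
                 subject_id = subject_id)
    }
    dye <- apply_noise(mk(dye_clean, "lipid_dye"),
                       read_noise_sd = params$read_noise_sd,
                       bit_depth = params$bit_depth, seed = NULL,
                       poisson = params$poisson_noise)
    protein <- apply_noise(mk(prot_clean, "protein"),
                           read_noise_sd = params$read_noise_sd,
                           bit_depth = params$bit_depth, seed = NULL,
                           poisson = params$poisson_noise)
    truth <- list(
      centers = centers, radii = radii,
      droplet_mask = droplet, rim_mask = rim, lumen_mask = lumen,
      roi = roi, time_hr = time_hr,
      true_rim_mean = cyto_t + rim_t, true_cyto_mean = cyto_t,
      rim_intensity = rim_t, cyto_intensity = cyto_t,
      read_noise_sd = params$read_noise_sd,
      poisson_noise = params$poisson_noise, seed = params$seed)
    list(dye = dye, protein = protein, truth = truth)
  })
}

#' Photon + read noise with quantization
#'
#' Each pixel is drawn as `Poisson(mean = clean)` (if `poisson`), plus
#' `Gaussian(0, read_noise_sd)`, then clamped to `[0, 2^bit_depth - 1]` and
#' rounded to an integer count. Deterministic given `seed`.
#'
#' @param clean a [micrograph] (or plain matrix) of noise-free mean
#'   intensities, all `>= 0`.
#' @param read_noise_sd Gaussian read-noise sd in counts (`>= 0`).
#' @param bit_depth quantization depth.
#' @param seed RNG seed, or `NULL` to draw from the current RNG stream (used
#'   by the scene generators, which consume one seeded stream per scene so
#'   that distinct scene seeds give independent noise).
#' @param poisson apply the photon-noise (Poisson) component.
#' @return Same type as `clean`, with quantized noisy intensities.
#' @export
apply_noise <- function(clean, read_noise_sd = 3, bit_depth = 12, seed = 1L,
                        poisson = TRUE) {
  if (read_noise_sd < 0) stop("read_noise_sd must be >= 0")
  px <- if (inherits(clean, "micrograph")) clean$pixels else clean
  if (any(px < 0)) stop("clean intensities must be >= 0")
  draw <- function() {
    v <- if (poisson) stats::rpois(length(px), px) else as.numeric(px)
    if (read_noise_sd > 0) v <- v + stats::rnorm(length(px), 0, read_noise_sd)
    v
  }
  noisy <- if (is.null(seed)) draw() else local_seed(seed, draw())
  noisy <- matrix(pmin(pmax(round(noisy), 0), 2^bit_depth - 1),
                  nrow(px), ncol(px))
  if (inherits(clean, "micrograph")) {
    out <- clean
    out$pixels <- noisy
    out$bit_depth <- as.integer(bit_depth)
    out
  } else noisy
}

#' Whole-mount organ image series with wild-type siblings
#'
#' Emulates whole-intestine reporter imaging over a post-meal time course:
#' reporter fish carry `organ_signal(t) + autofluor_level` in a fixed organ
#' region (zero elsewhere), wild-type siblings carry the autofluorescence
#' only. Per-fish multiplicative variation of the reporter signal (lognormal,
#' mean 1) emulates variability in the amount of lipid consumed.
#'
#' @param n_fish_per_group fish per genotype per time-point (>= 2 wild-type).
#' @param time_points vector of hours post-meal.
#' @param organ_signal function of time returning the mean reporter intensity
#'   in the organ region (counts).
#' @param autofluor_level autofluorescence intensity in the organ region.
#' @param seed RNG seed.
#' @param image_size image dimensions.
#' @param variation_sd sdlog of the per-fish lognormal signal factor
#'   (0 disables).
#' @param read_noise_sd,poisson,bit_depth noise model, as [apply_noise()].
#' @return A list with `images` (list of [micrograph]s), `truth` (data.frame
#'   of per-fish true organ totals), and `roi` (the organ region).
#' @export
make_wholemount_series <- function(n_fish_per_group = 6,
                                   time_points = c(0, 2, 4, 6, 8),
                                   organ_signal = function(t) 100 * t,
                                   autofluor_level = 50, seed = 1L,
                                   image_size = c(64, 64),
                                   variation_sd = 0.2,
                                   read_noise_sd = 3, poisson = TRUE,
                                   bit_depth = 12) {
  if (length(time_points) == 0) stop("time_points must be non-empty")
  if (n_fish_per_group < 2) stop("need at least 2 wild-type fish per time-point")
  nr <- image_size[1]; nc <- image_size[2]
  organ <- matrix(FALSE, nr, nc)
  organ[round(nr * 0.25):round(nr * 0.75), round(nc * 0.15):round(nc * 0.85)] <- TRUE
  roi <- region_of_interest(organ)
  organ_px <- sum(organ)

  local_seed(seed, {
    images <- list(); rows <- list(); k <- 0L
    for (t in time_points) {
      for (g in c("reporter", "wild_type")) {
        for (f in seq_len(n_fish_per_group)) {
          k <- k + 1L
          fac <- if (variation_sd > 0) {
            stats::rlnorm(1, -variation_sd^2 / 2, variation_sd)
          } else 1
          sig <- if (g == "reporter") organ_signal(t) * fac else 0
          clean <- matrix(0, nr, nc)
          clean[organ] <- sig + autofluor_level
          mg <- micrograph(pmin(clean, 2^bit_depth - 1),
                           bit_depth = bit_depth, time_hr = t,
                           channel_role = "protein", genotype_label = g,
                           subject_id = sprintf("fish%03d", k))
          mg <- apply_noise(mg, read_noise_sd = read_noise_sd,
                            bit_depth = bit_depth, seed = NULL,
                            poisson = poisson)
          images[[k]] <- mg
          rows[[k]] <- data.frame(
            subject_id = mg$subject_id, genotype_label = g, time_hr = t,
            true_signal_mean = sig,
            true_total_signal = sig * organ_px,
            autofluor_level = autofluor_level,
            organ_px = organ_px, stringsAsFactors = FALSE)
        }
      }
    }
    list(images = images, truth = do.call(rbind, rows), roi = roi)
  })
}
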