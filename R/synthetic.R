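# Synthetic apple-scene generator: raw NIR hypercubes plus white/dark
# references and full ground truth, emulating calyx-view apple images so
# the whole pipeline is exercisable end to end. The emulated structure:
# smooth NIR reflectance with water-absorption valleys near 950, 1200 and
# 1400 nm, systematically lower reflectance for infested tissue, a bright
# fruit disk on a dark background with a darker calyx cavity, per-pixel
# gain (path-length proxy) and additive sensor noise, and dark current.

#' Scene configuration for the synthetic generator
#'
#' Defaults are the generator's study conditions: a 200 x 200 px calyx-view
#' scene with 128 bands over 900--1700 nm (`n_bands = 256` gives the
#' full-resolution preset), a fruit disk of radius 80 px with a dark calyx
#' cavity of radius 8 px at its centre, an infested lesion of radius 25 px
#' around the calyx, a multiplicative reflectance depression of 0.85 for
#' infested tissue, absorption valleys at 950/1200/1400 nm, additive noise
#' sd 0.01 (reflectance units), per-pixel gain sd 0.03, and a dark current
#' of 80 counts under a ~3500-count white level.
#'
#' The infested depression is wavelength-dependent,
#' `healthy * (effect + (1 - effect) * w(lambda))` with `w` a fixed ramp
#' from 0.8 at 900 nm to 0 at 1700 nm: reflectance is strictly lower at
#' every band (effect < 1) yet the spectral *shape* changes too, so the
#' class signal survives maximum normalization, which removes any flat
#' multiplicative factor.
#'
#' @param image_size `(H, W)` in pixels.
#' @param n_bands number of spectral bands.
#' @param wl_range wavelength range in nm.
#' @param apple_center,apple_radius fruit-disk geometry in px (centre
#'   defaults to the image centre).
#' @param calyx_center,calyx_radius calyx-cavity geometry in px (centre
#'   defaults to the apple centre); the cavity must lie inside the fruit.
#' @param lesion_radius infested-lesion radius around the calyx centre, px.
#' @param infested logical: does this scene carry an infestation?
#' @param effect multiplicative reflectance depression for infested tissue
#'   (1 = null effect; default 0.85).
#' @param valleys list of `(center_nm, depth, width_nm)` absorption valleys;
#'   depths in (0,1).
#' @param noise_add_sd additive noise sd in reflectance units.
#' @param noise_mult_sd per-pixel multiplicative gain sd.
#' @param dark_current dark level in counts.
#' @param white_level peak white-reference level in counts.
#' @param seed integer seed.
#' @return a `scene_config` list.
#' @export
scene_config <- function(image_size = c(200, 200), n_bands = 128,
                         wl_range = c(900, 1700),
                         apple_center = NULL, apple_radius = 80,
                         calyx_center = NULL, calyx_radius = 8,
                         lesion_radius = 25, infested = FALSE,
                         effect = 0.85,
                         valleys = list(c(950, 0.12, 30),
                                        c(1200, 0.18, 45),
                                        c(1400, 0.30, 55)),
                         noise_add_sd = 0.01, noise_mult_sd = 0.03,
                         dark_current = 80, white_level = 3500,
                         seed = 1) {
  if (is.null(apple_center)) apple_center <- (image_size + 1) / 2
  if (is.null(calyx_center)) calyx_center <- apple_center
  cs_assert(apple_radius > 0 && calyx_radius > 0 && lesion_radius > 0,
            "all radii must be positive")
  cs_assert(effect > 0 && effect <= 1, "`effect` must be in (0, 1]")
  for (v in valleys) {
    cs_assert(length(v) == 3L && v[2] > 0 && v[2] < 1 && v[3] > 0,
              "each valley is (center_nm, depth in (0,1), width_nm)")
  }
  # calyx cavity must sit fully inside the fruit disk
  d_cc <- sqrt(sum((calyx_center - apple_center)^2))
  if (d_cc + calyx_radius > apple_radius) {
    cs_stop("calyx disk extends outside the apple disk",
            "calyxscan_config_error")
  }
  structure(list(
    image_size = image_size, n_bands = n_bands, wl_range = wl_range,
    apple_center = apple_center, apple_radius = apple_radius,
    calyx_center = calyx_center, calyx_radius = calyx_radius,
    lesion_radius = lesion_radius, infested = infested, effect = effect,
    valleys = valleys, noise_add_sd = noise_add_sd,
    noise_mult_sd = noise_mult_sd, dark_current = dark_current,
    white_level = white_level, seed = seed
  ), class = "scene_config")
}

scene_wavelengths <- function(config) {
  seq(config$wl_range[1L], config$wl_range[2L], length.out = config$n_bands)
}

#' Noiseless endmember spectrum of a scene material
#'
#' Healthy fruit flesh: a smooth concave baseline minus Gaussian absorption
#' valleys at the configured centres. Infested tissue: the healthy spectrum
#' times the wavelength-dependent depression described in [scene_config()].
#' Calyx cavity: strongly darkened healthy tissue (x 0.25). Background:
#' a flat near-dark-current reflectance of 0.02.
#'
#' @param kind one of `"healthy"`, `"infested"`, `"calyx"`, `"background"`.
#' @param config a [scene_config()].
#' @return numeric reflectance spectrum of length `n_bands`.
#' @export
endmember_spectrum <- function(kind = c("healthy", "infested", "calyx",
                                        "background"),
                               config = scene_config()) {
  kind <- match.arg(kind)
  wl <- scene_wavelengths(config)
  u <- (wl - config$wl_range[1L]) / diff(config$wl_range)
  baseline <- 0.72 + 0.18 * u - 0.38 * u^2
  vall <- rep(0, length(wl))
  for (v in config$valleys) {
    vall <- vall + v[2] * exp(-(wl - v[1])^2 / (2 * v[3]^2))
  }
  healthy <- baseline * (1 - vall)
  switch(kind,
    healthy = healthy,
    infested = healthy * (config$effect + (1 - config$effect) * 0.8 * (1 - u)),
    calyx = healthy * 0.25,
    background = rep(0.02, length(wl))
  )
}

#' Generate one raw apple scene with references and ground truth
#'
#' Composes the endmember reflectances over the scene masks, applies a
#' per-pixel multiplicative gain and additive band noise, then maps
#' reflectance to raw counts through a mildly non-flat white envelope and a
#' dark-current offset, so that [calibrate()] recovers the (noisy)
#' reflectances. Reference frames are returned noiseless, representing
#' daily-averaged white/dark captures. Raw counts are clamped at zero.
#'
#' @param config a [scene_config()].
#' @return list with `raw` (counts [hypercube]), `refs` ([reference_pair]),
#'   `truth` (list of masks `background`/`fruit`/`calyx`/`infested`, the
#'   per-pixel `labels` matrix, and the noiseless `endmembers`).
#' @export
generate_scene <- function(config = scene_config()) {
  H <- config$image_size[1L]; W <- config$image_size[2L]
  B <- config$n_bands
  wl <- scene_wavelengths(config)

  dist2 <- function(center) {
    outer((seq_len(H) - center[1L])^2, (seq_len(W) - center[2L])^2, `+`)
  }
  fruit <- dist2(config$apple_center) <= config$apple_radius^2
  calyx <- dist2(config$calyx_center) <= config$calyx_radius^2
  lesion <- if (config$infested) {
    dist2(config$calyx_center) <= config$lesion_radius^2 & fruit & !calyx
  } else {
    matrix(FALSE, H, W)
  }
  background <- !fruit
  healthy_m <- fruit & !calyx & !lesion

  em <- list(healthy = endmember_spectrum("healthy", config),
             infested = endmember_spectrum("infested", config),
             calyx = endmember_spectrum("calyx", config),
             background = endmember_spectrum("background", config))

  labels <- matrix("background", H, W)
  labels[healthy_m] <- "healthy"
  labels[lesion] <- "infested"
  labels[calyx] <- "calyx"

  set.seed(config$seed)
  refl <- matrix(0, H * W, B)
  for (kind in names(em)) {
    sel <- which(labels == switch(kind, healthy = "healthy",
                                  infested = "infested", calyx = "calyx",
                                  background = "background"))
    if (length(sel)) refl[sel, ] <- rep(em[[kind]], each = length(sel))
  }
  if (config$noise_mult_sd > 0) {
    gain <- pmax(0.2, stats::rnorm(H * W, 1, config$noise_mult_sd))
    refl <- refl * gain
  }
  if (config$noise_add_sd > 0) {
    refl <- refl + matrix(stats::rnorm(H * W * B, 0, config$noise_add_sd),
                          H * W, B)
  }

  white_env <- config$white_level * (0.8 + 0.2 * sin(pi * (wl - min(wl)) /
                                                       diff(range(wl))))
  denom <- white_env - config$dark_current
  raw <- sweep(refl, 2L, denom, `*`) + config$dark_current
  raw[raw < 0] <- 0

  raw_cube <- hypercube(array(raw, c(H, W, B)), wl,
                        name = sprintf("scene_seed%d", config$seed),
                        meta = list(
                          label = if (config$infested) "infested" else "healthy",
                          infested = as.character(config$infested)))
  white_cube <- hypercube(
    array(rep(white_env, each = H * W), c(H, W, B)), wl, name = "white_ref")
  dark_cube <- hypercube(
    array(config$dark_current, c(H, W, B)), wl, name = "dark_ref")

  list(raw = raw_cube,
       refs = reference_pair(white_cube, dark_cube),
       truth = list(background = background, fruit = fruit, calyx = calyx,
                    infested = lesion, labels = labels, endmembers = em,
                    config = config))
}

#' Generate a labeled study of control and infested apples
#'
#' One scene per apple with apple-level labels. Between-apple variability is
#' a geometric jitter of the fruit/calyx placement plus a scalar baseline
#' gain -- exactly the nuisance factors the preprocessing chain (maximum
#' normalization) is designed to remove, so a null-effect study carries no
#' exploitable apple signature. Per-apple seeds derive deterministically
#' from the master seed. The default 20/40 control/infested split mirrors a
#' typical artificial-infestation study design.
#'
#' @param n_control,n_infested apple counts per class.
#' @param config template [scene_config()]; per-apple copies get
#'   `infested` set and jittered geometry.
#' @param seed master seed.
#' @param jitter list: `center_px` (max uniform centre shift), `radius_px`
#'   (max uniform radius shift), `gain_sd` (sd of the per-apple scalar
#'   reflectance gain).
#' @return list of scenes as returned by [generate_scene()], each with
#'   `$apple_id` and `$label` added.
#' @export
generate_study <- function(n_control = 20, n_infested = 40,
                           config = scene_config(), seed = 1,
                           jitter = list(center_px = 3, radius_px = 4,
                                         gain_sd = 0.05)) {
  cs_assert(is_count(n_control) && is_count(n_infested),
            "apple counts must be positive integers")
  n <- n_control + n_infested
  labels <- rep(c("healthy", "infested"), c(n_control, n_infested))
  scenes <- vector("list", n)
  for (i in seq_len(n)) {
    apple_seed <- derive_seed(seed, i)
    set.seed(apple_seed)
    cfg <- config
    cfg$infested <- labels[i] == "infested"
    if (jitter$center_px > 0) {
      shift <- stats::runif(2, -jitter$center_px, jitter$center_px)
      cfg$apple_center <- config$apple_center + shift
      cfg$calyx_center <- config$calyx_center + shift
    }
    if (jitter$radius_px > 0) {
      cfg$apple_radius <- config$apple_radius +
        stats::runif(1, -jitter$radius_px, jitter$radius_px)
    }
    gain <- if (jitter$gain_sd > 0) {
      max(0.5, stats::rnorm(1, 1, jitter$gain_sd))
    } else 1
    cfg$seed <- derive_seed(apple_seed, 1000L)
    sc <- generate_scene(cfg)
    if (gain != 1) {
      # scalar apple-level reflectance gain, applied in the count domain
      # above dark current so calibration recovers gain * reflectance
      dc <- cfg$dark_current
      sc$raw$data <- (sc$raw$data - dc) * gain + dc
      sc$raw$data[sc$raw$data < 0] <- 0
    }
    sc$apple_id <- sprintf("apple%03d", i)
    sc$label <- labels[i]
    scenes[[i]] <- sc
  }
  scenes
}
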