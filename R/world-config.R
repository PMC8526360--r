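#' Configuration of the simulated visual world
#'
#' Defines the procedural world of bumpy, glossy/matte sheets from which all
#' stimuli are rendered: a flat square sheet with irregular bumps, viewed
#' top-down, lit by one of a fixed set of seeded multi-directional light
#' fields, with diffuse albedo, surface relief and specular reflectance drawn
#' independently per scene.
#'
#' Gloss regimes:
#' * `"bimodal"` — half the scenes low gloss (specular magnitude U(0.1, 0.3),
#'   concentration U(0.2, 0.4)), half high gloss (magnitude U(0.3, 0.5),
#'   concentration U(0.75, 0.95)).
#' * `"continuous"` — magnitude and concentration independently U(0.1, 0.8).
#' * `"rating_probe"` — magnitude U(0.2, 1.0) with concentration set equal to
#'   the magnitude.
#' * `"higher_variation"` — as bimodal, but with 10 bump-kernel families,
#'   50 seeded light fields and camera-height jitter (scale factor 0.8–1.2).
#'
#' @param image_size Pixels per side of rendered images (default 64; 32 is a
#'   convenient small scale, 128 the full scale).
#' @param sheet_extent Side length of the sheet in scene units (cm).
#' @param n_lightfields Number of distinct fixed light fields.
#' @param relief_range Min/max surface relief (max - min elevation), scene units.
#' @param albedo_range Per-channel diffuse reflectance range.
#' @param gloss_regime One of `"bimodal"`, `"continuous"`, `"rating_probe"`,
#'   `"higher_variation"`.
#' @param bimodal_low,bimodal_high Lists with `magnitude` and `concentration`
#'   ranges for the two gloss modes.
#' @param continuous_range Magnitude/concentration range for the continuous regime.
#' @param rating_probe_range Magnitude range for the rating-probe regime.
#' @param camera_jitter List with `translation` (max offset, scene units) and
#'   `rotation` (max rotation, degrees).
#' @param camera_height Camera height above the sheet, scene units (12).
#' @param camera_fov Field of view in degrees (60); together with the height
#'   this sets the visible window (about 14 units) and the per-pixel view
#'   directions used for specular shading.
#' @param supersample Anti-aliasing factor: scenes are shaded at
#'   `supersample` times the target resolution and block-averaged down, so
#'   that tight specular lobes are sampled adequately.
#' @param lightfield_offset Integer added to light-field ids; use a non-zero
#'   offset to obtain light fields disjoint from the default six (novel
#'   illumination for generalization tests).
#' @param master_seed Integer seed recorded with the configuration.
#' @return A `world_config` object (a validated list).
#' @export
world_config <- function(image_size = 64L,
                         sheet_extent = 40,
                         n_lightfields = 6L,
                         relief_range = c(0.1, 2.5),
                         albedo_range = c(0.3, 0.7),
                         gloss_regime = c("bimodal", "continuous",
                                          "rating_probe", "higher_variation"),
                         bimodal_low = list(magnitude = c(0.1, 0.3),
                                            concentration = c(0.2, 0.4)),
                         bimodal_high = list(magnitude = c(0.3, 0.5),
                                             concentration = c(0.75, 0.95)),
                         continuous_range = c(0.1, 0.8),
                         rating_probe_range = c(0.2, 1.0),
                         camera_jitter = list(translation = 5, rotation = 15),
                         camera_height = 12,
                         camera_fov = 60,
                         supersample = 2L,
                         lightfield_offset = 0L,
                         master_seed = 1L) {
  gloss_regime <- match.arg(gloss_regime)
  stopifnot(image_size >= 16, n_lightfields >= 2,
            length(relief_range) == 2, relief_range[1] <= relief_range[2],
            relief_range[1] >= 0,
            length(albedo_range) == 2, albedo_range[1] < albedo_range[2],
            albedo_range[1] >= 0, albedo_range[2] <= 1)
  rng_ok <- function(r) length(r) == 2 && r[1] < r[2] && r[1] >= 0
  stopifnot(rng_ok(bimodal_low$magnitude), rng_ok(bimodal_low$concentration),
            rng_ok(bimodal_high$magnitude), rng_ok(bimodal_high$concentration),
            rng_ok(continuous_range), rng_ok(rating_probe_range))
  structure(list(image_size = as.integer(image_size),
                 sheet_extent = sheet_extent,
                 n_lightfields = as.integer(n_lightfields),
                 relief_range = relief_range,
                 albedo_range = albedo_range,
                 gloss_regime = gloss_regime,
                 bimodal_low = bimodal_low,
                 bimodal_high = bimodal_high,
                 continuous_range = continuous_range,
                 rating_probe_range = rating_probe_range,
                 camera_jitter = camera_jitter,
                 camera_height = camera_height,
                 camera_fov = camera_fov,
                 supersample = as.integer(supersample),
                 lightfield_offset = as.integer(lightfield_offset),
                 master_seed = as.integer(master_seed)),
            class = "world_config")
}

#' @export
print.world_config <- function(x, ...) {
  cat("<world_config> ", x$image_size, "px, ", x$n_lightfields,
      " light fields, regime '", x$gloss_regime, "'\n", sep = "")
  invisible(x)
}

# Deterministic 31-bit child seed; keeps every derived seed inside R's
# integer range.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 16807 + 12345) %%
               2147483647)
}

# Evaluate thunk under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Sample scene parameters from the configured world
#'
#' Draws all generative factors of one or more scenes: light field, surface
#' relief, per-channel diffuse albedo, specular magnitude/concentration per
#' the configured gloss regime, bump-layout seed, and camera jitter. In the
#' bimodal regime each scene is low or high gloss with probability 0.5.
#'
#' @param config A [world_config()].
#' @param n Number of scenes.
#' @param seed Optional seed; if `NULL`, the current RNG stream is used.
#' @return A tibble with one row per scene: `scene_id`, `lightfield_id`,
#'   `lamp_angle` (NA unless a lamp scene), `relief_depth`, `albedo_r/g/b`,
#'   `spec_magnitude`, `spec_concentration`, `gloss_label`, `bump_seed`,
#'   `cam_dx`, `cam_dy`, `cam_rot`, `cam_scale`.
#' @export
sample_scene <- function(config, n = 1L, seed = NULL) {
  stopifnot(inherits(config, "world_config"))
  if (!is.null(seed)) return(with_seed(seed, sample_scene(config, n)))
  regime <- config$gloss_regime
  runif2 <- function(m, r) stats::runif(m, r[1], r[2])
  if (regime == "bimodal" || regime == "higher_variation") {
    lab <- sample(c("low", "high"), n, replace = TRUE)
    lo <- lab == "low"
    mag <- numeric(n); conc <- numeric(n)
    mag[lo] <- runif2(sum(lo), config$bimodal_low$magnitude)
    conc[lo] <- runif2(sum(lo), config$bimodal_low$concentration)
    mag[!lo] <- runif2(sum(!lo), config$bimodal_high$magnitude)
    conc[!lo] <- runif2(sum(!lo), config$bimodal_high$concentration)
  } else if (regime == "continuous") {
    lab <- rep("unlabeled", n)
    mag <- runif2(n, config$continuous_range)
    conc <- runif2(n, config$continuous_range)
  } else if (regime == "rating_probe") {
    lab <- rep("unlabeled", n)
    mag <- runif2(n, config$rating_probe_range)
    conc <- mag
  } else {
    stop("unknown gloss regime: ", regime)
  }
  n_lf <- if (regime == "higher_variation") 50L else config$n_lightfields
  n_fam <- if (regime == "higher_variation") 10L else 1L
  cam_scale <- if (regime == "higher_variation") stats::runif(n, 0.8, 1.2) else rep(1, n)
  jt <- config$camera_jitter$translation
  jr <- config$camera_jitter$rotation
  tibble::tibble(
    scene_id = seq_len(n),
    lightfield_id = sample.int(n_lf, n, replace = TRUE) + config$lightfield_offset,
    lamp_angle = rep(NA_real_, n),
    relief_depth = runif2(n, config$relief_range),
    albedo_r = runif2(n, config$albedo_range),
    albedo_g = runif2(n, config$albedo_range),
    albedo_b = runif2(n, config$albedo_range),
    spec_magnitude = mag,
    spec_concentration = conc,
    gloss_label = lab,
    bump_family = sample.int(n_fam, n, replace = TRUE),
    bump_seed = sample.int(2147483646L, n, replace = TRUE),
    cam_dx = stats::runif(n, -jt, jt),
    cam_dy = stats::runif(n, -jt, jt),
    cam_rot = stats::runif(n, -jr, jr),
    cam_scale = cam_scale
  )
}
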