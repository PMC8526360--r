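# Procedural renderer: height-field geometry, Lambertian diffuse shading and
# a Blinn-style specular lobe under fixed seeded multi-directional light
# fields, with the diffuse and specular components kept separate.

# Visible window of the sheet, in scene units: 2 * height * tan(fov / 2).
window_extent <- function(config) {
  h <- if (is.null(config$camera_height)) 12 else config$camera_height
  fov <- if (is.null(config$camera_fov)) 60 else config$camera_fov
  2 * h * tan(fov / 2 * pi / 180)
}

# Shininess exponent from specular concentration: exp(a + b * conc), anchored
# so concentration 0.2 gives a broad lobe (~5) and 0.95 a tight one (~200).
shininess_from_concentration <- function(conc) {
  b <- log(40) / 0.75
  a <- log(5) - 0.2 * b
  exp(a + b * conc)
}

#' Construct a fixed light field
#'
#' Each light-field id maps deterministically to a set of 8–16 directional
#' lights with a distinct dominant azimuth and colour temperature, plus an
#' ambient term. Intensities are normalized so that a flat white Lambertian
#' sheet renders to mean intensity 0.55. `lamp_lightfield()` gives the single
#' directional "lamp" illumination at a stated elevation used by the
#' constancy-pair stimuli.
#'
#' @param id Integer light-field index (any integer; ids beyond the default
#'   six give novel illumination).
#' @param lighting_seed Global seed shared by all light fields.
#' @return A `lightfield` list with `dirs` (n x 3 unit rows, z up), `intensity`,
#'   `color` (n x 3), and `ambient`.
#' @export
make_lightfield <- function(id, lighting_seed = 2024L) {
  with_seed(derive_seed(lighting_seed, id), {
    n <- sample(8:16, 1)
    dom_az <- (id * 61.8) %% 360
    az <- (dom_az + stats::rnorm(n, sd = 50)) * pi / 180
    el <- stats::runif(n, 25, 70) * pi / 180
    dirs <- cbind(cos(el) * cos(az), cos(el) * sin(az), sin(el))
    # one dominant source (sun-like) plus dimmer fill lights, as in natural
    # light probes
    intensity <- stats::runif(n, 0.05, 0.25)
    intensity[1] <- sum(intensity) * stats::runif(1, 0.8, 1.6)
    temp <- stats::runif(1, -1, 1)
    color <- cbind(pmax(0.5, 1 + 0.15 * temp + stats::rnorm(n, sd = 0.03)),
                   rep(1, n),
                   pmax(0.5, 1 - 0.15 * temp + stats::rnorm(n, sd = 0.03)))
    color <- color / apply(color, 1, max)
    ambient <- stats::runif(1, 0.05, 0.15)
    flat <- sum(intensity * rowMeans(color) * dirs[, 3])
    intensity <- intensity * (0.55 - ambient) / flat
    structure(list(id = id, dirs = dirs, intensity = intensity,
                   color = color, ambient = ambient),
              class = "lightfield")
  })
}

#' @rdname make_lightfield
#' @param elevation Lamp elevation above the sheet plane, degrees (30 or 90
#'   in the constancy pairs).
#' @param azimuth Lamp azimuth, degrees.
#' @export
lamp_lightfield <- function(elevation, azimuth = 0) {
  el <- elevation * pi / 180; az <- azimuth * pi / 180
  ambient <- 0.08
  dirs <- matrix(c(cos(el) * cos(az), cos(el) * sin(az), sin(el)), 1)
  structure(list(id = NA_integer_, dirs = dirs,
                 intensity = (0.55 - ambient) / max(dirs[1, 3], 0.05),
                 color = matrix(1, 1, 3), ambient = ambient),
            class = "lightfield")
}

#' Build the bump height field of a scene
#'
#' Sums randomly placed radial (Gaussian) bump kernels seeded by the scene's
#' `bump_seed`, evaluates them on the pixel grid under the scene's camera
#' offset/rotation/scale, and affinely rescales so that max - min equals the
#' scene's relief depth. Deterministic given (bump_seed, size, relief_depth,
#' camera).
#'
#' @param params One scene row (see [sample_scene()]) as a list or one-row
#'   data frame.
#' @param size Grid resolution in pixels.
#' @param config A [world_config()] (supplies the sheet extent).
#' @param margin Extra pixels rendered above/left of the nominal window
#'   (supports the translate-highlights manipulation).
#' @return A (size + margin) square matrix of elevations in scene units.
#' @export
build_heightfield <- function(params, size, config, margin = 0L) {
  params <- as.list(params)
  stopifnot(size >= 16)
  ext <- config$sheet_extent
  fam <- if (is.null(params$bump_family)) 1L else params$bump_family
  bumps <- with_seed(derive_seed(params$bump_seed, fam), {
    n_b <- 30L
    list(x = stats::runif(n_b, -0.25 * ext, 1.25 * ext),
         y = stats::runif(n_b, -0.25 * ext, 1.25 * ext),
         r = stats::runif(n_b, 0.05 * ext, 0.15 * ext) *
           (1 + 0.25 * ((fam - 1) %% 5) / 4),
         h = stats::runif(n_b, 0.5, 1))
  })
  n <- size + margin
  # the camera sees a window of the sheet set by height and field of view
  wext <- window_extent(config)
  px <- wext / size
  # pixel centre coordinates within the window; the margin extends up/left
  cx <- (seq_len(n) - 0.5 - margin) * px
  cy <- (seq_len(n) - 0.5 - margin) * px
  th <- params$cam_rot * pi / 180
  sc <- if (is.null(params$cam_scale)) 1 else params$cam_scale
  gx <- outer(rep(1, n), cx) - wext / 2
  gy <- outer(cy, rep(1, n)) - wext / 2
  wx <- (cos(th) * gx - sin(th) * gy) * sc + ext / 2 + params$cam_dx
  wy <- (sin(th) * gx + cos(th) * gy) * sc + ext / 2 + params$cam_dy
  h <- matrix(0, n, n)
  for (i in seq_along(bumps$x)) {
    h <- h + bumps$h[i] *
      exp(-((wx - bumps$x[i])^2 + (wy - bumps$y[i])^2) / (2 * bumps$r[i]^2))
  }
  rng <- max(h) - min(h)
  if (rng < .Machine$double.eps || params$relief_depth == 0) {
    h[] <- 0
  } else {
    h <- (h - min(h)) / rng * params$relief_depth
  }
  h
}

#' Render one scene
#'
#' Computes per-pixel surface normals from central finite differences of the
#' height field, then shades each light: the diffuse channel is
#' albedo * sum(intensity * color * max(0, n.l)) plus an ambient term, and the
#' specular channel is magnitude * sum(intensity * color * max(0, n.h)^s)
#' where h is the half-vector to the top-down viewer and s the shininess
#' mapped from specular concentration. Components are stored separately;
#' the composite is the clipped sum.
#'
#' @inheritParams build_heightfield
#' @param lightfield Optional pre-built [make_lightfield()] object; by default
#'   it is derived from `params$lightfield_id` (or from `params$lamp_angle`
#'   when that is non-missing).
#' @return A `rendered_scene` list: `diffuse`, `specular`, `composite`
#'   (H x W x 3 arrays in \[0,1\]), `specular_raw` (pre-clipping), `params`.
#' @export
render_scene <- function(params, config, lightfield = NULL, margin = 0L) {
  params <- as.list(params)
  ss <- if (is.null(config$supersample)) 1L else config$supersample
  h <- build_heightfield(params, config$image_size * ss, config,
                         margin = margin * ss)
  if (any(!is.finite(h))) stop("non-finite elevation in height field")
  if (is.null(lightfield)) {
    lightfield <- if (!is.null(params$lamp_angle) && !is.na(params$lamp_angle))
      lamp_lightfield(params$lamp_angle)
    else make_lightfield(params$lightfield_id)
  }
  n <- nrow(h)
  size_ss <- config$image_size * ss
  margin_ss <- n - size_ss
  wext <- window_extent(config)
  px <- wext / size_ss
  pad <- function(m) m[c(1, seq_len(n), n), c(1, seq_len(n), n)]
  hp <- pad(h)
  gx <- (hp[2:(n + 1), 3:(n + 2)] - hp[2:(n + 1), 1:n]) / (2 * px)
  gy <- (hp[3:(n + 2), 2:(n + 1)] - hp[1:n, 2:(n + 1)]) / (2 * px)
  norm <- sqrt(gx^2 + gy^2 + 1)
  nx <- -gx / norm; ny <- -gy / norm; nz <- 1 / norm
  # per-pixel view vector to the perspective camera above the window centre
  cam_h <- if (is.null(config$camera_height)) 12 else config$camera_height
  ux_ <- (seq_len(n) - 0.5 - margin_ss) * px - wext / 2
  ux <- outer(rep(1, n), ux_)
  uy <- outer(ux_, rep(1, n))
  vnorm <- sqrt(ux^2 + uy^2 + cam_h^2)
  vx <- -ux / vnorm; vy <- -uy / vnorm; vz <- cam_h / vnorm
  albedo <- c(params$albedo_r, params$albedo_g, params$albedo_b)
  shin <- shininess_from_concentration(params$spec_concentration)
  # energy-conserving lobe: tight lobes are small but bright, broad lobes dim
  lobe_norm <- (shin + 2) / (2 * pi)
  diff_img <- array(0, c(n, n, 3))
  spec_img <- array(0, c(n, n, 3))
  for (i in seq_along(lightfield$intensity)) {
    l <- lightfield$dirs[i, ]
    ndl <- pmax(0, nx * l[1] + ny * l[2] + nz * l[3])
    hx <- l[1] + vx; hy <- l[2] + vy; hz <- l[3] + vz
    hn <- sqrt(hx^2 + hy^2 + hz^2)
    ndh <- pmax(0, (nx * hx + ny * hy + nz * hz) / hn)^shin
    for (ch in 1:3) {
      diff_img[, , ch] <- diff_img[, , ch] +
        albedo[ch] * lightfield$intensity[i] * lightfield$color[i, ch] * ndl
      spec_img[, , ch] <- spec_img[, , ch] +
        params$spec_magnitude * lobe_norm * lightfield$intensity[i] *
        lightfield$color[i, ch] * ndh
    }
  }
  for (ch in 1:3)
    diff_img[, , ch] <- diff_img[, , ch] + lightfield$ambient * albedo[ch]
  if (ss > 1) {
    diff_img <- block_mean3(diff_img, ss)
    spec_img <- block_mean3(spec_img, ss)
  }
  spec_raw <- spec_img
  diff_img <- pmin(pmax(diff_img, 0), 1)
  spec_img <- pmin(pmax(spec_img, 0), 1)
  structure(list(diffuse = diff_img,
                 specular = spec_img,
                 composite = pmin(diff_img + spec_img, 1),
                 specular_raw = spec_raw,
                 margin = margin,
                 params = params),
            class = "rendered_scene")
}

#' @export
print.rendered_scene <- function(x, ...) {
  cat("<rendered_scene> ", dim(x$composite)[1], "x", dim(x$composite)[2],
      ", gloss mag ", signif(x$params$spec_magnitude, 3), "\n", sep = "")
  invisible(x)
}

#' Crop the margin off an oversized render component
#'
#' Keeps the lower-right `size` x `size` window, matching the convention that
#' translated specular components are cropped after shifting.
#' @param img H x W x 3 array with margin rows/cols at top/left.
#' @param size Target size in pixels.
#' @export
crop_margin <- function(img, size) {
  n <- dim(img)[1]
  stopifnot(n >= size)
  img[(n - size + 1):n, (n - size + 1):n, , drop = FALSE]
}

#' Quantize an image to 8-bit levels
#'
#' @param img Array in \[0,1\].
#' @return Integer array of the same shape with values 0..255.
#' @export
quantize8 <- function(img) {
  q <- as.integer(round(pmin(pmax(img, 0), 1) * 255))
  array(q, dim(img))
}

#' BT.601 greyscale conversion
#' @param img H x W x 3 array.
#' @return H x W matrix.
#' @export
rgb_to_grey <- function(img) {
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Generate a rendered dataset
#'
#' Samples `n` scenes from the configured world, renders them, quantizes the
#' composites to 8 bits, and records a manifest with a deterministic split:
#' the first 90% train, next 5% validation, final 5% test.
#'
#' @param config A [world_config()].
#' @param n Number of images.
#' @param seed Integer seed controlling everything.
#' @param keep_components Keep per-image diffuse/specular component arrays
#'   (needed by highlight-cue analyses); off by default to save memory.
#' @param dir Optional directory; when given, composites are written as PNG
#'   files and the manifest/config as CSV/JSON sidecars.
#' @return A `gloss_dataset` list: `manifest` (tibble with `path`, `split` and
#'   all scene parameters), `images` (n x H x W x 3 integer array, 0..255),
#'   optional `diffuse`/`specular` arrays in \[0,1\], and `config`.
#' @export
generate_dataset <- function(config, n, seed, keep_components = FALSE,
                             dir = NULL) {
  stopifnot(n >= 1)
  manifest <- sample_scene(config, n = n, seed = seed)
  n_train <- floor(0.9 * n)
  n_val <- floor(0.05 * n)
  split <- rep("train", n)
  if (n_val > 0) split[(n_train + 1):(n_train + n_val)] <- "validation"
  if (n_train + n_val < n) split[(n_train + n_val + 1):n] <- "test"
  sz <- config$image_size
  images <- array(0L, c(n, sz, sz, 3))
  diffuse <- if (keep_components) array(0, c(n, sz, sz, 3)) else NULL
  specular <- if (keep_components) array(0, c(n, sz, sz, 3)) else NULL
  for (i in seq_len(n)) {
    sc <- render_scene(manifest[i, ], config)
    images[i, , , ] <- quantize8(sc$composite)
    if (keep_components) {
      diffuse[i, , , ] <- sc$diffuse
      specular[i, , , ] <- sc$specular
    }
  }
  manifest$split <- split
  manifest$path <- sprintf("img_%05d.png", seq_len(n))
  manifest <- manifest[, c("path", "split",
                           setdiff(names(manifest), c("path", "split")))]
  ds <- structure(list(manifest = manifest, images = images,
                       diffuse = diffuse, specular = specular,
                       config = config, seed = seed),
                  class = "gloss_dataset")
  if (!is.null(dir)) write_dataset(ds, dir)
  ds
}

#' @export
print.gloss_dataset <- function(x, ...) {
  cat("<gloss_dataset> ", dim(x$images)[1], " images, ",
      dim(x$images)[2], "px, regime '", x$config$gloss_regime, "'\n", sep = "")
  invisible(x)
}

#' Write a dataset's images and manifest to disk
#'
#' PNG files are 8-bit RGB in linear encoding (no gamma), as documented in the
#' JSON sidecar next to the manifest.
#' @param dataset A [generate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @export
write_dataset <- function(dataset, dir) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required to write image files")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- dim(dataset$images)[1]
  for (i in seq_len(n)) {
    img <- dataset$images[i, , , ] / 255
    png::writePNG(img, file.path(dir, dataset$manifest$path[i]))
  }
  utils::write.csv(dataset$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  cfg <- dataset$config
  class(cfg) <- NULL
  jsonlite::write_json(list(config = cfg, seed = dataset$seed,
                            encoding = "linear-8bit"),
                       file.path(dir, "config.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Relief schedules for the constancy sequences
#'
#' The default is the geometric progression from 0.10 to 3.0 scene units in
#' 7 steps (0.10, 0.18, 0.31, 0.55, 0.97, 1.70, 3.0). An alternative
#' `"as_printed"` schedule with a non-monotonic sixth step (0.70) is kept for
#' reference.
#' @param type `"geometric"` or `"as_printed"`.
#' @export
relief_schedule <- function(type = c("geometric", "as_printed")) {
  type <- match.arg(type)
  if (type == "geometric") 0.10 * (3.0 / 0.10)^((0:6) / 6)
  else c(0.10, 0.18, 0.31, 0.55, 0.97, 0.70, 3.0)
}

#' Render a relief sequence
#'
#' All scenes share material, lighting, camera and bump layout; only the
#' relief depth varies over the (default 7) steps.
#' @param params One scene row; its `relief_depth` is ignored.
#' @param reliefs Positive relief depths, default [relief_schedule()].
#' @param config A [world_config()].
#' @return List of `rendered_scene`s, one per relief step.
#' @export
render_relief_sequence <- function(params, reliefs = relief_schedule(),
                                   config) {
  stopifnot(all(reliefs >= 0))
  params <- as.list(params)
  lapply(reliefs, function(r) {
    p <- params
    p$relief_depth <- r
    render_scene(p, config)
  })
}

#' Sample candidate relief-sequence base scenes
#'
#' High-gloss base materials for the constancy sequences: variant `"3a"` draws
#' specular magnitude U(0.2, 1.0) and concentration U(0.7, 1.0); variant
#' `"3b"` magnitude U(0.1, 0.3) and concentration U(0.8, 1.0). All other
#' factors vary as in the main world.
#' @param config A [world_config()].
#' @param n Number of candidate sequences.
#' @param variant `"3a"` or `"3b"`.
#' @param seed Integer seed.
#' @export
sample_sequence_params <- function(config, n, variant = c("3a", "3b"), seed) {
  variant <- match.arg(variant)
  with_seed(seed, {
    base <- sample_scene(config, n = n)
    if (variant == "3a") {
      base$spec_magnitude <- stats::runif(n, 0.2, 1.0)
      base$spec_concentration <- stats::runif(n, 0.7, 1.0)
    } else {
      base$spec_magnitude <- stats::runif(n, 0.1, 0.3)
      base$spec_concentration <- stats::runif(n, 0.8, 1.0)
    }
    base
  })
}

#' Render candidate constancy pairs
#'
#' Each pair shares material and camera; the differing factor depends on the
#' group: (1) same light field, relief 0.40 vs 1.5; (2) same lamp angle,
#' relief 0.40 vs 1.5; (3) same relief, different light fields; (4) same
#' relief, lamp at 30 vs 90 degrees elevation.
#'
#' @param config A [world_config()].
#' @param group Integer 1–4.
#' @param n_candidates Pairs to generate.
#' @param seed Integer seed.
#' @return Tibble with two rows per pair (`member` "A"/"B") holding full scene
#'   parameters.
#' @export
render_pair_set <- function(config, group, n_candidates, seed) {
  stopifnot(group %in% 1:4)
  with_seed(seed, {
    base <- sample_scene(config, n = n_candidates)
    a <- base; b <- base
    a$member <- "A"; b$member <- "B"
    if (group %in% 1:2) {
      a$relief_depth <- 0.40
      b$relief_depth <- 1.5
    }
    if (group == 2 || group == 4) {
      ang <- if (group == 2) sample(c(30, 90), n_candidates, replace = TRUE)
             else rep(NA_real_, n_candidates)
      a$lamp_angle <- if (group == 2) ang else 30
      b$lamp_angle <- if (group == 2) ang else 90
    }
    if (group == 3) {
      shift <- sample.int(config$n_lightfields - 1L, n_candidates, replace = TRUE)
      b$lightfield_id <- ((b$lightfield_id - config$lightfield_offset - 1L + shift) %%
                            config$n_lightfields) + 1L + config$lightfield_offset
    }
    out <- dplyr::bind_rows(a, b)
    out$pair_id <- rep(seq_len(n_candidates), 2)
    out$group <- group
    dplyr::arrange(out, .data$pair_id, .data$member)
  })
}

# Block-average downsampling of an H x W x 3 array by factor ss.
block_mean3 <- function(img, ss) {
  n <- dim(img)[1] / ss
  out <- array(0, c(n, n, 3))
  for (ch in 1:3) {
    m <- img[, , ch]
    # average ss x ss blocks
    m <- matrix(colMeans(matrix(m, ss)), n, n * ss)        # rows pooled
    m <- t(matrix(colMeans(matrix(t(m), ss)), n, n))        # cols pooled
    out[, , ch] <- m
  }
  out
}

# Convert an H x W x 3 array to the (HW x 3) raster-order matrix the network
# core uses (row index = r*W + c).
image_to_mat <- function(img) {
  cbind(as.vector(t(img[, , 1])), as.vector(t(img[, , 2])),
        as.vector(t(img[, , 3])))
}

mat_to_image <- function(m, H, W) {
  arr <- array(0, c(H, W, 3))
  for (ch in 1:3) arr[, , ch] <- matrix(m[, ch], H, W, byrow = TRUE)
  arr
}
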