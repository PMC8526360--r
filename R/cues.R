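# Highlight-cue measurement and manipulation: coverage, sharpness and
# contrast of the specular component, the four specular manipulations
# (translate, erode, blur, contrast), recombination, and cue-based analyses
# of gloss predictors.

#' Coverage of specular highlights
#'
#' Fraction of pixels whose greyscale intensity in the full (composite) image
#' exceeds that of the diffuse component image.
#'
#' @param composite,diffuse H x W x 3 arrays in \[0,1\] of matched shape.
#' @param tol Comparison tolerance (half an 8-bit level).
#' @return Proportion in \[0, 1\].
#' @export
measure_coverage <- function(composite, diffuse, tol = 0.5 / 255) {
  if (!all(dim(composite) == dim(diffuse))) stop("shape mismatch")
  mean(rgb_to_grey(composite) > rgb_to_grey(diffuse) + tol)
}

# Pixels treated as highlight: greyscale specular component above 4 of 255.
highlight_mask <- function(specular) {
  rgb_to_grey(specular) > 4 / 255
}

#' Sharpness of specular highlights (local phase coherence)
#'
#' Cross-scale phase agreement of a 3-scale, 4-orientation complex log-Gabor
#' pyramid: at each pixel and orientation, the modulus of the sum of the
#' scale responses divided by the sum of their moduli, averaged over
#' orientations and over the highlight region. Blurring disperses cross-scale
#' phase and lowers the score; a constant image scores 0.
#'
#' @param specular H x W x 3 array (or greyscale matrix) of the specular
#'   component.
#' @return Phase-coherence score in \[0, 1\].
#' @export
measure_sharpness <- function(specular) {
  g <- if (length(dim(specular)) == 3) rgb_to_grey(specular) else specular
  if (max(g) - min(g) < 1e-12) return(0)
  mask <- if (length(dim(specular)) == 3) highlight_mask(specular)
          else g > 4 / 255
  if (!any(mask)) return(0)
  bank <- loggabor_bank(g, scales = 3, orientations = 4)
  eps <- 1e-9
  pc <- matrix(0, nrow(g), ncol(g))
  for (o in 1:4) {
    tot <- matrix(0 + 0i, nrow(g), ncol(g))
    amp <- matrix(0, nrow(g), ncol(g))
    fine <- matrix(0, nrow(g), ncol(g))
    for (s in 1:3) {
      r <- bank[[(s - 1) * 4 + o]]$resp
      tot <- tot + r
      amp <- amp + Mod(r)
      fine <- fine + c(1, 0.5, 0)[s] * Mod(r)
    }
    # phase agreement across scales, weighted by the fine-scale energy
    # fraction: a blurred feature keeps coarse energy only and scores low
    pc <- pc + (Mod(tot) / (amp + eps)) * (fine / (amp + eps))
  }
  mean(pc[mask]) / 4
}

#' Contrast of specular highlights (summed bandpass RMS)
#'
#' Root-mean-square contrast of eight octave-spaced bandpass-filtered
#' versions of the greyscale specular component, summed over bands.
#' Homogeneous of degree 1 in image intensity; 0 for a constant image.
#'
#' @inheritParams measure_sharpness
#' @export
measure_contrast <- function(specular) {
  g <- if (length(dim(specular)) == 3) rgb_to_grey(specular) else specular
  n <- nrow(g)
  f0s <- (1 / 4) / 2^(0:7)
  bands <- bandpass_stack(g, f0s)
  sum(vapply(bands, function(b) sqrt(mean(b^2)), numeric(1)))
}

#' Measure all three highlight cues of a rendered scene
#'
#' @param scene A [render_scene()] result (or a list with `composite`,
#'   `diffuse`, `specular`).
#' @return One-row tibble: `coverage`, `sharpness`, `contrast`.
#' @export
measure_cues <- function(scene) {
  tibble::tibble(coverage = measure_coverage(scene$composite, scene$diffuse),
                 sharpness = measure_sharpness(scene$specular),
                 contrast = measure_contrast(scene$specular))
}

#' Manipulate a specular component image
#'
#' Four manipulations in ten progressive steps: `translate` shifts the
#' component rightwards in five-pixel steps (the source must carry an
#' oversized render margin; the lower-right window is then cropped);
#' `erode` applies morphological erosion with a 2 x 2 kernel, `step`
#' iterations; `blur` convolves with a Gaussian kernel growing from 1 x 1 to
#' 11 x 11 over the steps (size = step + 1); `contrast` multiplies the
#' standard deviation of the highlight-mask pixels by a factor declining
#' linearly from 1 to 0.1 over steps 1..10 while retaining their mean.
#'
#' @param specular H x W x 3 specular component (with margin for
#'   `translate`).
#' @param kind `"translate"`, `"erode"`, `"blur"` or `"contrast"`.
#' @param step Integer 1–10 (0 returns the input unchanged, cropped for
#'   `translate`).
#' @param size Output size for `translate` (required when the input carries
#'   a margin).
#' @return Modified specular component (H x W x 3; for `translate`, size x
#'   size).
#' @export
manipulate_specular <- function(specular, kind = c("translate", "erode",
                                                   "blur", "contrast"),
                                step, size = NULL) {
  kind <- match.arg(kind)
  stopifnot(step >= 0, step <= 10)
  if (kind == "translate") {
    n <- dim(specular)[1]
    if (is.null(size)) stop("translate needs the target crop `size`")
    # five pixels per step at the full 800-px scale; at other resolutions the
    # same fraction of the image, so the misalignment control stays a control
    shift <- as.integer(round(step * 5 * size / 800))
    if (n - size < shift)
      stop("render margin too small for a ", shift, "-pixel shift")
    out <- array(0, c(size, size, 3))
    rows <- (n - size + 1):n
    cols <- (n - size + 1):n - shift
    out[, , ] <- specular[rows, cols, , drop = FALSE]
    return(out)
  }
  if (step == 0) return(specular)
  if (kind == "erode") {
    # greyscale erosion: min filter over a 2 x 2 neighbourhood (edge
    # replicated), applied `step` times
    min2x2 <- function(m) {
      n <- nrow(m)
      right <- m[, c(2:n, n)]
      down <- m[c(2:n, n), ]
      diagm <- m[c(2:n, n), c(2:n, n)]
      pmin(m, right, down, diagm)
    }
    out <- specular
    for (ch in 1:3) {
      m <- out[, , ch]
      for (i in seq_len(step)) m <- min2x2(m)
      out[, , ch] <- m
    }
    return(out)
  }
  if (kind == "blur") {
    ksize <- step + 1L
    if (ksize %% 2 == 0) ksize <- ksize + 1L   # convolution kernels are odd
    sigma <- (step + 1) / 4
    half <- (ksize - 1) / 2
    xs <- seq(-half, half, length.out = ksize)
    k1 <- exp(-xs^2 / (2 * sigma^2))
    kern <- outer(k1, k1)
    kern <- kern / sum(kern)
    out <- specular
    for (ch in 1:3)
      out[, , ch] <- EBImage::filter2(specular[, , ch], kern)
    return(out)
  }
  # contrast
  mask <- highlight_mask(specular)
  fac <- 1 - 0.9 * (step - 1) / 9
  out <- specular
  for (ch in 1:3) {
    m <- specular[, , ch]
    mu <- mean(m[mask])
    m[mask] <- mu + (m[mask] - mu) * fac
    out[, , ch] <- m
  }
  out
}

#' Recombine diffuse and (modified) specular components
#'
#' Clipped sum, the same convention as the renderer.
#' @param diffuse,specular Matched H x W x 3 arrays.
#' @export
recombine <- function(diffuse, specular) {
  if (!all(dim(diffuse) == dim(specular))) stop("shape mismatch")
  pmin(pmax(diffuse + specular, 0), 1)
}

#' Decode the three highlight cues from latent features
#'
#' Linear regression (OLS) from features to each cue with held-out
#' R-squared, plus the mean over the three cues.
#'
#' @param features n x d matrix of latent codes.
#' @param cues Tibble/data frame with columns `coverage`, `sharpness`,
#'   `contrast` aligned with rows.
#' @param split_seed Train/test split seed (75/25).
#' @return List: `per_cue` tibble (cue, r_squared) and `mean_r_squared`.
#' @export
cue_decoding <- function(features, cues, split_seed = 1L) {
  stopifnot(nrow(features) == nrow(cues))
  per <- purrr::map_dfr(c("coverage", "sharpness", "contrast"), function(cu) {
    rep <- regress_relief(features, cues[[cu]], split_seed)
    tibble::tibble(cue = cu, r_squared = rep$r_squared)
  })
  list(per_cue = per, mean_r_squared = mean(per$r_squared))
}

#' Predicted-gloss response curves under highlight manipulations
#'
#' For each base scene, applies each manipulation over steps 1..n_steps,
#' recombines with the unmodified diffuse component, obtains the model's
#' predicted gloss (decision value) for every image, and reports values
#' relative to the unmanipulated image (step 0 = 0 by construction).
#'
#' @param model A trained [train_pixelvae()] model.
#' @param axis A [fit_gloss_classifier()] axis on the model's latents.
#' @param scenes List of rendered scenes; for the translate manipulation they
#'   must carry a 50-pixel (or larger) margin.
#' @param kinds Manipulations to run.
#' @param n_steps Steps per manipulation (default 10).
#' @return Tibble (`scene`, `kind`, `step`, `relative_gloss`).
#' @export
cue_response_curves <- function(model, axis, scenes,
                                kinds = c("erode", "blur", "contrast",
                                          "translate"),
                                n_steps = 10L) {
  sz <- model$config$image_size
  purrr::map_dfr(seq_along(scenes), function(si) {
    sc <- scenes[[si]]
    margin <- dim(sc$specular)[1] - sz
    crop <- function(img) if (dim(img)[1] > sz) crop_margin(img, sz) else img
    d0 <- crop(sc$diffuse)
    base_pred <- function(spec_img) {
      img <- quantize8(recombine(d0, spec_img))
      predict_gloss(axis, encode_latents(model, img))
    }
    need <- as.integer(ceiling(50 * sz / 800))
    s0 <- if ("translate" %in% kinds && margin >= need)
      manipulate_specular(sc$specular, "translate", 0L, size = sz)
    else crop(sc$specular)
    p0 <- base_pred(s0)
    purrr::map_dfr(kinds, function(kind) {
      purrr::map_dfr(seq_len(n_steps), function(st) {
        sp <- if (kind == "translate")
          manipulate_specular(sc$specular, kind, st, size = sz)
        else manipulate_specular(s0, kind, st)
        tibble::tibble(scene = si, kind = kind, step = st,
                       relative_gloss = base_pred(sp) - p0)
      })
    })
  })
}

#' Plot cue response curves
#' @param curves A [cue_response_curves()] tibble.
#' @export
plot_cue_curves <- function(curves) {
  ggplot2::ggplot(curves,
                  ggplot2::aes(.data$step, .data$relative_gloss,
                               group = .data$scene)) +
    ggplot2::geom_line(alpha = 0.4, colour = "seagreen") +
    ggplot2::stat_summary(ggplot2::aes(group = 1), fun = mean,
                          geom = "line", linewidth = 1) +
    ggplot2::facet_wrap(~kind, nrow = 1) +
    ggplot2::labs(x = "manipulation step",
                  y = "predicted gloss (relative to original)") +
    ggplot2::theme_minimal()
}
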