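# FFT-based log-Gabor filter bank shared by the simplified texture statistics
# and the highlight-cue measurements (bandpass contrast, phase coherence).

freq_grid <- function(n) {
  f <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1) / n
  fx <- outer(rep(1, n), f)
  fy <- outer(f, rep(1, n))
  list(r = sqrt(fx^2 + fy^2), theta = atan2(fy, fx))
}

# Radial log-Gabor transfer function, centre frequency f0 in cycles/pixel.
log_gabor_radial <- function(r, f0, sigma_ratio = 0.65) {
  g <- exp(-(log(pmax(r, 1e-12) / f0))^2 / (2 * log(sigma_ratio)^2))
  g[r < 1e-12] <- 0
  g
}

# Angular Gaussian around orientation `ang` (radians), wrapped.
angular_spread <- function(theta, ang, sigma_theta) {
  d <- atan2(sin(theta - ang), cos(theta - ang))
  exp(-d^2 / (2 * sigma_theta^2))
}

# Complex (analytic) oriented log-Gabor responses of a greyscale image.
# Returns a list over scales x orientations of complex matrices.
#' @keywords internal
loggabor_bank <- function(img, scales = 3, orientations = 4,
                          f0_max = 1 / 6, mult = 2) {
  n <- nrow(img)
  g <- freq_grid(n)
  F <- stats::fft(img)
  out <- vector("list", scales * orientations)
  k <- 1
  for (s in seq_len(scales)) {
    f0 <- f0_max / mult^(s - 1)
    rad <- log_gabor_radial(g$r, f0)
    for (o in seq_len(orientations)) {
      ang <- (o - 1) * pi / orientations
      spread <- angular_spread(g$theta, ang, pi / orientations / 1.2)
      # analytic: keep only the half-plane around +ang
      resp <- stats::fft(F * rad * spread, inverse = TRUE) / n^2
      out[[k]] <- list(scale = s, orientation = o, resp = resp)
      k <- k + 1
    }
  }
  out
}

# Non-oriented bandpass (real) filtered versions of an image at the given
# centre frequencies (cycles/pixel).
bandpass_stack <- function(img, f0s) {
  n <- nrow(img)
  g <- freq_grid(n)
  F <- stats::fft(img)
  # tight-frame normalization: band energies sum to the (bandlimited)
  # signal energy, so a pure tone lands almost entirely in one band
  gains <- lapply(f0s, function(f0) log_gabor_radial(g$r, f0))
  tot <- sqrt(Reduce(`+`, lapply(gains, function(G) G^2)))
  lapply(gains, function(G) {
    Gn <- ifelse(tot > 1e-8, G / pmax(tot, 1e-8), 0)
    Re(stats::fft(F * Gn, inverse = TRUE) / n^2)
  })
}
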