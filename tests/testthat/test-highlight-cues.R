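# Coverage, sharpness and contrast of specular highlights, the four
# manipulations, and recombination.

cue_scene <- function() {
  fixture("cue_scene", function() {
    w <- world_config(image_size = 32L, supersample = 1L)
    p <- sample_scene(w, 1, seed = 901)
    p$spec_magnitude <- 0.45
    p$spec_concentration <- 0.85
    render_scene(p, w, margin = 50L)
  })
}

test_that("coverage counts brightened pixels exactly", {
  d <- array(0.4, c(4, 4, 3))
  expect_equal(measure_coverage(d, d), 0)
  s <- array(0.1, c(4, 4, 3))
  expect_equal(measure_coverage(recombine(d, s), d), 1)
  s5 <- array(0, c(4, 4, 3))
  idx <- cbind(c(1, 2, 3, 4, 2), c(1, 2, 3, 4, 3))
  for (k in 1:5) s5[idx[k, 1], idx[k, 2], ] <- 0.2
  expect_equal(measure_coverage(recombine(d, s5), d), 5 / 16)
  expect_error(measure_coverage(d, array(0, c(3, 3, 3))), "shape")
})

test_that("sharpness is zero for flat images and falls under blur", {
  expect_equal(measure_sharpness(array(0.3, c(32, 32, 3))), 0)
  sc <- cue_scene()
  spec <- crop_margin(sc$specular, 32)
  s0 <- measure_sharpness(spec)
  s_blur <- measure_sharpness(manipulate_specular(spec, "blur", 8))
  expect_gt(s0, s_blur)
  # step edges beat their blurred versions across random placements
  set.seed(41)
  wins <- 0
  for (i in 1:20) {
    img <- matrix(0, 32, 32)
    img[, seq_len(sample(8:24, 1))] <- 0.8
    blur <- matrix(0, 32, 32)
    k <- exp(-(-4:4)^2 / (2 * 2^2)); k <- k / sum(k)
    for (r in 1:32) blur[r, ] <- stats::filter(img[r, ], k, circular = TRUE)
    arr <- function(m) array(rep(m, 3), c(32, 32, 3))
    if (measure_sharpness(arr(img)) > measure_sharpness(arr(blur)))
      wins <- wins + 1
  }
  expect_gte(wins, 19)
})

test_that("contrast is linear, zero for flat input, and band-localized", {
  expect_equal(measure_contrast(array(0.2, c(32, 32, 3))), 0)
  sc <- cue_scene()
  spec <- crop_margin(sc$specular, 32)
  c1 <- measure_contrast(spec)
  expect_equal(measure_contrast(spec * 0.37), 0.37 * c1, tolerance = 1e-12)
  # single-frequency grating: energy concentrated in the matching band,
  # total close to the analytic RMS of the grating
  n <- 64
  A <- 0.3
  gr <- A * sin(2 * pi * 8 * (0:(n - 1)) / n)
  img <- matrix(rep(gr, each = n), n)
  bands <- glossim:::bandpass_stack(img, (1 / 4) / 2^(0:7))
  rms <- vapply(bands, function(b) sqrt(mean(b^2)), numeric(1))
  # 8 cycles / 64 px = 0.125 cycles/px: band 2 (f0 = 1/8)
  expect_equal(which.max(rms), 2)
  expect_gt(rms[2] / sum(rms), 0.6)
  expect_equal(rms[2], A / sqrt(2), tolerance = 0.12)
  expect_equal(sum(rms), A / sqrt(2), tolerance = 0.5)  # filter leakage
})

test_that("erosion shrinks coverage monotonically; blur lowers sharpness", {
  sc <- cue_scene()
  spec <- crop_margin(sc$specular, 32)
  diffu <- crop_margin(sc$diffuse, 32)
  cov <- vapply(0:6, function(st) {
    sp <- manipulate_specular(spec, "erode", st)
    measure_coverage(recombine(diffu, sp), diffu)
  }, numeric(1))
  expect_true(all(diff(cov) <= 1e-12))
  # a lamp-lit scene has localized highlights with true zeros, so erosion
  # strictly shrinks coverage there
  w <- world_config(image_size = 32L, supersample = 1L)
  p <- sample_scene(w, 1, seed = 905)
  p$spec_magnitude <- 0.45; p$spec_concentration <- 0.85; p$lamp_angle <- 60
  lsc <- render_scene(p, w)
  lcov <- vapply(c(0, 4), function(st) {
    sp <- manipulate_specular(lsc$specular, "erode", st)
    measure_coverage(recombine(lsc$diffuse, sp), lsc$diffuse)
  }, numeric(1))
  expect_lt(lcov[2], lcov[1])
  sharp <- vapply(0:10, function(st)
    measure_sharpness(manipulate_specular(spec, "blur", st)), numeric(1))
  expect_true(all(diff(sharp[-1]) <= 1e-4))  # step 0 -> 1 can denoise slightly
  expect_lt(sharp[11], sharp[1])
})

test_that("the contrast manipulation scales highlight sd and keeps the mean", {
  sc <- cue_scene()
  spec <- crop_margin(sc$specular, 32)
  mask <- glossim:::highlight_mask(spec)
  m10 <- manipulate_specular(spec, "contrast", 10)
  for (ch in 1:3) {
    orig <- spec[, , ch][mask]
    new <- m10[, , ch][mask]
    expect_equal(mean(new), mean(orig), tolerance = 1e-9)
    expect_equal(sd(new), 0.1 * sd(orig), tolerance = 1e-6)
  }
  m1 <- manipulate_specular(spec, "contrast", 1)
  expect_equal(m1, spec, tolerance = 1e-12)   # factor 1 at step 1
})

test_that("translation leaves all three cues nearly unchanged", {
  sc <- cue_scene()
  d0 <- crop_margin(sc$diffuse, 32)
  s0 <- manipulate_specular(sc$specular, "translate", 0, size = 32)
  base <- c(measure_coverage(recombine(d0, s0), d0),
            measure_sharpness(s0), measure_contrast(s0))
  for (st in c(3, 10)) {
    sp <- manipulate_specular(sc$specular, "translate", st, size = 32)
    cues <- c(measure_coverage(recombine(d0, sp), d0),
              measure_sharpness(sp), measure_contrast(sp))
    expect_true(all(abs(cues - base) / pmax(base, 1e-6) < 0.15))
  }
  expect_error(manipulate_specular(s0, "translate", 10, size = 32), "margin")
})

test_that("sharpness is intensity-invariant and recombination round-trips", {
  sc <- cue_scene()
  spec <- crop_margin(sc$specular, 32)
  s1 <- measure_sharpness(spec)
  s2 <- measure_sharpness(spec * 0.5)
  # phase ratios are exactly scale-invariant; the highlight mask shifts a
  # little under scaling, which moves the average slightly
  expect_lt(abs(s1 - s2) / s1, 0.02)
  d <- crop_margin(sc$diffuse, 32)
  expect_identical(recombine(d, array(0, dim(d))), d)
  comp <- crop_margin(sc$composite, 32)
  expect_equal(recombine(d, crop_margin(sc$specular, 32)), comp,
               tolerance = 1e-12)
  over <- array(0.9, c(2, 2, 3))
  expect_true(all(recombine(over, over) == 1))
})

test_that("invalid manipulations are rejected", {
  s <- array(0.1, c(8, 8, 3))
  expect_error(manipulate_specular(s, "shear", 1))
  expect_error(manipulate_specular(s, "blur", 12))
})
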