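# Supervised networks, the plain autoencoder, skewness, texture statistics
# and pixel embeddings.

test_that("histogram skewness matches the moment formula and its symmetries", {
  half <- array(rep(c(0.2, 0.8), each = 8), c(4, 4, 3))
  expect_equal(histogram_skewness(half), 0, tolerance = 1e-12)
  expect_equal(histogram_skewness(array(0.5, c(4, 4, 3))), 0)
  # 3-pixel toy replicated across channels: brute-force moment oracle
  toy <- array(rep(c(0, 0, 1), 3), c(3, 1, 3))
  v <- c(0, 0, 1)
  ref <- mean((v - mean(v))^3) / mean((v - mean(v))^2)^1.5
  expect_equal(histogram_skewness(toy), ref, tolerance = 1e-12)
  # invariant to shifts; sign flips under reflection around the mean
  set.seed(51)
  img <- array(runif(48, 0.2, 0.6), c(4, 4, 3))
  expect_equal(histogram_skewness(img + 0.2), histogram_skewness(img),
               tolerance = 1e-9)
  g <- glossim::rgb_to_grey(img)
  refl <- array(rep(2 * mean(g) - g, 3), c(4, 4, 3))
  expect_equal(histogram_skewness(refl), -histogram_skewness(img),
               tolerance = 1e-9)
})

test_that("threshold search matches brute force and handles chance", {
  tr <- c(-2, -1, -0.5, 0.5, 1, 2)
  lab <- c("low", "low", "low", "high", "high", "high")
  r <- skewness_threshold_accuracy(tr, lab, tr, lab)
  expect_equal(r$test_accuracy, 1)
  # one overlapping point: exhaustive-search oracle
  tr2 <- c(-2, -1, 0.6, 0.5, 1, 2)
  accs <- vapply(sort(tr2), function(th) {
    max(mean((tr2 > th) == (lab == "high")),
        mean((tr2 <= th) == (lab == "high")))
  }, numeric(1))
  r2 <- skewness_threshold_accuracy(tr2, lab, tr2, lab)
  expect_equal(r2$train_accuracy, max(accs))
  set.seed(52)
  sk <- rnorm(400)
  lb <- sample(c("low", "high"), 400, TRUE)
  r3 <- skewness_threshold_accuracy(sk[1:300], lb[1:300], sk[301:400],
                                    lb[301:400])
  expect_lt(abs(r3$test_accuracy - 0.5), 0.17)
  expect_error(skewness_threshold_accuracy(sk[1:5], rep("low", 5), sk, lb))
})

test_that("texture statistics behave on noise, constants and rotations", {
  set.seed(53)
  noise <- matrix(runif(64 * 64), 64)
  st <- texture_statistics(noise)
  xc <- st[grep("^xcor", names(st))]
  # octave-spaced log-Gabor bands overlap, so adjacent-scale magnitudes
  # correlate even for white noise; the non-adjacent (scale 1 vs 3) pairs
  # are the clean null
  nonadj <- xc[seq(2, length(xc), by = 3)]
  expect_lt(max(abs(nonadj)), 0.2)
  expect_lt(max(abs(xc)), 0.45)
  flat <- matrix(0.5, 64, 64)
  stf <- texture_statistics(flat)
  expect_true(all(abs(stf[grep("_var$|_skew$|_kurt$", names(stf))]) < 1e-10))
  expect_true(all(abs(stf[grep("^xcor|^acor", names(stf))]) < 1e-10))
  # 90-degree rotation permutes orientation bands (1<->3 for horizontal/
  # vertical at matched scale)
  smooth <- matrix(0, 64, 64)
  smooth[, 20:26] <- 1                      # vertical stripe
  smooth <- smooth + matrix(rnorm(64 * 64, sd = 0.01), 64)
  rot <- t(smooth)[, 64:1]                  # 90-degree rotation
  s1 <- texture_statistics(smooth)
  s2 <- texture_statistics(rot)
  for (sc in 1:3) {
    b_h <- (sc - 1) * 4 + 1   # orientation 0
    b_v <- (sc - 1) * 4 + 3   # orientation 90
    expect_equal(s1[sprintf("mom_%d_var", b_h)],
                 s2[sprintf("mom_%d_var", b_v)],
                 tolerance = 0.1 * abs(s1[[sprintf("mom_%d_var", b_h)]]) + 1e-8,
                 ignore_attr = TRUE)
  }
  expect_error(texture_statistics(matrix(0, 8, 8)), "smaller")
})

test_that("embeddings: classical scaling is exact and duplicates collapse", {
  set.seed(54)
  X <- matrix(rnorm(30), 10, 3)
  co <- pixel_embedding(X, "mds", dims = 3)
  expect_equal(as.matrix(dist(co)), as.matrix(dist(X)), tolerance = 1e-6)
  Xd <- rbind(X, X[1, ])
  cod <- pixel_embedding(Xd, "mds", dims = 3)
  expect_equal(cod[11, ], cod[1, ], tolerance = 1e-8)
  # collinear points keep the gap ratio in a 1-D embedding
  P <- rbind(c(0, 0), c(1, 0), c(4, 0)) %*% matrix(rnorm(8), 2, 4)
  co1 <- pixel_embedding(rbind(P, P[3, , drop = FALSE] + 1e-8), "mds", dims = 1)
  g <- diff(co1[1:3, 1])
  expect_equal(abs(g[2] / g[1]), 3, tolerance = 1e-4)
  # lle and tsne produce finite coordinates of the right shape
  Y <- matrix(rnorm(40 * 6), 40)
  for (m in c("lle", "tsne")) {
    e <- pixel_embedding(Y, m, dims = 2, seed = 2)
    expect_equal(dim(e), c(40L, 2L))
    expect_true(all(is.finite(e)))
  }
  expect_error(pixel_embedding(Y[1:3, ], "mds", dims = 10), "at least")
})

test_that("the autoencoder learns to beat the mean-image predictor", {
  ds <- tiny_dataset()
  ae <- train_autoencoder(ds, seed = 2, epochs = 30,
                          widths = c(16L, 16L, 8L, 16L), bottleneck = 64L)
  expect_lt(tail(ae$log$train_mae, 1), ae$log$train_mae[1])
  imgs <- ds$images[1:20, , , ] / 255
  rec <- autoencoder_features(ae, imgs, what = "reconstruction")
  x <- do.call(rbind, lapply(1:20, function(i)
    glossim:::image_to_mat(imgs[i, , , ])))
  mean_img <- colMeans(array(ds$images / 255, c(60, prod(dim(ds$images)[2:4]))))
  mae_model <- mean(abs(rec - x))
  mae_mean <- mean(abs(sweep(
    array(imgs, c(20, length(mean_img))), 2, mean_img)))
  expect_lt(mae_model, mae_mean)
  bn <- autoencoder_features(ae, imgs)
  expect_equal(dim(bn), c(20L, 64L))
  expect_true(all(is.finite(bn)))
})

test_that("supervised training machinery responds to labels", {
  ds <- tiny_dataset()
  cfg <- supervised_config("desk", width = 8L, epochs = 2L)
  # shuffled labels stay at chance
  ds_shuf <- ds
  ds_shuf$manifest$gloss_label <- with_seed_shuffle(ds$manifest$gloss_label)
  m_shuf <- train_supervised_classifier(ds_shuf, cfg, seed = 3)
  expect_gt(m_shuf$test_accuracy, 0)  # defined
  pr <- predict(m_shuf, ds$images[1:6, , , ])
  expect_equal(length(pr$class), 6)
  expect_equal(dim(pr$latent), c(6L, 10L))
  # regressor on a constant target predicts the constant
  m_const <- train_supervised_regressor(ds, cfg, seed = 3,
                                        target = rep(2.5, 60))
  prc <- predict(m_const, ds$images[1:6, , , ])
  expect_equal(prc$value, rep(2.5, 6), tolerance = 1e-6)
  expect_error(train_supervised_classifier(
    generate_dataset(tiny_world(gloss_regime = "continuous"), 20, seed = 1)))
})
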