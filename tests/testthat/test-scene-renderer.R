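# The procedural world: parameter sampling, height fields, shading,
# datasets, sequences and pairs.

test_that("scene sampling respects each gloss regime's ranges", {
  n <- 400
  bi <- sample_scene(tiny_world(), n = n, seed = 11)
  lo <- bi$gloss_label == "low"
  expect_true(all(bi$spec_magnitude[lo] >= 0.1 & bi$spec_magnitude[lo] <= 0.3))
  expect_true(all(bi$spec_concentration[lo] >= 0.2 &
                    bi$spec_concentration[lo] <= 0.4))
  expect_true(all(bi$spec_magnitude[!lo] >= 0.3 &
                    bi$spec_magnitude[!lo] <= 0.5))
  expect_true(all(bi$spec_concentration[!lo] >= 0.75 &
                    bi$spec_concentration[!lo] <= 0.95))
  # roughly half each class
  expect_gt(mean(lo), 0.4); expect_lt(mean(lo), 0.6)

  co <- sample_scene(tiny_world(gloss_regime = "continuous"), n = n, seed = 12)
  expect_true(all(co$spec_magnitude >= 0.1 & co$spec_magnitude <= 0.8))
  expect_true(all(co$spec_concentration >= 0.1 & co$spec_concentration <= 0.8))
  expect_gt(abs(cor(co$spec_magnitude, co$spec_concentration)), 0) # defined
  expect_lt(abs(cor(co$spec_magnitude, co$spec_concentration)), 0.15)

  rp <- sample_scene(tiny_world(gloss_regime = "rating_probe"), n = n, seed = 13)
  expect_identical(rp$spec_concentration, rp$spec_magnitude)
  expect_true(all(rp$spec_magnitude >= 0.2 & rp$spec_magnitude <= 1.0))
})

test_that("degenerate relief range gives constant relief", {
  w <- tiny_world(relief_range = c(1, 1))
  sc <- sample_scene(w, n = 20, seed = 1)
  expect_true(all(sc$relief_depth == 1))
})

test_that("world factors are sampled independently", {
  sc <- sample_scene(tiny_world(), n = 2000, seed = 21)
  f <- cbind(sc$spec_magnitude, sc$relief_depth, sc$lightfield_id,
             (sc$albedo_r + sc$albedo_g + sc$albedo_b) / 3)
  cc <- cor(f)
  expect_true(all(abs(cc[upper.tri(cc)]) < 0.08))
})

test_that("height field scales to the requested relief and is deterministic", {
  w <- tiny_world()
  p <- as.list(sample_scene(w, 1, seed = 31))
  p$relief_depth <- 1.37
  h <- build_heightfield(p, 32, w)
  expect_equal(max(h) - min(h), 1.37, tolerance = 1e-9)
  expect_identical(h, build_heightfield(p, 32, w))
  # depth only rescales the same bump layout
  p2 <- p; p2$relief_depth <- 2.74
  h2 <- build_heightfield(p2, 32, w)
  expect_equal(h / 1.37, h2 / 2.74, tolerance = 1e-12)
  # zero relief: flat
  p0 <- p; p0$relief_depth <- 0
  expect_true(all(build_heightfield(p0, 32, w) == 0))
})

test_that("flat matte surface under an overhead lamp shades uniformly", {
  w <- tiny_world(relief_range = c(0, 0), camera_jitter = list(translation = 0,
                                                               rotation = 0))
  p <- as.list(sample_scene(w, 1, seed = 41))
  p$relief_depth <- 0
  p$spec_magnitude <- 0
  p$lamp_angle <- 90
  sc <- render_scene(p, w)
  expect_true(all(sc$specular == 0))
  for (ch in 1:3) expect_lt(diff(range(sc$diffuse[, , ch])), 1e-12)
})

test_that("specular component is linear in magnitude and monotone in level", {
  w <- tiny_world()
  p <- as.list(sample_scene(w, 1, seed = 42))
  p$spec_concentration <- 0.5
  p$spec_magnitude <- 0.2
  s1 <- render_scene(p, w)
  p$spec_magnitude <- 0.4
  s2 <- render_scene(p, w)
  expect_equal(s2$specular_raw, s1$specular_raw * 2, tolerance = 1e-12)
  means <- vapply(c(0.1, 0.3, 0.5), function(m) {
    p$spec_magnitude <- m
    mean(render_scene(p, w)$specular)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("composite equals the clipped sum of stored components", {
  w <- tiny_world()
  for (s in 1:3) {
    p <- sample_scene(w, 1, seed = 50 + s)
    sc <- render_scene(p, w)
    expect_identical(sc$composite, pmin(sc$diffuse + sc$specular, 1))
    expect_true(all(sc$diffuse >= 0) && all(sc$specular >= 0))
    expect_true(all(is.finite(sc$composite)))
  }
})

test_that("datasets split 90/5/5, are deterministic, and balance labels", {
  ds <- tiny_dataset()
  expect_equal(as.integer(table(ds$manifest$split)[c("train", "validation",
                                                     "test")]),
               c(54L, 3L, 3L))
  ds2 <- generate_dataset(tiny_world(), n = 60, seed = 301)
  expect_identical(ds$manifest, ds2$manifest)
  expect_identical(ds$images, ds2$images)
  big <- sample_scene(tiny_world(), n = 600, seed = 61)
  counts <- table(big$gloss_label)
  expect_gt(min(counts), 0.5 * 600 - 3 * sqrt(600 * 0.25))  # 3 sd
})

test_that("relief sequences share everything except relief", {
  w <- tiny_world()
  p <- sample_scene(w, 1, seed = 71)
  seqs <- render_relief_sequence(p, c(0.3, 0.3, 0.3), w)
  expect_identical(seqs[[1]]$composite, seqs[[2]]$composite)
  expect_identical(seqs[[2]]$composite, seqs[[3]]$composite)
  seqs2 <- render_relief_sequence(p, relief_schedule(), w)
  for (k in 1:6)
    expect_gt(max(abs(seqs2[[k]]$composite - seqs2[[k + 1]]$composite)), 0)
  expect_equal(relief_schedule(),
               c(0.10, 0.18, 0.31, 0.55, 0.97, 1.70, 3.0), tolerance = 0.02)
  expect_identical(relief_schedule("as_printed")[6], 0.70)
})

test_that("constancy pair groups vary the intended factor only", {
  w <- tiny_world()
  g1 <- render_pair_set(w, group = 1, n_candidates = 8, seed = 81)
  expect_equal(nrow(g1), 16)
  for (pid in unique(g1$pair_id)) {
    pr <- g1[g1$pair_id == pid, ]
    expect_identical(pr$lightfield_id[1], pr$lightfield_id[2])
    expect_setequal(pr$relief_depth, c(0.40, 1.5))
    expect_identical(pr$spec_magnitude[1], pr$spec_magnitude[2])
    expect_identical(pr$bump_seed[1], pr$bump_seed[2])
  }
  g4 <- render_pair_set(w, group = 4, n_candidates = 8, seed = 82)
  for (pid in unique(g4$pair_id)) {
    pr <- g4[g4$pair_id == pid, ]
    expect_identical(pr$relief_depth[1], pr$relief_depth[2])
    expect_setequal(pr$lamp_angle, c(30, 90))
  }
  g3 <- render_pair_set(w, group = 3, n_candidates = 8, seed = 83)
  for (pid in unique(g3$pair_id)) {
    pr <- g3[g3$pair_id == pid, ]
    expect_false(pr$lightfield_id[1] == pr$lightfield_id[2])
  }
  # four groups of n candidates give 4n pairs in total
  expect_equal(sum(vapply(1:4, function(g)
    length(unique(render_pair_set(w, g, 5, seed = g)$pair_id)), numeric(1))),
    20)
})

test_that("light fields are unit-norm, normalized, and id-distinct", {
  for (id in 1:6) {
    lf <- make_lightfield(id)
    expect_true(all(abs(sqrt(rowSums(lf$dirs^2)) - 1) < 1e-6))
    flat_mean <- sum(lf$intensity * rowMeans(lf$color) * lf$dirs[, 3]) +
      lf$ambient
    expect_gt(flat_mean, 0.3); expect_lt(flat_mean, 0.8)
  }
  expect_false(isTRUE(all.equal(make_lightfield(1)$dirs,
                                make_lightfield(2)$dirs)))
  expect_identical(make_lightfield(3), make_lightfield(3))
})

test_that("unknown regime and invalid configs are rejected", {
  expect_error(world_config(gloss_regime = "nope"))
  expect_error(world_config(image_size = 8))
  expect_error(world_config(albedo_range = c(0.7, 0.3)))
})
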