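# The generative model's likelihood core, variational objective, causal
# masking, encoding and conditional generation.

test_that("discretized logistic mixture behaves at its edges", {
  # collapsed component puts all mass on its bin
  expect_gt(dlogismix_prob(1, 128, 1e-4, 128), 1 - 1e-10)
  # symmetric tails around a half-integer location
  expect_equal(dlogismix_prob(1, 127.5, 3, 127),
               dlogismix_prob(1, 127.5, 3, 128), tolerance = 1e-12)
})

test_that("mixture bin probabilities normalize and match quadrature", {
  set.seed(99)
  for (rep in 1:5) {
    k <- sample(1:4, 1)
    w <- rexp(k); w <- w / sum(w)
    loc <- runif(k, -30, 290)
    sc <- runif(k, 0.5, 40)
    p <- dlogismix_prob(w, loc, sc, 0:255)
    expect_equal(sum(p), 1, tolerance = 1e-6)
    # quadrature oracle for interior bins of a 2-component mixture
    v <- sample(10:240, 3)
    for (vv in v) {
      q <- sum(vapply(seq_len(k), function(j)
        w[j] * integrate(function(x) dlogis(x, loc[j], sc[j]),
                         vv - 0.5, vv + 0.5, rel.tol = 1e-10)$value,
        numeric(1)))
      expect_equal(dlogismix_prob(w, loc, sc, vv), q, tolerance = 1e-6)
    }
  }
})

test_that("divergence term has its closed form and is non-negative", {
  kl <- glossim:::kl_gaussian
  expect_identical(kl(matrix(0, 1, 10), matrix(0, 1, 10)), 0)
  m <- matrix(rnorm(10), 1)
  expect_equal(kl(m, matrix(0, 1, 10)), sum(m^2) / 2, tolerance = 1e-12)
  set.seed(3)
  for (i in 1:20) {
    mu <- matrix(rnorm(8, sd = 3), 1)
    lv <- matrix(rnorm(8, sd = 2), 1)
    expect_gte(kl(mu, lv), 0)
  }
})

test_that("the model's reconstruction term matches a brute-force oracle", {
  # independent straight-line reimplementation of the teacher-forced NLL on a
  # tiny image, using the exported scalar bin probability
  cfg <- pixelvae_config(image_size = 16L, cond_widths = c(4L, 4L, 4L),
                         cond_fc = 8L, ar_blocks = 1L, ar_layers = 1L,
                         ar_maps = 4L, mixture_components = 2L,
                         latent_dim = 3L)
  params <- glossim:::init_pixelvae_params(cfg, 17L)
  masks <- glossim:::decoder_masks(cfg)
  set.seed(4)
  xi <- matrix(sample(0:255, 16 * 16 * 3, TRUE), 16 * 16, 3)
  xs <- 2 * xi / 255 - 1
  z <- matrix(rnorm(3), 1)
  out <- glossim:::decoder_forward(params, xs, z, 1L, cfg, masks,
                                   need_cache = FALSE)$out
  ml <- glossim:::mixture_loss(out, xi, 2L, want_grad = FALSE)
  K <- 2
  nll_ref <- 0
  for (p in seq_len(nrow(out))) {
    o <- out[p, ]
    logits <- o[1:K]; pi_k <- exp(logits - max(logits))
    pi_k <- pi_k / sum(pi_k)
    means <- o[K + 1:(3 * K)]; logsc <- pmax(o[4 * K + 1:(3 * K)], -7)
    coef <- tanh(o[7 * K + 1:(3 * K)])
    lik <- 0
    for (k in 1:K) {
      # per-component product over channels with linear RGB coupling,
      # on the 0..255 scale (scale factor 255/2 from the [-1,1] model units)
      mu_r <- means[k]
      mu_g <- means[K + k] + coef[k] * xs[p, 1]
      mu_b <- means[2 * K + k] + coef[K + k] * xs[p, 1] +
        coef[2 * K + k] * xs[p, 2]
      mus <- (c(mu_r, mu_g, mu_b) + 1) * 255 / 2
      scs <- exp(logsc[c(k, K + k, 2 * K + k)]) * 255 / 2
      pr <- 1
      for (c in 1:3) pr <- pr * max(dlogismix_prob(1, mus[c], scs[c],
                                                   xi[p, c]), 1e-12)
      lik <- lik + pi_k[k] * pr
    }
    nll_ref <- nll_ref - log(lik)
  }
  expect_equal(ml$nll, nll_ref, tolerance = 1e-4)
})

test_that("the compiled likelihood agrees with the pure-R reference", {
  set.seed(71)
  for (K in c(2L, 5L)) {
    N <- 60
    out <- matrix(rnorm(N * 10 * K, sd = 1.5), N)
    xi <- matrix(sample(0:255, N * 3, TRUE), N, 3)
    a <- glossim:::mixture_loss(out, xi, K)
    b <- glossim:::mixture_loss_ref(out, xi, K)
    expect_equal(a$nll, b$nll, tolerance = 1e-10)
    expect_equal(a$dout, b$dout, tolerance = 1e-9)
  }
})

test_that("autoregressive masking: future pixels cannot influence a pixel", {
  m <- tiny_vae()
  img <- tiny_dataset()$images[1, , , ]
  base <- glossim:::pixelvae_pixel_params(m, img)
  sz <- m$config$image_size
  probe <- c(20L, 130L, 250L)   # raster positions (row-major, 1-based)
  for (p in probe) {
    img2 <- img
    # perturb a strictly later pixel
    later <- p + 5L
    r <- (later - 1) %/% sz + 1; cc <- (later - 1) %% sz + 1
    img2[r, cc, ] <- (img2[r, cc, ] + 100L) %% 256L
    out2 <- glossim:::pixelvae_pixel_params(m, img2)
    expect_equal(out2[p, ], base[p, ], tolerance = 1e-10)
    # perturbing an earlier pixel inside the causal receptive field (the
    # pixel directly above) does change the distribution
    img3 <- img
    earlier <- p - sz
    r <- (earlier - 1) %/% sz + 1; cc <- (earlier - 1) %% sz + 1
    img3[r, cc, ] <- (img3[r, cc, ] + 100L) %% 256L
    out3 <- glossim:::pixelvae_pixel_params(m, img3)
    expect_gt(max(abs(out3[p, ] - base[p, ])), 1e-8)
  }
})

test_that("encoding is deterministic with the configured dimensionality", {
  m <- tiny_vae()
  img <- tiny_dataset()$images[2, , , ]
  z1 <- encode_latents(m, img)
  z2 <- encode_latents(m, img)
  expect_identical(z1, z2)
  expect_equal(ncol(z1), m$config$latent_dim)
  expect_true(all(is.finite(z1)))
  expect_equal(dim(attr(z1, "log_variance")), dim(unclass(z1)))
})

test_that("elbo_loss is finite, deterministic, and penalizes posterior drift", {
  m <- tiny_vae()
  img <- tiny_dataset()$images[3, , , ]
  l1 <- elbo_loss(m, img)
  expect_true(all(is.finite(l1)))
  expect_gte(l1[["divergence"]], 0)
  expect_identical(l1, elbo_loss(m, img))
})

test_that("generation is reproducible and respects temperature zero", {
  m <- tiny_vae()
  z <- encode_latents(m, tiny_dataset()$images[1, , , ])
  g1 <- generate_image(m, z[1, ], seed = 9)
  g2 <- generate_image(m, z[1, ], seed = 9)
  expect_identical(g1, g2)
  expect_false(identical(g1, generate_image(m, z[1, ], seed = 10)))
  d1 <- generate_image(m, z[1, ], seed = 1, temperature = 0)
  d2 <- generate_image(m, z[1, ], seed = 2, temperature = 0)
  expect_identical(d1, d2)
  expect_true(all(g1 >= 0 & g1 <= 255))
})

test_that("training improves the validation objective and is deterministic", {
  ds <- tiny_dataset()
  m <- train_pixelvae(ds, tiny_vae_config(epochs = 3L), seed = 11L)
  expect_lt(m$log$val_nll[3], m$log$val_nll[1])
  m2 <- train_pixelvae(ds, tiny_vae_config(epochs = 3L), seed = 11L)
  expect_identical(m$log$val_nll, m2$log$val_nll)
})

test_that("a zero learning rate leaves parameters unchanged", {
  ds <- tiny_dataset()
  cfg <- tiny_vae_config(epochs = 1L)
  cfg$learning_rate <- 0
  m <- train_pixelvae(ds, cfg, seed = 13L)
  init <- glossim:::init_pixelvae_params(cfg, glossim:::derive_seed(13L, 1))
  expect_identical(m$params$enc$conv1$W, init$enc$conv1$W)
  expect_identical(m$params$dec$out2$W, init$dec$out2$W)
})

test_that("tidy and glance expose the training log", {
  m <- tiny_vae()
  expect_tibble(tidy(m))
  g <- glance(m)
  expect_equal(g$epochs, nrow(m$log))
})
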