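# Simulated 2AFC, constancy-pattern classification, stimulus selection,
# experiment transforms, evaluation metrics and synthetic observers.

test_that("simulated 2AFC enumerates pairs with the tie convention", {
  expect_equal(simulate_2afc(1:7)$prop_glossier, (0:6) / 6)
  expect_equal(simulate_2afc(rep(2, 5))$prop_glossier, rep(0.5, 5))
  expect_equal(simulate_2afc(c(3, 1, 2))$prop_glossier, c(1, 0, 0.5))
  set.seed(31)
  for (i in 1:10) {
    pr <- rnorm(sample(3:9, 1))
    expect_equal(mean(simulate_2afc(pr)$prop_glossier), 0.5)
  }
})

test_that("sequence ranking reproduces a sums-of-squares ANOVA oracle", {
  set.seed(32)
  # identical models rank last with negligible interaction
  flat <- matrix(rep(seq(0, 1, length.out = 7), each = 3) +
                   rnorm(21, sd = 0.01), 3)
  strong_a <- matrix(rep(seq(0, 1, length.out = 7), each = 3) +
                       rnorm(21, sd = 0.02), 3)
  strong_b <- matrix(rep(seq(1, 0, length.out = 7), each = 3) +
                       rnorm(21, sd = 0.02), 3)
  rk <- rank_sequences_by_disagreement(list(flat, strong_a),
                                       list(flat + rnorm(21, sd = 0.01),
                                            strong_b))
  expect_equal(rk$sequence[1], 2L)   # disagreement sequence first
  expect_gt(rk$f_interaction[1], 100)
  # oracle: explicit two-way ANOVA sums of squares on a hand-built table
  a <- matrix(c(0.1, 0.2, 0.15, 0.3, 0.25, 0.35, 0.5,
                0.12, 0.18, 0.2, 0.28, 0.3, 0.4, 0.45), 2, byrow = TRUE)
  b <- matrix(c(0.5, 0.45, 0.4, 0.3, 0.2, 0.15, 0.1,
                0.48, 0.5, 0.38, 0.33, 0.22, 0.12, 0.14), 2, byrow = TRUE)
  f_pkg <- rank_sequences_by_disagreement(list(a), list(b))$f_interaction
  y <- c(as.vector(a), as.vector(b))
  model <- rep(c(0, 1), each = 14)
  step <- rep(rep(1:7, each = 2), 2)
  cell <- interaction(model, step)
  ss_cells <- sum(tapply(y, cell, function(v) length(v) * (mean(v) - mean(y))^2))
  ss_model <- sum(tapply(y, model, function(v) length(v) * (mean(v) - mean(y))^2))
  ss_step <- sum(tapply(y, step, function(v) length(v) * (mean(v) - mean(y))^2))
  ss_int <- ss_cells - ss_model - ss_step
  ss_err <- sum((y - ave(y, cell))^2)
  f_ref <- (ss_int / 6) / (ss_err / (28 - 14))
  expect_equal(f_pkg, f_ref, tolerance = 1e-8)
})

test_that("constancy patterns are classified as specified", {
  expect_equal(classify_constancy_pattern(rep(0.5, 7)), "constant")
  expect_equal(classify_constancy_pattern((0:6) / 6), "linear")
  x <- 0:6
  bump <- -(x - 3)^2 / 9 + 1
  bump <- (bump - min(bump)) / diff(range(bump)) * 0.6 + 0.2
  expect_equal(classify_constancy_pattern(bump), "non_monotonic")
  expect_equal(classify_constancy_pattern(0.8 - bump), "nonlinear_upward")
  # brute-force agreement on random profiles with an independent
  # reimplementation of the rules
  ref <- function(p) {
    x <- seq_along(p)
    rng <- diff(range(p))
    sst <- sum((p - mean(p))^2)
    r2l <- if (sst < 1e-18) 1 else
      1 - sum(resid(lm(p ~ poly(x, 1)))^2) / sst
    qf <- lm(p ~ x + I(x^2))
    r2q <- if (sst < 1e-18) 1 else 1 - sum(resid(qf)^2) / sst
    qc <- coef(qf)[3]
    if (is.na(qc) || abs(qc) < 1e-8) qc <- 0
    if (rng < 0.25 && r2l > 0.70) "constant"
    else if (rng > 0.50 && r2q > 0.90 && qc < 0) "non_monotonic"
    else if (rng > 0.50 && r2q > 0.90 && qc > 0) "nonlinear_upward"
    else if (rng > 0.50 && r2l > 0.90) "linear"
    else "unclassified"
  }
  set.seed(33)
  for (i in 1:300) {
    p <- runif(7)
    expect_identical(classify_constancy_pattern(p), ref(p))
  }
})

test_that("decile pair selection follows the rank convention", {
  set.seed(34)
  d200 <- runif(200)
  sel <- select_percentile_pairs(d200)
  expect_equal(nrow(sel), 10)
  expect_equal(sel$abs_delta, sort(d200)[ceiling((1:10) * 20)])
  sel10 <- select_percentile_pairs(runif(10))
  expect_equal(nrow(sel10), 10)
  expect_equal(sel10$abs_delta, sort(sel10$abs_delta))
  expect_equal(select_percentile_pairs(1:100)$abs_delta, seq(10, 100, by = 10))
})

test_that("unit-range normalization and pair transforms are exact", {
  expect_equal(normalize_unit_range(c(2, 4, 6)), c(0, 0.5, 1))
  expect_warning(z <- normalize_unit_range(rep(3, 4)), "constant")
  expect_equal(z, rep(0.5, 4))
  v <- c(-1.2, 0.4, 2.2, 0.9, -0.3)
  expect_equal(normalize_unit_range(v), (v - min(v)) / (max(v) - min(v)))
  expect_equal(model_delta_for_pairs(c(1, -2, 0.5), c(0, 0, 0)),
               c(0.25, -0.5, 0.125))
  expect_error(model_delta_for_pairs(c(1, 1), c(1, 1)), "zero")
})

test_that("choice aggregation matches hand enumeration in both designs", {
  ch <- tibble::tibble(image_a = c("A", "A", "B"), image_b = c("B", "C", "C"),
                       count_a = c(2, 2, 1), count_b = c(0, 0, 1))
  pr <- choices_to_proportions(ch, "sequence")
  expect_equal(pr$prop_glossier[pr$step == "A"], 1)
  expect_equal(pr$prop_glossier[pr$step == "B"], 0.25)
  expect_equal(pr$prop_glossier[pr$step == "C"], 0.25)
  pair <- choices_to_proportions(
    tibble::tibble(image_a = "A", image_b = "B", count_a = 8, count_b = 0),
    "pair")
  expect_equal(pair$centered_proportion, 0.5)
  pair0 <- choices_to_proportions(
    tibble::tibble(image_a = "A", image_b = "B", count_a = 4, count_b = 4),
    "pair")
  expect_equal(pair0$centered_proportion, 0)
})

test_that("rankings convert to mean positions per step", {
  rk <- tidyr::expand_grid(observer = 1, family = "matte", set = 1:2,
                           step = 1:5)
  rk$position <- c(1:5, 1:5)
  mp <- ranks_to_positions(rk)
  expect_equal(mp$mean_position, 1:5)
  rk2 <- rk
  rk2$position <- c(1:5, 5:1)
  expect_equal(ranks_to_positions(rk2)$mean_position, rep(3, 5))
  rk3 <- tidyr::expand_grid(observer = 1, family = "m", set = 1:3, step = 1:3)
  rk3$position <- c(1, 2, 3, 2, 1, 3, 3, 2, 1)
  expect_equal(ranks_to_positions(rk3)$mean_position, c(2, 5 / 3, 7 / 3))
  rk_bad <- rk
  rk_bad$position <- c(1, 1, 3, 4, 5, 1:5)
  expect_error(ranks_to_positions(rk_bad), "duplicate")
})

test_that("evaluation metrics are exact on constructed data", {
  m <- c(0.1, 0.4, 0.5, 0.8, 1.0)
  ev <- evaluate_predictions(m, m)
  expect_equal(ev$rmse, 0)
  expect_equal(ev$r_squared, 1)
  suppressWarnings(evc <- evaluate_predictions(rep(0.5, 5), m))
  expect_lte(evc$r_squared, 0)
  h <- c(0.2, 0.3, 0.7, 0.6, 0.9)
  ev2 <- evaluate_predictions(m, h)
  mn <- (m - min(m)) / diff(range(m)); hn <- (h - min(h)) / diff(range(h))
  expect_equal(ev2$rmse, sqrt(mean((mn - hn)^2)), tolerance = 1e-12)
  expect_equal(ev2$correlation, cor(mn, hn), tolerance = 1e-12)
  ev3 <- evaluate_predictions(m, h, logistic_link = TRUE)
  expect_gte(ev3$r_squared_logistic, ev3$r_squared - 1e-6)
})

test_that("the noise ceiling reflects shared signal and observer noise", {
  set.seed(36)
  ident <- matrix(rep(runif(30), 4), 30)
  nc <- noise_ceiling(ident)
  expect_equal(max(nc$rmse), 0, tolerance = 1e-12)
  indep <- matrix(runif(200 * 4), 200)
  nci <- noise_ceiling(indep)
  expect_lt(abs(mean(nci$correlation)), 0.15)
  # analytic attenuation: x_i = s + e_i
  sig <- rnorm(800)
  obs <- sapply(1:3, function(i) sig + rnorm(800, sd = 1))
  ncs <- noise_ceiling(obs)
  rho_ref <- 1 / sqrt((1 + 1) * (1 + 1 / 2))
  expect_equal(mean(ncs$correlation), rho_ref, tolerance = 0.06)
})

test_that("synthetic observers reduce to the deterministic simulation", {
  gl <- c(0.1, 0.3, 0.5, 0.7, 0.9, 0.2, 0.8)
  p_inf <- observer_params(1, beta_median = 1e6, lapse_max = 0, seed = 2)
  p_inf$lapse <- 0
  ch <- synthetic_observer(gl, p_inf, "choice", n_reps = 4, seed = 3)
  pr <- choices_to_proportions(ch, "sequence")
  det <- simulate_2afc(gl)
  expect_equal(pr$prop_glossier[order(as.numeric(pr$step))],
               det$prop_glossier, tolerance = 1e-12)
  p0 <- observer_params(1, beta_median = 1e-9, lapse_max = 0, seed = 2)
  ch0 <- synthetic_observer(gl, p0, "choice", n_reps = 200, seed = 4)
  expect_lt(abs(mean(ch0$count_a / 200) - 0.5), 0.05)
})

test_that("ratings respect the criteria and the scale", {
  gl <- seq(0, 1, length.out = 20)
  pars <- observer_params(3, seed = 5)
  rt <- synthetic_observer(gl, pars, "rating", n_reps = 3, seed = 6)
  expect_true(all(rt$rating %in% 1:6))
  expect_equal(nrow(rt), 3 * 3 * 20)
  # monotone on average: top stimuli rated higher than bottom
  agg <- tapply(rt$rating, rt$stimulus, mean)
  expect_gt(mean(agg[15:20]), mean(agg[1:6]))
})

test_that("observer parameters are recoverable from choice data", {
  gl <- runif(10, 0, 1) * 4 - 2
  set.seed(37)
  pars <- observer_params(6, beta_median = 2, beta_log_sd = 0.2,
                          lapse_max = 0.08, seed = 7)
  ch <- synthetic_observer(gl, pars, "choice", n_reps = 16, seed = 8)
  fit <- fit_observer_params(ch, gl)
  expect_lt(median(abs(log(fit$beta / pars$beta))), log(1.35))
  expect_lt(median(abs(fit$lapse - pars$lapse)), 0.06)
  # lapse fixed at zero reduces to logistic regression on the difference
  p1 <- observer_params(1, beta_median = 1.5, lapse_max = 0, seed = 9)
  ch1 <- synthetic_observer(gl, p1, "choice", n_reps = 50, seed = 10)
  f0 <- fit_observer_params(ch1, gl, fix_lapse = 0)
  dg <- gl[ch1$image_a] - gl[ch1$image_b]
  gfit <- glm(cbind(ch1$count_a, ch1$count_b) ~ 0 + dg, family = binomial)
  expect_equal(f0$beta, unname(coef(gfit)[1]), tolerance = 1e-3)
  expect_error(fit_observer_params(ch1[0, ], gl), "no trials")
})
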