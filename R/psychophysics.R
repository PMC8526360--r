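# The experiment-analysis layer: simulated two-alternative forced choice
# (2AFC) from model predictions, the stimulus-selection algorithms for the
# relief-sequence and constancy-pair experiments, the transforms applied to
# rating/ranking/choice data, model-evaluation metrics with a noise ceiling,
# and a synthetic-observer generator that stands in for human data.

#' Simulate a 2AFC experiment from model predictions
#'
#' Every unordered pair of images is compared; the image with the higher
#' predicted gloss wins deterministically, exact ties are split 0.5/0.5.
#' Each image's profile value is wins / comparisons. The mean over steps is
#' exactly 0.5.
#'
#' @param predictions Numeric gloss predictions for the sequence (length >= 2).
#' @return A tibble (`step`, `prop_glossier`, `n_comparisons`) with source
#'   `"model_simulation"`.
#' @export
simulate_2afc <- function(predictions) {
  n <- length(predictions)
  stopifnot(n >= 2)
  wins <- numeric(n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (predictions[i] > predictions[j]) wins[i] <- wins[i] + 1
    else if (predictions[j] > predictions[i]) wins[j] <- wins[j] + 1
    else { wins[i] <- wins[i] + 0.5; wins[j] <- wins[j] + 0.5 }
  }
  tibble::tibble(step = seq_len(n), prop_glossier = wins / (n - 1),
                 n_comparisons = n - 1, source = "model_simulation")
}

#' Rank candidate sequences by model disagreement
#'
#' For each candidate relief sequence, runs a 2 x steps (model x relief)
#' two-way ANOVA on the instance-level simulated "proportion glossier"
#' values of two models and sorts sequences by descending interaction F.
#'
#' @param profiles_a,profiles_b Lists (one element per sequence) of
#'   instance x step matrices of simulated proportions for models A and B.
#' @return Tibble (`sequence`, `f_interaction`) sorted by descending F.
#' @export
rank_sequences_by_disagreement <- function(profiles_a, profiles_b) {
  stopifnot(length(profiles_a) == length(profiles_b))
  f_int <- vapply(seq_along(profiles_a), function(s) {
    pa <- as.matrix(profiles_a[[s]]); pb <- as.matrix(profiles_b[[s]])
    if (is.null(dim(pa)) || nrow(pa) < 1) stop("missing instances")
    df <- rbind(
      data.frame(model = "A", step = factor(rep(seq_len(ncol(pa)),
                                                each = nrow(pa))),
                 y = as.vector(pa)),
      data.frame(model = "B", step = factor(rep(seq_len(ncol(pb)),
                                                each = nrow(pb))),
                 y = as.vector(pb)))
    df$model <- factor(df$model)
    fit <- stats::aov(y ~ model * step, data = df)
    tab <- summary(fit)[[1]]
    idx <- grep("model:step", rownames(tab))
    fv <- tab[idx, "F value"]
    if (length(fv) == 0 || is.na(fv)) Inf else fv  # no residual variance
  }, numeric(1))
  dplyr::arrange(tibble::tibble(sequence = seq_along(profiles_a),
                                f_interaction = f_int),
                 dplyr::desc(.data$f_interaction))
}

#' Classify the constancy pattern of a relief-sequence profile
#'
#' Qualitative groups based on the instance-averaged "proportion glossier"
#' profile: `constant` (range < 0.25, linear fit R^2 > 0.70), `linear`
#' (range > 0.50, linear R^2 > 0.90), `non_monotonic` (range > 0.50,
#' quadratic R^2 > 0.90 with negative squared-term coefficient),
#' `nonlinear_upward` (same with positive coefficient), otherwise
#' `unclassified`. Evaluation order: constant, non_monotonic,
#' nonlinear_upward, linear — quadratic classes take precedence over linear
#' because a strong quadratic also fits a line moderately well.
#'
#' @param profile Numeric vector (default length 7) of proportions.
#' @return Character scalar, one of the group names above.
#' @export
classify_constancy_pattern <- function(profile) {
  x <- seq_along(profile)
  rng <- max(profile) - min(profile)
  r2 <- function(fit) {
    ssr <- sum(stats::residuals(fit)^2)
    sst <- sum((profile - mean(profile))^2)
    if (sst < 1e-18) 1 else 1 - ssr / sst
  }
  lin <- stats::lm(profile ~ x)
  qua <- stats::lm(profile ~ x + I(x^2))
  # a numerically-zero squared term (an exact line) is not a quadratic class
  q_coef <- stats::coef(qua)[["I(x^2)"]]
  if (is.na(q_coef) || abs(q_coef) < 1e-8) q_coef <- 0
  if (rng < 0.25 && r2(lin) > 0.70) return("constant")
  if (rng > 0.50 && r2(qua) > 0.90 && q_coef < 0) return("non_monotonic")
  if (rng > 0.50 && r2(qua) > 0.90 && q_coef > 0) return("nonlinear_upward")
  if (rng > 0.50 && r2(lin) > 0.90) return("linear")
  "unclassified"
}

#' Select pairs at the deciles of prediction difference
#'
#' Within each group, pairs are ranked by the absolute difference in predicted
#' gloss and the pair at rank ceiling(k * n / 10), k = 1..10, of the ascending
#' ranking is selected.
#'
#' @param abs_delta Absolute prediction differences of the candidate pairs.
#' @return Tibble (`decile`, `index`, `abs_delta`) of the 10 selected pairs
#'   (fewer if `length(abs_delta) < 10`, in rank order).
#' @export
select_percentile_pairs <- function(abs_delta) {
  n <- length(abs_delta)
  if (n < 10) {
    if (n < 1) stop("no candidate pairs")
    ord <- order(abs_delta)
    return(tibble::tibble(decile = seq_len(n), index = ord,
                          abs_delta = abs_delta[ord]))
  }
  ord <- order(abs_delta)
  ranks <- ceiling((1:10) * n / 10)
  idx <- ord[ranks]
  tibble::tibble(decile = 1:10, index = idx, abs_delta = abs_delta[idx])
}

#' Normalize values into the unit range
#'
#' Affine map sending the minimum to 0 and the maximum to 1, applied
#' per participant or per model instance. A constant input maps to all 0.5
#' with a warning.
#' @param values Numeric vector.
#' @export
normalize_unit_range <- function(values) {
  rng <- range(values)
  if (diff(rng) < 1e-15) {
    warning("constant input; returning 0.5 for all values")
    return(rep(0.5, length(values)))
  }
  (values - rng[1]) / diff(rng)
}

#' Aggregate choice data into proportions
#'
#' Sequence designs give per-image win proportions across pairings and
#' repetitions; pair designs give the proportion image A was chosen minus
#' 0.5, so that 0 indicates equal apparent gloss (perfect constancy) and
#' +0.5 that A was always judged glossier.
#'
#' @param choices Tibble with columns `image_a`, `image_b`, `count_a`,
#'   `count_b` (one row per pair, per observer if `observer` present).
#' @param design `"sequence"` or `"pair"`.
#' @return Sequence design: tibble (`step`, `prop_glossier`) per observer.
#'   Pair design: tibble (`pair`, `centered_proportion`) per observer.
#' @export
choices_to_proportions <- function(choices, design = c("sequence", "pair")) {
  design <- match.arg(design)
  if (!"observer" %in% names(choices)) choices$observer <- 1L
  stopifnot(all(choices$count_a >= 0), all(choices$count_b >= 0))
  if (design == "pair") {
    return(dplyr::transmute(
      choices, observer = .data$observer,
      pair = paste(.data$image_a, .data$image_b, sep = ":"),
      centered_proportion =
        .data$count_a / (.data$count_a + .data$count_b) - 0.5))
  }
  long <- dplyr::bind_rows(
    dplyr::transmute(choices, observer = .data$observer,
                     step = .data$image_a, wins = .data$count_a,
                     n = .data$count_a + .data$count_b),
    dplyr::transmute(choices, observer = .data$observer,
                     step = .data$image_b, wins = .data$count_b,
                     n = .data$count_a + .data$count_b))
  steps <- sort(unique(c(choices$image_a, choices$image_b)))
  complete <- dplyr::summarise(
    dplyr::group_by(long, .data$observer, .data$step),
    prop_glossier = sum(.data$wins) / sum(.data$n), .groups = "drop")
  miss <- setdiff(steps, unique(complete$step))
  if (length(miss)) warning("incomplete design: steps without comparisons: ",
                            paste(miss, collapse = ", "))
  complete
}

#' Scale model prediction differences for constancy pairs
#'
#' The difference (A - B) is divided by the maximum absolute difference over
#' the pair set and multiplied by 0.5, retaining the original zero point, so
#' model values are comparable to centered human choice proportions.
#'
#' @param pred_a,pred_b Predictions for image A and B of each pair.
#' @export
model_delta_for_pairs <- function(pred_a, pred_b) {
  d <- pred_a - pred_b
  m <- max(abs(d))
  if (m < 1e-15) stop("all prediction differences are zero")
  d / m * 0.5
}

#' Average rank position per modulation step
#'
#' Converts full rankings of image sets (e.g. five gloss-modulation steps) to
#' the average rank position of each step, per observer, averaged within
#' sequence families (matte-seed vs glossy-seed).
#'
#' @param rankings Tibble with columns `observer`, `family`, `set`, `step`,
#'   `position` (1 = least glossy). Each (observer, set) must use each
#'   position exactly once.
#' @return Tibble (`observer`, `family`, `step`, `mean_position`).
#' @export
ranks_to_positions <- function(rankings) {
  chk <- dplyr::summarise(
    dplyr::group_by(rankings, .data$observer, .data$set),
    dup = anyDuplicated(.data$position) > 0, .groups = "drop")
  if (any(chk$dup)) stop("duplicate positions within a ranking")
  dplyr::summarise(
    dplyr::group_by(rankings, .data$observer, .data$family, .data$step),
    mean_position = mean(.data$position), .groups = "drop")
}

#' Evaluate model predictions against (human) responses
#'
#' Both sides are normalized into \[0, 1\] first (per observer / instance);
#' reports per-observer RMSE, Pearson correlation, and R-squared of the
#' identity fit (1 - SSE/SST on normalized values). Optionally a 4-parameter
#' logistic link (floor, ceiling, midpoint, slope) is least-squares fitted
#' from model values to responses before computing R-squared.
#'
#' @param model_values Numeric predictions over the stimulus set.
#' @param human_values Matrix/data frame (stimuli x observers) or vector.
#' @param logistic_link Also fit the 4-parameter logistic transform.
#' @return Tibble: one row per observer (`rmse`, `correlation`, `r_squared`,
#'   and `r_squared_logistic` if requested).
#' @export
evaluate_predictions <- function(model_values, human_values,
                                 logistic_link = FALSE) {
  hv <- as.matrix(human_values)
  if (length(model_values) != nrow(hv)) stop("length mismatch")
  m <- normalize_unit_range(model_values)
  purrr::map_dfr(seq_len(ncol(hv)), function(o) {
    h <- normalize_unit_range(hv[, o])
    rmse <- sqrt(mean((m - h)^2))
    r <- if (stats::sd(m) < 1e-14 || stats::sd(h) < 1e-14) 0
         else stats::cor(m, h)
    r2 <- 1 - sum((h - m)^2) / sum((h - mean(h))^2)
    row <- tibble::tibble(observer = o, rmse = rmse, correlation = r,
                          r_squared = r2)
    if (logistic_link) {
      fit <- fit_logistic_link(m, h)
      row$r_squared_logistic <-
        1 - sum((h - fit$predicted)^2) / sum((h - mean(h))^2)
    }
    row
  })
}

# Least-squares 4-parameter logistic y = lo + (hi - lo) / (1 + exp(-k(x - x0)))
# with multi-start initialization.
fit_logistic_link <- function(x, y) {
  f <- function(p) {
    pred <- p[1] + (p[2] - p[1]) * stats::plogis(p[4] * (x - p[3]))
    sum((y - pred)^2)
  }
  starts <- list(c(min(y), max(y), stats::median(x), 5),
                 c(min(y), max(y), stats::median(x), 1),
                 c(0, 1, 0.5, 10),
                 c(mean(y), mean(y) + 0.1, 0.5, -2))
  best <- NULL
  for (s in starts) {
    o <- try(stats::optim(s, f, method = "Nelder-Mead",
                          control = list(maxit = 2000)), silent = TRUE)
    if (!inherits(o, "try-error") && (is.null(best) || o$value < best$value))
      best <- o
  }
  p <- best$par
  list(par = p,
       predicted = p[1] + (p[2] - p[1]) * stats::plogis(p[4] * (x - p[3])))
}

#' Noise ceiling of inter-observer agreement
#'
#' Predicts each observer's normalized responses by the mean of all other
#' observers' normalized responses, reporting the same metrics as
#' [evaluate_predictions()]. This is the best agreement any fixed model could
#' reach given inter-observer variability.
#'
#' @param human_values Stimuli x observers matrix (>= 3 observers).
#' @return Tibble: one row per observer plus attributes via `summarise`.
#' @export
noise_ceiling <- function(human_values) {
  hv <- as.matrix(human_values)
  if (ncol(hv) < 3) stop("need at least 3 observers")
  hn <- apply(hv, 2, normalize_unit_range)
  purrr::map_dfr(seq_len(ncol(hn)), function(o) {
    others <- rowMeans(hn[, -o, drop = FALSE])
    ev <- evaluate_predictions(others, hn[, o, drop = FALSE])
    ev$observer <- o
    ev
  })
}

#' Parameters of a synthetic observer population
#'
#' Choice behaviour follows a logistic psychometric function with lapses:
#' P(choose A) = lapse/2 + (1 - lapse) * plogis(beta * (g_A - g_B)). Ratings
#' pass the stimulus's gloss value plus Gaussian criterion noise through 5
#' ordered criteria into a 1–6 rating. Defaults: 20 observers, beta
#' log-normal (median 2, sd 0.3 log10 units), lapse uniform on \[0, 0.1\].
#'
#' @param n_observers Number of observers.
#' @param beta_median,beta_log_sd Sensitivity distribution across observers.
#' @param lapse_max Upper bound of the uniform lapse distribution.
#' @param rating_noise_sd Criterion noise for ratings.
#' @param seed Integer seed.
#' @return Tibble: `observer`, `beta`, `lapse`, `rating_noise_sd`, and 5
#'   criterion columns.
#' @export
observer_params <- function(n_observers = 20L, beta_median = 2,
                            beta_log_sd = 0.3, lapse_max = 0.1,
                            rating_noise_sd = 0.1, seed = 1L) {
  with_seed(seed, {
    beta <- 10^(log10(beta_median) + stats::rnorm(n_observers, 0, beta_log_sd))
    lapse <- stats::runif(n_observers, 0, lapse_max)
    crit <- t(vapply(seq_len(n_observers), function(i)
      sort(stats::runif(5, 0.05, 0.95)), numeric(5)))
    colnames(crit) <- paste0("criterion_", 1:5)
    dplyr::bind_cols(tibble::tibble(observer = seq_len(n_observers),
                                    beta = beta, lapse = lapse,
                                    rating_noise_sd = rating_noise_sd),
                     tibble::as_tibble(crit))
  })
}

#' Simulate synthetic observers
#'
#' Generates rating or 2AFC choice data from "true" per-stimulus gloss values
#' under the observer model of [observer_params()].
#'
#' @param gloss True gloss value per stimulus, for choices on the scale the
#'   sensitivity beta applies to. For ratings, values are unit-normalized
#'   internally.
#' @param params One or more observer rows from [observer_params()].
#' @param design `"rating"` (n_reps ratings per stimulus per observer) or
#'   `"choice"` (all stimulus pairs, n_reps presentations each).
#' @param n_reps Repetitions (rating default 3; choice default 8).
#' @param pairs Optional two-column matrix of stimulus index pairs for the
#'   choice design (default: all unordered pairs).
#' @param seed Integer seed.
#' @return Rating design: tibble (`observer`, `stimulus`, `repetition`,
#'   `rating` 1–6). Choice design: tibble (`observer`, `image_a`, `image_b`,
#'   `count_a`, `count_b`).
#' @export
synthetic_observer <- function(gloss, params, design = c("rating", "choice"),
                               n_reps = NULL, pairs = NULL, seed = 1L) {
  design <- match.arg(design)
  if (is.null(n_reps)) n_reps <- if (design == "rating") 3L else 8L
  with_seed(seed, {
    if (design == "rating") {
      g01 <- normalize_unit_range(gloss)
      purrr::map_dfr(seq_len(nrow(params)), function(oi) {
        p <- params[oi, ]
        crit <- as.numeric(p[paste0("criterion_", 1:5)])
        purrr::map_dfr(seq_len(n_reps), function(rep) {
          noisy <- g01 + stats::rnorm(length(g01), 0, p$rating_noise_sd)
          tibble::tibble(observer = p$observer,
                         stimulus = seq_along(gloss), repetition = rep,
                         rating = findInterval(noisy, crit) + 1L)
        })
      })
    } else {
      if (is.null(pairs)) {
        pairs <- t(utils::combn(length(gloss), 2))
      }
      purrr::map_dfr(seq_len(nrow(params)), function(oi) {
        p <- params[oi, ]
        pa <- p$lapse / 2 + (1 - p$lapse) *
          stats::plogis(p$beta * (gloss[pairs[, 1]] - gloss[pairs[, 2]]))
        ca <- stats::rbinom(nrow(pairs), n_reps, pa)
        tibble::tibble(observer = p$observer,
                       image_a = pairs[, 1], image_b = pairs[, 2],
                       count_a = ca, count_b = n_reps - ca)
      })
    }
  })
}

#' Maximum-likelihood recovery of observer parameters from choice data
#'
#' Fits sensitivity beta and lapse rate under the lapse-logistic choice model
#' by L-BFGS-B on the binomial log-likelihood (one fit per observer).
#'
#' @param choices A choice tibble from [synthetic_observer()] (or real data in
#'   the same shape).
#' @param gloss True gloss value per stimulus index.
#' @param fix_lapse Optionally fix lapse (e.g. 0 reduces the model to
#'   logistic regression on the gloss difference).
#' @return Tibble (`observer`, `beta`, `lapse`, `converged`).
#' @export
fit_observer_params <- function(choices, gloss, fix_lapse = NULL) {
  if (nrow(choices) == 0) stop("no trials to fit")
  purrr::map_dfr(split(choices, choices$observer), function(ch) {
    dg <- gloss[ch$image_a] - gloss[ch$image_b]
    nll <- function(par) {
      beta <- exp(par[1])
      lapse <- if (is.null(fix_lapse)) stats::plogis(par[2]) * 0.2
               else fix_lapse
      p <- lapse / 2 + (1 - lapse) * stats::plogis(beta * dg)
      p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
      -sum(ch$count_a * log(p) + ch$count_b * log(1 - p))
    }
    init <- if (is.null(fix_lapse)) c(log(2), -2) else log(2)
    o <- stats::optim(init, nll, method = "BFGS",
                      control = list(maxit = 500))
    if (o$convergence != 0) warning("fit did not converge for observer ",
                                    ch$observer[1])
    tibble::tibble(observer = ch$observer[1],
                   beta = exp(o$par[1]),
                   lapse = if (is.null(fix_lapse)) stats::plogis(o$par[2]) * 0.2
                           else fix_lapse,
                   converged = o$convergence == 0)
  })
}
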