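# Linear readouts from any feature space: maximum-margin gloss
# classification, continuous gloss prediction as signed hyperplane distance,
# multi-way light-field classification, relief regression, per-dimension
# decoding, and latent-space traversal along the gloss axis.

split_train_test <- function(n, split_seed, train_frac = 0.75) {
  with_seed(split_seed, {
    tr <- sort(sample.int(n, round(train_frac * n)))
    list(train = tr, test = setdiff(seq_len(n), tr))
  })
}

standardizer <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  list(center = ctr, scale = scl)
}

apply_std <- function(X, st) scale(X, st$center, st$scale)

#' Fit the linear gloss readout
#'
#' Trains a soft-margin linear maximum-margin classifier (cost 1) on
#' standardized features under a 75/25 train/test split, orients the
#' hyperplane so that positive decision values mean "high gloss", and
#' reports held-out accuracy.
#'
#' @param features n x d numeric matrix (rows = images).
#' @param labels Two-level labels aligned with rows; level `"high"` (or the
#'   alphabetically later level) is the positive class.
#' @param split_seed Seed for the random 75/25 split.
#' @param positive Label treated as high gloss (default `"high"` when present).
#' @return A `gloss_axis` object: unit-normalized `weights` and `bias` in
#'   standardized feature space, the standardization constants, and a
#'   `report` tibble (task, accuracy, split sizes, seed).
#' @export
fit_gloss_classifier <- function(features, labels, split_seed = 1L,
                                 positive = NULL) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2) stop("need exactly two classes, got: ",
                             paste(lev, collapse = ", "))
  if (is.null(positive)) positive <- if ("high" %in% lev) "high" else lev[2]
  sp <- split_train_test(nrow(features), split_seed)
  st <- standardizer(features[sp$train, , drop = FALSE])
  Xtr <- apply_std(features[sp$train, , drop = FALSE], st)
  Xte <- apply_std(features[sp$test, , drop = FALSE], st)
  ytr <- factor(labels[sp$train], levels = lev)
  fit <- e1071::svm(Xtr, ytr, kernel = "linear", cost = 1, scale = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  # orient: positive side = positive class
  pred_tr <- drop(Xtr %*% w + b)
  if (mean(pred_tr[ytr == positive]) < mean(pred_tr[ytr != positive])) {
    w <- -w; b <- -b
  }
  nrm <- sqrt(sum(w^2))
  if (nrm < 1e-12) stop("degenerate hyperplane (all-zero weights)")
  axis <- structure(list(weights = w / nrm, bias = b / nrm,
                         center = st$center, scale = st$scale,
                         positive = positive, levels = lev,
                         split_seed = split_seed),
                    class = "gloss_axis")
  dec_te <- predict_gloss(axis, features[sp$test, , drop = FALSE])
  acc <- mean((dec_te > 0) == (labels[sp$test] == positive))
  axis$report <- tibble::tibble(task = "gloss2way", accuracy = acc,
                                n_train = length(sp$train),
                                n_test = length(sp$test),
                                seed = split_seed)
  axis
}

#' @export
print.gloss_axis <- function(x, ...) {
  cat("<gloss_axis> ", length(x$weights), "D, held-out accuracy ",
      round(x$report$accuracy, 4), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.gloss_axis <- function(x, ...) {
  tibble::tibble(term = paste0("dim", seq_along(x$weights)),
                 estimate = x$weights)
}

#' @export
glance.gloss_axis <- function(x, ...) x$report

#' Continuous gloss prediction: signed distance from the gloss hyperplane
#'
#' Features are standardized with the constants stored in the axis; the
#' decision value is (w . x + b) / ||w|| in that space, so values are in
#' (standardized) feature-space units. Positive values indicate high-gloss
#' classifications; the magnitude is the strength of evidence.
#'
#' @param axis A [fit_gloss_classifier()] axis.
#' @param features Vector (single image) or n x d matrix.
#' @return Numeric decision values.
#' @export
predict_gloss <- function(axis, features) {
  if (is.null(dim(features))) features <- matrix(features, 1)
  if (ncol(features) != length(axis$weights))
    stop("feature dimensionality does not match the axis")
  Xs <- apply_std(as.matrix(features), list(center = axis$center,
                                            scale = axis$scale))
  drop(Xs %*% axis$weights + axis$bias)
}

#' Multi-way light-field decoding
#'
#' One-vs-rest linear maximum-margin classification of the light field from
#' features, with held-out proportion correct (chance = 1 / number of fields).
#'
#' @inheritParams fit_gloss_classifier
#' @param labels Light-field labels (any number of levels >= 2).
#' @return A `decoding_report` tibble (task, accuracy, chance, split sizes).
#' @export
decode_lightfield <- function(features, labels, split_seed = 1L) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) < 2) stop("need at least two light fields")
  sp <- split_train_test(nrow(features), split_seed)
  st <- standardizer(features[sp$train, , drop = FALSE])
  Xtr <- apply_std(features[sp$train, , drop = FALSE], st)
  Xte <- apply_std(features[sp$test, , drop = FALSE], st)
  scores <- sapply(lev, function(l) {
    y <- factor(labels[sp$train] == l, levels = c(FALSE, TRUE))
    if (length(unique(y)) < 2) return(rep(-Inf, length(sp$test)))
    fit <- e1071::svm(Xtr, y, kernel = "linear", cost = 1, scale = FALSE)
    w <- drop(crossprod(fit$coefs, fit$SV)); b <- -fit$rho
    d <- drop(Xtr %*% w + b)
    if (mean(d[y == TRUE]) < mean(d[y == FALSE])) { w <- -w; b <- -b }
    drop(Xte %*% w + b)
  })
  pred <- lev[max.col(scores)]
  tibble::tibble(task = "lightfield", accuracy = mean(pred == labels[sp$test]),
                 chance = 1 / length(lev), n_train = length(sp$train),
                 n_test = length(sp$test), seed = split_seed)
}

#' Linear regression of surface relief (or any numeric factor) from features
#'
#' Ordinary least squares on the training split; held-out R-squared reported
#' as computed (it may be negative).
#'
#' @inheritParams fit_gloss_classifier
#' @param target Numeric target per row.
#' @return A `decoding_report` tibble with `r_squared`.
#' @export
regress_relief <- function(features, target, split_seed = 1L) {
  features <- as.matrix(features)
  colnames(features) <- paste0("f", seq_len(ncol(features)))
  sp <- split_train_test(nrow(features), split_seed)
  df_tr <- data.frame(y = target[sp$train], features[sp$train, , drop = FALSE])
  fit <- stats::lm(y ~ ., data = df_tr)
  if (any(is.na(stats::coef(fit))))
    warning("degenerate design matrix: some coefficients not estimable")
  pred <- stats::predict(fit, newdata = as.data.frame(features[sp$test, ,
                                                               drop = FALSE]))
  sse <- sum((target[sp$test] - pred)^2)
  sst <- sum((target[sp$test] - mean(target[sp$train]))^2)
  tibble::tibble(task = "relief_regression", r_squared = 1 - sse / sst,
                 n_train = length(sp$train), n_test = length(sp$test),
                 seed = split_seed)
}

#' Decoding from each single feature dimension
#'
#' Repeats the relevant decode with each feature dimension alone and returns
#' per-dimension scores plus the best dimension, for comparison with the
#' full-dimensional readout.
#'
#' @inheritParams fit_gloss_classifier
#' @param target Labels (two-level -> classification accuracy) or numeric
#'   (-> held-out R-squared).
#' @return List with `per_dimension` tibble and `best` row.
#' @export
per_dimension_decoding <- function(features, target, split_seed = 1L) {
  features <- as.matrix(features)
  stopifnot(ncol(features) >= 2)
  is_class <- !is.numeric(target)
  rows <- purrr::map_dfr(seq_len(ncol(features)), function(j) {
    f1 <- features[, j, drop = FALSE]
    if (is_class) {
      ax <- fit_gloss_classifier(f1, target, split_seed)
      tibble::tibble(dimension = j, score = ax$report$accuracy)
    } else {
      rep <- regress_relief(f1, target, split_seed)
      tibble::tibble(dimension = j, score = rep$r_squared)
    }
  })
  list(per_dimension = rows, best = rows[which.max(rows$score), ])
}

#' Traverse latent space along the gloss axis
#'
#' Starting at a seed image's posterior mean, takes `n_steps - 1` further
#' points each displaced `step` units along the unit normal of the gloss
#' hyperplane (in the standardized latent space the axis is defined in), and
#' generates an image at each point with a fixed sampling seed. Decision
#' values of the visited points form an arithmetic sequence with common
#' difference +/- `step`.
#'
#' @param model A trained [train_pixelvae()] model.
#' @param axis A [fit_gloss_classifier()] axis fitted on this model's latent
#'   means.
#' @param seed_image H x W x 3 image (0..255).
#' @param n_steps Number of points (default 5).
#' @param step Displacement per step in latent units (default 0.07).
#' @param direction `"glossy"` (positive side) or `"matte"`.
#' @param sample_seed Seed for pixel sampling.
#' @param generate Set `FALSE` to skip image generation (latents only).
#' @return List with `latents` (n_steps x d, raw latent space), `decision`
#'   values, and `images` (list of generated arrays, or NULL).
#' @export
gloss_axis_traversal <- function(model, axis, seed_image, n_steps = 5L,
                                 step = 0.07, direction = c("glossy", "matte"),
                                 sample_seed = 1L, generate = TRUE) {
  direction <- match.arg(direction)
  if (length(axis$weights) != model$config$latent_dim)
    stop("axis dimensionality does not match the model's latent code")
  z0 <- drop(encode_latents(model, seed_image))
  sgn <- if (direction == "glossy") 1 else -1
  zs0 <- (z0 - axis$center) / axis$scale
  lat_std <- t(vapply(0:(n_steps - 1), function(k)
    zs0 + sgn * k * step * axis$weights, numeric(length(z0))))
  lat <- sweep(sweep(lat_std, 2, axis$scale, "*"), 2, axis$center, "+")
  dec <- drop(lat_std %*% axis$weights + axis$bias)
  imgs <- NULL
  if (generate)
    imgs <- lapply(seq_len(n_steps), function(i)
      generate_image(model, lat[i, ], seed = sample_seed))
  list(latents = lat, decision = dec, images = imgs,
       direction = direction, step = step)
}
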