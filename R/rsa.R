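# Representational similarity analysis: pairwise dissimilarity matrices over
# latent representations, condition-block averaging, same-vs-different
# contrasts across model training instances, and dissimilarities between
# model prediction vectors.

#' Correlation-distance matrix of a feature space
#'
#' Entry (i, j) is 1 minus the Pearson correlation between feature rows i
#' and j; distances lie in \[0, 2\], the diagonal is 0. Zero-variance rows
#' cannot be correlated: their pairs are recorded in the `excluded` attribute
#' and set to NA.
#'
#' @param features n x d matrix, d >= 2.
#' @return A `dissimilarity_matrix` (square, symmetric) with `metric`
#'   attribute `"correlation_distance"`.
#' @export
correlation_distance_matrix <- function(features) {
  features <- as.matrix(features)
  stopifnot(nrow(features) >= 2, ncol(features) >= 2)
  sds <- apply(features, 1, stats::sd)
  bad <- which(sds < 1e-14)
  D <- 1 - stats::cor(t(features))
  if (length(bad)) {
    warning(length(bad), " zero-variance row(s) excluded from correlation")
    D[bad, ] <- NA_real_
    D[, bad] <- NA_real_
  }
  diag(D) <- 0
  structure(D, metric = "correlation_distance", excluded = bad,
            class = c("dissimilarity_matrix", class(D)))
}

#' Euclidean-distance matrix between model prediction vectors
#'
#' Each model's predictions over a common stimulus set are first normalized
#' into \[0, 1\] (per model), then pairwise Euclidean distances are computed.
#'
#' @param predictions Named list of numeric vectors (one per model, equal
#'   lengths), or a models x stimuli matrix.
#' @return A `dissimilarity_matrix` with metric `"euclidean"`.
#' @export
prediction_distance_matrix <- function(predictions) {
  if (is.list(predictions)) {
    len <- lengths(predictions)
    if (length(unique(len)) != 1) stop("prediction vectors differ in length")
    predictions <- do.call(rbind, predictions)
  }
  P <- t(apply(predictions, 1, function(v) {
    if (diff(range(v)) < 1e-15) v else normalize_unit_range(v)
  }))
  D <- as.matrix(stats::dist(P))
  structure(D, metric = "euclidean", class = c("dissimilarity_matrix",
                                               class(D)))
}

#' Average a dissimilarity matrix within condition blocks
#'
#' Returns the condition x condition matrix of mean dissimilarities, with the
#' self-diagonal entries (i = j pairs) excluded from every block.
#'
#' @param matrix A square dissimilarity matrix.
#' @param labels Condition label per item.
#' @return Condition x condition matrix of block means.
#' @export
block_average <- function(matrix, labels) {
  stopifnot(nrow(matrix) == length(labels))
  lev <- sort(unique(as.character(labels)))
  out <- matrix(NA_real_, length(lev), length(lev),
                dimnames = list(lev, lev))
  lab <- as.character(labels)
  for (a in seq_along(lev)) for (b in seq_along(lev)) {
    ia <- which(lab == lev[a]); ib <- which(lab == lev[b])
    block <- matrix[ia, ib, drop = FALSE]
    if (a == b) {
      if (length(ia) < 2) {
        warning("condition '", lev[a], "' has a single item; ",
                "its same-condition block is undefined")
        next
      }
      block <- block[row(block) != col(block)]
    }
    out[a, b] <- mean(block, na.rm = TRUE)
  }
  out
}

#' Same-vs-different condition contrast across model instances
#'
#' For each instance's dissimilarity matrix, computes mean(different-
#' condition pairs) - mean(same-condition pairs); positive values mean that
#' same-condition images are represented more similarly. Across instances, a
#' paired (one-sample) t-test with df = instances - 1, Cohen's d, and a
#' percentile bootstrap CI (default 10,000 resamples) are reported.
#'
#' @param matrices List of dissimilarity matrices, one per model instance.
#' @param labels Condition labels (shared item order).
#' @param n_boot Bootstrap resamples for the CI.
#' @param boot_seed Seed for the bootstrap.
#' @return List: `contrasts` (per instance), `statistic` tibble (t, df, p,
#'   cohens_d, ci_lower, ci_upper) when >= 2 instances.
#' @export
same_vs_different_contrast <- function(matrices, labels, n_boot = 10000L,
                                       boot_seed = 1L) {
  if (inherits(matrices, "dissimilarity_matrix")) matrices <- list(matrices)
  lab <- as.character(labels)
  same <- outer(lab, lab, "==")
  diag(same) <- NA  # exclude self-pairs
  contrasts <- vapply(matrices, function(D) {
    stopifnot(nrow(D) == length(lab))
    mean(D[!same & !is.na(same)], na.rm = TRUE) -
      mean(D[same & !is.na(same)], na.rm = TRUE)
  }, numeric(1))
  out <- list(contrasts = contrasts)
  if (length(contrasts) >= 2) {
    sdc <- stats::sd(contrasts)
    if (sdc < 1e-14) {
      warning("zero variance across instances; t statistic undefined")
      tt <- list(statistic = NA_real_, parameter = length(contrasts) - 1,
                 p.value = NA_real_)
      d <- NA_real_
    } else {
      tt <- stats::t.test(contrasts)
      d <- mean(contrasts) / sdc
    }
    ci <- with_seed(boot_seed, {
      bm <- vapply(seq_len(n_boot), function(i)
        mean(sample(contrasts, replace = TRUE)), numeric(1))
      stats::quantile(bm, c(0.025, 0.975), names = FALSE)
    })
    out$statistic <- tibble::tibble(
      mean_contrast = mean(contrasts),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value, cohens_d = d,
      ci_lower = ci[1], ci_upper = ci[2])
  }
  out
}

#' Two-dimensional embedding for visualization
#'
#' Delegates to the pixel-space embedding machinery (used for figures only,
#' never for statistics).
#' @inheritParams pixel_embedding
#' @export
embed_for_visualization <- function(images, method = c("tsne", "mds", "lle"),
                                    dims = 2L, seed = 1L) {
  method <- match.arg(method)
  pixel_embedding(images, method = method, dims = dims, seed = seed)
}

#' Plot a dissimilarity matrix
#' @param object A `dissimilarity_matrix`.
#' @param ... Unused.
#' @export
autoplot.dissimilarity_matrix <- function(object, ...) {
  df <- tidyr::expand_grid(i = seq_len(nrow(object)),
                           j = seq_len(ncol(object)))
  df$value <- object[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(.data$j, .data$i, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = attr(object, "metric")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
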