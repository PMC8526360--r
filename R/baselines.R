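# Comparison models: a supervised residual-network classifier/regressor, a
# plain convolutional autoencoder, histogram skewness, simplified multiscale
# texture statistics, and pixel-space embeddings.

#' Configuration for the supervised residual network
#'
#' Three residual blocks of three convolutional layers each (56 maps at full
#' scale, 16 at desk scale), a 10-unit penultimate fully connected layer
#' treated as the model's latent code, and a softmax output. Trained with
#' softmax cross-entropy, Adam at learning rate 0.001 decayed by 0.99995 per
#' epoch, batch size 32 (full scale: 21 epochs).
#'
#' @param scale_preset `"desk"` or `"full"`.
#' @param width,epochs,latent_dim,batch_size,learning_rate,lr_decay Overrides.
#' @export
supervised_config <- function(scale_preset = c("desk", "full"),
                              width = NULL, epochs = NULL,
                              latent_dim = 10L, batch_size = 32L,
                              learning_rate = 0.001, lr_decay = 0.99995) {
  scale_preset <- match.arg(scale_preset)
  structure(list(scale_preset = scale_preset,
                 width = as.integer(if (is.null(width))
                   if (scale_preset == "desk") 8L else 56L else width),
                 n_blocks = 3L, layers_per_block = 3L,
                 epochs = as.integer(if (is.null(epochs)) 21L else epochs),
                 latent_dim = as.integer(latent_dim),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, lr_decay = lr_decay),
            class = "supervised_config")
}

init_resnet_params <- function(cfg, seed, out_units, image_size) {
  with_seed(seed, {
    f <- cfg$width
    blocks <- lapply(seq_len(cfg$n_blocks), function(b) {
      lst <- list(c1 = new_conv(f, f), c2 = new_conv(f, f), c3 = new_conv(f, f))
      if (b > 1) lst$proj <- new_conv(f, f, 1L)
      lst
    })
    names(blocks) <- paste0("b", seq_len(cfg$n_blocks))
    c(list(conv_in = new_conv(3L, f)),
      blocks,
      list(fc_lat = new_fc(f, cfg$latent_dim),
           fc_out = new_fc(cfg$latent_dim, out_units)))
  })
}

resnet_forward <- function(params, xs, B, cfg, image_size, need_cache = TRUE) {
  f <- cfg$width
  sz <- image_size
  cin <- conv_fwd(xs, params$conv_in, B, sz, sz)
  h <- relu(cin$y)
  cache <- list(cin = cin, a_in = h, sizes = integer(0))
  cur <- sz
  for (b in seq_len(cfg$n_blocks)) {
    blk <- params[[paste0("b", b)]]
    s <- if (b == 1) 1L else 2L
    c1 <- conv_fwd(h, blk$c1, B, cur, cur, stride = s)
    a1 <- relu(c1$y)
    nxt <- cur %/% s
    c2 <- conv_fwd(a1, blk$c2, B, nxt, nxt)
    a2 <- relu(c2$y)
    c3 <- conv_fwd(a2, blk$c3, B, nxt, nxt)
    if (s > 1) {
      pj <- conv_fwd(h, blk$proj, B, cur, cur, stride = s, pad = 0L)
      skip <- pj$y
    } else {
      pj <- NULL
      skip <- h
    }
    hout <- relu(c3$y + skip)
    if (need_cache)
      cache[[paste0("b", b)]] <- list(c1 = c1, a1 = a1, c2 = c2, a2 = a2,
                                      c3 = c3, pj = pj, hin = h, hout = hout,
                                      cur = cur, nxt = nxt, stride = s)
    h <- hout
    cur <- nxt
  }
  hw <- cur * cur
  rep_idx <- rep(seq_len(B), each = hw)
  gap <- rowsum(h, rep_idx) / hw
  lat <- fc_fwd(gap, params$fc_lat)
  alat <- relu(lat)
  out <- fc_fwd(alat, params$fc_out)
  cache$h_last <- h; cache$gap <- gap; cache$lat <- lat; cache$alat <- alat
  cache$rep_idx <- rep_idx; cache$hw <- hw
  list(out = out, latent = lat, cache = if (need_cache) cache)
}

resnet_backward <- function(dout, cache, params, B, cfg, image_size) {
  g <- list()
  bo <- fc_bwd(dout, cache$alat, params$fc_out)
  g$fc_out <- list(W = bo$dW, b = bo$db)
  dlat <- relu_bwd(bo$dx, cache$alat)
  bl <- fc_bwd(dlat, cache$gap, params$fc_lat)
  g$fc_lat <- list(W = bl$dW, b = bl$db)
  dh <- bl$dx[cache$rep_idx, , drop = FALSE] / cache$hw
  for (b in rev(seq_len(cfg$n_blocks))) {
    bc <- cache[[paste0("b", b)]]
    blk <- params[[paste0("b", b)]]
    dsum <- relu_bwd(dh, bc$hout)
    gb <- list()
    b3 <- conv_bwd(dsum, bc$c3, blk$c3, B, bc$nxt, bc$nxt)
    gb$c3 <- list(W = b3$dW, b = b3$db)
    da2 <- relu_bwd(b3$dx, bc$a2)
    b2 <- conv_bwd(da2, bc$c2, blk$c2, B, bc$nxt, bc$nxt)
    gb$c2 <- list(W = b2$dW, b = b2$db)
    da1 <- relu_bwd(b2$dx, bc$a1)
    b1 <- conv_bwd(da1, bc$c1, blk$c1, B, bc$cur, bc$cur, stride = bc$stride)
    gb$c1 <- list(W = b1$dW, b = b1$db)
    dh_in <- b1$dx
    if (bc$stride > 1) {
      bp <- conv_bwd(dsum, bc$pj, blk$proj, B, bc$cur, bc$cur,
                     stride = bc$stride, pad = 0L)
      gb$proj <- list(W = bp$dW, b = bp$db)
      dh_in <- dh_in + bp$dx
    } else {
      dh_in <- dh_in + dsum
    }
    g[[paste0("b", b)]] <- gb
    dh <- dh_in
  }
  dh <- relu_bwd(dh, cache$a_in)
  bi <- conv_bwd(dh, cache$cin, params$conv_in, B, image_size, image_size)
  g$conv_in <- list(W = bi$dW, b = bi$db)
  g
}

train_resnet <- function(dataset, cfg, seed, target, task) {
  manifest <- dataset$manifest
  tr_idx <- which(manifest$split == "train")
  te_idx <- which(manifest$split == "test")
  if (length(te_idx) == 0) te_idx <- which(manifest$split == "validation")
  sz <- dim(dataset$images)[2]
  if (task == "classify") {
    ylab <- factor(target)
    if (nlevels(ylab) < 2) stop("need at least two classes")
    y <- as.integer(ylab)
    out_units <- nlevels(ylab)
  } else {
    mu_t <- mean(target[tr_idx]); sd_t <- stats::sd(target[tr_idx])
    if (sd_t < 1e-12) {
      # degenerate constant target: the fitted predictor is the constant
      y <- target * 0
      sd_t <- 0
    } else {
      y <- (target - mu_t) / sd_t
    }
    out_units <- 1L
  }
  params <- init_resnet_params(cfg, derive_seed(seed, 1), out_units, sz)
  opt <- adam_init(params)
  lr <- cfg$learning_rate
  xmat <- function(idx) do.call(rbind, lapply(idx, function(i)
    2 * image_to_mat(dataset$images[i, , , ]) / 255 - 1))
  set.seed(derive_seed(seed, 2))
  log_rows <- list()
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(tr_idx)
    tot <- 0
    for (start in seq(1, length(ord), by = cfg$batch_size)) {
      ii <- ord[start:min(start + cfg$batch_size - 1, length(ord))]
      B <- length(ii)
      fw <- resnet_forward(params, xmat(ii), B, cfg, sz)
      if (task == "classify") {
        o <- fw$out
        o <- o - apply(o, 1, max)
        p <- exp(o) / rowSums(exp(o))
        loss <- -sum(log(pmax(p[cbind(seq_len(B), y[ii])], 1e-12))) / B
        dout <- p
        dout[cbind(seq_len(B), y[ii])] <- dout[cbind(seq_len(B), y[ii])] - 1
        dout <- dout / B
      } else {
        err <- fw$out[, 1] - y[ii]
        loss <- mean(err^2)
        dout <- matrix(2 * err / B, B)
      }
      if (!is.finite(loss)) stop("non-finite loss at epoch ", ep)
      tot <- tot + loss * B
      grads <- resnet_backward(dout, fw$cache, params, B, cfg, sz)
      stepped <- adam_step(params, grads, opt, lr)
      params <- stepped$params
      opt <- stepped$state
    }
    lr <- lr * cfg$lr_decay
    log_rows[[ep]] <- tibble::tibble(epoch = ep, train_loss = tot / length(ord))
  }
  model <- structure(list(params = params, config = cfg, task = task,
                          image_size = sz, log = dplyr::bind_rows(log_rows),
                          seed = seed,
                          levels = if (task == "classify") levels(ylab),
                          target_center = if (task == "regress") mu_t,
                          target_scale = if (task == "regress") sd_t),
                     class = "gloss_resnet")
  # held-out performance
  if (length(te_idx) > 0) {
    pr <- predict(model, dataset$images[te_idx, , , , drop = FALSE])
    if (task == "classify") {
      model$test_accuracy <- mean(pr$class == target[te_idx])
    } else {
      sse <- sum((pr$value - target[te_idx])^2)
      sst <- sum((target[te_idx] - mean(target[tr_idx]))^2)
      model$test_r2 <- 1 - sse / sst
    }
  }
  model
}

#' Train the supervised gloss classifier
#'
#' Residual-network classifier trained on ground-truth gloss labels
#' (softmax cross-entropy); its 10-unit penultimate layer is the feature
#' space used in model comparisons.
#'
#' @param dataset A labeled (bimodal-regime) [generate_dataset()] result.
#' @param config A [supervised_config()].
#' @param seed Integer seed.
#' @return A `gloss_resnet` model with `test_accuracy` on the held-out split.
#' @export
train_supervised_classifier <- function(dataset, config = supervised_config(),
                                        seed = 1L) {
  lab <- dataset$manifest$gloss_label
  if (all(lab == "unlabeled")) stop("dataset has no gloss labels")
  train_resnet(dataset, config, seed, lab, "classify")
}

#' Train the supervised gloss regressor
#'
#' Same backbone with a scalar output and squared-error loss on (standardized)
#' specular magnitude, giving continuous gloss estimates.
#' @inheritParams train_supervised_classifier
#' @param target Numeric target per image; defaults to the manifest's
#'   `spec_magnitude`.
#' @export
train_supervised_regressor <- function(dataset, config = supervised_config(),
                                       seed = 1L,
                                       target = dataset$manifest$spec_magnitude) {
  train_resnet(dataset, config, seed, target, "regress")
}

#' @export
print.gloss_resnet <- function(x, ...) {
  cat("<gloss_resnet> ", x$task, ", ", x$config$width, " maps, ",
      nrow(x$log), " epochs\n", sep = "")
  invisible(x)
}

#' @export
predict.gloss_resnet <- function(object, newdata, ...) {
  images <- newdata
  if (length(dim(images)) == 3) images <- array(images, c(1, dim(images)))
  n <- dim(images)[1]
  sz <- object$image_size
  outs <- vector("list", ceiling(n / 32))
  lats <- vector("list", length(outs))
  j <- 1
  for (start in seq(1, n, by = 32)) {
    ii <- start:min(start + 31, n)
    xs <- do.call(rbind, lapply(ii, function(i)
      2 * image_to_mat(images[i, , , ]) / 255 - 1))
    fw <- resnet_forward(object$params, xs, length(ii), object$config, sz,
                         need_cache = FALSE)
    outs[[j]] <- fw$out
    lats[[j]] <- fw$latent
    j <- j + 1
  }
  out <- do.call(rbind, outs)
  latent <- do.call(rbind, lats)
  if (object$task == "classify") {
    cls <- object$levels[max.col(out)]
    list(class = cls, score = out, latent = latent)
  } else {
    list(value = out[, 1] * object$target_scale + object$target_center,
         latent = latent)
  }
}

#' Penultimate-layer features of the supervised network
#' @param model A `gloss_resnet`.
#' @param images n x H x W x 3 array.
#' @return n x latent_dim matrix.
#' @export
supervised_features <- function(model, images) {
  predict(model, images)$latent
}

#' @export
glance.gloss_resnet <- function(x, ...) {
  tibble::tibble(task = x$task, epochs = nrow(x$log),
                 final_train_loss = utils::tail(x$log$train_loss, 1),
                 test_accuracy = if (!is.null(x$test_accuracy)) x$test_accuracy
                   else NA_real_,
                 test_r2 = if (!is.null(x$test_r2)) x$test_r2 else NA_real_)
}

#' @export
tidy.gloss_resnet <- function(x, ...) x$log

# ---- Plain convolutional autoencoder ------------------------------------

#' Train the plain convolutional autoencoder
#'
#' Four conv layers alternating with 2 x 2 (average) pooling, a fully
#' connected bottleneck (256 units at desk scale), mirrored upsampling
#' decoder, trained to minimize mean absolute error between input and
#' reconstruction.
#'
#' @param dataset A [generate_dataset()] result.
#' @param seed Integer seed.
#' @param epochs Training epochs.
#' @param widths Feature-map counts of the four encoder conv layers.
#' @param bottleneck Bottleneck units.
#' @param batch_size,learning_rate Optimization knobs (Adam defaults).
#' @return A `gloss_autoencoder` with a per-epoch `log` of training MAE.
#' @export
train_autoencoder <- function(dataset, seed = 1L, epochs = 5L,
                              widths = c(16L, 16L, 8L, 16L),
                              bottleneck = 256L, batch_size = 32L,
                              learning_rate = 0.001) {
  sz <- dim(dataset$images)[2]
  s3 <- sz / 8
  flat <- s3 * s3 * widths[4]
  params <- with_seed(derive_seed(seed, 1), list(
    e1 = new_conv(3L, widths[1]), e2 = new_conv(widths[1], widths[2]),
    e3 = new_conv(widths[2], widths[3]), e4 = new_conv(widths[3], widths[4]),
    fc_b = new_fc(flat, bottleneck), fc_u = new_fc(bottleneck, flat),
    d4 = new_conv(widths[4], widths[3]), d3 = new_conv(widths[3], widths[2]),
    d2 = new_conv(widths[2], widths[1]), d1 = new_conv(widths[1], 3L)))
  opt <- adam_init(params)
  tr_idx <- which(dataset$manifest$split == "train")
  xmat <- function(idx) do.call(rbind, lapply(idx, function(i)
    image_to_mat(dataset$images[i, , , ]) / 255))
  fwd <- function(params, x, B, cache = TRUE) {
    c1 <- conv_fwd(x, params$e1, B, sz, sz); a1 <- relu(c1$y)
    p1 <- avgpool2_cpp(a1, B, sz, sz)
    c2 <- conv_fwd(p1, params$e2, B, sz / 2, sz / 2); a2 <- relu(c2$y)
    p2 <- avgpool2_cpp(a2, B, sz / 2, sz / 2)
    c3 <- conv_fwd(p2, params$e3, B, sz / 4, sz / 4); a3 <- relu(c3$y)
    p3 <- avgpool2_cpp(a3, B, sz / 4, sz / 4)
    c4 <- conv_fwd(p3, params$e4, B, s3, s3); a4 <- relu(c4$y)
    fl <- flatten_maps(a4, B)
    bn <- relu(fc_fwd(fl, params$fc_b))
    uu <- relu(fc_fwd(bn, params$fc_u))
    u4 <- unflatten_maps(uu, B, widths[4])
    c5 <- conv_fwd(u4, params$d4, B, s3, s3); a5 <- relu(c5$y)
    up1 <- upsample2_cpp(a5, B, s3, s3)
    c6 <- conv_fwd(up1, params$d3, B, sz / 4, sz / 4); a6 <- relu(c6$y)
    up2 <- upsample2_cpp(a6, B, sz / 4, sz / 4)
    c7 <- conv_fwd(up2, params$d2, B, sz / 2, sz / 2); a7 <- relu(c7$y)
    up3 <- upsample2_cpp(a7, B, sz / 2, sz / 2)
    c8 <- conv_fwd(up3, params$d1, B, sz, sz)
    env <- environment()
    list(recon = c8$y, bottleneck = bn,
         cache = if (cache) mget(c("c1","a1","p1","c2","a2","p2","c3","a3",
                                   "p3","c4","a4","fl","bn","uu","u4","c5",
                                   "a5","up1","c6","a6","up2","c7","a7","up3",
                                   "c8","x"), envir = env))
  }
  bwd <- function(drec, K, params, B) {
    g <- list()
    b8 <- conv_bwd(drec, K$c8, params$d1, B, sz, sz)
    g$d1 <- list(W = b8$dW, b = b8$db)
    da7 <- relu_bwd(avgpool2_cpp(b8$dx, B, sz, sz) * 4, K$a7)
    b7 <- conv_bwd(da7, K$c7, params$d2, B, sz / 2, sz / 2)
    g$d2 <- list(W = b7$dW, b = b7$db)
    da6 <- relu_bwd(avgpool2_cpp(b7$dx, B, sz / 2, sz / 2) * 4, K$a6)
    b6 <- conv_bwd(da6, K$c6, params$d3, B, sz / 4, sz / 4)
    g$d3 <- list(W = b6$dW, b = b6$db)
    da5 <- relu_bwd(avgpool2_cpp(b6$dx, B, sz / 4, sz / 4) * 4, K$a5)
    b5 <- conv_bwd(da5, K$c5, params$d4, B, s3, s3)
    g$d4 <- list(W = b5$dW, b = b5$db)
    duu <- relu_bwd(flatten_maps(b5$dx, B), K$uu)
    bu <- fc_bwd(duu, K$bn, params$fc_u)
    g$fc_u <- list(W = bu$dW, b = bu$db)
    dbn <- relu_bwd(bu$dx, K$bn)
    bb <- fc_bwd(dbn, K$fl, params$fc_b)
    g$fc_b <- list(W = bb$dW, b = bb$db)
    da4 <- relu_bwd(unflatten_maps(bb$dx, B, widths[4]), K$a4)
    b4 <- conv_bwd(da4, K$c4, params$e4, B, s3, s3)
    g$e4 <- list(W = b4$dW, b = b4$db)
    da3 <- relu_bwd(upsample2_cpp(b4$dx, B, s3, s3) / 4, K$a3)
    b3 <- conv_bwd(da3, K$c3, params$e3, B, sz / 4, sz / 4)
    g$e3 <- list(W = b3$dW, b = b3$db)
    da2 <- relu_bwd(upsample2_cpp(b3$dx, B, sz / 4, sz / 4) / 4, K$a2)
    b2 <- conv_bwd(da2, K$c2, params$e2, B, sz / 2, sz / 2)
    g$e2 <- list(W = b2$dW, b = b2$db)
    da1 <- relu_bwd(upsample2_cpp(b2$dx, B, sz / 2, sz / 2) / 4, K$a1)
    b1 <- conv_bwd(da1, K$c1, params$e1, B, sz, sz)
    g$e1 <- list(W = b1$dW, b = b1$db)
    g
  }
  lr <- learning_rate
  set.seed(derive_seed(seed, 2))
  log_rows <- list()
  for (ep in seq_len(epochs)) {
    ord <- sample(tr_idx)
    tot <- 0
    for (start in seq(1, length(ord), by = batch_size)) {
      ii <- ord[start:min(start + batch_size - 1, length(ord))]
      B <- length(ii)
      x <- xmat(ii)
      fw <- fwd(params, x, B)
      err <- fw$recon - x
      mae <- mean(abs(err))
      tot <- tot + mae * B
      drec <- sign(err) / length(err) * B  # d(mean abs err per image)/drecon
      grads <- bwd(drec, fw$cache, params, B)
      stepped <- adam_step(params, grads, opt, lr)
      params <- stepped$params
      opt <- stepped$state
    }
    log_rows[[ep]] <- tibble::tibble(epoch = ep, train_mae = tot / length(ord))
  }
  structure(list(params = params, widths = widths, bottleneck = bottleneck,
                 image_size = sz, log = dplyr::bind_rows(log_rows),
                 seed = seed, fwd = fwd),
            class = "gloss_autoencoder")
}

#' @export
print.gloss_autoencoder <- function(x, ...) {
  cat("<gloss_autoencoder> bottleneck ", x$bottleneck, ", ",
      nrow(x$log), " epochs\n", sep = "")
  invisible(x)
}

#' Bottleneck features / reconstructions of the autoencoder
#' @param model A `gloss_autoencoder`.
#' @param images n x H x W x 3 array (0..255 or \[0,1\]).
#' @param what `"bottleneck"` or `"reconstruction"`.
#' @export
autoencoder_features <- function(model, images, what = c("bottleneck",
                                                         "reconstruction")) {
  what <- match.arg(what)
  if (length(dim(images)) == 3) images <- array(images, c(1, dim(images)))
  if (max(images) > 1) images <- images / 255
  n <- dim(images)[1]
  res <- vector("list", ceiling(n / 32))
  j <- 1
  for (start in seq(1, n, by = 32)) {
    ii <- start:min(start + 31, n)
    x <- do.call(rbind, lapply(ii, function(i) image_to_mat(images[i, , , ])))
    fw <- model$fwd(model$params, x, length(ii), cache = FALSE)
    res[[j]] <- if (what == "bottleneck") fw$bottleneck else fw$recon
    j <- j + 1
  }
  do.call(rbind, res)
}

# ---- Non-learning feature spaces ----------------------------------------

#' Histogram skewness of an image
#'
#' Third standardized moment of the greyscale (BT.601) pixel intensities;
#' defined as 0 for a constant image.
#' @param image H x W x 3 array or H x W matrix.
#' @export
histogram_skewness <- function(image) {
  g <- if (length(dim(image)) == 3) rgb_to_grey(image) else image
  m <- mean(g)
  v <- mean((g - m)^2)
  if (v < 1e-18) return(0)
  mean((g - m)^3) / v^1.5
}

#' Optimal-threshold gloss classification from skewness
#'
#' Chooses the skewness threshold (and polarity) maximizing training accuracy
#' — ties resolved by the midpoint of the best-accuracy threshold interval —
#' and reports accuracy on the test set.
#'
#' @param train_skew,train_labels Training skewness values and two-level labels.
#' @param test_skew,test_labels Test set.
#' @return List with `threshold`, `polarity` (+1: higher skew = second level),
#'   `train_accuracy`, `test_accuracy`.
#' @export
skewness_threshold_accuracy <- function(train_skew, train_labels,
                                        test_skew, test_labels) {
  lev <- sort(unique(as.character(train_labels)))
  if (length(lev) != 2) stop("need exactly two classes in the training set")
  y <- as.integer(as.character(train_labels) == lev[2])
  s <- sort(unique(train_skew))
  cand <- c(s[1] - 1, (utils::head(s, -1) + utils::tail(s, -1)) / 2, s[length(s)] + 1)
  best <- NULL
  for (pol in c(1, -1)) {
    acc <- vapply(cand, function(th)
      mean((pol * train_skew > pol * th) == (y == 1)), numeric(1))
    mx <- max(acc)
    ths <- cand[acc == mx]
    th <- (min(ths) + max(ths)) / 2
    if (is.null(best) || mx > best$train_accuracy)
      best <- list(threshold = th, polarity = pol, train_accuracy = mx)
  }
  yt <- as.integer(as.character(test_labels) == lev[2])
  best$test_accuracy <- mean((best$polarity * test_skew >
                                best$polarity * best$threshold) == (yt == 1))
  best
}

#' Simplified multiscale texture statistics
#'
#' A compact stand-in for full texture-analysis feature sets: an oriented
#' log-Gabor decomposition (default 3 scales x 4 orientations) of the
#' greyscale image, with per-band marginal moments (mean, variance, skewness,
#' kurtosis) of the real bandpass response, within-band local autocorrelation
#' over a 7 x 7 lag neighbourhood, and cross-scale magnitude correlations
#' per orientation. Feature ordering is fixed: all moments (band-major), all
#' autocorrelations, all cross-scale correlations.
#'
#' @param image H x W x 3 array or greyscale matrix.
#' @param scales,orientations Bank size.
#' @param neighborhood Autocorrelation window (odd; default 7).
#' @return Named numeric feature vector.
#' @export
texture_statistics <- function(image, scales = 3, orientations = 4,
                               neighborhood = 7) {
  g <- if (length(dim(image)) == 3) rgb_to_grey(image) else image
  if (max(g) > 1) g <- g / 255
  n <- nrow(g)
  if (n < 4 * neighborhood) stop("image smaller than the filter support")
  bank <- loggabor_bank(g, scales, orientations)
  half <- (neighborhood - 1) / 2
  moments <- c(); acors <- c(); xcors <- c()
  mags <- vector("list", length(bank))
  for (k in seq_along(bank)) {
    re <- Re(bank[[k]]$resp)
    mags[[k]] <- Mod(bank[[k]]$resp)
    m <- mean(re); v <- mean((re - m)^2)
    sk <- if (v < 1e-18) 0 else mean((re - m)^3) / v^1.5
    ku <- if (v < 1e-18) 0 else mean((re - m)^4) / v^2
    moments <- c(moments, m, v, sk, ku)
    # FFT autocorrelation, normalized; zero for a flat band
    if (v < 1e-18) {
      ac <- matrix(0, neighborhood, neighborhood)
    } else {
      F <- stats::fft(re - m)
      full <- Re(stats::fft(F * Conj(F), inverse = TRUE)) / n^2 / (n^2 * v)
      sel <- c(n - half + seq_len(half) - 1, 1:(half + 1))
      ac <- full[sel, sel]
    }
    acors <- c(acors, as.vector(ac))
  }
  for (o in seq_len(orientations)) {
    for (s1 in seq_len(scales - 1)) for (s2 in (s1 + 1):scales) {
      k1 <- (s1 - 1) * orientations + o
      k2 <- (s2 - 1) * orientations + o
      m1 <- mags[[k1]]; m2 <- mags[[k2]]
      xcors <- c(xcors,
                 if (stats::sd(m1) < 1e-12 || stats::sd(m2) < 1e-12) 0
                 else stats::cor(as.vector(m1), as.vector(m2)))
    }
  }
  stats::setNames(c(moments, acors, xcors),
                  c(paste0("mom_", rep(seq_along(bank), each = 4), "_",
                           c("mean", "var", "skew", "kurt")),
                    paste0("acor_", rep(seq_along(bank),
                                        each = neighborhood^2), "_",
                           seq_len(neighborhood^2)),
                    paste0("xcor_", seq_along(xcors))))
}

# ---- Pixel-space embeddings ---------------------------------------------

#' Low-dimensional embedding of images in pixel space
#'
#' Classical multidimensional scaling delegates to [stats::cmdscale()];
#' t-SNE and locally linear embedding are compact reference implementations
#' (standard perplexity-calibrated t-SNE; LLE with k-nearest-neighbour
#' reconstruction weights and bottom eigenvectors). Probe images must be
#' embedded jointly with the training images: none of these methods supports
#' out-of-sample projection.
#'
#' @param images n x H x W x 3 array, or an n x p feature matrix.
#' @param method `"mds"`, `"tsne"` or `"lle"`.
#' @param dims Embedding dimensionality (default 10).
#' @param seed Seed (t-SNE initialization).
#' @param perplexity,k Method parameters.
#' @return n x dims coordinate matrix.
#' @export
pixel_embedding <- function(images, method = c("mds", "tsne", "lle"),
                            dims = 10L, seed = 1L, perplexity = 30, k = 5L) {
  method <- match.arg(method)
  X <- if (length(dim(images)) == 4) {
    n <- dim(images)[1]
    t(vapply(seq_len(n), function(i) as.numeric(images[i, , , ]),
             numeric(length(images[1, , , ]))))
  } else as.matrix(images)
  if (nrow(X) < dims + 2) stop("need at least dims + 2 images")
  switch(method,
         mds = {
           co <- stats::cmdscale(stats::dist(X), k = dims)
           if (ncol(co) < dims)  # degenerate: pad zero columns
             co <- cbind(co, matrix(0, nrow(co), dims - ncol(co)))
           co
         },
         tsne = tsne_embed(X, dims = dims, perplexity = perplexity, seed = seed),
         lle = lle_embed(X, dims = dims, k = k))
}

# Standard t-SNE (exact pairwise version) -- adequate for the modest image
# counts used here.
tsne_embed <- function(X, dims = 2L, perplexity = 30, seed = 1L,
                       n_iter = 400L, eta = 100) {
  n <- nrow(X)
  perplexity <- min(perplexity, floor((n - 1) / 3))
  D2 <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1; betamin <- -Inf; betamax <- Inf
    di <- D2[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sump <- sum(p)
      H <- log(sump) + beta * sum(di * p) / sump
      diff <- H - log(perplexity)
      if (abs(diff) < 1e-5) break
      if (diff > 0) { betamin <- beta
        beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2
      } else { betamax <- beta
        beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2 }
    }
    P[i, -i] <- p / sum(p)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  with_seed(seed, {
    Y <- matrix(stats::rnorm(n * dims, sd = 1e-4), n)
    gain <- matrix(1, n, dims); inc <- matrix(0, n, dims)
    for (it in seq_len(n_iter)) {
      Pu <- if (it <= 100) P * 4 else P
      num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      M <- (Pu - Q) * num
      grad <- 4 * (diag(rowSums(M)) - M) %*% Y
      gain <- ifelse(sign(grad) != sign(inc), gain + 0.2, gain * 0.8)
      gain[gain < 0.01] <- 0.01
      inc <- (if (it <= 250) 0.5 else 0.8) * inc - eta * gain * grad
      Y <- Y + inc
      Y <- sweep(Y, 2, colMeans(Y))
    }
    Y
  })
}

# Standard locally linear embedding.
lle_embed <- function(X, dims = 2L, k = 5L, reg = 1e-3) {
  n <- nrow(X)
  k <- min(k, n - 1)
  D <- as.matrix(stats::dist(X))
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[2:(k + 1)]
    Z <- sweep(X[nb, , drop = FALSE], 2, X[i, ])
    G <- Z %*% t(Z)
    G <- G + diag(k) * reg * sum(diag(G) + 1e-12) / k
    w <- solve(G, rep(1, k))
    W[i, nb] <- w / sum(w)
  }
  M <- crossprod(diag(n) - W)
  e <- eigen(M, symmetric = TRUE)
  idx <- order(e$values)[2:(dims + 1)]
  e$vectors[, idx, drop = FALSE] * sqrt(n)
}
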