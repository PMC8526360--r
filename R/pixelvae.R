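# The unsupervised generative model: a convolutional variational encoder
# producing a compact latent code, and an autoregressive pixel stream with a
# discretized logistic mixture likelihood (PixelCNN++-style output head with
# linear channel coupling). The latent enters the autoregressive stream as a
# spatially broadcast bias at each residual block input.

#' Configuration for the unsupervised generative model
#'
#' The `"full"` preset is the full-scale architecture (128-px images, encoder
#' widths 64/128/256 with a 512-unit fully connected layer, six residual
#' blocks of three 64-map layers, 12 mixture components, 200 epochs). The
#' `"desk"` preset keeps every architectural mechanism — strided conv encoder,
#' reparameterized 10-D latent, causal masked decoder with residual blocks,
#' latent-bias conditioning, skip links between early and late blocks,
#' discretized logistic mixture with RGB coupling — at CPU-trainable size:
#' 32-px images, widths 16/32/64, 128-unit fc, three residual blocks of two
#' 16-map layers, 5 mixture components.
#'
#' @param scale_preset `"desk"` or `"full"`.
#' @param latent_dim Latent dimensionality (default 10).
#' @param epochs Training epochs (desk default 18).
#' @param image_size,cond_widths,cond_fc,ar_blocks,ar_layers,ar_maps,mixture_components
#'   Architecture knobs; defaults follow the preset.
#' @param learning_rate,lr_decay,batch_size Optimization schedule: Adam at
#'   0.001, multiplicative decay 0.999995 per epoch, batch size 5.
#' @return A `pixelvae_config` list.
#' @export
pixelvae_config <- function(scale_preset = c("desk", "full"),
                            latent_dim = 10L,
                            epochs = NULL,
                            image_size = NULL,
                            cond_widths = NULL,
                            cond_fc = NULL,
                            ar_blocks = NULL,
                            ar_layers = NULL,
                            ar_maps = NULL,
                            mixture_components = NULL,
                            learning_rate = 0.001,
                            lr_decay = 0.999995,
                            batch_size = 5L) {
  scale_preset <- match.arg(scale_preset)
  d <- if (scale_preset == "desk")
    list(image_size = 32L, cond_widths = c(16L, 32L, 64L), cond_fc = 128L,
         ar_blocks = 3L, ar_layers = 2L, ar_maps = 16L,
         mixture_components = 5L, epochs = 18L)
  else
    list(image_size = 128L, cond_widths = c(64L, 128L, 256L), cond_fc = 512L,
         ar_blocks = 6L, ar_layers = 3L, ar_maps = 64L,
         mixture_components = 12L, epochs = 200L)
  pick <- function(x, nm) if (is.null(x)) d[[nm]] else x
  cfg <- list(scale_preset = scale_preset,
              latent_dim = as.integer(latent_dim),
              image_size = as.integer(pick(image_size, "image_size")),
              cond_widths = as.integer(pick(cond_widths, "cond_widths")),
              cond_fc = as.integer(pick(cond_fc, "cond_fc")),
              ar_blocks = as.integer(pick(ar_blocks, "ar_blocks")),
              ar_layers = as.integer(pick(ar_layers, "ar_layers")),
              ar_maps = as.integer(pick(ar_maps, "ar_maps")),
              mixture_components = as.integer(pick(mixture_components,
                                                   "mixture_components")),
              learning_rate = learning_rate,
              lr_decay = lr_decay,
              batch_size = as.integer(batch_size),
              epochs = as.integer(pick(epochs, "epochs")))
  stopifnot(cfg$latent_dim >= 1, cfg$mixture_components >= 1,
            cfg$lr_decay > 0, cfg$lr_decay <= 1, length(cfg$cond_widths) == 3)
  structure(cfg, class = "pixelvae_config")
}

init_pixelvae_params <- function(cfg, seed) {
  with_seed(seed, {
    w <- cfg$cond_widths
    M <- cfg$ar_maps
    K <- cfg$mixture_components
    sz <- cfg$image_size
    flat <- (sz / 8)^2 * w[3]
    blocks <- lapply(seq_len(cfg$ar_blocks), function(b) {
      convs <- lapply(seq_len(cfg$ar_layers), function(l) new_conv(M, M, 3L))
      names(convs) <- paste0("c", seq_len(cfg$ar_layers))
      c(list(zproj = new_fc(cfg$latent_dim, M)), convs)
    })
    names(blocks) <- paste0("b", seq_len(cfg$ar_blocks))
    list(enc = list(conv1 = new_conv(3L, w[1]),
                    conv2 = new_conv(w[1], w[2]),
                    conv3 = new_conv(w[2], w[3]),
                    fc1 = new_fc(flat, cfg$cond_fc),
                    fc_mu = new_fc(cfg$cond_fc, cfg$latent_dim),
                    fc_lv = new_fc(cfg$cond_fc, cfg$latent_dim)),
         dec = c(list(conv_in = new_conv(3L, M)),
                 blocks,
                 list(out1 = new_conv(M, 2L * M, 1L),
                      out2 = new_conv(2L * M, 10L * K, 1L))))
  })
}

# Pairs (i, j) of residual blocks whose outputs/inputs are skip-linked
# (first with last, second with second-to-last), mirroring the full-scale
# 1<->6, 2<->5 wiring at any block count.
skip_pairs <- function(nb) {
  if (nb < 2) return(list())
  pairs <- list()
  if (nb >= 2) pairs[[1]] <- c(1L, nb)
  if (nb >= 4) pairs[[2]] <- c(2L, nb - 1L)
  pairs
}

encoder_forward <- function(params, xs, B, cfg) {
  sz <- cfg$image_size
  e <- params$enc
  c1 <- conv_fwd(xs, e$conv1, B, sz, sz, stride = 2L, pad = 1L)
  a1 <- relu(c1$y)
  c2 <- conv_fwd(a1, e$conv2, B, sz / 2, sz / 2, stride = 2L, pad = 1L)
  a2 <- relu(c2$y)
  c3 <- conv_fwd(a2, e$conv3, B, sz / 4, sz / 4, stride = 2L, pad = 1L)
  a3 <- relu(c3$y)
  fl <- flatten_maps(a3, B)
  f1 <- fc_fwd(fl, e$fc1)
  af <- relu(f1)
  mu <- fc_fwd(af, e$fc_mu)
  lv <- fc_fwd(af, e$fc_lv)
  list(mu = mu, lv = lv,
       cache = list(c1 = c1, a1 = a1, c2 = c2, a2 = a2, c3 = c3, a3 = a3,
                    fl = fl, f1 = f1, af = af, xs = xs))
}

encoder_backward <- function(dmu, dlv, cache, params, B, cfg) {
  sz <- cfg$image_size
  e <- params$enc
  g <- list()
  bmu <- fc_bwd(dmu, cache$af, e$fc_mu)
  blv <- fc_bwd(dlv, cache$af, e$fc_lv)
  g$fc_mu <- bmu[c("dW", "db")]
  g$fc_lv <- blv[c("dW", "db")]
  daf <- relu_bwd(bmu$dx + blv$dx, cache$af)
  b1 <- fc_bwd(daf, cache$fl, e$fc1)
  g$fc1 <- b1[c("dW", "db")]
  da3 <- relu_bwd(unflatten_maps(b1$dx, B, ncol(cache$a3)), cache$a3)
  b3 <- conv_bwd(da3, cache$c3, e$conv3, B, sz / 4, sz / 4, stride = 2L, pad = 1L)
  g$conv3 <- b3[c("dW", "db")]
  da2 <- relu_bwd(b3$dx, cache$a2)
  b2 <- conv_bwd(da2, cache$c2, e$conv2, B, sz / 2, sz / 2, stride = 2L, pad = 1L)
  g$conv2 <- b2[c("dW", "db")]
  da1 <- relu_bwd(b2$dx, cache$a1)
  bb1 <- conv_bwd(da1, cache$c1, e$conv1, B, sz, sz, stride = 2L, pad = 1L)
  g$conv1 <- bb1[c("dW", "db")]
  lapply(g, function(x) list(W = x$dW, b = x$db))
}

decoder_masks <- function(cfg) {
  M <- cfg$ar_maps
  list(inA = causal_mask(3L, 3L, M, "A"),
       B = causal_mask(3L, M, M, "B"))
}

decoder_forward <- function(params, xs, z, B, cfg, masks, need_cache = TRUE) {
  sz <- cfg$image_size
  hw <- sz * sz
  d <- params$dec
  rep_idx <- rep(seq_len(B), each = hw)
  cin <- conv_fwd(xs, d$conv_in, B, sz, sz, mask = masks$inA)
  h <- cin$y
  nb <- cfg$ar_blocks
  sp <- skip_pairs(nb)
  skip_from <- integer(0); skip_to <- integer(0)
  for (p in sp) { skip_from <- c(skip_from, p[1]); skip_to <- c(skip_to, p[2]) }
  block_out <- vector("list", nb)
  bc <- vector("list", nb)
  for (bi in seq_len(nb)) {
    blk <- d[[paste0("b", bi)]]
    hin <- h
    if (bi %in% skip_to) hin <- hin + block_out[[skip_from[match(bi, skip_to)]]]
    zb <- fc_fwd(z, blk$zproj)
    hin <- hin + zb[rep_idx, , drop = FALSE]
    acts <- list(); cs <- list()
    a <- relu(hin)
    acts[[1]] <- a
    for (li in seq_len(cfg$ar_layers)) {
      cc <- conv_fwd(a, blk[[paste0("c", li)]], B, sz, sz, mask = masks$B)
      cs[[li]] <- cc
      if (li < cfg$ar_layers) {
        a <- relu(cc$y)
        acts[[li + 1]] <- a
      }
    }
    hout <- h + cs[[cfg$ar_layers]]$y
    block_out[[bi]] <- hout
    if (need_cache) bc[[bi]] <- list(hin = hin, acts = acts, cs = cs)
    h <- hout
  }
  ao <- relu(h)
  o1 <- conv_fwd(ao, d$out1, B, sz, sz, pad = 0L)
  a1 <- relu(o1$y)
  o2 <- conv_fwd(a1, d$out2, B, sz, sz, pad = 0L)
  list(out = o2$y,
       cache = if (need_cache)
         list(cin = cin, bc = bc, block_out = block_out, ao = ao, o1 = o1,
              a1 = a1, h_final = h, rep_idx = rep_idx, z = z))
}

decoder_backward <- function(dout, cache, params, B, cfg, masks) {
  sz <- cfg$image_size
  d <- params$dec
  g <- list()
  bo2 <- conv_bwd(dout, list(P = cache$a1), d$out2, B, sz, sz, pad = 0L)
  g$out2 <- list(W = bo2$dW, b = bo2$db)
  da1 <- relu_bwd(bo2$dx, cache$a1)
  bo1 <- conv_bwd(da1, list(P = cache$ao), d$out1, B, sz, sz, pad = 0L)
  g$out1 <- list(W = bo1$dW, b = bo1$db)
  dh <- relu_bwd(bo1$dx, cache$ao)
  nb <- cfg$ar_blocks
  sp <- skip_pairs(nb)
  skip_from <- integer(0); skip_to <- integer(0)
  for (p in sp) { skip_from <- c(skip_from, p[1]); skip_to <- c(skip_to, p[2]) }
  dskip <- vector("list", nb)  # gradient flowing into block i's *output* via skips
  dz <- matrix(0, nrow(cache$z), ncol(cache$z))
  for (bi in rev(seq_len(nb))) {
    blk <- d[[paste0("b", bi)]]
    bcache <- cache$bc[[bi]]
    if (!is.null(dskip[[bi]])) dh <- dh + dskip[[bi]]
    # dh is gradient at block output hout = h_in_res + c_last
    dclast <- dh
    gb <- list()
    dcur <- dclast
    for (li in rev(seq_len(cfg$ar_layers))) {
      bcl <- conv_bwd(dcur, bcache$cs[[li]], blk[[paste0("c", li)]],
                      B, sz, sz, mask = masks$B)
      gb[[paste0("c", li)]] <- list(W = bcl$dW, b = bcl$db)
      dcur <- relu_bwd(bcl$dx, bcache$acts[[li]])
    }
    dhin <- dcur
    # latent bias
    dzb <- rowsum(dhin, cache$rep_idx)
    gb$zproj <- list(W = crossprod(cache$z, dzb), b = colSums(dzb))
    dz <- dz + dzb %*% t(blk$zproj$W)
    # residual pass-through + the input-path gradient
    dh <- dh + dhin
    if (bi %in% skip_to) {
      src <- skip_from[match(bi, skip_to)]
      dskip[[src]] <- if (is.null(dskip[[src]])) dhin else dskip[[src]] + dhin
    }
    g[[paste0("b", bi)]] <- gb
  }
  bin <- conv_bwd(dh, cache$cin, d$conv_in, B, sz, sz, mask = masks$inA)
  g$conv_in <- list(W = bin$dW, b = bin$db)
  list(grads = g, dz = dz)
}

# ---- Discretized logistic mixture likelihood ----------------------------

#' Probability of an 8-bit value under a discretized logistic mixture
#'
#' Assigns to `value` the probability mass of the bin \[value - 0.5,
#' value + 0.5\] on the 0..255 scale, with the edge bins absorbing the open
#' tails, under a mixture of logistic distributions. Sums to 1 over the 256
#' values.
#'
#' @param weights Mixture weights (simplex).
#' @param locations,scales Component locations and scales on the 0..255 scale.
#' @param value Integer vector of 8-bit values.
#' @return Probability for each entry of `value`.
#' @export
dlogismix_prob <- function(weights, locations, scales, value) {
  stopifnot(abs(sum(weights) - 1) < 1e-6, all(scales > 0),
            all(is.finite(c(weights, locations, scales))))
  sapply(value, function(v) {
    hi <- if (v >= 255) rep(1, length(weights))
          else stats::plogis((v + 0.5 - locations) / scales)
    lo <- if (v <= 0) rep(0, length(weights))
          else stats::plogis((v - 0.5 - locations) / scales)
    sum(weights * (hi - lo))
  })
}

# Mixture loss on network output `out` (N x 10K) against integer images
# x_int (N x 3, 0..255). Values are modelled on the [-1, 1] scale with bin
# half-width 1/255. Returns nll (sum over pixels) and, on request, the
# gradient with respect to `out`. Computed in compiled code; the pure-R
# reference below is kept as the cross-check used by the tests.
mixture_loss <- function(out, x_int, K, want_grad = TRUE) {
  mixture_loss_cpp(out, x_int, as.integer(K), isTRUE(want_grad))
}

mixture_loss_ref <- function(out, x_int, K, want_grad = TRUE) {
  N <- nrow(out)
  xs <- 2 * x_int / 255 - 1
  logits <- out[, 1:K, drop = FALSE]
  means <- out[, K + 1:(3 * K), drop = FALSE]
  logsc <- out[, 4 * K + 1:(3 * K), drop = FALSE]
  coefr <- out[, 7 * K + 1:(3 * K), drop = FALSE]
  logsc_c <- pmax(logsc, -7)
  tanhc <- tanh(coefr)
  ch_cols <- function(m, c) m[, (c - 1) * K + 1:K, drop = FALSE]
  mu <- list(ch_cols(means, 1),
             ch_cols(means, 2) + ch_cols(tanhc, 1) * xs[, 1],
             ch_cols(means, 3) + ch_cols(tanhc, 2) * xs[, 1] +
               ch_cols(tanhc, 3) * xs[, 2])
  invs <- lapply(1:3, function(c) exp(-ch_cols(logsc_c, c)))
  sig_hi <- sig_lo <- P <- logP <- vector("list", 3)
  for (c in 1:3) {
    x <- xs[, c]
    ahi <- (x + 1 / 255 - mu[[c]]) * invs[[c]]
    alo <- (x - 1 / 255 - mu[[c]]) * invs[[c]]
    shi <- stats::plogis(ahi)
    slo <- stats::plogis(alo)
    hi_edge <- x > 0.999
    lo_edge <- x < -0.999
    shi[hi_edge, ] <- 1
    slo[lo_edge, ] <- 0
    Pc <- pmax(shi - slo, 1e-12)
    sig_hi[[c]] <- list(s = shi, a = ahi, edge = hi_edge)
    sig_lo[[c]] <- list(s = slo, a = alo, edge = lo_edge)
    P[[c]] <- Pc
    logP[[c]] <- log(Pc)
  }
  lse <- function(m) {
    mx <- do.call(pmax, as.data.frame(m))
    mx + log(rowSums(exp(m - mx)))
  }
  logpi <- logits - lse(logits)
  comp <- logpi + logP[[1]] + logP[[2]] + logP[[3]]
  ll <- lse(comp)
  nll <- -sum(ll)
  if (!want_grad) return(list(nll = nll))
  r <- exp(comp - ll)             # posterior responsibilities, N x K
  pi_hat <- exp(logpi)
  dlogits <- pi_hat - r
  dmeans <- matrix(0, N, 3 * K)
  dlogsc <- matrix(0, N, 3 * K)
  dcoef <- matrix(0, N, 3 * K)
  dmu <- vector("list", 3)
  for (c in 1:3) {
    shi <- sig_hi[[c]]$s; slo <- sig_lo[[c]]$s
    phi <- shi * (1 - shi); plo <- slo * (1 - slo)
    phi[sig_hi[[c]]$edge, ] <- 0
    plo[sig_lo[[c]]$edge, ] <- 0
    dP <- -r / P[[c]]
    dmu_c <- dP * (plo - phi) * invs[[c]]
    ahi <- sig_hi[[c]]$a; alo <- sig_lo[[c]]$a
    ahi[sig_hi[[c]]$edge, ] <- 0
    alo[sig_lo[[c]]$edge, ] <- 0
    dls <- dP * (alo * plo - ahi * phi)
    dls[ch_cols(logsc, c) < -7] <- 0
    dmu[[c]] <- dmu_c
    dmeans[, (c - 1) * K + 1:K] <- dmu_c
    dlogsc[, (c - 1) * K + 1:K] <- dls
  }
  sech2 <- 1 - tanhc^2
  dcoef[, 1:K] <- dmu[[2]] * xs[, 1] * ch_cols(sech2, 1)
  dcoef[, K + 1:K] <- dmu[[3]] * xs[, 1] * ch_cols(sech2, 2)
  dcoef[, 2 * K + 1:K] <- dmu[[3]] * xs[, 2] * ch_cols(sech2, 3)
  dout <- cbind(dlogits, dmeans, dlogsc, dcoef)
  list(nll = nll, dout = dout)
}

kl_gaussian <- function(mu, lv) {
  0.5 * sum(mu^2 + exp(lv) - 1 - lv)
}

# ---- Training -----------------------------------------------------------

#' Train the unsupervised generative model
#'
#' Gradient training of the two-term variational objective (teacher-forced
#' reconstruction negative log-likelihood under the discretized logistic
#' mixture, plus the closed-form divergence of the diagonal-Gaussian
#' posterior from the standard-normal prior) with Adam, per-epoch learning
#' rate decay, gradient clipping at norm 5, and no other regularization.
#'
#' @param dataset A [generate_dataset()] result whose image size matches the
#'   model configuration.
#' @param config A [pixelvae_config()].
#' @param seed Integer seed for weight init, batching and reparameterization
#'   noise.
#' @param max_val Validation images used for the per-epoch validation score.
#' @param verbose Print per-epoch progress.
#' @return A `pixelvae` model: parameters, config, masks, and a `log` tibble
#'   (per-epoch reconstruction NLL in nats/pixel, divergence term, validation
#'   NLL, learning rate, seconds).
#' @export
train_pixelvae <- function(dataset, config = pixelvae_config(), seed = 1L,
                           max_val = 64L, verbose = FALSE) {
  stopifnot(inherits(config, "pixelvae_config"),
            dim(dataset$images)[2] == config$image_size)
  manifest <- dataset$manifest
  tr_idx <- which(manifest$split == "train")
  va_idx <- utils::head(which(manifest$split == "validation"), max_val)
  if (length(tr_idx) == 0) stop("dataset has no training split")
  params <- init_pixelvae_params(config, derive_seed(seed, 1))
  masks <- decoder_masks(config)
  opt <- adam_init(params)
  lr <- config$learning_rate
  K <- config$mixture_components
  sz <- config$image_size
  hw <- sz * sz
  xmat <- function(idx) {
    do.call(rbind, lapply(idx, function(i) image_to_mat(dataset$images[i, , , ])))
  }
  eval_nll <- function(idx) {
    if (length(idx) == 0) return(NA_real_)
    tot <- 0
    for (start in seq(1, length(idx), by = 8)) {
      ii <- idx[start:min(start + 7, length(idx))]
      B <- length(ii)
      xi <- xmat(ii)
      xs <- 2 * xi / 255 - 1
      enc <- encoder_forward(params, xs, B, config)
      dec <- decoder_forward(params, xs, enc$mu, B, config, masks,
                             need_cache = FALSE)
      ml <- mixture_loss(dec$out, xi, K, want_grad = FALSE)
      tot <- tot + ml$nll + kl_gaussian(enc$mu, enc$lv)
    }
    tot / (length(idx) * hw)
  }
  log_rows <- vector("list", config$epochs)
  set.seed(derive_seed(seed, 2))
  for (ep in seq_len(config$epochs)) {
    t0 <- Sys.time()
    ord <- sample(tr_idx)
    ep_nll <- 0; ep_kl <- 0
    for (start in seq(1, length(ord), by = config$batch_size)) {
      ii <- ord[start:min(start + config$batch_size - 1, length(ord))]
      B <- length(ii)
      xi <- xmat(ii)
      xs <- 2 * xi / 255 - 1
      enc <- encoder_forward(params, xs, B, config)
      eps <- matrix(stats::rnorm(B * config$latent_dim), B)
      z <- enc$mu + exp(0.5 * enc$lv) * eps
      dec <- decoder_forward(params, xs, z, B, config, masks)
      ml <- mixture_loss(dec$out, xi, K)
      klv <- kl_gaussian(enc$mu, enc$lv)
      if (!is.finite(ml$nll) || !is.finite(klv))
        stop("non-finite loss at epoch ", ep, " (nll=", ml$nll,
             ", kl=", klv, ")")
      ep_nll <- ep_nll + ml$nll; ep_kl <- ep_kl + klv
      db <- decoder_backward(ml$dout / B, dec$cache, params, B, config, masks)
      dz <- db$dz
      dmu <- dz + enc$mu / B
      dlv <- dz * eps * 0.5 * exp(0.5 * enc$lv) + 0.5 * (exp(enc$lv) - 1) / B
      ge <- encoder_backward(dmu, dlv, enc$cache, params, B, config)
      grads <- list(enc = ge, dec = db$grads)
      stepped <- adam_step(params, grads, opt, lr)
      params <- stepped$params
      opt <- stepped$state
    }
    val <- eval_nll(va_idx)
    lr <- lr * config$lr_decay
    secs <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    log_rows[[ep]] <- tibble::tibble(
      epoch = ep,
      recon_nll = ep_nll / (length(ord) * hw),
      divergence = ep_kl / length(ord),
      val_nll = val,
      lr = lr,
      seconds = secs,
      seed = seed)
    if (verbose)
      message(sprintf("epoch %d: recon %.4f nats/px, KL %.2f, val %.4f (%.1fs)",
                      ep, ep_nll / (length(ord) * hw), ep_kl / length(ord),
                      val, secs))
  }
  structure(list(params = params, config = config, masks = masks,
                 log = dplyr::bind_rows(log_rows), seed = seed,
                 trained = TRUE),
            class = "pixelvae")
}

#' @export
print.pixelvae <- function(x, ...) {
  cat("<pixelvae> ", x$config$scale_preset, " preset, latent ",
      x$config$latent_dim, "D, ", nrow(x$log), " epochs trained\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.pixelvae <- function(x, ...) x$log

#' @importFrom generics glance
#' @export
glance.pixelvae <- function(x, ...) {
  tibble::tibble(epochs = nrow(x$log),
                 final_val_nll = utils::tail(x$log$val_nll, 1),
                 final_recon_nll = utils::tail(x$log$recon_nll, 1),
                 latent_dim = x$config$latent_dim,
                 seed = x$seed)
}

#' Encode images into the latent code
#'
#' Returns the posterior parameters of each image. Downstream decoding uses
#' the posterior mean, giving deterministic features.
#'
#' @param model A trained [train_pixelvae()] model.
#' @param images Either a single H x W x 3 image (0..255 integers or \[0,1\]
#'   reals) or an n x H x W x 3 array.
#' @return Matrix of posterior means (n x latent_dim) with the posterior
#'   `log_variance` matrix attached as an attribute.
#' @export
encode_latents <- function(model, images) {
  stopifnot(inherits(model, "pixelvae"))
  if (is.null(model$trained) || !model$trained) stop("model is not trained")
  if (length(dim(images)) == 3) images <- array(images, c(1, dim(images)))
  n <- dim(images)[1]
  if (max(images) <= 1 && is.double(images)) images <- images * 255
  mu_all <- matrix(0, n, model$config$latent_dim)
  lv_all <- matrix(0, n, model$config$latent_dim)
  for (start in seq(1, n, by = 16)) {
    ii <- start:min(start + 15, n)
    xs <- do.call(rbind, lapply(ii, function(i)
      2 * image_to_mat(images[i, , , ]) / 255 - 1))
    enc <- encoder_forward(model$params, xs, length(ii), model$config)
    mu_all[ii, ] <- enc$mu
    lv_all[ii, ] <- enc$lv
  }
  attr(mu_all, "log_variance") <- lv_all
  mu_all
}

#' Evaluate the two-term variational objective on one image
#'
#' @param model A trained model.
#' @param image H x W x 3 image (0..255).
#' @param eps Optional reparameterization noise (vector of latent_dim);
#'   default 0 (the latent is the posterior mean), making the value
#'   deterministic.
#' @return Named numeric: `recon_nll` (nats, summed over pixels) and
#'   `divergence`.
#' @export
elbo_loss <- function(model, image, eps = NULL) {
  cfg <- model$config
  stopifnot(dim(image)[1] == cfg$image_size)
  xi <- image_to_mat(image)
  if (max(xi) <= 1) xi <- xi * 255
  xs <- 2 * xi / 255 - 1
  enc <- encoder_forward(model$params, xs, 1L, cfg)
  z <- if (is.null(eps)) enc$mu else enc$mu + exp(0.5 * enc$lv) * matrix(eps, 1)
  dec <- decoder_forward(model$params, xs, z, 1L, cfg, model$masks,
                         need_cache = FALSE)
  ml <- mixture_loss(dec$out, xi, cfg$mixture_components, want_grad = FALSE)
  c(recon_nll = ml$nll, divergence = kl_gaussian(enc$mu, enc$lv))
}

# Raw mixture parameters of the autoregressive head for an image/latent pair
# (used by tests of the causal masking property).
pixelvae_pixel_params <- function(model, image, z = NULL) {
  cfg <- model$config
  xi <- image_to_mat(image)
  if (max(xi) <= 1) xi <- xi * 255
  xs <- 2 * xi / 255 - 1
  if (is.null(z)) z <- matrix(0, 1, cfg$latent_dim)
  dec <- decoder_forward(model$params, xs, z, 1L, cfg, model$masks,
                         need_cache = FALSE)
  dec$out
}

#' Generate an image from the model
#'
#' Samples pixels in raster order (top-left to bottom-right); each pixel's
#' RGB value is drawn from the discretized logistic mixture conditioned on
#' previously sampled pixels and on the supplied latent values, with the
#' green/blue channels linearly coupled to the sampled values of preceding
#' channels.
#'
#' @param model A trained model.
#' @param latent Numeric vector of latent_dim latent values.
#' @param seed Integer seed for the sampling stream.
#' @param temperature Softens (`> 1`) or sharpens (`< 1`) sampling; `0` gives
#'   the deterministic argmax-component, location-valued image.
#' @return H x W x 3 integer array (0..255).
#' @export
generate_image <- function(model, latent, seed = 1L, temperature = 1) {
  cfg <- model$config
  sz <- cfg$image_size
  K <- cfg$mixture_components
  z <- matrix(latent, 1)
  x <- matrix(0, sz * sz, 3)         # on [-1, 1]
  with_seed(seed, {
    for (p in seq_len(sz * sz)) {
      dec <- decoder_forward(model$params, x, z, 1L, cfg, model$masks,
                             need_cache = FALSE)
      o <- dec$out[p, ]
      logits <- o[1:K]
      means <- o[K + 1:(3 * K)]
      logsc <- pmax(o[4 * K + 1:(3 * K)], -7)
      coef <- tanh(o[7 * K + 1:(3 * K)])
      if (temperature <= 0) {
        k <- which.max(logits)
      } else {
        pr <- exp((logits - max(logits)) / temperature)
        k <- sample.int(K, 1, prob = pr / sum(pr))
      }
      val <- numeric(3)
      for (c in 1:3) {
        mu <- means[(c - 1) * K + k]
        if (c == 2) mu <- mu + coef[k] * val[1]
        if (c == 3) mu <- mu + coef[K + k] * val[1] + coef[2 * K + k] * val[2]
        if (temperature <= 0) {
          v <- mu
        } else {
          u <- stats::runif(1, 1e-5, 1 - 1e-5)
          v <- mu + exp(logsc[(c - 1) * K + k]) * temperature *
            (log(u) - log1p(-u))
        }
        val[c] <- min(1, max(-1, v))
      }
      # snap to the 8-bit lattice the likelihood is defined on
      val <- round((val + 1) / 2 * 255) / 255 * 2 - 1
      x[p, ] <- val
    }
  })
  img <- array(0L, c(sz, sz, 3))
  for (ch in 1:3)
    img[, , ch] <- matrix(as.integer(round((x[, ch] + 1) / 2 * 255)),
                          sz, sz, byrow = TRUE)
  img
}
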