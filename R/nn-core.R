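# Minimal convolutional-network core used by all trained models in the package.
# Feature maps live in (B*H*W) x C matrices (raster order within each image);
# convolution is im2col + GEMM in compiled code, autodiff is hand-written
# layer adjoints. This keeps every model (variational autoregressive model,
# supervised residual network, plain autoencoder) on one small, testable core.

relu <- function(x) relu_cpp(x)

relu_bwd <- function(dy, y) relu_bwd_cpp(dy, y)

#' @keywords internal
fan_in_init <- function(nin, nout, rng) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}

new_conv <- function(cin, cout, k = 3L) {
  list(W = fan_in_init(k * k * cin, cout), b = numeric(cout),
       k = k, cin = cin, cout = cout)
}

new_fc <- function(nin, nout) {
  list(W = fan_in_init(nin, nout), b = numeric(nout))
}

conv_fwd <- function(x, layer, B, H, W, stride = 1L, pad = 1L, mask = NULL) {
  Wm <- if (is.null(mask)) layer$W else layer$W * mask
  conv_fwd_full_cpp(x, Wm, layer$b, B, H, W, layer$k, layer$k, stride, pad)
}

conv_bwd <- function(dy, cache, layer, B, H, W, stride = 1L, pad = 1L, mask = NULL) {
  Wm <- if (is.null(mask)) layer$W else layer$W * mask
  res <- conv_bwd_cpp(dy, cache$P, Wm, B, H, W, layer$cin, layer$k, layer$k,
                      stride, pad)
  dW <- res$dW
  if (!is.null(mask)) dW <- dW * mask
  list(dW = dW, db = as.numeric(res$db), dx = res$dx)
}

fc_fwd <- function(x, layer) sweep(x %*% layer$W, 2L, layer$b, "+")

fc_bwd <- function(dy, x, layer) {
  list(dW = crossprod(x, dy), db = colSums(dy), dx = dy %*% t(layer$W))
}

# Autoregressive causal mask for a k x k convolution over C_in -> C_out maps.
# type "A" excludes the centre pixel entirely (first layer: the distribution at
# a pixel may not see any channel of that pixel); type "B" includes the centre
# (later layers: centre features already depend only on strictly-previous pixels).
causal_mask <- function(k, cin, cout, type = c("A", "B")) {
  type <- match.arg(type)
  centre <- (k * k - 1L) %/% 2L  # 0-based spatial index of the centre tap
  keep_centre <- type == "B"
  m <- matrix(0, k * k * cin, cout)
  for (pos in 0:(k * k - 1L)) {
    keep <- pos < centre || (pos == centre && keep_centre)
    if (keep) m[pos * cin + seq_len(cin), ] <- 1
  }
  m
}

# Image b, pixel-raster rows -> one flat row per image (channel fastest).
flatten_maps <- function(x, B) flatten_maps_cpp(x, B)

unflatten_maps <- function(f, B, ch) unflatten_maps_cpp(f, B, ch)

# Adam optimizer over an arbitrary nested list of parameter matrices.
adam_init <- function(params) {
  zeros <- rapply(params, function(p) p * 0, classes = c("matrix", "numeric"),
                  how = "replace")
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, clip = 5) {
  gvec <- unlist(grads, use.names = FALSE)
  gnorm <- sqrt(sum(gvec^2))
  scale <- if (is.finite(gnorm) && gnorm > clip) clip / gnorm else 1
  state$t <- state$t + 1L
  tt <- state$t
  walk_names <- function(p, g, m, v) {
    if (is.null(g)) return(list(p = p, m = m, v = v))
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (nm in names(p)) {
        res <- walk_names(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out_p[[nm]] <- res$p; out_m[[nm]] <- res$m; out_v[[nm]] <- res$v
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    if (!is.numeric(p)) return(list(p = p, m = m, v = v))
    g <- g * scale
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^tt)
    vhat <- v / (1 - beta2^tt)
    p <- p - lr * mhat / (sqrt(vhat) + eps)
    list(p = p, m = m, v = v)
  }
  res <- walk_names(params, grads, state$m, state$v)
  list(params = res$p, state = list(m = res$m, v = res$v, t = tt))
}

# Sum two grad trees with identical shape.
grad_add <- function(a, b) {
  if (is.list(a)) {
    for (nm in names(a)) a[[nm]] <- grad_add(a[[nm]], b[[nm]])
    return(a)
  }
  a + b
}

global_grad_zero <- function(params) {
  rapply(params, function(p) p * 0, classes = c("matrix", "numeric"), how = "replace")
}
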