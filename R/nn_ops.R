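# Small numerical building blocks shared by the encoder and the two decode
# heads.  Everything here is deliberately dependency-free, vectorized base R;
# forward functions return whatever the matching backward needs as a cache.

rnorm_mat <- function(nr, nc, sd = 0.02) {
  matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
}

# numerically stable row-wise softmax
softmax_rows <- function(x) {
  m <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x - m)
  e / rowSums(e)
}

# backward of y = softmax_rows(x): dx = y * (dy - rowSums(dy * y))
softmax_rows_bwd <- function(y, dy) {
  y * (dy - rowSums(dy * y))
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

gelu <- function(x) x * stats::pnorm(x)

gelu_bwd <- function(x, dy) dy * (stats::pnorm(x) + x * stats::dnorm(x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

## ---- layer normalization ---------------------------------------------------

LN_EPS <- 1e-5

# per-row layer norm; returns list(y, cache)
layernorm_fwd <- function(x, gain, bias) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  istd <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * istd
  y <- sweep(xhat, 2, gain, `*`)
  y <- sweep(y, 2, bias, `+`)
  list(y = y, xhat = xhat, istd = istd)
}

layernorm_bwd <- function(cache, gain, dy) {
  xhat <- cache$xhat; istd <- cache$istd
  H <- ncol(xhat)
  dgain <- colSums(dy * xhat)
  dbias <- colSums(dy)
  dxhat <- sweep(dy, 2, gain, `*`)
  # dx = istd * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat)) per row
  dx <- istd * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dgain = dgain, dbias = dbias)
}

## ---- parameter tree utilities ---------------------------------------------

# parameters live in nested lists of numeric arrays; these helpers walk the
# tree pairwise, preserving structure

param_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- Map(function(x, y) param_map2(x, y, f), a, b)
    return(out)
  }
  f(a, b)
}

param_zeros_like <- function(p) {
  if (is.list(p)) return(lapply(p, param_zeros_like))
  p * 0   # preserves vector/matrix structure exactly
}

param_global_norm <- function(g) {
  if (is.list(g)) return(sqrt(sum(vapply(g, function(x)
    param_global_norm(x)^2, numeric(1)))))
  sqrt(sum(g * g))
}

param_scale <- function(g, s) {
  if (is.list(g)) return(lapply(g, param_scale, s = s))
  g * s
}

## ---- Adam(W) ---------------------------------------------------------------

adam_init <- function(params) {
  list(m = param_zeros_like(params), v = param_zeros_like(params), t = 0L)
}

# one AdamW step over the full tree; lr_of(name_path) gives the per-tensor
# learning rate, decay_of(name_path) the weight-decay coefficient
adam_step <- function(params, grads, state, lr_of, decay_of,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  walk <- function(p, g, m, v, path) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (nm in names(p)) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]], c(path, nm))
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    m2 <- beta1 * m + (1 - beta1) * g
    v2 <- beta2 * v + (1 - beta2) * g * g
    lr <- lr_of(path)
    upd <- lr * (m2 / bc1) / (sqrt(v2 / bc2) + eps)
    wd <- decay_of(path)
    p2 <- p - upd - lr * wd * p
    list(p = p2, m = m2, v = v2)
  }
  r <- walk(params, grads, state$m, state$v, character())
  state$m <- r$m; state$v <- r$v
  list(params = r$p, state = state)
}
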