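# Entity type recognition head: two parallel convolutional banks — one over
# the entity-enhanced encoder outputs, one over radical embeddings — with
# kernel widths {2, 3, 4}, concatenated per token and passed through a fully
# connected layer; classification by angular-margin (A-) softmax.
#
# Type supervision is per token (the no-entity case is its own class); span
# types are resolved afterwards by majority vote (resolve_span_type).

typehead_init <- function(cfg, n_radicals, n_types) {
  H <- cfg$H_c
  FF <- cfg$filters
  bank <- function() lapply(cfg$kernel_widths, function(w)
    list(K = rnorm_mat(w * H, FF), b = rep(0, FF)))
  n_feat <- 2L * length(cfg$kernel_widths) * FF
  W_cls <- rnorm_mat(n_types + 1L, cfg$feature_dim)
  W_cls <- W_cls / sqrt(rowSums(W_cls^2))
  list(E_r = rnorm_mat(n_radicals, H),
       conv_enc = bank(), conv_rad = bank(),
       W_fc = rnorm_mat(n_feat, cfg$feature_dim),
       b_fc = rep(0, cfg$feature_dim),
       W_cls = W_cls)
}

# zero-pad to 'same' length and unfold into T x (w*H) sliding windows
conv_unfold <- function(X, w) {
  T_ <- nrow(X); H <- ncol(X)
  pl <- (w - 1L) %/% 2L
  Xp <- rbind(matrix(0, pl, H), X, matrix(0, w - 1L - pl, H))
  U <- matrix(0, T_, w * H)
  for (i in seq_len(w))
    U[, (i - 1L) * H + seq_len(H)] <- Xp[i:(i + T_ - 1L), , drop = FALSE]
  U
}

conv_bank_fwd <- function(X, bank, widths) {
  Us <- vector("list", length(widths))
  As <- vector("list", length(widths))
  for (i in seq_along(widths)) {
    U <- conv_unfold(X, widths[i])
    A <- sweep(U %*% bank[[i]]$K, 2, bank[[i]]$b, `+`)
    Us[[i]] <- U
    As[[i]] <- relu(A)
  }
  list(act = do.call(cbind, As), Us = Us, As = As)
}

# dAct: T x (n_width*F); returns grads for the bank and dX
conv_bank_bwd <- function(X, bank, widths, cache, dAct) {
  T_ <- nrow(X); H <- ncol(X)
  FF <- ncol(cache$As[[1]])
  dX <- matrix(0, T_, H)
  gbank <- vector("list", length(widths))
  for (i in seq_along(widths)) {
    w <- widths[i]
    dA <- dAct[, (i - 1L) * FF + seq_len(FF), drop = FALSE]
    dA <- dA * (cache$As[[i]] > 0)
    U <- cache$Us[[i]]
    gbank[[i]] <- list(K = crossprod(U, dA), b = colSums(dA))
    dU <- tcrossprod(dA, bank[[i]]$K)
    pl <- (w - 1L) %/% 2L
    dXp <- matrix(0, T_ + w - 1L, H)
    for (k in seq_len(w))
      dXp[k:(k + T_ - 1L), ] <- dXp[k:(k + T_ - 1L), , drop = FALSE] +
        dU[, (k - 1L) * H + seq_len(H), drop = FALSE]
    dX <- dX + dXp[pl + seq_len(T_), , drop = FALSE]
  }
  list(bank = gbank, dX = dX)
}

#' Per-token fused character/radical convolutional features
#'
#' Branch A convolves the encoder outputs, branch B the radical embeddings;
#' each uses kernel widths 2/3/4 with same-padding, so every token keeps a
#' feature vector.  The two branches' activations are concatenated and passed
#' through a fully connected layer.
#'
#' @param enc_states `T x H_c` encoder outputs.
#' @param rad_ids integer radical ids (rows of the radical embedding table).
#' @param tp type-head parameter list (see [typehead_init()] fields).
#' @param cfg model configuration (uses `kernel_widths`, `use_radical_branch`).
#' @return list with `features` (`T x feature_dim`) and the forward cache.
#' @export
radical_features <- function(enc_states, rad_ids, tp, cfg) {
  T_ <- nrow(enc_states)
  if (T_ < 1L) stop("empty sentence")
  widths <- cfg$kernel_widths
  Xr <- if (isTRUE(cfg$use_radical_branch))
    tp$E_r[rad_ids, , drop = FALSE]
  else matrix(0, T_, ncol(tp$E_r))
  ca <- conv_bank_fwd(enc_states, tp$conv_enc, widths)
  cb <- conv_bank_fwd(Xr, tp$conv_rad, widths)
  C <- cbind(ca$act, cb$act)
  feats <- sweep(C %*% tp$W_fc, 2, tp$b_fc, `+`)
  list(features = feats,
       cache = list(ca = ca, cb = cb, C = C, Xr = Xr))
}

radical_features_bwd <- function(enc_states, rad_ids, tp, cfg, cache, dfeats) {
  widths <- cfg$kernel_widths
  g <- list()
  g$W_fc <- crossprod(cache$C, dfeats)
  g$b_fc <- colSums(dfeats)
  dC <- tcrossprod(dfeats, tp$W_fc)
  na <- ncol(cache$ca$act)
  ba <- conv_bank_bwd(enc_states, tp$conv_enc, widths, cache$ca,
                      dC[, seq_len(na), drop = FALSE])
  bb <- conv_bank_bwd(cache$Xr, tp$conv_rad, widths, cache$cb,
                      dC[, na + seq_len(ncol(cache$cb$act)), drop = FALSE])
  g$conv_enc <- ba$bank
  g$conv_rad <- bb$bank
  g$E_r <- array(0, dim = dim(tp$E_r))
  if (isTRUE(cfg$use_radical_branch)) {
    acc <- rowsum(bb$dX, group = rad_ids)
    rows <- as.integer(rownames(acc))
    g$E_r[rows, ] <- g$E_r[rows, , drop = FALSE] + acc
  }
  list(grads = g, d_enc = ba$dX)
}

## ---- angular-margin softmax ------------------------------------------------

# SphereFace margin function: phi(theta) = (-1)^k cos(m theta) - 2k on
# theta in [k pi/m, (k+1) pi/m]; monotone decreasing on [0, pi]
asoftmax_phi <- function(cos_theta, m) {
  c <- pmin(pmax(cos_theta, -1), 1)
  theta <- acos(c)
  k <- pmin(floor(m * theta / pi), m - 1)
  (-1)^k * cos(m * theta) - 2 * k
}

asoftmax_phi_grad <- function(cos_theta, m) {
  c <- pmin(pmax(cos_theta, -1), 1)
  theta <- acos(c)
  k <- pmin(floor(m * theta / pi), m - 1)
  s <- pmax(sqrt(1 - c * c), 1e-6)
  (-1)^k * m * sin(m * theta) / s
}

#' Angular-margin softmax classification loss
#'
#' Mean over samples of
#' `-log( exp(||x|| phi(theta_y)) / (exp(||x|| phi(theta_y)) +
#'  sum_{j != y} exp(||x|| cos theta_j)) )`
#' where `theta_j` is the angle between feature `x` and the unit-norm class
#' direction `w_j`, and `phi` is the margin-sharpened SphereFace function for
#' integer margin `m >= 1` (for `m = 1`, `phi = cos` and the loss reduces to
#' cosine-softmax cross-entropy).  During training an annealing blend
#' `(lambda cos + phi) / (1 + lambda)` replaces `phi`; `lambda = 0` gives the
#' pure margin loss.
#'
#' @param features `N x D` feature matrix (rows may not all be zero).
#' @param labels integer class labels in `1..nrow(weights)`.
#' @param weights `C x D` class-direction matrix with unit-norm rows.
#' @param m integer margin `>= 1`.
#' @param lambda annealing weight on the plain cosine logit (default 0).
#' @return scalar loss.
#' @export
asoftmax_loss <- function(features, labels, weights, m = 1, lambda = 0) {
  asoftmax_loss_grad(features, labels, weights, m, lambda)$loss
}

asoftmax_loss_grad <- function(features, labels, weights, m = 1, lambda = 0) {
  if (m < 1 || m != round(m)) stop("margin m must be a positive integer")
  N <- nrow(features)
  norms <- sqrt(rowSums(features^2))
  safe <- pmax(norms, 1e-12)
  cosall <- (features %*% t(weights)) / safe
  cosall[norms == 0, ] <- 0                  # zero-norm guard: cos treated as 0
  gold <- cbind(seq_len(N), labels)
  cy <- cosall[gold]
  phi <- asoftmax_phi(cy, m)
  fy <- (lambda * cy + phi) / (1 + lambda)
  Z <- norms * cosall
  Z[gold] <- norms * fy
  mx <- Z[cbind(seq_len(N), max.col(Z, ties.method = "first"))]
  lse <- mx + log(rowSums(exp(Z - mx)))
  loss <- mean(lse - Z[gold])
  # gradients
  P <- exp(Z - lse)
  dZ <- P
  dZ[gold] <- dZ[gold] - 1
  dZ <- dZ / N
  dZ_gold <- dZ[gold]
  dZ[gold] <- 0                              # non-gold part handled as x.w_j
  dX <- dZ %*% weights
  dW <- crossprod(dZ, features)
  fpy <- (lambda + asoftmax_phi_grad(cy, m)) / (1 + lambda)
  xhat <- features / safe
  # d(||x|| f(c))/dx = f(c) xhat + f'(c) (w_y - c xhat)
  dX <- dX + dZ_gold * (fy * xhat +
                          fpy * (weights[labels, , drop = FALSE] - cy * xhat))
  dWy <- (dZ_gold * fpy) * features
  acc <- rowsum(dWy, group = labels)
  rows <- as.integer(rownames(acc))
  dW[rows, ] <- dW[rows, , drop = FALSE] + acc
  list(loss = loss, dX = dX, dW = dW, prob = P)
}

# inference-time type probabilities: plain cosine logits, no margin
type_probs <- function(features, weights) {
  norms <- sqrt(rowSums(features^2))
  safe <- pmax(norms, 1e-12)
  Z <- (features %*% t(weights))
  Z[norms == 0, ] <- 0
  softmax_rows(Z)
}
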