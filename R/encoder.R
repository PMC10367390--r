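# Character transformer encoder with directional relative position encoding
# and entity-dictionary key/value fusion.
#
# Layer l receives hidden states h^{l-1} (T x H_c) and the sentence's entity
# tag sequence e (0 = no dictionary match).  Queries are plain projections;
# keys and values of characters covered by a dictionary match are averaged
# with the matched entity's embedding projection:
#     k_t = h_t W_hk                         if e_t = 0
#     k_t = (h_t W_hk + E_ent[e_t] W_ek)/2   otherwise      (same for v_t)
# Attention logits add directional relative-position terms
#     (q_t k_j' + q_t R_{t-j}' + u k_j' + v R_{t-j}') / sqrt(d_k)
# where R_t interleaves sin(c_i t), cos(c_i t) with the standard sinusoidal
# frequency schedule, so R_{-t} negates the sin slots only.
# Sublayers: fused multi-head attention -> residual + layer norm ->
# position-wise GELU feed-forward -> residual + layer norm.  There is no
# output projection after head concatenation (the parameter set is exactly
# W_q, W_k, W_v, W_ek, W_ev plus the biases u, v per layer).

#' Directional relative position encoding
#'
#' Returns the d-dimensional encoding of a signed token offset: slots
#' alternate `sin(c_i t)` and `cos(c_i t)` with `c_i = 10000^(-2i/d)`, so the
#' encoding of `-t` equals that of `t` with every sin slot negated and every
#' cos slot preserved — attention can tell left context from right context.
#'
#' @param offset signed integer offset (or vector of offsets).
#' @param d embedding dimension (even).
#' @return a length-`d` vector, or a `length(offset) x d` matrix.
#' @export
relative_position <- function(offset, d) {
  if (d %% 2 != 0) stop("relative position dimension must be even")
  i <- seq_len(d / 2) - 1
  freq <- 10000^(-2 * i / d)
  ang <- outer(offset, freq)              # n x d/2, signed offsets
  out <- matrix(0, length(offset), d)
  out[, 2 * i + 1] <- sin(ang)
  out[, 2 * i + 2] <- cos(ang)
  if (length(offset) == 1L) out[1, ] else out
}

# table of R_o for o in -(T-1)..(T-1); row index o + T
rel_pos_block <- function(T_, d) {
  relative_position(seq.int(-(T_ - 1L), T_ - 1L), d)
}

#' Character embedding layer
#'
#' The first-layer hidden state is the sum of the character embedding and
#' (optionally) the absolute position embedding: `h_t = E_c[c_t] + E_p[t]`.
#'
#' @param E_c character embedding table (vocab x H_c).
#' @param E_p absolute position table (max_len x H_c).
#' @param char_ids integer ids into `E_c`.
#' @param use_absolute_position if `FALSE`, `E_p` is not added.
#' @return `T x H_c` matrix.
#' @export
embed_chars <- function(E_c, E_p, char_ids, use_absolute_position = TRUE) {
  T_ <- length(char_ids)
  if (T_ > nrow(E_p)) stop("sentence length ", T_, " exceeds max_len ", nrow(E_p))
  X <- E_c[char_ids, , drop = FALSE]
  if (use_absolute_position) X <- X + E_p[seq_len(T_), , drop = FALSE]
  X
}

#' Fuse hidden-state and entity-embedding projections into keys and values
#'
#' @param hidden `T x H_c` hidden states from the previous layer.
#' @param ent_ids integer entity tag sequence (0 = no match).
#' @param Wk,Wv `H_c x H_c` key/value projections.
#' @param Wek,Wev `H_e x H_c` entity key/value projections.
#' @param E_ent entity embedding table (`(N+1) x H_e`; row 1 is id 0, unused).
#' @param use_entity_fusion disable to get plain self-attention projections.
#' @return list with `K` and `V` (`T x H_c`).
#' @export
fuse_key_value <- function(hidden, ent_ids, Wk, Wv, Wek, Wev, E_ent,
                           use_entity_fusion = TRUE) {
  K <- hidden %*% Wk
  V <- hidden %*% Wv
  idx <- which(ent_ids > 0L)
  if (use_entity_fusion && length(idx) > 0L) {
    if (any(ent_ids[idx] + 1L > nrow(E_ent)))
      stop("entity id out of embedding table range")
    E <- E_ent[ent_ids[idx] + 1L, , drop = FALSE]
    K[idx, ] <- 0.5 * K[idx, , drop = FALSE] + 0.5 * (E %*% Wek)
    V[idx, ] <- 0.5 * V[idx, , drop = FALSE] + 0.5 * (E %*% Wev)
  }
  list(K = K, V = V)
}

# offset index matrix IDX[t, j] = t - j + T (row of R holding R_{t-j}) and
# the linear gather indices for A[t, j] = P[t, IDX[t, j]]
rel_gather_idx <- function(T_) {
  IDX <- outer(seq_len(T_), seq_len(T_), `-`) + T_
  list(IDX = IDX,
       li = rep(seq_len(T_), times = T_) + (as.vector(IDX) - 1L) * T_)
}

#' Fused multi-head attention weights
#'
#' Computes the per-head row-stochastic attention weight matrices from
#' queries and fused keys, including the directional relative-position terms
#' (which can be disabled).
#'
#' @param Q,K `T x H_c` query and (fused) key matrices.
#' @param u,v `heads x d_k` relative-attention bias matrices.
#' @param heads number of attention heads.
#' @param use_relative_position include the `R_{t-j}` terms?
#' @return `T x T x heads` array; each `[, , h]` has rows summing to 1.
#' @export
attention_scores <- function(Q, K, u, v, heads, use_relative_position = TRUE) {
  T_ <- nrow(Q)
  dh <- ncol(Q) / heads
  R <- if (use_relative_position) rel_pos_block(T_, dh) else NULL
  gi <- if (use_relative_position) rel_gather_idx(T_) else NULL
  W <- array(0, dim = c(T_, T_, heads))
  for (h in seq_len(heads)) {
    cols <- (h - 1L) * dh + seq_len(dh)
    Qh <- Q[, cols, drop = FALSE]
    Kh <- K[, cols, drop = FALSE]
    L <- tcrossprod(Qh, Kh)
    if (use_relative_position) {
      P <- tcrossprod(Qh, R)
      L <- L + matrix(P[gi$li], T_, T_)
      vR <- as.vector(R %*% v[h, ])
      L <- L + matrix(vR[gi$IDX], T_, T_)
    }
    uk <- as.vector(Kh %*% u[h, ])
    L <- L + matrix(rep(uk, each = T_), T_, T_)
    L <- L / sqrt(dh)
    if (any(!is.finite(L))) stop("non-finite attention logits")
    W[, , h] <- softmax_rows(matrix(L, T_, T_))
  }
  W
}

## ---- full encoder forward / backward --------------------------------------

encoder_init <- function(cfg, vocab_size, n_entities) {
  H <- cfg$H_c; He <- cfg$H_e
  layers <- lapply(seq_len(cfg$layers), function(l) {
    list(
      Wq = rnorm_mat(H, H), Wk = rnorm_mat(H, H), Wv = rnorm_mat(H, H),
      Wek = rnorm_mat(He, H), Wev = rnorm_mat(He, H),
      u = matrix(0, cfg$heads, H / cfg$heads),  # zero: first pass is content-only
      v = matrix(0, cfg$heads, H / cfg$heads),
      g1 = rep(1, H), b1 = rep(0, H),
      W1 = rnorm_mat(H, cfg$ffn_mult * H), bf1 = rep(0, cfg$ffn_mult * H),
      W2 = rnorm_mat(cfg$ffn_mult * H, H), bf2 = rep(0, H),
      g2 = rep(1, H), b2 = rep(0, H)
    )
  })
  list(
    E_c = rnorm_mat(vocab_size, H),
    E_p = rnorm_mat(cfg$max_len, H),
    E_ent = rnorm_mat(n_entities + 1L, He),
    layers = layers
  )
}

# forward pass for one sentence; returns final states + caches for backward
encoder_fwd <- function(enc, cfg, char_ids, ent_ids, train = FALSE) {
  T_ <- length(char_ids)
  X <- embed_chars(enc$E_c, enc$E_p, char_ids, cfg$use_absolute_position)
  dh <- cfg$H_c / cfg$heads
  sc <- sqrt(dh)
  userel <- isTRUE(cfg$use_relative_position)
  R <- if (userel) rel_pos_block(T_, dh) else NULL
  gi <- if (userel) rel_gather_idx(T_) else NULL
  drop_p <- if (train) cfg$dropout else 0
  caches <- vector("list", cfg$layers)
  for (l in seq_len(cfg$layers)) {
    lp <- enc$layers[[l]]
    Q <- X %*% lp$Wq
    kv <- fuse_key_value(X, ent_ids, lp$Wk, lp$Wv, lp$Wek, lp$Wev, enc$E_ent,
                         cfg$use_entity_fusion)
    K <- kv$K; V <- kv$V
    AO <- matrix(0, T_, cfg$H_c)
    Wts <- vector("list", cfg$heads)
    for (h in seq_len(cfg$heads)) {
      cols <- (h - 1L) * dh + seq_len(dh)
      Qh <- Q[, cols, drop = FALSE]
      Kh <- K[, cols, drop = FALSE]
      L <- tcrossprod(Qh, Kh)
      if (userel) {
        P <- tcrossprod(Qh, R)
        L <- L + matrix(P[gi$li], T_, T_)
        vR <- as.vector(R %*% lp$v[h, ])
        L <- L + matrix(vR[gi$IDX], T_, T_)
      }
      uk <- as.vector(Kh %*% lp$u[h, ])
      L <- L + matrix(rep(uk, each = T_), T_, T_)
      L <- L / sc
      if (any(!is.finite(L)))
        stop("non-finite attention logits in encoder layer ", l)
      Wt <- softmax_rows(L)
      Wts[[h]] <- Wt
      AO[, cols] <- Wt %*% V[, cols, drop = FALSE]
    }
    mask1 <- if (drop_p > 0)
      matrix((stats::runif(T_ * cfg$H_c) >= drop_p) / (1 - drop_p), T_, cfg$H_c)
      else NULL
    AOd <- if (is.null(mask1)) AO else AO * mask1
    ln1 <- layernorm_fwd(X + AOd, lp$g1, lp$b1)
    X2 <- ln1$y
    Fi <- sweep(X2 %*% lp$W1, 2, lp$bf1, `+`)
    Fa <- gelu(Fi)
    Fo <- sweep(Fa %*% lp$W2, 2, lp$bf2, `+`)
    mask2 <- if (drop_p > 0)
      matrix((stats::runif(T_ * cfg$H_c) >= drop_p) / (1 - drop_p), T_, cfg$H_c)
      else NULL
    Fod <- if (is.null(mask2)) Fo else Fo * mask2
    ln2 <- layernorm_fwd(X2 + Fod, lp$g2, lp$b2)
    if (any(!is.finite(ln2$y)))
      stop("non-finite states in encoder layer ", l)
    caches[[l]] <- list(X = X, Q = Q, K = K, V = V, Wts = Wts,
                        mask1 = mask1, mask2 = mask2,
                        ln1 = ln1, X2 = X2, Fi = Fi, Fa = Fa, ln2 = ln2)
    X <- ln2$y
  }
  list(H = X, caches = caches, R = R, gi = gi, T_ = T_)
}

# backward pass; returns list(grads = encoder grad tree, dE implicit inside)
encoder_bwd <- function(enc, cfg, char_ids, ent_ids, fwd, dH) {
  T_ <- fwd$T_
  dh <- cfg$H_c / cfg$heads
  sc <- sqrt(dh)
  userel <- isTRUE(cfg$use_relative_position)
  R <- fwd$R; gi <- fwd$gi
  g <- param_zeros_like(enc)
  ent_idx <- which(ent_ids > 0L)
  fuse_on <- isTRUE(cfg$use_entity_fusion) && length(ent_idx) > 0L
  dX <- dH
  for (l in rev(seq_len(cfg$layers))) {
    lp <- enc$layers[[l]]
    ca <- fwd$caches[[l]]
    gl <- g$layers[[l]]
    # LN2 / FFN
    b2 <- layernorm_bwd(ca$ln2, lp$g2, dX)
    gl$g2 <- gl$g2 + b2$dgain; gl$b2 <- gl$b2 + b2$dbias
    dsum2 <- b2$dx
    dFo <- if (is.null(ca$mask2)) dsum2 else dsum2 * ca$mask2
    dX2 <- dsum2
    dFa <- dFo %*% t(lp$W2)
    gl$W2 <- gl$W2 + crossprod(ca$Fa, dFo)
    gl$bf2 <- gl$bf2 + colSums(dFo)
    dFi <- gelu_bwd(ca$Fi, dFa)
    dX2 <- dX2 + dFi %*% t(lp$W1)
    gl$W1 <- gl$W1 + crossprod(ca$X2, dFi)
    gl$bf1 <- gl$bf1 + colSums(dFi)
    # LN1 / attention
    b1 <- layernorm_bwd(ca$ln1, lp$g1, dX2)
    gl$g1 <- gl$g1 + b1$dgain; gl$b1 <- gl$b1 + b1$dbias
    dsum1 <- b1$dx
    dXl <- dsum1                      # residual path into layer input
    dAO <- if (is.null(ca$mask1)) dsum1 else dsum1 * ca$mask1
    dQ <- matrix(0, T_, cfg$H_c)
    dK <- matrix(0, T_, cfg$H_c)
    dV <- matrix(0, T_, cfg$H_c)
    for (h in seq_len(cfg$heads)) {
      cols <- (h - 1L) * dh + seq_len(dh)
      Wt <- ca$Wts[[h]]
      dOh <- dAO[, cols, drop = FALSE]
      Vh <- ca$V[, cols, drop = FALSE]
      Qh <- ca$Q[, cols, drop = FALSE]
      Kh <- ca$K[, cols, drop = FALSE]
      dV[, cols] <- dV[, cols] + crossprod(Wt, dOh)
      dWt <- tcrossprod(dOh, Vh)
      dL <- softmax_rows_bwd(Wt, dWt) / sc
      dQ[, cols] <- dQ[, cols] + dL %*% Kh
      dK[, cols] <- dK[, cols] + crossprod(dL, Qh)
      cs <- colSums(dL)
      gl$u[h, ] <- gl$u[h, ] + as.vector(cs %*% Kh)
      dK[, cols] <- dK[, cols] + outer(cs, lp$u[h, ])
      if (userel) {
        dP <- matrix(0, T_, 2L * T_ - 1L)
        dP[gi$li] <- as.vector(dL)
        dQ[, cols] <- dQ[, cols] + dP %*% R
        gl$v[h, ] <- gl$v[h, ] + as.vector(crossprod(R, colSums(dP)))
      }
    }
    X <- ca$X
    dXl <- dXl + dQ %*% t(lp$Wq)
    gl$Wq <- gl$Wq + crossprod(X, dQ)
    # fused keys/values: char side gets factor 1 (e=0) or 1/2 (e>0)
    dKc <- dK; dVc <- dV
    if (fuse_on) {
      dKc[ent_idx, ] <- 0.5 * dKc[ent_idx, , drop = FALSE]
      dVc[ent_idx, ] <- 0.5 * dVc[ent_idx, , drop = FALSE]
    }
    dXl <- dXl + dKc %*% t(lp$Wk) + dVc %*% t(lp$Wv)
    gl$Wk <- gl$Wk + crossprod(X, dKc)
    gl$Wv <- gl$Wv + crossprod(X, dVc)
    if (fuse_on) {
      E <- enc$E_ent[ent_ids[ent_idx] + 1L, , drop = FALSE]
      dKe <- 0.5 * dK[ent_idx, , drop = FALSE]
      dVe <- 0.5 * dV[ent_idx, , drop = FALSE]
      gl$Wek <- gl$Wek + crossprod(E, dKe)
      gl$Wev <- gl$Wev + crossprod(E, dVe)
      dE <- dKe %*% t(lp$Wek) + dVe %*% t(lp$Wev)
      acc <- rowsum(dE, group = ent_ids[ent_idx])
      rows <- as.integer(rownames(acc)) + 1L
      g$E_ent[rows, ] <- g$E_ent[rows, , drop = FALSE] + acc
    }
    g$layers[[l]] <- gl
    dX <- dXl
  }
  # embedding layer
  accc <- rowsum(dX, group = char_ids)
  rows <- as.integer(rownames(accc))
  g$E_c[rows, ] <- g$E_c[rows, , drop = FALSE] + accc
  if (isTRUE(cfg$use_absolute_position))
    g$E_p[seq_len(T_), ] <- g$E_p[seq_len(T_), , drop = FALSE] + dX
  list(grads = g, dX1 = dX)
}
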