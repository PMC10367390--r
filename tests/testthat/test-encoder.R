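test_that("embedding layer is the exact sum of character and position rows", {
  set.seed(1)
  E_c <- matrix(rnorm(5 * 4), 5, 4)
  E_p <- matrix(rnorm(8 * 4), 8, 4)
  ids <- c(2L, 5L, 3L)
  X <- embed_chars(E_c, E_p, ids)
  expect_equal(X, E_c[ids, ] + E_p[1:3, ])
  # zeroing one table leaves the other
  expect_equal(embed_chars(E_c * 0, E_p, ids), E_p[1:3, ])
  expect_equal(embed_chars(E_c, E_p, ids, use_absolute_position = FALSE),
               E_c[ids, ])
  expect_error(embed_chars(E_c, E_p, rep(1L, 9)), "max_len")
})

test_that("relative position encoding is directional with unit sin/cos pairs", {
  d <- 8L
  r0 <- relative_position(0L, d)
  expect_equal(r0[seq(1, d, 2)], rep(0, d / 2))  # sin slots
  expect_equal(r0[seq(2, d, 2)], rep(1, d / 2))  # cos slots
  for (t in 1:16) {
    rp <- relative_position(t, d)
    rn <- relative_position(-t, d)
    expect_identical(rn[seq(2, d, 2)], rp[seq(2, d, 2)])
    expect_identical(rn[seq(1, d, 2)], -rp[seq(1, d, 2)])
    expect_equal(sum(rp^2), d / 2, tolerance = 1e-12)
  }
  # directionality: a generic query separates left from right offsets
  set.seed(2)
  q <- rnorm(d)
  expect_false(isTRUE(all.equal(sum(q * relative_position(3L, d)),
                                sum(q * relative_position(-3L, d)))))
})

test_that("fuse_key_value averages entity projections into keys and values", {
  set.seed(3)
  H <- 4L; He <- 3L
  hidden <- matrix(rnorm(2 * H), 2, H)
  Wk <- matrix(rnorm(H * H), H, H); Wv <- matrix(rnorm(H * H), H, H)
  Wek <- matrix(rnorm(He * H), He, H); Wev <- matrix(rnorm(He * H), He, H)
  E_ent <- matrix(rnorm(3 * He), 3, He)
  # no entities: plain projections
  kv0 <- fuse_key_value(hidden, c(0L, 0L), Wk, Wv, Wek, Wev, E_ent)
  expect_equal(kv0$K, hidden %*% Wk)
  expect_equal(kv0$V, hidden %*% Wv)
  # one entity: hand-computed average at that position
  kv1 <- fuse_key_value(hidden, c(0L, 2L), Wk, Wv, Wek, Wev, E_ent)
  expect_equal(kv1$K[1, ], (hidden %*% Wk)[1, ])
  expect_equal(kv1$K[2, ],
               0.5 * (hidden %*% Wk)[2, ] + 0.5 * as.vector(E_ent[3, ] %*% Wek))
  expect_equal(kv1$V[2, ],
               0.5 * (hidden %*% Wv)[2, ] + 0.5 * as.vector(E_ent[3, ] %*% Wev))
  # fusion disabled ignores the entity tags entirely
  kvoff <- fuse_key_value(hidden, c(0L, 2L), Wk, Wv, Wek, Wev, E_ent,
                          use_entity_fusion = FALSE)
  expect_equal(kvoff, kv0)
  # equal projections make fusion a no-op (average of equal terms)
  hid1 <- matrix(rnorm(H), 1, H)
  E_eq <- rbind(rep(0, H), hid1)       # entity id 1 embeds as the hidden state
  kv_eq <- fuse_key_value(hid1, 1L, Wk, Wv, Wk, Wv, E_eq)
  expect_equal(kv_eq$K, hid1 %*% Wk)
  expect_equal(kv_eq$V, hid1 %*% Wv)
  expect_error(fuse_key_value(hidden, c(0L, 9L), Wk, Wv, Wek, Wev, E_ent),
               "range")
})

test_that("attention rows are stochastic and match the geometric-mean identity", {
  set.seed(5)
  heads <- 2L; dh <- 4L; H <- heads * dh
  for (rep in 1:25) {
    T_ <- sample(2:6, 1L)
    hidden <- matrix(rnorm(T_ * H), T_, H)
    Wq <- matrix(rnorm(H * H), H, H)
    Wk <- matrix(rnorm(H * H), H, H); Wv <- diag(H)
    Wek <- matrix(rnorm(H * H), H, H); Wev <- diag(H)
    E_ent <- matrix(rnorm((T_ + 1) * H), T_ + 1, H)
    ents <- seq_len(T_)                      # every position has an entity
    Q <- hidden %*% Wq
    kv <- fuse_key_value(hidden, ents, Wk, Wv, Wek, Wev, E_ent)
    W <- attention_scores(Q, kv$K, matrix(0, heads, dh), matrix(0, heads, dh),
                          heads, use_relative_position = FALSE)
    Kc <- hidden %*% Wk
    Ke <- E_ent[ents + 1L, ] %*% Wek
    for (h in seq_len(heads)) {
      expect_equal(rowSums(W[, , h]), rep(1, T_), tolerance = 1e-6)
      cols <- (h - 1L) * dh + seq_len(dh)
      for (t in seq_len(T_)) {
        expect_equal(W[t, , h],
                     oracle_geomean_row(Q[t, cols, drop = FALSE],
                                        Kc[, cols, drop = FALSE],
                                        Ke[, cols, drop = FALSE], dh),
                     tolerance = 1e-5)
      }
    }
  }
  # T = 1: the single weight is exactly 1
  W1 <- attention_scores(matrix(rnorm(H), 1, H), matrix(rnorm(H), 1, H),
                         matrix(0, heads, dh), matrix(0, heads, dh), heads)
  expect_equal(as.vector(W1), rep(1, heads))
})

test_that("encoder forward is deterministic in eval mode and layerwise sane", {
  cfg <- tiny_config(layers = 2L)
  params <- tiny_params(cfg)
  ids <- c(2L, 3L, 4L, 5L)
  ents <- c(0L, 1L, 1L, 0L)
  f1 <- lexner:::encoder_fwd(params$enc, cfg, ids, ents)
  f2 <- lexner:::encoder_fwd(params$enc, cfg, ids, ents)
  expect_identical(f1$H, f2$H)
  # no cross-sentence state: other sentences do not change this one's output
  other <- lexner:::encoder_fwd(params$enc, cfg, c(6L, 7L), c(0L, 0L))
  f3 <- lexner:::encoder_fwd(params$enc, cfg, ids, ents)
  expect_identical(f1$H, f3$H)
  # zero-layer stack returns the embedding
  cfg0 <- tiny_config(layers = 0L)
  p0 <- tiny_params(cfg0)
  f0 <- lexner:::encoder_fwd(p0$enc, cfg0, ids, ents)
  expect_equal(f0$H, embed_chars(p0$enc$E_c, p0$enc$E_p, ids))
  # disabling fusion equals matching nothing
  cfg_nf <- tiny_config(use_entity_fusion = FALSE)
  pf <- tiny_params(cfg_nf)
  expect_equal(lexner:::encoder_fwd(pf$enc, cfg_nf, ids, ents)$H,
               lexner:::encoder_fwd(pf$enc, cfg_nf, ids, c(0L, 0L, 0L, 0L))$H)
})

test_that("encoder and heads backward agree with finite differences", {
  set.seed(9)
  cfg <- tiny_config(layers = 2L, heads = 2L, H_c = 8L, H_e = 6L,
                     filters = 3L, feature_dim = 5L, margin = 4L)
  params <- tiny_params(cfg, vocab = 7L, ents = 3L, rads = 4L, types = 2L,
                        seed = 9L)
  es <- list(char_ids = c(2L, 3L, 4L, 2L), ent_ids = c(0L, 2L, 2L, 0L),
             rad_ids = c(2L, 3L, 2L, 4L),
             boundary_idx = c(3L, 1L, 2L, 3L), type_idx = c(3L, 1L, 1L, 3L))
  r <- lexner:::model_loss_grads(params, cfg, es, train = FALSE,
                                 lambda = 0.5, alpha = 1.2, beta = 0.7)
  loss_at <- function(p) lexner:::model_loss_grads(
    p, cfg, es, train = FALSE, lambda = 0.5, alpha = 1.2, beta = 0.7)$loss
  eps <- 1e-5
  check <- list(
    list(list("enc", "E_c"), cbind(2, 1)),
    list(list("enc", "E_ent"), cbind(3, 2)),
    list(list("enc", "layers", 1L, "Wq"), cbind(1, 2)),
    list(list("enc", "layers", 2L, "Wek"), cbind(2, 3)),
    list(list("enc", "layers", 1L, "v"), cbind(1, 2)),
    list(list("crf", "trans"), cbind(1, 2)),
    list(list("type", "W_fc"), cbind(3, 2)),
    list(list("type", "conv_rad", 1L, "K"), cbind(4, 2)),
    list(list("type", "W_cls"), cbind(1, 3)))
  for (ck in check) {
    path <- ck[[1]]; at <- ck[[2]]
    g <- r$grads; for (nm in path) g <- g[[nm]]
    pp <- params; pm <- params
    get_set <- function(tree, delta) {
      x <- tree
      ref <- x
      for (nm in path) ref <- ref[[nm]]
      ref[at] <- ref[at] + delta
      expr <- paste0("x", paste0("[[path[[", seq_along(path), "]]]]",
                                 collapse = ""), " <- ref")
      eval(parse(text = expr))
      x
    }
    num <- (loss_at(get_set(params, eps)) -
            loss_at(get_set(params, -eps))) / (2 * eps)
    expect_equal(unname(g[at]), num, tolerance = 1e-4,
                 label = paste(path, collapse = "$"))
  }
})
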