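# Model assembly: configuration, parameter initialization, the per-sentence
# joint forward/backward pass (boundary CRF loss + type A-Softmax loss), and
# sentence-level prediction.

#' Model configuration
#'
#' Desk-scale defaults (2 layers, width 64, 4 heads) train in minutes on one
#' CPU; the paper-scale regime (hidden 768, 12 heads, 12 layers, dropout 0.3,
#' max length 128) is reachable through the same fields.  The `use_*` flags
#' are the ablation switches: each disables one information channel without
#' changing the code path.
#'
#' @param layers number of encoder layers.
#' @param heads attention heads (`H_c` must be divisible by `heads`).
#' @param H_c encoder width (character hidden size).
#' @param H_e entity embedding width.
#' @param dropout dropout rate applied to each sublayer output in training.
#' @param max_len maximum sentence length.
#' @param ffn_mult feed-forward inner width multiplier.
#' @param filters CNN filters per kernel width in each branch.
#' @param kernel_widths CNN kernel widths.
#' @param feature_dim width of the fused type-feature vector.
#' @param margin integer angular margin `m` of the type classifier.
#' @param use_entity_fusion fuse dictionary-entity embeddings into K/V?
#' @param use_relative_position include directional relative-position terms?
#' @param use_absolute_position add the absolute position table at the input?
#' @param use_radical_branch include the radical CNN branch?
#' @param forbid_invalid_transitions hard-forbid O->I (and start->I) in the CRF?
#' @return a list of class `"lexner_config"`.
#' @export
lexner_config <- function(layers = 2L, heads = 4L, H_c = 64L, H_e = 64L,
                          dropout = 0.1, max_len = 64L, ffn_mult = 4L,
                          filters = 32L, kernel_widths = c(2L, 3L, 4L),
                          feature_dim = 64L, margin = 4L,
                          use_entity_fusion = TRUE,
                          use_relative_position = TRUE,
                          use_absolute_position = TRUE,
                          use_radical_branch = TRUE,
                          forbid_invalid_transitions = TRUE) {
  if (H_c %% heads != 0) stop("H_c must be divisible by heads")
  structure(list(layers = layers, heads = heads, H_c = H_c, H_e = H_e,
                 dropout = dropout, max_len = max_len, ffn_mult = ffn_mult,
                 filters = filters, kernel_widths = kernel_widths,
                 feature_dim = feature_dim, margin = margin,
                 use_entity_fusion = use_entity_fusion,
                 use_relative_position = use_relative_position,
                 use_absolute_position = use_absolute_position,
                 use_radical_branch = use_radical_branch,
                 forbid_invalid_transitions = forbid_invalid_transitions),
            class = "lexner_config")
}

## ---- vocabularies ----------------------------------------------------------

# id 1 is the unknown symbol in both vocabularies
build_vocab <- function(symbols) {
  syms <- unique(symbols)
  ids <- seq_along(syms) + 1L
  names(ids) <- syms
  ids
}

vocab_ids <- function(symbols, vocab) {
  out <- unname(vocab[symbols])
  out[is.na(out)] <- 1L
  out
}

# precompute integer encodings for a corpus
encode_corpus <- function(corpus, model) {
  lapply(corpus, function(s) encode_sentence(s, model))
}

encode_sentence <- function(s, model) {
  chars <- s$chars
  ent <- match_entities(chars, model$dict)
  rad <- radical_lookup(chars, model$radicals)
  enc <- list(chars = chars,
              char_ids = vocab_ids(chars, model$char_vocab),
              ent_ids = ent,
              rad_ids = vocab_ids(rad, model$rad_vocab))
  if (!is.null(s$labels)) {
    br <- split_labels(s$labels)
    enc$boundary_idx <- match(br$boundary, boundary_label_set())
    ty <- match(br$types, model$types)
    ty[is.na(ty)] <- length(model$types) + 1L    # no-entity class, last
    enc$type_idx <- ty
    enc$labels <- s$labels
  }
  enc
}

## ---- parameter init --------------------------------------------------------

model_init_params <- function(cfg, vocab_size, n_entities, n_radicals, n_types) {
  list(enc = encoder_init(cfg, vocab_size, n_entities),
       crf = crf_init(cfg$H_c),
       type = typehead_init(cfg, n_radicals, n_types))
}

## ---- joint forward / backward ---------------------------------------------

# forward + loss for one encoded sentence; returns losses and caches
model_fwd <- function(params, cfg, es, train = FALSE, lambda = 0) {
  fwd <- encoder_fwd(params$enc, cfg, es$char_ids, es$ent_ids, train = train)
  em <- sweep(fwd$H %*% params$crf$emit_W, 2, params$crf$emit_b, `+`)
  trans <- crf_effective(params$crf, cfg$forbid_invalid_transitions)
  rf <- radical_features(fwd$H, es$rad_ids, params$type, cfg)
  list(fwd = fwd, emissions = em, trans = trans, rf = rf)
}

model_loss_grads <- function(params, cfg, es, train = TRUE, lambda = 0,
                             alpha = 1, beta = 1) {
  fw <- model_fwd(params, cfg, es, train = train, lambda = lambda)
  T_ <- length(es$char_ids)
  cg <- crf_loss_grad(fw$emissions, fw$trans, es$boundary_idx)
  ag <- asoftmax_loss_grad(fw$rf$features, es$type_idx, params$type$W_cls,
                           m = cfg$margin, lambda = lambda)
  loss_B <- cg$loss
  loss_F <- ag$loss
  # backward: d(joint)/d(...) with joint = alpha*loss_B + beta*loss_F
  g <- list()
  g$crf <- list(emit_W = alpha * crossprod(fw$fwd$H, cg$d_emissions),
                emit_b = alpha * colSums(cg$d_emissions),
                trans = alpha * cg$d_trans,
                start = alpha * cg$d_start,
                stop = alpha * cg$d_stop)
  rb <- radical_features_bwd(fw$fwd$H, es$rad_ids, params$type, cfg,
                             fw$rf$cache, beta * ag$dX)
  g$type <- rb$grads
  g$type$W_cls <- beta * ag$dW
  dH <- alpha * cg$d_emissions %*% t(params$crf$emit_W) + rb$d_enc
  eb <- encoder_bwd(params$enc, cfg, es$char_ids, es$ent_ids, fw$fwd, dH)
  g$enc <- eb$grads
  list(loss = joint_loss(loss_B, loss_F, alpha, beta),
       loss_B = loss_B, loss_F = loss_F, grads = g)
}

## ---- prediction ------------------------------------------------------------

# decode one encoded sentence; returns labels and diagnostics
model_decode <- function(params, cfg, es, type_names) {
  fw <- model_fwd(params, cfg, es, train = FALSE)
  path <- viterbi_decode(fw$emissions, fw$trans)
  boundary <- boundary_label_set()[path]
  probs <- type_probs(fw$rf$features, params$type$W_cls)
  colnames(probs) <- c(type_names, "O")
  arg <- max.col(probs, ties.method = "first")
  types <- c(type_names, NA_character_)[arg]
  labels <- merge_labels(boundary, types, probs)
  # sentence confidence for self-training: normalized CRF path probability
  # times mean max type probability over predicted entity tokens
  logZ <- crf_log_partition(fw$emissions, fw$trans)
  sc <- crf_path_score(fw$emissions, fw$trans, path)
  conf_crf <- exp((sc - logZ) / length(path))
  ent_tok <- which(boundary != "O")
  conf_type <- if (length(ent_tok) > 0L)
    mean(apply(probs[ent_tok, , drop = FALSE], 1L, max)) else 1
  list(labels = labels, boundary = boundary, types = types,
       type_prob = probs, confidence = conf_crf * conf_type)
}

#' Combine branch losses into the joint training loss
#'
#' `Loss = alpha * loss_B + beta * loss_F`, the weighted sum of the boundary
#' (CRF) loss and the type (angular-margin softmax) loss.
#'
#' @param loss_B boundary-branch loss (finite, `>= 0`).
#' @param loss_F type-branch loss (finite, `>= 0`).
#' @param alpha,beta non-negative weights (their sum must be positive).
#' @return scalar joint loss.
#' @export
joint_loss <- function(loss_B, loss_F, alpha = 1, beta = 1) {
  if (alpha < 0 || beta < 0) stop("loss weights must be non-negative")
  if (alpha + beta <= 0) stop("at least one loss weight must be positive")
  alpha * loss_B + beta * loss_F
}

#' Combine labeled and pseudo-labeled losses for self-training
#'
#' `Loss = (1 - theta) * loss_labeled + theta * loss_pseudo`: a convex
#' combination controlled by the unlabeled-loss weight `theta`.
#'
#' @param loss_labeled mean loss over labeled data.
#' @param loss_pseudo mean loss over pseudo-labeled data.
#' @param theta weight in `[0, 1)`.
#' @return scalar.
#' @export
selftrain_loss <- function(loss_labeled, loss_pseudo, theta) {
  if (theta < 0 || theta >= 1) stop("theta must be in [0, 1)")
  (1 - theta) * loss_labeled + theta * loss_pseudo
}
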