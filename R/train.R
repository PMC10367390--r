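# Joint training of both branches: AdamW with differential learning rates
# (encoder vs. decode heads), global gradient-norm clipping, optional FGM
# adversarial perturbation of the character embeddings, and an annealed
# margin for the angular-margin classifier.

#' Training configuration
#'
#' @param epochs training epochs.
#' @param batch_size sentences per optimizer step.
#' @param lr_encoder learning rate for the encoder (embeddings + transformer).
#' @param lr_heads learning rate for the CRF and type heads.
#' @param alpha,beta joint-loss weights on the boundary and type branches.
#' @param grad_clip global gradient-norm clip.
#' @param weight_decay decoupled weight decay on projection/filter matrices.
#' @param grad_accum_steps batches accumulated per optimizer step.
#' @param fgm_enabled add single-step adversarial perturbation of the
#'   character embedding table to each step?
#' @param fgm_epsilon perturbation radius (L2, over the embedding table).
#' @param lambda_base,lambda_min,lambda_gamma annealing schedule of the
#'   angular-margin blend: `lambda = max(lambda_min,
#'   lambda_base / (1 + lambda_gamma * step))`; large `lambda` means the
#'   classifier behaves like plain cosine softmax early in training.
#' @param dev_fraction fraction of the training set held out for epoch
#'   checkpoint selection when no explicit dev set is given.
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @param verbose print per-epoch progress?
#' @return list of class `"train_config"`.
#' @export
train_config <- function(epochs = 30L, batch_size = 16L,
                         lr_encoder = 1e-3, lr_heads = 1e-2,
                         alpha = 1, beta = 1,
                         grad_clip = 2, weight_decay = 0.01,
                         grad_accum_steps = 1L,
                         fgm_enabled = FALSE, fgm_epsilon = 1,
                         lambda_base = 1000, lambda_min = 5,
                         lambda_gamma = 0.12,
                         dev_fraction = 0.1, seed = 1L, verbose = FALSE) {
  if (alpha < 0 || beta < 0 || alpha + beta <= 0)
    stop("alpha and beta must be non-negative with a positive sum")
  if (fgm_epsilon < 0) stop("fgm_epsilon must be >= 0")
  structure(as.list(environment()), class = "train_config")
}

param_add <- function(a, b) param_map2(a, b, `+`)

DECAYED <- c("Wq", "Wk", "Wv", "Wek", "Wev", "W1", "W2",
             "emit_W", "W_fc", "K")

make_lr_of <- function(tcfg) {
  function(path) if (path[1] == "enc") tcfg$lr_encoder else tcfg$lr_heads
}

make_decay_of <- function(tcfg) {
  function(path) {
    if (path[length(path)] %in% DECAYED) tcfg$weight_decay else 0
  }
}

lambda_at <- function(tcfg, step) {
  max(tcfg$lambda_min, tcfg$lambda_base / (1 + tcfg$lambda_gamma * step))
}

# mean loss and summed (weight-scaled) gradients over a batch of encoded
# sentences; weights w sum to 1 within the batch
batch_loss_grads <- function(params, cfg, batch, w, tcfg, lambda) {
  total <- NULL
  loss <- 0
  for (i in seq_along(batch)) {
    r <- model_loss_grads(params, cfg, batch[[i]], train = TRUE,
                          lambda = lambda, alpha = tcfg$alpha,
                          beta = tcfg$beta)
    loss <- loss + w[i] * r$loss
    g <- if (w[i] == 1) r$grads else param_scale(r$grads, w[i])
    total <- if (is.null(total)) g else param_add(total, g)
  }
  list(loss = loss, grads = total)
}

#' Single-step adversarial (FGM) loss and gradients
#'
#' Perturbs the character embedding table by `epsilon * g / ||g||` where `g`
#' is the gradient of the batch loss with respect to the table, recomputes
#' the loss and gradients at the perturbed point, and restores the table
#' exactly.  With `epsilon = 0`, or a zero gradient, the adversarial loss
#' equals the clean loss.
#'
#' @param params model parameter tree.
#' @param cfg model configuration.
#' @param batch list of encoded sentences.
#' @param w per-sentence weights (summing to 1).
#' @param tcfg training configuration (uses `alpha`, `beta`).
#' @param epsilon perturbation radius.
#' @param lambda current margin-annealing weight.
#' @param clean optional precomputed clean `batch_loss_grads()` result.
#' @return list with `loss` (adversarial), `grads` (at the perturbed point),
#'   `clean` (the clean result) and `perturbation` (the applied delta).
#' @export
fgm_step <- function(params, cfg, batch, w, tcfg, epsilon, lambda = 0,
                     clean = NULL) {
  if (is.null(clean))
    clean <- batch_loss_grads(params, cfg, batch, w, tcfg, lambda)
  g_emb <- clean$grads$enc$E_c
  nrm <- sqrt(sum(g_emb^2))
  if (epsilon == 0 || nrm == 0) {
    return(list(loss = clean$loss, grads = clean$grads, clean = clean,
                perturbation = array(0, dim = dim(g_emb))))
  }
  delta <- epsilon * g_emb / nrm
  orig <- params$enc$E_c
  params$enc$E_c <- orig + delta
  adv <- batch_loss_grads(params, cfg, batch, w, tcfg, lambda)
  params$enc$E_c <- orig                      # restore exactly (copy semantics)
  list(loss = adv$loss, grads = adv$grads, clean = clean, perturbation = delta)
}

# core optimization loop over encoded sentences.
# weights: per-sentence loss multipliers (relative; renormalized per batch).
fit_loop <- function(params, model_env, encoded, weights, tcfg, cfg,
                     dev_encoded = NULL, dev_gold = NULL,
                     adam = NULL, step0 = 0L) {
  n <- length(encoded)
  if (n == 0L) stop("empty training corpus")
  if (is.null(adam)) adam <- adam_init(params)
  lr_of <- make_lr_of(tcfg)
  decay_of <- make_decay_of(tcfg)
  step <- step0
  best <- list(f1 = -Inf, params = params)
  log <- data.frame(epoch = integer(), loss = numeric(), dev_f1 = numeric())
  for (epoch in seq_len(tcfg$epochs)) {
    ord <- sample.int(n)
    epoch_loss <- 0
    nb <- 0
    acc_grads <- NULL
    acc_count <- 0L
    for (bs in split(ord, ceiling(seq_along(ord) / tcfg$batch_size))) {
      batch <- encoded[bs]
      w <- weights[bs]
      w <- w / sum(w)
      lambda <- lambda_at(tcfg, step + 1L)
      r <- batch_loss_grads(params, cfg, batch, w, tcfg, lambda)
      if (!is.finite(r$loss)) stop("training diverged: non-finite loss")
      grads <- r$grads
      if (tcfg$fgm_enabled) {
        adv <- fgm_step(params, cfg, batch, w, tcfg, tcfg$fgm_epsilon,
                        lambda, clean = r)
        grads <- param_add(grads, adv$grads)
      }
      acc_grads <- if (is.null(acc_grads)) grads else
        param_add(acc_grads, grads)
      acc_count <- acc_count + 1L
      epoch_loss <- epoch_loss + r$loss
      nb <- nb + 1
      if (acc_count >= tcfg$grad_accum_steps) {
        if (acc_count > 1L)
          acc_grads <- param_scale(acc_grads, 1 / acc_count)
        gn <- param_global_norm(acc_grads)
        if (gn > tcfg$grad_clip)
          acc_grads <- param_scale(acc_grads, tcfg$grad_clip / gn)
        st <- adam_step(params, acc_grads, adam, lr_of, decay_of)
        params <- st$params
        adam <- st$state
        # keep the angular-margin class directions unit-norm
        params$type$W_cls <- params$type$W_cls /
          sqrt(rowSums(params$type$W_cls^2))
        step <- step + 1L
        acc_grads <- NULL
        acc_count <- 0L
      }
    }
    dev_f1 <- NA_real_
    if (!is.null(dev_encoded) && length(dev_encoded) > 0L) {
      pred <- predict_encoded(params, cfg, dev_encoded, model_env$types)
      dev_f1 <- entity_f1(dev_gold, pred)$micro$f1
      if (dev_f1 >= best$f1) best <- list(f1 = dev_f1, params = params)
    }
    log <- rbind(log, data.frame(epoch = epoch, loss = epoch_loss / nb,
                                 dev_f1 = dev_f1))
    if (isTRUE(tcfg$verbose))
      message(sprintf("epoch %3d  loss %.4f  dev F1 %s", epoch,
                      epoch_loss / nb,
                      if (is.na(dev_f1)) "-" else sprintf("%.4f", dev_f1)))
  }
  final_params <- if (is.finite(best$f1)) best$params else params
  list(params = final_params, last_params = params, adam = adam,
       step = step, log = log,
       best_f1 = if (is.finite(best$f1)) best$f1 else NA_real_)
}

# decode a list of encoded sentences into labeled bio_sentences
predict_encoded <- function(params, cfg, encoded, type_names) {
  lapply(encoded, function(es) {
    d <- model_decode(params, cfg, es, type_names)
    s <- bio_sentence(es$chars, d$labels)
    attr(s, "confidence") <- d$confidence
    s
  })
}
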