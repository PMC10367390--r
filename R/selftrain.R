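# Confidence-filtered self-training: train on the labeled pool, pseudo-label
# the unlabeled pool, move the confident sentences over, and continue
# training with the pseudo-labeled loss down-weighted by theta:
#     Loss = (1 - theta) * Loss_labeled + theta * Loss_pseudo
# Pseudo-labels are frozen once admitted.

#' Self-training configuration
#'
#' @param tau confidence threshold in `(0, 1]` for admitting a
#'   pseudo-labeled sentence.
#' @param rounds maximum self-training rounds.
#' @param theta weight of the pseudo-labeled loss in `[0, 1)`.
#' @param round_cap per-round cap on admissions, as a fraction of the
#'   original unlabeled pool (prevents one-round flooding).
#' @param round_epochs training epochs per round after the initial fit.
#' @return list of class `"selftrain_config"`.
#' @export
selftrain_config <- function(tau = 0.9, rounds = 3L, theta = 0.3,
                             round_cap = 0.2, round_epochs = 6L) {
  if (tau <= 0 || tau > 1) stop("tau must be in (0, 1]")
  if (theta < 0 || theta >= 1) stop("theta must be in [0, 1)")
  structure(as.list(environment()), class = "selftrain_config")
}

#' Pseudo-label unlabeled sentences with a fitted model
#'
#' Each sentence is decoded and scored with a sentence-level confidence in
#' `[0, 1]`: the geometric-mean per-token probability of the Viterbi path
#' under the CRF, times the mean maximum type probability over predicted
#' entity tokens (1 when no entity is predicted).  Only sentences with
#' confidence `>= tau` are returned.
#'
#' @param object a fitted `"lexner"` model.
#' @param unlabeled list of unlabeled sentences.
#' @param tau confidence threshold.
#' @return list with `sentences` (labeled [bio_sentence()]s), `confidence`
#'   (parallel numeric) and `index` (positions in `unlabeled`).
#' @export
pseudo_label <- function(object, unlabeled, tau) {
  pred <- predict.lexner(object, unlabeled)
  conf <- vapply(pred, function(s) attr(s, "confidence"), numeric(1))
  keep <- which(conf >= tau)
  list(sentences = pred[keep], confidence = conf[keep], index = keep)
}

#' Train with confidence-filtered self-training
#'
#' Fits a supervised model on the labeled corpus, then repeatedly
#' pseudo-labels the unlabeled pool, admits the most confident sentences
#' (up to the per-round cap) and continues training on the union with the
#' pseudo-labeled loss weighted by `theta`.  Stops after
#' `selftrain$rounds` rounds or as soon as no sentence passes `tau` (in
#' which case the supervised model is returned unchanged).
#'
#' @inheritParams lexner
#' @param unlabeled list of unlabeled sentences (should outnumber `train`).
#' @param selftrain a [selftrain_config()].
#' @return a `"lexner"` object with an additional `rounds` data.frame
#'   logging, per round, the admissions, pool sizes and held-out F1.
#' @export
self_train <- function(train, unlabeled, dictionary, radicals,
                       config = lexner_config(), control = train_config(),
                       selftrain = selftrain_config(), dev = NULL,
                       types = NULL) {
  if (length(unlabeled) == 0L) {
    warning("no unlabeled data; degenerating to supervised training")
    return(lexner(train, dictionary, radicals, config, control, dev = dev,
                  types = types))
  }
  if (length(unlabeled) <= length(train))
    warning("unlabeled pool is not larger than the labeled set")
  model <- lexner(train, dictionary, radicals, config, control, dev = dev,
                  unlabeled = unlabeled, types = types)
  # rebuild the internal dev split deterministically for round evaluation
  set.seed(control$seed)
  if (is.null(dev) && control$dev_fraction > 0 && length(train) >= 10L) {
    n_dev <- max(1L, round(control$dev_fraction * length(train)))
    dev_idx <- sample.int(length(train), n_dev)
    dev <- train[dev_idx]
    train <- train[-dev_idx]
  }
  dev_encoded <- if (!is.null(dev)) encode_corpus(dev, model) else NULL
  lab_encoded <- encode_corpus(train, model)
  pool <- list()                      # admitted pseudo-labeled sentences
  remaining <- unlabeled
  cap <- max(1L, floor(selftrain$round_cap * length(unlabeled)))
  log <- data.frame(round = integer(), admitted = integer(),
                    pool_size = integer(), unlabeled_left = integer(),
                    dev_f1 = numeric())
  params <- model$params
  adam <- model$adam
  step <- model$step
  for (round in seq_len(selftrain$rounds)) {
    if (length(remaining) == 0L) break
    model$params <- params
    sel <- pseudo_label(model, remaining, selftrain$tau)
    if (length(sel$index) == 0L) break
    ord <- order(sel$confidence, decreasing = TRUE)[
      seq_len(min(cap, length(sel$index)))]
    take <- sel$index[ord]
    pool <- c(pool, sel$sentences[ord])
    remaining <- remaining[-take]
    pool_encoded <- encode_corpus(pool, model)
    all_encoded <- c(lab_encoded, pool_encoded)
    n_l <- length(lab_encoded); n_p <- length(pool_encoded)
    # weights realize (1-theta)*mean(labeled) + theta*mean(pseudo)
    n_tot <- n_l + n_p
    w <- c(rep((1 - selftrain$theta) * n_tot / n_l, n_l),
           rep(selftrain$theta * n_tot / n_p, n_p))
    rcfg <- control
    rcfg$epochs <- selftrain$round_epochs
    fit <- fit_loop(params, model, all_encoded, w, rcfg, config,
                    dev_encoded, dev, adam = adam, step0 = step)
    params <- fit$params
    adam <- fit$adam
    step <- fit$step
    log <- rbind(log, data.frame(round = round,
                                 admitted = length(take),
                                 pool_size = length(pool),
                                 unlabeled_left = length(remaining),
                                 dev_f1 = fit$best_f1))
    model$metrics <- rbind(model$metrics, fit$log)
  }
  model$params <- params
  model$adam <- adam
  model$step <- step
  model$rounds <- log
  if (nrow(log) > 0L && any(is.finite(log$dev_f1)))
    model$best_f1 <- max(c(model$best_f1, log$dev_f1), na.rm = TRUE)
  model
}
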