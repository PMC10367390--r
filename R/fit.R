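#' Fit a lexicon- and radical-enhanced neural entity recognizer
#'
#' Trains the dual-branch tagger: a character transformer encoder with
#' directional relative position encoding and entity-dictionary key/value
#' fusion, decoded jointly by (a) a linear-chain CRF over entity boundaries
#' and (b) a radical-CNN + angular-margin-softmax classifier over entity
#' types.  Training is deterministic given `control$seed`.
#'
#' @param train list of labeled [bio_sentence()] objects (the training
#'   corpus), e.g. from [read_bio_corpus()] or [generate_synth()].
#' @param dictionary an [entity_dictionary()] used for maximum entity
#'   matching and entity-embedding fusion.
#' @param radicals a [radical_table()] mapping characters to radicals.
#' @param config model architecture, a [lexner_config()].
#' @param control optimization settings, a [train_config()].
#' @param dev optional labeled corpus for epoch checkpoint selection; when
#'   `NULL`, `control$dev_fraction` of `train` is held out instead.
#' @param unlabeled optional unlabeled sentences whose characters join the
#'   vocabulary (useful before self-training).
#' @param types optional character vector fixing the entity type inventory;
#'   defaults to the types seen in `train` and `dictionary`.
#' @return an object of class `"lexner"` with components `params` (all
#'   parameter tables), `config`, `control`, `dict`, `radicals`, vocabulary
#'   maps, `types`, the per-epoch `metrics` log and `best_f1`.
#' @seealso [predict.lexner()], [self_train()], [lexner_evaluate()]
#' @export
lexner <- function(train, dictionary, radicals,
                   config = lexner_config(), control = train_config(),
                   dev = NULL, unlabeled = NULL, types = NULL) {
  if (length(train) == 0L) stop("empty training corpus")
  set.seed(control$seed)
  if (is.null(types)) {
    lab_types <- unique(unlist(lapply(train, function(s)
      stats::na.omit(tag_type(s$labels)))))
    types <- sort(unique(c(lab_types, dictionary$type)))
  }
  all_chars <- c(unlist(lapply(train, `[[`, "chars")),
                 unlist(strsplit(dictionary$surface, "", fixed = TRUE)),
                 unlist(lapply(unlabeled, `[[`, "chars")))
  char_vocab <- build_vocab(all_chars)
  rad_vocab <- build_vocab(c(radicals$unknown_radical, unique(radicals$map)))
  model <- list(dict = dictionary, radicals = radicals,
                char_vocab = char_vocab, rad_vocab = rad_vocab,
                types = types, config = config)
  # validation split for checkpointing
  if (is.null(dev) && control$dev_fraction > 0 && length(train) >= 10L) {
    n_dev <- max(1L, round(control$dev_fraction * length(train)))
    dev_idx <- sample.int(length(train), n_dev)
    dev <- train[dev_idx]
    train <- train[-dev_idx]
  }
  encoded <- encode_corpus(train, model)
  dev_encoded <- if (!is.null(dev)) encode_corpus(dev, model) else NULL
  params <- model_init_params(config, length(char_vocab) + 1L,
                              nrow(dictionary), length(rad_vocab) + 1L,
                              length(types))
  fit <- fit_loop(params, model, encoded, rep(1, length(encoded)),
                  control, config, dev_encoded, dev)
  structure(list(params = fit$params, config = config, control = control,
                 dict = dictionary, radicals = radicals,
                 char_vocab = char_vocab, rad_vocab = rad_vocab,
                 types = types, metrics = fit$log, best_f1 = fit$best_f1,
                 adam = fit$adam, step = fit$step,
                 last_params = fit$last_params,
                 n_train = length(train), call = match.call()),
            class = "lexner")
}

#' Predict BIO-type labels for new sentences
#'
#' Runs the encoder, decodes the boundary path by Viterbi, assigns each
#' predicted span the type resolved from the per-token type probabilities,
#' and merges both branches into BIO-type tags.
#'
#' @param object a fitted `"lexner"` model.
#' @param newdata a list of [bio_sentence()] objects (labels ignored), a
#'   single character vector of tokens, or a single string (split into
#'   characters).
#' @param ... unused.
#' @return a list of labeled [bio_sentence()] objects; each carries a
#'   `"confidence"` attribute (sentence-level score in `[0, 1]` combining the
#'   normalized CRF path probability and the mean type confidence).
#' @export
predict.lexner <- function(object, newdata, ...) {
  corpus <- as_corpus(newdata)
  encoded <- encode_corpus(corpus, object)
  predict_encoded(object$params, object$config, encoded, object$types)
}

as_corpus <- function(x) {
  if (inherits(x, "bio_sentence")) return(list(x))
  if (is.character(x)) {
    if (length(x) == 1L && nchar(x) > 1L)
      x <- strsplit(x, "", fixed = TRUE)[[1]]
    return(list(bio_sentence(x)))
  }
  lapply(x, function(s) if (inherits(s, "bio_sentence")) s else
    bio_sentence(s))
}

#' Evaluate a fitted model on a labeled corpus
#'
#' @param object a `"lexner"` model.
#' @param corpus labeled corpus.
#' @return an [entity_f1()] result (micro and per-type P/R/F1).
#' @export
lexner_evaluate <- function(object, corpus) {
  pred <- predict.lexner(object, corpus)
  entity_f1(corpus, pred)
}

#' Token-level type accuracy over gold entity tokens
#'
#' Isolates the type-recognition branch: for every gold entity token the
#' type head's argmax class (over the K types plus no-entity) is compared
#' with the gold type, independently of the boundary decode.
#'
#' @param object a `"lexner"` model.
#' @param corpus labeled corpus.
#' @return fraction of gold entity tokens typed correctly.
#' @export
lexner_type_accuracy <- function(object, corpus) {
  encoded <- encode_corpus(corpus, object)
  K <- length(object$types)
  correct <- 0L; total <- 0L
  for (es in encoded) {
    fw <- model_fwd(object$params, object$config, es)
    probs <- type_probs(fw$rf$features, object$params$type$W_cls)
    pred <- max.col(probs, ties.method = "first")
    ent <- which(es$type_idx <= K)
    correct <- correct + sum(pred[ent] == es$type_idx[ent])
    total <- total + length(ent)
  }
  if (total == 0L) return(NA_real_)
  correct / total
}

#' @export
print.lexner <- function(x, ...) {
  cfg <- x$config
  cat("Lexicon- and radical-enhanced neural NER model\n")
  cat(sprintf("  encoder: %d layer(s), %d head(s), width %d (entity width %d)\n",
              cfg$layers, cfg$heads, cfg$H_c, cfg$H_e))
  cat(sprintf("  heads:   CRF boundary decoder + radical-CNN type head (margin m = %d)\n",
              cfg$margin))
  cat(sprintf("  lexicon: %d entities, %d types; vocabulary %d characters, %d radicals\n",
              nrow(x$dict), length(x$types), length(x$char_vocab),
              length(x$rad_vocab)))
  cat(sprintf("  trained: %d sentences, %d epochs", x$n_train,
              nrow(x$metrics)))
  if (!is.na(x$best_f1))
    cat(sprintf("; best held-out entity F1 %.4f", x$best_f1))
  cat("\n")
  invisible(x)
}

#' @export
summary.lexner <- function(object, ...) {
  print(object)
  cat("\nAblation flags:\n")
  for (f in c("use_entity_fusion", "use_relative_position",
              "use_absolute_position", "use_radical_branch"))
    cat(sprintf("  %-24s %s\n", f, object$config[[f]]))
  cat("\nLast epochs:\n")
  print(utils::tail(object$metrics, 5L), row.names = FALSE)
  invisible(object)
}

#' @export
plot.lexner <- function(x, ...) {
  m <- x$metrics
  op <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op))
  plot(m$epoch, m$loss, type = "l", xlab = "epoch", ylab = "training loss",
       main = "Training curve", ...)
  if (any(!is.na(m$dev_f1))) {
    graphics::par(new = TRUE)
    plot(m$epoch, m$dev_f1, type = "l", col = "steelblue", axes = FALSE,
         xlab = "", ylab = "", ylim = c(0, 1))
    graphics::axis(4)
    graphics::mtext("held-out entity F1", side = 4, line = 2.5,
                    col = "steelblue")
  }
  invisible(x)
}

#' @export
coef.lexner <- function(object, ...) object$params
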