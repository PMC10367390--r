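# Seeded synthetic corpora with the statistical structure the model
# exploits: a gazetteer of multi-character entity surfaces drawn from
# type-specific character pools, planted into background text drawn from a
# disjoint sub-vocabulary, with radicals assigned type-consistently with
# probability rho (emulating the "sickness-radical -> disease" regularity of
# clinical Chinese).  Characters and radicals are abstract single Unicode
# codepoints so every on-disk format round-trips exactly.

#' Synthetic corpus configuration
#'
#' Defaults describe the reference desk-scale world: 4 entity types, a
#' 40-entry dictionary of 2-4 character surfaces, ~2 planted entities per
#' sentence, 12-20 background characters per sentence, and a 0.9
#' radical-type association.
#'
#' @param n_types number of entity types K.
#' @param chars_per_type characters in each type-specific pool.
#' @param background_chars characters in the disjoint background pool.
#' @param n_neutral_radicals radicals not associated with any type.
#' @param dict_size dictionary entries.
#' @param entity_len `c(min, max)` surface length.
#' @param entities_per_sentence Poisson mean of planted entities.
#' @param sentence_len `c(min, max)` background characters per sentence.
#' @param rho probability that a type-pool character takes its type's
#'   radical (otherwise uniform over all radicals).
#' @param ambiguity fraction of dictionary surfaces whose characters are
#'   drawn from a *different* type's pool, so surface characters and
#'   radicals alone suggest the wrong type and only the dictionary id
#'   resolves it.
#' @param n_train,n_dev,n_test,n_unlabeled corpus sizes.
#' @param seed RNG seed; all outputs are deterministic given it.
#' @return list of class `"synth_config"`.
#' @export
synth_config <- function(n_types = 4L, chars_per_type = 25L,
                         background_chars = 60L, n_neutral_radicals = 6L,
                         dict_size = 40L, entity_len = c(2L, 4L),
                         entities_per_sentence = 2,
                         sentence_len = c(12L, 20L),
                         rho = 0.9, ambiguity = 0,
                         n_train = 500L, n_dev = 100L, n_test = 100L,
                         n_unlabeled = 0L, seed = 1L) {
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]")
  if (ambiguity < 0 || ambiguity > 1) stop("ambiguity must be in [0, 1]")
  if (entity_len[1] < 1L) stop("entities must have length >= 1")
  if (sentence_len[1] < 2L) stop("sentences must have at least 2 background characters")
  structure(as.list(environment()), class = "synth_config")
}

# disjoint single-codepoint alphabets (Latin-Extended chars, Greek radicals)
synth_char_alphabet <- function(n) {
  cp <- setdiff(seq(0x00C0, 0x024F), c(0x00D7, 0x00F7))
  if (n > length(cp)) stop("character alphabet exhausted (max ", length(cp), ")")
  vapply(cp[seq_len(n)], intToUtf8, character(1))
}

synth_radical_alphabet <- function(n) {
  cp <- setdiff(seq(0x0391, 0x03C9), 0x03A2)
  if (n > length(cp)) stop("radical alphabet exhausted (max ", length(cp), ")")
  vapply(cp[seq_len(n)], intToUtf8, character(1))
}

#' Generate a synthetic NER world: corpora, dictionary, radical table
#'
#' @param config a [synth_config()].
#' @return list with labeled `train`, `dev`, `test` corpora, `unlabeled`
#'   sentences, the `dictionary`, the `radicals` table, and a `manifest`
#'   recording every planted span (split, sentence, start, end, type,
#'   dictionary id) plus the generating configuration.
#' @export
generate_synth <- function(config = synth_config()) {
  cfg <- config
  set.seed(cfg$seed)
  K <- cfg$n_types
  types <- paste0("T", seq_len(K))
  n_chars <- K * cfg$chars_per_type + cfg$background_chars
  chars <- synth_char_alphabet(n_chars)
  pools <- split(chars[seq_len(K * cfg$chars_per_type)],
                 rep(seq_len(K), each = cfg$chars_per_type))
  background <- chars[(K * cfg$chars_per_type + 1L):n_chars]
  radicals <- synth_radical_alphabet(K + cfg$n_neutral_radicals)
  type_rad <- radicals[seq_len(K)]
  neutral_rad <- radicals[(K + 1L):(K + cfg$n_neutral_radicals)]
  # radical assignment per character
  rad_of <- character(n_chars)
  names(rad_of) <- chars
  for (k in seq_len(K)) {
    for (ch in pools[[k]]) {
      rad_of[ch] <- if (stats::runif(1) < cfg$rho) type_rad[k]
                    else sample(radicals, 1L)
    }
  }
  rad_of[background] <- sample(neutral_rad, length(background), replace = TRUE)
  rtab <- radical_table(chars, unname(rad_of))
  # dictionary: unique surfaces from type pools; ambiguous surfaces draw
  # their characters from a different type's pool
  surfaces <- character(0); s_types <- character(0)
  while (length(surfaces) < cfg$dict_size) {
    ty <- sample.int(K, 1L)
    src <- if (K > 1L && stats::runif(1) < cfg$ambiguity)
      sample(setdiff(seq_len(K), ty), 1L) else ty
    len <- sample(seq(cfg$entity_len[1], cfg$entity_len[2]), 1L)
    surf <- paste(sample(pools[[src]], len, replace = TRUE), collapse = "")
    if (!(surf %in% surfaces)) {
      surfaces <- c(surfaces, surf)
      s_types <- c(s_types, types[ty])
    }
  }
  dict <- entity_dictionary(surfaces, s_types)
  make_sentence <- function() {
    n_ent <- min(stats::rpois(1L, cfg$entities_per_sentence), 4L)
    b <- sample(seq(cfg$sentence_len[1], cfg$sentence_len[2]), 1L)
    bg <- sample(background, b, replace = TRUE)
    if (n_ent == 0L)
      return(list(chars = bg, labels = rep("O", b), spans = NULL))
    ids <- sample.int(nrow(dict), n_ent, replace = TRUE)
    # n_ent + 1 background runs; interior runs >= 1 so entities never touch
    n_int <- max(0L, n_ent - 1L)
    rem <- b - n_int
    runs <- as.vector(stats::rmultinom(1L, rem, rep(1, n_ent + 1L))) +
      c(0L, rep(1L, n_int), 0L)
    chars_out <- character(0); labels_out <- character(0)
    spans <- data.frame(start = integer(), end = integer(),
                        type = character(), id = integer())
    pos <- cumsum(c(0L, runs[1]))
    used <- 0L
    for (j in seq_len(n_ent)) {
      take <- bg[seq_len(runs[j]) + used]; used <- used + runs[j]
      chars_out <- c(chars_out, take)
      labels_out <- c(labels_out, rep("O", runs[j]))
      sc <- strsplit(dict$surface[ids[j]], "", fixed = TRUE)[[1]]
      st <- length(chars_out) + 1L
      chars_out <- c(chars_out, sc)
      labels_out <- c(labels_out, paste0("B-", dict$type[ids[j]]),
                      rep(paste0("I-", dict$type[ids[j]]), length(sc) - 1L))
      spans <- rbind(spans, data.frame(start = st,
                                       end = st + length(sc) - 1L,
                                       type = dict$type[ids[j]],
                                       id = dict$id[ids[j]]))
    }
    tail_run <- runs[n_ent + 1L]
    if (tail_run > 0L) {
      take <- bg[seq_len(tail_run) + used]
      chars_out <- c(chars_out, take)
      labels_out <- c(labels_out, rep("O", tail_run))
    }
    list(chars = chars_out, labels = labels_out, spans = spans)
  }
  gen_split <- function(n, split, labeled = TRUE) {
    out <- vector("list", n)
    spans_all <- NULL
    for (i in seq_len(n)) {
      s <- make_sentence()
      out[[i]] <- bio_sentence(s$chars, if (labeled) s$labels else NULL)
      if (!is.null(s$spans) && nrow(s$spans) > 0L)
        spans_all <- rbind(spans_all,
                           cbind(data.frame(split = split, sentence = i),
                                 s$spans))
    }
    list(corpus = out, spans = spans_all)
  }
  tr <- gen_split(cfg$n_train, "train")
  de <- gen_split(cfg$n_dev, "dev")
  te <- gen_split(cfg$n_test, "test")
  un <- gen_split(cfg$n_unlabeled, "unlabeled", labeled = FALSE)
  manifest <- list(config = unclass(cfg),
                   types = types,
                   spans = rbind(tr$spans, de$spans, te$spans, un$spans))
  list(train = tr$corpus, dev = de$corpus, test = te$corpus,
       unlabeled = un$corpus, dictionary = dict, radicals = rtab,
       manifest = manifest)
}

#' Split a labeled corpus into a labeled subset and an unlabeled remainder
#'
#' Seeded sentence-level split used for semi-supervised experiments: the
#' remainder is stripped of its tags.
#'
#' @param corpus labeled corpus.
#' @param fraction fraction kept labeled, in `(0, 1]`.
#' @param seed RNG seed.
#' @return list with `labeled` and `unlabeled` (tag-stripped) corpora.
#' @export
degrade_labels <- function(corpus, fraction, seed = 1L) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  set.seed(seed)
  n <- length(corpus)
  n_lab <- round(n * fraction)
  idx <- sample.int(n, n_lab)
  list(labeled = corpus[idx],
       unlabeled = lapply(corpus[setdiff(seq_len(n), idx)],
                          function(s) bio_sentence(s$chars)))
}

#' Write a generated synthetic world to a directory
#'
#' Emits `train.bio`, `dev.bio`, `test.bio` (CoNLL BIO), `unlabeled.txt`,
#' `dictionary.tsv`, `radicals.tsv` and `manifest.json`.
#'
#' @param data result of [generate_synth()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synth <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_bio_corpus(data$train, file.path(dir, "train.bio"))
  write_bio_corpus(data$dev, file.path(dir, "dev.bio"))
  write_bio_corpus(data$test, file.path(dir, "test.bio"))
  write_unlabeled_corpus(data$unlabeled, file.path(dir, "unlabeled.txt"))
  write_entity_dictionary(data$dictionary, file.path(dir, "dictionary.tsv"))
  write_radical_table(data$radicals, file.path(dir, "radicals.tsv"))
  jsonlite::write_json(data$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
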