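# Shared fixtures and independent brute-force oracles.

write_tmp_lines <- function(lines) {
  path <- tempfile()
  con <- file(path, open = "wb")
  writeLines(lines, con)
  close(con)
  path
}

# brute-force maximum-matching oracle: enumerate every (start, surface)
# occurrence, then per position take the longest covering occurrence,
# breaking ties by earliest start then lowest id
oracle_match <- function(chars, dict) {
  T_ <- length(chars)
  out <- integer(T_)
  if (T_ == 0L) return(out)
  occ <- list()
  for (k in seq_len(nrow(dict))) {
    sc <- strsplit(dict$surface[k], "", fixed = TRUE)[[1]]
    L <- length(sc)
    if (L > T_) next
    for (s in 1:(T_ - L + 1L)) {
      if (identical(chars[s:(s + L - 1L)], sc))
        occ[[length(occ) + 1L]] <- c(start = s, len = L, id = dict$id[k])
    }
  }
  for (t in seq_len(T_)) {
    cand <- Filter(function(o) o["start"] <= t && t <= o["start"] + o["len"] - 1,
                   occ)
    if (length(cand) == 0L) next
    best <- cand[[1]]
    for (o in cand[-1]) {
      if (o["len"] > best["len"] ||
          (o["len"] == best["len"] && o["start"] < best["start"]) ||
          (o["len"] == best["len"] && o["start"] == best["start"] &&
           o["id"] < best["id"])) best <- o
    }
    out[t] <- best["id"]
  }
  out
}

# enumerate all L^T paths of a linear-chain CRF: exact logZ and best path
oracle_crf <- function(emissions, transitions) {
  T_ <- nrow(emissions); L <- ncol(emissions)
  paths <- as.matrix(expand.grid(rep(list(seq_len(L)), T_)))[, T_:1, drop = FALSE]
  scores <- apply(paths, 1L, function(p)
    crf_path_score(emissions, transitions, as.integer(p)))
  list(logZ = max(scores) + log(sum(exp(scores - max(scores)))),
       best_score = max(scores),
       best_path = as.integer(paths[which.max(scores), ]))
}

# independent implementation of the normalized geometric-mean attention row:
# w_j = sqrt(s_j^c s_j^e) / sum_j sqrt(s_j^c s_j^e)
oracle_geomean_row <- function(q, Kc, Ke, dk) {
  s_c <- exp(as.vector(q %*% t(Kc)) / sqrt(dk))
  s_e <- exp(as.vector(q %*% t(Ke)) / sqrt(dk))
  w <- sqrt(s_c * s_e)
  w / sum(w)
}

random_dictionary <- function(n_entries, alphabet, max_len = 5L) {
  surfs <- character(0)
  while (length(surfs) < n_entries) {
    s <- paste(sample(alphabet, sample(1:max_len, 1L), replace = TRUE),
               collapse = "")
    if (!(s %in% surfs)) surfs <- c(surfs, s)
  }
  entity_dictionary(surfs, sample(c("A", "B"), n_entries, replace = TRUE))
}

tiny_config <- function(...) {
  defaults <- list(layers = 1L, heads = 2L, H_c = 16L, H_e = 8L, dropout = 0,
                   max_len = 32L, filters = 4L, feature_dim = 8L)
  do.call(lexner_config, utils::modifyList(defaults, list(...)))
}

tiny_params <- function(cfg = tiny_config(), vocab = 10L, ents = 4L,
                        rads = 5L, types = 2L, seed = 1L) {
  set.seed(seed)
  lexner:::model_init_params(cfg, vocab, ents, rads, types)
}

# small labeled world shared by training tests
tiny_world <- function(seed = 21L, n_train = 24L, n_dev = 8L, n_test = 8L,
                       n_unlabeled = 0L, ...) {
  generate_synth(synth_config(n_train = n_train, n_dev = n_dev,
                              n_test = n_test, n_unlabeled = n_unlabeled,
                              seed = seed, ...))
}
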