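test_that("generation is byte-identical under a fixed seed", {
  cfg <- synth_config(n_train = 15L, n_dev = 5L, n_test = 5L,
                      n_unlabeled = 20L, seed = 33L)
  d1 <- generate_synth(cfg)
  d2 <- generate_synth(cfg)
  t1 <- tempfile(); t2 <- tempfile()
  write_synth(d1, t1)
  write_synth(d2, t2)
  for (f in c("train.bio", "dev.bio", "test.bio", "unlabeled.txt",
              "dictionary.tsv", "radicals.tsv")) {
    expect_identical(readBin(file.path(t1, f), "raw", file.size(file.path(t1, f))),
                     readBin(file.path(t2, f), "raw", file.size(file.path(t2, f))),
                     label = f)
  }
})

test_that("emitted files parse back to the generated corpus and manifest", {
  cfg <- synth_config(n_train = 30L, n_dev = 5L, n_test = 5L, seed = 9L)
  d <- generate_synth(cfg)
  dir <- tempfile()
  write_synth(d, dir)
  back <- read_bio_corpus(file.path(dir, "train.bio"))
  expect_length(back, 30L)
  expect_identical(lapply(back, `[[`, "labels"),
                   lapply(d$train, `[[`, "labels"))
  # every manifest span matches the labels in the emitted corpus
  sp <- d$manifest$spans
  tr_sp <- sp[sp$split == "train", ]
  parsed_n <- sum(vapply(back, function(s) nrow(entity_spans(s$labels)),
                         integer(1)))
  expect_equal(parsed_n, nrow(tr_sp))
  for (k in seq_len(min(nrow(tr_sp), 50L))) {
    row <- tr_sp[k, ]
    labs <- back[[row$sentence]]$labels
    expect_equal(labs[row$start], paste0("B-", row$type))
    if (row$end > row$start)
      expect_true(all(labs[(row$start + 1):row$end] == paste0("I-", row$type)))
  }
  # dictionary round-trips and every planted surface is a dictionary entry
  dict <- read_entity_dictionary(file.path(dir, "dictionary.tsv"))
  expect_identical(dict$surface, d$dictionary$surface)
  for (k in seq_len(min(nrow(tr_sp), 30L))) {
    row <- tr_sp[k, ]
    surf <- paste(back[[row$sentence]]$chars[row$start:row$end], collapse = "")
    expect_true(surf %in% dict$surface)
  }
})

test_that("maximum matching fully covers planted spans", {
  d <- generate_synth(synth_config(n_train = 25L, n_dev = 0L, n_test = 0L,
                                   seed = 14L))
  sp <- d$manifest$spans
  sp <- sp[sp$split == "train", ]
  for (i in unique(sp$sentence)) {
    tags <- match_entities(d$train[[i]]$chars, d$dictionary)
    rows <- sp[sp$sentence == i, ]
    for (k in seq_len(nrow(rows)))
      expect_true(all(tags[rows$start[k]:rows$end[k]] > 0L))
  }
})

test_that("rho = 1 makes every entity character carry its type radical", {
  d <- generate_synth(synth_config(n_types = 2L, rho = 1, n_train = 20L,
                                   n_dev = 0L, n_test = 0L, seed = 4L))
  sp <- d$manifest$spans
  type_rad <- lexner:::synth_radical_alphabet(2L)
  names(type_rad) <- c("T1", "T2")
  for (k in seq_len(nrow(sp))) {
    row <- sp[k, ]
    ch <- d$train[[row$sentence]]$chars[row$start:row$end]
    surf_type <- d$dictionary$type[row$id]
    expect_true(all(radical_lookup(ch, d$radicals) == type_rad[surf_type]))
  }
})

test_that("ambiguous surfaces are typed by the dictionary, not their characters", {
  d <- generate_synth(synth_config(n_types = 3L, ambiguity = 1, rho = 1,
                                   n_train = 5L, n_dev = 0L, n_test = 0L,
                                   seed = 8L))
  # with ambiguity 1 every surface's characters come from a different
  # type's pool than its assigned label
  type_rad <- lexner:::synth_radical_alphabet(3L)
  names(type_rad) <- paste0("T", 1:3)
  mismatches <- vapply(seq_len(nrow(d$dictionary)), function(k) {
    ch <- strsplit(d$dictionary$surface[k], "")[[1]]
    rad <- radical_lookup(ch, d$radicals)
    all(rad != type_rad[d$dictionary$type[k]])
  }, logical(1))
  expect_true(all(mismatches))
})

test_that("degrade_labels splits and conserves the corpus", {
  d <- generate_synth(synth_config(n_train = 50L, n_dev = 0L, n_test = 0L,
                                   seed = 3L))
  sp <- degrade_labels(d$train, 0.3, seed = 6L)
  expect_length(sp$labeled, 15L)
  expect_length(sp$unlabeled, 35L)
  expect_true(all(vapply(sp$unlabeled, function(s) is.null(s$labels),
                         logical(1))))
  # conservation of the sentence multiset (compare character strings)
  str_of <- function(s) paste(s$chars, collapse = "")
  expect_setequal(c(vapply(sp$labeled, str_of, character(1)),
                    vapply(sp$unlabeled, str_of, character(1))),
                  vapply(d$train, str_of, character(1)))
  full <- degrade_labels(d$train, 1, seed = 6L)
  expect_length(full$unlabeled, 0L)
  expect_error(degrade_labels(d$train, 0, seed = 1L), "fraction")
  expect_error(degrade_labels(d$train, 1.2, seed = 1L), "fraction")
})

test_that("corpus statistics track the configuration", {
  cfg <- synth_config(n_train = 200L, n_dev = 0L, n_test = 0L,
                      entities_per_sentence = 2, sentence_len = c(12L, 20L),
                      seed = 17L)
  d <- generate_synth(cfg)
  sp <- d$manifest$spans
  # mean planted entities per sentence near the (truncated) Poisson mean
  expect_gt(nrow(sp) / 200, 1.4)
  expect_lt(nrow(sp) / 200, 2.4)
  lens <- vapply(d$train, function(s) length(s$chars), integer(1))
  ent_chars <- sum(sp$end - sp$start + 1)
  bg_chars <- sum(lens) - ent_chars
  expect_gt(bg_chars / 200, 11.9)
  expect_lt(bg_chars / 200, 20.1)
  # entity lengths within the configured range
  expect_true(all(sp$end - sp$start + 1 >= cfg$entity_len[1]))
  expect_true(all(sp$end - sp$start + 1 <= cfg$entity_len[2]))
})
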