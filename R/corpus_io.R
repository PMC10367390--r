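#' Construct a labeled sentence
#'
#' A sentence is a list with a character vector of single-character tokens
#' (`chars`) and, optionally, a parallel vector of BIO-type tags (`labels`),
#' e.g. `"B-Dis"`, `"I-Dis"`, `"O"`.  Corpora are plain lists of sentences.
#'
#' @param chars character vector of tokens (one character each).
#' @param labels character vector of BIO-type tags of the same length, or
#'   `NULL` for an unlabeled sentence.
#' @return a list of class `"bio_sentence"`.
#' @export
bio_sentence <- function(chars, labels = NULL) {
  chars <- as.character(chars)
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != length(chars))
      stop("labels and chars must have the same length")
  }
  structure(list(chars = chars, labels = labels), class = "bio_sentence")
}

## ---- tag parsing -----------------------------------------------------------

parse_tag <- function(tag) {
  # returns list(prefix, type); type NA for "O"
  if (tag == "O") return(list(prefix = "O", type = NA_character_))
  if (nchar(tag) >= 3 && substr(tag, 2, 2) == "-" &&
      substr(tag, 1, 1) %in% c("B", "I")) {
    return(list(prefix = substr(tag, 1, 1), type = substr(tag, 3, nchar(tag))))
  }
  stop("unknown tag prefix in tag '", tag, "'")
}

tag_prefix <- function(labels) {
  ifelse(labels == "O", "O", substr(labels, 1, 1))
}

tag_type <- function(labels) {
  ifelse(labels == "O", NA_character_, substr(labels, 3, nchar(labels)))
}

#' Repair a BIO tag sequence
#'
#' Promotes orphan `I-X` tags (an `I-X` not preceded by `B-X` or `I-X`) to
#' `B-X` so the sequence is scheme-valid.
#'
#' @param labels character vector of BIO-type tags.
#' @return repaired character vector.
#' @export
repair_bio <- function(labels) {
  if (length(labels) == 0L) return(labels)
  pre <- tag_prefix(labels)
  bad <- pre %in% c("O", "B", "I")
  if (!all(bad)) stop("unknown tag prefix in tag '", labels[which(!bad)[1]], "'")
  ty <- tag_type(labels)
  out <- labels
  prev_ty <- NA_character_
  prev_in <- FALSE
  for (t in seq_along(labels)) {
    if (pre[t] == "I") {
      if (!prev_in || !identical(prev_ty, ty[t])) {
        out[t] <- paste0("B-", ty[t])
      }
      prev_in <- TRUE
      prev_ty <- ty[t]
    } else if (pre[t] == "B") {
      prev_in <- TRUE
      prev_ty <- ty[t]
    } else {
      prev_in <- FALSE
      prev_ty <- NA_character_
    }
  }
  out
}

validate_bio <- function(labels) {
  identical(labels, repair_bio(labels))
}

## ---- corpus reading / writing ---------------------------------------------

#' Read a CoNLL-style BIO corpus
#'
#' One token and tag per line separated by a TAB, blank line between
#' sentences, UTF-8.
#'
#' @param path file path.
#' @param scheme `"repair"` (orphan `I-X` promoted to `B-X`) or `"strict"`
#'   (orphan tags are an error).
#' @return list of [bio_sentence()] objects, in file order.
#' @export
read_bio_corpus <- function(path, scheme = c("repair", "strict")) {
  scheme <- match.arg(scheme)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  sentences <- list()
  chars <- character()
  labels <- character()
  flush <- function() {
    if (length(chars) > 0L) {
      labs <- if (scheme == "repair") repair_bio(labels) else {
        if (!validate_bio(labels))
          stop("orphan I- tag under strict scheme in sentence ending before line ",
               i, " of ", path)
        labels
      }
      sentences[[length(sentences) + 1L]] <<- bio_sentence(chars, labs)
      chars <<- character(); labels <<- character()
    }
  }
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (line == "") { flush(); next }
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("malformed line ", i, " of ", path, ": expected 2 TAB-separated columns")
    parse_tag(parts[2])  # validates the prefix early, with the line number
    chars <- c(chars, parts[1])
    labels <- c(labels, parts[2])
  }
  flush()
  sentences
}

#' Write a BIO corpus
#'
#' @param corpus list of [bio_sentence()] objects (all labeled).
#' @param path output file path.
#' @export
write_bio_corpus <- function(corpus, path) {
  blocks <- vapply(corpus, function(s) {
    if (is.null(s$labels)) stop("cannot write unlabeled sentence to BIO file")
    paste0(paste(s$chars, s$labels, sep = "\t", collapse = "\n"), "\n")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(blocks, con, sep = "\n", useBytes = FALSE)
  invisible(path)
}

#' Read an unlabeled corpus (one sentence of characters per line)
#' @param path file path.
#' @return list of unlabeled [bio_sentence()] objects.
#' @export
read_unlabeled_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[lines != ""]
  lapply(lines, function(x) bio_sentence(strsplit(x, "", fixed = TRUE)[[1]]))
}

#' Write an unlabeled corpus (characters concatenated, one sentence per line)
#' @param corpus list of sentences.
#' @param path output path.
#' @export
write_unlabeled_corpus <- function(corpus, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(vapply(corpus, function(s) paste(s$chars, collapse = ""),
                    character(1)), con)
  invisible(path)
}

## ---- dual-branch label conversion -----------------------------------------

#' Split BIO-type labels into boundary and type branches
#'
#' The dual-branch decoder supervises entity boundaries (`B`/`I`/`O`) and
#' entity types separately; this decomposes gold tags into those two targets.
#'
#' @param sentence a labeled [bio_sentence()], or a character vector of tags.
#' @return list of class `"branch_labels"` with `boundary` (over B/I/O) and
#'   `types` (type name per token, `NA` for O).
#' @export
split_labels <- function(sentence) {
  labels <- if (inherits(sentence, "bio_sentence")) sentence$labels else sentence
  if (is.null(labels)) stop("sentence is unlabeled")
  structure(list(boundary = tag_prefix(labels), types = tag_type(labels)),
            class = "branch_labels")
}

#' Merge boundary and type predictions into BIO-type labels
#'
#' Inverse of [split_labels()] for valid inputs; for raw predictions each
#' maximal `B..I` run in the boundary path becomes one span whose single type
#' is chosen by [resolve_span_type()].
#'
#' @param branch a `"branch_labels"` list, or the boundary vector itself.
#' @param types per-token type names (used when `branch` is a vector).
#' @param type_prob optional `T x K` matrix of per-token type probabilities
#'   (columns named by type) used for tie-breaking.
#' @return character vector of BIO-type tags.
#' @export
merge_labels <- function(branch, types = NULL, type_prob = NULL) {
  if (inherits(branch, "branch_labels")) {
    boundary <- branch$boundary
    types <- branch$types
  } else boundary <- branch
  T_ <- length(boundary)
  labels <- rep("O", T_)
  if (T_ == 0L) return(labels)
  spans <- boundary_spans(boundary)
  for (k in seq_len(nrow(spans))) {
    s <- spans$start[k]; e <- spans$end[k]
    ty <- resolve_span_type(types[s:e], if (is.null(type_prob)) NULL else
      type_prob[s:e, , drop = FALSE])
    labels[s] <- paste0("B-", ty)
    if (e > s) labels[(s + 1):e] <- paste0("I-", ty)
  }
  labels
}

# maximal B..I runs in a raw boundary path; orphan I starts a new span
boundary_spans <- function(boundary) {
  starts <- integer(); ends <- integer()
  open <- FALSE
  for (t in seq_along(boundary)) {
    if (boundary[t] == "B") {
      starts <- c(starts, t); ends <- c(ends, t); open <- TRUE
    } else if (boundary[t] == "I") {
      if (open) ends[length(ends)] <- t
      else { starts <- c(starts, t); ends <- c(ends, t); open <- TRUE }
    } else open <- FALSE
  }
  data.frame(start = starts, end = ends)
}

#' Resolve the single type of a predicted span
#'
#' Majority vote over the span tokens' argmax types; ties broken by highest
#' mean type probability, then lowest column index.  A span whose every vote
#' is `NA` (no entity type) takes the non-`NA` type with the highest mean
#' probability.
#'
#' @param span_types type votes (one per token; `NA` = no-entity vote).
#' @param span_prob optional per-token probability matrix with one named
#'   column per type (a no-entity column, if present, must be named `"O"`).
#' @return a single type name.
#' @export
resolve_span_type <- function(span_types, span_prob = NULL) {
  votes <- span_types[!is.na(span_types)]
  type_names <- if (!is.null(span_prob)) setdiff(colnames(span_prob), "O")
                else unique(votes)
  mean_prob <- function(ty) {
    if (is.null(span_prob) || !(ty %in% colnames(span_prob))) 0
    else mean(span_prob[, ty])
  }
  if (length(votes) == 0L) {
    if (length(type_names) == 0L) return("UNK")
    mp <- vapply(type_names, mean_prob, numeric(1))
    return(type_names[which.max(mp)])
  }
  tab <- table(votes)
  top <- names(tab)[tab == max(tab)]
  if (length(top) == 1L) return(top)
  mp <- vapply(top, mean_prob, numeric(1))
  top[which.max(mp)]   # which.max: lowest index on residual ties
}

## ---- entity-level metrics --------------------------------------------------

#' Extract entity spans from BIO-type labels
#' @param labels character vector of tags (repaired if necessary).
#' @return data.frame with columns `start`, `end`, `type`.
#' @export
entity_spans <- function(labels) {
  labels <- repair_bio(labels)
  pre <- tag_prefix(labels)
  ty <- tag_type(labels)
  starts <- integer(); ends <- integer(); types <- character()
  for (t in seq_along(labels)) {
    if (pre[t] == "B") {
      starts <- c(starts, t); ends <- c(ends, t); types <- c(types, ty[t])
    } else if (pre[t] == "I") {
      ends[length(ends)] <- t
    }
  }
  data.frame(start = starts, end = ends, type = types,
             stringsAsFactors = FALSE)
}

#' Entity-level precision, recall and F1
#'
#' Exact-match spans: a predicted entity counts as a true positive only when
#' its start, end and type all equal a gold entity's.  Micro scores pool
#' counts over all types; per-type rows condition on the gold/predicted type.
#' A zero denominator yields 0 by convention.
#'
#' @param gold,pred equally shaped lists of labeled sentences.
#' @return list with `micro` (precision, recall, f1) and `per_type`
#'   data.frame (type, tp, fp, fn, precision, recall, f1).
#' @export
entity_f1 <- function(gold, pred) {
  if (length(gold) != length(pred))
    stop("gold and pred have different numbers of sentences")
  key <- function(i, sp) {
    if (nrow(sp) == 0L) return(character(0))
    paste(i, sp$start, sp$end, sp$type, sep = ":")
  }
  gold_keys <- character(); gold_types <- character()
  pred_keys <- character(); pred_types <- character()
  for (i in seq_along(gold)) {
    gs <- gold[[i]]; ps <- pred[[i]]
    if (length(gs$chars) != length(ps$chars))
      stop("sentence ", i, " differs in length between gold and pred")
    g <- entity_spans(gs$labels); p <- entity_spans(ps$labels)
    gold_keys <- c(gold_keys, key(i, g)); gold_types <- c(gold_types, g$type)
    pred_keys <- c(pred_keys, key(i, p)); pred_types <- c(pred_types, p$type)
  }
  hit <- pred_keys %in% gold_keys
  safe_div <- function(a, b) if (b == 0) 0 else a / b
  prf <- function(tp, fp, fn) {
    p <- safe_div(tp, tp + fp); r <- safe_div(tp, tp + fn)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    c(precision = p, recall = r, f1 = f)
  }
  types <- sort(unique(c(gold_types, pred_types)))
  per_type <- do.call(rbind, lapply(types, function(ty) {
    tp <- sum(hit & pred_types == ty)
    fp <- sum(!hit & pred_types == ty)
    fn <- sum(!(gold_keys %in% pred_keys) & gold_types == ty)
    data.frame(type = ty, tp = tp, fp = fp, fn = fn, t(prf(tp, fp, fn)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(per_type))
    per_type <- data.frame(type = character(), tp = integer(), fp = integer(),
                           fn = integer(), precision = numeric(),
                           recall = numeric(), f1 = numeric())
  tp <- sum(hit); fp <- sum(!hit); fn <- sum(!(gold_keys %in% pred_keys))
  list(micro = as.list(prf(tp, fp, fn)), per_type = per_type)
}

## ---- entity dictionary -----------------------------------------------------

#' Construct an entity dictionary
#'
#' An ordered gazetteer of entity surfaces.  Integer ids are dense, start at
#' 1 and follow insertion order; id 0 is reserved for "no matching entity"
#' and is never assigned to an entry.
#'
#' @param surfaces character vector of entity surface strings (non-empty).
#' @param types parallel character vector of type names.
#' @return data.frame of class `"entity_dictionary"` with columns `id`,
#'   `surface`, `type`.
#' @export
entity_dictionary <- function(surfaces, types) {
  surfaces <- as.character(surfaces); types <- as.character(types)
  if (length(surfaces) != length(types))
    stop("surfaces and types must have the same length")
  if (any(nchar(surfaces) == 0)) stop("empty entity surface")
  dup <- duplicated(surfaces)
  if (any(dup)) {
    warning("duplicate dictionary surface(s) dropped: ",
            paste(unique(surfaces[dup]), collapse = ", "))
    surfaces <- surfaces[!dup]; types <- types[!dup]
  }
  structure(data.frame(id = seq_along(surfaces), surface = surfaces,
                       type = types, stringsAsFactors = FALSE),
            class = c("entity_dictionary", "data.frame"))
}

#' Read an entity dictionary file (`surface TAB type`, one per line)
#' @param path file path.
#' @return an [entity_dictionary()].
#' @export
read_entity_dictionary <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[lines != ""]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 2L)
  if (length(bad) > 0L)
    stop("malformed line ", bad[1], " of ", path, ": expected 2 columns")
  surfaces <- vapply(parts, `[`, character(1), 1)
  if (any(surfaces == "")) stop("empty entity surface in ", path)
  entity_dictionary(surfaces, vapply(parts, `[`, character(1), 2))
}

#' Write an entity dictionary file
#' @param dict an [entity_dictionary()].
#' @param path output path.
#' @export
write_entity_dictionary <- function(dict, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(dict$surface, dict$type, sep = "\t"), con)
  invisible(path)
}

## ---- radical table ---------------------------------------------------------

#' Construct a radical table
#'
#' Maps each character to its semantic sub-character component (radical).
#' Lookup is total: characters absent from the table resolve to a reserved
#' unknown-radical symbol that owns its own embedding row.
#'
#' @param chars character vector of characters.
#' @param radicals parallel vector of radical symbols.
#' @param unknown_radical symbol returned for unmapped characters.
#' @return list of class `"radical_table"`.
#' @export
radical_table <- function(chars, radicals, unknown_radical = "<unk>") {
  if (length(chars) != length(radicals))
    stop("chars and radicals must have the same length")
  map <- as.character(radicals)
  names(map) <- as.character(chars)
  if (anyDuplicated(names(map))) map <- map[!duplicated(names(map))]
  structure(list(map = map, unknown_radical = unknown_radical),
            class = "radical_table")
}

#' Read a radical table file (`char TAB radical`, one per line)
#' @param path file path.
#' @param unknown_radical symbol for unmapped characters.
#' @return a [radical_table()].
#' @export
read_radical_table <- function(path, unknown_radical = "<unk>") {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[lines != ""]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 2L)
  if (length(bad) > 0L)
    stop("malformed line ", bad[1], " of ", path, ": expected 2 columns")
  radical_table(vapply(parts, `[`, character(1), 1),
                vapply(parts, `[`, character(1), 2),
                unknown_radical = unknown_radical)
}

#' Write a radical table file
#' @param table a [radical_table()].
#' @param path output path.
#' @export
write_radical_table <- function(table, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(table$map), table$map, sep = "\t"), con)
  invisible(path)
}

#' Look up radicals for a character sequence
#' @param chars character vector.
#' @param table a [radical_table()].
#' @return character vector of radical symbols (total: unknowns map to the
#'   reserved symbol).
#' @export
radical_lookup <- function(chars, table) {
  out <- unname(table$map[chars])
  out[is.na(out)] <- table$unknown_radical
  out
}
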