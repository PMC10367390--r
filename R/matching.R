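#' Maximum entity matching against a dictionary
#'
#' Labels each character position with the integer id of the longest
#' dictionary surface that occurs in the sentence as a contiguous substring
#' covering that position; positions covered by no surface get 0.  The rule
#' is per position (argmax over covering occurrences), not a left-to-right
#' greedy segmentation.  Ties on length are broken by earliest occurrence
#' start, then by lowest dictionary id, so the result is deterministic.
#'
#' @param chars character vector of single-character tokens (may be empty).
#' @param dict an [entity_dictionary()].
#' @return integer vector of entity ids, same length as `chars`.
#' @export
match_entities <- function(chars, dict) {
  T_ <- length(chars)
  tags <- integer(T_)
  if (T_ == 0L || nrow(dict) == 0L) return(tags)
  # best (length, start, id) per position, in tie-break order
  best_len <- integer(T_); best_start <- integer(T_); best_id <- integer(T_)
  surf_chars <- strsplit(dict$surface, "", fixed = TRUE)
  lens <- lengths(surf_chars)
  ord <- order(dict$id)  # ids are file order already; explicit for clarity
  for (k in ord) {
    sc <- surf_chars[[k]]
    L <- lens[k]
    if (L > T_) next
    id <- dict$id[k]
    for (start in 1:(T_ - L + 1L)) {
      if (all(chars[start:(start + L - 1L)] == sc)) {
        for (t in start:(start + L - 1L)) {
          better <- L > best_len[t] ||
            (L == best_len[t] && (start < best_start[t] ||
               (start == best_start[t] && id < best_id[t])))
          if (better) {
            best_len[t] <- L; best_start[t] <- start; best_id[t] <- id
          }
        }
      }
    }
  }
  best_id
}
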