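# Linear-chain CRF over boundary labels {B, I, O}.
#
# A path's score is the sum of transition scores (including virtual start and
# stop transitions) and per-position emission scores; the training loss is
# the negative log-likelihood, with the partition function computed by the
# forward recursion in log space.  An optional hard constraint forbids the
# transitions O -> I and start -> I with a large negative pseudo-score.

CRF_NEG_INF <- -1e4

boundary_label_set <- function() c("B", "I", "O")

crf_init <- function(H, forbid = TRUE) {
  list(emit_W = rnorm_mat(H, 3L), emit_b = rep(0, 3L),
       trans = matrix(0, 3L, 3L), start = rep(0, 3L), stop = rep(0, 3L))
}

# constraint mask added to the raw (trainable) transition scores
crf_constraints <- function(forbid) {
  mask_t <- matrix(0, 3L, 3L)
  mask_s <- rep(0, 3L)
  if (forbid) {
    mask_t[3L, 2L] <- CRF_NEG_INF   # O -> I
    mask_s[2L] <- CRF_NEG_INF       # start -> I
  }
  list(trans = mask_t, start = mask_s)
}

crf_effective <- function(crf, forbid = TRUE) {
  m <- crf_constraints(forbid)
  list(trans = crf$trans + m$trans, start = crf$start + m$start,
       stop = crf$stop)
}

#' Score of one label path under a linear-chain CRF
#'
#' `S = start[y_1] + sum_t M[t, y_t] + sum_{t>1} A[y_{t-1}, y_t] + stop[y_T]`.
#'
#' @param emissions `T x L` matrix of per-position label scores.
#' @param transitions list with `trans` (`L x L`), `start`, `stop` (length L).
#' @param path integer label indices, length `T`.
#' @return scalar path score.
#' @export
crf_path_score <- function(emissions, transitions, path) {
  T_ <- nrow(emissions); L <- ncol(emissions)
  if (length(path) != T_) stop("path length does not match emissions")
  if (any(path < 1L | path > L)) stop("invalid label index in path")
  s <- transitions$start[path[1]] + transitions$stop[path[T_]] +
    sum(emissions[cbind(seq_len(T_), path)])
  if (T_ > 1L)
    s <- s + sum(transitions$trans[cbind(path[-T_], path[-1L])])
  s
}

#' Log partition function of a linear-chain CRF
#'
#' Log of the sum over every possible label sequence of the exponentiated
#' path score, via the forward recursion in log space.
#'
#' @inheritParams crf_path_score
#' @return scalar `log Z`.
#' @export
crf_log_partition <- function(emissions, transitions) {
  crf_forward(emissions, transitions)$logZ
}

# forward recursion; returns alphas (T x L, log space) and logZ
crf_forward <- function(emissions, transitions) {
  T_ <- nrow(emissions); L <- ncol(emissions)
  alpha <- matrix(0, T_, L)
  alpha[1L, ] <- transitions$start + emissions[1L, ]
  if (T_ > 1L) for (t in 2:T_) {
    # alpha[t, b] = logsumexp_a(alpha[t-1, a] + A[a, b]) + M[t, b]
    m <- alpha[t - 1L, ] + transitions$trans       # L x L (a rows, b cols)
    mx <- apply(m, 2L, max)
    alpha[t, ] <- mx + log(colSums(exp(sweep(m, 2L, mx, `-`)))) + emissions[t, ]
  }
  v <- alpha[T_, ] + transitions$stop
  list(alpha = alpha, logZ = log_sum_exp(v))
}

crf_backwardrec <- function(emissions, transitions) {
  T_ <- nrow(emissions); L <- ncol(emissions)
  beta <- matrix(0, T_, L)
  beta[T_, ] <- transitions$stop
  if (T_ > 1L) for (t in (T_ - 1L):1L) {
    # beta[t, a] = logsumexp_b(A[a, b] + M[t+1, b] + beta[t+1, b])
    m <- sweep(transitions$trans, 2L, emissions[t + 1L, ] + beta[t + 1L, ], `+`)
    mx <- apply(m, 1L, max)
    beta[t, ] <- mx + log(rowSums(exp(m - mx)))
  }
  beta
}

#' Negative log-likelihood of a gold path under a linear-chain CRF
#'
#' @inheritParams crf_path_score
#' @param path gold label indices.
#' @return scalar loss, always `>= 0`.
#' @export
crf_loss <- function(emissions, transitions, path) {
  crf_log_partition(emissions, transitions) -
    crf_path_score(emissions, transitions, path)
}

# loss + gradients wrt emissions and the raw transition parameters
crf_loss_grad <- function(emissions, transitions, path) {
  T_ <- nrow(emissions); L <- ncol(emissions)
  fw <- crf_forward(emissions, transitions)
  beta <- crf_backwardrec(emissions, transitions)
  logZ <- fw$logZ
  marg <- exp(fw$alpha + beta - logZ)             # P(y_t = l)
  d_em <- marg
  d_em[cbind(seq_len(T_), path)] <- d_em[cbind(seq_len(T_), path)] - 1
  d_start <- exp(transitions$start + emissions[1L, ] + beta[1L, ] - logZ)
  d_start[path[1L]] <- d_start[path[1L]] - 1
  d_stop <- exp(fw$alpha[T_, ] + transitions$stop - logZ)
  d_stop[path[T_]] <- d_stop[path[T_]] - 1
  d_trans <- matrix(0, L, L)
  if (T_ > 1L) {
    for (t in 2:T_) {
      pair <- exp(outer(fw$alpha[t - 1L, ], emissions[t, ] + beta[t, ], `+`) +
                    transitions$trans - logZ)
      d_trans <- d_trans + pair
    }
    cnt <- tabulate(path[-T_] + (path[-1L] - 1L) * L, nbins = L * L)
    d_trans <- d_trans - matrix(cnt, L, L)
  }
  loss <- logZ - crf_path_score(emissions, transitions, path)
  list(loss = loss, d_emissions = d_em, d_trans = d_trans,
       d_start = d_start, d_stop = d_stop)
}

#' Viterbi decoding of the best label path
#'
#' Returns the label sequence with the maximum path score; score ties are
#' broken deterministically toward the lexicographically smallest label
#' indices.
#'
#' @inheritParams crf_path_score
#' @return integer vector of label indices, length `T`.
#' @export
viterbi_decode <- function(emissions, transitions) {
  T_ <- nrow(emissions); L <- ncol(emissions)
  delta <- transitions$start + emissions[1L, ]
  bp <- matrix(0L, T_, L)
  if (T_ > 1L) for (t in 2:T_) {
    m <- delta + transitions$trans                # a rows, b cols
    best <- apply(m, 2L, which.max)               # first max = lowest index
    delta <- m[cbind(best, seq_len(L))] + emissions[t, ]
    bp[t, ] <- best
  }
  v <- delta + transitions$stop
  path <- integer(T_)
  path[T_] <- which.max(v)
  if (T_ > 1L) for (t in (T_ - 1L):1L) path[t] <- bp[t + 1L, path[t + 1L]]
  path
}
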