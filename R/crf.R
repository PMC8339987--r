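## Linear-chain conditional random field, implemented from scratch.
## A path score is sum of per-position emission scores plus transition
## scores between consecutive labels plus start/stop scores. All
## computations are in log space.

#' Create CRF parameters
#' @param label_set character vector of labels.
#' @param init initial score value (matrices are filled with it).
#' @return object of class `crf_params`: list(transitions LxL, start,
#'   stop, label_set).
#' @export
crf_params <- function(label_set, init = 0) {
  L <- length(label_set)
  structure(list(transitions = matrix(init, L, L,
                                      dimnames = list(label_set, label_set)),
                 start = stats::setNames(rep(init, L), label_set),
                 stop = stats::setNames(rep(init, L), label_set),
                 label_set = label_set),
            class = "crf_params")
}

check_emissions <- function(emissions, params) {
  if (!is.matrix(emissions) || nrow(emissions) < 1L) {
    stopf("emissions must be a matrix with at least one position")
  }
  if (ncol(emissions) != length(params$label_set)) {
    stopf("emissions have %d labels but params define %d",
          ncol(emissions), length(params$label_set))
  }
}

#' Log-partition function of a linear-chain CRF
#'
#' Equals the log of the sum over all label paths of exp(path score).
#'
#' @param emissions T x L matrix of per-position per-label scores.
#' @param params a `crf_params`.
#' @return scalar log-sum score.
#' @export
crf_log_partition <- function(emissions, params) {
  check_emissions(emissions, params)
  alpha <- params$start + emissions[1L, ]
  T_ <- nrow(emissions)
  for (t in seq_len(T_)[-1L]) {
    ## (trans + alpha)[i, j] = alpha[i] + trans[i -> j]
    alpha <- col_logsumexp(params$transitions + alpha) + emissions[t, ]
  }
  logsumexp(alpha + params$stop)
}

## score of one label path (1-based label indices)
crf_path_score <- function(emissions, params, path) {
  T_ <- nrow(emissions)
  s <- params$start[path[1L]] + sum(emissions[cbind(seq_len(T_), path)]) +
    params$stop[path[T_]]
  if (T_ > 1L) s <- s + sum(params$transitions[cbind(path[-T_], path[-1L])])
  unname(s)
}

## forward-backward: unary marginals, expected transition counts
crf_forward_backward <- function(emissions, params) {
  check_emissions(emissions, params)
  T_ <- nrow(emissions); L <- ncol(emissions)
  alpha <- matrix(0, T_, L); beta <- matrix(0, T_, L)
  alpha[1L, ] <- params$start + emissions[1L, ]
  for (t in seq_len(T_)[-1L]) {
    alpha[t, ] <- col_logsumexp(params$transitions + alpha[t - 1L, ]) + emissions[t, ]
  }
  logZ <- logsumexp(alpha[T_, ] + params$stop)
  beta[T_, ] <- params$stop
  for (t in rev(seq_len(T_ - 1L))) {
    ## beta[t, i] = logsumexp_j trans[i, j] + e[t+1, j] + beta[t+1, j]
    M <- sweep(params$transitions, 2L, emissions[t + 1L, ] + beta[t + 1L, ], "+")
    beta[t, ] <- col_logsumexp(t(M))
  }
  marg <- exp(alpha + beta - logZ)
  pair <- matrix(0, L, L)
  for (t in seq_len(T_)[-1L]) {
    Mt <- outer(alpha[t - 1L, ], emissions[t, ] + beta[t, ], "+") +
      params$transitions - logZ
    pair <- pair + exp(Mt)
  }
  list(logZ = logZ, marginals = marg, pair = pair)
}

## negative log-likelihood of a gold path and its gradients w.r.t.
## emissions and CRF parameters
crf_loss_grad <- function(emissions, params, gold) {
  fb <- crf_forward_backward(emissions, params)
  T_ <- nrow(emissions); L <- ncol(emissions)
  loss <- fb$logZ - crf_path_score(emissions, params, gold)
  d_em <- fb$marginals
  d_em[cbind(seq_len(T_), gold)] <- d_em[cbind(seq_len(T_), gold)] - 1
  d_trans <- fb$pair
  if (T_ > 1L) {
    idx <- cbind(gold[-T_], gold[-1L])
    for (k in seq_len(nrow(idx))) {
      d_trans[idx[k, 1L], idx[k, 2L]] <- d_trans[idx[k, 1L], idx[k, 2L]] - 1
    }
  }
  d_start <- fb$marginals[1L, ]; d_start[gold[1L]] <- d_start[gold[1L]] - 1
  d_stop <- fb$marginals[T_, ]; d_stop[gold[T_]] <- d_stop[gold[T_]] - 1
  list(loss = loss, d_emissions = d_em, d_transitions = d_trans,
       d_start = d_start, d_stop = d_stop)
}

#' Viterbi decoding
#'
#' Returns a maximum-scoring label path; score ties are broken toward the
#' lowest label index (via the first maximum at each backtracking step).
#'
#' @inheritParams crf_log_partition
#' @return integer vector of 1-based label indices (length = positions).
#' @export
viterbi_decode <- function(emissions, params) {
  check_emissions(emissions, params)
  T_ <- nrow(emissions); L <- ncol(emissions)
  delta <- matrix(-Inf, T_, L); psi <- matrix(1L, T_, L)
  delta[1L, ] <- params$start + emissions[1L, ]
  for (t in seq_len(T_)[-1L]) {
    M <- params$transitions + delta[t - 1L, ]   # M[i, j] = delta[i] + trans[i->j]
    psi[t, ] <- apply(M, 2L, which.max)
    delta[t, ] <- M[cbind(psi[t, ], seq_len(L))] + emissions[t, ]
  }
  fin <- delta[T_, ] + params$stop
  path <- integer(T_)
  path[T_] <- which.max(fin)
  for (t in rev(seq_len(T_ - 1L))) path[t] <- psi[t + 1L, path[t + 1L]]
  path
}
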