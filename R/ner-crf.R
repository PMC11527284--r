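# Linear-chain CRF primitives. Labels are 1..k; the transition matrix B is
# (k+2) x (k+2) with START = k+1 and STOP = k+2. A path y scores
#   B[START, y1] + sum_j B[y_j, y_{j+1}] + B[y_N, STOP] + sum_j P[j, y_j].
# The partition function is computed by the forward algorithm in log space;
# decoding by Viterbi with ties broken to the smallest label index.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

row_logsumexp <- function(M) {
  r <- M[, 1]
  for (j in seq_len(ncol(M))[-1]) r <- pmax(r, M[, j])
  r + log(rowSums(exp(M - r)))
}

crf_check <- function(B, P) {
  k <- ncol(P)
  if (nrow(B) != k + 2 || ncol(B) != k + 2) {
    abort("B must be (k+2) x (k+2) for k emission labels")
  }
  k
}

#' Score a label sequence under a linear-chain CRF
#'
#' @param B `(k+2) x (k+2)` transition matrix (rows/cols `1..k` are labels,
#'   `k+1` is START, `k+2` is STOP).
#' @param P `N x k` emission score matrix.
#' @param y Integer label sequence of length `N` with values in `1..k`.
#' @return The path score (transitions START -> y -> STOP plus emissions).
#' @export
crf_score <- function(B, P, y) {
  k <- crf_check(B, P)
  n <- nrow(P)
  if (length(y) != n) abort("length(y) must equal nrow(P)")
  if (any(y < 1 | y > k)) abort("label out of range")
  START <- k + 1L; STOP <- k + 2L
  trans <- B[START, y[1]] + B[y[n], STOP]
  if (n > 1) trans <- trans + sum(B[cbind(y[-n], y[-1])])
  trans + sum(P[cbind(seq_len(n), y)])
}

#' Log partition function of a linear-chain CRF
#'
#' `log sum_y exp(crf_score(B, P, y))` over all `k^N` label sequences,
#' computed by the forward algorithm in log space.
#'
#' @inheritParams crf_score
#' @return A single number.
#' @export
crf_log_partition <- function(B, P) {
  k <- crf_check(B, P)
  n <- nrow(P)
  START <- k + 1L; STOP <- k + 2L
  alpha <- B[START, 1:k] + P[1, ]
  if (n > 1) {
    for (t in 2:n) {
      alpha <- vapply(1:k, function(j) logsumexp(alpha + B[1:k, j]),
                      numeric(1)) + P[t, ]
    }
  }
  logsumexp(alpha + B[1:k, STOP])
}

#' Viterbi decoding of a linear-chain CRF
#'
#' Returns an argmax label sequence of [crf_score()]; at every backtrack
#' step ties break to the smallest label index.
#'
#' @inheritParams crf_score
#' @return A list with `y` (integer sequence) and `score`.
#' @export
viterbi_decode <- function(B, P) {
  k <- crf_check(B, P)
  n <- nrow(P)
  START <- k + 1L; STOP <- k + 2L
  delta <- B[START, 1:k] + P[1, ]
  psi <- matrix(0L, n, k)
  if (n > 1) {
    for (t in 2:n) {
      cand <- delta + B[1:k, 1:k]          # cand[i, j] = delta_i + B[i, j]
      best <- apply(cand, 2, which.max)    # first max = smallest index
      delta <- cand[cbind(best, 1:k)] + P[t, ]
      psi[t, ] <- best
    }
  }
  fin <- delta + B[1:k, STOP]
  y <- integer(n)
  y[n] <- which.max(fin)
  if (n > 1) {
    for (t in n:2) y[t - 1] <- psi[t, y[t]]
  }
  list(y = y, score = unname(fin[y[n]]))
}

# ---- batched CRF (training internals) -------------------------------------
# P_list: per time step a (batch x k) emission matrix; len: sentence lengths;
# y_mat: (batch x T) gold labels (NA on padding). Returns per-sentence logZ,
# gold scores, and the gradient pieces (dP per t, dB) of the mean NLL.

crf_batch_forward <- function(B, P_list, len) {
  k <- ncol(P_list[[1]])
  bsz <- nrow(P_list[[1]])
  Tm <- length(P_list)
  START <- k + 1L; STOP <- k + 2L
  alphas <- vector("list", Tm)
  alpha <- matrix(B[START, 1:k], bsz, k, byrow = TRUE) + P_list[[1]]
  alphas[[1]] <- alpha
  if (Tm > 1) {
    for (t in 2:Tm) {
      anew <- matrix(0, bsz, k)
      for (j in 1:k) {
        anew[, j] <- row_logsumexp(alpha + matrix(B[1:k, j], bsz, k,
                                                  byrow = TRUE))
      }
      anew <- anew + P_list[[t]]
      live <- len >= t
      alpha[live, ] <- anew[live, , drop = FALSE]
      alphas[[t]] <- alpha
    }
  }
  logZ <- row_logsumexp(alpha + matrix(B[1:k, STOP], bsz, k, byrow = TRUE))
  list(alphas = alphas, logZ = logZ)
}

crf_batch_backward <- function(B, P_list, len) {
  k <- ncol(P_list[[1]])
  bsz <- nrow(P_list[[1]])
  Tm <- length(P_list)
  STOP <- k + 2L
  betas <- vector("list", Tm)
  bstop <- matrix(B[1:k, STOP], bsz, k, byrow = TRUE)
  betas[[Tm]] <- bstop
  if (Tm > 1) {
    for (t in (Tm - 1):1) {
      nxt <- P_list[[t + 1]] + betas[[t + 1]]
      bnew <- matrix(0, bsz, k)
      for (i in 1:k) {
        bnew[, i] <- row_logsumexp(nxt + matrix(B[i, 1:k], bsz, k,
                                                byrow = TRUE))
      }
      bnew[len == t, ] <- bstop[len == t, , drop = FALSE]
      betas[[t]] <- bnew
    }
  }
  betas
}

# Gradient of mean (over batch) CRF NLL w.r.t. emissions and transitions.
crf_batch_grad <- function(B, P_list, len, y_mat) {
  k <- ncol(P_list[[1]])
  bsz <- nrow(P_list[[1]])
  Tm <- length(P_list)
  START <- k + 1L; STOP <- k + 2L
  fw <- crf_batch_forward(B, P_list, len)
  betas <- crf_batch_backward(B, P_list, len)
  logZ <- fw$logZ
  dP <- vector("list", Tm)
  dB <- matrix(0, k + 2, k + 2)
  gold <- numeric(bsz)
  half <- logZ / 2
  for (t in seq_len(Tm)) {
    live <- len >= t
    m <- exp(fw$alphas[[t]] + betas[[t]] - logZ)
    g <- m
    yt <- y_mat[, t]
    oh <- cbind(which(live), yt[live])
    g[oh] <- g[oh] - 1
    g[!live, ] <- 0
    dP[[t]] <- g / bsz
    gold[live] <- gold[live] + P_list[[t]][oh]
    if (t == 1) {
      dB[START, 1:k] <- dB[START, 1:k] + colSums(m[live, , drop = FALSE])
      cnt <- tabulate(yt[live], nbins = k)
      dB[START, 1:k] <- dB[START, 1:k] - cnt
      gold[live] <- gold[live] + B[START, yt[live]]
    }
    at_end <- len == t
    if (any(at_end)) {
      dB[1:k, STOP] <- dB[1:k, STOP] + colSums(m[at_end, , drop = FALSE])
      cnt <- tabulate(yt[at_end], nbins = k)
      dB[1:k, STOP] <- dB[1:k, STOP] - cnt
      gold[at_end] <- gold[at_end] + B[cbind(yt[at_end], STOP)]
    }
    if (t < Tm) {
      mid <- len >= t + 1
      if (any(mid)) {
        Ae <- exp(fw$alphas[[t]] - half)
        Ae[!mid, ] <- 0
        Be <- exp(P_list[[t + 1]] + betas[[t + 1]] - half)
        Be[!mid, ] <- 0
        dB[1:k, 1:k] <- dB[1:k, 1:k] +
          (t(Ae) %*% Be) * exp(B[1:k, 1:k])
        yt1 <- y_mat[, t + 1]
        idx <- cbind(yt[mid], yt1[mid])
        for (r in seq_len(nrow(idx))) {
          dB[idx[r, 1], idx[r, 2]] <- dB[idx[r, 1], idx[r, 2]] - 1
        }
        gold[mid] <- gold[mid] + B[idx]
      }
    }
  }
  list(dP = dP, dB = dB / bsz, nll = mean(logZ - gold), logZ = logZ,
       gold_score = gold)
}

# Per-position softmax objective (the argmax baseline, no transitions).
softmax_batch_grad <- function(P_list, len, y_mat) {
  Tm <- length(P_list)
  bsz <- nrow(P_list[[1]])
  dP <- vector("list", Tm)
  nll <- 0; n_tok <- 0
  for (t in seq_len(Tm)) {
    live <- len >= t
    P <- P_list[[t]]
    m <- P - row_logsumexp(P)
    sm <- exp(m)
    g <- sm
    yt <- y_mat[, t]
    oh <- cbind(which(live), yt[live])
    g[oh] <- g[oh] - 1
    g[!live, ] <- 0
    nll <- nll - sum(m[oh])
    n_tok <- n_tok + sum(live)
    dP[[t]] <- g / bsz
  }
  list(dP = dP, dB = NULL, nll = nll / max(n_tok, 1))
}
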