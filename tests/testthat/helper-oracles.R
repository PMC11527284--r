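# Independent oracles used by several test files. These deliberately share
# no code with the implementation paths they check: exhaustive path
# enumeration for the CRF, a scalar gate-by-gate recomputation for the
# LSTM cell, and permutation matching for planted-topic recovery.

# Enumerate all k^N label paths and score each by explicit summation.
enum_crf <- function(B, P) {
  k <- ncol(P)
  n <- nrow(P)
  START <- k + 1L; STOP <- k + 2L
  paths <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  sc <- B[cbind(rep(START, nrow(paths)), paths[, 1])] +
    B[cbind(paths[, n], rep(STOP, nrow(paths)))]
  for (t in seq_len(n)) sc <- sc + P[t, ][paths[, t]]
  if (n > 1) {
    for (t in 2:n) sc <- sc + B[cbind(paths[, t - 1], paths[, t])]
  }
  list(paths = paths, scores = sc)
}

rand_crf_instance <- function(seed, n_max = 6, k_max = 5) {
  set.seed(seed)
  n <- sample(1:n_max, 1)
  k <- sample(2:k_max, 1)
  list(B = matrix(rnorm((k + 2)^2), k + 2),
       P = matrix(rnorm(n * k), n, k), n = n, k = k)
}

# Gate-by-gate scalar recomputation of the peephole LSTM update.
lstm_step_oracle <- function(p, x, h, cc) {
  H <- p$hidden_dim
  sig <- function(z) 1 / (1 + exp(-z))
  lin <- function(W1, v1, W2, v2, W3, v3, b) {
    out <- numeric(H)
    for (j in seq_len(H)) {
      out[j] <- sum(v1 * W1[, j]) + sum(v2 * W2[, j]) +
        (if (is.null(W3)) 0 else sum(v3 * W3[, j])) + b[j]
    }
    out
  }
  i <- sig(lin(p$Wxi, x, p$Whi, h, p$Wci, cc, p$bi))
  f <- sig(lin(p$Wxf, x, p$Whf, h, p$Wcf, cc, p$bf))
  g <- tanh(lin(p$Wxc, x, p$Whc, h, NULL, NULL, p$bc))
  cn <- f * cc + i * g
  o <- sig(lin(p$Wxo, x, p$Who, h, p$Wco, cn, p$bo))
  list(h = o * tanh(cn), c = cn)
}

# Mean top-n word overlap between true and estimated topic-word tables,
# maximized over topic permutations (exact for small K).
matched_topic_overlap <- function(true_phi, est_phi, top_n = 10) {
  K <- nrow(true_phi)
  stopifnot(K <= 8)
  top_true <- lapply(seq_len(K), function(k) {
    colnames(true_phi)[order(-true_phi[k, ])][seq_len(top_n)]
  })
  top_est <- lapply(seq_len(K), function(k) {
    colnames(est_phi)[order(-est_phi[k, ])][seq_len(top_n)]
  })
  perms <- as.matrix(expand.grid(rep(list(seq_len(K)), K)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == K), ,
                 drop = FALSE]
  best <- 0
  for (r in seq_len(nrow(perms))) {
    ov <- mean(vapply(seq_len(K), function(k) {
      length(intersect(top_true[[k]], top_est[[perms[r, k]]])) / top_n
    }, numeric(1)))
    best <- max(best, ov)
  }
  best
}

random_valid_bio <- function(seed, len = 8) {
  set.seed(seed)
  types <- c("SEX", "EDU", "ORG")
  labels <- character(0)
  while (length(labels) < len) {
    if (runif(1) < 0.5) {
      labels <- c(labels, "O")
    } else {
      tp <- sample(types, 1)
      span <- min(sample(1:3, 1), len - length(labels))
      labels <- c(labels, paste0("B-", tp),
                  rep(paste0("I-", tp), span - 1))
    }
  }
  labels[seq_len(len)]
}
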