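# Peephole LSTM, implemented as written in the model equations: the input
# and forget gates read c_{t-1}, the output gate reads the fresh c_t, and
# peephole connections are full H x H matrices. A config switch zeroes the
# peephole weights for the standard variant. Convention is row-vectors:
# activations are (batch x dim) and pre-activations are X %*% W + b.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Initialize LSTM parameters
#'
#' Weights are uniform in `[-s, s]` with `s = sqrt(6 / (fan_in + H))`;
#' biases start at zero except the forget bias (1). With
#' `peephole = FALSE` the cell-to-gate matrices are fixed at zero.
#'
#' @param input_dim Input dimension.
#' @param hidden_dim Hidden/cell dimension `H`.
#' @param seed Integer seed.
#' @param peephole Keep the cell-to-gate connections (default `TRUE`).
#' @return An object of class `"lstm_params"` (a named list of matrices).
#' @export
lstm_params <- function(input_dim, hidden_dim, seed = 1, peephole = TRUE) {
  set.seed(seed)
  d <- input_dim; H <- hidden_dim
  u <- function(nr, nc, fan) {
    s <- sqrt(6 / fan)
    matrix(runif(nr * nc, -s, s), nr, nc)
  }
  p <- list(
    Wxi = u(d, H, d + H), Whi = u(H, H, 2 * H), Wci = u(H, H, 2 * H),
    bi = rep(0, H),
    Wxf = u(d, H, d + H), Whf = u(H, H, 2 * H), Wcf = u(H, H, 2 * H),
    bf = rep(1, H),
    Wxo = u(d, H, d + H), Who = u(H, H, 2 * H), Wco = u(H, H, 2 * H),
    bo = rep(0, H),
    Wxc = u(d, H, d + H), Whc = u(H, H, 2 * H),
    bc = rep(0, H)
  )
  if (!peephole) {
    p$Wci[] <- 0; p$Wcf[] <- 0; p$Wco[] <- 0
  }
  structure(c(p, list(input_dim = d, hidden_dim = H, peephole = peephole)),
            class = "lstm_params")
}

#' One LSTM step
#'
#' Computes the gate activations and state update:
#' `i = sigma(x Wxi + h Whi + c Wci + bi)`,
#' `f = sigma(x Wxf + h Whf + c Wcf + bf)`,
#' `g = tanh(h Whc + x Wxc + bc)`, `c' = f * c + i * g`,
#' `o = sigma(x Wxo + h Who + c' Wco + bo)`, `h' = o * tanh(c')`.
#'
#' @param params An [lstm_params()] object.
#' @param x_t Input vector (length `input_dim`).
#' @param h_prev,c_prev Previous hidden and cell vectors (length `H`).
#' @return A list with `h` and `c`.
#' @export
lstm_step <- function(params, x_t, h_prev, c_prev) {
  if (length(x_t) != params$input_dim || length(h_prev) != params$hidden_dim ||
      length(c_prev) != params$hidden_dim) {
    abort("lstm_step: shape mismatch")
  }
  x <- matrix(x_t, 1); h <- matrix(h_prev, 1); cc <- matrix(c_prev, 1)
  i <- sigmoid(x %*% params$Wxi + h %*% params$Whi + cc %*% params$Wci +
                 rep(params$bi, each = 1))
  f <- sigmoid(x %*% params$Wxf + h %*% params$Whf + cc %*% params$Wcf +
                 rep(params$bf, each = 1))
  g <- tanh(h %*% params$Whc + x %*% params$Wxc + rep(params$bc, each = 1))
  cn <- f * cc + i * g
  o <- sigmoid(x %*% params$Wxo + h %*% params$Who + cn %*% params$Wco +
                 rep(params$bo, each = 1))
  list(h = as.vector(o * tanh(cn)), c = as.vector(cn))
}

#' Bidirectional LSTM encoding of one sequence
#'
#' Runs a left-to-right and a right-to-left pass and concatenates the
#' hidden states position-wise: row `t` is `[h_fwd_t, h_bwd_t]`.
#'
#' @param fwd,bwd [lstm_params()] for the two directions (same `H`).
#' @param X `N x input_dim` matrix of token vectors.
#' @return An `N x 2H` matrix.
#' @export
bilstm_encode <- function(fwd, bwd, X) {
  if (!is.matrix(X) || nrow(X) == 0) abort("empty sequence")
  if (fwd$hidden_dim != bwd$hidden_dim) abort("directions must share H")
  n <- nrow(X); H <- fwd$hidden_dim
  run <- function(p, idx) {
    h <- rep(0, H); cc <- rep(0, H)
    out <- matrix(0, n, H)
    for (t in idx) {
      st <- lstm_step(p, X[t, ], h, cc)
      h <- st$h; cc <- st$c
      out[t, ] <- h
    }
    out
  }
  cbind(run(fwd, seq_len(n)), run(bwd, rev(seq_len(n))))
}

# ---- batched forward / backward (training internals) ----------------------

lstm_forward_batch <- function(p, X_list) {
  Tm <- length(X_list)
  bsz <- nrow(X_list[[1]])
  H <- p$hidden_dim
  h <- matrix(0, bsz, H); cc <- matrix(0, bsz, H)
  Hs <- vector("list", Tm)
  cache <- vector("list", Tm)
  for (t in seq_len(Tm)) {
    x <- X_list[[t]]
    ai <- x %*% p$Wxi + h %*% p$Whi + cc %*% p$Wci +
      matrix(p$bi, bsz, H, byrow = TRUE)
    af <- x %*% p$Wxf + h %*% p$Whf + cc %*% p$Wcf +
      matrix(p$bf, bsz, H, byrow = TRUE)
    i <- sigmoid(ai); f <- sigmoid(af)
    g <- tanh(h %*% p$Whc + x %*% p$Wxc + matrix(p$bc, bsz, H, byrow = TRUE))
    cn <- f * cc + i * g
    o <- sigmoid(x %*% p$Wxo + h %*% p$Who + cn %*% p$Wco +
                   matrix(p$bo, bsz, H, byrow = TRUE))
    tc <- tanh(cn)
    hn <- o * tc
    cache[[t]] <- list(i = i, f = f, o = o, g = g, c = cn, tanh_c = tc,
                       h_prev = h, c_prev = cc)
    h <- hn; cc <- cn
    Hs[[t]] <- h
  }
  list(H = Hs, cache = cache)
}

zero_like <- function(p) {
  g <- lapply(p[c("Wxi", "Whi", "Wci", "bi", "Wxf", "Whf", "Wcf", "bf",
                  "Wxo", "Who", "Wco", "bo", "Wxc", "Whc", "bc")],
              function(m) { m[] <- 0; m })
  g
}

lstm_backward_batch <- function(p, X_list, cache, dH_list) {
  Tm <- length(X_list)
  bsz <- nrow(X_list[[1]])
  H <- p$hidden_dim
  gr <- zero_like(p)
  dh_next <- matrix(0, bsz, H); dc_next <- matrix(0, bsz, H)
  for (t in rev(seq_len(Tm))) {
    cs <- cache[[t]]
    x <- X_list[[t]]
    dh <- dH_list[[t]] + dh_next
    do_ <- dh * cs$tanh_c
    da_o <- do_ * cs$o * (1 - cs$o)
    dc <- dc_next + dh * cs$o * (1 - cs$tanh_c^2) + da_o %*% t(p$Wco)
    dg <- dc * cs$i
    da_g <- dg * (1 - cs$g^2)
    di <- dc * cs$g
    da_i <- di * cs$i * (1 - cs$i)
    df <- dc * cs$c_prev
    da_f <- df * cs$f * (1 - cs$f)
    dc_next <- dc * cs$f + da_i %*% t(p$Wci) + da_f %*% t(p$Wcf)
    dh_next <- da_i %*% t(p$Whi) + da_f %*% t(p$Whf) +
      da_o %*% t(p$Who) + da_g %*% t(p$Whc)
    gr$Wxi <- gr$Wxi + crossprod(x, da_i)
    gr$Whi <- gr$Whi + crossprod(cs$h_prev, da_i)
    gr$Wci <- gr$Wci + crossprod(cs$c_prev, da_i)
    gr$bi <- gr$bi + colSums(da_i)
    gr$Wxf <- gr$Wxf + crossprod(x, da_f)
    gr$Whf <- gr$Whf + crossprod(cs$h_prev, da_f)
    gr$Wcf <- gr$Wcf + crossprod(cs$c_prev, da_f)
    gr$bf <- gr$bf + colSums(da_f)
    gr$Wxo <- gr$Wxo + crossprod(x, da_o)
    gr$Who <- gr$Who + crossprod(cs$h_prev, da_o)
    gr$Wco <- gr$Wco + crossprod(cs$c, da_o)
    gr$bo <- gr$bo + colSums(da_o)
    gr$Wxc <- gr$Wxc + crossprod(x, da_g)
    gr$Whc <- gr$Whc + crossprod(cs$h_prev, da_g)
    gr$bc <- gr$bc + colSums(da_g)
  }
  if (!p$peephole) {
    gr$Wci[] <- 0; gr$Wcf[] <- 0; gr$Wco[] <- 0
  }
  gr
}
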