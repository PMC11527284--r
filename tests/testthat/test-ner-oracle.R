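# Oracle tests for the sequence-model primitives: exhaustive enumeration
# for the CRF, scalar recomputation for the LSTM cell, finite differences
# for the training gradients.

test_that("crf_score sums transitions and emissions as defined", {
  k <- 3
  B0 <- matrix(0, k + 2, k + 2)
  P0 <- matrix(0, 4, k)
  for (y in list(c(1, 1, 1, 1), c(3, 2, 1, 2))) {
    expect_equal(crf_score(B0, P0, y), 0)
  }
  # single emission, zero transitions
  expect_equal(crf_score(matrix(0, 4, 4), rbind(c(1, 3)), 1), 1)
  expect_equal(crf_score(matrix(0, 4, 4), rbind(c(1, 3)), 2), 3)
  # random instance vs a term-by-term loop
  set.seed(7)
  B <- matrix(rnorm(25), 5); P <- matrix(rnorm(12), 4, 3)
  y <- c(2, 3, 1, 3)
  manual <- B[4, y[1]] + B[y[4], 5] + sum(sapply(1:3, function(t) B[y[t], y[t + 1]])) +
    sum(sapply(1:4, function(t) P[t, y[t]]))
  expect_equal(crf_score(B, P, y), manual)
  expect_error(crf_score(B, P, c(1, 2, 3, 9)), "out of range")
})

test_that("log partition matches closed forms on trivial instances", {
  # all-zero scores, N = 2, k = 3: nine equal paths
  expect_equal(crf_log_partition(matrix(0, 5, 5), matrix(0, 2, 3)), log(9))
  # N = 1: logsumexp of emissions plus start/stop transitions
  set.seed(1)
  B <- matrix(rnorm(16), 4); P <- matrix(rnorm(2), 1, 2)
  manual <- log(sum(exp(B[3, 1:2] + P[1, ] + B[1:2, 4])))
  expect_equal(crf_log_partition(B, P), manual)
})

test_that("viterbi reduces to per-position argmax without transitions", {
  set.seed(3)
  P <- matrix(rnorm(15), 5, 3)
  vd <- viterbi_decode(matrix(0, 5, 5), P)
  expect_equal(vd$y, apply(P, 1, which.max))
})

test_that("strong transitions force an alternating decode", {
  k <- 2
  B <- matrix(-50, k + 2, k + 2)
  B[3, 1] <- 50            # START -> 1
  B[1, 2] <- 50; B[2, 1] <- 50
  B[1, 4] <- 50; B[2, 4] <- 50
  P <- matrix(0, 6, k)
  vd <- viterbi_decode(B, P)
  expect_equal(vd$y, c(1, 2, 1, 2, 1, 2))
  en <- enum_crf(B, P)
  expect_equal(vd$score, max(en$scores))
})

test_that("viterbi and forward agree with enumeration on random instances", {
  # moderate batch here; the full 1000-instance sweep runs in the
  # acceptance suite
  for (s in 1:150) {
    inst <- rand_crf_instance(s)
    en <- enum_crf(inst$B, inst$P)
    vd <- viterbi_decode(inst$B, inst$P)
    expect_equal(vd$score, max(en$scores), tolerance = 1e-10)
    expect_equal(crf_score(inst$B, inst$P, vd$y), max(en$scores),
                 tolerance = 1e-10)
    expect_equal(crf_log_partition(inst$B, inst$P),
                 log(sum(exp(en$scores - max(en$scores)))) + max(en$scores),
                 tolerance = 1e-8)
  }
})

test_that("lstm_step matches an independent gate-by-gate recomputation", {
  for (s in 1:20) {
    p <- lstm_params(4, 3, seed = s)
    set.seed(1000 + s)
    x <- rnorm(4); h <- rnorm(3); cc <- rnorm(3)
    got <- lstm_step(p, x, h, cc)
    want <- lstm_step_oracle(p, x, h, cc)
    expect_equal(got$h, want$h, tolerance = 1e-10)
    expect_equal(got$c, want$c, tolerance = 1e-10)
  }
})

test_that("the all-zero configuration gives h = c = 0 exactly", {
  p <- lstm_params(3, 2, seed = 1)
  for (nm in c("Wxi", "Whi", "Wci", "Wxf", "Whf", "Wcf", "Wxo", "Who",
               "Wco", "Wxc", "Whc")) p[[nm]][] <- 0
  p$bi[] <- 0; p$bf[] <- 0; p$bo[] <- 0; p$bc[] <- 0
  st <- lstm_step(p, rnorm(3), rep(0, 2), rep(0, 2))
  expect_identical(st$c, c(0, 0))
  expect_identical(st$h, c(0, 0))
})

test_that("a large cell bias saturates tanh so c approaches i", {
  p <- lstm_params(1, 1, seed = 2)
  for (nm in c("Wxi", "Whi", "Wci", "Wxf", "Whf", "Wcf", "Wxo", "Who",
               "Wco", "Wxc", "Whc")) p[[nm]][] <- 0
  p$bi[] <- 0; p$bf[] <- 0; p$bo[] <- 0
  p$bc[] <- 50
  st <- lstm_step(p, 0, 0, 0)
  expect_equal(st$c, 0.5, tolerance = 1e-9)  # i_t * tanh(large) = 0.5
})

test_that("bilstm encoding equals two independent unidirectional passes", {
  set.seed(5)
  fwd <- lstm_params(3, 4, seed = 8)
  bwd <- lstm_params(3, 4, seed = 9)
  X <- matrix(rnorm(15), 5, 3)
  H2 <- bilstm_encode(fwd, bwd, X)
  # manual forward pass
  h <- rep(0, 4); cc <- rep(0, 4)
  for (t in 1:5) {
    st <- lstm_step(fwd, X[t, ], h, cc); h <- st$h; cc <- st$c
    expect_equal(H2[t, 1:4], h)
  }
  # manual backward pass
  h <- rep(0, 4); cc <- rep(0, 4)
  for (t in 5:1) {
    st <- lstm_step(bwd, X[t, ], h, cc); h <- st$h; cc <- st$c
    expect_equal(H2[t, 5:8], h)
  }
  # length-1 input: single row, both directions on the same token
  x1 <- X[1, , drop = FALSE]
  H1 <- bilstm_encode(fwd, bwd, x1)
  expect_equal(H1[1, 1:4], lstm_step(fwd, X[1, ], rep(0, 4), rep(0, 4))$h)
  expect_equal(H1[1, 5:8], lstm_step(bwd, X[1, ], rep(0, 4), rep(0, 4))$h)
})

test_that("palindromic input with tied directions is mirror-symmetric", {
  p <- lstm_params(2, 3, seed = 4)
  set.seed(6)
  a <- rnorm(2); b <- rnorm(2); c2 <- rnorm(2)
  X <- rbind(a, b, c2, b, a)
  H2 <- bilstm_encode(p, p, X)
  n <- nrow(X)
  for (t in 1:n) {
    expect_equal(H2[t, 1:3], H2[n + 1 - t, 4:6])
  }
})

test_that("batched forward matches the single-sequence path", {
  g <- generate_ner_corpus(n_sentences = 6, tokens_per_sentence = 7, seed = 3)
  enc <- hash_encoder(dim = 6, seed = 2)
  sents <- stresslens:::ner_prep_sentences(g$sentences, enc,
                                           ner_label_set(), 50)
  H <- 4; k <- 7
  model <- list(fwd = lstm_params(6, H, seed = 1),
                bwd = lstm_params(6, H, seed = 2),
                Wemit = matrix(rnorm(2 * H * k, 0, 0.3), 2 * H, k),
                bemit = rnorm(k, 0, 0.1),
                B = matrix(rnorm((k + 2)^2, 0, 0.3), k + 2, k + 2))
  batch <- stresslens:::ner_make_batch(sents)
  fo <- stresslens:::ner_forward_batch(model, batch)
  for (b in c(1, 4, 6)) {
    X <- sents[[b]]$X
    H2 <- bilstm_encode(model$fwd, model$bwd, X)
    P_single <- H2 %*% model$Wemit +
      matrix(model$bemit, nrow(X), k, byrow = TRUE)
    P_batch <- t(vapply(seq_len(nrow(X)), function(t) fo$P_list[[t]][b, ],
                        numeric(k)))
    expect_equal(P_batch, P_single, tolerance = 1e-12)
  }
})

test_that("batched CRF NLL gradients match finite differences", {
  g <- generate_ner_corpus(n_sentences = 4, tokens_per_sentence = 5, seed = 9)
  enc <- hash_encoder(dim = 5, seed = 1)
  sents <- stresslens:::ner_prep_sentences(g$sentences, enc,
                                           ner_label_set(), 50)
  batch <- stresslens:::ner_make_batch(sents)
  H <- 3; k <- 7
  set.seed(12)
  model <- list(fwd = lstm_params(5, H, seed = 21),
                bwd = lstm_params(5, H, seed = 22),
                Wemit = matrix(rnorm(2 * H * k, 0, 0.3), 2 * H, k),
                bemit = rnorm(k, 0, 0.1),
                B = matrix(rnorm((k + 2)^2, 0, 0.3), k + 2, k + 2))
  loss_of <- function(m) {
    fo <- stresslens:::ner_forward_batch(m, batch)
    stresslens:::crf_batch_grad(m$B, fo$P_list, batch$lens, batch$y_mat)$nll
  }
  fo <- stresslens:::ner_forward_batch(model, batch)
  obj <- stresslens:::crf_batch_grad(model$B, fo$P_list, batch$lens,
                                     batch$y_mat)
  gr <- stresslens:::ner_backward_batch(model, batch, fo, obj$dP)
  eps <- 1e-6
  fd <- function(mutate) {
    m1 <- mutate(model, -eps); m2 <- mutate(model, +eps)
    (loss_of(m2) - loss_of(m1)) / (2 * eps)
  }
  # one entry from every parameter family
  for (nm in c("Wxi", "Whf", "Wco", "Wxc", "bi", "bc")) {
    num <- fd(function(m, e) { m$fwd[[nm]][2] <- m$fwd[[nm]][2] + e; m })
    expect_equal(gr$fwd[[nm]][2], num, tolerance = 1e-5)
  }
  num <- fd(function(m, e) { m$bwd$Who[3] <- m$bwd$Who[3] + e; m })
  expect_equal(gr$bwd$Who[3], num, tolerance = 1e-5)
  num <- fd(function(m, e) { m$Wemit[5] <- m$Wemit[5] + e; m })
  expect_equal(gr$Wemit[5], num, tolerance = 1e-5)
  num <- fd(function(m, e) { m$B[8, 2] <- m$B[8, 2] + e; m })
  expect_equal(obj$dB[8, 2], num, tolerance = 1e-5)
  num <- fd(function(m, e) { m$B[2, 3] <- m$B[2, 3] + e; m })
  expect_equal(obj$dB[2, 3], num, tolerance = 1e-5)
})

test_that("CRF marginals are normalized on every live position", {
  g <- generate_ner_corpus(n_sentences = 5, tokens_per_sentence = 6, seed = 4)
  enc <- hash_encoder(dim = 4, seed = 3)
  sents <- stresslens:::ner_prep_sentences(g$sentences, enc,
                                           ner_label_set(), 50)
  batch <- stresslens:::ner_make_batch(sents)
  set.seed(2)
  k <- 7
  P_list <- lapply(seq_len(batch$Tm), function(t) {
    matrix(rnorm(batch$bsz * k), batch$bsz, k)
  })
  B <- matrix(rnorm((k + 2)^2, 0, 0.5), k + 2, k + 2)
  fw <- stresslens:::crf_batch_forward(B, P_list, batch$lens)
  be <- stresslens:::crf_batch_backward(B, P_list, batch$lens)
  for (t in seq_len(batch$Tm)) {
    live <- batch$lens >= t
    m <- exp(fw$alphas[[t]] + be[[t]] - fw$logZ)
    expect_equal(unname(rowSums(m)[live]), rep(1, sum(live)),
                 tolerance = 1e-8)
  }
})
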