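make_fused_fixture <- function(M = 20, K = 2, seed = 3) {
  g <- generate_topic_corpus(M = M, K_true = K, V = 20, tokens_per_doc = 12,
                             seed = seed)
  enc <- hash_encoder(dim = 8, seed = 4)
  e <- encode_posts(g$tokens, enc)
  m <- fit_lda(g$tokens, K = K, iters = 20, seed = 5)
  list(g = g, e = e, m = m)
}

test_that("single-topic vectors are corpus centroids", {
  fx <- make_fused_fixture(K = 2)
  m1 <- fit_lda(fx$g$tokens, K = 1, iters = 3, seed = 1)
  tv <- topic_vectors(m1, fx$e)
  all_vecs <- do.call(rbind, fx$e$embedding)
  expect_equal(tv$topics[1, ], colMeans(all_vecs))
  # every doc vector equals the single topic vector
  for (i in 1:3) expect_equal(unname(tv$docs[i, ]), unname(tv$topics[1, ]))
})

test_that("doc topic vectors equal the theta-weighted combination", {
  fx <- make_fused_fixture()
  tv <- topic_vectors(fx$m, fx$e)
  theta <- lda_theta(fx$m)
  # brute-force re-summation, doc by doc
  for (i in c(1, 7, 13)) {
    z_manual <- colSums(theta[i, ] * tv$topics)
    expect_equal(unname(tv$docs[i, ]), z_manual)
  }
})

test_that("disjoint token sets give their own centroids", {
  # two docs with disjoint vocab; force assignments via disjoint topics
  tokens <- tibble::tibble(
    post_id = rep(c("a", "b"), each = 4),
    token = rep(c("aa", "bb"), each = 4),
    position = rep(0:3, 2), sentence = 1L)
  m <- fit_lda(tokens, K = 2, alpha = 0.01, beta = 0.01, iters = 80, seed = 2)
  enc <- hash_encoder(dim = 6, seed = 9)
  e <- encode_posts(tokens, enc)
  tv <- suppressWarnings(topic_vectors(m, e))
  # each topic centroid must equal one of the two unique token vectors
  # (plus identical position/segment terms), since assignments split by doc
  z <- unlist(m$assignments)
  if (length(unique(z[1:4])) == 1 && length(unique(z[5:8])) == 1 &&
      z[1] != z[5]) {
    expect_equal(unname(tv$topics[z[1], ]), colMeans(e$embedding[[1]]))
    expect_equal(unname(tv$topics[z[5], ]), colMeans(e$embedding[[2]]))
  }
})

test_that("cosine similarity matches the analytic identities", {
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(2, 0), c(1, 0)), 1)
  expect_equal(cosine_similarity(c(1, 1), c(1, 0)), sqrt(2) / 2,
               tolerance = 1e-9)
  expect_error(cosine_similarity(c(0, 0), c(1, 0)), "zero vector")
})

test_that("optimal-topic assignment maximizes cosine with stated ties", {
  topics <- rbind(c(1, 0), c(0, 1))
  expect_equal(assign_optimal_topic(c(1, 0), topics), 1L)
  # cos with topic 1 is 0.6, with topic 2 is 0.8
  expect_equal(assign_optimal_topic(c(0.6, 0.8), topics), 2L)
  # identical topic vectors tie -> smallest id
  expect_equal(assign_optimal_topic(c(1, 1), rbind(c(1, 0), c(1, 0))), 1L)
  # invariant under positive rescaling of all vectors
  set.seed(8)
  tm <- matrix(rnorm(12), 4, 3)
  v <- rnorm(3)
  expect_equal(assign_optimal_topic(v, tm),
               assign_optimal_topic(5 * v, 0.3 * tm))
  expect_error(assign_optimal_topic(c(1, 1), matrix(0, 2, 2)), "zero")
})

test_that("fusion adds the topic vector and is invertible", {
  X <- rbind(c(1, 2), c(3, 4))
  expect_equal(fuse(X, c(0, 0)), X)
  expect_equal(fuse(rbind(c(1, 2)), c(3, 4)), rbind(c(4, 6)))
  z <- c(0.5, -1)
  expect_equal(sweep(fuse(X, z), 2, z, "-"), X)
  expect_error(fuse(X, c(1, 2, 3)), "dimension mismatch")
})

test_that("merge_topics validates the partition and merges phi rows", {
  fx <- make_fused_fixture(K = 2)
  sf <- merge_topics(fx$m, list(1L, 2L), c("fa", "fb"))
  expect_equal(sf$mapping$feature, c("fa", "fb"))
  # singleton groups reproduce each topic's own ranking
  phi <- lda_phi(fx$m)
  top_fa <- sf$top_words$token[sf$top_words$feature == "fa"][1]
  expect_equal(top_fa, names(which.max(phi[1, ])))
  # probabilities are non-increasing in rank
  for (f in c("fa", "fb")) {
    p <- sf$top_words$probability[sf$top_words$feature == f]
    expect_true(all(diff(p) <= 1e-12))
  }
  expect_error(merge_topics(fx$m, list(1L), "x"), "partition")
  expect_error(merge_topics(fx$m, list(1:2), c("x", "y")), "one name per")
})

test_that("merging identical topics reproduces the shared ranking", {
  # a 2-topic fit on a one-word-per-doc corpus where both topics see the
  # same data profile: merged ranking equals the mean, which for equal
  # rows is either row
  fx <- make_fused_fixture(K = 2)
  phi <- lda_phi(fx$m)
  merged <- merge_topics(fx$m, list(c(1L, 2L)), "all")
  expected <- colMeans(phi)
  ord <- order(-expected, fx$m$vocab)
  expect_equal(merged$top_words$token, fx$m$vocab[ord])
  expect_equal(merged$top_words$probability, unname(expected[ord]))
})

test_that("splitting one planted topic across two groups recovers its words", {
  g <- generate_topic_corpus(M = 120, K_true = 2, V = 40,
                             tokens_per_doc = 25, seed = 13)
  # overfit with K=4: the two planted topics split across learned topics;
  # grouping learned topics by best-matching planted topic must recover
  # the planted top words
  m <- fit_lda(g$tokens, K = 4, alpha = 0.5, iters = 120, seed = 3)
  phi <- lda_phi(m)
  true_top <- lapply(1:2, function(k) {
    colnames(g$true_phi)[order(-g$true_phi[k, ])][1:10]
  })
  sim_to_true <- vapply(1:4, function(j) {
    which.max(vapply(1:2, function(k) {
      sum(phi[j, true_top[[k]]])
    }, numeric(1)))
  }, integer(1))
  if (length(unique(sim_to_true)) == 2) {
    groups <- split(1:4, sim_to_true)
    sf <- merge_topics(m, unname(groups), c("g1", "g2"))
    rec <- sf$top_words$token[sf$top_words$feature == "g1"][1:10]
    expect_gte(length(intersect(rec, true_top[[1]])), 8)
  }
})

test_that("auto grouping respects the trivial cases and separates clusters", {
  fx <- make_fused_fixture(K = 2)
  tv <- topic_vectors(fx$m, fx$e)
  expect_equal(auto_group_topics(tv, 2), list(1L, 2L))
  expect_equal(auto_group_topics(tv, 1), list(1:2))
  # 4 planted vectors in 2 well-separated cosine clusters
  topics <- rbind(c(10, 0.1), c(9, -0.1), c(0.1, 10), c(-0.1, 9))
  gr <- auto_group_topics(topics, 2)
  expect_equal(gr, list(c(1L, 2L), c(3L, 4L)))
})

test_that("the shipped 20-topic grouping is a labelled partition", {
  gr <- default_topic_groups()
  expect_equal(sort(unname(unlist(gr))), 1:20)
  expect_equal(names(gr), stress_feature_labels())
})
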