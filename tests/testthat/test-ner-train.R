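test_that("training loss is finite, non-negative, and decreases early", {
  g <- generate_ner_corpus(n_sentences = 60, tokens_per_sentence = 8,
                           seed = 14)
  hy <- ner_hyper(lr = 0.02, hidden_dim = 12, dropout = 0, batch_size = 30,
                  epochs = 5, seed = 5)
  m <- train_ner(g$sentences, encoder = hash_encoder(dim = 12, seed = 2),
                 hyper = hy)
  expect_true(all(is.finite(m$history$nll)))
  expect_true(all(m$history$nll >= 0))
  expect_lt(tail(m$history$nll, 1), m$history$nll[1])
})

test_that("a small training set is memorized to perfect entity F1", {
  g <- generate_ner_corpus(n_sentences = 30, tokens_per_sentence = 7,
                           seed = 8)
  hy <- ner_hyper(lr = 0.05, hidden_dim = 16, dropout = 0, batch_size = 30,
                  epochs = 60, seed = 3)
  m <- train_ner(g$sentences, encoder = hash_encoder(dim = 16, seed = 4),
                 hyper = hy)
  expect_equal(overall_f1(m, g$sentences), 1)
})

test_that("training rejects unknown labels before starting", {
  bad <- tibble::tibble(sentence_id = 1L, position = 0:1,
                        token = c("a", "b"), label = c("B-LOC", "O"))
  expect_error(train_ner(bad, hyper = ner_hyper(epochs = 1)),
               "unknown label")
})

test_that("training is reproducible given the seed", {
  g <- generate_ner_corpus(n_sentences = 40, tokens_per_sentence = 6,
                           seed = 2)
  enc <- hash_encoder(dim = 10, seed = 1)
  hy <- ner_hyper(lr = 0.02, hidden_dim = 8, dropout = 0.3, batch_size = 20,
                  epochs = 3, seed = 7)
  m1 <- train_ner(g$sentences, encoder = enc, hyper = hy)
  m2 <- train_ner(g$sentences, encoder = enc, hyper = hy)
  expect_equal(m1$Wemit, m2$Wemit, tolerance = 1e-12)
  expect_equal(m1$B, m2$B, tolerance = 1e-12)
  expect_equal(m1$history$nll, m2$history$nll, tolerance = 1e-12)
})

test_that("evaluation follows the exact-span conventions", {
  # build a model whose predictions we control by decoding gold directly:
  # instead, check the conventions on the tally level via two tiny models
  # is brittle; check evaluate_ner against a memorizing model
  g <- generate_ner_corpus(n_sentences = 12, tokens_per_sentence = 6,
                           seed = 19)
  hy <- ner_hyper(lr = 0.05, hidden_dim = 12, dropout = 0, batch_size = 12,
                  epochs = 60, seed = 2)
  m <- train_ner(g$sentences, encoder = hash_encoder(dim = 12, seed = 9),
                 hyper = hy)
  ev <- evaluate_ner(m, g$sentences)
  overall <- ev$metrics[ev$metrics$entity_type == "overall", ]
  expect_equal(overall$precision, 1)
  expect_equal(overall$recall, 1)
  expect_equal(overall$f1, 1)
  # the F1 convention: zero predicted and zero correct means P = R = F1 = 0
  all_o <- g$sentences
  all_o$label <- "O"
  # model trained on all-O data predicts no spans; gold has spans
  hy0 <- ner_hyper(lr = 0.05, hidden_dim = 8, dropout = 0, batch_size = 12,
                   epochs = 5, seed = 2)
  m0 <- train_ner(all_o, encoder = hash_encoder(dim = 12, seed = 9),
                  hyper = hy0)
  ev0 <- evaluate_ner(m0, g$sentences)
  ov0 <- ev0$metrics[ev0$metrics$entity_type == "overall", ]
  expect_equal(ov0$n_pred, 0L)
  expect_equal(ov0$precision, 0)
  expect_equal(ov0$recall, 0)
  expect_equal(ov0$f1, 0)
})

test_that("extracted entities are BIO2-consistent spans with surfaces", {
  g <- generate_ner_corpus(n_sentences = 40, tokens_per_sentence = 7,
                           seed = 23)
  hy <- ner_hyper(lr = 0.05, hidden_dim = 16, dropout = 0, batch_size = 40,
                  epochs = 40, seed = 6)
  m <- train_ner(g$sentences, encoder = hash_encoder(dim = 16, seed = 5),
                 hyper = hy)
  docs <- tibble::tibble(
    post_id = paste0("d", g$sentences$sentence_id),
    token = g$sentences$token)
  ents <- extract_entities(m, docs)
  expect_true(all(ents$entity_type %in% c("SEX", "EDU", "ORG")))
  expect_true(all(ents$start < ents$end))
  expect_true(all(nzchar(ents$surface)))
  # decoding is deterministic
  expect_identical(ents, extract_entities(m, docs))
})

test_that("entity-free sentences rarely produce spurious spans", {
  g <- generate_ner_corpus(n_sentences = 200, tokens_per_sentence = 8,
                           seed = 33)
  hy <- ner_hyper(lr = 0.05, hidden_dim = 20, dropout = 0, batch_size = 64,
                  epochs = 20, seed = 4)
  m <- train_ner(g$sentences, encoder = hash_encoder(dim = 20, seed = 3),
                 hyper = hy)
  neg <- generate_ner_corpus(n_sentences = 100,
                             plant_prob = c(SEX = 0, EDU = 0, ORG = 0),
                             tokens_per_sentence = 8, seed = 34)
  docs <- tibble::tibble(post_id = paste0("n", neg$sentences$sentence_id),
                         token = neg$sentences$token)
  ents <- extract_entities(m, docs)
  # false-positive rate per sentence below 0.05
  expect_lt(length(unique(ents$post_id)) / 100, 0.05)
})

test_that("continued training keeps encoder and labels of the base model", {
  g1 <- generate_ner_corpus(n_sentences = 30, org_only = TRUE, seed = 3)
  g2 <- generate_ner_corpus(n_sentences = 30, seed = 4)
  enc <- hash_encoder(dim = 10, seed = 8)
  hy <- ner_hyper(lr = 0.03, hidden_dim = 8, dropout = 0, batch_size = 30,
                  epochs = 2, seed = 1)
  base <- train_ner(g1$sentences, encoder = enc, hyper = hy)
  cont <- train_ner(g2$sentences, continue_from = base, hyper = hy)
  expect_identical(cont$encoder$id, enc$id)
  expect_identical(cont$label_set, base$label_set)
  expect_false(identical(cont$Wemit, base$Wemit))
})
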