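# Shared fixtures, built once per test run and cached. The NER benchmark
# (2,000 train / 500 test sentences, hidden dim 50) backs both the
# parameter-recovery and the architecture-ordering checks, so the trained
# models are reused across test blocks.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

ner_bench_data <- function() {
  fixture("ner_bench_data", function() {
    list(train = generate_ner_corpus(n_sentences = 2000, seed = 101),
         test = generate_ner_corpus(n_sentences = 500, seed = 102),
         org_train = generate_ner_corpus(n_sentences = 1000, org_only = TRUE,
                                         seed = 103))
  })
}

bench_encoder <- function() hash_encoder(dim = 32, seed = 7)

bench_hyper <- function(objective = "crf", epochs = 10) {
  ner_hyper(lr = 0.03, hidden_dim = 50, dropout = 0.2, batch_size = 128,
            epochs = epochs, objective = objective, seed = 11)
}

ner_bench_crf_model <- function() {
  fixture("ner_bench_crf_model", function() {
    train_ner(ner_bench_data()$train$sentences, encoder = bench_encoder(),
              hyper = bench_hyper("crf"))
  })
}

ner_bench_softmax_model <- function() {
  fixture("ner_bench_softmax_model", function() {
    train_ner(ner_bench_data()$train$sentences, encoder = bench_encoder(),
              hyper = bench_hyper("softmax"))
  })
}

overall_f1 <- function(model, test_sentences) {
  m <- evaluate_ner(model, test_sentences)$metrics
  m$f1[m$entity_type == "overall"]
}

type_f1 <- function(model, test_sentences, type) {
  m <- evaluate_ner(model, test_sentences)$metrics
  m$f1[m$entity_type == type]
}

# Small labelled corpus with entities AND planted sentiment labels, for
# end-to-end pipeline runs.
pipeline_smoke_posts <- function(n = 150, seed = 31) {
  g <- generate_profile_corpus(n_docs = n, seed = seed)
  posts <- g$posts
  set.seed(seed + 1)
  posts$label_sentiment <- ifelse(runif(nrow(posts)) < 0.85,
                                  "negative", "positive")
  posts
}

pipeline_smoke_config <- function(seed = 21) {
  pipeline_config(
    seed = seed,
    lda = list(K = 4, iters = 60),
    topics = list(K = 5, iters = 60, n_groups = 5),
    encoder = list(dim = 24, max_seq_len = 64),
    ner = list(lr = 0.05, hidden_dim = 24, dropout = 0.2,
               batch_size = 64, epochs = 15)
  )
}
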