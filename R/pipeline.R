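# End-to-end orchestration. One user-facing seed fans out to per-stage
# seeds by stable derivation; every artifact is written with the config
# hash so a rerun with the same config and data is byte-identical.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    tokenize = list(mode = "whitespace", stopwords = NULL),
    encoder = list(dim = 64L, max_seq_len = 256L),
    lda = list(K = 20L, alpha = NULL, beta = 0.01, iters = 200L),
    sentiment = list(holdout = 0.2, class_weights = FALSE, threshold = 0.5),
    topics = list(K = 20L, iters = 200L, n_groups = 5L, groups = NULL,
                  labels = NULL, top_n = 10L),
    ner = list(lr = 2e-5, hidden_dim = 200L, dropout = 0.5,
               batch_size = 64L, epochs = 3L, max_seq_len = 256L,
               peephole = TRUE, objective = "crf"),
    profile = list(dims = c("sex", "edu"), top_n = 10L)
  )
}

merge_config <- function(defaults, overrides, path = "") {
  if (is.null(overrides)) return(defaults)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad)) {
    abort(paste0("unknown config key(s): ",
                 paste0(path, bad, collapse = ", ")))
  }
  for (nm in names(overrides)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_config(defaults[[nm]], overrides[[nm]],
                                     paste0(path, nm, "."))
    } else {
      defaults[[nm]] <- overrides[[nm]]
    }
  }
  defaults
}

#' Build a validated pipeline configuration
#'
#' Defaults reproduce the reference settings: 20 topics with
#' `alpha = 50/K`, `beta = 0.01`; NER with learning rate `2e-5`, hidden
#' dimension 200, dropout 0.5, `max_seq_len` 256. Unknown keys are
#' rejected before any computation.
#'
#' @param ... Named overrides, nested lists per stage (e.g.
#'   `lda = list(K = 5)`), or a single list argument.
#' @return A `"pipeline_config"` list.
#' @export
pipeline_config <- function(...) {
  dots <- list(...)
  if (length(dots) == 1 && is.null(names(dots)) && is.list(dots[[1]])) {
    dots <- dots[[1]]
  }
  cfg <- merge_config(pipeline_defaults(), dots)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with stage-keyed parameters.
#' @return A validated `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

write_csv_stable <- function(df, path) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE)
  path
}

file_checksum <- function(path) {
  rlang::hash(readLines(path, warn = FALSE))
}

#' Run the full stress-detection pipeline
#'
#' Stages, in order: tokenize and encode all posts; fit LDA and build
#' topic vectors; fuse token embeddings with each document's optimal
#' topic vector; train the sentiment head on the labelled posts and split
#' the corpus, keeping the negative predictions as the stress document
#' set; refit topics on the stress set and merge them into the five
#' stress features; train (or reuse) the entity tagger and extract
#' SEX/EDU/ORG mentions from the stress set; derive facets and the
#' per-category stress profile. Every artifact lands in `out_dir`
#' together with a manifest (config hash, seeds, artifact checksums) and
#' a structured log.
#'
#' @param posts A posts table; sentiment training uses the rows whose
#'   `label_sentiment` is set.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @param ner_train Optional BIO-annotated sentences for tagger training;
#'   by default a synthetic planted-entity corpus is generated.
#' @param ner_model Optional pre-trained `"ner_model"` (skips training).
#' @param verbose Print stage progress.
#' @return Invisibly, a list with the fitted objects and artifact paths.
#' @export
run_pipeline <- function(posts, config = pipeline_config(), out_dir,
                         ner_train = NULL, ner_model = NULL,
                         verbose = FALSE) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  posts <- posts_tbl(posts)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  logs <- list()
  say <- function(stage, ...) {
    msg <- paste0(...)
    logs[[length(logs) + 1]] <<- list(stage = stage, message = msg)
    if (verbose) cat("[", stage, "] ", msg, "\n", sep = "")
  }
  stage <- "tokenize"
  tokens <- tokenize_posts(posts, mode = config$tokenize$mode,
                           stopwords = config$tokenize$stopwords)
  posts <- posts[posts$id %in% unique(tokens$post_id), , drop = FALSE]
  say(stage, nrow(posts), " posts, ", nrow(tokens), " tokens")

  stage <- "encode"
  enc <- hash_encoder(dim = config$encoder$dim,
                      seed = derive_seed(seed, "encoder"),
                      max_seq_len = config$encoder$max_seq_len)
  encoded <- encode_posts(tokens, enc)
  say(stage, "dim ", enc$dim)

  stage <- "lda-fuse"
  K1 <- min(config$lda$K, max(1L, nrow(posts) - 1L))
  lda_all <- fit_lda(tokens, K = K1, alpha = config$lda$alpha,
                     beta = config$lda$beta, iters = config$lda$iters,
                     seed = derive_seed(seed, "lda-all"))
  tv_all <- suppressWarnings(topic_vectors(lda_all, encoded))
  fused <- fuse_posts(encoded, tv_all)
  say(stage, "K = ", K1)

  stage <- "sentiment"
  feat <- sentiment_features(fused)
  lab_idx <- !is.na(posts$label_sentiment %||% rep(NA, nrow(posts)))
  if (sum(lab_idx) < 2 || length(unique(posts$label_sentiment[lab_idx])) < 2) {
    abort("sentiment training needs labelled posts of both classes")
  }
  sm <- train_sentiment(feat[lab_idx, , drop = FALSE],
                        posts$label_sentiment[lab_idx],
                        holdout = config$sentiment$holdout,
                        class_weights = config$sentiment$class_weights,
                        threshold = config$sentiment$threshold,
                        seed = derive_seed(seed, "sentiment"))
  split <- split_corpus(posts, sm, feat)
  dt <- split$negative
  say(stage, nrow(dt), " negative / ", nrow(split$positive),
      " positive; held-out accuracy ",
      signif(sm$heldout_accuracy, 3))
  if (!nrow(dt)) abort("empty stress document set; nothing to profile")

  stage <- "topics"
  dt_tokens <- tokens[tokens$post_id %in% dt$id, , drop = FALSE]
  K2 <- min(config$topics$K, max(1L, nrow(dt) - 1L))
  lda_dt <- fit_lda(dt_tokens, K = K2, beta = config$lda$beta,
                    iters = config$topics$iters,
                    seed = derive_seed(seed, "lda-dt"))
  tv_dt <- suppressWarnings(
    topic_vectors(lda_dt, encoded[encoded$post_id %in% dt$id, , drop = FALSE]))
  groups <- config$topics$groups
  if (is.null(groups)) {
    groups <- auto_group_topics(tv_dt, min(config$topics$n_groups, K2))
  }
  labels <- config$topics$labels
  if (is.null(labels) && length(groups) == 5) labels <- stress_feature_labels()
  fmap <- merge_topics(lda_dt, groups, labels)
  say(stage, "K = ", K2, " merged into ", length(groups), " features")

  stage <- "ner"
  if (is.null(ner_model)) {
    if (is.null(ner_train)) {
      ner_train <- generate_ner_corpus(
        n_sentences = 800, seed = derive_seed(seed, "ner-synth"))$sentences
    }
    hy <- ner_hyper(lr = config$ner$lr, hidden_dim = config$ner$hidden_dim,
                    dropout = config$ner$dropout,
                    batch_size = config$ner$batch_size,
                    epochs = config$ner$epochs,
                    max_seq_len = config$ner$max_seq_len,
                    peephole = config$ner$peephole,
                    objective = config$ner$objective,
                    seed = derive_seed(seed, "ner"))
    ner_model <- train_ner(ner_train, encoder = enc, hyper = hy)
  }
  entities <- extract_entities(ner_model, dt_tokens)
  say(stage, nrow(entities), " entity mentions in the stress set")

  stage <- "profile"
  facets <- suppressWarnings(
    facets_from_entities(entities, post_ids = dt$id))
  prof <- stress_profile(dt_tokens, facets, fmap,
                         dims = config$profile$dims,
                         top_n = config$profile$top_n)
  say(stage, length(unique(prof$category)), " categories, ",
      attr(prof, "n_excluded"), " docs excluded (unknown facets)")

  paths <- list(
    models = file.path(out_dir, "models.json"),
    dt = file.path(out_dir, "stress_set.jsonl"),
    positive = file.path(out_dir, "positive_set.jsonl"),
    feature_map = file.path(out_dir, "feature_map.csv"),
    entities = file.path(out_dir, "entities.csv"),
    profile = file.path(out_dir, "profile.csv"),
    manifest = file.path(out_dir, "manifest.json"),
    log = file.path(out_dir, "run.log")
  )
  jsonlite::write_json(list(
    lda_all = as.list(glance(lda_all)),
    lda_stress = as.list(glance(lda_dt)),
    sentiment = list(bias = sm$bias, weights = sm$weights,
                     heldout_accuracy = sm$heldout_accuracy),
    ner = as.list(glance(ner_model))
  ), paths$models, auto_unbox = TRUE, digits = NA)
  write_posts_jsonl(dt, paths$dt)
  write_posts_jsonl(split$positive, paths$positive)
  write_csv_stable(feature_top_words(fmap, config$topics$top_n),
                   paths$feature_map)
  write_csv_stable(entities, paths$entities)
  write_csv_stable(
    as.data.frame(prof)[, c("category", "feature", "n_docs", "hits",
                            "probability")],
    paths$profile)
  writeLines(vapply(logs, function(l) {
    paste0(l$stage, "\t", l$message)
  }, character(1)), paths$log)
  artifact_names <- c("models", "dt", "positive", "feature_map",
                      "entities", "profile")
  manifest <- list(
    package_version = as.character(utils::packageVersion("stresslens")),
    seed = seed,
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    stage_seeds = list(
      encoder = derive_seed(seed, "encoder"),
      lda_all = derive_seed(seed, "lda-all"),
      sentiment = derive_seed(seed, "sentiment"),
      lda_dt = derive_seed(seed, "lda-dt"),
      ner = derive_seed(seed, "ner")
    ),
    checksums = setNames(
      lapply(artifact_names, function(a) file_checksum(paths[[a]])),
      artifact_names)
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(list(posts = posts, stress_set = dt, sentiment = sm,
                 lda = lda_dt, feature_map = fmap, ner = ner_model,
                 entities = entities, facets = facets, profile = prof,
                 paths = paths, manifest = manifest))
}
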