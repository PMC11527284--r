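# Seeded synthetic-corpus generators. Each generator is a pure function of
# its arguments (all randomness flows through the seed), returns the
# ground truth alongside the corpus, and emits the same tabular shapes the
# readers produce, so every pipeline stage can be validated by parameter
# recovery without any external data. Tokens are abstract strings
# ("w0017", "ORG3_a"): the pipeline is script-agnostic, and a real-language
# corpus is a lexicon swap away.

synth_vocab <- function(V) sprintf("w%04d", seq_len(V))

#' Synthetic entity lexicons
#'
#' Surface forms for the three entity facets: four single-token gender
#' surfaces, six degree surfaces, and `n_org` institution names of one to
#' three tokens (`"ORG7_a ORG7_b"` style).
#'
#' @param n_org Number of institution names (default 20).
#' @return A list with character vectors `SEX`, `EDU`, `ORG`.
#' @export
default_ner_lexicons <- function(n_org = 20) {
  orgs <- vapply(seq_len(n_org), function(i) {
    len <- (i %% 3) + 1
    paste(sprintf("ORG%d_%s", i, letters[seq_len(len)]), collapse = " ")
  }, character(1))
  list(
    SEX = c("male", "female", "man", "woman"),
    EDU = c("master", "masters", "msc", "phd", "doctoral", "doctorate"),
    ORG = orgs
  )
}

#' Synthetic world-class institution lexicon
#'
#' The first eight institutions of [default_ner_lexicons()] play the role
#' of "world-class" universities; the rest are non-top-tier.
#'
#' @return Character vector of surfaces.
#' @export
default_world_class_lexicon <- function() {
  default_ner_lexicons()$ORG[1:8]
}

#' Generate an LDA corpus with planted topics
#'
#' Documents follow the LDA generative process with a planted topic-word
#' table: a `topic_separation` fraction of each topic's mass sits on its
#' own disjoint vocabulary block (1 = fully disjoint supports), the rest
#' is spread over the whole vocabulary. Document-topic weights are
#' symmetric-Dirichlet(`alpha_true`); document lengths are Poisson around
#' `tokens_per_doc` (minimum 2).
#'
#' @param M Number of documents.
#' @param K_true Number of planted topics.
#' @param V Vocabulary size (must allow `K_true` non-empty blocks).
#' @param tokens_per_doc Mean document length.
#' @param alpha_true Document-topic Dirichlet concentration (default 0.2:
#'   short stress posts are near-single-topic).
#' @param beta_true Within-block Dirichlet concentration of the planted
#'   topic-word rows (default 0.5).
#' @param topic_separation Fraction of each topic's mass on its own
#'   vocabulary block, in `[0, 1]` (default 1).
#' @param seed Integer seed.
#' @return A list: `posts` (posts tibble, whitespace-joined text),
#'   `tokens` (tokenized tibble), `true_theta` (`M x K`), `true_phi`
#'   (`K x V`, columns named), `true_assignments` (per-document integer
#'   topic vectors).
#' @export
generate_topic_corpus <- function(M = 300, K_true = 3, V = 60,
                                  tokens_per_doc = 40, alpha_true = 0.2,
                                  beta_true = 0.5, topic_separation = 1,
                                  seed = 1) {
  if (topic_separation < 0 || topic_separation > 1) {
    abort("topic_separation must be in [0, 1]")
  }
  if (V < K_true) abort("infeasible config: V < K_true")
  set.seed(seed)
  vocab <- synth_vocab(V)
  block <- sort(rep(seq_len(K_true), length.out = V))
  phi <- matrix(0, K_true, V, dimnames = list(NULL, vocab))
  for (k in seq_len(K_true)) {
    own <- which(block == k)
    w_own <- rgamma(length(own), beta_true, 1)
    phi[k, own] <- topic_separation * w_own / sum(w_own)
    if (topic_separation < 1) {
      w_all <- rgamma(V, 1, 1)
      phi[k, ] <- phi[k, ] + (1 - topic_separation) * w_all / sum(w_all)
    }
  }
  theta <- matrix(rgamma(M * K_true, alpha_true, 1), M, K_true)
  theta <- theta / rowSums(theta)
  if (K_true == 1) theta[] <- 1
  docs <- vector("list", M)
  zs <- vector("list", M)
  for (i in seq_len(M)) {
    n <- max(2L, rpois(1, tokens_per_doc))
    z <- sample.int(K_true, n, replace = TRUE, prob = theta[i, ])
    w <- vapply(z, function(k) sample.int(V, 1, prob = phi[k, ]), integer(1))
    docs[[i]] <- vocab[w]
    zs[[i]] <- z
  }
  ids <- sprintf("topic%04d", seq_len(M))
  posts <- tibble::tibble(
    id = ids,
    text = vapply(docs, paste, character(1), collapse = " "),
    platform = "synthetic"
  )
  tokens <- tibble::tibble(
    post_id = rep(ids, lengths(docs)),
    token = unlist(docs),
    position = unlist(lapply(lengths(docs), function(n) seq_len(n) - 1L)),
    sentence = 1L
  )
  list(posts = posts, tokens = tokens, true_theta = theta, true_phi = phi,
       true_assignments = zs)
}

#' Generate a sentiment corpus with planted labels
#'
#' Each document is negative with probability `balance_negative` (default
#' 0.883, the negative share of the corpus this pipeline targets). A
#' document of class `c` draws each token from its class's valence block
#' with probability `valence_rate[c]`, otherwise from the shared
#' background vocabulary.
#'
#' @param n Number of documents.
#' @param balance_negative P(negative) per document.
#' @param valence_rate Named vector with `negative` and `positive` rates
#'   in `[0, 1]`.
#' @param tokens_per_doc Mean document length (Poisson, minimum 2).
#' @param V_background Background vocabulary size.
#' @param n_valence Valence-block size per class.
#' @param seed Integer seed.
#' @return A list: `posts` (with `label_sentiment`), `labels` (character
#'   vector aligned with posts).
#' @export
generate_sentiment_corpus <- function(n = 1000, balance_negative = 0.883,
                                      valence_rate = c(negative = 0.5,
                                                       positive = 0.5),
                                      tokens_per_doc = 20,
                                      V_background = 100, n_valence = 20,
                                      seed = 1) {
  if (any(valence_rate < 0) || any(valence_rate > 1)) {
    abort("valence_rate must be in [0, 1]")
  }
  if (balance_negative < 0 || balance_negative > 1) {
    abort("balance_negative must be in [0, 1]")
  }
  set.seed(seed)
  bg <- synth_vocab(V_background)
  neg_block <- sprintf("neg%03d", seq_len(n_valence))
  pos_block <- sprintf("pos%03d", seq_len(n_valence))
  labels <- ifelse(runif(n) < balance_negative, "negative", "positive")
  docs <- lapply(seq_len(n), function(i) {
    len <- max(2L, rpois(1, tokens_per_doc))
    rate <- valence_rate[[labels[i]]]
    block <- if (labels[i] == "negative") neg_block else pos_block
    use_val <- runif(len) < rate
    toks <- character(len)
    toks[use_val] <- sample(block, sum(use_val), replace = TRUE)
    toks[!use_val] <- sample(bg, sum(!use_val), replace = TRUE)
    toks
  })
  ids <- sprintf("sent%04d", seq_len(n))
  posts <- tibble::tibble(
    id = ids,
    text = vapply(docs, paste, character(1), collapse = " "),
    platform = "synthetic",
    label_sentiment = labels
  )
  list(posts = posts, labels = labels)
}

#' Generate BIO-annotated sentences with planted entities
#'
#' Sentences of background tokens with entity mentions planted from the
#' synthetic lexicons; multi-token institution names get `B-ORG I-ORG ...`
#' labels. `org_only = TRUE` restricts planting to ORG (the first-stage
#' pretraining regime). Gold spans equal the planting log exactly.
#'
#' @param n_sentences Number of sentences.
#' @param plant_prob Named per-sentence planting probabilities for `SEX`,
#'   `EDU`, `ORG`.
#' @param tokens_per_sentence Mean background length (Poisson, minimum 4).
#' @param V_background Background vocabulary size.
#' @param lexicons Entity lexicons (default [default_ner_lexicons()]).
#' @param org_only Plant only ORG entities.
#' @param seed Integer seed.
#' @return A list: `sentences` (tibble `sentence_id`, `position`, `token`,
#'   `label`) and `spans` (gold plant log: `sentence_id`, `entity_type`,
#'   `start`, `end`, `surface`).
#' @export
generate_ner_corpus <- function(n_sentences = 2000,
                                plant_prob = c(SEX = 0.4, EDU = 0.4,
                                               ORG = 0.5),
                                tokens_per_sentence = 10,
                                V_background = 200,
                                lexicons = default_ner_lexicons(),
                                org_only = FALSE, seed = 1) {
  types <- if (org_only) "ORG" else c("SEX", "EDU", "ORG")
  for (tp in types) {
    if (!length(lexicons[[tp]])) abort(paste0("empty lexicon for ", tp))
  }
  set.seed(seed)
  bg <- sprintf("b%04d", seq_len(V_background))
  sent_rows <- vector("list", n_sentences)
  span_rows <- vector("list", n_sentences)
  for (i in seq_len(n_sentences)) {
    len <- max(4L, rpois(1, tokens_per_sentence))
    toks <- sample(bg, len, replace = TRUE)
    labs <- rep("O", len)
    plant <- types[runif(length(types)) < plant_prob[types]]
    spans <- NULL
    for (tp in plant) {
      surface <- sample(lexicons[[tp]], 1)
      ent <- strsplit(surface, " ", fixed = TRUE)[[1]]
      # insert at a position currently labelled O, keeping entities disjoint
      at <- which(labs == "O")
      at <- at[at + length(ent) - 1 <= length(toks)]
      at <- at[vapply(at, function(a) {
        all(labs[a:(a + length(ent) - 1)] == "O")
      }, logical(1))]
      if (!length(at)) next
      a <- at[sample.int(length(at), 1)]
      idx <- a:(a + length(ent) - 1)
      toks[idx] <- ent
      labs[idx] <- c(paste0("B-", tp),
                     rep(paste0("I-", tp), length(ent) - 1))
      spans <- rbind(spans, data.frame(entity_type = tp, start = a - 1L,
                                       end = a - 1L + length(ent),
                                       surface = surface))
    }
    sent_rows[[i]] <- tibble::tibble(
      sentence_id = i, position = seq_along(toks) - 1L,
      token = toks, label = labs
    )
    if (!is.null(spans)) {
      spans$sentence_id <- i
      span_rows[[i]] <- tibble::as_tibble(spans)
    }
  }
  spans <- dplyr::bind_rows(span_rows)
  if (nrow(spans)) {
    spans <- spans[order(spans$sentence_id, spans$start),
                   c("sentence_id", "entity_type", "start", "end", "surface")]
  } else {
    spans <- tibble::tibble(sentence_id = integer(), entity_type = character(),
                            start = integer(), end = integer(),
                            surface = character())
  }
  list(sentences = dplyr::bind_rows(sent_rows), spans = spans)
}

#' Synthetic stress-feature map
#'
#' Five features with ten dedicated words each (`research_w01`, ...),
#' uniform within-feature probabilities; used as planted ground truth by
#' [generate_profile_corpus()].
#'
#' @return A `"stress_features"` object.
#' @export
synthetic_feature_map <- function() {
  feats <- stress_feature_labels()
  top_words <- dplyr::bind_rows(lapply(feats, function(f) {
    tibble::tibble(feature = f, token = sprintf("%s_w%02d", f, 1:10),
                   probability = 0.1, rank = 1:10)
  }))
  structure(list(mapping = tibble::tibble(topic = seq_along(feats),
                                          feature = feats),
                 top_words = top_words),
            class = "stress_features")
}

#' Generate a profile corpus with planted facets and feature mixtures
#'
#' Each document draws a mixed-label category (over sex x edu), plants the
#' corresponding gender and degree surface tokens (plus an institution
#' mention with probability `org_rate`), and draws its remaining tokens
#' from the category's stress-feature mixture (rate `feature_rate`) or
#' the background vocabulary.
#'
#' @param n_docs Number of documents.
#' @param category_probs Named probabilities over the four sex x edu
#'   categories; must sum to 1.
#' @param feature_mixture A 4 x 5 matrix (categories x features), each row
#'   summing to 1; default rows emphasize different features.
#' @param feature_rate Probability a non-entity token is a feature word.
#' @param tokens_per_doc Mean number of non-entity tokens.
#' @param org_rate Probability of planting an institution mention.
#' @param seed Integer seed.
#' @return A list: `posts`, `tokens`, `facets` (planted truth incl.
#'   `category`), `mixtures` (the planted 4 x 5 matrix), `feature_map`.
#' @export
generate_profile_corpus <- function(n_docs = 2000,
                                    category_probs = c("male:doctor" = 0.25,
                                                       "female:doctor" = 0.25,
                                                       "male:master" = 0.25,
                                                       "female:master" = 0.25),
                                    feature_mixture = NULL,
                                    feature_rate = 0.4, tokens_per_doc = 20,
                                    org_rate = 0.5, seed = 1) {
  if (abs(sum(category_probs) - 1) > 1e-9) {
    abort("category_probs must sum to 1")
  }
  feats <- stress_feature_labels()
  if (is.null(feature_mixture)) {
    feature_mixture <- rbind(
      c(0.50, 0.20, 0.20, 0.05, 0.05),
      c(0.20, 0.50, 0.10, 0.10, 0.10),
      c(0.10, 0.10, 0.50, 0.20, 0.10),
      c(0.05, 0.05, 0.20, 0.50, 0.20)
    )
  }
  rownames(feature_mixture) <- names(category_probs)
  colnames(feature_mixture) <- feats
  if (any(abs(rowSums(feature_mixture) - 1) > 1e-9)) {
    abort("feature_mixture rows must sum to 1")
  }
  fmap <- synthetic_feature_map()
  top <- feature_top_words(fmap, 10)
  lex <- default_ner_lexicons()
  sex_surf <- list(male = c("male", "man"), female = c("female", "woman"))
  edu_surf <- list(master = c("master", "masters", "msc"),
                   doctor = c("phd", "doctoral", "doctorate"))
  wc <- default_world_class_lexicon()
  set.seed(seed)
  bg <- sprintf("g%04d", seq_len(150))
  cat_draw <- sample(names(category_probs), n_docs, replace = TRUE,
                     prob = category_probs)
  docs <- vector("list", n_docs)
  org_tier <- rep(NA_character_, n_docs)
  for (i in seq_len(n_docs)) {
    parts <- strsplit(cat_draw[i], ":", fixed = TRUE)[[1]]
    n <- max(4L, rpois(1, tokens_per_doc))
    is_feat <- runif(n) < feature_rate
    toks <- character(n)
    if (any(is_feat)) {
      f <- sample(feats, sum(is_feat), replace = TRUE,
                  prob = feature_mixture[cat_draw[i], ])
      toks[is_feat] <- vapply(f, function(ff) {
        sample(top$token[top$feature == ff], 1)
      }, character(1))
    }
    toks[!is_feat] <- sample(bg, sum(!is_feat), replace = TRUE)
    ent <- c(sample(sex_surf[[parts[1]]], 1), sample(edu_surf[[parts[2]]], 1))
    if (runif(1) < org_rate) {
      org <- sample(lex$ORG, 1)
      org_tier[i] <- if (org %in% wc) "world_class" else "non_top_tier"
      ent <- c(ent, strsplit(org, " ", fixed = TRUE)[[1]])
    }
    at <- sample.int(n + 1, 1) - 1L
    docs[[i]] <- append(toks, ent, after = at)
  }
  ids <- sprintf("prof%05d", seq_len(n_docs))
  facets <- tibble::tibble(
    post_id = ids,
    sex = vapply(strsplit(cat_draw, ":"), `[`, character(1), 1),
    edu = vapply(strsplit(cat_draw, ":"), `[`, character(1), 2),
    org_tier = org_tier,
    category = cat_draw
  )
  posts <- tibble::tibble(
    id = ids,
    text = vapply(docs, paste, character(1), collapse = " "),
    platform = "synthetic"
  )
  tokens <- tibble::tibble(
    post_id = rep(ids, lengths(docs)),
    token = unlist(docs),
    position = unlist(lapply(lengths(docs), function(n) seq_len(n) - 1L)),
    sentence = 1L
  )
  list(posts = posts, tokens = tokens, facets = facets,
       mixtures = feature_mixture, feature_map = fmap)
}
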