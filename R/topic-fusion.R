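# Embedding-topic fusion: topics fitted on discrete token counts are lifted
# into the embedding space as centroids of the token vectors assigned to
# them; a document's topic vector is the theta-weighted combination of those
# centroids; the best topic for a document maximizes cosine similarity with
# the mean document embedding; the chosen topic vector is added to every
# token vector to give topic-aware "fused" token representations.

#' Topic vectors in embedding space
#'
#' The vector of topic `k` is the centroid of all token embeddings whose
#' Gibbs assignment is `k` (across the whole corpus). Each document also
#' gets a combined vector `z_i = sum_k theta_ik t_k`. A topic with no
#' assigned token gets the zero vector with a warning. Documents longer
#' than the encoder's `max_seq_len` contribute only their encoded prefix.
#'
#' @param model A fitted [fit_lda()] model.
#' @param encoded An [encode_posts()] tibble covering every model document.
#' @return An object of class `"topic_vectors"`: `topics` (`K x d` matrix),
#'   `docs` (`M x d` matrix, rows named by post id), `n_assigned` (tokens
#'   per topic that contributed).
#' @export
topic_vectors <- function(model, encoded) {
  idx <- match(model$doc_ids, encoded$post_id)
  if (anyNA(idx)) abort("`encoded` must cover every document in the model")
  d <- ncol(encoded$embedding[[1]])
  K <- model$K
  sums <- matrix(0, K, d)
  counts <- integer(K)
  for (i in seq_along(model$doc_ids)) {
    emb <- encoded$embedding[[idx[i]]]
    z <- model$assignments[[i]]
    n <- min(nrow(emb), length(z))
    if (n < 1) next
    z <- z[seq_len(n)]
    emb <- emb[seq_len(n), , drop = FALSE]
    for (k in unique(z)) {
      rows <- z == k
      sums[k, ] <- sums[k, ] + colSums(emb[rows, , drop = FALSE])
      counts[k] <- counts[k] + sum(rows)
    }
  }
  if (any(counts == 0)) {
    warn(paste0("topic(s) with no assigned tokens get zero vectors: ",
                paste(which(counts == 0), collapse = ", ")))
  }
  topics <- sums / pmax(counts, 1L)
  topics[counts == 0, ] <- 0
  docs <- lda_theta(model) %*% topics
  structure(list(topics = topics, docs = docs, n_assigned = counts),
            class = "topic_vectors")
}

#' Cosine similarity of two vectors
#'
#' @param a,b Numeric vectors of equal length, both non-zero.
#' @return `a . b / (|a| |b|)`, in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) abort("cosine similarity of a zero vector is undefined")
  sum(a * b) / (na * nb)
}

#' Assign the optimal topic to document embeddings
#'
#' The optimal topic maximizes cosine similarity (equivalently, minimizes
#' cosine distance) between the document embedding and the topic vectors.
#' Ties break to the smallest topic id; zero-norm topic vectors are never
#' selected (all-zero topic matrices are an error).
#'
#' @param doc_vec A length-`d` vector or an `M x d` matrix of document
#'   embeddings.
#' @param topics A `K x d` topic-vector matrix (or a `"topic_vectors"`
#'   object).
#' @return Integer topic id(s) in `1..K`.
#' @export
assign_optimal_topic <- function(doc_vec, topics) {
  if (inherits(topics, "topic_vectors")) topics <- topics$topics
  if (is.null(dim(doc_vec))) doc_vec <- matrix(doc_vec, nrow = 1)
  tn <- sqrt(rowSums(topics^2))
  if (all(tn == 0)) abort("all topic vectors are zero")
  dn <- sqrt(rowSums(doc_vec^2))
  if (any(dn == 0)) abort("zero document embedding")
  sims <- (doc_vec %*% t(topics)) / outer(dn, tn)
  sims[, tn == 0] <- -Inf
  out <- apply(sims, 1, which.max)  # first max = smallest id on ties
  as.integer(out)
}

#' Fuse an embedding sequence with a topic vector
#'
#' Adds the selected topic vector to every token vector, yielding the
#' topic-aware dynamic representation.
#'
#' @param seq An `N x d` token-embedding matrix.
#' @param topic_vec A length-`d` topic vector.
#' @return An `N x d` matrix.
#' @export
fuse <- function(seq, topic_vec) {
  if (ncol(seq) != length(topic_vec)) abort("dimension mismatch in fuse()")
  sweep(seq, 2, topic_vec, "+")
}

#' Fuse a whole encoded corpus
#'
#' For each document, selects the optimal topic by cosine similarity
#' between the mean document embedding and the topic vectors, then fuses.
#'
#' @param encoded An [encode_posts()] tibble.
#' @param tv A `"topic_vectors"` object (or `K x d` matrix).
#' @return `encoded` with extra columns `topic` (selected topic id) and
#'   `fused` (list-column of `N x d` matrices).
#' @export
fuse_posts <- function(encoded, tv) {
  topics <- if (inherits(tv, "topic_vectors")) tv$topics else tv
  dmat <- doc_embeddings(encoded)
  sel <- assign_optimal_topic(dmat, topics)
  encoded$topic <- sel
  encoded$fused <- lapply(seq_len(nrow(encoded)), function(i) {
    fuse(encoded$embedding[[i]], topics[sel[i], ])
  })
  encoded
}

#' Default topic-to-feature grouping for a 20-topic model
#'
#' The shipped grouping merges a 20-topic model four-per-feature into the
#' five stress features; it is corpus-specific and meant as an editable
#' starting point (see [auto_group_topics()] for a data-driven default).
#' Topic ids are 1-based.
#'
#' @return A named list of integer vectors partitioning `1:20`.
#' @export
default_topic_groups <- function() {
  list(
    research   = c(2L, 7L, 12L, 13L),
    employment = c(1L, 3L, 15L, 19L),
    affection  = c(4L, 8L, 9L, 10L),
    financial  = c(5L, 14L, 16L, 18L),
    other      = c(6L, 11L, 17L, 20L)
  )
}

#' The five stress feature labels
#' @return Character vector.
#' @export
stress_feature_labels <- function() {
  c("research", "employment", "affection", "financial", "other")
}

#' Merge topics into labelled stress features
#'
#' Each feature's word distribution is the mean of its member topics'
#' smoothed topic-word rows, re-ranked by probability. `groups` must
#' partition `1:K`.
#'
#' @param model A fitted [fit_lda()] model.
#' @param groups List of integer vectors partitioning `1:K`.
#' @param labels Feature names, one per group (defaults to the five stress
#'   features when there are five groups).
#' @return An object of class `"stress_features"`: `mapping` (tibble of
#'   `topic`, `feature`) and `top_words` (tibble of `feature`, `token`,
#'   `probability`, `rank`).
#' @export
merge_topics <- function(model, groups, labels = NULL) {
  K <- model$K
  flat <- sort(unlist(groups))
  if (!identical(as.integer(flat), seq_len(K))) {
    abort("`groups` must partition the topic ids 1..K")
  }
  if (is.null(labels)) {
    labels <- names(groups) %||%
      (if (length(groups) == 5) stress_feature_labels() else
         paste0("feature", seq_along(groups)))
  }
  if (length(labels) != length(groups)) {
    abort("`labels` must have one name per group")
  }
  phi <- lda_phi(model)
  rows <- lapply(seq_along(groups), function(g) {
    p <- unname(colMeans(phi[groups[[g]], , drop = FALSE]))
    ord <- order(-p, model$vocab)
    tibble::tibble(feature = labels[g], token = model$vocab[ord],
                   probability = p[ord], rank = seq_along(ord))
  })
  structure(
    list(
      mapping = tibble::tibble(
        topic = unlist(groups),
        feature = rep(labels, lengths(groups))
      ) |> dplyr::arrange(.data$topic),
      top_words = dplyr::bind_rows(rows)
    ),
    class = "stress_features"
  )
}

#' @export
print.stress_features <- function(x, n = 5, ...) {
  cat("<stress_features>", dplyr::n_distinct(x$mapping$feature),
      "features over", nrow(x$mapping), "topics\n")
  print(dplyr::slice_head(dplyr::group_by(x$top_words, .data$feature), n = n))
  invisible(x)
}

#' @export
tidy.stress_features <- function(x, ...) x$top_words

#' Top feature words
#'
#' @param features A `"stress_features"` object.
#' @param top_n Words per feature (default 10).
#' @return A tibble of `feature`, `token`, `probability`, `rank`.
#' @export
feature_top_words <- function(features, top_n = 10) {
  dplyr::ungroup(dplyr::slice_head(
    dplyr::group_by(features$top_words, .data$feature), n = top_n))
}

#' Group topics by embedding similarity
#'
#' Agglomerative clustering (average linkage) of the topic centroid vectors
#' under cosine distance; a reproducible default for the manual merging of
#' similar topics into features. Zero-vector topics are assigned to their
#' own groups last.
#'
#' @param tv A `"topic_vectors"` object.
#' @param n_groups Number of groups (`<= K`).
#' @return A list of integer vectors partitioning `1:K`, ordered by their
#'   smallest member.
#' @export
auto_group_topics <- function(tv, n_groups) {
  topics <- if (inherits(tv, "topic_vectors")) tv$topics else tv
  K <- nrow(topics)
  if (n_groups > K) abort("n_groups must be <= K")
  if (n_groups == K) return(as.list(seq_len(K)))
  nrm <- sqrt(rowSums(topics^2))
  unit <- topics / pmax(nrm, .Machine$double.eps)
  cosd <- 1 - tcrossprod(unit)
  cosd[nrm == 0, ] <- 2; cosd[, nrm == 0] <- 2  # zero topics are far from all
  diag(cosd) <- 0
  hc <- hclust(as.dist(cosd), method = "average")
  cl <- cutree(hc, k = n_groups)
  groups <- split(seq_len(K), cl)
  groups <- groups[order(vapply(groups, min, integer(1)))]
  unname(lapply(groups, as.integer))
}
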