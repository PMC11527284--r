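# Binary sentiment stratification. The head is deliberately minimal -- a
# logistic decision over mean-pooled fused token vectors -- because its job
# in the pipeline is to exercise the fused representation and carve out the
# negative "stress document set", not to be a state-of-the-art classifier.

#' Mean-pool a fused token sequence
#'
#' @param fused An `N x d` matrix of fused token vectors.
#' @return A length-`d` vector (the arithmetic mean over tokens).
#' @export
pool <- function(fused) {
  if (!is.matrix(fused) || nrow(fused) == 0) abort("empty fused sequence")
  colMeans(fused)
}

#' Pooled feature matrix for a fused corpus
#'
#' @param fused_tbl A tibble from [fuse_posts()] (with a `fused`
#'   list-column).
#' @return An `M x d` matrix, rows named by post id.
#' @export
sentiment_features <- function(fused_tbl) {
  out <- t(vapply(fused_tbl$fused, pool,
                  numeric(ncol(fused_tbl$fused[[1]]))))
  rownames(out) <- fused_tbl$post_id
  out
}

#' Train the logistic sentiment head
#'
#' Fits P(negative | pooled vector) by maximum-likelihood logistic
#' regression. A seeded held-out split reports accuracy. Optional
#' inverse-frequency class weights counter class imbalance (the corpus this
#' pipeline targets is roughly 88% negative); off by default.
#'
#' @param x `M x d` feature matrix (pooled fused vectors).
#' @param labels Character vector in `{"negative", "positive"}`.
#' @param holdout Held-out fraction for the reported accuracy (default 0.2;
#'   0 trains on everything and reports `NA`).
#' @param class_weights Use inverse-frequency observation weights.
#' @param threshold Decision threshold on P(negative), in (0, 1).
#' @param seed Seed for the held-out split.
#' @return An object of class `"sentiment_model"`.
#' @export
train_sentiment <- function(x, labels, holdout = 0.2, class_weights = FALSE,
                            threshold = 0.5, seed = 1) {
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  if (threshold <= 0 || threshold >= 1) abort("threshold must be in (0, 1)")
  bad <- setdiff(unique(labels), c("negative", "positive"))
  if (length(bad)) abort("labels must be 'negative' or 'positive'")
  if (length(unique(labels)) < 2) {
    abort("training set must contain both classes")
  }
  y <- as.integer(labels == "negative")
  set.seed(derive_seed(seed, "sentiment-split"))
  n <- nrow(x)
  idx_hold <- if (holdout > 0) sample(n, max(1L, floor(n * holdout))) else integer()
  idx_train <- setdiff(seq_len(n), idx_hold)
  if (length(unique(y[idx_train])) < 2) {
    abort("training split lost a class; lower `holdout`")
  }
  w <- rep(1, length(idx_train))
  if (class_weights) {
    freq <- table(y[idx_train]) / length(idx_train)
    w <- as.numeric(1 / (2 * freq[as.character(y[idx_train])]))
  }
  df <- as.data.frame(x[idx_train, , drop = FALSE])
  names(df) <- paste0("f", seq_len(ncol(x)))
  df$.y <- y[idx_train]
  fit <- suppressWarnings(
    glm(.y ~ ., data = df, family = binomial(), weights = w)
  )
  coefs <- coef(fit)
  coefs[is.na(coefs)] <- 0
  model <- structure(
    list(weights = unname(coefs[-1]), bias = unname(coefs[1]),
         threshold = threshold, seed = seed,
         n_train = length(idx_train), heldout_accuracy = NA_real_),
    class = "sentiment_model"
  )
  if (length(idx_hold)) {
    pred <- predict(model, x[idx_hold, , drop = FALSE])
    model$heldout_accuracy <- mean(pred == labels[idx_hold])
  }
  model
}

#' @export
print.sentiment_model <- function(x, ...) {
  cat("<sentiment_model> d =", length(x$weights),
      " held-out accuracy =", signif(x$heldout_accuracy, 4), "\n")
  invisible(x)
}

#' Predict sentiment labels or probabilities
#'
#' @param object A `"sentiment_model"`.
#' @param x Feature matrix (or single vector).
#' @param type `"label"` (default) or `"prob"` (P(negative)).
#' @param ... Unused.
#' @return Character labels or numeric probabilities.
#' @export
predict.sentiment_model <- function(object, x, type = c("label", "prob"),
                                    ...) {
  type <- match.arg(type)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  p <- as.vector(stats::plogis(x %*% object$weights + object$bias))
  if (type == "prob") return(p)
  ifelse(p >= object$threshold, "negative", "positive")
}

#' Split a corpus into the stress document set and its complement
#'
#' Partitions posts by predicted sentiment: the negative predictions form
#' the stress document set `DT`. The split is exact -- every post lands in
#' exactly one side.
#'
#' @param posts A posts table.
#' @param model A trained `"sentiment_model"`.
#' @param x `M x d` pooled feature matrix aligned with `posts` rows.
#' @return A list with tibbles `negative` (the stress set) and `positive`.
#' @export
split_corpus <- function(posts, model, x) {
  posts <- posts_tbl(posts)
  stopifnot(nrow(x) == nrow(posts))
  lab <- predict(model, x)
  list(negative = posts[lab == "negative", , drop = FALSE],
       positive = posts[lab == "positive", , drop = FALSE])
}

#' @export
tidy.sentiment_model <- function(x, ...) {
  tibble::tibble(term = c("(bias)", paste0("f", seq_along(x$weights))),
                 estimate = c(x$bias, x$weights))
}

#' @export
glance.sentiment_model <- function(x, ...) {
  tibble::tibble(n_train = x$n_train, threshold = x$threshold,
                 heldout_accuracy = x$heldout_accuracy)
}
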