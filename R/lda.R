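# Latent Dirichlet allocation by collapsed Gibbs sampling.
#
# theta and phi are integrated out; the sampler walks per-token topic
# assignments using the count-based conditionals, which gives exact count
# invariants (sum of topic-word counts per topic == sum of doc-topic counts
# per topic == tokens assigned to that topic) checkable after every run.

lda_docs_from_tokens <- function(tokens, vocab = NULL) {
  stopifnot(all(c("post_id", "token") %in% names(tokens)))
  ids <- unique(tokens$post_id)
  if (is.null(vocab)) vocab <- sort(unique(tokens$token))
  wid <- match(tokens$token, vocab) - 1L  # 0-based; NA = out of vocabulary
  docs <- split(wid, factor(tokens$post_id, levels = ids))
  list(docs = docs, vocab = vocab, ids = ids)
}

#' Fit LDA by collapsed Gibbs sampling
#'
#' Symmetric Dirichlet priors: `alpha` on document-topic weights (default
#' `50 / K`) and `beta` on topic-word weights (default `0.01`). Smoothed
#' estimates are `phi[k, w] = (n_kw + beta) / (n_k + V beta)` and
#' `theta[i, k] = (n_ik + alpha) / (N_i + K alpha)`. Deterministic given
#' `seed`.
#'
#' @param tokens A tokenized corpus tibble (`post_id`, `token`).
#' @param K Number of topics (>= 1).
#' @param alpha,beta Dirichlet concentrations; `alpha = NULL` means `50 / K`.
#' @param iters Number of Gibbs sweeps (>= 1).
#' @param seed Integer seed.
#' @return An object of class `"lda_model"`.
#' @export
fit_lda <- function(tokens, K, alpha = NULL, beta = 0.01, iters = 200,
                    seed = 1) {
  if (K < 1) abort("K must be >= 1")
  if (iters < 1) abort("iters must be >= 1")
  if (is.null(alpha)) alpha <- 50 / K
  if (alpha <= 0 || beta <= 0) abort("alpha and beta must be positive")
  dd <- lda_docs_from_tokens(tokens)
  n_tok <- sum(lengths(dd$docs))
  if (K > n_tok) abort("K exceeds the total token count")
  if (any(lengths(dd$docs) == 0)) abort("every document must be non-empty")
  fit <- gibbs_lda_cpp(lapply(dd$docs, as.integer), as.integer(K),
                       length(dd$vocab), alpha, beta, as.integer(iters),
                       as.integer(seed))
  structure(
    list(K = as.integer(K), alpha = alpha, beta = beta, iters = iters,
         seed = as.integer(seed), vocab = dd$vocab, doc_ids = dd$ids,
         nkw = fit$nkw, ndk = fit$ndk, nk = as.integer(fit$nk),
         doc_len = as.integer(lengths(dd$docs)),
         assignments = lapply(fit$z, function(z) z + 1L)),
    class = "lda_model"
  )
}

#' @export
print.lda_model <- function(x, ...) {
  cat("<lda_model> K =", x$K, " V =", length(x$vocab),
      " docs =", length(x$doc_ids), " alpha =", signif(x$alpha, 4),
      " beta =", x$beta, "\n")
  invisible(x)
}

#' Smoothed topic-word distribution
#'
#' @param model A fitted [fit_lda()] model.
#' @return A `K x V` matrix whose rows sum to 1; columns named by token.
#' @export
lda_phi <- function(model) {
  V <- length(model$vocab)
  phi <- (model$nkw + model$beta) / (model$nk + V * model$beta)
  colnames(phi) <- model$vocab
  phi
}

#' Smoothed document-topic distribution
#'
#' @param model A fitted [fit_lda()] model.
#' @return An `M x K` matrix whose rows sum to 1; rows named by post id.
#' @export
lda_theta <- function(model) {
  theta <- (model$ndk + model$alpha) /
    (model$doc_len + model$K * model$alpha)
  rownames(theta) <- model$doc_ids
  theta
}

#' Corpus perplexity under a fitted model
#'
#' `exp(-mean log p(w))` per token with `p(w) = sum_k theta_ik phi_kw`.
#' If the scored documents are exactly the training documents (matched by
#' post id) the fitted theta is reused; otherwise document-topic weights are
#' estimated by fold-in Gibbs sampling with the topic-word statistics held
#' fixed. With `estimation_tokens`, theta is folded in on those tokens
#' instead (document completion: estimate on one half of each held-out
#' document, score the other half -- this removes the optimistic bias that
#' otherwise favours large topic counts). Out-of-vocabulary tokens are
#' excluded from the sum; their count is attached as the `"n_oov"`
#' attribute and reported.
#'
#' @param model A fitted [fit_lda()] model.
#' @param tokens The tokenized corpus to score.
#' @param estimation_tokens Optional tokenized corpus (same post ids) used
#'   only to estimate theta; documents absent from it fall back to the
#'   prior mean.
#' @param foldin_iters Gibbs sweeps for fold-in (default 20).
#' @param seed Seed for fold-in sampling.
#' @return Perplexity (a number >= 1 for any normalized model).
#' @export
lda_perplexity <- function(model, tokens, estimation_tokens = NULL,
                           foldin_iters = 20, seed = 1) {
  phi <- lda_phi(model)
  dd <- lda_docs_from_tokens(tokens, vocab = model$vocab)
  n_oov <- sum(vapply(dd$docs, function(w) sum(is.na(w)), integer(1)))
  docs <- lapply(dd$docs, function(w) as.integer(w[!is.na(w)]))
  keep <- lengths(docs) > 0
  if (n_oov > 0) inform(paste0(n_oov, " out-of-vocabulary token(s) excluded"))
  if (!any(keep)) abort("no in-vocabulary tokens to score")
  train_ids <- match(dd$ids, model$doc_ids)
  if (is.null(estimation_tokens) && !anyNA(train_ids)) {
    theta <- lda_theta(model)[train_ids, , drop = FALSE]
  } else {
    est <- if (is.null(estimation_tokens)) dd else {
      lda_docs_from_tokens(estimation_tokens, vocab = model$vocab)
    }
    est_docs <- lapply(est$docs, function(w) as.integer(w[!is.na(w)]))
    est_keep <- lengths(est_docs) > 0
    ndk <- gibbs_foldin_cpp(est_docs[est_keep], model$nkw, model$nk, model$K,
                            length(model$vocab), model$alpha, model$beta,
                            as.integer(foldin_iters), as.integer(seed))
    est_theta <- matrix(1 / model$K, length(est_docs), model$K)
    est_theta[est_keep, ] <- (ndk + model$alpha) /
      (lengths(est_docs)[est_keep] + model$K * model$alpha)
    idx <- match(dd$ids, est$ids)
    theta <- matrix(1 / model$K, length(docs), model$K)
    theta[!is.na(idx), ] <- est_theta[idx[!is.na(idx)], , drop = FALSE]
  }
  ll <- 0; n <- 0
  for (d in which(keep)) {
    pw <- as.vector(theta[d, , drop = FALSE] %*% phi[, docs[[d]] + 1L, drop = FALSE])
    ll <- ll + sum(log(pw))
    n <- n + length(docs[[d]])
  }
  out <- exp(-ll / n)
  attr(out, "n_oov") <- n_oov
  out
}

#' Select the number of topics by held-out perplexity
#'
#' Splits documents 80/20 (seeded), fits each candidate `K` with
#' `seeds_per_K` restarts on the training split, and scores held-out
#' perplexity by document completion: theta is folded in on the even-
#' indexed tokens of each held-out document and the odd-indexed tokens are
#' scored. The winner minimizes mean held-out perplexity, ties broken by
#' lower across-restart variance, then by smaller `K`.
#'
#' @param tokens Tokenized corpus tibble.
#' @param candidate_Ks Non-empty integer vector of candidate topic counts.
#' @param seeds_per_K Restarts per candidate (default 3).
#' @param iters Gibbs sweeps per fit.
#' @param holdout Held-out document fraction (default 0.2).
#' @param beta Topic-word prior (alpha follows `50 / K` per candidate).
#' @param seed Master seed (drives the split and the restart seeds).
#' @return A list with `K` (the selection) and `table` (a tibble of per-K
#'   mean and variance of held-out perplexity).
#' @export
select_topic_count <- function(tokens, candidate_Ks, seeds_per_K = 3,
                               iters = 200, holdout = 0.2, beta = 0.01,
                               seed = 1) {
  if (!length(candidate_Ks)) abort("candidate_Ks must be non-empty")
  ids <- unique(tokens$post_id)
  set.seed(derive_seed(seed, "k-select-split"))
  n_hold <- max(1L, floor(length(ids) * holdout))
  hold_ids <- sample(ids, n_hold)
  train_tok <- tokens[!(tokens$post_id %in% hold_ids), , drop = FALSE]
  hold_tok <- tokens[tokens$post_id %in% hold_ids, , drop = FALSE]
  # document completion split: alternate tokens within each held-out doc
  pos_in_doc <- stats::ave(seq_len(nrow(hold_tok)), hold_tok$post_id,
                           FUN = seq_along)
  est_tok <- hold_tok[pos_in_doc %% 2 == 0, , drop = FALSE]
  score_tok <- hold_tok[pos_in_doc %% 2 == 1, , drop = FALSE]
  rows <- lapply(sort(unique(as.integer(candidate_Ks))), function(K) {
    pp <- vapply(seq_len(seeds_per_K), function(r) {
      m <- fit_lda(train_tok, K, beta = beta, iters = iters,
                   seed = derive_seed(seed, paste0("k", K, "r", r)))
      as.numeric(suppressMessages(
        lda_perplexity(m, score_tok, estimation_tokens = est_tok,
                       seed = derive_seed(seed, paste0("f", K, r)))))
    }, numeric(1))
    tibble::tibble(K = K, mean_perplexity = mean(pp),
                   var_perplexity = if (length(pp) > 1) var(pp) else 0)
  })
  tab <- dplyr::bind_rows(rows)
  ord <- order(tab$mean_perplexity, tab$var_perplexity, tab$K)
  list(K = tab$K[ord[1]], table = tab)
}

#' @export
tidy.lda_model <- function(x, ...) {
  phi <- lda_phi(x)
  tibble::tibble(
    topic = rep(seq_len(x$K), times = length(x$vocab)),
    token = rep(x$vocab, each = x$K),
    phi = as.vector(phi)
  ) |> dplyr::arrange(.data$topic, dplyr::desc(.data$phi))
}

#' @export
glance.lda_model <- function(x, ...) {
  tibble::tibble(K = x$K, alpha = x$alpha, beta = x$beta, iters = x$iters,
                 n_docs = length(x$doc_ids), n_vocab = length(x$vocab),
                 n_tokens = sum(x$doc_len))
}
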