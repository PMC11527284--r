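# Deterministic offline token encoder.
#
# The encoder contract required downstream is only: (a) per-token vectors of
# a fixed dimension, (b) determinism given (encoder state, document), and
# (c) the "dynamic" property that the same token at different positions /
# sentences gets different vectors. The fallback here composes a seeded
# integer-hash token vector, a sinusoidal position vector and a constant
# per-sentence segment vector. All hashing is pure 31-bit integer arithmetic
# (exact in doubles) before any float conversion, so vectors are identical
# across platforms. Any pretrained contextual encoder honouring the same
# contract can be substituted.

M31 <- 2147483648  # 2^31; multiplier 69069 keeps products exact in doubles

hash_chain <- function(h, x) (h * 69069 + x + 1) %% M31

hash_string <- function(s, seed) {
  h <- (2166136261 %% M31)
  h <- hash_chain(h, seed %% M31)
  for (ch in utf8ToInt(s)) h <- hash_chain(h, ch * 101)
  h
}

hash_unit_vector <- function(s, seed, dim) {
  h <- hash_string(s, seed)
  out <- numeric(dim)
  for (i in seq_len(dim)) {
    h <- hash_chain(h, i * 7919)
    h <- hash_chain(h, (h %/% 65536))
    out[i] <- h / M31 * 2 - 1
  }
  out
}

sinusoid_position <- function(positions, dim) {
  # standard transformer positional code; positions are 0-based
  i <- seq_len(dim) - 1L
  freq <- 1 / 10000^((i %/% 2) * 2 / dim)
  phase <- ifelse(i %% 2 == 0, 0, pi / 2)  # sin for even dims, cos for odd
  outer(positions, freq) |>
    (\(m) sin(sweep(m, 2, phase, "+")))()
}

#' Deterministic fallback token encoder
#'
#' Produces per-token "dynamic" vectors without any pretrained model:
#' `vector = hash(token) + sinusoidal(position) + segment(sentence)`.
#' Reproducible across runs and platforms for a given seed.
#'
#' @param dim Embedding dimension (default 64).
#' @param seed Integer seed for the token hash.
#' @param max_seq_len Documents longer than this are truncated with a
#'   warning (default 256).
#' @param position_scale,segment_scale Scales of the position and segment
#'   terms relative to the token hash term.
#' @return An object of class `"hash_encoder"`.
#' @export
hash_encoder <- function(dim = 64, seed = 1, max_seq_len = 256,
                         position_scale = 0.5, segment_scale = 0.2) {
  stopifnot(dim >= 2, max_seq_len >= 1)
  structure(
    list(dim = as.integer(dim), seed = as.integer(seed),
         max_seq_len = as.integer(max_seq_len),
         position_scale = position_scale, segment_scale = segment_scale,
         id = paste0("hash-d", dim, "-s", seed)),
    class = "hash_encoder"
  )
}

#' @export
print.hash_encoder <- function(x, ...) {
  cat("<hash_encoder>", x$id, "max_seq_len =", x$max_seq_len, "\n")
  invisible(x)
}

encoder_token_matrix <- function(encoder, tokens) {
  uniq <- unique(tokens)
  mat <- matrix(0, length(uniq), encoder$dim,
                dimnames = list(uniq, NULL))
  for (u in uniq) mat[u, ] <- hash_unit_vector(u, encoder$seed, encoder$dim)
  mat[tokens, , drop = FALSE]
}

#' Encode one tokenized document
#'
#' @param tokens Character vector of tokens.
#' @param sentences Integer vector of 1-based sentence indices (same
#'   length); defaults to a single sentence.
#' @param encoder A [hash_encoder()] (or compatible) object.
#' @return An `N x dim` matrix of token vectors (truncated at
#'   `max_seq_len` with a warning).
#' @export
encode_doc <- function(tokens, sentences = NULL, encoder = hash_encoder()) {
  if (!length(tokens)) abort("cannot encode an empty document")
  if (is.null(sentences)) sentences <- rep(1L, length(tokens))
  if (length(tokens) > encoder$max_seq_len) {
    warn(paste0("document truncated from ", length(tokens), " to ",
                encoder$max_seq_len, " tokens"))
    tokens <- tokens[seq_len(encoder$max_seq_len)]
    sentences <- sentences[seq_len(encoder$max_seq_len)]
  }
  n <- length(tokens)
  tok <- encoder_token_matrix(encoder, tokens)
  pos <- sinusoid_position(seq_len(n) - 1, encoder$dim) * encoder$position_scale
  uniq_s <- unique(sentences)
  seg_mat <- matrix(0, length(uniq_s), encoder$dim)
  for (k in seq_along(uniq_s)) {
    seg_mat[k, ] <- hash_unit_vector(paste0("SEG", uniq_s[k]),
                                     encoder$seed, encoder$dim)
  }
  seg <- seg_mat[match(sentences, uniq_s), , drop = FALSE] * encoder$segment_scale
  unname(tok + pos + seg)
}

#' Encode a tokenized corpus
#'
#' @param tokens A tibble from [tokenize_posts()] (`post_id`, `token`,
#'   `position`, `sentence`).
#' @param encoder A [hash_encoder()] (or compatible) object.
#' @return A tibble with one row per document: `post_id`, `n_tokens`, and
#'   an `embedding` list-column of `N x dim` matrices.
#' @export
encode_posts <- function(tokens, encoder = hash_encoder()) {
  stopifnot(all(c("post_id", "token", "sentence") %in% names(tokens)))
  ids <- unique(tokens$post_id)
  by_doc <- split(tokens[, c("token", "sentence")], tokens$post_id)[ids]
  emb <- unname(lapply(by_doc, function(d) {
    encode_doc(d$token, d$sentence, encoder)
  }))
  tibble::tibble(
    post_id = ids,
    n_tokens = vapply(emb, nrow, integer(1)),
    embedding = emb
  )
}

#' Mean-pooled document embedding
#'
#' The document vector is the arithmetic mean of its token vectors.
#'
#' @param seq An `N x d` matrix of token vectors.
#' @return A length-`d` numeric vector.
#' @export
doc_embedding <- function(seq) {
  if (!is.matrix(seq) || nrow(seq) == 0) abort("empty embedding sequence")
  if (!all(is.finite(seq))) abort("non-finite embedding entries")
  colMeans(seq)
}

#' Document-embedding matrix for an encoded corpus
#'
#' @param encoded A tibble from [encode_posts()].
#' @return An `M x d` matrix with post ids as row names.
#' @export
doc_embeddings <- function(encoded) {
  out <- t(vapply(encoded$embedding, doc_embedding,
                  numeric(ncol(encoded$embedding[[1]]))))
  rownames(out) <- encoded$post_id
  out
}
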