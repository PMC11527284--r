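# BiLSTM-CRF tagger: token vectors -> two LSTM passes -> concatenated
# hidden states -> linear emission scores -> CRF (or per-position softmax
# for the argmax baseline). Training minimizes mean per-sentence negative
# log-likelihood with Adam; gradients are exact (peephole BPTT plus CRF
# forward-backward marginals) and finite-difference checked in the tests.

#' NER training hyperparameters
#'
#' Defaults mirror the reference configuration of the model family this
#' tagger implements: learning rate `2e-5`, hidden dimension 200, dropout
#' 0.5 on the BiLSTM output, batch size 64, `max_seq_len` 256. The default
#' learning rate suits fine-tuning on top of a pretrained encoder; training
#' from random initialization (as the synthetic experiments do) needs a
#' larger rate -- pass one explicitly.
#'
#' @param lr Adam learning rate.
#' @param hidden_dim LSTM hidden dimension `H` per direction.
#' @param dropout Dropout rate on the BiLSTM output during training.
#' @param batch_size Sentences per gradient step.
#' @param epochs Training epochs.
#' @param max_seq_len Sentences are truncated to this many tokens.
#' @param peephole Use the cell-to-gate connections (default `TRUE`).
#' @param objective `"crf"` (global normalization, Viterbi decoding) or
#'   `"softmax"` (the per-position argmax baseline).
#' @param seed Seed for initialization, shuffling and dropout.
#' @return A named list of class `"ner_hyper"`.
#' @export
ner_hyper <- function(lr = 2e-5, hidden_dim = 200, dropout = 0.5,
                      batch_size = 64, epochs = 3, max_seq_len = 256,
                      peephole = TRUE, objective = c("crf", "softmax"),
                      seed = 1) {
  structure(list(lr = lr, hidden_dim = as.integer(hidden_dim),
                 dropout = dropout, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 max_seq_len = as.integer(max_seq_len),
                 peephole = isTRUE(peephole),
                 objective = match.arg(objective),
                 seed = as.integer(seed)),
            class = "ner_hyper")
}

ner_prep_sentences <- function(data, encoder, label_set, max_seq_len,
                               with_labels = TRUE) {
  stopifnot(all(c("sentence_id", "token") %in% names(data)))
  ids <- unique(data$sentence_id)
  cols <- intersect(c("token", "label"), names(data))
  by_sent <- split(data[, cols, drop = FALSE], factor(data$sentence_id, ids))
  lapply(seq_along(by_sent), function(i) {
    s <- by_sent[[i]]
    toks <- s$token
    n <- min(length(toks), max_seq_len, encoder$max_seq_len)
    toks <- toks[seq_len(n)]
    X <- suppressWarnings(encode_doc(toks, rep(1L, length(toks)), encoder))
    y <- NULL
    if (with_labels) {
      y <- match(s$label[seq_len(n)], label_set)
      if (anyNA(y)) {
        abort(paste0("unknown label(s) in sentence ", ids[i], ": ",
                     paste(unique(s$label[is.na(match(s$label, label_set))]),
                           collapse = ", ")))
      }
    }
    list(id = ids[i], tokens = toks, X = X, y = y)
  })
}

# Pack a list of prepared sentences into padded time-major batch arrays.
ner_make_batch <- function(sents) {
  bsz <- length(sents)
  lens <- vapply(sents, function(s) nrow(s$X), integer(1))
  Tm <- max(lens)
  d <- ncol(sents[[1]]$X)
  Xall <- matrix(0, Tm * bsz, d)
  Xrev <- matrix(0, Tm * bsz, d)
  y_mat <- matrix(NA_integer_, bsz, Tm)
  gidx <- rep(NA_integer_, Tm * bsz)  # (t,b) -> stacked row of (len-t+1, b)
  for (b in seq_len(bsz)) {
    L <- lens[b]
    rows <- (seq_len(L) - 1L) * bsz + b
    Xall[rows, ] <- sents[[b]]$X
    Xrev[rows, ] <- sents[[b]]$X[L:1, , drop = FALSE]
    gidx[rows] <- (L - seq_len(L)) * bsz + b
    if (!is.null(sents[[b]]$y)) y_mat[b, seq_len(L)] <- sents[[b]]$y
  }
  split_t <- function(M) lapply(seq_len(Tm), function(t) {
    M[(t - 1L) * bsz + seq_len(bsz), , drop = FALSE]
  })
  list(bsz = bsz, Tm = Tm, lens = lens, y_mat = y_mat,
       X_list = split_t(Xall), Xrev_list = split_t(Xrev), gidx = gidx)
}

stack_t <- function(lst) do.call(rbind, lst)

# Full forward pass on a batch. Returns emissions per time step plus the
# caches needed for the backward pass.
ner_forward_batch <- function(model, batch, drop_mask = NULL) {
  H <- model$fwd$hidden_dim
  fw <- lstm_forward_batch(model$fwd, batch$X_list)
  bw <- lstm_forward_batch(model$bwd, batch$Xrev_list)
  Hf_all <- stack_t(fw$H)
  Hr_all <- stack_t(bw$H)
  Hb_all <- matrix(0, nrow(Hr_all), H)
  valid <- !is.na(batch$gidx)
  Hb_all[valid, ] <- Hr_all[batch$gidx[valid], , drop = FALSE]
  H2 <- cbind(Hf_all, Hb_all)
  if (!is.null(drop_mask)) H2 <- H2 * drop_mask
  P_all <- H2 %*% model$Wemit +
    matrix(model$bemit, nrow(H2), length(model$bemit), byrow = TRUE)
  bsz <- batch$bsz
  P_list <- lapply(seq_len(batch$Tm), function(t) {
    P_all[(t - 1L) * bsz + seq_len(bsz), , drop = FALSE]
  })
  list(P_list = P_list, H2 = H2, fw = fw, bw = bw, valid = valid)
}

ner_backward_batch <- function(model, batch, fwd_out, dP_list,
                               drop_mask = NULL) {
  H <- model$fwd$hidden_dim
  bsz <- batch$bsz
  dP_all <- stack_t(dP_list)
  gWemit <- crossprod(fwd_out$H2, dP_all)
  gbemit <- colSums(dP_all)
  dH2 <- dP_all %*% t(model$Wemit)
  if (!is.null(drop_mask)) dH2 <- dH2 * drop_mask
  dHf_all <- dH2[, seq_len(H), drop = FALSE]
  dHb_all <- dH2[, H + seq_len(H), drop = FALSE]
  dHr_all <- matrix(0, nrow(dHb_all), H)
  valid <- fwd_out$valid
  dHr_all[batch$gidx[valid], ] <- dHb_all[valid, , drop = FALSE]
  to_list <- function(M) lapply(seq_len(batch$Tm), function(t) {
    M[(t - 1L) * bsz + seq_len(bsz), , drop = FALSE]
  })
  gfwd <- lstm_backward_batch(model$fwd, batch$X_list, fwd_out$fw$cache,
                              to_list(dHf_all))
  gbwd <- lstm_backward_batch(model$bwd, batch$Xrev_list, fwd_out$bw$cache,
                              to_list(dHr_all))
  list(fwd = gfwd, bwd = gbwd, Wemit = gWemit, bemit = gbemit)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  rapply(params, function(x) { x[] <- 0; x }, classes = "ANY", how = "replace")
}

adam_step <- function(params, grads, m, v, lr, t, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  walk <- function(p, g, mm, vv) {
    if (is.list(p)) {
      for (nm in names(g)) {
        r <- walk(p[[nm]], g[[nm]], mm[[nm]], vv[[nm]])
        p[[nm]] <- r$p; mm[[nm]] <- r$m; vv[[nm]] <- r$v
      }
      return(list(p = p, m = mm, v = vv))
    }
    mm <- b1 * mm + (1 - b1) * g
    vv <- b2 * vv + (1 - b2) * g^2
    mhat <- mm / (1 - b1^t)
    vhat <- vv / (1 - b2^t)
    p <- p - lr * mhat / (sqrt(vhat) + eps)
    list(p = p, m = mm, v = vv)
  }
  walk(params, grads, m, v)
}

# ---- training --------------------------------------------------------------

#' Train the BiLSTM(-CRF) tagger
#'
#' @param train A BIO-annotated sentence tibble (`sentence_id`, `token`,
#'   `label`), e.g. from [read_conll()] or [generate_ner_corpus()].
#' @param dev Optional tibble of the same shape; entity-level F1 on it is
#'   recorded per epoch.
#' @param encoder Token encoder (default [hash_encoder()] with the hyper
#'   seed); continued training reuses the original model's encoder.
#' @param hyper A [ner_hyper()] configuration.
#' @param label_set The BIO label set (default [ner_label_set()]).
#' @param continue_from An existing `"ner_model"` to continue training
#'   (the two-stage protocol: pretrain on single-type data, then continue
#'   on the full tag set); its parameters, encoder and label set are kept.
#' @param verbose Print per-epoch loss.
#' @return An object of class `"ner_model"`.
#' @export
train_ner <- function(train, dev = NULL, encoder = NULL,
                      hyper = ner_hyper(), label_set = ner_label_set(),
                      continue_from = NULL, verbose = FALSE) {
  if (!is.null(continue_from)) {
    encoder <- continue_from$encoder
    label_set <- continue_from$label_set
  }
  if (is.null(encoder)) encoder <- hash_encoder(dim = 64, seed = hyper$seed)
  k <- length(label_set)
  sents <- ner_prep_sentences(train, encoder, label_set, hyper$max_seq_len)
  if (!length(sents)) abort("empty training set")
  d <- encoder$dim; H <- hyper$hidden_dim
  if (is.null(continue_from)) {
    set.seed(derive_seed(hyper$seed, "ner-init"))
    model <- list(
      fwd = lstm_params(d, H, seed = derive_seed(hyper$seed, "fwd"),
                        peephole = hyper$peephole),
      bwd = lstm_params(d, H, seed = derive_seed(hyper$seed, "bwd"),
                        peephole = hyper$peephole),
      Wemit = matrix(runif(2 * H * k, -0.08, 0.08), 2 * H, k),
      bemit = rep(0, k),
      B = matrix(0, k + 2, k + 2),
      label_set = label_set, encoder = encoder
    )
  } else {
    model <- continue_from[c("fwd", "bwd", "Wemit", "bemit", "B",
                             "label_set", "encoder")]
    if (model$fwd$input_dim != d || model$fwd$hidden_dim != H) {
      H <- model$fwd$hidden_dim
    }
  }
  trainable <- function(m) {
    list(fwd = m$fwd[c("Wxi", "Whi", "Wci", "bi", "Wxf", "Whf", "Wcf", "bf",
                       "Wxo", "Who", "Wco", "bo", "Wxc", "Whc", "bc")],
         bwd = m$bwd[c("Wxi", "Whi", "Wci", "bi", "Wxf", "Whf", "Wcf", "bf",
                       "Wxo", "Who", "Wco", "bo", "Wxc", "Whc", "bc")],
         Wemit = m$Wemit, bemit = m$bemit, B = m$B)
  }
  put_back <- function(m, p) {
    for (nm in names(p$fwd)) m$fwd[[nm]] <- p$fwd[[nm]]
    for (nm in names(p$bwd)) m$bwd[[nm]] <- p$bwd[[nm]]
    m$Wemit <- p$Wemit; m$bemit <- p$bemit; m$B <- p$B
    m
  }
  params <- trainable(model)
  mstate <- adam_init(params); vstate <- adam_init(params)
  step <- 0L
  history <- list()
  n <- length(sents)
  for (epoch in seq_len(hyper$epochs)) {
    set.seed(derive_seed(hyper$seed, paste0("shuffle", epoch)))
    ord <- sample(n)
    losses <- numeric(0)
    starts <- seq(1, n, by = hyper$batch_size)
    for (s0 in starts) {
      idx <- ord[s0:min(s0 + hyper$batch_size - 1, n)]
      batch <- ner_make_batch(sents[idx])
      model <- put_back(model, params)
      drop_mask <- NULL
      if (hyper$dropout > 0) {
        set.seed(derive_seed(hyper$seed, paste0("drop", epoch, "s", s0)))
        drop_mask <- matrix(
          rbinom(batch$Tm * batch$bsz * 2 * H, 1, 1 - hyper$dropout),
          batch$Tm * batch$bsz, 2 * H) / (1 - hyper$dropout)
      }
      fo <- ner_forward_batch(model, batch, drop_mask)
      obj <- if (hyper$objective == "crf") {
        crf_batch_grad(model$B, fo$P_list, batch$lens, batch$y_mat)
      } else {
        softmax_batch_grad(fo$P_list, batch$lens, batch$y_mat)
      }
      gr <- ner_backward_batch(model, batch, fo, obj$dP, drop_mask)
      gr$B <- if (is.null(obj$dB)) model$B * 0 else obj$dB
      gr <- gr[c("fwd", "bwd", "Wemit", "bemit", "B")]
      step <- step + 1L
      upd <- adam_step(params, gr, mstate, vstate, hyper$lr, step)
      params <- upd$p; mstate <- upd$m; vstate <- upd$v
      losses <- c(losses, obj$nll)
    }
    dev_f1 <- NA_real_
    if (!is.null(dev)) {
      model <- put_back(model, params)
      tmp <- structure(c(model, list(hyper = hyper)), class = "ner_model")
      dm <- evaluate_ner(tmp, dev)$metrics
      dev_f1 <- dm$f1[dm$entity_type == "overall"]
    }
    history[[epoch]] <- tibble::tibble(epoch = epoch, nll = mean(losses),
                                       dev_f1 = dev_f1)
    if (verbose) {
      cat(sprintf("epoch %d  nll %.4f  dev_f1 %s\n", epoch, mean(losses),
                  ifelse(is.na(dev_f1), "-", sprintf("%.3f", dev_f1))))
    }
  }
  model <- put_back(model, params)
  structure(c(model, list(hyper = hyper,
                          history = dplyr::bind_rows(history))),
            class = "ner_model")
}

#' @export
print.ner_model <- function(x, ...) {
  cat("<ner_model>", x$hyper$objective, " H =", x$fwd$hidden_dim,
      " d =", x$fwd$input_dim, " labels =", length(x$label_set), "\n")
  if (nrow(x$history)) {
    cat("  final training nll:", signif(tail(x$history$nll, 1), 5), "\n")
  }
  invisible(x)
}

#' @export
glance.ner_model <- function(x, ...) {
  tibble::tibble(objective = x$hyper$objective,
                 hidden_dim = x$fwd$hidden_dim,
                 input_dim = x$fwd$input_dim,
                 epochs = nrow(x$history),
                 final_nll = if (nrow(x$history)) tail(x$history$nll, 1)
                             else NA_real_)
}

# Decoded label sequences are repaired to BIO2 before span extraction:
# transitions are learned, not constrained, so an undertrained model (and
# the softmax baseline by construction) can emit illegal I- openings.
decoded_spans <- function(model, y, tokens = NULL) {
  labs <- repair_bio(model$label_set[y])
  attributes(labs) <- NULL
  spans_from_bio(labs, tokens)
}

# Decode prepared sentences; returns a list of integer label sequences.
ner_decode <- function(model, sents) {
  out <- vector("list", length(sents))
  chunk <- 256L
  for (s0 in seq(1, length(sents), by = chunk)) {
    idx <- s0:min(s0 + chunk - 1, length(sents))
    batch <- ner_make_batch(sents[idx])
    fo <- ner_forward_batch(model, batch)
    for (b in seq_along(idx)) {
      L <- batch$lens[b]
      P <- t(vapply(seq_len(L), function(t) fo$P_list[[t]][b, ],
                    numeric(length(model$bemit))))
      out[[idx[b]]] <- if (model$hyper$objective == "crf") {
        viterbi_decode(model$B, P)$y
      } else {
        apply(P, 1, which.max)
      }
    }
  }
  out
}

#' Predict BIO labels for sentences
#'
#' @param model A trained `"ner_model"`.
#' @param data A sentence tibble (`sentence_id`, `token`).
#' @return `data` (truncated to `max_seq_len` tokens per sentence) with a
#'   `pred_label` column.
#' @export
predict_ner <- function(model, data) {
  sents <- ner_prep_sentences(data, model$encoder, model$label_set,
                              model$hyper$max_seq_len, with_labels = FALSE)
  ys <- ner_decode(model, sents)
  tibble::tibble(
    sentence_id = rep(vapply(sents, function(s) s$id[[1]], sents[[1]]$id),
                      lengths(ys)),
    position = unlist(lapply(lengths(ys), function(n) seq_len(n) - 1L)),
    token = unlist(lapply(sents, function(s) s$tokens)),
    pred_label = model$label_set[unlist(ys)]
  )
}

#' Entity-level evaluation
#'
#' Exact-span micro precision/recall/F1, overall and per entity type.
#' A predicted span counts as correct only if type, start and end all
#' match a gold span. `F1 = 2PR / (P + R)`, with the convention that an
#' undefined precision/recall/F1 (zero denominator) is 0.
#'
#' @param model A trained `"ner_model"`.
#' @param test A BIO-annotated sentence tibble.
#' @return An object of class `"ner_eval"` whose `metrics` tibble has
#'   columns `entity_type`, `n_gold`, `n_pred`, `n_correct`, `precision`,
#'   `recall`, `f1` (proportions in `[0, 1]`).
#' @export
evaluate_ner <- function(model, test) {
  sents <- ner_prep_sentences(test, model$encoder, model$label_set,
                              model$hyper$max_seq_len)
  ys <- ner_decode(model, sents)
  types <- c("SEX", "EDU", "ORG")
  tally <- matrix(0L, length(types), 3,
                  dimnames = list(types, c("gold", "pred", "correct")))
  for (i in seq_along(sents)) {
    gold <- spans_from_bio(model$label_set[sents[[i]]$y])
    pred <- decoded_spans(model, ys[[i]])
    for (tp in types) {
      g <- gold[gold$entity_type == tp, c("start", "end")]
      p <- pred[pred$entity_type == tp, c("start", "end")]
      tally[tp, "gold"] <- tally[tp, "gold"] + nrow(g)
      tally[tp, "pred"] <- tally[tp, "pred"] + nrow(p)
      if (nrow(g) && nrow(p)) {
        key <- function(df) paste(df$start, df$end)
        tally[tp, "correct"] <- tally[tp, "correct"] +
          length(intersect(key(g), key(p)))
      }
    }
  }
  tot <- colSums(tally)
  tab <- rbind(tally, overall = tot)
  prf <- function(g, p, c) {
    prec <- if (p > 0) c / p else 0
    rec <- if (g > 0) c / g else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(prec, rec, f1)
  }
  met <- t(apply(tab, 1, function(r) prf(r["gold"], r["pred"], r["correct"])))
  structure(
    list(metrics = tibble::tibble(
      entity_type = rownames(tab),
      n_gold = unname(as.integer(tab[, "gold"])),
      n_pred = unname(as.integer(tab[, "pred"])),
      n_correct = unname(as.integer(tab[, "correct"])),
      precision = unname(met[, 1]), recall = unname(met[, 2]),
      f1 = unname(met[, 3])
    ), n_sentences = length(sents)),
    class = "ner_eval"
  )
}

#' @export
print.ner_eval <- function(x, ...) {
  cat("<ner_eval>", x$n_sentences, "sentences\n")
  print(x$metrics)
  invisible(x)
}

#' @export
tidy.ner_eval <- function(x, ...) x$metrics

#' Extract entity mentions from documents
#'
#' Decodes each document with the tagger and converts the BIO output to
#' maximal spans.
#'
#' @param model A trained `"ner_model"`.
#' @param tokens A tokenized corpus tibble (`post_id`, `token`).
#' @return A tibble of `post_id`, `entity_type`, `start`, `end`, `surface`.
#' @export
extract_entities <- function(model, tokens) {
  data <- tibble::tibble(sentence_id = tokens$post_id, token = tokens$token)
  sents <- ner_prep_sentences(data, model$encoder, model$label_set,
                              model$hyper$max_seq_len, with_labels = FALSE)
  ys <- ner_decode(model, sents)
  rows <- lapply(seq_along(sents), function(i) {
    sp <- decoded_spans(model, ys[[i]], sents[[i]]$tokens)
    if (nrow(sp)) sp$post_id <- sents[[i]]$id
    sp
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    return(tibble::tibble(post_id = character(), entity_type = character(),
                          start = integer(), end = integer(),
                          surface = character()))
  }
  out[, c("post_id", "entity_type", "start", "end", "surface")]
}
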