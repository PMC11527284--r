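#' Validate a posts table
#'
#' A corpus is a tibble with one row per post. `id` and `text` are required;
#' `platform` (one of `"douban"`, `"zhihu"`, `"weibo"`, `"synthetic"`),
#' `timestamp` (ISO-8601 string) and `label_sentiment` (`"positive"` /
#' `"negative"`) are optional.
#'
#' @param posts A data frame with at least `id` and `text` columns.
#' @return A tibble with validated columns, invisibly classed as-is.
#' @export
posts_tbl <- function(posts) {
  posts <- tibble::as_tibble(posts)
  if (!all(c("id", "text") %in% names(posts))) {
    abort("a posts table needs `id` and `text` columns")
  }
  posts$id <- as.character(posts$id)
  posts$text <- as.character(posts$text)
  if (anyNA(posts$id) || any(!nzchar(posts$id))) {
    abort("post ids must be non-empty")
  }
  if (anyDuplicated(posts$id)) {
    abort("post ids must be unique within a corpus")
  }
  if (any(!nzchar(trimws(posts$text)))) {
    abort("post text must be non-empty after whitespace stripping")
  }
  if ("platform" %in% names(posts)) {
    bad <- setdiff(unique(posts$platform),
                   c("douban", "zhihu", "weibo", "synthetic", NA))
    if (length(bad)) abort(paste0("unknown platform(s): ",
                                  paste(bad, collapse = ", ")))
  }
  posts
}

#' Tokenize a single text
#'
#' Splits a text into sentences (ICU sentence boundaries) and tokens.
#' `mode = "character"` splits into Unicode code points (the natural unit
#' for CJK text and the default for it), `"whitespace"` splits on runs of
#' whitespace (the synthetic-corpus default), `"segmenter"` uses ICU
#' dictionary-based word boundaries. Whitespace-only tokens are dropped;
#' a supplied stop-word list is removed after splitting.
#'
#' @param text A single non-empty string.
#' @param mode Tokenization mode.
#' @param stopwords Optional character vector of tokens to drop.
#' @return A tibble with columns `token`, `position` (0-based) and
#'   `sentence` (1-based sentence index).
#' @export
tokenize <- function(text, mode = c("whitespace", "character", "segmenter"),
                     stopwords = NULL) {
  mode <- match.arg(mode)
  if (!is.character(text) || length(text) != 1 || is.na(text) ||
      !nzchar(trimws(text))) {
    abort("empty document")
  }
  sents <- unlist(stringi::stri_split_boundaries(text, type = "sentence"))
  sents <- sents[nzchar(trimws(sents))]
  tok_one <- function(s) {
    toks <- switch(mode,
      whitespace = unlist(strsplit(trimws(s), "\\s+")),
      character  = unlist(strsplit(s, "", fixed = FALSE)),
      segmenter  = unlist(stringi::stri_split_boundaries(s, type = "word"))
    )
    toks <- toks[nzchar(trimws(toks))]
    if (!is.null(stopwords)) toks <- toks[!(toks %in% stopwords)]
    toks
  }
  per_sent <- lapply(sents, tok_one)
  keep <- lengths(per_sent) > 0
  per_sent <- per_sent[keep]
  if (!length(per_sent)) abort("empty document")
  tokens <- unlist(per_sent)
  tibble::tibble(
    token = tokens,
    position = seq_along(tokens) - 1L,
    sentence = rep(seq_along(per_sent), lengths(per_sent))
  )
}

#' Tokenize every post in a corpus
#'
#' @param posts A posts table (see [posts_tbl()]).
#' @inheritParams tokenize
#' @return A tibble with columns `post_id`, `token`, `position`, `sentence`.
#'   Posts that are empty after cleaning are dropped with a warning.
#' @export
tokenize_posts <- function(posts,
                           mode = c("whitespace", "character", "segmenter"),
                           stopwords = NULL) {
  posts <- posts_tbl(posts)
  mode <- match.arg(mode)
  out <- vector("list", nrow(posts))
  dropped <- character()
  for (i in seq_len(nrow(posts))) {
    tk <- tryCatch(tokenize(posts$text[i], mode, stopwords),
                   error = function(e) NULL)
    if (is.null(tk)) {
      dropped <- c(dropped, posts$id[i])
    } else {
      tk$post_id <- posts$id[i]
      out[[i]] <- tk
    }
  }
  if (length(dropped)) {
    warn(paste0(length(dropped), " post(s) empty after cleaning, dropped: ",
                paste(head(dropped, 5), collapse = ", ")))
  }
  dplyr::bind_rows(out)[, c("post_id", "token", "position", "sentence")]
}

#' Default cohort-identification patterns
#'
#' Regular expressions flagging self-identified postgraduate authors:
#' first-person degree statements plus mentions of an advisor or research
#' group. Matching is case-insensitive.
#'
#' @return A character vector of regular expressions.
#' @export
default_cohort_patterns <- function() {
  c(
    "I am (pursuing )?(a )?(master|doctor|ph\\.?d\\.?)('s)?( degree)?( candidate| student)?",
    "my advisor",
    "my research group"
  )
}

#' Flag posts written by the target cohort
#'
#' @param posts A posts table.
#' @param patterns Non-empty character vector of regular expressions; a post
#'   matches if any pattern matches its text (case-insensitive).
#' @return A logical vector, one element per post.
#' @export
match_postgraduate <- function(posts, patterns = default_cohort_patterns()) {
  posts <- posts_tbl(posts)
  if (!length(patterns)) abort("`patterns` must be non-empty")
  for (p in patterns) {
    ok <- tryCatch({ suppressWarnings(grepl(p, "x", perl = TRUE)); TRUE },
                   error = function(e) FALSE)
    if (!ok) abort(paste0("invalid regular expression: ", p))
  }
  hit <- rep(FALSE, nrow(posts))
  for (p in patterns) {
    hit <- hit | grepl(p, posts$text, ignore.case = TRUE, perl = TRUE)
  }
  hit
}

#' Keep only cohort posts
#'
#' @inheritParams match_postgraduate
#' @return The matching subset of `posts`.
#' @export
filter_cohort <- function(posts, patterns = default_cohort_patterns()) {
  posts <- posts_tbl(posts)
  posts[match_postgraduate(posts, patterns), , drop = FALSE]
}

#' Read posts from JSON-lines
#'
#' One JSON object per line with at least `id` and `text`. Malformed lines
#' and records missing required fields are skipped, counted, and reported
#' via a warning and the `"bad_lines"` attribute (line numbers).
#'
#' @param path Path to a JSONL file.
#' @return A posts tibble.
#' @export
read_posts_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines))
  recs <- vector("list", length(lines))
  bad <- integer()
  for (i in which(keep)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e) NULL)
    if (is.null(obj) || !is.list(obj) ||
        is.null(obj$id) || is.null(obj$text) ||
        !nzchar(as.character(obj$id)) || !nzchar(trimws(as.character(obj$text)))) {
      bad <- c(bad, i)
      next
    }
    recs[[i]] <- tibble::tibble(
      id = as.character(obj$id),
      text = as.character(obj$text),
      platform = as.character(obj$platform %||% NA_character_),
      timestamp = as.character(obj$timestamp %||% NA_character_),
      label_sentiment = as.character(obj$label_sentiment %||% NA_character_)
    )
  }
  out <- dplyr::bind_rows(recs)
  if (!nrow(out)) {
    out <- tibble::tibble(id = character(), text = character(),
                          platform = character(), timestamp = character(),
                          label_sentiment = character())
  }
  if (length(bad)) {
    warn(paste0(length(bad), " malformed line(s) skipped at: ",
                paste(head(bad, 10), collapse = ", ")))
  }
  attr(out, "bad_lines") <- bad
  posts_tbl(out)
}

#' Write posts to JSON-lines
#'
#' @param posts A posts table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_posts_jsonl <- function(posts, path) {
  posts <- posts_tbl(posts)
  lines <- vapply(seq_len(nrow(posts)), function(i) {
    rec <- as.list(posts[i, , drop = FALSE])
    rec <- rec[!vapply(rec, function(x) is.na(x[[1]]), logical(1))]
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# ---- BIO / CoNLL ----------------------------------------------------------

#' The BIO2 label set used by the tagger
#'
#' `O` plus `B-`/`I-` pairs for the three entity facets: gender mentions
#' (`SEX`), degree-level mentions (`EDU`) and institution mentions (`ORG`).
#'
#' @return Character vector of 7 labels.
#' @export
ner_label_set <- function() {
  c("O", "B-SEX", "I-SEX", "B-EDU", "I-EDU", "B-ORG", "I-ORG")
}

bio_type <- function(label) sub("^[BI]-", "", label)

#' Check BIO2 validity of a label sequence
#'
#' Valid BIO2: every `I-T` is preceded by `B-T` or `I-T` of the same type.
#'
#' @param labels Character vector of BIO labels.
#' @return `TRUE` or `FALSE`.
#' @export
is_valid_bio <- function(labels) {
  prev <- "O"
  for (lab in labels) {
    if (startsWith(lab, "I-")) {
      if (!(startsWith(prev, "B-") || startsWith(prev, "I-")) ||
          bio_type(prev) != bio_type(lab)) {
        return(FALSE)
      }
    }
    prev <- lab
  }
  TRUE
}

#' Repair illegal I- openings
#'
#' Rewrites any `I-T` whose predecessor is not `B-T`/`I-T` of the same type
#' to `B-T` (common in hand-annotated data).
#'
#' @param labels Character vector of BIO labels.
#' @return Repaired label vector; the number of rewrites is attached as the
#'   `"n_repaired"` attribute.
#' @export
repair_bio <- function(labels) {
  prev <- "O"
  n <- 0L
  for (j in seq_along(labels)) {
    lab <- labels[j]
    if (startsWith(lab, "I-")) {
      ok <- (startsWith(prev, "B-") || startsWith(prev, "I-")) &&
        bio_type(prev) == bio_type(lab)
      if (!ok) {
        labels[j] <- sub("^I-", "B-", lab)
        n <- n + 1L
      }
    }
    prev <- labels[j]
  }
  attr(labels, "n_repaired") <- n
  labels
}

#' Read BIO-annotated sentences from a CoNLL-style file
#'
#' Two tab-separated columns (`token<TAB>label`), blank lines separating
#' sentences. Labels whose entity type is outside `keep_types` are projected
#' to `"O"` (the retention rule used when mixing annotation sets that only
#' share some types). Illegal `I-` openings are repaired to `B-` by default;
#' with `repair = FALSE` they are an error.
#'
#' @param path Input path.
#' @param keep_types Optional character vector of entity types to keep
#'   (e.g. `"ORG"`); `NULL` keeps everything.
#' @param repair Repair illegal `I-` openings (default) or fail.
#' @return A tibble with columns `sentence_id`, `position` (0-based),
#'   `token`, `label`.
#' @export
read_conll <- function(path, keep_types = NULL, repair = TRUE) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  sid <- 0L
  open <- FALSE
  toks <- list(); labs <- list(); cur_t <- character(); cur_l <- character()
  flush_sent <- function() {
    if (length(cur_t)) {
      sid <<- sid + 1L
      toks[[sid]] <<- cur_t
      labs[[sid]] <<- cur_l
    }
    cur_t <<- character(); cur_l <<- character()
  }
  for (ln in lines) {
    if (!nzchar(trimws(ln))) { flush_sent(); next }
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2) {
      abort(paste0("malformed CoNLL line (need token<TAB>label): ", ln))
    }
    cur_t <- c(cur_t, parts[1])
    cur_l <- c(cur_l, parts[2])
  }
  flush_sent()
  n_rep <- 0L
  for (i in seq_along(labs)) {
    l <- labs[[i]]
    if (!is.null(keep_types)) {
      drop <- l != "O" & !(bio_type(l) %in% keep_types)
      l[drop] <- "O"
    }
    if (!is_valid_bio(l)) {
      if (!repair) abort(paste0("invalid BIO sequence in sentence ", i))
      l <- repair_bio(l)
      n_rep <- n_rep + attr(l, "n_repaired")
      attributes(l) <- NULL
    }
    labs[[i]] <- l
  }
  if (n_rep > 0) warn(paste0(n_rep, " illegal I- opening(s) repaired to B-"))
  tibble::tibble(
    sentence_id = rep(seq_along(toks), lengths(toks)),
    position = unlist(lapply(lengths(toks), function(n) seq_len(n) - 1L)),
    token = unlist(toks),
    label = unlist(labs)
  )
}

#' Write BIO-annotated sentences to a CoNLL-style file
#'
#' @param sentences A tibble as returned by [read_conll()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conll <- function(sentences, path) {
  stopifnot(all(c("sentence_id", "token", "label") %in% names(sentences)))
  by_sent <- split(sentences[, c("token", "label")], sentences$sentence_id)
  chunks <- vapply(by_sent, function(s) {
    paste0(paste(s$token, s$label, sep = "\t", collapse = "\n"), "\n")
  }, character(1))
  writeLines(paste(chunks, collapse = "\n"), path, sep = "", useBytes = TRUE)
  invisible(path)
}

#' Extract entity spans from a BIO2 label sequence
#'
#' Spans are maximal, 0-based, half-open `[start, end)`.
#'
#' @param labels BIO2-valid character vector of labels.
#' @param tokens Optional token vector of the same length; when given, the
#'   `surface` column joins the span's tokens with spaces.
#' @return A tibble with columns `entity_type`, `start`, `end`, `surface`,
#'   sorted by `start`.
#' @export
spans_from_bio <- function(labels, tokens = NULL) {
  if (!is_valid_bio(labels)) abort("labels are not BIO2-valid; see repair_bio()")
  starts <- integer(); ends <- integer(); types <- character()
  open_start <- NA_integer_; open_type <- NA_character_
  close_span <- function(end_at) {
    if (!is.na(open_start)) {
      starts <<- c(starts, open_start)
      ends <<- c(ends, end_at)
      types <<- c(types, open_type)
    }
    open_start <<- NA_integer_; open_type <<- NA_character_
  }
  for (j in seq_along(labels)) {
    lab <- labels[j]
    if (startsWith(lab, "B-")) {
      close_span(j - 1L)
      open_start <- j - 1L
      open_type <- bio_type(lab)
    } else if (lab == "O") {
      close_span(j - 1L)
    }
  }
  close_span(length(labels))
  surface <- if (is.null(tokens)) {
    rep(NA_character_, length(starts))
  } else {
    vapply(seq_along(starts), function(i) {
      paste(tokens[(starts[i] + 1L):ends[i]], collapse = " ")
    }, character(1))
  }
  tibble::tibble(entity_type = types, start = starts, end = ends,
                 surface = surface)
}

#' Rebuild a BIO2 label sequence from entity spans
#'
#' Inverse of [spans_from_bio()] on valid inputs.
#'
#' @param spans A tibble with `entity_type`, `start`, `end` (0-based,
#'   half-open, non-overlapping).
#' @param length Sentence length in tokens.
#' @return Character vector of BIO2 labels.
#' @export
bio_from_spans <- function(spans, length) {
  labels <- rep("O", length)
  if (!nrow(spans)) return(labels)
  spans <- spans[order(spans$start), , drop = FALSE]
  if (any(spans$start < 0) || any(spans$end > length) ||
      any(spans$start >= spans$end)) {
    abort("span out of range or empty")
  }
  if (any(spans$start[-1] < spans$end[-nrow(spans)])) {
    abort("overlapping spans")
  }
  for (i in seq_len(nrow(spans))) {
    s <- spans$start[i] + 1L; e <- spans$end[i]
    labels[s] <- paste0("B-", spans$entity_type[i])
    if (e > s) labels[(s + 1L):e] <- paste0("I-", spans$entity_type[i])
  }
  labels
}
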