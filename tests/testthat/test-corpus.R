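test_that("tokenize splits by mode and drops empty material", {
  ws <- tokenize("a b  c", mode = "whitespace")
  expect_equal(ws$token, c("a", "b", "c"))
  expect_equal(ws$position, 0:2)

  ch <- tokenize("abc", mode = "character")
  expect_equal(ch$token, c("a", "b", "c"))

  expect_error(tokenize("   "), "empty document")
  expect_error(tokenize("the a", stopwords = c("the", "a")), "empty document")

  # stop-word removal only when a list is supplied
  expect_equal(nrow(tokenize("the a b")), 3)
  expect_equal(tokenize("the a b", stopwords = "the")$token, c("a", "b"))
})

test_that("tokenize records sentence structure", {
  tk <- tokenize("A b. C d!", mode = "whitespace")
  expect_equal(unique(tk$sentence), 1:2)
  expect_equal(sum(tk$sentence == 1), 2)
  # sentence indices partition positions in order
  expect_true(all(diff(tk$sentence) >= 0))
})

test_that("token counts match the generator on synthetic documents", {
  g <- generate_topic_corpus(M = 5, K_true = 2, V = 20, tokens_per_doc = 50,
                             seed = 3)
  tk <- tokenize_posts(g$posts)
  n_gen <- table(g$tokens$post_id)
  n_tok <- table(tk$post_id)
  expect_equal(as.vector(n_tok[names(n_gen)]), as.vector(n_gen))
})

test_that("cohort matching finds the default keys and is pure", {
  posts <- tibble::tibble(
    id = as.character(1:4),
    text = c("struggling with my advisor again",
             "nice weather today",
             "I am a master candidate in physics",
             "my research group meets daily"))
  hits <- match_postgraduate(posts)
  expect_equal(hits, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(match_postgraduate(posts), hits)
  expect_equal(filter_cohort(posts)$id, c("1", "3", "4"))
  expect_error(match_postgraduate(posts, character(0)), "non-empty")
  expect_error(match_postgraduate(posts, "(unclosed"), "invalid regular")
})

test_that("seeded cohort posts are recovered exactly", {
  set.seed(42)
  n <- 100
  seeded <- sort(sample(n, 40))
  text <- replicate(n, paste(sample(letters, 5), collapse = " "))
  text[seeded] <- paste(text[seeded], "my advisor")
  posts <- tibble::tibble(id = as.character(1:n), text = text)
  expect_equal(which(match_postgraduate(posts)), seeded)
})

test_that("JSONL round-trip is identity and bad lines are reported", {
  posts <- tibble::tibble(
    id = c("a", "b", "c"),
    text = c("one two", "three", "four five six"),
    platform = c("weibo", "douban", "synthetic"),
    timestamp = c("2021-01-01T00:00:00Z", NA, NA),
    label_sentiment = c("negative", NA, "positive"))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_posts_jsonl(posts, path)
  back <- read_posts_jsonl(path)
  expect_equal(as.data.frame(back), as.data.frame(posts),
               ignore_attr = TRUE)

  lines <- readLines(path)
  writeLines(c(lines[1], "not json", lines[2], "{\"id\":\"\",\"text\":\"x\"}"),
             path)
  expect_warning(back2 <- read_posts_jsonl(path), "2 malformed")
  expect_equal(nrow(back2), 2)
  expect_equal(attr(back2, "bad_lines"), c(2L, 4L))

  writeLines(character(0), path)
  expect_equal(nrow(read_posts_jsonl(path)), 0)
})

test_that("CoNLL round-trip, projection and repair follow the contract", {
  sents <- tibble::tibble(
    sentence_id = c(1L, 1L, 1L, 2L, 2L),
    position = c(0:2, 0:1),
    token = c("x", "y", "z", "u", "v"),
    label = c("B-ORG", "I-ORG", "O", "B-SEX", "O"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_conll(sents, path)
  back <- read_conll(path)
  expect_equal(as.data.frame(back), as.data.frame(sents))
  expect_equal(as.vector(table(back$sentence_id)), c(3L, 2L))

  # labels outside the kept set are projected to O
  writeLines("per\tB-PER\n", path)
  proj <- read_conll(path, keep_types = "ORG")
  expect_equal(proj$label, "O")

  # illegal I- opening repaired to B- with one warning, or strict failure
  writeLines("a\tI-ORG\nb\tI-ORG\n", path)
  expect_warning(rep <- read_conll(path), "1 illegal")
  expect_equal(rep$label, c("B-ORG", "I-ORG"))
  expect_error(read_conll(path, repair = FALSE), "invalid BIO")
})

test_that("BIO spans round-trip and degenerate cases", {
  labs <- c("B-SEX", "O", "B-ORG", "I-ORG")
  sp <- spans_from_bio(labs, tokens = c("w", "x", "y", "z"))
  expect_equal(sp$entity_type, c("SEX", "ORG"))
  expect_equal(sp$start, c(0L, 2L))
  expect_equal(sp$end, c(1L, 4L))
  expect_equal(sp$surface, c("w", "y z"))
  expect_equal(bio_from_spans(sp, 4), labs)

  expect_equal(nrow(spans_from_bio(c("O", "O", "O"))), 0)
  expect_error(spans_from_bio(c("I-ORG")), "not BIO2-valid")
  bad <- tibble::tibble(entity_type = c("ORG", "SEX"),
                        start = c(0L, 1L), end = c(2L, 2L))
  expect_error(bio_from_spans(bad, 3), "overlapping")
})

test_that("span round-trip holds on many random valid label lists", {
  for (s in 1:100) {
    labs <- random_valid_bio(s, len = 5 + s %% 10)
    sp <- spans_from_bio(labs)
    expect_identical(bio_from_spans(sp, length(labs)), labs)
    # spans are sorted and non-overlapping
    if (nrow(sp) > 1) {
      expect_true(all(diff(sp$start) > 0))
      expect_true(all(sp$start[-1] >= sp$end[-nrow(sp)]))
    }
  }
})

test_that("posts table invariants are enforced", {
  expect_error(posts_tbl(tibble::tibble(id = c("a", "a"), text = c("x", "y"))),
               "unique")
  expect_error(posts_tbl(tibble::tibble(id = "a", text = "  ")), "non-empty")
  expect_error(posts_tbl(tibble::tibble(id = "a", text = "x",
                                        platform = "myspace")),
               "unknown platform")
})
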