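test_that("read_corpus parses 5-field lines and preserves order", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("q1\t1\tSurgery\tQ-text\tA-text",
               "q1\t0\tSurgery\tQ-text\tOther answer"), tmp)
  s <- read_corpus(tmp)
  expect_s3_class(s, "qa_corpus")
  expect_equal(nrow(s), 2L)
  expect_equal(s$question_id, c("q1", "q1"))
  expect_equal(s$label, c(1L, 0L))
  expect_equal(s$category[1], "Surgery")
  expect_equal(s$question[1], "Q-text")
  expect_equal(s$answer[2], "Other answer")
})

test_that("read_corpus handles empty files and malformed lines", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  file.create(tmp)
  expect_equal(nrow(read_corpus(tmp)), 0L)

  writeLines("a\tb\tc", tmp)
  expect_error(read_corpus(tmp, strict = TRUE), "line 1")
  expect_warning(s <- read_corpus(tmp, strict = FALSE), "malformed")
  expect_equal(nrow(s), 0L)

  writeLines("q1\t2\tcat\tq\ta", tmp)
  expect_error(read_corpus(tmp), "label")
})

test_that("write_corpus round-trips and sanitizes reserved characters", {
  s <- make_fixture("tiny")
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_corpus(s, tmp)
  expect_equal(read_corpus(tmp), s)

  # each serialized line has exactly 4 tabs (5 fields)
  expect_true(all(lengths(gregexpr("\t", readLines(tmp))) == 4L))

  dirty <- s
  dirty$answer[1] <- "tab\there\nand newline"
  write_corpus(dirty, tmp)
  back <- read_corpus(tmp)
  expect_equal(back$answer[1], "tab here and newline")

  write_corpus(s[0, ], tmp)
  expect_equal(nrow(read_corpus(tmp)), 0L)
})

test_that("clean_text keeps only the allowed character classes and is idempotent", {
  expect_equal(clean_text("<b>头痛</b> see http://x.cn now!"),
               "头痛 see now!")
  expect_equal(clean_text("头痛abc123，。"),
               "头痛abc123，。")
  expect_equal(clean_text(""), "")
  # emoji and control bytes are stripped; whitespace collapses
  expect_equal(clean_text("a \U0001F600  b\tc"), "a b c")
  cases <- c("<i>x</i> y", "a   b", "痛!", "www.site.com link",
             "mixed 中文 and English 42")
  expect_equal(clean_text(clean_text(cases)), clean_text(cases))
})

test_that("filter_questions keeps single-positive questions within the length cap", {
  s <- make_fixture("boundary")
  kept <- filter_questions(s)
  ids <- unique(kept$question_id)
  expect_setequal(ids, c("bq1", "bq5"))      # 500-char kept, 501 dropped,
                                             # dup positives dropped, no-pos dropped
  expect_equal(nchar(kept$answer[kept$label == 1L & kept$question_id == "bq1"]), 500L)
})

test_that("sample_negatives builds 1 positive + n_neg negatives deterministically", {
  s <- make_fixture("boundary")
  kept <- filter_questions(s)
  lists <- sample_negatives(kept, n_neg = 4L, seed = 42L)
  expect_length(lists, 2L)
  for (l in lists) {
    expect_equal(nrow(l$candidates), 5L)
    expect_equal(sum(l$candidates$label), 1L)
  }
  # bq1 has exactly 4 native negatives: no choice involved
  bq1 <- lists[[which(vapply(lists, `[[`, "", "question_id") == "bq1")]]
  expect_setequal(bq1$candidates$answer[bq1$candidates$label == 0L],
                  paste0("neg 1.", 1:4))
  # bq5 has 2 native negatives: 2 supplemented from other questions,
  # never its own answers
  bq5 <- lists[[which(vapply(lists, `[[`, "", "question_id") == "bq5")]]
  own <- s$answer[s$question_id == "bq5"]
  supplemented <- setdiff(bq5$candidates$answer[bq5$candidates$label == 0L],
                          c("neg 5.1", "neg 5.2"))
  expect_length(supplemented, 2L)
  expect_false(any(supplemented %in% own))
  # determinism
  expect_equal(sample_negatives(kept, n_neg = 4L, seed = 42L), lists)
})

test_that("sample_negatives subsamples when more negatives exist than needed", {
  s <- qa_samples <- lists_to_corpus(list(
    ranking_list("q1", "c", "q text", c("pos", paste0("n", 1:6)),
                 c(1L, rep(0L, 6L)))))
  lists <- sample_negatives(s, n_neg = 4L, seed = 9L)
  negs <- lists[[1]]$candidates$answer[lists[[1]]$candidates$label == 0L]
  expect_length(negs, 4L)
  expect_true(all(negs %in% paste0("n", 1:6)))
})

test_that("split_corpus is stratified, 8:1:1 within rounding, disjoint and exhaustive", {
  lists <- lapply(seq_len(100L), function(i) {
    ranking_list(paste0("q", i), "onecat", "q", c("a", "b"), c(1L, 0L))
  })
  sp <- split_corpus(lists, seed = 3L)
  expect_equal(lengths(sp)[c("train", "dev", "test")],
               c(train = 80L, dev = 10L, test = 10L))
  ids <- function(part) vapply(part, `[[`, "", "question_id")
  all_ids <- c(ids(sp$train), ids(sp$dev), ids(sp$test))
  expect_setequal(all_ids, paste0("q", 1:100))
  expect_equal(anyDuplicated(all_ids), 0L)

  # two categories of 10: exact 8/1/1 within each
  lists2 <- lapply(seq_len(20L), function(i) {
    ranking_list(paste0("p", i), if (i <= 10L) "catA" else "catB",
                 "q", c("a", "b"), c(1L, 0L))
  })
  sp2 <- split_corpus(lists2, seed = 4L)
  for (cat_name in c("catA", "catB")) {
    in_cat <- function(part) sum(vapply(part, `[[`, "", "category") == cat_name)
    expect_equal(c(in_cat(sp2$train), in_cat(sp2$dev), in_cat(sp2$test)),
                 c(8L, 1L, 1L))
  }
  expect_identical(split_corpus(lists2, seed = 4L), sp2)
  expect_false(identical(split_corpus(lists2, seed = 5L), sp2))

  tiny <- lists2[1:2]
  expect_warning(sp3 <- split_corpus(tiny, seed = 1L), "train")
  expect_length(sp3$train, 2L)
})

test_that("corpus_stats reports character-length statistics and category counts", {
  s <- qa_corpus <- lists_to_corpus(list(
    ranking_list("q1", "catA", "ab", c(strrep("x", 2), strrep("y", 500)),
                 c(1L, 0L))))
  st <- corpus_stats(s)
  expect_equal(unname(st$answer_len), c(2, 251, 500))
  expect_equal(unname(st$question_len), c(2, 2, 2))
  expect_equal(st$n_questions, 1L)
  expect_equal(st$n_answers, 2L)

  three <- lists_to_corpus(list(
    ranking_list("q1", "A", "q", "a", 1L),
    ranking_list("q2", "A", "q", "a", 1L),
    ranking_list("q3", "B", "q", "a", 1L),
    ranking_list("q4", "C", "q", "a", 1L)))
  st3 <- corpus_stats(three)
  expect_equal(sort(unname(st3$category_counts)), c(1L, 1L, 2L))
  expect_equal(sum(st3$category_counts), st3$n_questions)

  empty <- corpus_stats(lists_to_corpus(list()))
  expect_equal(empty$n_answers, 0L)
  expect_true(all(is.na(empty$answer_len)))
})
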