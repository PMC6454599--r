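#' Configuration for the synthetic QA corpus generator
#'
#' The generator emulates the structure of a consultancy QA ranking corpus:
#' each question belongs to a topical category, its adopted answer shares
#' the question's topic vocabulary at a controllable rate, and the four
#' distractor answers come from other topics with a controllable leakage of
#' the question's topic tokens. Tokens are CJK-range code points so both
#' character- and word-level pipelines are exercised on realistic input.
#'
#' Difficulty dials:
#' \describe{
#'   \item{`overlap`}{fraction of question and adopted-answer tokens drawn
#'     from the question's topic vocabulary (the rest come from the shared
#'     pool). At `overlap = 0` positives are statistically indistinguishable
#'     from negatives generated with `noise = 0`.}
#'   \item{`noise`}{fraction of each negative answer's tokens leaked from
#'     the question's topic vocabulary, making distractors lexically harder
#'     without flipping any label.}
#' }
#'
#' Default lengths mimic the length profile of real consultancy data
#' (questions around 87 tokens, answers around 147); tests and desk-scale
#' experiments pass ranges scaled down about 10x.
#'
#' @param n_questions number of questions (default 200).
#' @param n_categories number of topical categories (default 5).
#' @param shared_vocab size of the topic-neutral shared token pool
#'   (default 100).
#' @param topic_vocab tokens per topic (default 40).
#' @param question_len inclusive integer range of question lengths in
#'   tokens (default `c(60, 110)`).
#' @param answer_len inclusive integer range of answer lengths
#'   (default `c(100, 190)`).
#' @param overlap question/positive topical rate in \[0,1\] (default 0.9).
#' @param noise distractor leakage rate in \[0,1\] (default 0.1).
#' @param n_neg distractors per question (default 4).
#' @param seed integer seed (default 7).
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_questions = 200L, n_categories = 5L,
                         shared_vocab = 100L, topic_vocab = 40L,
                         question_len = c(60L, 110L),
                         answer_len = c(100L, 190L),
                         overlap = 0.9, noise = 0.1,
                         n_neg = 4L, seed = 7L) {
  stopifnot(overlap >= 0, overlap <= 1, noise >= 0, noise <= 1,
            n_questions >= 1, n_categories >= 2,
            length(question_len) == 2L, length(answer_len) == 2L,
            question_len[1] >= 1, answer_len[1] >= 1,
            question_len[1] <= question_len[2],
            answer_len[1] <= answer_len[2])
  if (shared_vocab < 1L || topic_vocab < 1L)
    stop("vocabulary too small: shared_vocab and topic_vocab must be >= 1")
  structure(list(n_questions = as.integer(n_questions),
                 n_categories = as.integer(n_categories),
                 shared_vocab = as.integer(shared_vocab),
                 topic_vocab = as.integer(topic_vocab),
                 question_len = as.integer(question_len),
                 answer_len = as.integer(answer_len),
                 overlap = overlap, noise = noise,
                 n_neg = as.integer(n_neg), seed = as.integer(seed)),
            class = "synth_config")
}

# token pools: one CJK block per topic plus a disjoint shared block
synth_token_pools <- function(config) {
  topics <- lapply(seq_len(config$n_categories), function(t) {
    vapply(0x4E00 + (t - 1L) * config$topic_vocab + seq_len(config$topic_vocab) - 1L,
           intToUtf8, character(1))
  })
  shared <- vapply(0x6E00 + seq_len(config$shared_vocab) - 1L,
                   intToUtf8, character(1))
  list(topics = topics, shared = shared)
}

#' Generate a synthetic ranking corpus
#'
#' Draws `n_questions` questions with one adopted answer and `n_neg`
#' distractors each, deterministic under the config seed. Serialized output
#' parses back through [read_corpus()].
#'
#' @param config a [synth_config()].
#' @param path optional output TSV path in the 5-field dialect.
#' @param segmented if `TRUE`, join tokens with spaces (pre-segmented
#'   word-level file); otherwise concatenate characters (char-level file).
#' @return A list of `ranking_list` objects (invisibly also written to
#'   `path` when given).
#' @export
generate_corpus <- function(config = synth_config(), path = NULL,
                            segmented = FALSE) {
  pools <- synth_token_pools(config)
  glue <- if (segmented) " " else ""
  with_seed(config$seed, {
    lists <- lapply(seq_len(config$n_questions), function(i) {
      topic <- sample.int(config$n_categories, 1L)
      qid <- sprintf("synthq%05d", i)
      cat_name <- sprintf("cat%02d", topic)
      draw <- function(len, p_qtopic, p_own = 0, own_topic = topic) {
        u <- stats::runif(len)
        src <- ifelse(u < p_qtopic, "q",
                      ifelse(u < p_qtopic + p_own, "o", "s"))
        toks <- character(len)
        toks[src == "q"] <- sample(pools$topics[[topic]], sum(src == "q"),
                                   replace = TRUE)
        toks[src == "o"] <- sample(pools$topics[[own_topic]], sum(src == "o"),
                                   replace = TRUE)
        toks[src == "s"] <- sample(pools$shared, sum(src == "s"),
                                   replace = TRUE)
        toks
      }
      q_len <- sample(config$question_len[1]:config$question_len[2], 1L)
      question <- paste(draw(q_len, config$overlap), collapse = glue)
      a_len <- sample(config$answer_len[1]:config$answer_len[2], 1L)
      positive <- paste(draw(a_len, config$overlap), collapse = glue)
      negatives <- vapply(seq_len(config$n_neg), function(j) {
        other <- sample(setdiff(seq_len(config$n_categories), topic), 1L)
        n_len <- sample(config$answer_len[1]:config$answer_len[2], 1L)
        paste(draw(n_len, config$noise,
                   p_own = (1 - config$noise) * config$overlap,
                   own_topic = other), collapse = glue)
      }, character(1))
      ranking_list(qid, category = cat_name, question = question,
                   answers = c(positive, negatives),
                   labels = c(1L, rep(0L, config$n_neg)))
    })
    if (!is.null(path)) write_corpus(lists_to_corpus(lists), path)
    lists
  })
}

#' Hand-authored fixture corpora for corpus-module tests
#'
#' @param kind one of:
#'   \describe{
#'     \item{`"tiny"`}{3 well-formed questions, 1 positive + 4 negatives
#'       each; round-trips through read/write.}
#'     \item{`"boundary"`}{exercises the filtering rules: a 500-character
#'       adopted answer (kept), a 501-character one (dropped), a question
#'       with two adopted answers (dropped), one with none (dropped), and
#'       one with fewer than 4 native negatives (needs supplementation).}
#'     \item{`"malformed"`}{raw lines that violate the 5-field contract,
#'       for strict-mode read errors.}
#'   }
#' @return For `"tiny"` and `"boundary"`, a `qa_corpus` data frame; for
#'   `"malformed"`, a character vector of raw lines to write to a file.
#' @export
make_fixture <- function(kind = c("tiny", "boundary", "malformed")) {
  kind <- match.arg(kind)
  if (kind == "tiny") {
    rows <- list()
    for (i in 1:3) {
      qid <- paste0("tiny", i)
      rows[[length(rows) + 1L]] <- c(qid, "1", "catA",
                                     paste0("question ", i, " text"),
                                     paste0("adopted answer ", i))
      for (j in 1:4) {
        rows[[length(rows) + 1L]] <- c(qid, "0", "catA",
                                       paste0("question ", i, " text"),
                                       paste0("distractor ", i, ".", j))
      }
    }
    m <- do.call(rbind, rows)
    return(qa_corpus_frame(m[, 1], as.integer(m[, 2]), m[, 3], m[, 4], m[, 5]))
  }
  if (kind == "boundary") {
    a500 <- strrep("a", 500)
    a501 <- strrep("b", 501)
    rows <- list(
      c("bq1", "1", "catA", "q1 text", a500),        # kept: exactly 500 chars
      c("bq1", "0", "catA", "q1 text", "neg 1.1"),
      c("bq1", "0", "catA", "q1 text", "neg 1.2"),
      c("bq1", "0", "catA", "q1 text", "neg 1.3"),
      c("bq1", "0", "catA", "q1 text", "neg 1.4"),
      c("bq2", "1", "catA", "q2 text", a501),        # dropped: 501 chars
      c("bq2", "0", "catA", "q2 text", "neg 2.1"),
      c("bq3", "1", "catA", "q3 text", "dup answer"),# dropped: two positives
      c("bq3", "1", "catA", "q3 text", "dup answer 2"),
      c("bq3", "0", "catA", "q3 text", "neg 3.1"),
      c("bq4", "0", "catA", "q4 text", "no adopted"),# dropped: no positive
      c("bq5", "1", "catB", "q5 text", "short pos"), # kept: needs supplementation
      c("bq5", "0", "catB", "q5 text", "neg 5.1"),
      c("bq5", "0", "catB", "q5 text", "neg 5.2")
    )
    m <- do.call(rbind, rows)
    return(qa_corpus_frame(m[, 1], as.integer(m[, 2]), m[, 3], m[, 4], m[, 5]))
  }
  # malformed: raw lines, not a parseable corpus
  c("m1\t1\tcatA",                                  # 3 fields
    "m2\t2\tcatA\tquestion\tanswer",                # label out of range
    "m3\t1\tcatA\tquestion\tanswer")                # well-formed control
}
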