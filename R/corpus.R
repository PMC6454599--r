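#' Read a QA corpus in the webMedQA 5-field dialect
#'
#' Each line of the file is one QA sample with five tab-separated fields:
#' question id, binary adoption label (1 = adopted answer), clinical
#' category, question text, answer text. No header, UTF-8.
#'
#' @param path path to a TSV corpus file.
#' @param strict if `TRUE` (default), a line with fewer than 5 fields or a
#'   label outside \{0,1\} aborts with the offending line number; otherwise
#'   malformed lines are skipped with a warning (bad labels always error).
#' @return A data frame of class `qa_corpus` with columns `question_id`,
#'   `label` (integer), `category`, `question`, `answer`, one row per line,
#'   input order preserved.
#' @export
#' @examples
#' tmp <- tempfile(fileext = ".tsv")
#' writeLines("q1\t1\tSurgery\tQ-text\tA-text", tmp)
#' read_corpus(tmp)
read_corpus <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("corpus file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines) | seq_along(lines) < length(lines)]
  if (length(lines) == 0L) return(qa_corpus_frame())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 5L & nzchar(lines))
  empty <- which(!nzchar(lines))
  if (length(bad) > 0L) {
    if (strict) {
      stop("malformed corpus line ", bad[1L], ": expected 5 tab-separated fields, got ",
           nf[bad[1L]])
    }
    warning("skipping ", length(bad), " malformed line(s): ",
            paste(utils::head(bad, 5L), collapse = ", "))
  }
  keep <- setdiff(seq_along(parts), c(bad, empty))
  if (length(keep) == 0L) return(qa_corpus_frame())
  parts <- parts[keep]
  # extra tabs beyond field 5 belong to the answer text
  field <- function(i) vapply(parts, `[[`, character(1), i)
  answer <- vapply(parts, function(p) paste(p[5:length(p)], collapse = "\t"),
                   character(1))
  lab_raw <- field(2L)
  if (!all(lab_raw %in% c("0", "1"))) {
    bad_lab <- keep[which(!(lab_raw %in% c("0", "1")))[1L]]
    stop("invalid label on line ", bad_lab, ": must be 0 or 1")
  }
  qa_corpus_frame(
    question_id = field(1L),
    label = as.integer(lab_raw),
    category = field(3L),
    question = field(4L),
    answer = answer
  )
}

qa_corpus_frame <- function(question_id = character(), label = integer(),
                            category = character(), question = character(),
                            answer = character()) {
  out <- data.frame(
    question_id = question_id, label = label, category = category,
    question = question, answer = answer, stringsAsFactors = FALSE
  )
  class(out) <- c("qa_corpus", "data.frame")
  out
}

#' Write a QA corpus in the webMedQA 5-field dialect
#'
#' Tabs and newlines inside the question or answer text are replaced by a
#' single space at write time: the dialect reserves both characters and
#' defines no escaping scheme, so collapsing them preserves the 5-field
#' contract. Round-trips with [read_corpus()] for any corpus whose text
#' fields contain neither.
#'
#' @param samples a `qa_corpus` data frame (or any data frame with the five
#'   corpus columns).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(samples, path) {
  stopifnot(all(c("question_id", "label", "category", "question", "answer")
                %in% names(samples)))
  if (!all(samples$label %in% c(0L, 1L))) stop("labels must be 0 or 1")
  flat <- function(x) gsub("[\t\r\n]+", " ", x)
  lines <- paste(flat(samples$question_id), samples$label,
                 flat(samples$category), flat(samples$question),
                 flat(samples$answer), sep = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con, useBytes = FALSE)
  invisible(path)
}

#' Clean raw consultancy text
#'
#' Strips HTML/XML tags and URLs, then keeps only decimal digits,
#' punctuation (Unicode category P plus CJK fullwidth punctuation), CJK
#' ideographs, Latin letters and spaces; runs of whitespace collapse to one
#' ASCII space. Idempotent.
#'
#' @param raw character vector of raw text.
#' @return Cleaned character vector of the same length.
#' @export
#' @examples
#' clean_text("<b>\u5934\u75db</b> see http://x.cn now!")
clean_text <- function(raw) {
  x <- enc2utf8(raw)
  x <- gsub("<[^<>]*>", " ", x, perl = TRUE)
  x <- gsub("(https?|ftp)://[^[:space:]]+", " ", x, perl = TRUE)
  x <- gsub("www\\.[^[:space:]]+", " ", x, perl = TRUE)
  # keep digits, Latin letters, CJK ideographs, Unicode punctuation,
  # fullwidth forms; everything else becomes a space. The pattern is built
  # as UTF-8 so PCRE compiles in Unicode mode for ASCII inputs too.
  keep <- enc2utf8(paste0("[^0-9A-Za-z\\p{Han}\\p{P}",
                          intToUtf8(0xFF00), "-", intToUtf8(0xFFEF),
                          intToUtf8(0x3000), "-", intToUtf8(0x303F), " ]"))
  x <- gsub(keep, " ", x, perl = TRUE)
  x <- gsub("[ \t\r\n]+", " ", x)
  trimws(x)
}

#' Filter questions to single-adopted-answer groups
#'
#' Retains only questions that have exactly one adopted (label 1) answer
#' whose length is at most `max_answer_chars` Unicode characters; questions
#' with zero or multiple adopted answers are dropped, as are questions whose
#' single adopted answer exceeds the cap.
#'
#' @param samples a `qa_corpus` data frame.
#' @param max_answer_chars adopted-answer length cap in characters
#'   (default 500).
#' @return The filtered `qa_corpus`, original row order preserved.
#' @export
filter_questions <- function(samples, max_answer_chars = 500L) {
  if (nrow(samples) == 0L) return(samples)
  pos <- samples$label == 1L
  npos <- tapply(pos, samples$question_id, sum)
  pos_len <- tapply(ifelse(pos, nchar(samples$answer, type = "chars"), NA_integer_),
                    samples$question_id, function(v) {
                      v <- v[!is.na(v)]
                      if (length(v) == 1L) v else NA_integer_
                    })
  ok_ids <- names(npos)[npos == 1L & !is.na(pos_len) & pos_len <= max_answer_chars]
  samples[samples$question_id %in% ok_ids, , drop = FALSE]
}

#' Build single-positive ranking lists by negative sampling
#'
#' Each question contributes one ranking list containing its adopted answer
#' plus `n_neg` negatives. Native (same-question) negatives are subsampled
#' without replacement when more than `n_neg` exist; when fewer exist the
#' deficit is drawn, seeded and without replacement, uniformly from other
#' questions' answers (the current question's own answers are excluded).
#'
#' @param samples a filtered `qa_corpus` (exactly one label-1 answer per
#'   question id).
#' @param n_neg negatives per question (default 4).
#' @param seed integer seed; the result is deterministic given the seed.
#' @return A list of `ranking_list` objects: each has `question_id`,
#'   `category`, `question`, and `candidates` (data frame of `answer`,
#'   `label` with exactly one positive).
#' @export
sample_negatives <- function(samples, n_neg = 4L, seed = 1L) {
  if (nrow(samples) == 0L) return(list())
  groups <- split(seq_len(nrow(samples)), samples$question_id)
  # preserve first-appearance order of question ids
  first <- vapply(groups, min, integer(1))
  groups <- groups[order(first)]
  for (idx in groups) {
    if (sum(samples$label[idx] == 1L) != 1L)
      stop("each question must have exactly one positive answer; run filter_questions() first")
  }
  with_seed(seed, {
    lapply(groups, function(idx) {
      qid <- samples$question_id[idx[1L]]
      pos_i <- idx[samples$label[idx] == 1L]
      neg_i <- idx[samples$label[idx] == 0L]
      if (length(neg_i) > n_neg) {
        neg_i <- sort(sample(neg_i, n_neg))
        negs <- samples$answer[neg_i]
      } else {
        negs <- samples$answer[neg_i]
        deficit <- n_neg - length(negs)
        if (deficit > 0L) {
          pool <- which(samples$question_id != qid)
          if (length(pool) < deficit)
            stop("not enough answers in other questions to supplement negatives for ", qid)
          negs <- c(negs, samples$answer[sample(pool, deficit)])
        }
      }
      ranking_list(qid,
                   category = samples$category[pos_i],
                   question = samples$question[pos_i],
                   answers = c(samples$answer[pos_i], negs),
                   labels = c(1L, rep(0L, length(negs))))
    })
  })
}

#' Construct a ranking list
#'
#' @param question_id question identifier shared by all candidates.
#' @param category clinical category string.
#' @param question question text.
#' @param answers character vector of candidate answers.
#' @param labels integer vector in \{0,1\}, same length as `answers`.
#' @return A `ranking_list` object.
#' @export
ranking_list <- function(question_id, category, question, answers, labels) {
  stopifnot(length(answers) == length(labels), all(labels %in% c(0L, 1L)))
  structure(
    list(question_id = question_id, category = category, question = question,
         candidates = data.frame(answer = answers, label = as.integer(labels),
                                 stringsAsFactors = FALSE)),
    class = "ranking_list"
  )
}

#' @export
print.ranking_list <- function(x, ...) {
  cat("<ranking_list> ", x$question_id, " [", x$category, "]: ",
      nrow(x$candidates), " candidates, ",
      sum(x$candidates$label), " positive\n", sep = "")
  invisible(x)
}

#' Stratified train/development/test split of ranking lists
#'
#' Splits by clinical category in the given proportions. Within each
#' category, dev and test sizes are `floor(n/10)` each (for the default
#' 8:1:1 ratios) with the remainder assigned to train - deterministic and
#' train-favoring. Categories with fewer than 3 questions go entirely to
#' train with a warning.
#'
#' @param lists list of `ranking_list` objects, each carrying a category.
#' @param ratios integer proportions for train/dev/test (default `c(8,1,1)`).
#' @param seed integer seed for the within-category shuffle.
#' @return A list with elements `train`, `dev`, `test`, each a list of
#'   `ranking_list`; a disjoint, exhaustive partition of the input.
#' @export
split_corpus <- function(lists, ratios = c(8, 1, 1), seed = 1L) {
  stopifnot(length(ratios) == 3L, all(ratios > 0))
  cats <- vapply(lists, function(l) l$category, character(1))
  total <- sum(ratios)
  out <- list(train = list(), dev = list(), test = list())
  with_seed(seed, {
    for (cat_name in unique(cats)) {
      idx <- which(cats == cat_name)
      n <- length(idx)
      if (n < 3L) {
        warning("category '", cat_name, "' has ", n,
                " question(s); assigning all to train")
        out$train <- c(out$train, lists[idx])
        next
      }
      idx <- sample(idx)
      n_dev <- floor(n * ratios[2] / total)
      n_test <- floor(n * ratios[3] / total)
      dev_i <- idx[seq_len(n_dev)]
      test_i <- idx[n_dev + seq_len(n_test)]
      train_i <- idx[-(seq_len(n_dev + n_test))]
      out$train <- c(out$train, lists[train_i])
      out$dev <- c(out$dev, lists[dev_i])
      out$test <- c(out$test, lists[test_i])
    }
  })
  out
}

#' Summary statistics of a QA corpus
#'
#' Character-length statistics of questions and answers plus per-category
#' question counts, in the style of a dataset summary table. Lengths are in
#' Unicode characters, not bytes.
#'
#' @param samples a `qa_corpus` data frame.
#' @return A `corpus_stats` list: `n_answers`, `n_questions`, `answer_len`
#'   and `question_len` (each `min`/`avg`/`max`, `NA` when empty), and
#'   `category_counts` (named integer vector over distinct questions).
#' @export
corpus_stats <- function(samples) {
  if (nrow(samples) == 0L) {
    return(structure(list(
      n_answers = 0L, n_questions = 0L,
      answer_len = c(min = NA_real_, avg = NA_real_, max = NA_real_),
      question_len = c(min = NA_real_, avg = NA_real_, max = NA_real_),
      category_counts = integer(0)
    ), class = "corpus_stats"))
  }
  alen <- nchar(samples$answer, type = "chars")
  qfirst <- !duplicated(samples$question_id)
  qlen <- nchar(samples$question[qfirst], type = "chars")
  cat_tab <- table(samples$category[qfirst])
  structure(list(
    n_answers = nrow(samples),
    n_questions = sum(qfirst),
    answer_len = c(min = min(alen), avg = mean(alen), max = max(alen)),
    question_len = c(min = min(qlen), avg = mean(qlen), max = max(qlen)),
    category_counts = stats::setNames(as.integer(cat_tab), names(cat_tab))
  ), class = "corpus_stats")
}

#' @export
print.corpus_stats <- function(x, ...) {
  cat("QA corpus:", x$n_questions, "questions,", x$n_answers, "answers\n")
  if (x$n_answers > 0L) {
    cat(sprintf("  answer length   min %g / avg %.2f / max %g chars\n",
                x$answer_len["min"], x$answer_len["avg"], x$answer_len["max"]))
    cat(sprintf("  question length min %g / avg %.2f / max %g chars\n",
                x$question_len["min"], x$question_len["avg"], x$question_len["max"]))
    cat("  categories:", length(x$category_counts), "\n")
  }
  invisible(x)
}

#' Flatten ranking lists back to a sample table
#'
#' Inverse of grouping: emits one corpus row per candidate, positives first
#' within each list.
#'
#' @param lists list of `ranking_list` objects.
#' @return A `qa_corpus` data frame.
#' @export
lists_to_corpus <- function(lists) {
  if (length(lists) == 0L) return(qa_corpus_frame())
  parts <- lapply(lists, function(l) {
    qa_corpus_frame(
      question_id = rep(l$question_id, nrow(l$candidates)),
      label = l$candidates$label,
      category = rep(l$category, nrow(l$candidates)),
      question = rep(l$question, nrow(l$candidates)),
      answer = l$candidates$answer
    )
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  class(out) <- c("qa_corpus", "data.frame")
  out
}

#' Group a sample table into ranking lists
#'
#' @param samples a `qa_corpus` data frame where every question id has
#'   exactly one positive.
#' @return A list of `ranking_list` objects in first-appearance order.
#' @export
corpus_to_lists <- function(samples) {
  if (nrow(samples) == 0L) return(list())
  groups <- split(seq_len(nrow(samples)), samples$question_id)
  first <- vapply(groups, min, integer(1))
  groups <- groups[order(first)]
  lapply(groups, function(idx) {
    pos_i <- idx[samples$label[idx] == 1L]
    if (length(pos_i) != 1L)
      stop("question ", samples$question_id[idx[1L]],
           " does not have exactly one positive answer")
    ranking_list(samples$question_id[idx[1L]],
                 category = samples$category[pos_i],
                 question = samples$question[pos_i],
                 answers = samples$answer[idx],
                 labels = samples$label[idx])
  })
}
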