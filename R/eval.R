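#' Rank candidates of a scored list
#'
#' Orders candidates by descending score. The rank reported for the positive
#' candidate depends on the tie policy: under `"pessimistic"` (default) the
#' positive ranks below every negative it is tied with, so tied scores never
#' overstate model quality; `"stable"` keeps input order among ties.
#'
#' @param scores numeric scores, one per candidate (finite).
#' @param labels integer labels in \{0,1\}, exactly one 1.
#' @param tie_policy `"pessimistic"` or `"stable"`.
#' @return A list: `order` (candidate indices best-first), `positive_rank`
#'   (1-based rank of the positive candidate).
#' @export
rank_candidates <- function(scores, labels, tie_policy = c("pessimistic", "stable")) {
  tie_policy <- match.arg(tie_policy)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  if (sum(labels == 1L) != 1L) stop("ranking list must contain exactly one positive")
  pos <- which(labels == 1L)
  s_pos <- scores[pos]
  neg <- scores[labels == 0L]
  r <- if (tie_policy == "pessimistic") {
    1L + sum(neg > s_pos) + sum(neg == s_pos)
  } else {
    above <- sum(neg > s_pos)
    tied_before <- sum(scores[seq_len(pos - 1L)][labels[seq_len(pos - 1L)] == 0L] == s_pos)
    1L + above + tied_before
  }
  ord <- order(-scores, seq_along(scores))
  list(order = ord, positive_rank = as.integer(r))
}

#' Precision at 1 over ranking lists
#'
#' The fraction of single-positive ranking lists whose adopted answer is
#' ranked first.
#'
#' @param ranks integer vector of positive-candidate ranks, one per list
#'   (as produced by [rank_candidates()]).
#' @return Scalar in \[0, 1\].
#' @export
p_at_1 <- function(ranks) {
  if (length(ranks) == 0L) stop("no ranking lists to evaluate")
  mean(ranks == 1L)
}

#' Mean average precision over single-positive ranking lists
#'
#' With exactly one positive per list, average precision reduces to the
#' reciprocal rank of that positive, so MAP is the mean reciprocal rank.
#'
#' @inheritParams p_at_1
#' @return Scalar in \[0, 1\]; always at least [p_at_1()] of the same ranks.
#' @export
mean_ap <- function(ranks) {
  if (length(ranks) == 0L) stop("no ranking lists to evaluate")
  mean(1 / ranks)
}

#' Evaluate a scoring function on encoded ranking lists
#'
#' @param score_fn function(encoded list) -> numeric candidate scores.
#' @param lists a list of encoded ranking lists (see [encode_lists()]).
#' @param tie_policy passed to [rank_candidates()].
#' @return List with `p_at_1`, `map`, `n_lists`, `ranks`.
#' @export
evaluate_ranker <- function(score_fn, lists, tie_policy = "pessimistic") {
  ranks <- vapply(lists, function(l) {
    s <- score_fn(l)
    rank_candidates(s, l$labels, tie_policy)$positive_rank
  }, integer(1))
  list(p_at_1 = p_at_1(ranks), map = mean_ap(ranks),
       n_lists = length(ranks), ranks = ranks)
}

#' Format metrics as percentages, one decimal
#'
#' @param metrics list with `p_at_1` and `map` in \[0,1\].
#' @return Named character vector, e.g. `c(p_at_1 = "20.0", map = "45.7")`.
#' @export
format_metrics <- function(metrics) {
  c(p_at_1 = sprintf("%.1f", 100 * metrics$p_at_1),
    map = sprintf("%.1f", 100 * metrics$map))
}
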