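#' Build a submission-by-representation score table
#'
#' @param data Tibble with columns `submission`, `representation`, `qscore`
#'   (one Q-score per submission and representation, typically over the
#'   original representation and the four design points).
#' @return A validated `score_table` tibble.
#' @export
score_table <- function(data) {
  stopifnot(all(c("submission", "representation", "qscore") %in% names(data)))
  if (anyNA(data$qscore)) stop("score table contains missing Q-scores")
  counts <- table(data$submission)
  if (length(unique(counts)) != 1) {
    stop("every submission needs the same set of representations")
  }
  structure(tibble::as_tibble(data), class = c("score_table",
                                               class(tibble::tibble())))
}

# leftmost 0-based insertion index of x into sorted sequence y
pos_insert <- function(x, y) sum(y < x)

#' Average Maximum Rank Change (AMRC)
#'
#' Measures how much a submission's rank among its peers can swing between
#' its best- and worst-scoring variant representation. Each submission's
#' presumed true performance is the median of its per-representation
#' Q-scores; ranks are insertion positions into the sorted medians of the
#' other submissions (the current submission's own median is omitted).
#' AMRC is the mean, over submissions, of the rank of the best
#' representation minus the rank of the worst. An evaluation completely
#' independent of representation yields 0.
#'
#' @param t A [score_table()] (or compatible tibble).
#' @return The AMRC (non-negative real).
#' @export
amrc <- function(t) {
  if (anyNA(t$qscore)) stop("missing Q-scores")
  by_sub <- split(t$qscore, t$submission)
  med <- vapply(by_sub, stats::median, numeric(1))
  best <- vapply(by_sub, max, numeric(1))
  worst <- vapply(by_sub, min, numeric(1))
  m_sorted <- sort(med)
  changes <- vapply(seq_along(by_sub), function(i) {
    others <- m_sorted[-match(med[i], m_sorted)] # drop one copy of own median
    pos_insert(best[i], others) - pos_insert(worst[i], others)
  }, numeric(1))
  mean(changes)
}

#' Representation-stability R-squared
#'
#' Coefficient of determination between each submission's
#' per-representation Q-scores and that submission's mean Q-score, pooled
#' across representations: `1 - SS_res / SS_tot` where the predictor of
#' every score is its submission mean and SS_tot is taken around the grand
#' mean. A table whose scores do not depend on representation gives exactly
#' 1; any representation-driven scatter lowers it.
#'
#' @param t A [score_table()] (or compatible tibble); needs at least two
#'   submissions.
#' @return R-squared in `(-Inf, 1]`.
#' @export
stability_r2 <- function(t) {
  if (anyNA(t$qscore)) stop("missing Q-scores")
  if (length(unique(t$submission)) < 2) {
    stop("need at least two submissions")
  }
  sub_mean <- stats::ave(t$qscore, t$submission)
  ss_tot <- sum((t$qscore - mean(t$qscore))^2)
  if (ss_tot == 0) stop("zero variance across the score table")
  1 - sum((t$qscore - sub_mean)^2) / ss_tot
}
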