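#' Edit distance and distinct edits of the 2DE + ED-optimal alignment
#'
#' Jointly minimizes the number of distinct edits (DE, weighted twice) and
#' the edit distance (ED, edited bases). Minimizing `2 * DE + ED` is
#' equivalent to affine-gap global alignment at design point B,
#' `(m, x, o, e) = (0, 3, 2, 1)`: opening a gap adds one distinct edit,
#' extending it adds one edited base, and a substitution adds one of each.
#' The reported ED is therefore the ED of the jointly optimal path, which
#' may exceed the Levenshtein minimum.
#'
#' @param a,b Sequences to compare (order does not matter).
#' @return Named numeric vector `c(ed = , de = )`.
#' @examples
#' ed_de("ACGT", paste0("ACGT", "TTTTT")) # insertion of 5: ED 5, DE 1
#' @export
ed_de <- function(a, b) {
  ops <- cpp_align_affine(toupper(a), toupper(b), 0, 3, 2, 1)$ops
  if (!nzchar(ops)) return(c(ed = 0, de = 0))
  r <- rle(strsplit(ops, "", fixed = TRUE)[[1]])
  subs <- sum(r$lengths[r$values == "X"])
  gap <- r$values %in% c("D", "I")
  c(ed = subs + sum(r$lengths[gap]), de = subs + sum(gap))
}

#' Alignment distance between two sequences
#'
#' Minimum affine-gap global alignment penalty; the standard representation
#' penalties (point C) are used by default, matching the parameter set used
#' for standardization.
#'
#' @param a,b Sequences to compare.
#' @param params [affine_params].
#' @return The minimum alignment penalty.
#' @export
aln_distance <- function(a, b, params = preset_params("C")) {
  p <- as_affine_params(params)
  cpp_align_affine(toupper(a), toupper(b), p$m, p$x, p$o, p$e)$penalty
}

qscore_ratio <- function(query, ref, cap = 100) {
  dplyr::case_when(
    ref == 0 ~ NA_real_,
    query == 0 ~ cap,
    TRUE ~ pmin(cap, -10 * log10(query / ref))
  )
}

#' Distance-based Q-scores
#'
#' Phred-like quality estimates from the remaining distance of the query to
#' the truth haplotypes, relative to the distance of the unedited reference
#' to the truth: `-10 * log10(metric_query / metric_ref)` for each of ED,
#' DE and alignment distance. A perfect query (zero remaining distance) is
#' capped at Q100; a zero reference term leaves the score undefined (`NA`).
#'
#' @param ds Tibble or data frame with columns `ed_query`, `de_query`,
#'   `aln_query`, `ed_ref`, `de_ref`, `aln_ref` (one row per quality
#'   threshold, e.g. from [run_evaluation()]).
#' @param cap Upper bound for the Q-scores.
#' @return `ds` with added columns `ed_qscore`, `de_qscore`, `aln_qscore`.
#' @export
distance_qscores <- function(ds, cap = 100) {
  dplyr::mutate(
    ds,
    ed_qscore = qscore_ratio(.data$ed_query, .data$ed_ref, cap),
    de_qscore = qscore_ratio(.data$de_query, .data$de_ref, cap),
    aln_qscore = qscore_ratio(.data$aln_query, .data$aln_ref, cap)
  )
}

#' F1 Q-score
#'
#' Phred-like transform of an F1 score: `-10 * log10(1 - F1)`, capped.
#'
#' @param f1 F1 score(s) in `[0, 1]`.
#' @param cap Value returned when `F1 == 1`.
#' @return Q-score(s).
#' @examples
#' f1_qscore(0.99) # 20
#' @export
f1_qscore <- function(f1, cap = 100) {
  ifelse(is.na(f1), NA_real_, pmin(cap, -10 * log10(pmax(1 - f1, 10^(-cap / 10)))))
}
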