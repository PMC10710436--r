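#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an evaluation into per-variant credit records
#'
#' @param x A `phasebench_eval` object from [run_evaluation()].
#' @param ... Unused.
#' @return Tibble of credit records: one row per evaluated variant per
#'   haplotype, with `category` (TP/FP/FN/PP) and fractional `credit`.
#' @export
tidy.phasebench_eval <- function(x, ...) {
  tibble::as_tibble(x$records)
}

#' One-row summary of an evaluation
#'
#' Reports, per variant class, the precision/recall/F1 at the
#' F1-maximizing quality threshold, plus switch errors and the distance
#' metrics at the lowest threshold.
#'
#' @param x A `phasebench_eval` object.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.phasebench_eval <- function(x, ...) {
  best <- function(cls) {
    cur <- x$pr_curve[x$pr_curve$class == cls & !is.na(x$pr_curve$f1), ]
    if (nrow(cur) == 0) {
      return(tibble::tibble(precision = NA_real_, recall = NA_real_,
                            f1 = NA_real_, f1_qscore = NA_real_,
                            threshold = NA_real_))
    }
    cur[which.max(cur$f1), c("precision", "recall", "f1", "f1_qscore",
                             "threshold")]
  }
  snp <- best("SNP"); indel <- best("INDEL"); all <- best("ALL")
  d0 <- x$distance_curve[1, ]
  tibble::tibble(
    snp_precision = snp$precision, snp_recall = snp$recall,
    snp_f1 = snp$f1, snp_f1_qscore = snp$f1_qscore,
    indel_precision = indel$precision, indel_recall = indel$recall,
    indel_f1 = indel$f1, indel_f1_qscore = indel$f1_qscore,
    all_f1 = all$f1, all_f1_qscore = all$f1_qscore,
    ed_query = d0$ed_query, de_query = d0$de_query,
    aln_query = d0$aln_query, ed_qscore = d0$ed_qscore,
    de_qscore = d0$de_qscore, aln_qscore = d0$aln_qscore,
    switch_errors = x$phasing$switch_errors,
    phase_errors = x$phasing$phase_errors,
    n_superclusters = nrow(x$superclusters)
  )
}

#' Plot an evaluation
#'
#' `type = "pr"` draws the precision-recall curve over query quality
#' thresholds for SNPs and INDELs; `type = "distance"` draws the remaining
#' edit distance and distinct edits against the quality threshold.
#'
#' @param object A `phasebench_eval` object.
#' @param type `"pr"` or `"distance"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phasebench_eval <- function(object, type = c("pr", "distance"),
                                     ...) {
  type <- match.arg(type)
  if (type == "pr") {
    dat <- object$pr_curve[object$pr_curve$class %in% c("SNP", "INDEL") &
                             !is.na(object$pr_curve$f1), ]
    ggplot2::ggplot(dat, ggplot2::aes(x = .data$recall, y = .data$precision,
                                      colour = .data$class)) +
      ggplot2::geom_path() +
      ggplot2::geom_point() +
      ggplot2::labs(x = "Recall", y = "Precision", colour = NULL) +
      ggplot2::theme_minimal()
  } else {
    dat <- tidyr::pivot_longer(
      object$distance_curve[, c("threshold", "ed_query", "de_query")],
      cols = c("ed_query", "de_query"), names_to = "metric",
      values_to = "value")
    dat$metric <- ifelse(dat$metric == "ed_query", "edit distance",
                         "distinct edits")
    ggplot2::ggplot(dat, ggplot2::aes(x = .data$threshold, y = .data$value,
                                      colour = .data$metric)) +
      ggplot2::geom_step() +
      ggplot2::labs(x = "Quality threshold", y = "Remaining errors",
                    colour = NULL) +
      ggplot2::theme_minimal()
  }
}

#' Write the evaluation report bundle
#'
#' Writes a text summary, the per-variant credit records, the
#' precision-recall curve, the distance curve and the phasing tables as
#' TSVs, plus (when a reference is supplied) the evaluated truth and query
#' callsets as phased VCFs in their final (standardized) representation.
#'
#' @param x A `phasebench_eval` object.
#' @param dir Output directory (created if missing).
#' @param reference Optional named character vector of contig sequences;
#'   enables VCF output.
#' @return `dir`, invisibly.
#' @export
write_report <- function(x, dir, reference = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(d, name) {
    utils::write.table(d, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  tsv(x$records, "variants.tsv")
  tsv(x$pr_curve, "precision_recall.tsv")
  tsv(x$distance_curve, "distance.tsv")
  tsv(x$phasing$states, "superclusters.tsv")
  tsv(x$phasing$blocks, "phase_blocks.tsv")
  g <- glance(x)
  lines <- c(
    "phasebench evaluation summary",
    sprintf("superclusters evaluated: %d", g$n_superclusters),
    sprintf("SNP   precision %.4f recall %.4f F1 %.4f (Q%.1f)",
            g$snp_precision, g$snp_recall, g$snp_f1, g$snp_f1_qscore),
    sprintf("INDEL precision %.4f recall %.4f F1 %.4f (Q%.1f)",
            g$indel_precision, g$indel_recall, g$indel_f1, g$indel_f1_qscore),
    sprintf("edit distance %g  distinct edits %g  alignment distance %g",
            g$ed_query, g$de_query, g$aln_query),
    sprintf("ED Q%.1f  DE Q%.1f  ALN Q%.1f",
            g$ed_qscore, g$de_qscore, g$aln_qscore),
    sprintf("switch errors: %d  supercluster phasing errors: %d",
            g$switch_errors, g$phase_errors)
  )
  writeLines(lines, file.path(dir, "summary.txt"))
  if (!is.null(reference)) {
    write_vcf(x$truth, file.path(dir, "truth.std.vcf"), reference)
    write_vcf(x$query, file.path(dir, "query.std.vcf"), reference)
  }
  invisible(dir)
}
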