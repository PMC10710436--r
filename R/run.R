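class_group <- function(class) ifelse(class == "SNP", "SNP", "INDEL")

# aggregate credit records into a 3 x 4 count matrix (SNP/INDEL/ALL rows)
count_credits <- function(records) {
  m <- matrix(0, 3, 4, dimnames = list(c("SNP", "INDEL", "ALL"),
                                       c("tp_query", "fp_query",
                                         "tp_truth", "fn_truth")))
  if (nrow(records) == 0) return(m)
  grp <- class_group(records$class)
  is_q <- records$role == "query"
  for (cls in c("SNP", "INDEL", "ALL")) {
    sel <- if (cls == "ALL") rep(TRUE, nrow(records)) else grp == cls
    q <- records$credit[sel & is_q]
    t <- records$credit[sel & !is_q]
    m[cls, ] <- c(sum(q), sum(1 - q), sum(t), sum(1 - t))
  }
  m
}

pr_metrics <- function(counts) {
  dplyr::mutate(
    counts,
    precision = ifelse(.data$tp_truth + .data$fp_query > 0,
                       .data$tp_truth / (.data$tp_truth + .data$fp_query),
                       NA_real_),
    recall = ifelse(.data$tp_truth + .data$fn_truth > 0,
                    .data$tp_truth / (.data$tp_truth + .data$fn_truth),
                    NA_real_),
    f1 = ifelse(!is.na(.data$precision) & !is.na(.data$recall) &
                  .data$precision + .data$recall > 0,
                2 * .data$precision * .data$recall /
                  (.data$precision + .data$recall), NA_real_),
    f1_qscore = f1_qscore(.data$f1)
  )
}

strictify_records <- function(records) {
  pp <- records$category == "PP"
  records$credit[pp] <- 0
  records$category[pp] <- ifelse(records$role[pp] == "query", "FP", "FN")
  records
}

#' Run a full benchmarking evaluation
#'
#' The complete pipeline: read the inputs, cluster dependent variants on
#' every haplotype, optionally standardize both callsets to the standard
#' representation (design point C), group truth and query clusters into
#' superclusters, align each supercluster's truth haplotypes against
#' variant-aware query graphs, select local phasings, assign exact or
#' partial credit at sync-point granularity, sweep precision/recall and
#' distance metrics over query quality thresholds, and recover global phase
#' blocks and switch errors.
#'
#' @param reference Named character vector of contig sequences, or a FASTA
#'   path.
#' @param truth,query Callsets ([new_callset()]) or VCF paths.
#' @param regions Optional BED tibble ([read_bed()]) or path.
#' @param params [affine_params] for clustering/standardization (point C).
#' @param standardize Re-express both callsets in the standard
#'   representation before evaluation.
#' @param partial_credit Award fractional credit to partial positives; when
#'   `FALSE`, partially correct calls count as FP/FN (strict mode).
#' @param clustering `"wfa"` (reach-based) or `"gap"` (fast heuristic).
#' @param supercluster_gap Supercluster grouping distance in bases.
#' @param cluster_gap Gap size for `"gap"` clustering.
#' @param subset_cap See [align_truth_to_query_graph()].
#' @param switch_cost,phase_error_cost Costs for the global phasing DP.
#' @return A `phasebench_eval` object; see [tidy.phasebench_eval()],
#'   [glance.phasebench_eval()], [autoplot.phasebench_eval()] and
#'   [write_report()].
#' @export
run_evaluation <- function(reference, truth, query, regions = NULL,
                           params = preset_params("C"), standardize = TRUE,
                           partial_credit = TRUE,
                           clustering = c("wfa", "gap"),
                           supercluster_gap = 50L, cluster_gap = 50L,
                           subset_cap = 8L, switch_cost = 1,
                           phase_error_cost = 1) {
  clustering <- match.arg(clustering)
  if (is.character(reference) && length(reference) == 1 &&
      is.null(names(reference)) && file.exists(reference)) {
    reference <- read_fasta(reference)
  }
  if (is.character(regions) && length(regions) == 1) {
    regions <- read_bed(regions)
  }
  if (is.character(truth)) {
    truth <- read_phased_vcf(truth, reference, regions, role = "truth")
  }
  if (is.character(query)) {
    query <- read_phased_vcf(query, reference, regions, role = "query")
  }
  stopifnot(inherits(truth, "callset"), inherits(query, "callset"))

  cl_args <- list(reference = reference, method = clustering,
                  params = params, gap_size = cluster_gap)
  # callsets that went through standardize_callset() carry their clusters
  truth_cl <- attr(truth, "clusters")
  query_cl <- attr(query, "clusters")
  if (is.null(truth_cl) || clustering == "gap") {
    truth_cl <- do.call(cluster_callset, c(list(truth), cl_args))
  }
  if (is.null(query_cl) || clustering == "gap") {
    query_cl <- do.call(cluster_callset, c(list(query), cl_args))
  }
  if (standardize) {
    truth <- standardize_callset(truth, reference, params = params,
                                 clusters = truth_cl)
    query <- standardize_callset(query, reference, params = params,
                                 clusters = query_cl)
    # re-cluster from the standardized records: their reach budgets no
    # longer depend on the input representation, so supercluster windows
    # (and hence phasing decisions) are representation-invariant
    truth_cl <- do.call(cluster_callset, c(list(truth), cl_args))
    query_cl <- do.call(cluster_callset, c(list(query), cl_args))
  }
  scs <- build_superclusters(truth_cl, query_cl, distance = supercluster_gap,
                             contig_lengths = truth$contigs)

  thresholds <- sort(unique(query$variants$qual))
  if (length(thresholds) == 0) thresholds <- 0

  eval_one <- function(sc, min_qual, ref_dist = NULL) {
    res <- eval_supercluster(sc, reference, min_qual = min_qual,
                             subset_cap = subset_cap, ref_dist = ref_dist)
    if (!partial_credit) res$records <- strictify_records(res$records)
    res
  }

  nt <- length(thresholds)
  cnt <- array(0, dim = c(nt, 3, 4))
  dst <- matrix(0, nt, 6,
                dimnames = list(NULL, c("ed_query", "de_query", "aln_query",
                                        "ed_ref", "de_ref", "aln_ref")))
  base_records <- list()
  sc_meta <- list()
  for (k in seq_len(nrow(scs))) {
    sc <- scs[k, ]
    quals <- sort(unique(sc$variants[[1]]$qual[sc$variants[[1]]$role == "query"]))
    cache <- list()
    ref_dist <- NULL
    for (ti in seq_len(nt)) {
      t <- thresholds[ti]
      sig <- paste0("s", paste(quals[quals >= t], collapse = ","))
      if (is.null(cache[[sig]])) {
        res <- eval_one(sc, t, ref_dist)
        ref_dist <- res$dist[4:6]
        res$counts <- count_credits(res$records)
        cache[[sig]] <- res
      }
      res <- cache[[sig]]
      cnt[ti, , ] <- cnt[ti, , ] + res$counts
      dst[ti, ] <- dst[ti, ] + res$dist
      if (ti == 1L) {
        base_records[[k]] <- res$records
        sc_meta[[k]] <- tibble::tibble(contig = sc$contig, sc_id = sc$sc_id,
                                       begin = sc$begin, end = sc$end,
                                       phase = res$phase)
      }
    }
  }
  records <- if (length(base_records)) dplyr::bind_rows(base_records) else
    credit_record_tbl()
  sc_meta <- if (length(sc_meta)) dplyr::bind_rows(sc_meta) else
    tibble::tibble(contig = character(), sc_id = integer(),
                   begin = integer(), end = integer(), phase = character())

  classes <- c("SNP", "INDEL", "ALL")
  pr_curve <- pr_metrics(tibble::tibble(
    threshold = rep(thresholds, times = 3),
    class = rep(classes, each = nt),
    tp_query = as.vector(cnt[, , 1]), fp_query = as.vector(cnt[, , 2]),
    tp_truth = as.vector(cnt[, , 3]), fn_truth = as.vector(cnt[, , 4])
  ))
  distance_curve <- distance_qscores(
    dplyr::bind_cols(tibble::tibble(threshold = thresholds),
                     tibble::as_tibble(dst)))

  # global phasing over supercluster categories, per contig
  phasing <- list(blocks = tibble::tibble(), states = sc_meta,
                  switch_errors = 0L, phase_errors = 0L)
  if (nrow(sc_meta) > 0) {
    blocks <- list()
    states <- character(nrow(sc_meta))
    switches <- 0L
    perrors <- 0L
    for (ctg in unique(sc_meta$contig)) {
      idx <- which(sc_meta$contig == ctg)
      res <- phase_forward_backward(sc_meta$phase[idx],
                                    switch_cost = switch_cost,
                                    phase_error_cost = phase_error_cost)
      states[idx] <- res$states
      blocks[[ctg]] <- dplyr::mutate(res$blocks, contig = ctg)
      switches <- switches + res$switch_errors
      perrors <- perrors + res$phase_errors
    }
    phasing <- list(blocks = dplyr::bind_rows(blocks),
                    states = dplyr::mutate(sc_meta, state = states),
                    switch_errors = switches, phase_errors = perrors)
  }

  structure(list(
    records = records, superclusters = sc_meta, pr_curve = pr_curve,
    distance_curve = distance_curve, phasing = phasing,
    truth = truth, query = query,
    config = list(standardize = standardize, partial_credit = partial_credit,
                  clustering = clustering, params = params,
                  supercluster_gap = supercluster_gap,
                  thresholds = thresholds)
  ), class = "phasebench_eval")
}

#' @export
print.phasebench_eval <- function(x, ...) {
  g <- glance(x)
  cat("phased small variant benchmarking evaluation\n")
  cat(sprintf("  superclusters: %d   switch errors: %d\n",
              nrow(x$superclusters), x$phasing$switch_errors))
  cat(sprintf("  SNP   best F1 %.4f (Q%.1f)\n", g$snp_f1, g$snp_f1_qscore))
  cat(sprintf("  INDEL best F1 %.4f (Q%.1f)\n", g$indel_f1, g$indel_f1_qscore))
  cat(sprintf("  ED %g  DE %g  ALN %g (at lowest threshold)\n",
              g$ed_query, g$de_query, g$aln_query))
  invisible(x)
}
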