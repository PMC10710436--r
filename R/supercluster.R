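#' Group truth and query clusters into superclusters
#'
#' Clusters from all four haplotypes (truth 0/1, query 0/1) of one contig
#' are merged transitively whenever their reach boundaries come within
#' `distance` bases of one another. Each resulting supercluster is an
#' independent evaluation unit: all alignment, phasing selection and credit
#' assignment happen inside its window. Superclusters with only query
#' clusters still produce false-positive candidates, and truth-only
#' superclusters produce false-negative candidates.
#'
#' @param truth_clusters,query_clusters Cluster tibbles from
#'   [cluster_callset()] (roles `"truth"` and `"query"`).
#' @param distance Grouping distance in bases (default 50).
#' @param contig_lengths Named integer vector (for window clamping).
#' @param pad Extra reference context added to each window edge, clamped so
#'   windows stay disjoint.
#' @return A tibble with one row per supercluster: `contig`, `sc_id`,
#'   `begin`, `end` and a `variants` list-column holding the member
#'   variants of all four haplotypes (with `role` column).
#' @export
build_superclusters <- function(truth_clusters, query_clusters,
                                distance = 50L, contig_lengths,
                                pad = 10L) {
  all_cl <- dplyr::bind_rows(truth_clusters, query_clusters)
  if (nrow(all_cl) == 0) {
    return(tibble::tibble(contig = character(), sc_id = integer(),
                          begin = integer(), end = integer(),
                          variants = list()))
  }
  pad <- min(pad, distance %/% 2L)
  out <- list()
  sc_id <- 0L
  for (ctg in sort(unique(all_cl$contig))) {
    cl <- dplyr::arrange(all_cl[all_cl$contig == ctg, ],
                         .data$left_reach, .data$begin)
    group_of <- integer(nrow(cl))
    cur <- 1L
    cur_rr <- cl$right_reach[1]
    group_of[1] <- cur
    for (k in seq_len(nrow(cl))[-1]) {
      if (cl$left_reach[k] - cur_rr < distance) {
        group_of[k] <- cur
        cur_rr <- max(cur_rr, cl$right_reach[k])
      } else {
        cur <- cur + 1L
        group_of[k] <- cur
        cur_rr <- cl$right_reach[k]
      }
    }
    for (g in seq_len(cur)) {
      idx <- which(group_of == g)
      sc_id <- sc_id + 1L
      begin <- max(0L, min(cl$left_reach[idx]) - pad)
      end <- min(contig_lengths[[ctg]], max(cl$right_reach[idx]) + pad)
      vars <- dplyr::bind_rows(lapply(idx, function(i) {
        dplyr::mutate(cl$variants[[i]], role = cl$role[i])
      }))
      out[[sc_id]] <- tibble::tibble(contig = ctg, sc_id = sc_id,
                                     begin = as.integer(begin),
                                     end = as.integer(end),
                                     variants = list(vars))
    }
  }
  dplyr::bind_rows(out)
}
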