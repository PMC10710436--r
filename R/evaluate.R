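unit_distance <- function(a, b) {
  as.numeric(utils::adist(a, b))
}

# prefix mapping: number of haplotype characters consumed once the reference
# prefix [begin, p) and all variants lying wholly before p are consumed.
# Insertions anchored exactly at p count as after the boundary.
hap_index_at <- function(p, begin, vars) {
  if (nrow(vars) == 0) return(p - begin)
  vend <- vars$start + nchar(vars$ref)
  before <- vend < p | (vend == p & nchar(vars$ref) > 0)
  (p - begin) + sum((nchar(vars$alt) - nchar(vars$ref))[before])
}

#' Align a truth haplotype to a variant-aware query graph
#'
#' The query haplotype is represented as the reference window plus optional
#' variant branches: each query variant is either taken wholly or skipped
#' wholly (no switching mid-variant), so false positive calls can be skipped
#' without penalty. The minimum unit-cost edit distance of the truth
#' haplotype over all branch choices is returned, together with the chosen
#' variant subset and the optimal alignment path. Branch subsets are
#' enumerated exhaustively up to `subset_cap` query variants (the chosen
#' subset is the largest among equal-distance optima); beyond the cap a
#' greedy leave-one-out search is used.
#'
#' @param truth_seq The truth haplotype sequence over the window.
#' @param window_ref Reference sequence of the window.
#' @param query_variants Variant tibble (one haplotype, within the window).
#' @param origin Contig offset of the window start.
#' @param subset_cap Exhaustive enumeration limit.
#' @return List with `distance`, `subset` (row indices of taken variants),
#'   `ops` (edit path of truth vs. the chosen query sequence) and
#'   `query_seq`.
#' @export
align_truth_to_query_graph <- function(truth_seq, window_ref, query_variants,
                                       origin = 0L, subset_cap = 8L) {
  k <- nrow(query_variants)
  best <- NULL
  consider <- function(idx) {
    q <- apply_variants(window_ref, query_variants[idx, , drop = FALSE],
                        origin = origin)
    d <- unit_distance(truth_seq, q)
    if (is.null(best) || d < best$distance) {
      best <<- list(distance = d, subset = idx, query_seq = q)
    }
  }
  if (k == 0) {
    consider(integer(0))
  } else if (k <= subset_cap) {
    # larger subsets first, so equal-distance ties keep more variants; a
    # zero-distance alignment cannot be improved, so stop there
    for (size in k:0) {
      if (!is.null(best) && best$distance == 0) break
      if (size == 0) consider(integer(0))
      else apply(utils::combn(k, size), 2, consider)
    }
  } else {
    idx <- seq_len(k)
    consider(idx)
    repeat {
      improved <- FALSE
      for (drop in best$subset) {
        cand <- setdiff(best$subset, drop)
        q <- apply_variants(window_ref, query_variants[cand, , drop = FALSE],
                            origin = origin)
        d <- unit_distance(truth_seq, q)
        if (d < best$distance) {
          best <- list(distance = d, subset = cand, query_seq = q)
          improved <- TRUE
          break
        }
      }
      if (!improved) break
    }
  }
  path <- cpp_align_affine(truth_seq, best$query_seq, 0, 1, 0, 1)
  list(distance = best$distance, subset = best$subset, ops = path$ops,
       query_seq = best$query_seq)
}

#' Select the local phasing of a supercluster
#'
#' @param d 2x2 matrix of truth-to-query graph alignment distances, rows
#'   truth haplotypes and columns query haplotypes.
#' @return `"X"` (truth1-query1 / truth2-query2), `"Y"` (crossed), or `"U"`
#'   when both pairings tie.
#' @export
select_phasing <- function(d) {
  stopifnot(is.matrix(d), all(dim(d) == c(2, 2)))
  straight <- d[1, 1] + d[2, 2]
  crossed <- d[1, 2] + d[2, 1]
  if (straight < crossed) "X" else if (crossed < straight) "Y" else "U"
}

#' Find sync points of a supercluster alignment
#'
#' Sync points are reference offsets, outside every truth and query variant
#' span, where the optimal truth-to-query alignment path passes through the
#' main diagonal; they partition the window into segments that can be
#' credited independently. The window boundaries are always sync points.
#'
#' @param ops Edit path of the truth haplotype against the chosen query
#'   sequence (from [align_truth_to_query_graph()]).
#' @param begin,end Window span (0-based half-open reference offsets).
#' @param truth_vars,query_vars Variant tibbles of this haplotype pairing
#'   (query restricted to the taken subset).
#' @return Sorted integer vector of sync offsets, beginning with `begin` and
#'   ending with `end`.
#' @export
find_sync_points <- function(ops, begin, end, truth_vars, query_vars) {
  oplist <- if (nzchar(ops)) strsplit(ops, "", fixed = TRUE)[[1]] else character(0)
  width <- length(oplist) + 2L
  nodes <- integer(length(oplist) + 1L)
  i <- 0L; j <- 0L
  nodes[1] <- 0L
  for (t in seq_along(oplist)) {
    op <- oplist[t]
    if (op %in% c("=", "X")) { i <- i + 1L; j <- j + 1L }
    else if (op == "D") i <- i + 1L
    else j <- j + 1L
    nodes[t + 1L] <- i * width + j
  }
  allv <- dplyr::bind_rows(truth_vars, query_vars)
  sync <- integer(0)
  for (p in begin:end) {
    if (nrow(allv) > 0 &&
        any(allv$start < p & p < allv$start + nchar(allv$ref))) next
    ip <- hap_index_at(p, begin, truth_vars)
    jp <- hap_index_at(p, begin, query_vars)
    if ((ip * width + jp) %in% nodes) sync <- c(sync, p)
  }
  sync
}

#' Credit category of one sync segment
#'
#' Compares the truth-vs-reference edit distance (`ed_ref`) of the segment
#' with the truth-vs-query edit distance (`ed_query`): true positive when
#' the query removes all distance, false positive/negative when the
#' distance is unchanged (or when a query call increases it, which is
#' clamped), and partial positive with credit `1 - ed_query / ed_ref`
#' otherwise.
#'
#' @param ed_ref,ed_query Segment edit distances.
#' @return List with `category` (`"TP"`, `"PP"`, `"FPFN"`) and `credit`.
#' @export
segment_credit <- function(ed_ref, ed_query) {
  if (ed_query == 0) {
    list(category = "TP", credit = 1)
  } else if (ed_ref == 0 || ed_query >= ed_ref) {
    list(category = "FPFN", credit = 0)
  } else {
    list(category = "PP", credit = 1 - ed_query / ed_ref)
  }
}

credit_record_tbl <- function() {
  tibble::tibble(contig = character(), start = integer(), ref = character(),
                 alt = character(), qual = numeric(), hap = integer(),
                 class = character(), role = character(),
                 category = character(), credit = numeric(),
                 sc_id = integer(), segment = integer())
}

# credit one truth-haplotype-to-query-haplotype pairing within a window
credit_pairing <- function(window_ref, begin, end, truth_vars, query_vars,
                           graph, sc_id) {
  taken <- query_vars[graph$subset, , drop = FALSE]
  skipped <- query_vars[setdiff(seq_len(nrow(query_vars)), graph$subset), ,
                        drop = FALSE]
  truth_seq <- apply_variants(window_ref, truth_vars, origin = begin)
  recs <- list()
  add <- function(vars, role, category, credit, segment) {
    if (nrow(vars) == 0) return()
    out <- vars[, c("contig", "start", "ref", "alt", "qual", "hap", "class")]
    out$role <- role
    out$category <- category
    out$credit <- credit
    out$sc_id <- sc_id
    out$segment <- segment
    recs[[length(recs) + 1L]] <<- out
  }
  add(skipped, "query", "FP", 0, NA_integer_)
  sync <- find_sync_points(graph$ops, begin, end, truth_vars, taken)
  for (s in seq_len(length(sync) - 1L)) {
    p1 <- sync[s]; p2 <- sync[s + 1L]
    tv <- truth_vars[truth_vars$start >= p1 & truth_vars$start < p2, ,
                     drop = FALSE]
    qv <- taken[taken$start >= p1 & taken$start < p2, , drop = FALSE]
    if (nrow(tv) == 0 && nrow(qv) == 0) next
    t_seg <- substr(truth_seq, hap_index_at(p1, begin, truth_vars) + 1L,
                    hap_index_at(p2, begin, truth_vars))
    q_seg <- substr(graph$query_seq, hap_index_at(p1, begin, taken) + 1L,
                    hap_index_at(p2, begin, taken))
    r_seg <- substr0(window_ref, p1 - begin, p2 - begin)
    ed_r <- unit_distance(t_seg, r_seg)
    ed_q <- unit_distance(t_seg, q_seg)
    cr <- segment_credit(ed_r, ed_q)
    qcat <- switch(cr$category, TP = "TP", PP = "PP", FPFN = "FP")
    tcat <- switch(cr$category, TP = "TP", PP = "PP", FPFN = "FN")
    add(qv, "query", qcat, cr$credit, s)
    add(tv, "truth", tcat, cr$credit, s)
  }
  if (length(recs) == 0) credit_record_tbl() else dplyr::bind_rows(recs)
}

#' Evaluate one supercluster
#'
#' Performs the four truth-to-query graph alignments, selects the local
#' phasing minimizing total edit distance, splits each chosen pairing at
#' sync points and assigns exact or partial credit to every variant. Also
#' accumulates the representation-independent distance metrics (ED, DE,
#' alignment distance) of the supercluster, computed from the full retained
#' query haplotype sequences.
#'
#' @param sc Single-row supercluster tibble from [build_superclusters()].
#' @param reference Named character vector of contig sequences.
#' @param min_qual Query variants below this QUAL are treated as absent.
#' @param subset_cap See [align_truth_to_query_graph()].
#' @param ref_dist Optional precomputed reference-side distance terms
#'   (`ed_ref`, `de_ref`, `aln_ref`); they depend only on the truth
#'   variants, so a quality-threshold sweep can reuse them.
#' @return List with `records` (credit records), `phase` and `dist` (named
#'   numeric vector of ED/DE/ALN terms).
#' @export
eval_supercluster <- function(sc, reference, min_qual = -Inf,
                              subset_cap = 8L, ref_dist = NULL) {
  vars <- sc$variants[[1]]
  begin <- sc$begin; end <- sc$end
  window_ref <- substr0(reference[[sc$contig]], begin, end)
  pick <- function(sel) {
    v <- vars[sel, , drop = FALSE]
    v[order(v$start, nchar(v$ref)), , drop = FALSE]
  }
  tv <- lapply(0:1, function(h) pick(vars$role == "truth" & vars$hap == h))
  qv <- lapply(0:1, function(h) pick(vars$role == "query" & vars$hap == h &
                                       vars$qual >= min_qual))
  truth_seq <- lapply(tv, function(v) apply_variants(window_ref, v, begin))
  graphs <- lapply(0:1, function(t) lapply(0:1, function(q) {
    align_truth_to_query_graph(truth_seq[[t + 1]], window_ref, qv[[q + 1]],
                               origin = begin, subset_cap = subset_cap)
  }))
  d <- matrix(c(graphs[[1]][[1]]$distance, graphs[[2]][[1]]$distance,
                graphs[[1]][[2]]$distance, graphs[[2]][[2]]$distance), 2, 2)
  phase <- select_phasing(d)
  qmap <- if (phase == "Y") c(2L, 1L) else c(1L, 2L)
  records <- list()
  dist <- c(ed_query = 0, de_query = 0, aln_query = 0,
            ed_ref = 0, de_ref = 0, aln_ref = 0)
  for (t in 1:2) {
    q <- qmap[t]
    records[[t]] <- credit_pairing(window_ref, begin, end, tv[[t]],
                                   qv[[q]], graphs[[t]][[q]], sc$sc_id)
    q_full <- apply_variants(window_ref, qv[[q]], origin = begin)
    edde_q <- if (identical(truth_seq[[t]], q_full)) c(ed = 0, de = 0) else
      ed_de(truth_seq[[t]], q_full)
    aln_q <- if (identical(truth_seq[[t]], q_full)) 0 else
      aln_distance(truth_seq[[t]], q_full)
    dist[1:3] <- dist[1:3] + c(edde_q[["ed"]], edde_q[["de"]], aln_q)
    if (is.null(ref_dist)) {
      edde_r <- ed_de(truth_seq[[t]], window_ref)
      dist[4:6] <- dist[4:6] + c(edde_r[["ed"]], edde_r[["de"]],
                                 aln_distance(truth_seq[[t]], window_ref))
    }
  }
  if (!is.null(ref_dist)) dist[4:6] <- ref_dist
  list(records = dplyr::bind_rows(records), phase = phase, dist = dist)
}
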