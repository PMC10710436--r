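new_cluster_tbl <- function() {
  tibble::tibble(contig = character(), hap = integer(), role = character(),
                 begin = integer(), end = integer(), penalty = numeric(),
                 left_reach = integer(), right_reach = integer(),
                 variants = list())
}

cluster_row <- function(vars, role, penalty = NA_real_,
                        left_reach = NA_integer_, right_reach = NA_integer_) {
  begin <- min(vars$start)
  end <- max(vars$start + nchar(vars$ref))
  tibble::tibble(contig = vars$contig[1], hap = vars$hap[1], role = role,
                 begin = as.integer(begin), end = as.integer(end),
                 penalty = penalty,
                 left_reach = if (is.na(left_reach)) as.integer(begin) else as.integer(left_reach),
                 right_reach = if (is.na(right_reach)) as.integer(end) else as.integer(right_reach),
                 variants = list(vars))
}

#' Gap-based clustering of variants
#'
#' The fast clustering heuristic: two adjacent variants on the same
#' haplotype share a cluster exactly when their reference spans are
#' separated by fewer than `gap_size` bases. Reach boundaries fall back to
#' the cluster spans.
#'
#' @param variants Variant tibble (single contig and haplotype, sorted).
#' @param gap_size Minimum separating distance, in reference bases.
#' @param role Role label recorded on the clusters.
#' @return A cluster tibble (one row per cluster, members in the `variants`
#'   list-column).
#' @export
gap_cluster <- function(variants, gap_size = 50L, role = "query") {
  if (nrow(variants) == 0) return(new_cluster_tbl())
  variants <- dplyr::arrange(variants, .data$start, nchar(.data$ref))
  ends <- as.numeric(variants$start + nchar(variants$ref))
  gap_before <- variants$start - dplyr::lag(cummax(ends), default = -Inf)
  grp <- cumsum(gap_before >= gap_size)
  dplyr::bind_rows(lapply(split(seq_len(nrow(variants)), grp), function(idx) {
    cluster_row(variants[idx, ], role = role)
  }))
}

#' Are two adjacent clusters dependent?
#'
#' Two clusters are independent when every optimal alignment path returns to
#' the main diagonal (the variant-free reference region) between them.
#' Operationally, the first cluster's rightward reach and the second
#' cluster's leftward reach are computed with [reach_extend()] under the
#' clusters' original-representation penalty budgets; the clusters are
#' dependent when the paths can meet off-diagonal, i.e. when the second
#' cluster's left reach is at or before the first cluster's right reach.
#'
#' @param a,b Single-row cluster tibbles, `a` entirely left of `b` on the
#'   same haplotype.
#' @param ref Contig sequence.
#' @param params [affine_params] defining penalties and budgets.
#' @param reach_limit Never test dependence across gaps of this many bases
#'   or more (reach windows are capped here).
#' @return `TRUE` if the clusters must be merged.
#' @export
clusters_dependent <- function(a, b, ref, params = preset_params("C"),
                               reach_limit = 64L) {
  if (b$begin < a$end) stop("clusters overlap; expected a left of b")
  if (b$begin - a$end >= reach_limit) return(FALSE)
  pa <- if (is.na(a$penalty)) original_penalty(a$variants[[1]], params) else a$penalty
  pb <- if (is.na(b$penalty)) original_penalty(b$variants[[1]], params) else b$penalty
  rr <- reach_extend(ref, a$begin, a$end, a$variants[[1]], params,
                     direction = "right", limit = b$begin, budget = pa)
  lr <- reach_extend(ref, b$begin, b$end, b$variants[[1]], params,
                     direction = "left", limit = a$end, budget = pb)
  lr <= rr
}

merge_cluster_rows <- function(a, b, params) {
  vars <- dplyr::arrange(dplyr::bind_rows(a$variants[[1]], b$variants[[1]]),
                         .data$start, nchar(.data$ref))
  cluster_row(vars, role = a$role, penalty = original_penalty(vars, params))
}

#' Iterative reach-based clustering
#'
#' Initializes one cluster per variant and repeatedly merges adjacent
#' dependent clusters (see [clusters_dependent()]) until no cluster grows or
#' `max_iters` passes have run. Budgets always use each cluster's
#' original-representation penalty. After convergence, the final reach
#' boundaries are recorded (capped at `reach_limit` bases beyond each span)
#' for use in superclustering.
#'
#' @param variants Variant tibble (single contig and haplotype).
#' @param ref Contig sequence.
#' @param params [affine_params]; defaults to the standard representation
#'   penalties (point C), the same set used for standardization.
#' @param max_iters Maximum merge passes; a warning is raised when reached.
#' @param reach_limit Cap on reach extension distance, in bases.
#' @param role Role label recorded on the clusters.
#' @return A cluster tibble sorted by `begin`.
#' @export
iterative_cluster <- function(variants, ref, params = preset_params("C"),
                              max_iters = 100L, reach_limit = 64L,
                              role = "query") {
  if (nrow(variants) == 0) return(new_cluster_tbl())
  variants <- dplyr::arrange(variants, .data$start, nchar(.data$ref))
  cl <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    cluster_row(v, role = role, penalty = original_penalty(v, params))
  })
  iter <- 0L
  repeat {
    iter <- iter + 1L
    merged_any <- FALSE
    out <- list(cl[[1]])
    for (k in seq_along(cl)[-1]) {
      a <- out[[length(out)]]
      b <- cl[[k]]
      if (clusters_dependent(a, b, ref, params, reach_limit)) {
        out[[length(out)]] <- merge_cluster_rows(a, b, params)
        merged_any <- TRUE
      } else {
        out[[length(out) + 1L]] <- b
      }
    }
    cl <- out
    if (!merged_any) break
    if (iter >= max_iters) {
      warning("clustering did not converge after ", max_iters, " iterations")
      break
    }
  }
  res <- dplyr::bind_rows(cl)
  n <- nchar(ref)
  for (k in seq_len(nrow(res))) {
    res$left_reach[k] <- as.integer(reach_extend(
      ref, res$begin[k], res$end[k], res$variants[[k]], params,
      direction = "left", limit = max(0L, res$begin[k] - reach_limit),
      budget = res$penalty[k]))
    res$right_reach[k] <- as.integer(reach_extend(
      ref, res$begin[k], res$end[k], res$variants[[k]], params,
      direction = "right", limit = min(n, res$end[k] + reach_limit),
      budget = res$penalty[k]))
  }
  res
}

#' Cluster every haplotype of a callset
#'
#' @param callset A [new_callset()] object.
#' @param reference Named character vector of contig sequences.
#' @param method `"wfa"` for reach-based [iterative_cluster()] (the
#'   default), `"gap"` for the [gap_cluster()] heuristic.
#' @param params [affine_params] for reach budgets (wfa method).
#' @param gap_size Gap threshold for the gap method.
#' @param ... Passed on to [iterative_cluster()].
#' @return A cluster tibble covering all contigs and haplotypes.
#' @export
cluster_callset <- function(callset, reference, method = c("wfa", "gap"),
                            params = preset_params("C"), gap_size = 50L,
                            ...) {
  method <- match.arg(method)
  v <- callset$variants
  if (nrow(v) == 0) return(new_cluster_tbl())
  groups <- split(seq_len(nrow(v)), list(v$contig, v$hap), drop = TRUE)
  dplyr::bind_rows(lapply(groups, function(idx) {
    vars <- v[idx, ]
    if (method == "gap") {
      gap_cluster(vars, gap_size = gap_size, role = callset$role)
    } else {
      iterative_cluster(vars, reference[[vars$contig[1]]], params = params,
                        role = callset$role, ...)
    }
  }))
}
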