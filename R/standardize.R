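# left-shift emitted INDELs against the full contig so the result does not
# depend on where the cluster window happened to start; `floor` bounds the
# shift (end of the previous cluster's last emitted variant)
contig_left_shift <- function(vars, ref, floor = 0L) {
  if (nrow(vars) == 0) return(vars)
  vars <- vars[order(vars$start, nchar(vars$ref)), , drop = FALSE]
  for (k in seq_len(nrow(vars))) {
    if (vars$class[k] %in% c("INS", "DEL")) {
      v <- left_shift_indel(ref, vars$start[k], vars$ref[k], vars$alt[k],
                            floor)
      vars$start[k] <- v$start
      vars$ref[k] <- v$ref
      vars$alt[k] <- v$alt
    }
    floor <- max(floor, vars$start[k] + nchar(vars$ref[k]))
  }
  vars[order(vars$start, nchar(vars$ref)), , drop = FALSE]
}

#' Standardize one cluster's variant representation
#'
#' Applies the cluster's variants to the reference window, realigns the
#' resulting sequence against the window under the standard penalties
#' (design point C by default) and re-derives the variants from the optimal
#' edit path. The emitted variants always reproduce the identical haplotype
#' sequence; INDELs are left-shifted against the full contig.
#'
#' @param cluster Single-row cluster tibble (see [iterative_cluster()]).
#' @param ref Contig sequence.
#' @param params [affine_params] of the standard representation.
#' @param floor Smallest reference offset left-shifting may reach (used to
#'   avoid colliding with the preceding cluster on the same haplotype).
#' @return A variant tibble in the standard representation; QUAL of every
#'   emitted record is the minimum QUAL of the cluster's members.
#' @export
standardize_cluster <- function(cluster, ref, params = preset_params("C"),
                                floor = 0L) {
  vars <- cluster$variants[[1]]
  if (nrow(vars) == 0) return(new_variant_tbl())
  begin <- cluster$begin; end <- cluster$end
  window <- substr0(ref, begin, end)
  alt <- apply_variants(window, vars, origin = begin)
  path <- align_affine(window, alt, params)
  out <- path_to_variants(path, window, alt, ref_origin = begin,
                          contig = vars$contig[1], hap = vars$hap[1])
  out$qual <- min(vars$qual)
  contig_left_shift(out, ref, floor = floor)
}

#' Standardize a whole callset
#'
#' Clusters each haplotype of the callset and re-expresses every cluster in
#' the standard representation (see [standardize_cluster()]). Each
#' haplotype is standardized independently; heterozygous variants are
#' re-emitted as separate per-haplotype records. Standardization preserves
#' every haplotype sequence exactly and is idempotent.
#'
#' @param callset A [new_callset()] object.
#' @param reference Named character vector of contig sequences.
#' @param params [affine_params] of the standard representation.
#' @param clusters Optional precomputed cluster tibble from
#'   [cluster_callset()]; computed with the wfa method if missing.
#' @param ... Passed to [cluster_callset()] when clusters are computed here.
#' @return A standardized [new_callset()] object. The cluster tibble of the
#'   standardized variants (same windows and reach boundaries, since reach
#'   budgets are defined by the original representation) is attached as
#'   attribute `"clusters"`.
#' @export
standardize_callset <- function(callset, reference,
                                params = preset_params("C"),
                                clusters = NULL, ...) {
  if (is.null(clusters)) {
    clusters <- cluster_callset(callset, reference, method = "wfa",
                                params = params, ...)
  }
  if (nrow(clusters) == 0) {
    out <- new_callset(new_variant_tbl(), role = callset$role,
                       contigs = callset$contigs)
    attr(out, "clusters") <- clusters
    return(out)
  }
  new_clusters <- clusters
  pieces <- vector("list", nrow(clusters))
  groups <- split(seq_len(nrow(clusters)),
                  list(clusters$contig, clusters$hap), drop = TRUE)
  for (idx in groups) {
    idx <- idx[order(clusters$begin[idx])]
    floor <- 0L
    for (k in idx) {
      std <- standardize_cluster(clusters[k, ],
                                 reference[[clusters$contig[k]]],
                                 params = params, floor = floor)
      pieces[[k]] <- std
      if (nrow(std) > 0) {
        floor <- max(std$start + nchar(std$ref))
        new_clusters$variants[[k]] <- std
        new_clusters$begin[k] <- min(new_clusters$begin[k], std$start[1])
        new_clusters$left_reach[k] <- min(new_clusters$left_reach[k],
                                          new_clusters$begin[k])
      }
    }
  }
  out <- new_callset(dplyr::bind_rows(pieces), role = callset$role,
                     contigs = callset$contigs)
  attr(out, "clusters") <- new_clusters
  out
}
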