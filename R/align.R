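# 0-based half-open substring of a contig sequence
substr0 <- function(seq, begin, end) {
  if (end <= begin) return("")
  substr(seq, begin + 1L, end)
}

str_rev <- function(s) {
  vapply(s, function(one) {
    paste(rev(strsplit(one, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Affine-gap global alignment
#'
#' Aligns two sequences globally under an affine-gap penalty scheme using the
#' three-state dynamic program, returning the minimum-penalty edit path. At
#' equal penalty the traceback prefers diagonal over deletion over insertion
#' and prefers extending an open gap over opening a new one, so output is
#' deterministic; gap placement is additionally left-normalized when paths
#' are converted to variants (see [path_to_variants()]).
#'
#' @param ref_seq,alt_seq DNA strings (reference-side and query-side).
#' @param params An [affine_params] object, preset name, or numeric (m,x,o,e).
#' @return An `alignment_path`: list with `penalty` and `ops`, a string over
#'   `=` (match), `X` (substitution), `D` (deletion, consumes reference) and
#'   `I` (insertion, consumes query).
#' @examples
#' align_affine("ACGT", "AGGT", preset_params("C"))
#' @export
align_affine <- function(ref_seq, alt_seq, params = preset_params("C")) {
  p <- as_affine_params(params)
  res <- cpp_align_affine(toupper(ref_seq), toupper(alt_seq), p$m, p$x, p$o, p$e)
  structure(list(penalty = res$penalty, ops = res$ops,
                 ref_seq = toupper(ref_seq), alt_seq = toupper(alt_seq),
                 params = p),
            class = "alignment_path")
}

#' @export
print.alignment_path <- function(x, ...) {
  cat(sprintf("alignment path: %s  penalty %g under %s\n",
              if (nzchar(x$ops)) x$ops else "<empty>",
              x$penalty, format(x$params)))
  invisible(x)
}

#' Run-length view of an alignment path
#'
#' @param path An `alignment_path` (or an ops string).
#' @return A tibble with columns `op` and `len`.
#' @export
path_runs <- function(path) {
  ops <- if (inherits(path, "alignment_path")) path$ops else path
  if (!nzchar(ops)) {
    return(tibble::tibble(op = character(), len = integer()))
  }
  r <- rle(strsplit(ops, "", fixed = TRUE)[[1]])
  tibble::tibble(op = r$values, len = r$lengths)
}

# recompute the affine penalty of an ops string; used to cross-check the DP
path_penalty <- function(ops, params) {
  p <- as_affine_params(params)
  runs <- path_runs(ops)
  if (nrow(runs) == 0) return(0)
  pen <- 0
  for (k in seq_len(nrow(runs))) {
    pen <- pen + switch(runs$op[k],
      "=" = p$m * runs$len[k],
      "X" = p$x * runs$len[k],
      "D" = p$o + runs$len[k] * p$e,
      "I" = p$o + runs$len[k] * p$e
    )
  }
  pen
}

variant_class <- function(ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  out <- rep("COMPLEX", length(nr))
  out[nr == 1 & na == 1] <- "SNP"
  out[nr == 0 & na > 0] <- "INS"
  out[na == 0 & nr > 0] <- "DEL"
  out
}

#' Construct a variant tibble
#'
#' The tidy variant record used throughout the package: 0-based half-open
#' reference coordinates, alleles already trimmed of shared prefix/suffix
#' bases (so insertions have an empty `ref` and deletions an empty `alt`),
#' and one row per haplotype carrying the variant. The `class` column is
#' derived from the allele lengths (SNP, INS, DEL or COMPLEX).
#'
#' @param contig,start,ref,alt,qual,hap Column values, recycled by
#'   [tibble::tibble()] rules.
#' @return A variant tibble.
#' @examples
#' new_variant_tbl("chr1", 10L, "A", "G", 30, 0L)
#' @export
new_variant_tbl <- function(contig = character(), start = integer(),
                            ref = character(), alt = character(),
                            qual = numeric(), hap = integer()) {
  tibble::tibble(
    contig = as.character(contig), start = as.integer(start),
    ref = as.character(ref), alt = as.character(alt),
    qual = as.numeric(qual), hap = as.integer(hap),
    class = variant_class(as.character(ref), as.character(alt))
  )
}

# shift one INDEL leftwards through identical flanking sequence; floor is the
# smallest admissible start (window origin or end of the previous variant)
left_shift_indel <- function(ref_seq, start, ref_allele, alt_allele, floor) {
  is_del <- nchar(alt_allele) == 0
  seq_len_ <- if (is_del) nchar(ref_allele) else nchar(alt_allele)
  allele <- if (is_del) ref_allele else alt_allele
  while (start > floor) {
    prev <- substr(ref_seq, start, start) # base at offset start-1 (0-based)
    last <- substr(allele, seq_len_, seq_len_)
    if (prev != last) break
    allele <- paste0(prev, substr(allele, 1, seq_len_ - 1))
    start <- start - 1L
  }
  if (is_del) {
    list(start = start, ref = allele, alt = "")
  } else {
    list(start = start, ref = "", alt = allele)
  }
}

#' Convert an alignment path to variants
#'
#' Walks the edit path of a global alignment and emits one SNP per
#' substituted base and one insertion/deletion per gap. INDELs are
#' left-shifted through identical flanking sequence (stopping at the window
#' origin or at the previous emitted variant) so equal-penalty placements
#' resolve to the conventional leftmost representation. Applying the emitted
#' variants to `ref_seq` always reproduces `alt_seq`.
#'
#' @param path An `alignment_path` from [align_affine()].
#' @param ref_seq,alt_seq The aligned sequences (defaults taken from `path`).
#' @param ref_origin Contig offset of the first base of `ref_seq` (0-based).
#' @param contig Contig name recorded on the emitted variants.
#' @param hap Haplotype index recorded on the emitted variants.
#' @return A variant tibble (columns `contig`, `start`, `ref`, `alt`,
#'   `qual`, `hap`, `class`), sorted and non-overlapping.
#' @export
path_to_variants <- function(path, ref_seq = path$ref_seq,
                             alt_seq = path$alt_seq, ref_origin = 0L,
                             contig = "ctg", hap = 0L) {
  runs <- path_runs(path)
  out <- list()
  i <- 0L # consumed ref bases
  j <- 0L # consumed alt bases
  floor <- 0L # leftmost admissible start for left-shifting (window-relative)
  for (k in seq_len(nrow(runs))) {
    op <- runs$op[k]; len <- runs$len[k]
    if (op == "=") {
      i <- i + len; j <- j + len
    } else if (op == "X") {
      for (t in seq_len(len)) {
        out[[length(out) + 1L]] <- list(start = i + t - 1L,
                                        ref = substr(ref_seq, i + t, i + t),
                                        alt = substr(alt_seq, j + t, j + t))
      }
      i <- i + len; j <- j + len
      floor <- i
    } else if (op == "D") {
      v <- left_shift_indel(ref_seq, i, substr(ref_seq, i + 1L, i + len), "",
                            floor)
      out[[length(out) + 1L]] <- v
      i <- i + len
      floor <- v$start + len
    } else { # I
      v <- left_shift_indel(ref_seq, i, "", substr(alt_seq, j + 1L, j + len),
                            floor)
      out[[length(out) + 1L]] <- v
      j <- j + len
      floor <- max(floor, v$start)
    }
  }
  if (length(out) == 0) return(new_variant_tbl())
  tbl <- new_variant_tbl(
    contig = contig,
    start = ref_origin + vapply(out, function(v) v$start, integer(1)),
    ref = vapply(out, function(v) v$ref, character(1)),
    alt = vapply(out, function(v) v$alt, character(1)),
    qual = NA_real_, hap = hap
  )
  dplyr::arrange(tbl, .data$start, nchar(.data$ref))
}

# penalty of a variant set in its given (original) representation: x per
# substituted base plus one affine gap for any length difference
original_penalty <- function(variants, params) {
  p <- as_affine_params(params)
  if (nrow(variants) == 0) return(0)
  nr <- nchar(variants$ref); na <- nchar(variants$alt)
  subs <- pmin(nr, na)
  gaps <- abs(nr - na)
  sum(p$x * subs + ifelse(gaps > 0, p$o + gaps * p$e, 0))
}

#' Budgeted off-diagonal reach of a variant cluster
#'
#' From one end of a cluster, finds the most distant reference offset that
#' any alignment path can touch while (a) never matching an inter-cluster
#' reference base to its own copy on the main diagonal and (b) keeping total
#' penalty no greater than the penalty of the cluster's original variant
#' representation. Two adjacent clusters whose reaches overlap can trade
#' penalty off-diagonal between them and must be evaluated jointly.
#'
#' @param ref Full contig sequence.
#' @param begin,end Cluster reference span, 0-based half-open.
#' @param variants Variant tibble of the cluster's members.
#' @param params [affine_params] used for the budget and extension costs.
#' @param direction `"right"` (extend from the cluster end rightwards) or
#'   `"left"`.
#' @param limit Reference offset bounding the extension (exclusive window
#'   edge; e.g. the neighboring cluster's boundary).
#' @param budget Penalty budget; defaults to the original-representation
#'   penalty of `variants`.
#' @return The extreme reachable reference offset (0-based).
#' @export
reach_extend <- function(ref, begin, end, variants, params,
                         direction = c("right", "left"), limit,
                         budget = NULL) {
  direction <- match.arg(direction)
  p <- as_affine_params(params)
  if (is.null(budget)) budget <- original_penalty(variants, p)
  if (nrow(variants) == 0) {
    return(if (direction == "right") end else begin)
  }
  alt <- apply_variants(substr0(ref, begin, end), variants, origin = begin)
  if (direction == "right") {
    limit <- min(limit, nchar(ref))
    a <- substr0(ref, begin, limit)
    b <- paste0(alt, substr0(ref, end, limit))
    reach <- cpp_reach_extend(a, b, end - begin, nchar(alt), budget,
                              p$m, p$x, p$o, p$e)
    begin + reach
  } else {
    limit <- max(limit, 0L)
    a <- str_rev(substr0(ref, limit, end))
    b <- str_rev(paste0(substr0(ref, limit, begin), alt))
    reach <- cpp_reach_extend(a, b, end - begin, nchar(alt), budget,
                              p$m, p$x, p$o, p$e)
    end - reach
  }
}
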