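#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file (optionally gzipped).
#' @return Named character vector of uppercase contig sequences.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Write contig sequences to FASTA (with a .fai index)
#'
#' @param seqs Named character vector of contig sequences.
#' @param path Output path; a samtools-style `.fai` is written alongside.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  fai <- character(0)
  offset <- 0
  for (nm in names(seqs)) {
    header <- paste0(">", nm)
    writeLines(header, con)
    offset <- offset + nchar(header) + 1L
    s <- seqs[[nm]]
    n <- nchar(s)
    starts <- seq(1L, max(n, 1L), by = width)
    lines <- substring(s, starts, pmin(starts + width - 1L, n))
    if (n == 0) lines <- character(0)
    writeLines(lines, con)
    fai <- c(fai, paste(nm, n, offset, width, width + 1L, sep = "\t"))
    offset <- offset + n + length(lines)
  }
  writeLines(fai, file.path(paste0(path, ".fai")))
  invisible(path)
}

#' Read a BED file of evaluation regions
#'
#' @param path BED file (0-based half-open intervals).
#' @return Tibble with columns `contig`, `begin`, `end`.
#' @export
read_bed <- function(path) {
  tbl <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("contig", "begin", "end"),
                           colClasses = c("character", "integer", "integer"))
  tibble::as_tibble(tbl)
}

# shared prefix/suffix trimming of a REF/ALT allele pair; start is 0-based
trim_alleles <- function(start, ref, alt) {
  # suffix first, then prefix (prefix shift moves the start coordinate)
  while (nchar(ref) > 0 && nchar(alt) > 0 &&
         substr(ref, nchar(ref), nchar(ref)) ==
         substr(alt, nchar(alt), nchar(alt)) &&
         !(nchar(ref) == 1 && nchar(alt) == 1)) {
    ref <- substr(ref, 1, nchar(ref) - 1)
    alt <- substr(alt, 1, nchar(alt) - 1)
  }
  while (nchar(ref) > 0 && nchar(alt) > 0 &&
         substr(ref, 1, 1) == substr(alt, 1, 1) &&
         !(nchar(ref) == 1 && nchar(alt) == 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    start <- start + 1L
  }
  list(start = as.integer(start), ref = ref, alt = alt)
}

#' Construct a phased callset
#'
#' A callset holds one ordered variant list per contig and haplotype, in a
#' single tidy tibble (column `hap` is 0 or 1). Variants on a haplotype must
#' be sorted and have disjoint reference spans. Homozygous records appear
#' once per haplotype, which is what makes a homozygous false positive count
#' twice downstream.
#'
#' @param variants Variant tibble (`contig`, `start`, `ref`, `alt`, `qual`,
#'   `hap`, `class`).
#' @param role `"truth"` or `"query"`.
#' @param contigs Named integer vector of contig lengths.
#' @return An object of class `callset`.
#' @export
new_callset <- function(variants, role = c("query", "truth"), contigs) {
  role <- match.arg(role)
  variants <- dplyr::arrange(variants, .data$contig, .data$hap, .data$start,
                             nchar(.data$ref))
  cs <- structure(list(variants = variants, role = role,
                       contigs = contigs), class = "callset")
  validate_callset(cs)
  cs
}

#' @export
print.callset <- function(x, ...) {
  cat(sprintf("phased %s callset: %d variants on %d contig(s)\n",
              x$role, nrow(x$variants), length(x$contigs)))
  invisible(x)
}

validate_callset <- function(cs) {
  v <- cs$variants
  if (nrow(v) == 0) return(invisible(cs))
  if (any(v$ref == v$alt)) stop("variant with REF == ALT after trimming")
  bad <- !v$contig %in% names(cs$contigs)
  if (any(bad)) stop("variant on unknown contig: ", v$contig[which(bad)[1]])
  ends <- v$start + nchar(v$ref)
  if (any(ends > cs$contigs[v$contig])) {
    stop("variant span exceeds contig length")
  }
  grp <- split(seq_len(nrow(v)), list(v$contig, v$hap), drop = TRUE)
  for (idx in grp) {
    if (length(idx) < 2) next
    s <- v$start[idx]; e <- ends[idx]
    ord <- order(s, e)
    if (any(s[ord][-1] < e[ord][-length(ord)])) {
      k <- which(s[ord][-1] < e[ord][-length(ord)])[1]
      stop(sprintf("overlapping variants on %s haplotype %d near offset %d",
                   v$contig[idx[1]], v$hap[idx[1]], s[ord][k + 1]))
    }
  }
  invisible(cs)
}

#' Apply variants to a reference sequence
#'
#' Splices alternate alleles over their reference spans, producing the
#' haplotype sequence the variants describe. The result has length
#' `nchar(ref_seq) - sum(nchar(ref)) + sum(nchar(alt))`.
#'
#' @param ref_seq Reference (window) sequence.
#' @param variants Variant tibble, sorted and non-overlapping, with `start`
#'   given as contig offsets.
#' @param origin Contig offset of the first base of `ref_seq` (0-based).
#' @return The haplotype sequence.
#' @examples
#' apply_variants("ACGT", new_variant_tbl("c", 1L, "C", "G", 30, 0L))
#' @export
apply_variants <- function(ref_seq, variants, origin = 0L) {
  if (nrow(variants) == 0) return(ref_seq)
  ord <- order(variants$start, nchar(variants$ref))
  if (is.unsorted(ord)) variants <- variants[ord, , drop = FALSE]
  s <- variants$start - origin
  e <- s + nchar(variants$ref)
  if (any(s < 0) || any(e > nchar(ref_seq))) {
    stop("variant span out of bounds of the reference window")
  }
  if (any(s[-1] < e[-length(e)])) stop("overlapping variants")
  n <- nrow(variants)
  pieces <- character(2 * n + 1)
  pieces[c(TRUE, FALSE)] <- substring(ref_seq, c(0L, e) + 1L,
                                      c(s, nchar(ref_seq)))
  pieces[c(FALSE, TRUE)] <- variants$alt
  paste(pieces, collapse = "")
}

#' Read a locally phased VCF into a callset
#'
#' Splits multi-allelic records into biallelic variants, trims shared
#' prefix/suffix bases, converts to 0-based coordinates and builds one
#' variant list per haplotype from the phased genotypes. Only the first
#' sample is read. Heterozygous genotypes must be phased (`|` separator);
#' unphased homozygous genotypes are unambiguous and accepted.
#'
#' @param path VCF file (plain or gzipped).
#' @param reference Named character vector of contig sequences (used for
#'   contig lengths), or a FASTA path.
#' @param regions Optional tibble from [read_bed()]; records whose trimmed
#'   start lies outside all regions are dropped.
#' @param role `"query"` or `"truth"`.
#' @param skip_invalid If `TRUE`, haploid/missing-genotype records are
#'   skipped with a warning instead of raising an error.
#' @param pass_only If `TRUE`, only records with FILTER `PASS` or `.` are
#'   kept; by default FILTER is ignored.
#' @return A [new_callset()] object.
#' @export
read_phased_vcf <- function(path, reference, regions = NULL,
                            role = c("query", "truth"),
                            skip_invalid = FALSE, pass_only = FALSE) {
  role <- match.arg(role)
  if (is.character(reference) && length(reference) == 1 &&
      file.exists(reference)) {
    reference <- read_fasta(reference)
  }
  contigs <- stats::setNames(as.integer(nchar(reference)), names(reference))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (!is.null(fix) && is.null(dim(fix))) {
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  n <- nrow(fix)
  rows <- list()
  if (!is.null(n) && n > 0) {
    gt <- vcf@gt
    if (is.null(dim(gt))) gt <- matrix(gt, nrow = n)
    sample_col <- which(colnames(gt) != "FORMAT")[1] # first sample only
    gt_raw <- if (!is.na(sample_col)) gt[, sample_col] else
      rep(NA_character_, n)
    gt <- sub(":.*$", "", gt_raw)
    for (r in seq_len(n)) {
      chrom <- fix[r, "CHROM"]; pos1 <- as.integer(fix[r, "POS"])
      refa <- toupper(fix[r, "REF"]); alts <- toupper(fix[r, "ALT"])
      qual <- suppressWarnings(as.numeric(fix[r, "QUAL"]))
      if (is.na(qual)) qual <- 0 # missing QUAL sinks to the lowest threshold
      filt <- fix[r, "FILTER"]
      if (pass_only && !is.na(filt) && !filt %in% c("PASS", ".")) next
      g <- gt[r]
      label <- sprintf("%s:%d", chrom, pos1)
      if (is.na(g) || g %in% c(".", "./.", ".|.")) {
        if (skip_invalid) { warning("skipping ungenotyped record ", label); next }
        stop("missing genotype at ", label)
      }
      phased <- grepl("|", g, fixed = TRUE)
      al <- strsplit(g, "[|/]")[[1]]
      if (length(al) != 2 || any(al == ".")) {
        if (skip_invalid) { warning("skipping non-diploid record ", label); next }
        stop("non-diploid genotype '", g, "' at ", label)
      }
      al <- as.integer(al)
      if (!phased && al[1] != al[2]) {
        stop("unphased heterozygous genotype '", g, "' at ", label,
             "; locally phased input is required")
      }
      alt_list <- strsplit(alts, ",", fixed = TRUE)[[1]]
      for (h in 0:1) {
        k <- al[h + 1]
        if (is.na(k) || k == 0) next
        if (k > length(alt_list)) stop("allele index out of range at ", label)
        tr <- trim_alleles(pos1 - 1L, refa, alt_list[k])
        if (tr$ref == tr$alt) {
          if (skip_invalid) { warning("skipping REF==ALT record ", label); next }
          stop("ALT equals REF at ", label)
        }
        rows[[length(rows) + 1L]] <- list(contig = chrom, start = tr$start,
                                          ref = tr$ref, alt = tr$alt,
                                          qual = qual, hap = h)
      }
    }
  }
  if (length(rows) == 0) {
    variants <- new_variant_tbl()
  } else {
    variants <- new_variant_tbl(
      contig = vapply(rows, `[[`, character(1), "contig"),
      start = vapply(rows, `[[`, integer(1), "start"),
      ref = vapply(rows, `[[`, character(1), "ref"),
      alt = vapply(rows, `[[`, character(1), "alt"),
      qual = vapply(rows, `[[`, numeric(1), "qual"),
      hap = vapply(rows, `[[`, integer(1), "hap")
    )
  }
  if (!is.null(regions) && nrow(variants) > 0) {
    keep <- vapply(seq_len(nrow(variants)), function(k) {
      any(regions$contig == variants$contig[k] &
            regions$begin <= variants$start[k] &
            variants$start[k] < regions$end)
    }, logical(1))
    variants <- variants[keep, ]
  }
  new_callset(variants, role = role, contigs = contigs)
}

#' Write a callset as a phased VCF
#'
#' Emits one record per heterozygous variant (`1|0` or `0|1`) and one `1|1`
#' record for variants present identically on both haplotypes. Coordinates
#' are converted back to 1-based positions; insertions and deletions receive
#' the conventional anchor base from the reference.
#'
#' @param callset A [new_callset()] object.
#' @param path Output VCF path.
#' @param reference Named character vector of contig sequences (for anchor
#'   bases and header contig lengths).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(callset, path, reference) {
  v <- callset$variants
  recs <- list()
  if (nrow(v) > 0) {
    keyed <- dplyr::summarise(
      dplyr::group_by(v, .data$contig, .data$start, .data$ref, .data$alt),
      haps = list(sort(.data$hap)), qual = min(.data$qual), .groups = "drop")
    for (k in seq_len(nrow(keyed))) {
      contig <- keyed$contig[k]; start <- keyed$start[k]
      refa <- keyed$ref[k]; alta <- keyed$alt[k]
      seqc <- reference[[contig]]
      if (nchar(refa) == 0 || nchar(alta) == 0) {
        if (start > 0) {
          anchor <- substr0(seqc, start - 1L, start)
          pos1 <- start # anchor base position, 1-based == start (0-based) - 1 + 1
          refa <- paste0(anchor, refa); alta <- paste0(anchor, alta)
        } else {
          after <- start + nchar(refa)
          anchor <- substr0(seqc, after, after + 1L)
          pos1 <- 1L
          refa <- paste0(refa, anchor); alta <- paste0(alta, anchor)
        }
      } else {
        pos1 <- start + 1L
      }
      haps <- keyed$haps[[k]]
      gt <- if (length(haps) == 2) "1|1" else if (haps == 0L) "1|0" else "0|1"
      recs[[length(recs) + 1L]] <- list(contig = contig, pos = pos1,
                                        ref = refa, alt = alta,
                                        qual = keyed$qual[k], gt = gt)
    }
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(callset$contigs),
            callset$contigs),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "FORMAT",
          toupper(callset$role), sep = "\t")
  )
  body <- character(0)
  if (length(recs) > 0) {
    ord <- order(vapply(recs, `[[`, character(1), "contig"),
                 vapply(recs, `[[`, numeric(1), "pos"))
    body <- vapply(recs[ord], function(r) {
      paste(r$contig, r$pos, ".", r$ref, r$alt,
            format(r$qual, trim = TRUE), ".", "GT", r$gt, sep = "\t")
    }, character(1))
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
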