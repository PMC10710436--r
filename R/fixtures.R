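rand_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic reference contig
#'
#' Interleaves random sequence with low-complexity tracts (homopolymers and
#' short tandem repeats) so that roughly `repeat_fraction` of the bases lie
#' in annotated tracts. INDELs are far more common in such low-complexity
#' sequence, so the tracts are where equivalent variant representations
#' proliferate. Deterministic under `seed`.
#'
#' @param length Contig length in bases.
#' @param repeat_fraction Target fraction of tract bases (0 disables tracts).
#' @param seed Optional RNG seed.
#' @param contig Contig name.
#' @return List with `seqs` (named character vector), `tracts` (tibble
#'   `contig`, `begin`, `end`, `type`) and `lengths`.
#' @export
make_reference <- function(length = 10000L, repeat_fraction = 0.3,
                           seed = NULL, contig = "ctg1") {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length > 0, repeat_fraction >= 0, repeat_fraction < 1)
  if (repeat_fraction == 0) {
    seqs <- stats::setNames(rand_dna(length), contig)
    return(list(seqs = seqs,
                tracts = tibble::tibble(contig = character(),
                                        begin = integer(), end = integer(),
                                        type = character()),
                lengths = stats::setNames(as.integer(length), contig)))
  }
  mean_tract <- 19 # homopolymers ~8-20 bp, STRs ~ (2-6 bp unit) x (4-8)
  mean_unique <- mean_tract * (1 - repeat_fraction) / repeat_fraction
  lo <- max(5L, round(0.7 * mean_unique)); hi <- round(1.3 * mean_unique)
  pieces <- character(0)
  tracts <- list()
  pos <- 0L
  while (pos < length) {
    run <- sample(lo:hi, 1)
    run <- min(run, length - pos)
    pieces <- c(pieces, rand_dna(run))
    pos <- pos + run
    if (pos >= length) break
    if (stats::runif(1) < 0.5) {
      type <- "homopolymer"
      tract <- strrep(sample(c("A", "C", "G", "T"), 1), sample(8:20, 1))
    } else {
      type <- "STR"
      unit <- rand_dna(sample(2:6, 1))
      tract <- strrep(unit, sample(4:8, 1))
    }
    tract <- substr(tract, 1, length - pos)
    tracts[[length(tracts) + 1L]] <-
      tibble::tibble(contig = contig, begin = pos,
                     end = pos + nchar(tract), type = type)
    pieces <- c(pieces, tract)
    pos <- pos + nchar(tract)
  }
  list(seqs = stats::setNames(paste(pieces, collapse = ""), contig),
       tracts = dplyr::bind_rows(tracts),
       lengths = stats::setNames(as.integer(length), contig))
}

#' Plant diploid truth variants on a synthetic reference
#'
#' Plants SNPs, INDELs (1-`max_indel` bp) and complex variants with a
#' heterozygous/homozygous mix, preferentially placing INDELs inside
#' annotated low-complexity tracts (where insertions duplicate local
#' sequence, creating genuinely ambiguous representations). Variant spans
#' never overlap, so the truth callset is valid on both haplotypes, and the
#' emitted haplotype sequences are exactly `apply_variants()` of the truth.
#'
#' @param ref A [make_reference()] object.
#' @param snp_rate,indel_rate,complex_rate Expected planted variants per
#'   base.
#' @param hom_fraction Probability a planted variant is homozygous.
#' @param tract_bias Probability an INDEL is placed inside a tract.
#' @param max_indel Maximum INDEL length.
#' @param seed Optional RNG seed.
#' @return List with `callset` (truth), `haplotypes` (per contig, character
#'   vector of the two haplotype sequences), `ref`, and `ledger` (tibble of
#'   planted variants).
#' @export
plant_variants <- function(ref, snp_rate = 0.002, indel_rate = 5e-4,
                           complex_rate = 1e-4, hom_fraction = 1 / 3,
                           tract_bias = 0.7, max_indel = 12L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  contig <- names(ref$seqs)[1]
  seqc <- ref$seqs[[1]]
  L <- nchar(seqc)
  occupied <- matrix(numeric(0), ncol = 2) # begin, end with 1-base buffer
  free_at <- function(b, e) {
    nrow(occupied) == 0 || all(e + 1 <= occupied[, 1] | b - 1 >= occupied[, 2])
  }
  take <- function(b, e) occupied <<- rbind(occupied, c(b, e))
  draw_pos <- function(span, in_tract) {
    for (try in 1:200) {
      if (in_tract && nrow(ref$tracts) > 0) {
        tr <- ref$tracts[sample.int(nrow(ref$tracts), 1,
                                    prob = ref$tracts$end - ref$tracts$begin), ]
        if (tr$end - tr$begin <= span) next
        p <- sample(tr$begin:(tr$end - span - 1L), 1)
      } else {
        p <- sample.int(L - span - 20L, 1) + 10L
      }
      if (free_at(p, p + span)) return(p)
    }
    NA_integer_
  }
  rows <- list()
  ledger <- list()
  plant <- function(type) {
    if (type == "SNP") {
      p <- draw_pos(1L, stats::runif(1) < 0.15)
      if (is.na(p)) return()
      rb <- substr0(seqc, p, p + 1L)
      ab <- sample(setdiff(c("A", "C", "G", "T"), rb), 1)
      refa <- rb; alta <- ab; span <- 1L
    } else if (type == "INDEL") {
      len <- sample.int(max_indel, 1, prob = 0.55^seq_len(max_indel))
      in_tract <- stats::runif(1) < tract_bias
      if (stats::runif(1) < 0.5) { # deletion
        p <- draw_pos(len, in_tract)
        if (is.na(p)) return()
        refa <- substr0(seqc, p, p + len); alta <- ""; span <- len
      } else { # insertion; duplicate local sequence inside tracts
        p <- draw_pos(1L, in_tract)
        if (is.na(p)) return()
        refa <- ""
        alta <- if (in_tract && nrow(ref$tracts) > 0 && p + len <= L) {
          substr0(seqc, p, p + len)
        } else {
          rand_dna(len)
        }
        span <- 0L
      }
    } else { # complex: substituted block with a length change
      nr <- sample(2:4, 1); na <- sample(2:5, 1)
      p <- draw_pos(nr, FALSE)
      if (is.na(p)) return()
      refa <- substr0(seqc, p, p + nr)
      repeat {
        alta <- rand_dna(na)
        ok <- substr(alta, 1, 1) != substr(refa, 1, 1) &&
          substr(alta, na, na) != substr(refa, nr, nr) && alta != refa
        if (ok) break
      }
      span <- nr
    }
    take(p, p + span)
    hom <- stats::runif(1) < hom_fraction
    haps <- if (hom) 0:1 else sample(0:1, 1)
    qual <- sample(40:60, 1)
    for (h in haps) {
      rows[[length(rows) + 1L]] <<- list(contig = contig, start = p,
                                         ref = refa, alt = alta,
                                         qual = qual, hap = h)
    }
    ledger[[length(ledger) + 1L]] <<- tibble::tibble(
      type = type, contig = contig, start = p, ref = refa, alt = alta,
      zygosity = if (hom) "hom" else "het", hap = if (hom) NA_integer_ else haps)
  }
  n_snp <- round(snp_rate * L); n_indel <- round(indel_rate * L)
  n_complex <- round(complex_rate * L)
  for (i in seq_len(n_complex)) plant("COMPLEX")
  for (i in seq_len(n_indel)) plant("INDEL")
  for (i in seq_len(n_snp)) plant("SNP")
  variants <- if (length(rows) == 0) new_variant_tbl() else new_variant_tbl(
    contig = vapply(rows, `[[`, character(1), "contig"),
    start = vapply(rows, `[[`, integer(1), "start"),
    ref = vapply(rows, `[[`, character(1), "ref"),
    alt = vapply(rows, `[[`, character(1), "alt"),
    qual = vapply(rows, `[[`, numeric(1), "qual"),
    hap = vapply(rows, `[[`, integer(1), "hap"))
  cs <- new_callset(variants, role = "truth", contigs = ref$lengths)
  haps <- vapply(0:1, function(h) {
    apply_variants(seqc, variants[variants$hap == h, , drop = FALSE])
  }, character(1))
  list(callset = cs, haplotypes = stats::setNames(list(haps), contig),
       ref = ref,
       ledger = if (length(ledger)) dplyr::bind_rows(ledger) else tibble::tibble())
}

#' Re-express a callset at a design point
#'
#' Realigns every cluster of the callset under the given preset's penalties
#' and emits that representation. All presets yield sequence-identical
#' haplotypes; only the reported records differ (e.g. at point A every SNP
#' becomes a 1-bp deletion plus a 1-bp insertion, and at the unit-cost
#' `"fragmented"` point complex variants shatter into many small records).
#'
#' @param callset A [new_callset()] object.
#' @param reference Named character vector of contig sequences.
#' @param preset Preset name (see [preset_params()]) or [affine_params].
#' @param role Role of the returned callset (defaults to the input role).
#' @return A re-expressed [new_callset()].
#' @export
render_representation <- function(callset, reference, preset = "C",
                                  role = callset$role) {
  params <- as_affine_params(preset)
  std <- standardize_callset(callset, reference, params = params)
  new_callset(std$variants, role = role, contigs = callset$contigs)
}

#' Plant evaluation errors into a query callset
#'
#' Derives a corrupted query callset from a (typically truth-derived)
#' callset, recording every planted error in a ledger for closed-loop
#' assertions: false positives (novel isolated SNPs), false negatives
#' (dropped sites), INDEL length errors (one base shaved off an INDEL of
#' length `n`, which evaluation should score as a partial positive with
#' credit `1 - 1/n`), flip errors (single heterozygous sites moved to the
#' other haplotype) and switch errors (haplotype assignment of every
#' variant downstream of a locus swapped).
#'
#' @param callset Input callset (haplotype-resolved).
#' @param reference Named character vector of contig sequences.
#' @param n_fp,n_fn,n_indel_len,n_flip Number of errors of each type.
#' @param switch_loci Reference offsets at which to plant switches.
#' @param fp_margin Minimum distance of planted FPs from any other variant.
#' @param error_margin When positive, FN/PP/flip errors are only planted at
#'   sites at least this many bases away from every other variant site, so
#'   each planted error is the sole occupant of its evaluation unit and can
#'   be recovered exactly.
#' @param seed Optional RNG seed.
#' @return List with `callset` (role `"query"`) and `ledger` (tibble:
#'   `type`, `contig`, `start`, `ref`, `alt`, `expected_credit`).
#' @export
corrupt <- function(callset, reference, n_fp = 0L, n_fn = 0L,
                    n_indel_len = 0L, n_flip = 0L,
                    switch_loci = integer(0), fp_margin = 100L,
                    error_margin = 0L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- callset$variants
  orig <- v # isolation is judged against every original site (truth keeps
            # dropped sites, so they still interact during evaluation)
  isolated_site <- function(v) {
    if (error_margin <= 0) return(rep(TRUE, nrow(v)))
    vapply(seq_len(nrow(v)), function(i) {
      same <- orig$contig == v$contig[i] & orig$start != v$start[i]
      all(abs(orig$start[same] - v$start[i]) >= error_margin)
    }, logical(1))
  }
  ledger <- list()
  note <- function(type, contig, start, ref = "", alt = "",
                   expected_credit = NA_real_) {
    ledger[[length(ledger) + 1L]] <<- tibble::tibble(
      type = type, contig = contig, start = start, ref = ref, alt = alt,
      expected_credit = expected_credit)
  }
  site_key <- function(v) paste(v$contig, v$start, v$ref, v$alt)
  # false negatives: drop whole sites
  if (n_fn > 0 && nrow(v) > 0) {
    sites <- unique(site_key(v)[isolated_site(v)])
    drop <- sample(sites, min(n_fn, length(sites)))
    for (s in drop) {
      row <- v[site_key(v) == s, ][1, ]
      note("FN", row$contig, row$start, row$ref, row$alt, 0)
    }
    v <- v[!site_key(v) %in% drop, ]
  }
  # INDEL length errors
  if (n_indel_len > 0 && nrow(v) > 0) {
    cand <- unique(site_key(v)[v$class %in% c("INS", "DEL") &
                                 pmax(nchar(v$ref), nchar(v$alt)) >= 2 &
                                 isolated_site(v)])
    pick <- sample(cand, min(n_indel_len, length(cand)))
    for (s in pick) {
      idx <- which(site_key(v) == s)
      n <- max(nchar(v$ref[idx[1]]), nchar(v$alt[idx[1]]))
      note("PP", v$contig[idx[1]], v$start[idx[1]], v$ref[idx[1]],
           v$alt[idx[1]], 1 - 1 / n)
      for (i in idx) {
        if (v$class[i] == "INS") {
          v$alt[i] <- substr(v$alt[i], 1, nchar(v$alt[i]) - 1L)
        } else {
          v$ref[i] <- substr(v$ref[i], 1, nchar(v$ref[i]) - 1L)
        }
        v$class[i] <- variant_class(v$ref[i], v$alt[i])
      }
    }
  }
  # false positives: isolated novel SNPs
  if (n_fp > 0) {
    for (ctr in seq_len(n_fp)) {
      contig <- names(callset$contigs)[1]
      seqc <- reference[[contig]]
      L <- callset$contigs[[contig]]
      for (try in 1:500) {
        p <- sample.int(L - 20L, 1) + 10L
        occupied <- rbind(orig[, c("contig", "start")],
                          v[, c("contig", "start")])
        clear <- nrow(occupied) == 0 ||
          all(occupied$contig != contig | abs(occupied$start - p) >= fp_margin)
        if (clear) break
        p <- NA_integer_
      }
      if (is.na(p)) next
      rb <- substr0(seqc, p, p + 1L)
      ab <- sample(setdiff(c("A", "C", "G", "T"), rb), 1)
      newv <- new_variant_tbl(contig, p, rb, ab,
                              qual = sample(10:35, 1), hap = sample(0:1, 1))
      v <- dplyr::bind_rows(v, newv)
      note("FP", contig, p, rb, ab, 0)
    }
  }
  # flip errors: move a heterozygous site to the other haplotype
  if (n_flip > 0 && nrow(v) > 0) {
    tab <- table(site_key(v))
    het <- intersect(names(tab)[tab == 1],
                     unique(site_key(v)[isolated_site(v)]))
    pick <- sample(het, min(n_flip, length(het)))
    for (s in pick) {
      i <- which(site_key(v) == s)
      v$hap[i] <- 1L - v$hap[i]
      note("flip", v$contig[i], v$start[i], v$ref[i], v$alt[i])
    }
  }
  # switch errors: swap haplotype assignment of everything downstream
  for (locus in switch_loci) {
    sel <- v$start >= locus
    v$hap[sel] <- 1L - v$hap[sel]
    note("switch", names(callset$contigs)[1], as.integer(locus))
  }
  list(callset = new_callset(v, role = "query", contigs = callset$contigs),
       ledger = if (length(ledger)) dplyr::bind_rows(ledger) else
         tibble::tibble())
}

#' Enumerate all local phasings of a set of variants
#'
#' Every heterozygous variant can sit on either haplotype, so `h` unphased
#' heterozygous sites admit `2^h` local phasings, each producing a
#' different pair of haplotype sequences. Benchmarking tools that discard
#' phasing implicitly search this whole space, which is what biases them
#' toward fragmented representations.
#'
#' @param variants Variant tibble; heterozygous sites are those whose
#'   (contig, start, ref, alt) appear on exactly one haplotype.
#' @param max_het Safety cap on the number of heterozygous sites.
#' @return List of variant tibbles, one per phasing assignment (length
#'   `2^h`).
#' @export
enumerate_local_phasings <- function(variants, max_het = 16L) {
  key <- paste(variants$contig, variants$start, variants$ref, variants$alt)
  tab <- table(key)
  het_keys <- names(tab)[tab == 1]
  h <- length(het_keys)
  if (h > max_het) stop("too many heterozygous sites to enumerate")
  if (h == 0) return(list(variants))
  grid <- expand.grid(rep(list(0:1), h))
  lapply(seq_len(nrow(grid)), function(r) {
    out <- variants
    for (k in seq_len(h)) {
      out$hap[key == het_keys[k]] <- as.integer(grid[r, k])
    }
    out
  })
}
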