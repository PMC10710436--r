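# shared helpers: tiny sequence generators and independent oracles

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  if (n == 0) return("")
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# exhaustive minimum over all global phase-state assignments
phase_cost_brute <- function(categories, switch_cost = 1,
                             phase_error_cost = 1) {
  n <- length(categories)
  best <- Inf
  for (mask in 0:(2^n - 1)) {
    states <- ifelse(bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L,
                     "Y", "X")
    cost <- sum(categories %in% c("X", "Y") & categories != states) *
      phase_error_cost
    if (n > 1) cost <- cost + sum(states[-1] != states[-n]) * switch_cost
    if (cost < best) best <- cost
  }
  best
}

# a small diploid fixture: reference, truth callset, haplotypes
small_fixture <- function(seed, length = 3000L, repeat_fraction = 0.3, ...) {
  ref <- make_reference(length, repeat_fraction, seed = seed)
  tr <- plant_variants(ref, seed = seed + 1000L, ...)
  list(ref = ref, truth = tr$callset, haplotypes = tr$haplotypes,
       ledger = tr$ledger)
}

# pick a reference offset for planting a switch error: between two groups of
# phase-informative sites (groups = sites within group_gap of each other,
# i.e. prospective superclusters), with at least two groups on each side so
# one switch is strictly cheaper than any phasing-error explanation
pick_switch_locus <- function(observable, group_gap = 110) {
  if (length(observable) < 4) return(NA_integer_)
  g <- cumsum(c(1, diff(observable) > group_gap))
  n <- max(g)
  if (n < 4) return(NA_integer_)
  firsts <- vapply(split(observable, g), min, numeric(1))
  lasts <- vapply(split(observable, g), max, numeric(1))
  k <- 2:(n - 2)
  kbest <- k[which.max(firsts[k + 1] - lasts[k])]
  as.integer((lasts[kbest] + firsts[kbest + 1]) %/% 2)
}

# a single cluster row spanning all given variants (joint window)
cluster_row_for_test <- function(vars, ref, params = preset_params("C")) {
  phasebench:::cluster_row(vars, role = "query",
                           penalty = phasebench:::original_penalty(vars,
                                                                   params))
}

as_query <- function(callset) {
  new_callset(callset$variants, role = "query", contigs = callset$contigs)
}

# haplotype sequences produced by a callset
callset_haplotypes <- function(callset, reference) {
  lapply(names(reference), function(ctg) {
    vapply(0:1, function(h) {
      v <- callset$variants
      apply_variants(reference[[ctg]],
                     v[v$contig == ctg & v$hap == h, , drop = FALSE])
    }, character(1))
  })
}
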