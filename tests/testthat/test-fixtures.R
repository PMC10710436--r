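test_that("reference generation is deterministic and hits the tract target", {
  r1 <- make_reference(1000, 0, seed = 5)
  expect_equal(nchar(r1$seqs[[1]]), 1000)
  expect_equal(nrow(r1$tracts), 0)

  r2 <- make_reference(10000, 0.3, seed = 6)
  frac <- sum(r2$tracts$end - r2$tracts$begin) / 10000
  expect_gt(frac, 0.25)
  expect_lt(frac, 0.35)

  r3 <- make_reference(10000, 0.3, seed = 6)
  expect_identical(r2$seqs, r3$seqs)
  expect_equal(r2$tracts, r3$tracts)
})

test_that("planted variants reconstruct the emitted haplotypes", {
  ref <- make_reference(5000, 0.3, seed = 7)
  tr <- plant_variants(ref, seed = 8)
  for (h in 0:1) {
    v <- tr$callset$variants
    expect_identical(
      apply_variants(ref$seqs[[1]], v[v$hap == h, , drop = FALSE]),
      tr$haplotypes[[1]][h + 1])
  }
  # zero rates give an empty callset and reference haplotypes
  tr0 <- plant_variants(ref, snp_rate = 0, indel_rate = 0, complex_rate = 0,
                        seed = 9)
  expect_equal(nrow(tr0$callset$variants), 0)
  expect_identical(tr0$haplotypes[[1]], rep(ref$seqs[[1]], 2))
  # determinism
  tr2 <- plant_variants(ref, seed = 8)
  expect_equal(tr$callset$variants, tr2$callset$variants)
})

test_that("representations are sequence-identical and class profiles differ", {
  fx <- small_fixture(21, length = 3000, snp_rate = 0.004)
  ref <- fx$ref$seqs
  h0 <- callset_haplotypes(fx$truth, ref)
  for (preset in c("A", "B", "C", "D", "fragmented")) {
    r <- render_representation(fx$truth, ref, preset)
    expect_identical(callset_haplotypes(r, ref), h0,
                     info = paste("preset", preset))
  }
  # a decomposing preset reports no SNP records at all
  ra <- render_representation(fx$truth, ref, "A")
  expect_equal(sum(ra$variants$class == "SNP"), 0)
  expect_gt(sum(fx$truth$variants$class == "SNP"), 0)
  # rendering at C is idempotent
  rc <- render_representation(fx$truth, ref, "C")
  rc2 <- render_representation(rc, ref, "C")
  expect_equal(rc$variants, rc2$variants)
})

test_that("corruption plants exactly the requested errors with a ledger", {
  fx <- small_fixture(22, length = 4000, indel_rate = 0.002)
  co <- corrupt(fx$truth, fx$ref$seqs, n_fp = 3, n_fn = 2, n_indel_len = 1,
                n_flip = 1, seed = 23)
  lg <- co$ledger
  expect_equal(sum(lg$type == "FP"), 3)
  expect_equal(sum(lg$type == "FN"), 2)
  expect_equal(sum(lg$type == "PP"), 1)
  expect_equal(sum(lg$type == "flip"), 1)
  # dropped sites really are gone, planted FPs really are present
  key <- function(v) paste(v$contig, v$start, v$ref, v$alt)
  qk <- key(co$callset$variants)
  for (i in which(lg$type == "FN")) {
    expect_false(paste(lg$contig[i], lg$start[i], lg$ref[i], lg$alt[i]) %in% qk)
  }
  for (i in which(lg$type == "FP")) {
    expect_true(paste(lg$contig[i], lg$start[i], lg$ref[i], lg$alt[i]) %in% qk)
  }
  # an empty error specification leaves the callset unchanged
  same <- corrupt(fx$truth, fx$ref$seqs, seed = 24)
  expect_equal(same$callset$variants, fx$truth$variants)
  expect_equal(nrow(same$ledger), 0)
})

test_that("heterozygous sites enumerate 2^h local phasings", {
  v <- new_variant_tbl("c", c(10L, 20L, 30L, 40L, 50L),
                       c("A", "C", "G", "T", "A"),
                       c("T", "G", "A", "C", "G"), 30, 0L)
  ph <- enumerate_local_phasings(v)
  expect_length(ph, 32) # 2^5
  sigs <- vapply(ph, function(x) paste(x$hap, collapse = ""), character(1))
  expect_equal(length(unique(sigs)), 32)
  # homozygous sites do not multiply the count
  hom <- new_variant_tbl("c", c(60L, 60L), "A", "G", 30, 0:1)
  ph2 <- enumerate_local_phasings(dplyr::bind_rows(v[1, ], hom))
  expect_length(ph2, 2)
})
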