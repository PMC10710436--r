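test_that("alignment reproduces simple known paths and penalties", {
  C <- preset_params("C")
  a <- align_affine("ACGT", "ACGT", C)
  expect_equal(a$penalty, 0)
  expect_identical(a$ops, "====")

  # a single substitution beats two gaps under C (5 < 2 * (6 + 2))
  a <- align_affine("ACGT", "AGGT", C)
  expect_equal(a$penalty, 5)
  expect_identical(a$ops, "=X==")

  # under a decomposing scheme the same SNP becomes a 1-bp gap pair
  A <- preset_params("A")
  a <- align_affine("ACGT", "AGGT", A)
  expect_equal(a$penalty, 4) # 2 * (o + e) = 4 < x = 8
  expect_false(grepl("X", a$ops))
  expect_true(grepl("I", a$ops) && grepl("D", a$ops))

  # empty inputs
  expect_equal(align_affine("", "", C)$penalty, 0)
  expect_equal(align_affine("ACG", "", C)$penalty, 6 + 3 * 2)
})

test_that("DP penalty equals the exhaustive-path minimum", {
  set.seed(21)
  params <- list(preset_params("C"), preset_params("B"), preset_params("A"),
                 affine_params(0, 2, 3, 1), affine_params(1, 3, 2, 2))
  for (i in 1:120) {
    a <- rand_seq(sample(0:8, 1))
    b <- rand_seq(sample(0:8, 1))
    p <- params[[sample(length(params), 1)]]
    got <- align_affine(a, b, p)$penalty
    want <- phasebench:::cpp_enum_affine(a, b, p$m, p$x, p$o, p$e)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("unit-cost alignment equals Levenshtein distance", {
  set.seed(22)
  unit <- affine_params(0, 1, 0, 1)
  for (i in 1:80) {
    a <- rand_seq(sample(0:10, 1), c("A", "C"))
    b <- rand_seq(sample(0:10, 1), c("A", "C"))
    expect_equal(align_affine(a, b, unit)$penalty,
                 as.numeric(utils::adist(a, b)))
  }
})

test_that("reported penalty equals recomputation from the op string", {
  set.seed(23)
  for (i in 1:40) {
    a <- rand_seq(sample(0:12, 1))
    b <- rand_seq(sample(0:12, 1))
    p <- affine_params(0, sample(1:5, 1), sample(0:6, 1), sample(1:3, 1))
    al <- align_affine(a, b, p)
    expect_equal(al$penalty, phasebench:::path_penalty(al$ops, p),
                 tolerance = 1e-9)
    runs <- path_runs(al)
    expect_equal(sum(runs$len[runs$op %in% c("=", "X", "D")]), nchar(a))
    expect_equal(sum(runs$len[runs$op %in% c("=", "X", "I")]), nchar(b))
  }
})

test_that("paths convert to variants that reproduce the query sequence", {
  # all-match path emits nothing
  al <- align_affine("ACGT", "ACGT", "C")
  expect_equal(nrow(path_to_variants(al)), 0)

  # one substitution emits one SNP
  al <- align_affine("ACGT", "AGGT", "C")
  v <- path_to_variants(al, contig = "chr1")
  expect_equal(v$start, 1L)
  expect_equal(v$ref, "C")
  expect_equal(v$alt, "G")
  expect_equal(v$class, "SNP")

  # deletions in repeats are left-shifted to the run start
  al <- align_affine("GGGG", "GG", "C")
  v <- path_to_variants(al)
  expect_equal(nrow(v), 1)
  expect_equal(v$start, 0L)
  expect_equal(v$ref, "GG")
  expect_equal(v$class, "DEL")

  # round-trip property over random pairs
  set.seed(24)
  for (i in 1:40) {
    a <- rand_seq(sample(1:30, 1))
    b <- rand_seq(sample(1:30, 1))
    p <- if (i %% 2) preset_params("C") else preset_params("B")
    al <- align_affine(a, b, p)
    v <- path_to_variants(al)
    expect_identical(apply_variants(a, v), b)
  }
})

test_that("reach extension matches exhaustive path enumeration", {
  C <- preset_params("C")
  set.seed(25)
  for (i in 1:30) {
    ref <- rand_seq(12, if (i %% 3 == 0) c("A", "T") else c("A", "C", "G", "T"))
    # isolated SNP at offset 2, budget = x
    alt_base <- setdiff(c("A", "C", "G", "T"), substr(ref, 3, 3))[1]
    v <- new_variant_tbl("c", 2L, substr(ref, 3, 3), alt_base, 50, 0L)
    got <- reach_extend(ref, 2L, 3L, v, C, "right", limit = 12L)
    alt <- apply_variants(phasebench:::substr0(ref, 2, 3), v, origin = 2L)
    a <- phasebench:::substr0(ref, 2, 12)
    b <- paste0(alt, phasebench:::substr0(ref, 3, 12))
    want <- 2L + phasebench:::cpp_reach_enum(a, b, 1L, nchar(alt),
                                             phasebench:::original_penalty(v, C),
                                             C$m, C$x, C$o, C$e)
    expect_equal(got, want)
  }
})

test_that("reach spans a homopolymer run for an insertion planted in it", {
  ref <- paste0("CT", strrep("A", 8), "GC")
  v <- new_variant_tbl("c", 4L, "", "A", 50, 0L) # 1-bp INS inside the run
  C <- preset_params("C")
  rr <- reach_extend(ref, 4L, 4L, v, C, "right", limit = nchar(ref),
                     budget = C$o + C$e)
  lr <- reach_extend(ref, 4L, 4L, v, C, "left", limit = 0L,
                     budget = C$o + C$e)
  expect_gte(rr, 10L) # shifted placements cover the run rightwards
  expect_lte(lr, 2L)  # and leftwards
})

test_that("a cluster with no variants reaches only its own boundary", {
  v <- new_variant_tbl()
  expect_equal(reach_extend("ACGTACGT", 3L, 3L, v, "C", "right", 8L), 3L)
  expect_equal(reach_extend("ACGTACGT", 3L, 3L, v, "C", "left", 0L), 3L)
})
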