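test_that("gap clustering splits on reference gaps", {
  v <- dplyr::bind_rows(new_variant_tbl("c", 0L, "A", "T", 30, 0L),
                        new_variant_tbl("c", 200L, "C", "G", 30, 0L))
  expect_equal(nrow(gap_cluster(v, 50L)), 2)
  v2 <- dplyr::bind_rows(new_variant_tbl("c", 0L, "A", "T", 30, 0L),
                         new_variant_tbl("c", 10L, "C", "G", 30, 0L))
  expect_equal(nrow(gap_cluster(v2, 50L)), 1)
  expect_equal(nrow(gap_cluster(new_variant_tbl(), 50L)), 0)
  # gap 1: every variant separated by at least one base stands alone
  expect_equal(nrow(gap_cluster(v2, 1L)), 2)
  # unbounded gap: single cluster
  expect_equal(nrow(gap_cluster(v, .Machine$integer.max)), 1)
})

test_that("dependence joins clusters that can trade penalty off-diagonal", {
  # two single-base deletions in one homopolymer merge: jointly they are a
  # cheaper single 2-bp deletion
  ref <- paste0("ACGTC", strrep("A", 6), "GCTAG")
  a <- gap_cluster(new_variant_tbl("c", 6L, "A", "", 50, 0L), 1L)
  b <- gap_cluster(new_variant_tbl("c", 9L, "A", "", 50, 0L), 1L)
  expect_true(clusters_dependent(a, b, ref))
  # oracle: joint realignment strictly beats the separate representations
  C <- preset_params("C")
  joint <- align_affine(phasebench:::substr0(ref, 6, 10), "AA", C)$penalty
  separate <- 2 * (C$o + C$e)
  expect_lt(joint, separate)

  # far-apart SNPs cannot interact: budget x cannot span the gap
  long_ref <- rand_seq(600)
  s1 <- gap_cluster(new_variant_tbl("c", 10L, substr(long_ref, 11, 11),
                                    "A", 50, 0L), 1L)
  s2 <- gap_cluster(new_variant_tbl("c", 510L, substr(long_ref, 511, 511),
                                    "C", 50, 0L), 1L)
  s1$variants[[1]]$alt <- setdiff(c("A", "C", "G", "T"),
                                  s1$variants[[1]]$ref)[1]
  s2$variants[[1]]$alt <- setdiff(c("A", "C", "G", "T"),
                                  s2$variants[[1]]$ref)[1]
  expect_false(clusters_dependent(s1, s2, long_ref))
  expect_error(clusters_dependent(s2, s1, long_ref), "overlap")
})

test_that("iterative clustering reaches a fixpoint and partitions variants", {
  set.seed(41)
  # isolated variants stay alone
  ref <- rand_seq(500)
  v <- new_variant_tbl("c", c(50L, 250L, 450L),
                       vapply(c(51L, 251L, 451L),
                              function(i) substr(ref, i, i), character(1)),
                       "N", 30, 0L)
  v$alt <- vapply(v$ref, function(r) setdiff(c("A", "C", "G", "T"), r)[1],
                  character(1))
  v$class <- phasebench:::variant_class(v$ref, v$alt)
  cl <- iterative_cluster(v, ref)
  expect_equal(nrow(cl), 3)

  # a chain of INDELs inside one STR collapses to a single cluster
  str_ref <- paste0(rand_seq(20), strrep("AT", 12), rand_seq(20))
  chain <- dplyr::bind_rows(
    new_variant_tbl("c", 22L, "AT", "", 30, 0L),
    new_variant_tbl("c", 30L, "AT", "", 30, 0L),
    new_variant_tbl("c", 38L, "AT", "", 30, 0L))
  cl <- iterative_cluster(chain, str_ref)
  expect_equal(nrow(cl), 1)
  expect_equal(nrow(cl$variants[[1]]), 3)

  # partition: every variant appears exactly once, in order
  all_members <- dplyr::bind_rows(cl$variants)
  expect_equal(all_members$start, sort(chain$start))
})

test_that("independent clusters standardize the same jointly or separately", {
  set.seed(42)
  checked <- 0
  for (i in 1:40) {
    ref <- rand_seq(40)
    b1 <- substr(ref, 6, 6); b2 <- substr(ref, 31, 31)
    v <- dplyr::bind_rows(
      new_variant_tbl("c", 5L, b1, setdiff(c("A", "C", "G", "T"), b1)[1],
                      30, 0L),
      new_variant_tbl("c", 30L, b2, setdiff(c("A", "C", "G", "T"), b2)[1],
                      30, 0L))
    cl <- iterative_cluster(v, ref)
    if (nrow(cl) != 2) next # dependent in this sequence; skip
    checked <- checked + 1
    sep <- dplyr::bind_rows(standardize_cluster(cl[1, ], ref),
                            standardize_cluster(cl[2, ], ref))
    joint <- cluster_row_for_test(v, ref)
    jnt <- standardize_cluster(joint, ref)
    expect_equal(sep[, c("start", "ref", "alt")],
                 jnt[, c("start", "ref", "alt")])
  }
  expect_gt(checked, 20)
})

test_that("re-clustering a converged clustering changes nothing", {
  set.seed(43)
  fx <- small_fixture(7, length = 2000)
  v <- fx$truth$variants
  v0 <- v[v$hap == 0, ]
  cl1 <- iterative_cluster(v0, fx$ref$seqs[[1]])
  flat <- dplyr::bind_rows(cl1$variants)
  cl2 <- iterative_cluster(flat, fx$ref$seqs[[1]])
  expect_equal(cl1$begin, cl2$begin)
  expect_equal(cl1$end, cl2$end)
})
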