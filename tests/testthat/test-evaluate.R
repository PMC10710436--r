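test_that("query graph alignment skips false positives without penalty", {
  W <- "ACGTACGTACGTACGT"
  # truth == reference, query holds one spurious SNP: skipped, distance 0
  fp <- new_variant_tbl("c", 5L, "C", "G", 30, 0L)
  g <- align_truth_to_query_graph(W, W, fp)
  expect_equal(g$distance, 0)
  expect_length(g$subset, 0)

  # truth equals the query-applied sequence: all variants taken, distance 0
  tv <- new_variant_tbl("c", c(2L, 10L), c("G", "G"), c("T", "A"), 30, 0L)
  truth_seq <- apply_variants(W, tv)
  g <- align_truth_to_query_graph(truth_seq, W, tv)
  expect_equal(g$distance, 0)
  expect_length(g$subset, 2)
})

test_that("a near-correct INDEL leaves the residual edit distance", {
  W <- "ACGTACGTACGTACGT"
  truth_ins <- new_variant_tbl("c", 8L, "", "TTT", 30, 0L)
  query_ins <- new_variant_tbl("c", 8L, "", "T", 30, 0L)
  truth_seq <- apply_variants(W, truth_ins)
  g <- align_truth_to_query_graph(truth_seq, W, query_ins)
  expect_equal(g$distance, 2)
  expect_length(g$subset, 1) # taking the short call beats skipping it (3)
})

test_that("local phasing selection follows the 2x2 distance matrix", {
  expect_equal(select_phasing(matrix(c(0, 3, 3, 0), 2, 2)), "X")
  expect_equal(select_phasing(matrix(c(3, 0, 0, 3), 2, 2)), "Y")
  expect_equal(select_phasing(matrix(c(1, 1, 1, 1), 2, 2)), "U")

  # a fully homozygous supercluster always ties by symmetry
  W <- "AACCGGTTAACCGGTT"
  v <- new_variant_tbl("c", c(4L, 4L), "G", "C", 30, 0:1)
  sc <- tibble::tibble(contig = "c", sc_id = 1L, begin = 0L,
                       end = nchar(W),
                       variants = list(dplyr::bind_rows(
                         dplyr::mutate(v, role = "truth"),
                         dplyr::mutate(v, role = "query"))))
  res <- eval_supercluster(sc, c(c = W))
  expect_equal(res$phase, "U")
  expect_true(all(res$records$category == "TP"))
})

test_that("sync points partition the window at variant-free diagonal bases", {
  W <- "ACGTACGTAC"
  # no variants: every boundary is a sync point
  al <- phasebench:::cpp_align_affine(W, W, 0, 1, 0, 1)
  sync <- find_sync_points(al$ops, 0L, 10L, new_variant_tbl(),
                           new_variant_tbl())
  expect_equal(sync, 0:10)

  # one mid-window SNP: boundaries survive, the variant spans no boundary
  tv <- new_variant_tbl("c", 4L, "A", "G", 30, 0L)
  truth_seq <- apply_variants(W, tv)
  g <- align_truth_to_query_graph(truth_seq, W, new_variant_tbl())
  sync <- find_sync_points(g$ops, 0L, 10L, tv, new_variant_tbl())
  expect_equal(sync, 0:10)

  # overlapping truth and query deletions leave no sync point inside
  tv <- new_variant_tbl("c", 2L, "GTAC", "", 30, 0L)
  qv <- new_variant_tbl("c", 4L, "ACGT", "", 30, 0L)
  truth_seq <- apply_variants(W, tv)
  g <- align_truth_to_query_graph(truth_seq, W, qv)
  sync <- find_sync_points(g$ops, 0L, 10L, tv, qv[g$subset, ])
  expect_false(any(sync > 2 & sync < 8))
  expect_true(all(c(0L, 10L) %in% sync))
})

test_that("segment credit follows the edit-distance reduction rule", {
  # the worked case: distance 3 reduced to 1 earns two-thirds credit
  cr <- segment_credit(3, 1)
  expect_equal(cr$category, "PP")
  expect_equal(cr$credit, 2 / 3)
  expect_equal(segment_credit(2, 0), list(category = "TP", credit = 1))
  expect_equal(segment_credit(2, 2), list(category = "FPFN", credit = 0))
  # a call that makes things worse is clamped to zero credit
  expect_equal(segment_credit(1, 3)$credit, 0)
  expect_equal(segment_credit(0, 1)$category, "FPFN")
})

test_that("summary metrics follow the truth-based precision definition", {
  set.seed(71)
  ref <- c(ctg = rand_seq(400))
  contigs <- c(ctg = 400L)
  # truth: het 3-bp insertion; query: same site, 2-bp insertion -> one PP
  # with credit 2/3 on a single haplotype
  tv <- new_variant_tbl("ctg", 200L, "", "GTA", 50, 0L)
  qv <- new_variant_tbl("ctg", 200L, "", "GT", 50, 0L)
  ev <- run_evaluation(ref, new_callset(tv, "truth", contigs),
                       new_callset(qv, "query", contigs))
  pr <- ev$pr_curve[ev$pr_curve$class == "ALL", ]
  expect_equal(pr$tp_truth, 2 / 3)
  expect_equal(pr$fn_truth, 1 / 3)
  expect_equal(pr$fp_query, 1 / 3)
  expect_equal(pr$precision, 2 / 3) # TP_truth / (TP_truth + FP_query)
  expect_equal(pr$recall, 2 / 3)

  # F1 Q-score examples
  expect_equal(f1_qscore(0.99), 20)
  expect_equal(f1_qscore(1), 100) # capped
})

test_that("a homozygous false positive counts as two false positives", {
  ref <- c(ctg = rand_seq(300))
  contigs <- c(ctg = 300L)
  truth <- new_callset(new_variant_tbl(), "truth", contigs)
  qv <- new_variant_tbl("ctg", c(150L, 150L), substr(ref, 151, 151),
                        setdiff(c("A", "C", "G", "T"),
                                substr(ref, 151, 151))[1], 50, 0:1)
  ev <- run_evaluation(ref, truth, new_callset(qv, "query", contigs))
  pr <- ev$pr_curve[ev$pr_curve$class == "ALL", ]
  expect_equal(pr$fp_query, 2)
})

test_that("credit fractions are conserved per variant", {
  for (seed in 1:4) {
    fx <- small_fixture(seed + 80, length = 3000)
    q <- corrupt(fx$truth, fx$ref$seqs, n_fp = 2, n_fn = 1, n_indel_len = 1,
                 seed = seed)$callset
    ev <- run_evaluation(fx$ref$seqs, fx$truth, q)
    rec <- tidy(ev)
    expect_true(all(rec$credit >= 0 & rec$credit <= 1))
    expect_true(all(rec$category[rec$credit == 1] == "TP"))
    expect_true(all(rec$category[rec$credit > 0 & rec$credit < 1] == "PP"))
    pr <- ev$pr_curve[ev$pr_curve$class == "ALL", ][1, ]
    expect_equal(pr$tp_query + pr$fp_query,
                 sum(rec$role == "query"))
    expect_equal(pr$tp_truth + pr$fn_truth, sum(rec$role == "truth"))
    expect_true(all(stats::na.omit(c(ev$pr_curve$precision,
                                     ev$pr_curve$recall)) >= 0))
    expect_true(all(stats::na.omit(c(ev$pr_curve$precision,
                                     ev$pr_curve$recall)) <= 1))
  }
})

test_that("swapping query haplotype labels flips X and Y but not counts", {
  fx <- small_fixture(91, length = 3000)
  q1 <- as_query(fx$truth)
  v <- q1$variants
  v$hap <- 1L - v$hap
  q2 <- new_callset(v, "query", q1$contigs)
  ev1 <- run_evaluation(fx$ref$seqs, fx$truth, q1)
  ev2 <- run_evaluation(fx$ref$seqs, fx$truth, q2)
  expect_equal(ev1$pr_curve[, -1], ev2$pr_curve[, -1])
  p1 <- ev1$superclusters$phase
  p2 <- ev2$superclusters$phase
  swap <- c(X = "Y", Y = "X", U = "U")
  expect_equal(p2, unname(swap[p1]))
  expect_equal(ev1$phasing$switch_errors, ev2$phasing$switch_errors)
})
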