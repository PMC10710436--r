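ref1 <- c(chr1 = "AACCACGTGGTTACGTACGTAAAACCCCGGGG")

write_test_vcf <- function(lines, contigs = ref1) {
  path <- tempfile(fileext = ".vcf")
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                   nchar(contigs)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "FORMAT", "S1", sep = "\t"))
  writeLines(c(hdr, lines), path)
  path
}

test_that("records are split, trimmed and assigned to haplotypes", {
  p <- write_test_vcf(c(
    "chr1\t5\t.\tACGT\tAGGT\t30\tPASS\tGT\t1|0",   # trims to C>G SNP at POS 6
    "chr1\t15\t.\tG\tG,A\t20\t.\tGT\t0|2",         # multi-allelic, hap1 only
    "chr1\t25\t.\tC\tT\t50\t.\tGT\t0|0"            # reference genotype
  ))
  cs <- read_phased_vcf(p, ref1, role = "query")
  v <- cs$variants
  expect_equal(nrow(v), 2)
  expect_equal(v$start, c(5L, 14L))
  expect_equal(v$ref, c("C", "G"))
  expect_equal(v$alt, c("G", "A"))
  expect_equal(v$hap, c(0L, 1L))
  expect_equal(v$qual, c(30, 20))
  expect_equal(v$class, c("SNP", "SNP"))
})

test_that("unphased heterozygous genotypes are rejected with the record name", {
  p <- write_test_vcf("chr1\t5\t.\tA\tT\t30\t.\tGT\t1/0")
  expect_error(read_phased_vcf(p, ref1), "unphased.*chr1:5")
  # unphased homozygous genotypes are unambiguous and accepted
  p <- write_test_vcf("chr1\t5\t.\tA\tT\t30\t.\tGT\t1/1")
  cs <- read_phased_vcf(p, ref1)
  expect_equal(nrow(cs$variants), 2) # one record per haplotype
  expect_setequal(cs$variants$hap, 0:1)
})

test_that("haploid or missing genotypes error by default, skip on request", {
  p <- write_test_vcf("chr1\t5\t.\tA\tT\t30\t.\tGT\t1")
  expect_error(read_phased_vcf(p, ref1), "non-diploid")
  expect_warning(cs <- read_phased_vcf(p, ref1, skip_invalid = TRUE),
                 "skipping")
  expect_equal(nrow(cs$variants), 0)
  p <- write_test_vcf("chr1\t5\t.\tA\tT\t30\t.\tGT\t.")
  expect_error(read_phased_vcf(p, ref1), "missing genotype")
})

test_that("missing QUAL sinks to zero and PASS filtering is opt-in", {
  p <- write_test_vcf(c("chr1\t5\t.\tA\tT\t.\t.\tGT\t1|0",
                        "chr1\t15\t.\tG\tA\t40\tLowQual\tGT\t0|1"))
  cs <- read_phased_vcf(p, ref1)
  expect_equal(sort(cs$variants$qual), c(0, 40))
  cs <- read_phased_vcf(p, ref1, pass_only = TRUE)
  expect_equal(nrow(cs$variants), 1)
  expect_equal(cs$variants$qual, 0)
})

test_that("BED regions restrict the callset", {
  p <- write_test_vcf(c("chr1\t5\t.\tA\tT\t30\t.\tGT\t1|0",
                        "chr1\t25\t.\tC\tA\t30\t.\tGT\t0|1"))
  regions <- tibble::tibble(contig = "chr1", begin = 0L, end = 10L)
  cs <- read_phased_vcf(p, ref1, regions = regions)
  expect_equal(cs$variants$start, 4L)
})

test_that("applying variants splices alleles and preserves length identity", {
  expect_identical(apply_variants("AAAA", new_variant_tbl()), "AAAA")
  v <- new_variant_tbl("c", 1L, "C", "G", 30, 0L)
  expect_identical(apply_variants("ACGT", v), "AGGT")
  v <- new_variant_tbl("c", 0L, "GG", "", 30, 0L)
  expect_identical(apply_variants("GGGG", v), "GG")

  set.seed(31)
  for (i in 1:20) {
    ref <- rand_seq(60)
    starts <- c(5L, 20L, 40L)
    v <- new_variant_tbl("c", starts,
                         c(substr(ref, 6, 6), "", substr(ref, 41, 43)),
                         c("T", rand_seq(2), ""), 30, 0L)
    v <- v[v$ref != v$alt, ]
    out <- apply_variants(ref, v)
    expect_equal(nchar(out),
                 nchar(ref) - sum(nchar(v$ref)) + sum(nchar(v$alt)))
  }
  expect_error(apply_variants("ACGT", new_variant_tbl("c", 3L, "TT", "A", 1, 0L)),
               "out of bounds")
})

test_that("VCF writing anchors INDELs and round-trips callsets", {
  ref <- c(ctg = "AACCAAGGTTACGTACGT")
  v <- dplyr::bind_rows(
    new_variant_tbl("ctg", 2L, "", "T", 25, 0L),          # het INS
    new_variant_tbl("ctg", c(6L, 6L), "G", "T", 41, 0:1), # hom SNP
    new_variant_tbl("ctg", 10L, "ACG", "", 33, 1L)        # het DEL
  )
  cs <- new_callset(v, role = "query",
                    contigs = stats::setNames(nchar(ref), names(ref)))
  path <- tempfile(fileext = ".vcf")
  write_vcf(cs, path, ref)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, 3)
  ins <- strsplit(body[1], "\t")[[1]]
  expect_equal(ins[2], "2")       # anchor base position
  expect_equal(ins[4], "A")       # REF = anchor
  expect_equal(ins[5], "AT")      # ALT = anchor + insertion
  expect_equal(strsplit(body[2], "\t")[[1]][9], "1|1")

  back <- read_phased_vcf(path, ref, role = "query")
  expect_equal(dplyr::arrange(back$variants, start, hap),
               dplyr::arrange(cs$variants, start, hap))
})

test_that("an empty callset writes a header-only VCF", {
  ref <- c(ctg = "ACGTACGT")
  cs <- new_callset(new_variant_tbl(), role = "truth",
                    contigs = c(ctg = 8L))
  path <- tempfile(fileext = ".vcf")
  write_vcf(cs, path, ref)
  expect_true(all(startsWith(readLines(path), "#")))
  back <- read_phased_vcf(path, ref, role = "truth")
  expect_equal(nrow(back$variants), 0)
})

test_that("overlapping variants on one haplotype are rejected", {
  v <- dplyr::bind_rows(new_variant_tbl("c", 2L, "ACG", "T", 30, 0L),
                        new_variant_tbl("c", 3L, "C", "G", 30, 0L))
  expect_error(new_callset(v, "query", c(c = 20L)), "overlapping")
})

test_that("FASTA round-trips through write_fasta/read_fasta", {
  seqs <- c(a = rand_seq(150), b = rand_seq(61))
  path <- tempfile(fileext = ".fa")
  write_fasta(seqs, path)
  expect_true(file.exists(paste0(path, ".fai")))
  back <- read_fasta(path)
  expect_identical(back, seqs)
})
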