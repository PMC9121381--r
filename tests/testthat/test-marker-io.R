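test_that("genotype TSV parsing normalises cells and enforces ploidy rules", {
  gt <- read_toy_genotypes()
  expect_s3_class(gt, "genotype_table")
  expect_equal(gt$genotypes["A", "D1S1"], "12/13")
  # microvariant sorts numerically after 12
  expect_equal(gt$genotypes["C", "D1S1"], "12/14.2")
  # male X is hemizygous, one allele
  expect_equal(gt$genotypes["A", "DXS1"], "21")
  # multi-copy Y combination is one token
  expect_equal(gt$genotypes["A", "DYS1"], "13-14")
  expect_true(is.na(gt$genotypes["B", "DYS1"]))

  bad <- write_toy_genotype_tsv()
  tx <- readLines(bad)
  tx[2] <- sub("12/13", "12/13/14", tx[2])
  writeLines(tx, bad)
  expect_error(read_genotype_table(bad, marker_class = toy_marker_classes),
               "row 'A', column 'D1S1'")

  tx <- readLines(write_toy_genotype_tsv())
  tx[2] <- sub("\t21\t", "\t21/22\t", tx[2])
  f2 <- tempfile(); writeLines(tx, f2)
  expect_error(read_genotype_table(f2, marker_class = toy_marker_classes),
               "2 distinct X alleles")
})

test_that("genotype tables round-trip through TSV up to allele order", {
  gt <- read_toy_genotypes()
  out <- tempfile(fileext = ".tsv")
  write_genotype_table(gt, out)
  gt2 <- read_genotype_table(out, marker_class = toy_marker_classes)
  expect_identical(gt$genotypes, gt2$genotypes)
  expect_identical(gt$samples, gt2$samples)
})

test_that("allele frequencies count gene copies by ploidy and sex", {
  gt <- read_toy_genotypes()
  ft <- allele_frequencies(gt, populations = "Yugu")
  fl <- freq_split(ft)
  # autosomal: {12/13, 12/12} -> p(12) = 3/4
  expect_equal(unname(fl$D1S1[c("12", "13")]), c(0.75, 0.25))
  expect_equal(gene_counts(ft, "D1S1"), 4)
  # X: male "21" contributes 1 copy, female "21/22" two -> p(21) = 2/3
  expect_equal(unname(fl$DXS1["21"]), 2 / 3)
  expect_equal(gene_counts(ft, "DXS1"), 3)
  # frequencies always sum to 1
  for (p in freq_split(allele_frequencies(gt)))
    expect_lt(abs(sum(p) - 1), 1e-9)

  # Y multi-copy combinations are alleles in their own right
  fy <- freq_split(allele_frequencies(gt))$DYS1
  expect_equal(unname(fy["13-14"]), 2 / 3)
  expect_equal(unname(fy["15-16"]), 1 / 3)

  expect_error(allele_frequencies(gt, populations = "nonexistent"),
               "empty sample selection")
})

test_that("Y null alleles are excluded from frequency denominators", {
  gt <- genotype_table(
    data.frame(sample_id = c("a", "b", "c"), population = "p",
               sex = "male"),
    data.frame(locus_id = "DYS9", marker_class = "y_str"),
    matrix(c("12", "null", "13"), ncol = 1))
  p <- freq_split(allele_frequencies(gt))$DYS9
  expect_equal(sort(names(p)), c("12", "13"))
  expect_equal(gene_counts(allele_frequencies(gt), "DYS9"), 2)
})

test_that("an all-missing locus is omitted with a warning", {
  gt <- genotype_table(
    data.frame(sample_id = c("a", "b"), population = "p", sex = "female"),
    data.frame(locus_id = c("L1", "L2"),
               marker_class = "autosomal_str"),
    cbind(c("12/13", "12/12"), c(NA, NA)))
  expect_warning(ft <- allele_frequencies(gt), "no observed gene copies")
  expect_identical(unique(ft$locus), "L1")
})

test_that("allele coverage ratio follows the min/max convention", {
  r <- allele_coverage_ratio(c(50, 100))
  expect_equal(r$ratio, 0.5)
  expect_true(r$pass[["0.50"]]); expect_false(r$pass[["0.75"]])
  expect_equal(allele_coverage_ratio(c(80, 80))$ratio, 1)
  expect_equal(allele_coverage_ratio(300)$ratio, 1)
  expect_error(allele_coverage_ratio(c(0, 0)), "uncalled")
  # symmetric in the two depths, and in (0, 1]
  set.seed(1)
  for (i in 1:20) {
    d <- sample(1:500, 2)
    a <- allele_coverage_ratio(d)$ratio
    expect_equal(a, allele_coverage_ratio(rev(d))$ratio)
    expect_true(a > 0 && a <= 1)
  }
})

test_that("depth summaries use the n-1 standard deviation", {
  d <- data.frame(Locus = "L1", Sample = c("s1", "s2"), Allele = "x",
                  Depth = c(1000, 2000))
  s <- depth_summary(d)
  expect_equal(s$mean_doc, 1500)
  expect_equal(s$sd_doc, sqrt(2 * 500^2), tolerance = 1e-12)
  # degenerate cases: one sample, constant depths
  expect_equal(depth_summary(d[1, ])$sd_doc, 0)
  dc <- data.frame(Locus = "L", Sample = c("a", "b", "c"), Allele = "x",
                   Depth = 5)
  expect_equal(depth_summary(dc)$mean_doc, 5)
  expect_equal(depth_summary(dc)$sd_doc, 0)
  # allele depths are summed within a call before averaging
  het <- data.frame(Locus = "L", Sample = c("a", "a", "b", "b"),
                    Allele = c("x", "y", "x", "y"),
                    Depth = c(600, 400, 900, 1100))
  expect_equal(depth_summary(het)$mean_doc, 1500)
})
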