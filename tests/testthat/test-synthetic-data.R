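test_that("Dirichlet frequency draws live on the simplex and are seeded", {
  ft <- sample_allele_freqs(5, k = 7, alpha = 1, seed = 3)
  for (p in freq_split(ft)) {
    expect_length(p, 7)
    expect_true(all(p > 0))
    expect_lt(abs(sum(p) - 1), 1e-9)
  }
  expect_identical(freq_split(sample_allele_freqs(5, k = 7, seed = 3)),
                   freq_split(ft))
  expect_error(sample_allele_freqs(1, k = 1), "k >= 2")

  # high concentration pulls draws to the centre of the simplex:
  # alpha = 1000, K = 4 keeps max|p - 0.25| < 0.05 in at least 99% of draws
  set.seed(4)
  dev <- replicate(1000, {
    p <- freq_split(sample_allele_freqs(1, k = 4, alpha = 1000))[[1]]
    max(abs(p - 0.25))
  })
  expect_gte(mean(dev < 0.05), 0.99)
})

test_that("Balding-Nichols draws have the prescribed mean and variance", {
  expect_identical(balding_nichols_freq(0.3, 0), 0.3)
  expect_identical(balding_nichols_freq(1, 0.1), 1)
  expect_identical(balding_nichols_freq(0, 0.1), 0)
  x <- balding_nichols_freq(rep(0.5, 1e4), fst = 0.05, seed = 5)
  expect_equal(var(x), 0.05 * 0.25, tolerance = 0.15)
  expect_equal(mean(x), 0.5, tolerance = 0.02)
  expect_identical(x, balding_nichols_freq(rep(0.5, 1e4), 0.05, seed = 5))
})

test_that("simulated genotypes follow Hardy-Weinberg sampling by sex", {
  mono <- freq_table(list(L1 = c(`12` = 1)), n = Inf)
  gt <- simulate_genotypes(mono, 20, seed = 1)
  expect_true(all(gt$genotypes == "12/12"))

  bi <- freq_table(list(L1 = c(A = 0.5, B = 0.5)), n = Inf)
  gt <- simulate_genotypes(bi, 10000, seed = 2)
  hob <- mean(gt$genotypes[, 1] == "A/B")
  expect_lt(abs(hob - 0.5), 3 * sqrt(0.25 / 10000))

  xy <- freq_table(list(X1 = c(a = 0.5, b = 0.5), Y1 = c(h1 = 0.7, h2 = 0.3)),
                   n = Inf, marker_class = c("x_str", "y_str"))
  gt <- simulate_genotypes(xy, 50, sexes = c("male", "female"), seed = 3)
  males <- gt$samples$sex == "male"
  expect_true(all(!grepl("/", gt$genotypes[males, "X1"])))
  expect_true(all(grepl("/", gt$genotypes[!males, "X1"])))
  expect_true(all(is.na(gt$genotypes[!males, "Y1"])))
  expect_false(anyNA(gt$genotypes[males, "Y1"]))

  expect_identical(simulate_genotypes(bi, 50, seed = 9)$genotypes,
                   simulate_genotypes(bi, 50, seed = 9)$genotypes)
})

test_that("gene-dropped pairs realise the Mendelian IBD distribution", {
  fq <- sample_allele_freqs(8, k = 6, seed = 11)
  pc <- simulate_relative_pairs(fq, "parent_child", 300, seed = 12)
  expect_true(all(pc$ibd == 1L))
  # transmission guarantee: parent and child share an allele everywhere
  share <- (pc$a1_1 == pc$a2_1) | (pc$a1_1 == pc$a2_2) |
           (pc$a1_2 == pc$a2_1) | (pc$a1_2 == pc$a2_2)
  expect_true(all(share))

  hs <- simulate_relative_pairs(fq, "half_sib", 2000, seed = 13)
  expect_true(all(hs$ibd <= 1L))

  fs <- simulate_relative_pairs(sample_allele_freqs(1, k = 8, seed = 14),
                                "full_sib", 10000, seed = 15)
  props <- prop.table(tabulate(fs$ibd + 1L, 3L))
  sds <- sqrt(c(0.25 * 0.75, 0.5 * 0.5, 0.25 * 0.75) / 10000)
  expect_true(all(abs(props - c(0.25, 0.5, 0.25)) < 3 * sds))
})

test_that("fully linked loci inherit identical IBD states in sib pairs", {
  lm <- data.frame(locus_id = sprintf("L%03d", 1:10), chromosome = 1,
                   theta = c(NA, rep(0, 9)))
  fq <- sample_allele_freqs(10, k = 4, seed = 41)
  pr <- simulate_relative_pairs(fq, "full_sib", 200, linkage_map = lm,
                                seed = 42)
  expect_true(all(pr$ibd == pr$ibd[, 1]))
  # and with theta = 0.5 the states decorrelate
  lm$theta <- c(NA, rep(0.5, 9))
  pr2 <- simulate_relative_pairs(fq, "full_sib", 2000, linkage_map = lm,
                                 seed = 43)
  agree <- mean(pr2$ibd[, 1] == pr2$ibd[, 2])
  expect_lt(agree, 0.55)
})

test_that("gene-dropped unrelated pairs reproduce HWE genotype frequencies", {
  fq <- sample_allele_freqs(50, k = 3, alpha = 2, seed = 22)
  pr <- simulate_relative_pairs(fq, "unrelated", 500, seed = 23)
  fl <- freq_split(fq)
  rejections <- 0L
  for (j in 1:50) {
    hw <- hwe_genotype_probs(fl[[j]])
    cells <- paste(pmin(pr$a2_1[, j], pr$a2_2[, j]),
                   pmax(pr$a2_1[, j], pr$a2_2[, j]), sep = "/")
    labs <- vapply(hw$genotypes, function(g)
      paste(sort(g), collapse = "/"), "")
    ob <- table(factor(cells, levels = labs))
    pv <- suppressWarnings(stats::chisq.test(ob, p = hw$probs))$p.value
    if (pv < 0.01) rejections <- rejections + 1L
  }
  expect_lte(rejections, 4L)  # Binomial(50, 0.01) upper tail
})

test_that("coalescent samples match Watterson's expectation", {
  expect_true(all(simulate_sequences(6, "constant", theta = 0, L = 50,
                                     seed = 1)$matrix == "A"))
  a <- simulate_sequences(10, "constant", theta = 5, L = 300, seed = 2)
  expect_identical(
    a$matrix, simulate_sequences(10, "constant", theta = 5, L = 300,
                                 seed = 2)$matrix)
  expect_error(simulate_sequences(20, "constant", theta = 50, L = 3,
                                  seed = 3), "segregating sites exceed")
  set.seed(31)
  S <- replicate(2000, diversity_summary(
    simulate_sequences(10, "constant", theta = 5, L = 400))$S)
  expect_equal(mean(S), 5 * sum(1 / (1:9)), tolerance = 0.02)
})
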