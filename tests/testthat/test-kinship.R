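test_that("kinship models validate their IBD coefficients", {
  expect_equal(kinship_model("full_sib")$k,
               c(k0 = 0.25, k1 = 0.5, k2 = 0.25))
  expect_equal(kinship_model("parent_child")$k, c(k0 = 0, k1 = 1, k2 = 0))
  expect_error(kinship_model("custom", k = c(0.5, 0, 0.5)),
               "k1\\^2 >= 4 k0 k2")
  expect_error(kinship_model("custom", k = c(0.5, 0.2, 0.2)))
})

test_that("single-locus LRs match hand enumeration of IBD cases", {
  fq <- freq_table(list(L1 = c(A = 0.5, B = 0.5)), n = Inf)
  lr_fs <- pair_likelihood_ratio(c(L1 = "A/A"), c(L1 = "A/A"), fq,
                                 kinship_model("full_sib"))
  expect_equal(lr_fs$LR, (0.25 * 0.25 + 0.5 * 0.5 + 0.25) / 0.25)
  lr_hs <- pair_likelihood_ratio(c(L1 = "A/A"), c(L1 = "A/A"), fq,
                                 kinship_model("half_sib"))
  expect_equal(lr_hs$LR, (0.5 * 0.25 + 0.5 * 0.5) / 0.25)
  # unrelated model: LR identically 1, whatever the pair
  set.seed(5)
  fq2 <- sample_allele_freqs(6, k = 5, seed = 6)
  gt <- simulate_genotypes(fq2, 20, seed = 7)
  un <- kinship_model("unrelated")
  for (i in 1:10) {
    lr <- pair_likelihood_ratio(gt$genotypes[2 * i - 1, ],
                                gt$genotypes[2 * i, ], fq2, un)
    expect_equal(lr$LR, 1)
  }
})

test_that("IBD transition kernels are normalised (brute force)", {
  set.seed(8)
  for (k in c(2, 4)) {
    p <- rgamma(k, 1); p <- setNames(p / sum(p), paste0("a", 1:k))
    fq <- freq_table(list(L = p), n = Inf)
    hw <- hwe_genotype_probs(p)
    for (model in c("full_sib", "half_sib", "parent_child", "unrelated")) {
      m <- kinship_model(model)
      for (g1 in hw$genotypes) {
        cell1 <- setNames(paste(sort(g1), collapse = "/"), "L")
        total <- 0
        for (gi in seq_along(hw$genotypes)) {
          g2 <- hw$genotypes[[gi]]
          cell2 <- setNames(paste(sort(g2), collapse = "/"), "L")
          lr <- pair_likelihood_ratio(cell1, cell2, fq, m)
          total <- total + lr$LR * hw$probs[gi]  # = k-mixture P(g2 | g1)
        }
        expect_equal(total, 1, tolerance = 1e-12)
      }
    }
  }
})

test_that("the expected LR under unrelatedness is 1", {
  set.seed(51)
  p <- c(A = 0.3, B = 0.2, C = 0.4, D = 0.1)
  n <- 1e5
  draw <- function() names(p)[sample.int(4, n, TRUE, p)]
  lr <- forensicpanel:::lr_locus(draw(), draw(), draw(), draw(), p,
                                 kinship_model("full_sib")$k)
  expect_lt(abs(mean(lr) - 1), 3 * sd(lr) / sqrt(n))
})

test_that("missing loci are skipped and unknown alleles need a floor", {
  fq <- freq_table(list(L1 = c(A = 0.5, B = 0.5), L2 = c(A = 0.9, B = 0.1)),
                   n = Inf)
  m <- kinship_model("full_sib")
  lr <- pair_likelihood_ratio(c(L1 = "A/A", L2 = NA),
                              c(L1 = "A/A", L2 = "A/B"), fq, m)
  expect_named(lr$per_locus, "L1")
  expect_error(pair_likelihood_ratio(c(L1 = "A/C"), c(L1 = "A/A"), fq, m),
               "min_freq")
  lr2 <- pair_likelihood_ratio(c(L1 = "A/C"), c(L1 = "A/A"), fq, m,
                               min_freq = 0.01)
  expect_true(is.finite(lr2$LR) && lr2$LR > 0)
})

test_that("LR study separates true relatives from unrelated pairs", {
  panel <- study_panel()
  sets <- list(strs = str_locus_ids())
  fs <- run_lr_study(panel, kinship_model("full_sib"),
                     kinship_model("full_sib"), n_pairs = 300,
                     seed = 201, marker_sets = sets)
  un <- run_lr_study(panel, kinship_model("unrelated"),
                     kinship_model("full_sib"), n_pairs = 300,
                     seed = 203, marker_sets = sets)
  expect_gt(fs$exceedance[["strs"]], 0.95)
  expect_lt(un$exceedance[["strs"]], 0.02)
  # true parent-child pairs share an allele at every locus: no zero LRs
  pc <- run_lr_study(panel, kinship_model("parent_child"),
                     kinship_model("parent_child"), n_pairs = 100,
                     seed = 204, marker_sets = sets)
  expect_true(all(is.finite(pc$log10_lr[["strs"]])))
})

test_that("exceedance probability is a simple tail fraction", {
  expect_equal(exceedance_probability(rep(1e5, 4), 1e4), 1)
  expect_equal(exceedance_probability(rep(1, 4), 1e4), 0)
  expect_equal(exceedance_probability(c(1e3, 1e5), 1e4), 0.5)
  expect_error(exceedance_probability(numeric(0), 1), "empty")
})
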