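test_that("diversity indices match hand counts on toy alignments", {
  d <- diversity_summary(toy_aln3())
  expect_equal(d$S, 2)
  expect_equal(d$k, (1 + 2 + 1) / 3)
  expect_equal(d$Pi, d$k / 3)
  expect_equal(d$H, 3)
  expect_equal(d$Hd, 1)

  same <- diversity_summary(seq_alignment(rep("ACGT", 4)))
  expect_equal(unlist(same[c("S", "k", "Pi", "Hd")]),
               c(S = 0, k = 0, Pi = 0, Hd = 0))
  expect_error(diversity_summary(seq_alignment("AAA")), "at least 2")
})

test_that("complete deletion removes gap/N columns before any index", {
  base <- toy_aln3()
  with_n <- seq_alignment(c("AAAN", "AATN", "ATTN"))
  with_gap <- seq_alignment(c("AA-A", "AA-T", "AT-T"))
  for (aug in list(with_n, with_gap)) {
    d0 <- diversity_summary(base); d1 <- diversity_summary(aug)
    expect_equal(d1$S, d0$S)
    expect_equal(d1$k, d0$k)
    expect_equal(d1$Pi, d0$Pi)   # L_effective excludes the masked column
    expect_equal(d1$Hd, d0$Hd)
  }
  expect_equal(tajimas_d(with_n)$D, tajimas_d(base)$D)
})

test_that("Tajima's D vanishes when k equals S/a1 and flags S = 0", {
  td <- tajimas_d(toy_aln3())
  expect_identical(td$D, 0)
  expect_identical(tajimas_d(seq_alignment(rep("AAAA", 5)))$significance,
                   "undefined")
  expect_true(is.na(tajimas_d(seq_alignment(rep("AAAA", 5)))$D))
  # sequence ids carry no information: relabelling leaves D unchanged
  a <- simulate_sequences(12, "constant", theta = 4, L = 300, seed = 17)
  b <- a; rownames(b$matrix) <- paste0("x", seq_len(12))
  expect_equal(tajimas_d(b)$D, tajimas_d(a)$D)
  # an excess of rare variants drives D negative
  grow <- simulate_sequences(40, "sudden_expansion", theta0 = 0.5,
                             theta1 = 200, tau = 4, L = 2000, seed = 18)
  expect_lt(tajimas_d(grow)$D, 0)
})

test_that("Fu and Li's D*/F* match the precomputed formula oracle", {
  # frozen from an independent evaluation of the published corrected
  # constants (eta, eta_s, k computed by hand on each toy)
  fl4 <- fu_li_stats(toy_aln4())
  expect_equal(fl4$eta, 3); expect_equal(fl4$eta_s, 2)
  expect_equal(fl4$Dstar, 0.1676557950, tolerance = 1e-9)
  expect_equal(fl4$Fstar, 0.1499234544, tolerance = 1e-9)
  fl5 <- fu_li_stats(toy_aln5())
  expect_equal(fl5$Dstar, 0.2734497665, tolerance = 1e-9)
  expect_equal(fl5$Fstar, 0.2783372502, tolerance = 1e-9)
  # no singletons at all: both statistics are positive
  fl0 <- fu_li_stats(toy_aln4_nosingleton())
  expect_equal(fl0$eta_s, 0)
  expect_equal(fl0$Dstar, 1.8930564477, tolerance = 1e-9)
  expect_gt(fl0$Fstar, 0)
  # S = 0 sentinel
  expect_true(is.na(fu_li_stats(seq_alignment(rep("AA", 4)))$Dstar))
  # the toy 3-sequence alignment is all singletons: both numerators vanish
  fl3 <- fu_li_stats(toy_aln3())
  expect_identical(fl3$Dstar, 0)
  expect_identical(fl3$Fstar, 0)
})

test_that("simulated significance classes flag expansion-like data", {
  grow <- simulate_sequences(60, "sudden_expansion", theta0 = 0.2,
                             theta1 = 300, tau = 6, L = 3000, seed = 19)
  fl <- fu_li_stats(grow, signif_reps = 300, seed = 20)
  expect_lt(fl$Dstar, 0)
  expect_true(fl$significance_Dstar %in% c("<0.01", "<0.02", "<0.05"))
})

test_that("the raggedness index uses the stated boundary convention", {
  expect_equal(raggedness_index(c(0.2, 0.5, 0.3)),
               0.3^2 + 0.2^2 + 0.3^2)
  expect_equal(raggedness_index(1), 1)  # all mass at zero differences
})

test_that("the expected mismatch curve is a proper distribution", {
  em <- expected_mismatch(200, 1, 100, 5)
  expect_true(all(em > -1e-12))
  expect_equal(sum(em), 1, tolerance = 1e-6)
  # tau = 0 collapses to the theta0 equilibrium geometric
  em0 <- expected_mismatch(50, 2, 100, 0)
  j <- 0:50
  expect_equal(em0, 2^j / 3^(j + 1), tolerance = 1e-12)
  # large tau approaches the theta1 equilibrium
  em_inf <- expected_mismatch(50, 2, 8, 200)
  expect_equal(em_inf, 8^j / 9^(j + 1), tolerance = 1e-6)
})

test_that("k equals the mean of the mismatch distribution exactly", {
  a <- simulate_sequences(15, "constant", theta = 6, L = 400, seed = 21)
  mm <- mismatch_distribution(a)
  expect_equal(sum(as.numeric(names(mm)) * mm), diversity_summary(a)$k)
})

test_that("mismatch analysis handles identical sequences and recovers fits", {
  flat <- mismatch_analysis(seq_alignment(rep("AAAA", 6)), B = 0)
  expect_equal(flat$SSD, 0)
  expect_equal(flat$p_SSD, 1)
  expect_equal(unname(flat$observed), 1)

  a <- simulate_sequences(50, "sudden_expansion", theta0 = 1, theta1 = 100,
                          tau = 5, L = 2000, seed = 22)
  fit <- mismatch_analysis(a, B = 0)
  expect_true(fit$theta0 <= fit$theta1)
  expect_gte(fit$SSD, 0)
  # fitted curve should track the observed unimodal distribution
  expect_lt(fit$SSD, 0.02)
  # tau in the right neighbourhood (mutational units)
  expect_gt(fit$tau, 1); expect_lt(fit$tau, 15)
})

test_that("bootstrap p-values accept data generated under the model", {
  a <- simulate_sequences(50, "sudden_expansion", theta0 = 1, theta1 = 100,
                          tau = 5, L = 2000, seed = 23)
  fit <- mismatch_analysis(a, B = 100, seed = 24)
  expect_gte(fit$p_SSD, 0.05)
  expect_true(fit$p_HRI >= 0 && fit$p_HRI <= 1)
})
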