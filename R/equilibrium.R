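#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional ("probability") test: genotype arrays compatible with
#' the observed allele counts follow the Levene/Haldane distribution, and the
#' p-value is the total probability mass of arrays no more probable than the
#' observed one -- the default exact HWE test of Genepop. The compatible
#' arrays are fully enumerated when there are at most `enumeration_limit` of
#' them (always the case for biallelic loci); otherwise the distribution is
#' sampled with `mc_reps` Monte-Carlo draws (shuffled gene-copy pairings) and
#' the add-one estimator `p = (1 + #{P <= P_obs}) / (mc_reps + 1)` is
#' reported, so a Monte-Carlo p-value is never below `1/(mc_reps + 1)`.
#'
#' A monomorphic locus has a single compatible array and p = 1.
#'
#' @param genotypes character vector of diploid cells `"a/b"` (NA dropped).
#' @param mc_reps Monte-Carlo draws when enumeration is infeasible.
#' @param seed optional integer seed (Monte-Carlo path).
#' @param enumeration_limit maximum number of arrays to enumerate.
#' @param bonferroni optional threshold from [bonferroni()] used to set the
#'   `significant` flag.
#' @param locus_id optional id stored on the result.
#' @return A `test_result` list: `locus`, `p_value`, `method`,
#'   `n_permutations`, `seed`, `bonferroni_threshold`, `significant`.
#' @export
hwe_exact <- function(genotypes, mc_reps = 1e5, seed = NULL,
                      enumeration_limit = 1e5, bonferroni = NULL,
                      locus_id = NA_character_) {
  genotypes <- genotypes[!is.na(genotypes)]
  parts <- strsplit(genotypes, "/", fixed = TRUE)
  if (any(lengths(parts) != 2L)) stop2("hwe_exact expects diploid genotypes")
  alleles <- sort_alleles(unique(unlist(parts)))
  K <- length(alleles)
  n <- length(parts)
  if (K == 1L)
    return(test_result(locus_id, 1, "exact_enumeration", NA, seed,
                       bonferroni))
  a1 <- match(vapply(parts, `[`, "", 1L), alleles)
  a2 <- match(vapply(parts, `[`, "", 2L), alleles)
  f <- matrix(0L, K, K)  # upper-triangle genotype counts
  for (i in seq_len(n)) {
    lo <- min(a1[i], a2[i]); hi <- max(a1[i], a2[i])
    f[lo, hi] <- f[lo, hi] + 1L
  }
  m_all <- tabulate(c(a1, a2), K)  # allele counts
  stat_obs <- hwe_stat(f)
  if (K == 2L) {
    # biallelic: arrays are indexed by the heterozygote count
    m1 <- min(m_all); h_obs <- f[1, 2]
    hs <- seq(m1 %% 2L, m1, by = 2L)
    stats <- hs * log(2) - lfactorial((m1 - hs) / 2) - lfactorial(hs) -
      lfactorial((max(m_all) - hs) / 2)
    w <- exp(stats - max(stats))
    p <- sum(w[stats <= stats[match(h_obs, hs)] + 1e-9]) / sum(w)
    return(test_result(locus_id, p, "exact_enumeration", NA, seed,
                       bonferroni))
  }
  arrays <- enumerate_hwe_arrays(m_all, n, enumeration_limit)
  if (!is.null(arrays)) {
    stats <- vapply(arrays, hwe_stat, 0)
    # log P(f) = const + h log 2 - sum lfactorial(f); const cancels
    logp <- stats - max(stats)
    w <- exp(logp)
    p <- sum(w[stats <= stat_obs + 1e-9]) / sum(w)
    return(test_result(locus_id, p, "exact_enumeration", NA, seed,
                       bonferroni))
  }
  cnt <- with_seed(seed, cpp_hwe_mc_count(c(a1, a2) - 1L, n, K,
                                          as.integer(mc_reps), stat_obs,
                                          1e-9))
  test_result(locus_id, (cnt + 1) / (mc_reps + 1), "monte_carlo", mc_reps,
              seed, bonferroni)
}

# array statistic: h log2 - sum lfactorial(f); P(f) proportional to exp(stat)
# once allele counts are fixed
hwe_stat <- function(f) {
  h <- sum(f[upper.tri(f)])
  h * log(2) - sum(lfactorial(f[f > 1L]))
}

# enumerate all genotype-count arrays with the given allele-count margins;
# NULL when more than `limit` arrays exist (decided by a cheap upper bound
# on the recursion size, so large tables are never visited)
enumerate_hwe_arrays <- function(m, n, limit) {
  K <- length(m)
  caps <- outer(m, m, pmin); diag(caps) <- m %/% 2L
  log_bound <- sum(log1p(caps[upper.tri(caps, diag = TRUE)]))
  if (log_bound > log(limit)) return(NULL)
  out <- vector("list", 0L)
  cells <- which(upper.tri(diag(K), diag = TRUE), arr.ind = TRUE)
  cells <- cells[order(cells[, 1], cells[, 2]), , drop = FALSE]
  nc <- nrow(cells)
  f <- matrix(0L, K, K)
  count <- 0L
  rec <- function(cell, rem) {
    if (count > limit) return(invisible())
    if (cell > nc) {
      if (all(rem == 0L)) {
        count <<- count + 1L
        if (count <= limit) out[[count]] <<- f
      }
      return(invisible())
    }
    i <- cells[cell, 1]; j <- cells[cell, 2]
    # remaining copies of allele i can only be placed in cells (i, j..K)
    cap <- if (i == j) rem[i] %/% 2L else min(rem[i], rem[j])
    for (x in 0:cap) {
      f[i, j] <<- x
      rem2 <- rem
      rem2[i] <- rem2[i] - if (i == j) 2L * x else x
      if (i != j) rem2[j] <- rem2[j] - x
      # allele i must be exhausted once its row is done
      if (j == K && rem2[i] != 0L) { f[i, j] <<- 0L; next }
      rec(cell + 1L, rem2)
      f[i, j] <<- 0L
      if (count > limit) return(invisible())
    }
  }
  rec(1L, m)
  if (count > limit) NULL else out
}

test_result <- function(locus, p, method, n_perm, seed, bonferroni) {
  thr <- if (is.null(bonferroni)) NA_real_
         else if (is.list(bonferroni)) bonferroni$threshold else bonferroni
  structure(list(locus = locus, p_value = p, method = method,
                 n_permutations = n_perm, seed = seed,
                 bonferroni_threshold = thr,
                 significant = if (is.na(thr)) NA else p < thr),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s test%s: p = %.4g (%s%s)\n",
              x$method,
              if (is.na(x$locus)) "" else paste0(" at ", x$locus),
              x$p_value,
              if (is.na(x$bonferroni_threshold)) "no threshold"
              else paste0("threshold ", signif(x$bonferroni_threshold, 3),
                          ", ", if (x$significant) "significant"
                                else "not significant"),
              ""))
  invisible(x)
}

#' Permutation test of linkage disequilibrium between two loci
#'
#' The association statistic is the G (likelihood-ratio) statistic of the
#' two-locus genotype contingency table -- the genotypic test appropriate
#' for unphased population data. The null distribution is built by permuting
#' one locus's genotypes across samples (margins fixed), and
#' `p = (1 + #{G_perm >= G_obs}) / (n_perm + 1)`, so p is never below
#' `1/(n_perm + 1)`. Fewer than two distinct genotypes at either locus gives
#' p = 1.
#'
#' @param g1,g2 genotype cells (any ploidy; compared as categories). Pairs
#'   with a missing call at either locus are dropped.
#' @param n_perm number of permutations (>= 100).
#' @param seed optional integer seed.
#' @param bonferroni optional threshold from [bonferroni()].
#' @param locus_pair optional label.
#' @return A `test_result`.
#' @export
ld_permutation <- function(g1, g2, n_perm = 1000, seed = NULL,
                           bonferroni = NULL, locus_pair = NA_character_) {
  stopifnot(n_perm >= 100)
  keep <- !is.na(g1) & !is.na(g2)
  g1 <- g1[keep]; g2 <- g2[keep]
  c1 <- as.integer(factor(g1)); c2 <- as.integer(factor(g2))
  k1 <- max(c1); k2 <- max(c2)
  if (k1 < 2L || k2 < 2L)
    return(test_result(locus_pair, 1, "permutation", n_perm, seed,
                       bonferroni))
  n <- length(c1)
  g_obs <- g_stat(c1, c2, k1, k2)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(r)
      g_stat(c1, c2[sample.int(n)], k1, k2), 0) >= g_obs - 1e-12)
  })
  test_result(locus_pair, (1 + exceed) / (n_perm + 1), "permutation",
              n_perm, seed, bonferroni)
}

g_stat <- function(c1, c2, k1, k2) {
  # column-major cell index to line up with as.vector(outer(...))
  o <- tabulate((c2 - 1L) * k1 + c1, k1 * k2)
  e <- as.vector(outer(tabulate(c1, k1), tabulate(c2, k2))) / length(c1)
  i <- o > 0L
  2 * sum(o[i] * log(o[i] / e[i]))
}

#' Bonferroni threshold with paper-style display value
#'
#' `alpha / m`, together with the rounded display form population reports
#' print (two significant digits, truncated to at most five decimal places:
#' 0.05/54 shows as 0.00093, 0.05/1431 as 0.00003, 0.05/27 as 0.0019).
#' Pairwise-test corrections conventionally use the number of unordered
#' locus pairs, `m = choose(L, 2)`.
#'
#' @param alpha familywise level.
#' @param m number of tests (>= 1).
#' @return List with `threshold` (exact), `display` (character), `alpha`, `m`.
#' @export
bonferroni <- function(alpha = 0.05, m = 1) {
  stopifnot(m >= 1, alpha > 0, alpha < 1)
  thr <- alpha / m
  disp <- signif(thr, 2)
  if (round(disp, 5) != disp) disp <- floor(thr * 1e5) / 1e5
  list(threshold = thr,
       display = format(disp, scientific = FALSE, trim = TRUE),
       alpha = alpha, m = m)
}
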