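#' Sequence diversity summary of a haploid alignment
#'
#' Complete-deletion convention: every column containing a gap or `N` in any
#' sequence is removed first (`L_effective` = retained sites), which keeps
#' S, k and Pi mutually consistent. Reports the number of sequences (N),
#' haplotype count (H) and haplotype diversity (Hd) over the retained-site
#' haplotypes, segregating sites (S), the mean number of pairwise
#' differences (k) and per-site nucleotide diversity (Pi = k / L_effective).
#'
#' @param aln a [seq_alignment()].
#' @return List of class `diversity_summary`.
#' @export
diversity_summary <- function(aln) {
  m <- complete_deletion(aln)
  n <- nrow(m)
  if (n < 2L) stop2("diversity summary requires at least 2 sequences")
  if (ncol(m) == 0L) stop2("no sites retained after complete deletion")
  poly <- which(colSums(m != rep(m[1, ], each = n)) > 0L)
  mm <- mismatch_counts_matrix(m, poly)
  k <- mean(mm[upper.tri(mm)])
  hap <- table(apply(m, 1, paste, collapse = ""))
  structure(list(N = n, H = length(hap),
                 Hd = haplotype_diversity(as.numeric(hap)),
                 S = length(poly), k = k, Pi = k / ncol(m),
                 L_effective = ncol(m)),
            class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat(sprintf(
    "N = %d  H = %d  Hd = %.4f  S = %d  k = %.3f  Pi = %.4f (L = %d)\n",
    x$N, x$H, x$Hd, x$S, x$k, x$Pi, x$L_effective))
  invisible(x)
}

# n x n matrix of pairwise difference counts; only polymorphic columns can
# contribute, so monomorphic ones are skipped up front
mismatch_counts_matrix <- function(m, poly = NULL) {
  n <- nrow(m)
  poly <- poly %||% which(colSums(m != rep(m[1, ], each = n)) > 0L)
  D <- matrix(0L, n, n)
  for (j in poly) D <- D + outer(m[, j], m[, j], "!=")
  D
}

#' Observed mismatch distribution
#'
#' Relative frequencies of pairwise difference counts 0..max over all
#' `N (N - 1) / 2` sequence pairs (complete-deletion sites).
#'
#' @param aln a [seq_alignment()].
#' @return Numeric vector named `0, 1, ...`; sums to 1.
#' @export
mismatch_distribution <- function(aln) {
  m <- complete_deletion(aln)
  d <- mismatch_counts_matrix(m)[upper.tri(diag(nrow(m)))]
  tab <- tabulate(d + 1L, max(d) + 1L)
  setNames(tab / sum(tab), 0:max(d))
}

#' Tajima's D with beta-approximation significance
#'
#' `D = (k - S/a1) / sqrt(e1 S + e2 S (S - 1))` with the standard constants
#' derived from the sample size. Significance uses the beta-distribution
#' approximation of D's null density on (Dmin, Dmax), reported as a
#' two-sided p-value and the conventional class (`"<0.01"`, `"<0.05"`,
#' `"ns"`). `S = 0` returns an undefined sentinel (`NA`), not 0.
#'
#' @param aln a [seq_alignment()].
#' @return List with `D`, `S`, `k`, `p_beta`, `significance`.
#' @export
tajimas_d <- function(aln) {
  ds <- diversity_summary(aln)
  n <- ds$N; S <- ds$S; k <- ds$k
  if (S == 0L)
    return(list(D = NA_real_, S = 0L, k = k, p_beta = NA_real_,
                significance = "undefined"))
  cst <- tajima_constants(n)
  num <- k - S / cst$a1
  den <- sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
  # at n = 3 the variance is identically 0 (k is determined by S) and the
  # numerator vanishes with it; the statistic is 0, not NaN
  D <- if (den == 0) {if (abs(num) < 1e-12) 0 else NA_real_} else num / den
  if (cst$e2 == 0)
    return(list(D = D, S = S, k = k, p_beta = NA_real_,
                significance = "undefined"))
  dmin <- (2 / n - 1 / cst$a1) / sqrt(cst$e2)
  dmax <- ((n / (2 * (n - 1))) - 1 / cst$a1) / sqrt(cst$e2)
  tmp1 <- 1 + dmin * dmax; tmp2 <- dmax - dmin
  shape_a <- -tmp1 * dmax / tmp2; shape_b <- tmp1 * dmin / tmp2
  cdf <- pbeta((D - dmin) / tmp2, shape_b, shape_a)
  p <- 2 * min(cdf, 1 - cdf)
  list(D = D, S = S, k = k, p_beta = p, significance = signif_class(p))
}

tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

signif_class <- function(p) {
  if (is.na(p)) "undefined"
  else if (p < 0.01) "<0.01"
  else if (p < 0.02) "<0.02"
  else if (p < 0.05) "<0.05"
  else "ns"
}

#' Fu and Li's D* and F* (outgroup-free) with simulated significance
#'
#' Uses the total number of mutations eta (multi-state retained columns
#' count states minus one) and the number of singleton mutations eta_s
#' (variants carried by exactly one sequence), with the corrected variance
#' constants of the outgroup-free statistics:
#' `D* = (n/(n-1) eta - a_n eta_s) / sqrt(u_D* eta + v_D* eta^2)` and
#' `F* = (k - (n-1)/n eta_s) / sqrt(u_F* eta + v_F* eta^2)`.
#' Significance classes are obtained by simulating the null distribution
#' under a constant-size coalescent at Watterson's theta (two-sided
#' empirical p; `signif_reps = 0` skips this).
#'
#' @param aln a [seq_alignment()].
#' @param signif_reps coalescent replicates for the significance classes.
#' @param seed optional integer seed for the significance simulation.
#' @return List with `Dstar`, `Fstar`, `eta`, `eta_s`, p-values and classes.
#' @export
fu_li_stats <- function(aln, signif_reps = 0, seed = NULL) {
  m <- complete_deletion(aln)
  n <- nrow(m)
  if (n < 3L) stop2("Fu and Li's statistics require at least 3 sequences")
  es <- eta_counts(m)
  if (es$eta == 0L)
    return(list(Dstar = NA_real_, Fstar = NA_real_, eta = 0L, eta_s = 0L,
                p_Dstar = NA_real_, p_Fstar = NA_real_,
                significance_Dstar = "undefined",
                significance_Fstar = "undefined"))
  k <- mean(mismatch_counts_matrix(m)[upper.tri(diag(n))])
  v <- fu_li_values(n, es$eta, es$eta_s, k)
  out <- list(Dstar = v$Dstar, Fstar = v$Fstar,
              eta = es$eta, eta_s = es$eta_s,
              p_Dstar = NA_real_, p_Fstar = NA_real_,
              significance_Dstar = NA_character_,
              significance_Fstar = NA_character_)
  if (signif_reps > 0) {
    a1 <- sum(1 / seq_len(n - 1))
    theta_w <- es$eta / a1
    null_d <- null_f <- numeric(signif_reps)
    with_seed(seed, {
      for (r in seq_len(signif_reps)) {
        sim <- simulate_sequences(n, "constant", theta = theta_w,
                                  L = max(1000L, 20L * es$eta))
        sm <- sim$matrix
        se <- eta_counts(sm)
        if (se$eta == 0L) { null_d[r] <- 0; null_f[r] <- 0; next }
        sk <- mean(mismatch_counts_matrix(sm)[upper.tri(diag(n))])
        sv <- fu_li_values(n, se$eta, se$eta_s, sk)
        null_d[r] <- sv$Dstar; null_f[r] <- sv$Fstar
      }
    })
    emp_p <- function(null, obs)
      2 * min((1 + sum(null <= obs)), (1 + sum(null >= obs))) /
        (length(null) + 1)
    out$p_Dstar <- min(1, emp_p(null_d, v$Dstar))
    out$p_Fstar <- min(1, emp_p(null_f, v$Fstar))
    out$significance_Dstar <- signif_class(out$p_Dstar)
    out$significance_Fstar <- signif_class(out$p_Fstar)
  }
  out
}

# eta (total mutations) and eta_s (singleton mutations) under complete
# deletion; a column's mutations = #states - 1, its singletons = #states
# observed in exactly one sequence (capped by the mutation count)
eta_counts <- function(m) {
  eta <- 0L; eta_s <- 0L
  poly <- which(colSums(m != rep(m[1, ], each = nrow(m))) > 0L)
  for (j in poly) {
    tab <- tabulate(factor(m[, j]))
    eta <- eta + length(tab) - 1L
    eta_s <- eta_s + min(sum(tab == 1L), length(tab) - 1L)
  }
  list(eta = eta, eta_s = eta_s)
}

fu_li_values <- function(n, eta, eta_s, k) {
  i <- seq_len(n - 1)
  an <- sum(1 / i); bn <- sum(1 / i^2); an1 <- an + 1 / n
  cn <- if (n == 2) 1 else 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (1.5 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vds <- ((n / (n - 1))^2 * bn + an^2 * dn -
            2 * (n * an * (an + 1)) / (n - 1)^2) / (an^2 + bn)
  uds <- (n / (n - 1)) * (an - n / (n - 1)) - vds
  vfs <- ((2 * n^3 + 110 * n^2 - 255 * n + 153) / (9 * n^2 * (n - 1)) +
            (2 * (n - 1) * an) / n^2 - 8 * bn / n) / (an^2 + bn)
  ufs <- ((4 * n^2 + 19 * n + 3 - 12 * (n + 1) * an1) /
            (3 * n * (n - 1))) / an - vfs
  den_d <- sqrt(uds * eta + vds * eta^2)
  den_f <- sqrt(ufs * eta + vfs * eta^2)
  num_d <- (n / (n - 1)) * eta - an * eta_s
  num_f <- k - ((n - 1) / n) * eta_s
  list(Dstar = if (den_d == 0) {if (num_d == 0) 0 else NA_real_}
               else num_d / den_d,
       Fstar = if (den_f == 0) {if (num_f == 0) 0 else NA_real_}
               else num_f / den_f)
}

#' Expected mismatch distribution under the sudden-expansion model
#'
#' Rogers-Harpending expectation for pairwise difference counts when a
#' population of scaled size `theta0` grew instantaneously to `theta1` at
#' `tau` mutational time units ago:
#' `F_j = Fhat_j(theta1) + exp(-tau (theta1 + 1)/theta1) *
#'   sum_i Pois(i; tau) (Fhat_{j-i}(theta0) - Fhat_{j-i}(theta1))`
#' with `Fhat_j(theta) = theta^j / (1 + theta)^{j+1}` the equilibrium
#' geometric distribution.
#'
#' @param jmax largest difference class.
#' @param theta0,theta1,tau model parameters (theta0 <= theta1).
#' @return Numeric vector of expected frequencies for classes `0..jmax`.
#' @export
expected_mismatch <- function(jmax, theta0, theta1, tau) {
  j <- 0:jmax
  fhat <- function(theta) {
    if (theta == 0) return(c(1, rep(0, jmax)))
    exp(j * log(theta) - (j + 1) * log1p(theta))
  }
  f1 <- fhat(theta1); f0 <- fhat(theta0)
  if (theta1 == 0) return(f1)
  pois <- exp(-tau) * tau^j / factorial(j)
  if (tau == 0) pois <- c(1, rep(0, jmax))
  conv <- vapply(j, function(jj)
    sum(pois[1:(jj + 1)] * (f0[(jj + 1):1] - f1[(jj + 1):1])), 0)
  f1 + exp(-tau / theta1) * conv
}

#' Harpending's raggedness index
#'
#' `r = sum_{i=1}^{d+1} (x_i - x_{i-1})^2` over the observed mismatch class
#' frequencies `x_0..x_d`, with the boundary convention `x_{d+1} = 0`.
#'
#' @param x mismatch class frequencies.
#' @return Numeric raggedness.
#' @export
raggedness_index <- function(x) {
  x <- c(x, 0)
  sum(diff(x)^2)
}

#' Mismatch-distribution expansion analysis
#'
#' Fits the sudden-expansion model (theta0, theta1, tau) to the observed
#' mismatch distribution by least squares (moment-seeded grid search plus
#' Nelder-Mead refinement), then assesses goodness of fit with the sum of
#' squared deviations (SSD) and Harpending's raggedness index via a
#' parametric bootstrap: `B` coalescent datasets are simulated under the
#' fitted expansion model (same sample size), each is refitted, and the
#' p-values are the fractions of replicates whose statistic is at least the
#' observed one. A sample of identical sequences yields the degenerate fit
#' (SSD = 0, p = 1).
#'
#' @param aln a [seq_alignment()].
#' @param B parametric-bootstrap replicates (>= 100 recommended).
#' @param seed optional integer seed.
#' @return Object of class `expansion_fit` with elements `theta0`, `theta1`,
#'   `tau`, `observed`, `expected`, `SSD`, `p_SSD`, `HRI`, `p_HRI`, `B`,
#'   `seed`.
#' @export
mismatch_analysis <- function(aln, B = 100, seed = NULL) {
  m <- complete_deletion(aln)
  n <- nrow(m)
  if (n < 3L) stop2("mismatch analysis requires at least 3 sequences")
  obs <- mismatch_distribution(aln)
  if (length(obs) == 1L) {
    return(structure(list(theta0 = 0, theta1 = 0, tau = 0, observed = obs,
                          expected = 1, SSD = 0, p_SSD = 1,
                          HRI = raggedness_index(obs), p_HRI = 1, B = B,
                          seed = seed),
                     class = "expansion_fit"))
  }
  fit <- fit_expansion(obs)
  hri <- raggedness_index(obs)
  out <- structure(c(fit, list(observed = obs, HRI = hri,
                               p_SSD = NA_real_, p_HRI = NA_real_,
                               B = B, seed = seed)),
                   class = "expansion_fit")
  if (B > 0) {
    with_seed(seed, {
      ssd_b <- hri_b <- numeric(B)
      for (r in seq_len(B)) {
        sim <- sim_expansion_retry(n, fit$theta0, fit$theta1, fit$tau)
        ob <- mismatch_distribution(sim)
        ssd_b[r] <- if (length(ob) == 1L) 0 else fit_expansion(ob)$SSD
        hri_b[r] <- raggedness_index(ob)
      }
      out$p_SSD <- mean(ssd_b >= fit$SSD - 1e-15)
      out$p_HRI <- mean(hri_b >= hri - 1e-15)
    })
  }
  out
}

#' @export
print.expansion_fit <- function(x, ...) {
  cat(sprintf(
    "expansion fit: theta0 = %.3g, theta1 = %.3g, tau = %.3g\n",
    x$theta0, x$theta1, x$tau))
  cat(sprintf("  SSD = %.5f (p = %s)   raggedness = %.5f (p = %s)\n",
              x$SSD, format(x$p_SSD), x$HRI, format(x$p_HRI)))
  invisible(x)
}

# least-squares fit of (theta0, theta1, tau) to a mismatch distribution
fit_expansion <- function(obs) {
  jmax <- length(obs) - 1L
  mbar <- sum((0:jmax) * obs)
  ssd_of <- function(t0, t1, tau) {
    e <- expected_mismatch(jmax, t0, t1, tau)
    sum((obs - e)^2)
  }
  # moment-seeded grid (Arlequin-style initialisation around the mean)
  grid <- expand.grid(t0 = c(0.01, 0.5, 1, max(0.1, mbar / 2)),
                      t1 = c(10, 100, 1000, 10000),
                      tau = unique(pmax(0.05, mbar * c(0.25, 0.5, 1, 1.5))))
  grid <- grid[grid$t1 >= grid$t0, ]
  ssd_g <- mapply(ssd_of, grid$t0, grid$t1, grid$tau)
  best <- grid[which.min(ssd_g), ]
  # refine on an unconstrained scale enforcing 0 <= theta0 <= theta1
  objective <- function(par) {
    t0 <- exp(par[1]); t1 <- t0 + exp(par[2]); tau <- exp(par[3])
    ssd_of(t0, t1, tau)
  }
  start <- c(log(best$t0), log(max(best$t1 - best$t0, 1e-3)), log(best$tau))
  opt <- optim(start, objective, method = "Nelder-Mead",
               control = list(maxit = 200, reltol = 1e-9))
  t0 <- exp(opt$par[1]); t1 <- t0 + exp(opt$par[2]); tau <- exp(opt$par[3])
  list(theta0 = t0, theta1 = t1, tau = tau,
       expected = expected_mismatch(jmax, t0, t1, tau), SSD = opt$value)
}

# simulate under the fitted expansion, growing L if the draw produces more
# segregating sites than fit
sim_expansion_retry <- function(n, theta0, theta1, tau, L = 2000L) {
  for (i in 1:6) {
    sim <- tryCatch(simulate_sequences(n, "sudden_expansion",
                                       theta0 = theta0, theta1 = theta1,
                                       tau = tau, L = L),
                    error = function(e) NULL)
    if (!is.null(sim)) return(sim)
    L <- L * 4L
  }
  stop2("could not accommodate simulated segregating sites")
}
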