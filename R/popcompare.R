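#' Population-by-category frequency matrix
#'
#' Rows are populations, columns are categories (haplogroups, or the alleles
#' of one marker); each row sums to 1. Per-population sample sizes (numbers
#' of sampled haploid gene copies) accompany the frequencies.
#'
#' @param freq numeric matrix (populations x categories) with rownames.
#' @param sizes per-population sample sizes (>= 1), recycled.
#' @return Object of class `pop_freq_matrix`.
#' @export
pop_freq_matrix <- function(freq, sizes) {
  freq <- as.matrix(freq)
  if (is.null(rownames(freq)))
    rownames(freq) <- paste0("pop", seq_len(nrow(freq)))
  if (any(abs(rowSums(freq) - 1) > 1e-9))
    stop2("each population row must sum to 1")
  sizes <- rep_len(sizes, nrow(freq))
  if (any(sizes < 1)) stop2("population sizes must be >= 1")
  structure(list(freq = freq, sizes = setNames(sizes, rownames(freq))),
            class = "pop_freq_matrix")
}

#' Pairwise FST between populations from category frequencies
#'
#' Heterozygosity-based estimators treating the categories as alleles of one
#' haploid locus. The default (`"hudson"`) is `1 - H_S / H_B`, where `H_S`
#' is the mean unbiased within-population gene diversity
#' (`n/(n-1) (1 - sum p^2)`) and `H_B = 1 - sum p_i q_i` the probability
#' that haplotypes drawn from the two populations differ; its expectation
#' recovers the Balding-Nichols divergence parameter without a
#' number-of-demes correction. `"nei_gst"` is the classical
#' `(H_T - H_S)/H_T` with `H_T` from size-weighted pooled frequencies,
#' which for two demes systematically reads about half the divergence
#' parameter. Negative estimates are floored at 0 in the reported matrix;
#' the raw values are retained. The estimator name is recorded on the
#' result so alternates can be compared.
#'
#' A list of `pop_freq_matrix` objects (loci) is combined by the
#' ratio-of-sums rule over the per-locus diversity components.
#'
#' @param m a [pop_freq_matrix()], or a list of them (multi-locus).
#' @param method `"hudson"` or `"nei_gst"`.
#' @return Object of class `fst_matrix`: `fst` (floored), `raw`, `method`.
#' @export
pairwise_fst <- function(m, method = c("hudson", "nei_gst")) {
  method <- match.arg(method)
  loci <- if (inherits(m, "pop_freq_matrix")) list(m) else m
  stopifnot(length(loci) >= 1L, all(vapply(loci, inherits, TRUE,
                                           "pop_freq_matrix")))
  pops <- rownames(loci[[1]]$freq)
  if (length(pops) < 2L) stop2("need at least 2 populations")
  K <- length(pops)
  raw <- matrix(0, K, K, dimnames = list(pops, pops))
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    num <- den <- 0
    for (lc in loci) {
      pi <- lc$freq[i, ]; pj <- lc$freq[j, ]
      ni <- lc$sizes[i]; nj <- lc$sizes[j]
      hw <- mean(c(ni / (ni - 1) * (1 - sum(pi^2)),
                   nj / (nj - 1) * (1 - sum(pj^2))))
      if (method == "hudson") {
        hb <- 1 - sum(pi * pj)
        num <- num + (hb - hw); den <- den + hb
      } else {
        pbar <- (ni * pi + nj * pj) / (ni + nj)
        ht <- 1 - sum(pbar^2)
        num <- num + (ht - hw); den <- den + ht
      }
    }
    raw[i, j] <- raw[j, i] <- if (den > 0) num / den else 0
  }
  structure(list(fst = pmax(raw, 0), raw = raw, method = method),
            class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, ...) {
  cat("pairwise FST (", x$method, " estimator):\n", sep = "")
  print(round(x$fst, 4))
  invisible(x)
}

#' Z-score standardisation of category frequencies across populations
#'
#' Each category (column) is standardised to mean 0 and sd 1 across the
#' populations (n-1 sd); a constant column becomes all zeros by convention.
#' This is the usual normalisation behind haplogroup-frequency heat maps.
#'
#' @param m a [pop_freq_matrix()] (or plain matrix).
#' @return Numeric matrix of Z scores, same dimensions.
#' @export
zscore_matrix <- function(m) {
  f <- if (inherits(m, "pop_freq_matrix")) m$freq else as.matrix(m)
  if (nrow(f) < 2L) stop2("need at least 2 populations")
  apply(f, 2, function(col) {
    s <- sd(col)
    if (s == 0) rep(0, length(col)) else (col - mean(col)) / s
  })
}

#' Rosenberg's informativeness for assignment (I_n)
#'
#' For one marker typed in K populations,
#' `I_n = sum_alleles [ -pbar log(pbar) + (1/K) sum_pops p log(p) ]`
#' with `pbar` the unweighted across-population mean frequency and the
#' convention `0 log 0 = 0`. Natural-log units (nats); 0 for identical
#' populations and bounded above by `log(K)`.
#'
#' @param p matrix (populations x alleles) of allele frequencies for one
#'   marker; rows sum to 1.
#' @return Numeric I_n.
#' @export
informativeness_in <- function(p) {
  p <- as.matrix(p)
  if (nrow(p) < 2L) stop2("need at least 2 populations")
  if (any(abs(rowSums(p) - 1) > 1e-9)) stop2("rows must sum to 1")
  xlx <- function(x) ifelse(x > 0, x * log(x), 0)
  pbar <- colMeans(p)
  sum(-xlx(pbar) + colMeans(xlx(p)))
}

#' Rank markers by informativeness for assignment
#'
#' @param marker_freqs named list of per-marker frequency matrices
#'   (populations x alleles).
#' @return Named numeric vector of I_n values, sorted descending.
#' @export
informativeness_ranking <- function(marker_freqs) {
  sort(vapply(marker_freqs, informativeness_in, 0), decreasing = TRUE)
}
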