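#' Draw synthetic allele frequency spectra
#'
#' One symmetric Dirichlet(alpha) draw per locus over `k` alleles. Larger
#' `alpha` gives flatter spectra (alpha -> Inf approaches equifrequent
#' alleles); alpha = 1 is uniform on the simplex and gives realistically
#' uneven STR-like spectra. Deterministic given `seed`.
#'
#' @param n_loci number of loci.
#' @param k alleles per locus (>= 2); scalar or vector.
#' @param alpha Dirichlet concentration (> 0).
#' @param marker_class marker class recorded on the result.
#' @param seed optional integer seed.
#' @param locus_prefix prefix for generated locus ids.
#' @return A [freq_table()] with parametric (infinite) gene counts.
#' @export
sample_allele_freqs <- function(n_loci = 1, k = 10, alpha = 1,
                                marker_class = "autosomal_str", seed = NULL,
                                locus_prefix = "L") {
  stopifnot(all(k >= 2), alpha > 0, n_loci >= 1)
  k <- rep_len(k, n_loci)
  with_seed(seed, {
    freqs <- lapply(seq_len(n_loci), function(i) {
      g <- rgamma(k[i], shape = alpha)
      # guard against exact zeros from tiny alpha
      while (sum(g) == 0 || any(g / sum(g) <= 0)) g <- rgamma(k[i], alpha)
      p <- g / sum(g)
      # STR-style integer allele labels for STRs, letters for SNPs
      labs <- if (k[i] == 2 && grepl("snp", marker_class))
        c("A", "C") else as.character(seq(8, length.out = k[i]))
      setNames(p, labs)
    })
    names(freqs) <- sprintf("%s%03d", locus_prefix, seq_len(n_loci))
    counts <- lapply(freqs, function(p) rep(NA_real_, length(p)))
    freq_table(freqs, n = Inf, marker_class = marker_class, counts = counts)
  })
}

#' Balding-Nichols derived population frequency
#'
#' Draws a descendant-population allele frequency around an ancestral value
#' `p` at divergence `fst`: Beta(p(1-fst)/fst, (1-p)(1-fst)/fst), whose mean
#' is p and variance fst*p*(1-p). `fst = 0` returns `p` exactly; boundary
#' frequencies 0 and 1 are returned unchanged (fixed alleles stay fixed).
#'
#' @param p ancestral allele frequency (vectorised).
#' @param fst divergence parameter in `[0, 1)`.
#' @param seed optional integer seed.
#' @return Numeric vector of derived frequencies.
#' @export
balding_nichols_freq <- function(p, fst, seed = NULL) {
  stopifnot(all(p >= 0), all(p <= 1), fst >= 0, fst < 1)
  if (fst == 0) return(p)
  with_seed(seed, {
    out <- p
    inner <- p > 0 & p < 1
    scale <- (1 - fst) / fst
    out[inner] <- rbeta(sum(inner), p[inner] * scale,
                        (1 - p[inner]) * scale)
    out
  })
}

#' Simulate Hardy-Weinberg genotypes from a frequency table
#'
#' Diploid genotypes are two independent gene copies; X loci give one copy to
#' males; Y loci give one copy to males only (females are missing, not an
#' error). Deterministic given `seed`.
#'
#' @param freqs a [freq_table()].
#' @param n_samples number of individuals.
#' @param sexes per-sample sexes (recycled); default alternates male/female.
#' @param population population label for the simulated samples.
#' @param seed optional integer seed.
#' @return A [genotype_table()].
#' @export
simulate_genotypes <- function(freqs, n_samples, sexes = NULL,
                               population = "sim", seed = NULL) {
  stopifnot(inherits(freqs, "freq_table"), n_samples >= 1)
  sexes <- rep_len(sexes %||% c("male", "female"), n_samples)
  fl <- freq_split(freqs)
  cls <- attr(freqs, "marker_class")
  with_seed(seed, {
    g <- matrix(NA_character_, n_samples, length(fl))
    for (j in seq_along(fl)) {
      p <- fl[[j]]
      labs <- names(p)
      mc <- cls[[names(fl)[j]]]
      a1 <- labs[sample.int(length(p), n_samples, TRUE, p)]
      a2 <- labs[sample.int(length(p), n_samples, TRUE, p)]
      cell <- paste(pmin_allele(a1, a2), pmax_allele(a1, a2), sep = "/")
      if (mc %in% c("autosomal_str", "autosomal_snp")) {
        g[, j] <- cell
      } else if (mc == "x_str") {
        g[, j] <- ifelse(sexes == "male", a1, cell)
      } else {
        g[, j] <- ifelse(sexes == "male", a1, NA_character_)
      }
    }
    genotype_table(
      data.frame(sample_id = sprintf("S%05d", seq_len(n_samples)),
                 population = population, sex = sexes,
                 stringsAsFactors = FALSE),
      data.frame(locus_id = names(fl), marker_class = unname(cls[names(fl)]),
                 stringsAsFactors = FALSE),
      g)
  })
}

# elementwise allele-label min/max under the numeric-aware ordering
pmin_allele <- function(a, b) {
  sw <- allele_lt(b, a)
  out <- a; out[sw] <- b[sw]; out
}
pmax_allele <- function(a, b) {
  sw <- allele_lt(b, a)
  out <- b; out[sw] <- a[sw]; out
}
allele_lt <- function(a, b) {
  na <- suppressWarnings(as.numeric(a)); nb <- suppressWarnings(as.numeric(b))
  both <- !is.na(na) & !is.na(nb)
  ifelse(both, na < nb,
         ifelse(!is.na(na), TRUE, ifelse(!is.na(nb), FALSE, a < b)))
}
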