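#' Pairwise kinship likelihood ratio at one or more loci
#'
#' LR of a tested relationship (IBD coefficients k0, k1, k2) against
#' unrelatedness for a genotype pair:
#' `LR = [k0 P(g2) + k1 P(g2 | g1, 1 IBD) + k2 P(g2 | g1, 2 IBD)] / P(g2)`,
#' with Hardy-Weinberg genotype probabilities and the standard conditional
#' transition probabilities (the shared IBD allele is a uniformly chosen
#' allele of g1; the non-shared allele is an independent population draw).
#' Loci are combined by the product rule (independence assumed). Missing
#' genotypes skip the locus; an allele absent from the frequency table is an
#' error unless a minimum-frequency floor is supplied.
#'
#' @param g1,g2 named character vectors of diploid cells (`locus -> "a/b"`).
#' @param freqs a [freq_table()] covering the loci.
#' @param model a [kinship_model()].
#' @param min_freq optional frequency floor substituted for alleles absent
#'   from `freqs` (forensic practice uses 5/(2N)); `NULL` errors instead.
#' @return List with `LR`, `log10_LR`, and the per-locus LR vector.
#' @export
pair_likelihood_ratio <- function(g1, g2, freqs, model, min_freq = NULL) {
  stopifnot(inherits(freqs, "freq_table"))
  loci <- intersect(names(g1), names(g2))
  if (length(loci) == 0L) stop2("no shared loci between the genotypes")
  fl <- freq_split(freqs)
  per <- setNames(numeric(0), character(0))
  for (l in loci) {
    if (is.na(g1[[l]]) || is.na(g2[[l]])) next
    a <- cell_alleles(g1[[l]]); b <- cell_alleles(g2[[l]])
    if (length(a) != 2L || length(b) != 2L)
      stop2("kinship LRs need diploid genotypes (locus ", l, ")")
    p <- fl[[l]]
    miss <- setdiff(c(a, b), names(p))
    if (length(miss)) {
      if (is.null(min_freq))
        stop2("allele(s) ", paste(miss, collapse = ", "),
              " absent from the frequency table at locus ", l,
              "; supply min_freq (e.g. 5/(2N)) to floor rare alleles")
      p <- c(p, setNames(rep(min_freq, length(miss)), miss))
      p <- p / sum(p)
    }
    per[l] <- lr_locus(a[1], a[2], b[1], b[2], p, model$k)
  }
  if (length(per) == 0L) stop2("all shared loci are missing")
  list(LR = prod(per), log10_LR = sum(log10(per)), per_locus = per)
}

# vectorised single-locus LR over many pairs (allele labels, frequency
# lookup vector p)
lr_locus <- function(a1, a2, b1, b2, p, k) {
  px <- p[b1]; py <- p[b2]
  hom2 <- b1 == b2
  p0 <- ifelse(hom2, px * py, 2 * px * py)
  p2 <- (a1 == b1 & a2 == b2) | (a1 == b2 & a2 == b1)
  term <- function(s)
    ifelse(hom2, (s == b1) * px, (s == b1) * py + (s == b2) * px)
  p1 <- 0.5 * term(a1) + 0.5 * term(a2)
  unname((k[["k0"]] * p0 + k[["k1"]] * p1 + k[["k2"]] * p2) / p0)
}

#' Monte-Carlo likelihood-ratio study for kinship testing
#'
#' Simulates `n_pairs` genotype pairs under `true_model` by gene dropping
#' (see [simulate_relative_pairs()]), evaluates each pair's combined LR for
#' `test_model` versus unrelated under locus independence, and reports the
#' log10 LR sample together with the exceedance probability at `threshold`
#' for each requested marker set. This mirrors the familiar
#' full-sibling/half-sibling simulation studies used to assess panels for
#' complex kinship casework.
#'
#' @param freqs a [freq_table()].
#' @param true_model,test_model [kinship_model()]s (generating and tested).
#' @param n_pairs simulated pairs per study.
#' @param threshold decision threshold on the LR scale (default 1e4).
#' @param seed optional integer seed.
#' @param marker_sets named list of locus-id vectors; default one set with
#'   every locus of `freqs`.
#' @param linkage_map optional map passed to the simulator (LRs still assume
#'   locus independence, as forensic software does).
#' @return Object of class `lr_study`: per-set `log10_lr` samples,
#'   `exceedance` probabilities, the realised IBD summary, and the settings.
#' @export
run_lr_study <- function(freqs, true_model, test_model, n_pairs = 1000,
                         threshold = 1e4, seed = NULL, marker_sets = NULL,
                         linkage_map = NULL) {
  fl <- freq_split(freqs)
  loci <- names(fl)
  marker_sets <- marker_sets %||% setNames(list(loci), "all")
  stopifnot(all(unlist(marker_sets) %in% loci))
  pairs <- simulate_relative_pairs(freqs, true_model$name, n_pairs,
                                   linkage_map = linkage_map, seed = seed)
  loglr <- matrix(0, n_pairs, length(loci), dimnames = list(NULL, loci))
  for (j in seq_along(loci)) {
    loglr[, j] <- log10(lr_locus(pairs$a1_1[, j], pairs$a1_2[, j],
                                 pairs$a2_1[, j], pairs$a2_2[, j],
                                 fl[[j]], test_model$k))
  }
  log10_lr <- lapply(marker_sets, function(set)
    rowSums(loglr[, set, drop = FALSE]))
  structure(list(
    log10_lr = log10_lr,
    exceedance = vapply(log10_lr, function(x)
      exceedance_probability(10^x, threshold), 0),
    threshold = threshold, n_pairs = n_pairs,
    true_model = true_model$name, test_model = test_model$name,
    ibd_proportions = prop.table(tabulate(pairs$ibd + 1L, 3L)),
    seed = seed), class = "lr_study")
}

#' @export
print.lr_study <- function(x, ...) {
  cat(sprintf("lr_study: %d pairs, true = %s, tested = %s, threshold = %g\n",
              x$n_pairs, x$true_model, x$test_model, x$threshold))
  for (s in names(x$log10_lr))
    cat(sprintf("  %s: median log10 LR %.2f, exceedance %.4f\n", s,
                median(x$log10_lr[[s]]), x$exceedance[[s]]))
  invisible(x)
}

#' Fraction of likelihood ratios above a decision threshold
#'
#' @param lrs LR sample (LR scale, not log).
#' @param threshold decision threshold.
#' @return `#\{LR > threshold\} / N`.
#' @export
exceedance_probability <- function(lrs, threshold) {
  if (length(lrs) == 0L) stop2("empty LR sample")
  mean(lrs > threshold)
}
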