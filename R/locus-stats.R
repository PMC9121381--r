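#' Per-locus forensic descriptive parameters
#'
#' Computes the standard forensic efficiency bundle for one autosomal locus:
#' observed heterozygosity (Hobs), plain expected heterozygosity
#' (He = 1 - sum p^2), Nei's gene diversity (GD = n He / (n - 1) over n gene
#' copies), polymorphism information content (PIC), match probability (PM),
#' power of discrimination (PD = 1 - PM), probability of exclusion (PE) and
#' typical paternity index (TPI = 1 / (2 (1 - Hobs))).
#'
#' PM defaults to the observed-genotype convention (the sum of squared
#' observed genotype-class frequencies, as computed by the STRAF/PowerStats
#' family of tools); the Hardy-Weinberg expected form is available with
#' `pm = "expected"`. PE follows the STRAF convention
#' `Hobs^2 (1 - 2 Hobs Hom^2)` with `Hom = 1 - Hobs`. With frequency-only
#' input the genotype-based quantities (Hobs, observed PM, PE, TPI) are `NA`
#' and PM is the expected form.
#'
#' A monomorphic locus yields Hobs = 0, He = 0, PIC = 0, PM = 1, PD = 0,
#' PE = 0, TPI = 0.5; a fully heterozygous locus reports `TPI = Inf`.
#'
#' @param genotypes character vector of diploid cells `"a/b"` (NA = missing),
#'   or NULL when `freqs` is given.
#' @param freqs named numeric allele frequency vector (used instead of
#'   counting from genotypes).
#' @param n gene count accompanying `freqs`.
#' @param pm `"observed"` or `"expected"` match probability.
#' @param locus_id optional id stored on the result.
#' @return One-row data frame of class `forensic_locus_summary`.
#' @export
locus_forensic_summary <- function(genotypes = NULL, freqs = NULL, n = NULL,
                                   pm = c("observed", "expected"),
                                   locus_id = NA_character_) {
  pm <- match.arg(pm)
  if (is.null(genotypes) && is.null(freqs))
    stop2("supply genotypes or freqs")
  hobs <- pe <- tpi <- pm_val <- NA_real_
  if (!is.null(genotypes)) {
    genotypes <- genotypes[!is.na(genotypes)]
    if (length(genotypes) < 2L && is.null(freqs))
      stop2("need at least 2 observed genotypes")
    parts <- strsplit(genotypes, "/", fixed = TRUE)
    if (any(lengths(parts) != 2L))
      stop2("locus_forensic_summary expects diploid genotypes")
    hobs <- mean(vapply(parts, function(a) a[1] != a[2], TRUE))
    gf <- table(genotypes) / length(genotypes)
    if (pm == "observed") pm_val <- sum(gf^2)
    if (is.null(freqs)) {
      cnt <- table(unlist(parts))
      n <- sum(cnt)
      freqs <- setNames(as.numeric(cnt) / n, names(cnt))
    }
    hom <- 1 - hobs
    pe <- hobs^2 * (1 - 2 * hobs * hom^2)
    tpi <- if (hom == 0) Inf else 1 / (2 * hom)
  }
  if (is.null(n)) stop2("gene count n required with frequency input")
  s2 <- sum(freqs^2); s4 <- sum(freqs^4)
  he <- 1 - s2
  gd <- if (is.finite(n)) n * he / (n - 1) else he
  pic <- 1 - s2 - s2^2 + s4
  if (is.na(pm_val))
    pm_val <- sum(freqs^4) + sum((2 * outer(freqs, freqs))[upper.tri(
      diag(length(freqs)))]^2)
  structure(
    data.frame(locus = locus_id, n_copies = n, Hobs = hobs, He = he,
               GD = gd, PIC = pic, PM = pm_val, PD = 1 - pm_val, PE = pe,
               TPI = tpi, stringsAsFactors = FALSE),
    class = c("forensic_locus_summary", "data.frame"))
}

#' Forensic summary of every autosomal locus in a genotype table
#'
#' @param x a [genotype_table()].
#' @param loci optional locus subset (default: all autosomal loci).
#' @param population optional population restriction.
#' @inheritParams locus_forensic_summary
#' @return Data frame with one row per locus.
#' @export
panel_forensic_summary <- function(x, loci = NULL, population = NULL,
                                   pm = c("observed", "expected")) {
  pm <- match.arg(pm)
  auto <- x$loci$locus_id[x$loci$marker_class %in%
                            c("autosomal_str", "autosomal_snp")]
  loci <- loci %||% auto
  keep <- if (is.null(population)) rep(TRUE, nrow(x$samples))
          else x$samples$population %in% population
  out <- do.call(rbind, lapply(loci, function(l)
    locus_forensic_summary(x$genotypes[keep, l], pm = pm, locus_id = l)))
  rownames(out) <- NULL
  out
}

#' Haplotype diversity
#'
#' `HD = n (1 - sum p_i^2) / (n - 1)` over haplotype frequencies, the
#' unbiased gene-diversity form; equals 1 when all n haplotypes are distinct
#' and 0 when all are identical.
#'
#' @param counts haplotype counts (or frequencies when `n` given).
#' @param n sample size; defaults to `sum(counts)`.
#' @return Numeric HD in `[0, 1]`.
#' @export
haplotype_diversity <- function(counts, n = NULL) {
  if (is.null(n)) {
    n <- sum(counts)
    p <- counts / n
  } else p <- counts / sum(counts)
  if (n < 2) stop2("haplotype diversity requires n >= 2")
  n * (1 - sum(p^2)) / (n - 1)
}

#' Gene diversity of a haploid (Y or mtDNA) locus
#'
#' Nei and Tajima's unbiased gene diversity `n (1 - sum p_i^2) / (n - 1)`
#' over haploid allele frequencies; multi-copy Y combinations are single
#' alleles.
#'
#' @param freqs named allele frequency vector.
#' @param n gene count.
#' @return Numeric GD.
#' @export
y_locus_gd <- function(freqs, n) haplotype_diversity(freqs, n = n)

#' Combined panel statistics
#'
#' Combined match probability `CMP = prod(PM_i)`, cumulative power of
#' discrimination `CPD = 1 - CMP`, combined probability of exclusion
#' `CPE = 1 - prod(1 - PE_i)`, plus the CMP-versus-locus-count curve in the
#' given locus order and in descending-PD order (the descending-PD curve is
#' pointwise the faster-dropping of the two).
#'
#' @param summaries data frame with columns `locus`, `PM`, `PD`, `PE`
#'   (as from [panel_forensic_summary()]).
#' @return List with `CMP`, `CPD`, `CPE`, `cmp_curve` (given order) and
#'   `cmp_curve_desc_pd` (descending PD), both named by locus.
#' @export
combined_stats <- function(summaries) {
  stopifnot(nrow(summaries) >= 1L,
            all(summaries$PM >= 0 & summaries$PM <= 1),
            all(is.na(summaries$PE) | (summaries$PE >= 0 & summaries$PE <= 1)))
  cmp <- prod(summaries$PM)
  pe <- summaries$PE[!is.na(summaries$PE)]
  curve <- cumprod(summaries$PM)
  names(curve) <- summaries$locus
  o <- order(-summaries$PD)
  curve_desc <- cumprod(summaries$PM[o])
  names(curve_desc) <- summaries$locus[o]
  list(CMP = cmp, CPD = 1 - cmp,
       CPE = if (length(pe)) 1 - prod(1 - pe) else NA_real_,
       cmp_curve = curve, cmp_curve_desc_pd = curve_desc)
}
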