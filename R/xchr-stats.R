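#' Allele-frequency power sums
#'
#' `S2 = sum p^2`, `S3 = sum p^3`, `S4 = sum p^4` of one locus; every
#' X-chromosomal efficiency parameter is a polynomial in these (and S5).
#'
#' @param freqs numeric allele frequency vector.
#' @return Named numeric vector (S2, S3, S4).
#' @export
x_power_sums <- function(freqs) {
  stopifnot(all(freqs > 0), abs(sum(freqs) - 1) < 1e-6)
  c(S2 = sum(freqs^2), S3 = sum(freqs^3), S4 = sum(freqs^4))
}

#' X-chromosomal forensic efficiency parameters of one locus
#'
#' The Desmarais/Krueger family of X-STR parameters, all functions of the
#' allele-frequency power sums:
#' \itemize{
#'   \item `He = 1 - S2` (plain expected heterozygosity; no n/(n-1)
#'     correction) and `PDM = He`, the power of discrimination among
#'     hemizygous males;
#'   \item `PDF = 1 - 2 S2^2 + S4`, the power of discrimination among
#'     (diploid) females;
#'   \item `PIC = 1 - S2 - S2^2 + S4` and `MEC_t = PIC`, the mean exclusion
#'     chance of a normal father-mother-daughter trio, where the paternal
#'     allele of the daughter is identified;
#'   \item `MEC_d = 1 - 2 S2 + S3`, the mean exclusion chance of a
#'     father-daughter duo (no mother);
#'   \item `MEC_df`, the mean exclusion chance for deficiency cases, i.e. a
#'     trio in which the alleged father is unavailable and a diploid relative
#'     is tested instead, so the paternal allele cannot always be resolved:
#'     the Krueger-type trio exclusion probability
#'     `1 - 2 S2 - 2 S2^2 + S3 + 3 S2 S3 + 2 S4 - 3 S5` (exact enumeration
#'     over mother-child-tested-woman genotypes);
#'   \item `PE = He^2 (1 - 2 He Hom^2)`, the trio exclusion probability in
#'     the expected-heterozygosity convention (`Hom = 1 - He`), or the
#'     observed-genotype PE when female genotypes are supplied.
#' }
#'
#' The deficiency formula is a pluggable slot: supply any
#' `function(freqs)` as `mec_df_formula` to compare conventions; the default
#' is the Krueger form above, validated against published 27-locus X-STR
#' reference values (see [xstr_reference_table()]).
#'
#' @param freqs named allele frequency vector (pooled male + female copies).
#' @param female_genotypes optional diploid cells for the observed PE.
#' @param mec_df_formula optional replacement deficiency-MEC function.
#' @param locus_id optional id stored on the result.
#' @return One-row data frame with S2-S4 and all parameters.
#' @export
x_forensic_summary <- function(freqs, female_genotypes = NULL,
                               mec_df_formula = NULL,
                               locus_id = NA_character_) {
  s <- x_power_sums(freqs)
  S2 <- s[["S2"]]; S3 <- s[["S3"]]; S4 <- s[["S4"]]
  he <- 1 - S2
  pic <- 1 - S2 - S2^2 + S4
  mec_df <- if (is.null(mec_df_formula)) mec_df_kruger(freqs)
            else mec_df_formula(freqs)
  pe <- if (!is.null(female_genotypes)) {
    locus_forensic_summary(female_genotypes)$PE
  } else he^2 * (1 - 2 * he * S2^2)
  data.frame(locus = locus_id, S2 = S2, S3 = S3, S4 = S4,
             PIC = pic, He = he, PE = pe,
             PDF = 1 - 2 * S2^2 + S4, PDM = he,
             MEC_df = mec_df, MEC_t = pic, MEC_d = 1 - 2 * S2 + S3,
             stringsAsFactors = FALSE)
}

#' Krueger-type deficiency mean exclusion chance
#'
#' Exact average probability of excluding a random diploid woman tested in
#' place of the unavailable alleged father of a mother-daughter pair:
#' `1 - 2 S2 - 2 S2^2 + S3 + 3 S2 S3 + 2 S4 - 3 S5`.
#'
#' @param freqs allele frequency vector.
#' @return Numeric exclusion chance.
#' @export
mec_df_kruger <- function(freqs) {
  S2 <- sum(freqs^2); S3 <- sum(freqs^3); S4 <- sum(freqs^4)
  S5 <- sum(freqs^5)
  1 - 2 * S2 - 2 * S2^2 + S3 + 3 * S2 * S3 + 2 * S4 - 3 * S5
}

#' Combine per-locus exclusion or discrimination values across a panel
#'
#' `1 - prod(1 - x)`: the chance that at least one locus excludes (or
#' discriminates). Invariant under permutation of the loci. A value of 1
#' anywhere forces the result to 1 (with a warning, since it usually
#' indicates an impossible per-locus value).
#'
#' @param values per-locus values in `[0, 1]`.
#' @return The combined value.
#' @export
x_combined <- function(values) {
  stopifnot(all(values >= 0 & values <= 1))
  if (any(values == 1)) warn2("per-locus value of exactly 1; combined is 1")
  1 - prod(1 - values)
}

#' Published X-STR efficiency reference values (27 loci, two populations)
#'
#' Forensic efficiency parameters (PIC, He, PE, PDF, PDM and the three mean
#' exclusion chances) of the 27-locus X-STR panel as published for two
#' Chinese population samples: the Yugu ethnic minority of Gansu province
#' (n = 165) and the Han population of the Inner Mongolia Autonomous Region
#' (NMH, n = 333), rounded to 4 decimals as printed. One cell is known to be
#' internally inconsistent (DXS7423/Yugu MEC_t disagrees with its PIC, which
#' the other columns of that row confirm); see the package vignette.
#'
#' @return Data frame with columns `Locus`, `Population`, `PIC`, `He`, `PE`,
#'   `PDF`, `PDM`, `MEC_df`, `MEC_t`, `MEC_d`, plus per-row recovered power
#'   sums `S2`, `S3`, `S4` (from He, MEC_d and PDF).
#' @export
xstr_reference_table <- function() {
  path <- system.file("extdata", "xstr_efficiency_yugu_nmh.tsv",
                      package = "forensicpanel", mustWork = TRUE)
  d <- read.delim(path)
  d$S2 <- 1 - d$He
  d$S3 <- d$MEC_d - 1 + 2 * d$S2
  d$S4 <- d$PDF - 1 + 2 * d$S2^2
  d
}
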