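#' Per-locus allele (or haplogroup) frequency tables
#'
#' A `freq_table` is a long data frame with columns `locus`, `allele`,
#' `count`, `freq`, carrying as attributes the per-locus gene counts `n`
#' (number of sampled gene copies) and marker classes. Frequencies at each
#' locus are strictly positive and sum to 1 (tolerance 1e-9).
#'
#' @param freqs named list: per locus, a named numeric vector of relative
#'   allele frequencies (names are allele labels).
#' @param n per-locus gene counts; scalar or named vector.
#' @param marker_class per-locus marker class; scalar or named vector.
#' @param counts optional named list of allele counts; derived from
#'   `freq * n` when omitted.
#' @return An object of class `freq_table`.
#' @export
freq_table <- function(freqs, n, marker_class = "autosomal_str",
                       counts = NULL) {
  stopifnot(is.list(freqs), length(freqs) >= 1L, !is.null(names(freqs)))
  loci <- names(freqs)
  n <- rep_len_named(n, loci)
  marker_class <- rep_len_named(marker_class, loci)
  rows <- lapply(loci, function(l) {
    p <- freqs[[l]]
    if (is.null(names(p)) || any(!nzchar(names(p))))
      stop2("allele labels missing at locus ", l)
    if (any(p <= 0)) stop2("non-positive allele frequency at locus ", l)
    if (abs(sum(p) - 1) > 1e-9)
      stop2("frequencies at locus ", l, " do not sum to 1 (got ", sum(p), ")")
    if (n[[l]] < 1) stop2("gene count below 1 at locus ", l)
    cnt <- if (is.null(counts)) p * n[[l]] else counts[[l]]
    data.frame(locus = l, allele = names(p), count = unname(cnt),
               freq = unname(p), stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            gene_counts = n, marker_class = marker_class,
            class = c("freq_table", "data.frame"))
}

rep_len_named <- function(x, loci) {
  if (length(x) == 1L) return(setNames(rep(x, length(loci)), loci))
  if (is.null(names(x))) return(setNames(rep_len(x, length(loci)), loci))
  x[loci]
}

#' Extract the per-locus frequency vectors of a freq_table
#' @param x a [freq_table()].
#' @return Named list of named numeric frequency vectors.
#' @export
freq_split <- function(x) {
  lapply(split(x[c("allele", "freq")], factor(x$locus, unique(x$locus))),
         function(d) setNames(d$freq, d$allele))
}

#' Gene counts of a freq_table
#' @param x a [freq_table()].
#' @param locus optional locus id.
#' @export
gene_counts <- function(x, locus = NULL) {
  n <- attr(x, "gene_counts")
  if (is.null(locus)) n else n[[locus]]
}

#' Estimate allele frequencies by gene counting
#'
#' Counts observed gene copies: autosomal genotypes contribute 2 copies,
#' X genotypes 1 copy for males and 2 for females, Y genotypes 1 copy for
#' males, with multi-copy Y combinations (e.g. `"13-14"`) counted as single
#' haplotype-alleles. Male and female X copies are pooled. Y null alleles
#' (label `"null"`, non-amplifications) are excluded from the denominator.
#' Missing calls are dropped pairwise; loci at which every genotype is
#' missing are omitted with a warning.
#'
#' @param x a [genotype_table()].
#' @param loci optional character vector of locus ids (default all).
#' @param populations optional character vector restricting samples.
#' @return A [freq_table()].
#' @export
allele_frequencies <- function(x, loci = NULL, populations = NULL) {
  stopifnot(inherits(x, "genotype_table"))
  loci <- loci %||% x$loci$locus_id
  if (!all(loci %in% x$loci$locus_id)) stop2("unknown locus requested")
  keep <- if (is.null(populations)) rep(TRUE, nrow(x$samples))
          else x$samples$population %in% populations
  if (!any(keep)) stop2("empty sample selection")
  freqs <- list(); ns <- c(); cls <- c()
  for (l in loci) {
    j <- match(l, x$loci$locus_id)
    mc <- x$loci$marker_class[j]
    cells <- x$genotypes[keep, l]
    sexes <- x$samples$sex[keep]
    copies <- character()
    for (i in seq_along(cells)) {
      if (is.na(cells[i])) next
      a <- cell_alleles(cells[i])
      if (mc == "x_str" && sexes[i] == "female" && length(a) == 1L)
        a <- rep(a, 2L)  # homozygous female written as single label
      copies <- c(copies, a)
    }
    if (mc == "y_str") copies <- copies[copies != "null"]
    if (length(copies) == 0L) {
      warn2("locus ", l, " has no observed gene copies; omitted")
      next
    }
    tab <- table(copies)
    tab <- tab[allele_order(names(tab))]
    freqs[[l]] <- setNames(as.numeric(tab) / sum(tab), names(tab))
    ns[l] <- sum(tab)
    cls[l] <- mc
  }
  if (length(freqs) == 0L) stop2("no locus with observed genotypes")
  freq_table(freqs, n = ns, marker_class = cls)
}

#' Write / read a frequency table as TSV
#'
#' Columns `Locus`, `Allele`, `Count`, `Freq`, `N`.
#' @param x a [freq_table()].
#' @param path file path.
#' @export
write_freq_table <- function(x, path) {
  out <- data.frame(Locus = x$locus, Allele = x$allele, Count = x$count,
                    Freq = x$freq,
                    N = unname(attr(x, "gene_counts")[x$locus]))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_freq_table
#' @param marker_class per-locus marker class for the loci in the file.
#' @export
read_freq_table <- function(path, marker_class = "autosomal_str") {
  d <- read.delim(path, colClasses = c(Allele = "character"))
  sp <- split(d, factor(d$Locus, unique(d$Locus)))
  freq_table(lapply(sp, function(s) setNames(s$Freq, s$Allele)),
             n = vapply(sp, function(s) s$N[1], 0),
             marker_class = marker_class,
             counts = lapply(sp, function(s) s$Count))
}
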