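#' Genotype tables for mixed-ploidy forensic marker panels
#'
#' A `genotype_table` holds called genotypes for a set of samples at a set of
#' loci of heterogeneous marker classes: autosomal markers are diploid, X
#' markers are diploid in females and hemizygous in males, Y markers are
#' haploid (and absent in females) but may carry multi-copy allele
#' combinations such as `"13-14"`, which are treated as single haplotype
#' alleles throughout. Allele labels are arbitrary non-empty strings so that
#' microvariants (`"14.2"`) and sequence-named alleles survive round trips.
#'
#' Cells use `"a/b"` for diploid calls, `"a"` for hemizygous/haploid calls,
#' `"a-b"` for one multi-copy Y combination, and `"."` (stored as `NA`) for
#' missing. Within a diploid cell the two alleles are unordered; on
#' construction they are normalised (numeric labels by value, others
#' lexicographically).
#'
#' @param samples data frame with columns `sample_id`, `population`, `sex`
#'   (one of `"male"`, `"female"`, `"unknown"`).
#' @param loci data frame with columns `locus_id`, `marker_class` (one of
#'   `"autosomal_str"`, `"autosomal_snp"`, `"x_str"`, `"y_str"`).
#' @param genotypes character matrix (samples x loci) of genotype cells;
#'   `NA` or `"."` for missing.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(samples, loci, genotypes) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "population", "sex") %in% names(samples)),
            all(c("locus_id", "marker_class") %in% names(loci)))
  if (anyDuplicated(samples$sample_id))
    stop2("duplicated sample_id values in genotype table")
  if (!all(samples$sex %in% c("male", "female", "unknown")))
    stop2("sex must be one of 'male', 'female', 'unknown'")
  if (!all(loci$marker_class %in% c("autosomal_str", "autosomal_snp",
                                    "x_str", "y_str")))
    stop2("unknown marker_class")
  genotypes <- as.matrix(genotypes)
  genotypes[genotypes %in% c(".", "")] <- NA_character_
  dimnames(genotypes) <- list(samples$sample_id, loci$locus_id)
  obj <- structure(list(samples = samples, loci = loci, genotypes = genotypes),
                   class = "genotype_table")
  validate_genotype_table(obj)
}

# normalise one cell and enforce the ploidy rules for its marker class/sex
parse_genotype_cell <- function(cell, marker_class, sex, where) {
  if (is.na(cell)) return(NA_character_)
  alleles <- strsplit(cell, "/", fixed = TRUE)[[1]]
  alleles <- trimws(alleles)
  if (any(!nzchar(alleles)))
    stop2("empty allele label in genotype cell ", where)
  n <- length(alleles)
  if (marker_class %in% c("autosomal_str", "autosomal_snp")) {
    if (n != 2L)
      stop2("autosomal genotype must have exactly 2 alleles in ", where,
            " (got '", cell, "')")
  } else if (marker_class == "x_str") {
    if (sex == "male") {
      if (n == 2L && alleles[1] != alleles[2])
        stop2("male sample with 2 distinct X alleles in ", where,
              " (got '", cell, "')")
      alleles <- alleles[1]
    } else if (sex == "female") {
      if (n != 2L)
        stop2("female X genotype must have exactly 2 alleles in ", where,
              " (got '", cell, "')")
    } else if (n > 2L) {
      stop2("X genotype with more than 2 alleles in ", where)
    }
  } else if (marker_class == "y_str") {
    if (sex == "female")
      stop2("female sample with a Y genotype in ", where)
    if (n != 1L)
      stop2("Y genotype cells hold one (possibly multi-copy) allele in ",
            where, " (got '", cell, "'); multi-copy combinations use '-'")
  }
  paste(sort_alleles(alleles), collapse = "/")
}

validate_genotype_table <- function(x) {
  g <- x$genotypes
  for (j in seq_len(ncol(g))) {
    cls <- x$loci$marker_class[j]
    for (i in seq_len(nrow(g))) {
      g[i, j] <- parse_genotype_cell(
        g[i, j], cls, x$samples$sex[i],
        sprintf("row '%s', column '%s'", x$samples$sample_id[i],
                x$loci$locus_id[j]))
    }
  }
  x$genotypes <- g
  x
}

#' Read a genotype table from TSV
#'
#' The file must have a header `Sample`, `Population`, `Sex`, followed by one
#' column per locus. Genotype cells use `"a/b"` (diploid), `"a"`
#' (haploid/hemizygous), `"a-b"` (one multi-copy Y combination) and `"."`
#' (missing). Marker classes are inferred from locus names (`DYS`/`DYF`
#' prefixes are Y, `DXS`/`GATA`/`HPRTB` are X, `rs` are autosomal SNPs,
#' everything else autosomal STR) unless given explicitly.
#'
#' @param path file path.
#' @param marker_class optional named character vector `locus -> class`
#'   overriding the inference.
#' @return A [genotype_table()].
#' @export
read_genotype_table <- function(path, marker_class = NULL) {
  raw <- read.delim(path, check.names = FALSE, colClasses = "character",
                    na.strings = c(".", "NA", ""))
  need <- c("Sample", "Population", "Sex")
  if (!all(need %in% names(raw)[1:3]))
    stop2("genotype TSV must start with columns Sample, Population, Sex")
  locus_ids <- setdiff(names(raw), need)
  if (is.null(marker_class)) marker_class <- infer_marker_class(locus_ids)
  samples <- data.frame(sample_id = raw$Sample, population = raw$Population,
                        sex = tolower(raw$Sex), stringsAsFactors = FALSE)
  loci <- data.frame(locus_id = locus_ids,
                     marker_class = unname(marker_class[locus_ids]),
                     stringsAsFactors = FALSE)
  genotype_table(samples, loci, as.matrix(raw[locus_ids]))
}

infer_marker_class <- function(locus_ids) {
  cls <- ifelse(grepl("^(DYS|DYF)", locus_ids), "y_str",
         ifelse(grepl("^(DXS|GATA|HPRTB)", locus_ids), "x_str",
         ifelse(grepl("^rs[0-9]", locus_ids), "autosomal_snp",
                "autosomal_str")))
  setNames(cls, locus_ids)
}

#' Write a genotype table to TSV
#'
#' Inverse of [read_genotype_table()]: cell contents are reproduced up to
#' allele-order normalisation, with `"."` for missing calls.
#'
#' @param x a [genotype_table()].
#' @param path file path.
#' @export
write_genotype_table <- function(x, path) {
  g <- x$genotypes
  g[is.na(g)] <- "."
  out <- data.frame(Sample = x$samples$sample_id,
                    Population = x$samples$population,
                    Sex = x$samples$sex, g,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", nrow(x$samples), "samples x", nrow(x$loci),
      "loci\n")
  cat("  populations:", paste(unique(x$samples$population), collapse = ", "),
      "\n")
  cat("  marker classes:",
      paste(names(table(x$loci$marker_class)), table(x$loci$marker_class),
            collapse = ", "), "\n")
  invisible(x)
}

# split a normalised cell into its allele labels (multi-copy Y combinations
# stay single tokens)
cell_alleles <- function(cell) {
  if (is.na(cell)) return(character())
  strsplit(cell, "/", fixed = TRUE)[[1]]
}
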