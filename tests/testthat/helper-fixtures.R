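# shared in-code fixtures

# tiny mixed-class genotype TSV on disk; returns the path
write_toy_genotype_tsv <- function(path = tempfile(fileext = ".tsv")) {
  writeLines(c(
    "Sample\tPopulation\tSex\tD1S1\tDXS1\tDYS1",
    "A\tYugu\tmale\t12/13\t21\t13-14",
    "B\tYugu\tfemale\t12/12\t21/22\t.",
    "C\tNMH\tmale\t14.2/12\t22\t13-14",
    "D\tNMH\tmale\t12/13\t21\t15-16"), path)
  path
}

toy_marker_classes <- c(D1S1 = "autosomal_str", DXS1 = "x_str",
                        DYS1 = "y_str")

read_toy_genotypes <- function() {
  read_genotype_table(write_toy_genotype_tsv(),
                      marker_class = toy_marker_classes)
}

# toy alignments with hand-computed diversity statistics
toy_aln3 <- function() seq_alignment(c("AAA", "AAT", "ATT"))

# n = 4: eta = 3 (two singleton sites, one 2/2 site), k = 10/6
toy_aln4 <- function() seq_alignment(c("AAAA", "AATA", "ATTA", "TTTA"))

# n = 4, both variant sites split 2/2: no singletons
toy_aln4_nosingleton <- function() seq_alignment(c("AT", "AT", "TA", "TA"))

toy_aln5 <- function() seq_alignment(c("AAAAA", "AAAAT", "AATAT", "ATTAT",
                                       "ATTTT"))

# STR-like study panel used by the kinship studies: 54 decaallelic STRs and
# 133 biallelic SNPs with Dirichlet(1) spectra
study_panel <- function() {
  strs <- sample_allele_freqs(54, k = 10, alpha = 1, seed = 101,
                              locus_prefix = "STR")
  snps <- sample_allele_freqs(133, k = 2, alpha = 1,
                              marker_class = "autosomal_snp", seed = 102,
                              locus_prefix = "SNP")
  freq_table(c(freq_split(strs), freq_split(snps)), n = Inf,
             marker_class = c(rep("autosomal_str", 54),
                              rep("autosomal_snp", 133)))
}

str_locus_ids <- function() sprintf("STR%03d", 1:54)

# enumerate unordered genotypes of a frequency vector with HWE probabilities
hwe_genotype_probs <- function(p) {
  labs <- names(p)
  gen <- list(); prob <- c()
  for (i in seq_along(p)) for (j in i:length(p)) {
    gen[[length(gen) + 1L]] <- c(labs[i], labs[j])
    prob <- c(prob, if (i == j) p[i]^2 else 2 * p[i] * p[j])
  }
  list(genotypes = gen, probs = unname(prob))
}
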