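#' Allele coverage ratio of one called locus
#'
#' ACR is the intra-locus balance of sequencing signal: `min(depth)/max(depth)`
#' over the called alleles of a heterozygous (or multi-allele) call, and 1 by
#' convention for single-allele (homozygous or hemizygous) calls. The two
#' conventional quality thresholds used in MPS validation work, 0.5 and 0.75,
#' are evaluated alongside.
#'
#' @param depths non-negative integer read depths, one per called allele.
#' @param thresholds numeric thresholds to flag.
#' @return List with `ratio`, and a logical `pass` named by threshold.
#' @export
allele_coverage_ratio <- function(depths, thresholds = c(0.5, 0.75)) {
  stopifnot(is.numeric(depths), length(depths) >= 1L, all(depths >= 0))
  if (all(depths == 0)) stop2("all allele depths are zero: uncalled locus")
  ratio <- if (length(depths) == 1L) 1 else min(depths) / max(depths)
  list(ratio = ratio,
       pass = setNames(ratio >= thresholds, format(thresholds)))
}

#' Read a per-allele depth table
#'
#' TSV with columns `Locus`, `Sample`, `Allele`, `Depth`.
#' @param path file path.
#' @return data frame of depth records.
#' @export
read_depth_table <- function(path) {
  d <- read.delim(path, colClasses = c(Allele = "character"))
  stopifnot(all(c("Locus", "Sample", "Allele", "Depth") %in% names(d)))
  if (any(d$Depth < 0)) stop2("negative read depth")
  d
}

#' Per-locus depth-of-coverage summary
#'
#' Sums allele depths within each sample-locus call, then reports the mean
#' and sample standard deviation (n-1 denominator; 0 for a single sample)
#' of those totals per locus -- the conventional "DoC mean +/- sd" summary.
#'
#' @param depths data frame as from [read_depth_table()].
#' @return data frame with columns `locus`, `n_samples`, `mean_doc`, `sd_doc`.
#' @export
depth_summary <- function(depths) {
  stopifnot(nrow(depths) >= 1L)
  per_call <- aggregate(Depth ~ Locus + Sample, depths, sum)
  out <- do.call(rbind, lapply(split(per_call, per_call$Locus), function(d) {
    data.frame(locus = d$Locus[1], n_samples = nrow(d),
               mean_doc = mean(d$Depth),
               sd_doc = if (nrow(d) > 1L) sd(d$Depth) else 0,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Allele coverage ratios for every heterozygous-capable call in a depth table
#'
#' @param depths data frame as from [read_depth_table()].
#' @param thresholds thresholds passed to [allele_coverage_ratio()].
#' @return data frame with one row per sample-locus call.
#' @export
acr_summary <- function(depths, thresholds = c(0.5, 0.75)) {
  sp <- split(depths, list(depths$Locus, depths$Sample), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    acr <- allele_coverage_ratio(d$Depth, thresholds)
    cbind(data.frame(locus = d$Locus[1], sample = d$Sample[1],
                     n_alleles = nrow(d), acr = acr$ratio,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(acr$pass), check.names = FALSE))
  }))
  rownames(out) <- NULL
  out
}
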