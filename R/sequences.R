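#' Aligned haploid sequence samples
#'
#' A `seq_alignment` holds equal-length aligned haploid sequences (e.g. mtDNA
#' hypervariable regions) over the alphabet `A, C, G, T, N, -`, together with
#' a population label per sequence. Internally a character matrix (sequences
#' x sites).
#'
#' @param seqs character vector of sequences, or a character matrix
#'   (sequences x sites); names are sequence ids.
#' @param population per-sequence population labels.
#' @return An object of class `seq_alignment`.
#' @export
seq_alignment <- function(seqs, population = "pop1") {
  if (is.character(seqs) && !is.matrix(seqs)) {
    L <- unique(nchar(seqs))
    if (length(L) != 1L) stop2("sequences have unequal lengths")
    m <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(m) <- names(seqs) %||% paste0("seq", seq_along(seqs))
  } else {
    m <- toupper(as.matrix(seqs))
    if (is.null(rownames(m))) rownames(m) <- paste0("seq", seq_len(nrow(m)))
  }
  if (ncol(m) < 1L) stop2("alignment must have at least one site")
  bad <- setdiff(unique(as.vector(m)), c("A", "C", "G", "T", "N", "-"))
  if (length(bad)) stop2("invalid characters in alignment: ",
                         paste(bad, collapse = ", "))
  structure(list(matrix = m,
                 population = rep_len(population, nrow(m))),
            class = "seq_alignment")
}

#' Read an aligned FASTA file as a seq_alignment
#'
#' @param path FASTA file path.
#' @param population per-sequence population labels (recycled).
#' @return A [seq_alignment()].
#' @export
read_alignment <- function(path, population = "pop1") {
  dna <- ape::read.FASTA(path)
  m <- toupper(as.character(as.matrix(dna)))
  seq_alignment(m, population = population)
}

#' Write a seq_alignment to FASTA
#' @param x a [seq_alignment()].
#' @param path file path.
#' @export
write_alignment <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(x$matrix))) {
    writeLines(c(paste0(">", rownames(x$matrix)[i]),
                 paste(x$matrix[i, ], collapse = "")), con)
  }
  invisible(path)
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat("seq_alignment:", nrow(x$matrix), "sequences x", ncol(x$matrix),
      "sites\n")
  invisible(x)
}

# retained sites after complete deletion of columns with gaps or Ns
complete_deletion <- function(x) {
  keep <- colSums(x$matrix == "N" | x$matrix == "-") == 0L
  x$matrix[, keep, drop = FALSE]
}
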