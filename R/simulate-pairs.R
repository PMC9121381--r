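#' Pairwise kinship models as IBD coefficient triples
#'
#' A pairwise relationship is summarised by (k0, k1, k2), the probabilities
#' that the pair shares 0, 1 or 2 alleles identical by descent at an
#' autosomal locus.
#'
#' @param name one of `"full_sib"`, `"half_sib"`, `"parent_child"`,
#'   `"unrelated"`, or `"custom"` with explicit coefficients.
#' @param k numeric length-3 vector (k0, k1, k2) for `name = "custom"`.
#' @return List with `name` and `k` (named k0, k1, k2).
#' @export
kinship_model <- function(name = c("full_sib", "half_sib", "parent_child",
                                   "unrelated", "custom"), k = NULL) {
  name <- match.arg(name)
  k <- switch(name,
              full_sib     = c(0.25, 0.5, 0.25),
              half_sib     = c(0.5, 0.5, 0),
              parent_child = c(0, 1, 0),
              unrelated    = c(1, 0, 0),
              custom       = k)
  stopifnot(length(k) == 3, all(k >= 0), abs(sum(k) - 1) < 1e-9)
  if (k[2]^2 < 4 * k[1] * k[3] - 1e-12)
    stop2("invalid relationship: requires k1^2 >= 4 k0 k2")
  list(name = name, k = setNames(k, c("k0", "k1", "k2")))
}

#' Gene-drop simulation of relative pairs
#'
#' Pairs are produced by explicit gamete-level gene dropping: founder
#' haplotypes are drawn from the allele frequencies, and gametes are
#' transmitted with recombination at fraction `theta` between adjacent
#' mapped loci (independent assortment across chromosomes and for unmapped
#' loci). The realised per-locus IBD state (0/1/2) is recorded alongside the
#' genotypes so that downstream likelihood-ratio results can be validated
#' against true relatedness. For half sibs only the shared parent is
#' gene-dropped jointly; the two unshared parents are simulated
#' independently. No mutation occurs in transmissions.
#'
#' @param freqs a [freq_table()] of autosomal loci.
#' @param relationship one of `"full_sib"`, `"half_sib"`, `"parent_child"`,
#'   `"unrelated"`.
#' @param n_pairs number of simulated pairs.
#' @param linkage_map optional data frame with columns `locus_id`,
#'   `chromosome`, `theta` (recombination fraction to the previous locus on
#'   the same chromosome, in `[0, 0.5]`; the first locus of a chromosome is
#'   ignored / may be NA). Loci absent from the map assort independently.
#' @param seed optional integer seed.
#' @return Object of class `relative_pairs`: allele-label matrices
#'   (`n_pairs` x loci) `a1_1`, `a1_2` (member 1) and `a2_1`, `a2_2`
#'   (member 2), an integer `ibd` matrix, plus `loci` and `relationship`.
#' @export
simulate_relative_pairs <- function(freqs, relationship, n_pairs,
                                    linkage_map = NULL, seed = NULL) {
  stopifnot(inherits(freqs, "freq_table"))
  relationship <- match.arg(relationship, c("full_sib", "half_sib",
                                            "parent_child", "unrelated"))
  fl <- freq_split(freqs)
  L <- length(fl)
  if (!is.null(linkage_map)) {
    stopifnot(all(c("locus_id", "chromosome", "theta") %in%
                    names(linkage_map)))
    th <- linkage_map$theta
    if (any(!is.na(th) & (th < 0 | th > 0.5)))
      stop2("recombination fractions must lie in [0, 0.5]")
  }
  with_seed(seed, {
    draw <- function() vapply(fl, function(p)
      names(p)[sample.int(length(p), n_pairs, TRUE, p)],
      character(n_pairs))
    fix <- function(m) if (n_pairs == 1L) matrix(m, 1L, L) else m
    founder <- function() list(h1 = fix(draw()), h2 = fix(draw()))
    # inheritance matrices: which founder haplotype each gamete copies,
    # Markov along mapped loci with switch probability theta
    inherit <- function() {
      v <- matrix(0L, n_pairs, L)
      theta <- rep(0.5, L)
      if (!is.null(linkage_map)) {
        idx <- match(names(fl), linkage_map$locus_id)
        chrom <- linkage_map$chromosome[idx]
        th <- linkage_map$theta[idx]
        for (j in seq_len(L)) {
          if (j == 1L || is.na(idx[j]) || is.na(idx[j - 1L])) next
          if (!is.na(chrom[j]) && identical(chrom[j], chrom[j - 1L]) &&
              !is.na(th[j]))
            theta[j] <- th[j]
        }
      }
      v[, 1L] <- rbinom(n_pairs, 1L, 0.5)
      for (j in seq_len(L)[-1L]) {
        if (theta[j] >= 0.5) v[, j] <- rbinom(n_pairs, 1L, 0.5)
        else {
          sw <- rbinom(n_pairs, 1L, theta[j])
          v[, j] <- (v[, j - 1L] + sw) %% 2L
        }
      }
      v
    }
    gamete <- function(par, v) {
      g <- par$h1
      g[v == 1L] <- par$h2[v == 1L]
      g
    }
    if (relationship == "unrelated") {
      r <- list(a1_1 = fix(draw()), a1_2 = fix(draw()),
                a2_1 = fix(draw()), a2_2 = fix(draw()),
                ibd = matrix(0L, n_pairs, L))
    } else if (relationship == "parent_child") {
      par <- founder(); other <- founder()
      vp <- inherit(); vo <- inherit()
      r <- list(a1_1 = par$h1, a1_2 = par$h2,
                a2_1 = gamete(par, vp), a2_2 = gamete(other, vo),
                ibd = matrix(1L, n_pairs, L))
    } else if (relationship == "full_sib") {
      f <- founder(); m <- founder()
      vf1 <- inherit(); vf2 <- inherit()
      vm1 <- inherit(); vm2 <- inherit()
      r <- list(a1_1 = gamete(f, vf1), a1_2 = gamete(m, vm1),
                a2_1 = gamete(f, vf2), a2_2 = gamete(m, vm2),
                ibd = (vf1 == vf2) + (vm1 == vm2))
    } else { # half_sib
      s <- founder(); o1 <- founder(); o2 <- founder()
      vs1 <- inherit(); vs2 <- inherit()
      vo1 <- inherit(); vo2 <- inherit()
      r <- list(a1_1 = gamete(s, vs1), a1_2 = gamete(o1, vo1),
                a2_1 = gamete(s, vs2), a2_2 = gamete(o2, vo2),
                ibd = (vs1 == vs2) + 0L)
    }
    structure(c(r, list(loci = names(fl), relationship = relationship)),
              class = "relative_pairs")
  })
}

#' @export
print.relative_pairs <- function(x, ...) {
  cat("relative_pairs:", nrow(x$ibd), x$relationship, "pairs over",
      length(x$loci), "loci\n")
  cat("  realised IBD proportions:",
      paste(round(prop.table(tabulate(x$ibd + 1L, 3L)), 3), collapse = "/"),
      "\n")
  invisible(x)
}
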