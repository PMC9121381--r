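# internal helpers shared across modules

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so that seeded generators are
#' pure functions of (arguments, seed) without disturbing the session RNG.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# numeric-aware allele label ordering: labels that parse fully as numbers sort
# by value (so "9.3" < "10"), everything else lexicographically after them
allele_order <- function(labels) {
  num <- suppressWarnings(as.numeric(labels))
  is_num <- !is.na(num)
  order(!is_num, ifelse(is_num, num, NA), labels, method = "radix")
}

sort_alleles <- function(labels) labels[allele_order(labels)]

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)
warn2 <- function(...) warning(..., call. = FALSE)
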