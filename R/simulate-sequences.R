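#' Coalescent simulation of haploid sequence samples
#'
#' Simulates a Kingman coalescent genealogy for `n` haploid sequences under
#' either a constant-size model or a sudden-expansion model, drops
#' infinite-sites mutations on the branches, and writes the result as a
#' binary-substitution alignment of length `L` (ancestral state `A`, derived
#' `T`, each mutation at its own site).
#'
#' Time is measured in mutational units (the pairwise mutation rate is 1, so
#' a lineage accrues mutations at rate 1/2): under the constant model the
#' expected number of pairwise differences is `theta` and the expected number
#' of segregating sites is `theta * sum(1/(1:(n-1)))`. Under the
#' sudden-expansion model the population coalesces at rate `1/theta1` more
#' recently than time `tau` and at rate `1/theta0` beyond it, matching the
#' (theta0, theta1, tau) parameterisation of the mismatch-distribution
#' expansion model, so that pairwise differences follow the
#' Rogers-Harpending distribution with those parameters.
#'
#' @param n sample size (>= 2).
#' @param model `"constant"` or `"sudden_expansion"`.
#' @param theta scaled mutation parameter of the constant model (>= 0).
#' @param theta0,theta1,tau expansion model parameters: pre- and
#'   post-expansion theta and the expansion time in mutational units.
#' @param L alignment length in sites.
#' @param seed optional integer seed.
#' @param population population label.
#' @return A [seq_alignment()].
#' @export
simulate_sequences <- function(n, model = c("constant", "sudden_expansion"),
                               theta = 5, theta0 = 1, theta1 = 100, tau = 5,
                               L = 500, seed = NULL, population = "sim") {
  model <- match.arg(model)
  stopifnot(n >= 2, L >= 1)
  if (model == "constant") stopifnot(theta >= 0)
  else stopifnot(theta0 >= 0, theta1 >= 0, tau >= 0)
  with_seed(seed, {
    n_nodes <- 2L * n - 1L
    parent <- integer(n_nodes)
    node_time <- numeric(n_nodes)
    active <- seq_len(n)
    t_now <- 0
    nxt <- n + 1L
    while (length(active) >= 2L) {
      k <- length(active)
      rate <- k * (k - 1) / 2
      e <- rexp(1)
      t_now <- t_now + coal_wait(e, rate, t_now, model, theta, theta0,
                                 theta1, tau)
      pick <- sample.int(k, 2L)
      node_time[nxt] <- t_now
      parent[active[pick]] <- nxt
      active <- c(active[-pick], nxt)
      nxt <- nxt + 1L
    }
    # mutations: Poisson(branch length / 2) per branch
    root <- n_nodes
    blen <- node_time[parent[-root]] - node_time[-root]
    nmut <- rpois(n_nodes - 1L, blen / 2)
    S <- sum(nmut)
    if (S > L)
      stop2(S, " segregating sites exceed alignment length L = ", L,
            "; increase L")
    m <- matrix("A", n, L)
    rownames(m) <- sprintf("%s_%04d", population, seq_len(n))
    if (S > 0) {
      sites <- sample.int(L, S)
      desc <- leaf_descendants(parent, n)
      s <- 1L
      for (node in which(nmut > 0)) {
        for (mm in seq_len(nmut[node])) {
          m[desc[[node]], sites[s]] <- "T"
          s <- s + 1L
        }
      }
    }
    seq_alignment(m, population = population)
  })
}

# waiting time (in mutational units) to consume integrated hazard e at
# coalescent rate `rate`, under the piecewise-constant population model
coal_wait <- function(e, rate, t_now, model, theta, theta0, theta1, tau) {
  if (model == "constant") {
    if (theta == 0) return(0)
    return(e * theta / rate)
  }
  if (t_now < tau) {
    if (theta1 == 0) return(0)
    cap <- (tau - t_now) * rate / theta1
    if (e <= cap) return(e * theta1 / rate)
    if (theta0 == 0) return(tau - t_now)
    return((tau - t_now) + (e - cap) * theta0 / rate)
  }
  if (theta0 == 0) return(0)
  e * theta0 / rate
}

# list of leaf indices below every node of the (parent-pointer) genealogy
leaf_descendants <- function(parent, n) {
  n_nodes <- length(parent)
  desc <- vector("list", n_nodes)
  for (i in seq_len(n)) desc[[i]] <- i
  # internal nodes were created in increasing time order, so children always
  # precede parents in index order
  for (node in seq_len(n_nodes)) {
    kids <- which(parent == node)
    if (length(kids)) desc[[node]] <- unlist(desc[kids], use.names = FALSE)
  }
  desc
}
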