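#' Generate a random valid GeneNetwork
#'
#' Draws a random signed topology at the requested edge density, routing
#' probabilities renormalized so each row plus the departure probability
#' sums to 1, and positive rates. The result always passes
#' [validateNetwork()] and is reproducible from the seed. Used for
#' property-style tests.
#'
#' @param N number of genes.
#' @param density probability that an ordered gene pair carries an edge
#'   (each edge is positive or negative with equal probability); must be in
#'   (0, 1\].
#' @param seed RNG seed.
#' @param stable if TRUE (default), rates are rescaled so the traffic
#'   fixed point is stable (all q < 1).
#' @return a [GeneNetwork-class].
#' @export
randomNetwork <- function(N, density = 0.3, seed = 1L, stable = TRUE) {
  if (N < 1) stop("N must be at least 1")
  if (density <= 0 || density > 1) stop("density must lie in (0, 1]")
  set.seed(seed)
  g <- paste0("g", seq_len(N))
  pp <- matrix(0, N, N)
  pm <- matrix(0, N, N)
  if (N > 1) {
    for (i in seq_len(N)) for (j in seq_len(N)) {
      if (i == j || stats::runif(1) > density) next
      if (stats::runif(1) < 0.5) pp[i, j] <- stats::runif(1, 0.1, 1)
      else pm[i, j] <- stats::runif(1, 0.1, 1)
    }
    ## keep total routing probability of each row at most 0.8 so that a
    ## positive departure probability remains
    rs <- rowSums(pp) + rowSums(pm)
    scale <- ifelse(rs > 0, pmin(1, stats::runif(N, 0.3, 0.8) / pmax(rs, 1e-12)), 1)
    pp <- pp * scale
    pm <- pm * scale
  }
  lp <- stats::runif(N, 0.5, 3)
  lm <- stats::runif(N, 0, 1.5)
  mu <- stats::runif(N, 1, 4)
  net <- GeneNetwork(g, lp, lm, mu, pp, pm)
  if (stable) {
    sol <- suppressWarnings(solveTraffic(net))
    if (any(qValues(sol) >= 0.95)) {
      ## raise service rates until comfortably stable
      mu <- mu * (max(qValues(sol)) / 0.7)
      net <- GeneNetwork(g, lp, lm, mu, pp, pm)
    }
  }
  net
}
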