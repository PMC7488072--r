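#' Solve the G-network traffic (balance) equations
#'
#' Iterates the nonlinear fixed point
#' \deqn{q_i = \frac{\lambda_i^+ + \sum_j q_j \mu_j p_{ji}^+}
#'                  {\mu_i + \lambda_i^- + \sum_j q_j \mu_j p_{ji}^-}}
#' from the initial guess \eqn{q = \lambda^+ / (\mu + \lambda^-)} until the
#' maximum absolute change falls below `tol`. When all \eqn{q_i < 1} the
#' joint stationary distribution is the product of the geometric marginals
#' \eqn{(1-q_i) q_i^{x_i}}; otherwise the solution is flagged unstable (a
#' warning is raised and the product form does not apply).
#'
#' @param net a valid [GeneNetwork-class].
#' @param tol convergence tolerance on the iterate (default 1e-12, so that
#'   four-decimal agreement with tabulated values is limited by their
#'   printed rounding, not by the solver).
#' @param maxIter iteration cap.
#' @return a [StationarySolution-class].
#' @examples
#' sol <- solveTraffic(builtinNetwork("normal"))
#' round(qValues(sol), 4)
#' @export
solveTraffic <- function(net, tol = 1e-12, maxIter = 100000L) {
  stopifnot(is(net, "GeneNetwork"))
  lp <- net@lambdaPlus; lm <- net@lambdaMinus; mu <- net@mu
  tpp <- t(net@pPlus); tpm <- t(net@pMinus)
  q <- lp / (mu + lm)
  res <- Inf
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    qNew <- (lp + as.vector(tpp %*% (q * mu))) /
            (mu + lm + as.vector(tpm %*% (q * mu)))
    res <- max(abs(qNew - q))
    q <- qNew
    if (res < tol) break
  }
  if (res >= tol)
    stop(sprintf(
      "traffic equations did not converge after %d iterations (residual %.3g; last iterate: %s)",
      maxIter, res, paste(signif(q, 8), collapse = ", ")))
  stable <- all(q < 1)
  if (!stable)
    warning("some q_i >= 1: the network is unstable and the product-form ",
            "stationary distribution does not exist")
  new("StationarySolution",
      q = stats::setNames(q, net@geneNames),
      iterations = it, residual = res, stable = stable)
}

#' Geometric stationary marginal of one gene
#'
#' Under the product-form stationary law the marginal pmf of gene i is
#' geometric: \eqn{P(x_i = x) = (1 - q_i) q_i^x}.
#'
#' @param q utilization in (0, 1).
#' @param x nonnegative integer level(s).
#' @return probability vector of the same length as `x`.
#' @export
marginalPMF <- function(q, x) {
  if (any(q <= 0 | q >= 1)) stop("q must lie strictly in (0, 1)")
  if (any(x < 0 | x != floor(x))) stop("x must be a nonnegative integer")
  (1 - q) * q^x
}

#' Tail of the theoretical stationary CDF
#'
#' Returns \eqn{P(x_i > x) = q^{x+1}}, the survival function of the
#' geometric stationary marginal. This is the quantity the simulator's
#' empirical CDF is compared against.
#'
#' @inheritParams marginalPMF
#' @return tail probabilities.
#' @export
cdfTail <- function(q, x) {
  if (any(q <= 0 | q >= 1)) stop("q must lie strictly in (0, 1)")
  if (any(x < 0 | x != floor(x))) stop("x must be a nonnegative integer")
  q^(x + 1)
}

#' Convert between a geometric mean level and its utilization
#'
#' For a geometric law with parameter \eqn{1 - q} the mean level is
#' \eqn{\bar x = q / (1 - q)}, hence \eqn{q = \bar x / (1 + \bar x)}. These
#' two helpers are exact inverses.
#'
#' @param mean nonnegative mean expression level \eqn{\bar x}.
#' @param q utilization in \[0, 1).
#' @return the converted value.
#' @examples
#' qFromMean(1)            # 0.5
#' meanFromQ(qFromMean(3)) # 3
#' @export
qFromMean <- function(mean) {
  if (any(mean < 0)) stop("mean must be nonnegative")
  mean / (1 + mean)
}

#' @rdname qFromMean
#' @export
meanFromQ <- function(q) {
  if (any(q < 0 | q >= 1)) stop("q must lie in [0, 1)")
  q / (1 - q)
}
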