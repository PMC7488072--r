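#' In-degree of each gene in a signed topology
#'
#' Counts incoming edges of either sign per gene. Genes with in-degree 0 are
#' the "initiating" genes of the calibration rules: they receive no
#' customers from within the system.
#'
#' @param pPlus,pMinus N x N routing matrices (only the zero pattern is
#'   used), or a [GeneNetwork-class] as first argument.
#' @return named integer vector of in-degrees.
#' @export
inDegree <- function(pPlus, pMinus = NULL) {
  if (is(pPlus, "GeneNetwork")) {
    net <- pPlus
    pPlus <- net@pPlus; pMinus <- net@pMinus
  }
  stopifnot(!is.null(pMinus))
  deg <- colSums(pPlus > 0) + colSums(pMinus > 0)
  out <- as.integer(deg)
  names(out) <- colnames(pPlus)
  out
}

#' External positive arrival rate rule
#'
#' Non-initiating genes receive \eqn{\lambda^+ = D^{in} + 3} (the offset 3
#' keeps the traffic-equation numerator away from 0); initiating genes
#' receive \eqn{\lambda^+ = \frac{\bar x}{\bar x + 1} \mu}, which makes
#' their stationary utilization match the mean expression level exactly.
#'
#' @param dIn in-degree(s).
#' @param mean mean expression level(s) (used for initiating genes).
#' @param mu service rate(s).
#' @return arrival rate(s).
#' @export
lambdaPlusRule <- function(dIn, mean, mu) {
  if (any(mean < 0)) stop("means must be nonnegative")
  ifelse(dIn > 0, dIn + 3, mean / (mean + 1) * mu)
}

#' External negative arrival rate rule
#'
#' Initiating genes are assumed to receive no external negative customers
#' (rate 0, so they stay consistently activated); all other genes have their
#' rate solved from the traffic equations via [solveLambdaMinus()].
#'
#' @param dIn in-degree(s).
#' @return numeric vector: 0 for initiating genes, NA (meaning "solve") for
#'   the rest.
#' @export
lambdaMinusRule <- function(dIn) {
  ifelse(dIn > 0, NA_real_, 0)
}

#' Solve external negative arrival rates from target utilizations
#'
#' Given routing probabilities, service rates, positive arrival rates and
#' target utilizations \eqn{\bar q_i = \bar x_i / (1 + \bar x_i)} derived
#' from mean expression levels, rearranges the traffic equation for each
#' gene:
#' \deqn{\lambda_i^- = \frac{\lambda_i^+ + \sum_j \bar q_j \mu_j p_{ji}^+}
#'       {\bar q_i} - \mu_i - \sum_j \bar q_j \mu_j p_{ji}^-}
#' so that the completed network's traffic fixed point equals \eqn{\bar q}.
#' For initiating genes (in-degree 0) the rate is set to 0 per
#' [lambdaMinusRule()]. Negative solutions indicate an infeasible
#' calibration and raise a warning.
#'
#' @param pPlus,pMinus routing matrices.
#' @param means mean expression levels (reference condition).
#' @param mu service rates.
#' @param lambdaPlus positive arrival rates; computed via
#'   [lambdaPlusRule()] when NULL.
#' @return named numeric vector of negative arrival rates.
#' @examples
#' net <- builtinNetwork("normal")
#' means <- c(4.724, 2.475, 2.484, 1.957, 2.662)
#' solveLambdaMinus(routingPos(net), routingNeg(net), means, serviceRates(net))
#' @export
solveLambdaMinus <- function(pPlus, pMinus, means, mu, lambdaPlus = NULL) {
  dIn <- inDegree(pPlus, pMinus)
  if (any(means < 0)) stop("means must be nonnegative")
  qbar <- qFromMean(means)
  if (any(qbar == 0 & dIn > 0))
    stop("mean expression is 0 for non-initiating gene(s) ",
         paste(which(qbar == 0 & dIn > 0), collapse = ", "),
         ": cannot divide by qbar = 0")
  if (is.null(lambdaPlus)) lambdaPlus <- lambdaPlusRule(dIn, means, mu)
  inPos <- as.vector(t(pPlus) %*% (qbar * mu))
  inNeg <- as.vector(t(pMinus) %*% (qbar * mu))
  lm <- (lambdaPlus + inPos) / qbar - mu - inNeg
  lm[dIn == 0] <- 0
  if (any(lm < 0))
    warning("calibration failure: negative lambda- for gene(s) ",
            paste(which(lm < 0), collapse = ", "))
  names(lm) <- names(dIn)
  lm
}

#' Calibrate a complete network from topology and mean expression levels
#'
#' Applies the arrival-rate rules ([lambdaPlusRule()], [lambdaMinusRule()],
#' [solveLambdaMinus()]) to a signed topology with given routing
#' probabilities and service rates, producing a fully parameterized
#' [GeneNetwork-class] whose stationary utilizations reproduce
#' \eqn{\bar x / (1 + \bar x)} of the supplied means.
#'
#' @param geneNames gene identifiers.
#' @param pPlus,pMinus routing-probability matrices (these are inputs to the
#'   calibration, not estimated).
#' @param means mean expression levels in the reference condition.
#' @param mu service rates.
#' @return a [GeneNetwork-class].
#' @export
calibrateNetwork <- function(geneNames, pPlus, pMinus, means, mu) {
  dIn <- inDegree(pPlus, pMinus)
  lp <- lambdaPlusRule(dIn, means, mu)
  lm <- solveLambdaMinus(pPlus, pMinus, means, mu, lambdaPlus = lp)
  if (any(lm < 0))
    stop("calibration failed: negative lambda- for gene(s) ",
         paste(geneNames[lm < 0], collapse = ", "))
  GeneNetwork(geneNames, lp, lm, mu, pPlus, pMinus)
}
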