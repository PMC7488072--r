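#' Construct a GeneNetwork
#'
#' Builds and (by default) validates a [GeneNetwork-class]. The departure
#' probabilities `d` may be omitted, in which case they are implied by
#' `d = 1 - rowSums(pPlus + pMinus)`. If given explicitly they must agree
#' with the implied values within `1e-9`.
#'
#' @param geneNames character vector of gene identifiers.
#' @param lambdaPlus,lambdaMinus external positive / negative customer
#'   arrival rates (events per unit time).
#' @param mu service rates (strictly positive).
#' @param pPlus,pMinus N x N routing-probability matrices (activation /
#'   repression); rows index the sending gene.
#' @param d optional departure probabilities.
#' @param validate if TRUE (default), stop when [validateNetwork()] reports
#'   violations. Set to FALSE to construct deliberately invalid networks
#'   (e.g. to inspect the violation report).
#' @return a [GeneNetwork-class] object.
#' @examples
#' net <- GeneNetwork("g1", lambdaPlus = 1, lambdaMinus = 0, mu = 2,
#'                    pPlus = matrix(0, 1, 1), pMinus = matrix(0, 1, 1))
#' @export
GeneNetwork <- function(geneNames, lambdaPlus, lambdaMinus, mu,
                        pPlus, pMinus, d = NULL, validate = TRUE) {
  geneNames <- as.character(geneNames)
  n <- length(geneNames)
  pPlus <- as.matrix(pPlus)
  pMinus <- as.matrix(pMinus)
  dimnames(pPlus) <- dimnames(pMinus) <- list(geneNames, geneNames)
  implied <- 1 - rowSums(pPlus) - rowSums(pMinus)
  if (is.null(d)) {
    d <- implied
  } else if (validate && any(abs(d - implied) > 1e-9)) {
    bad <- geneNames[abs(d - implied) > 1e-9]
    stop("explicit departure probabilities disagree with 1 - rowSums(p+ + p-) for gene(s): ",
         paste(bad, collapse = ", "))
  }
  net <- new("GeneNetwork",
             geneNames = geneNames,
             lambdaPlus = stats::setNames(as.numeric(lambdaPlus), geneNames),
             lambdaMinus = stats::setNames(as.numeric(lambdaMinus), geneNames),
             mu = stats::setNames(as.numeric(mu), geneNames),
             pPlus = pPlus, pMinus = pMinus,
             d = stats::setNames(as.numeric(d), geneNames))
  if (validate) {
    v <- validateNetwork(net)
    if (length(v)) stop("invalid network:\n  ", paste(v, collapse = "\n  "))
  }
  net
}

#' Validate a GeneNetwork against the G-network invariants
#'
#' Checks, per gene: probabilities in \[0, 1\] with zero diagonals, the
#' routing identity \eqn{d_i + \sum_j (p_{ij}^+ + p_{ij}^-) = 1} within
#' 1e-9, strictly positive service rates, and nonnegative arrival rates.
#' Violations are reported, not raised.
#'
#' @param net a [GeneNetwork-class].
#' @return a character vector of violation messages; empty iff the network
#'   satisfies every invariant.
#' @export
validateNetwork <- function(net) {
  stopifnot(is(net, "GeneNetwork"))
  g <- net@geneNames
  out <- character(0)
  say <- function(idx, what) sprintf("gene %s: %s", g[idx], what)
  for (nm in c("pPlus", "pMinus")) {
    p <- slot(net, nm)
    sgn <- if (nm == "pPlus") "p+" else "p-"
    bad <- which(p < 0 | p > 1, arr.ind = TRUE)
    if (nrow(bad)) out <- c(out, say(bad[, 1],
      sprintf("%s entries must lie in [0, 1]", sgn)))
    dg <- which(diag(p) != 0)
    if (length(dg)) out <- c(out, say(dg,
      sprintf("%s diagonal must be 0 (no self-routing)", sgn)))
  }
  rowTot <- net@d + rowSums(net@pPlus) + rowSums(net@pMinus)
  off <- which(abs(rowTot - 1) > 1e-9)
  if (length(off)) out <- c(out, say(off, sprintf(
    "d + sum(p+ + p-) must equal 1 (got %s)", format(rowTot[off]))))
  dbad <- which(net@d < -1e-9 | net@d > 1 + 1e-9)
  if (length(dbad)) out <- c(out, say(dbad, "departure probability must lie in [0, 1]"))
  mubad <- which(net@mu <= 0)
  if (length(mubad)) out <- c(out, say(mubad, "service rate must be positive"))
  for (nm in c("lambdaPlus", "lambdaMinus")) {
    lbad <- which(slot(net, nm) < 0)
    if (length(lbad)) out <- c(out, say(lbad, sprintf("%s must be nonnegative",
      if (nm == "lambdaPlus") "lambda+" else "lambda-")))
  }
  unname(out)
}

#' Enumerate the synchronizing events of a network
#'
#' Each nonzero off-diagonal routing probability defines one synchronizing
#' transition: the master gene completes a service and sends a positive or
#' negative customer to the slave gene. Events are ordered by master index,
#' then slave index, with positive before negative.
#'
#' @param net a valid [GeneNetwork-class].
#' @return a data.frame with columns `master`, `slave` (1-based indices),
#'   `masterName`, `slaveName`, `sign` ("+" or "-") and `rate`
#'   (\eqn{\mu_{master} \cdot p}).
#' @export
syncEvents <- function(net) {
  stopifnot(is(net, "GeneNetwork"))
  n <- nGenes(net)
  rows <- list()
  for (m in seq_len(n)) for (s in seq_len(n)) {
    if (m == s) next
    for (sgn in c("+", "-")) {
      p <- if (sgn == "+") net@pPlus[m, s] else net@pMinus[m, s]
      if (p > 0)
        rows[[length(rows) + 1L]] <- data.frame(
          master = m, slave = s,
          masterName = net@geneNames[m], slaveName = net@geneNames[s],
          sign = sgn, rate = net@mu[[m]] * p,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(master = integer(0), slave = integer(0),
                      masterName = character(0), slaveName = character(0),
                      sign = character(0), rate = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Built-in telomere-maintenance networks
#'
#' The five-gene network (CEBPA, E2F1, FOXM1, c-MYC, hTERT) governing
#' telomere maintenance, parameterized for normal fibroblast cell lines or
#' for ALT (alternative lengthening of telomeres) cancer cell lines. The
#' external arrival and service rates are shared between conditions; the
#' routing probabilities differ. Normal-condition probabilities printed to
#' three decimals are stored as the exact rationals 1/3 and 1/2; this is
#' what makes the calibrated degradation rates reproducible to five
#' significant digits (see [solveLambdaMinus()]).
#'
#' @param condition "normal" or "alt".
#' @return a [GeneNetwork-class].
#' @examples
#' net <- builtinNetwork("normal")
#' syncEvents(net)   # seven synchronizing transitions
#' @export
builtinNetwork <- function(condition = c("normal", "alt")) {
  condition <- match.arg(condition)
  g <- c("CEBPA", "E2F1", "FOXM1", "c-MYC", "hTERT")
  lp <- c(4, 4, 4, 5, 5)
  lm <- c(1.18489, 1.79118, 2.78510, 6.70809, 6.07682)
  mu <- c(3, 3, 2, 3, 1)
  pp <- matrix(0, 5, 5)
  pm <- matrix(0, 5, 5)
  if (condition == "normal") {
    pp[2, 4] <- 1 / 3   # E2F1 -> c-MYC
    pp[3, 4] <- 1 / 2   # FOXM1 -> c-MYC
    pp[4, 5] <- 1 / 3   # c-MYC -> hTERT
    pm[1, 2] <- 1 / 3   # CEBPA -| E2F1
    pm[1, 3] <- 1 / 3   # CEBPA -| FOXM1
    pm[2, 5] <- 1 / 3   # E2F1 -| hTERT
    pm[4, 1] <- 1 / 3   # c-MYC -| CEBPA
  } else {
    pp[2, 4] <- 0.5574
    pp[3, 4] <- 0.7583
    pp[4, 5] <- 0.3855
    pm[1, 2] <- 0.2268
    pm[1, 3] <- 0.2230
    pm[2, 5] <- 0.3168
    pm[4, 1] <- 0.5865
  }
  GeneNetwork(g, lp, lm, mu, pp, pm)
}

#' Mean expression levels bundled with the package
#'
#' Mean mRNA expression levels (normalized and scaled) of the five
#' telomere-maintenance genes, for two case/control cohorts: "alt"
#' (4 normal fibroblast lines vs 18 ALT lines) and "telomerase" (normal vs
#' 16 telomerase-positive lines). These drive the calibration examples.
#'
#' @param cohort "alt" or "telomerase".
#' @return a data.frame with columns `gene`, `condition`, `mean`.
#' @export
builtinExpression <- function(cohort = c("alt", "telomerase")) {
  cohort <- match.arg(cohort)
  path <- system.file("extdata",
                      paste0("expression_means_", cohort, "_cohort.tsv"),
                      package = "sangnet", mustWork = TRUE)
  readExpression(path)
}
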