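#' @import methods
#' @import Matrix
NULL

#' GeneNetwork: a G-network parameterization of a gene regulatory network
#'
#' A G-network models each gene as a queue holding "positive customers"
#' (mRNA molecules). Positive customers arrive externally at rate
#' \eqn{\lambda_i^+} (translation / protein bursting), negative customers
#' (degradation signals) at rate \eqn{\lambda_i^-}; a negative customer
#' removes one positive customer from a non-empty queue. Service completions
#' occur at rate \eqn{\mu_i}; the served customer either leaves the system
#' (probability \eqn{d_i}) or moves to gene \eqn{j} as a positive
#' (activation, \eqn{p_{ij}^+}) or negative (repression, \eqn{p_{ij}^-})
#' customer. Routing probabilities satisfy
#' \eqn{d_i + \sum_j (p_{ij}^+ + p_{ij}^-) = 1}.
#'
#' @slot geneNames character vector of gene identifiers (ordering is the
#'   authoritative index order used by all other modules).
#' @slot lambdaPlus,nonnegative external positive-customer arrival rates.
#' @slot lambdaMinus nonnegative external negative-customer arrival rates.
#' @slot mu strictly positive service rates.
#' @slot pPlus,pMinus N x N matrices of activation / repression routing
#'   probabilities (zero diagonal).
#' @slot d departure probabilities, implied by the routing rows.
#'
#' @seealso [GeneNetwork()], [validateNetwork()], [builtinNetwork()]
#' @export
setClass("GeneNetwork",
  slots = c(
    geneNames   = "character",
    lambdaPlus  = "numeric",
    lambdaMinus = "numeric",
    mu          = "numeric",
    pPlus       = "matrix",
    pMinus      = "matrix",
    d           = "numeric"
  )
)

setValidity("GeneNetwork", function(object) {
  n <- length(object@geneNames)
  msg <- character(0)
  if (n < 1L) msg <- c(msg, "network must contain at least one gene")
  for (sl in c("lambdaPlus", "lambdaMinus", "mu", "d"))
    if (length(slot(object, sl)) != n)
      msg <- c(msg, sprintf("slot '%s' must have length %d", sl, n))
  for (sl in c("pPlus", "pMinus"))
    if (!all(dim(slot(object, sl)) == c(n, n)))
      msg <- c(msg, sprintf("slot '%s' must be a %d x %d matrix", sl, n, n))
  if (anyDuplicated(object@geneNames))
    msg <- c(msg, "gene names must be unique")
  if (length(msg)) msg else TRUE
})

#' StationarySolution: fixed point of the G-network traffic equations
#'
#' Holds the per-gene stationary utilizations \eqn{q_i}, i.e. the limiting
#' probabilities that gene \eqn{i}'s queue is non-empty. When every
#' \eqn{q_i < 1} the joint stationary law is the product of geometric
#' marginals \eqn{(1-q_i) q_i^{x_i}}.
#'
#' @slot q named numeric vector of utilizations.
#' @slot iterations number of fixed-point iterations performed.
#' @slot residual maximum absolute change at termination.
#' @slot stable TRUE iff all q < 1 (product form valid).
#' @export
setClass("StationarySolution",
  slots = c(
    q          = "numeric",
    iterations = "integer",
    residual   = "numeric",
    stable     = "logical"
  )
)

#' TruncatedGenerator: the truncated global CTMC generator
#'
#' Sparse \eqn{K^N \times K^N} infinitesimal generator of the network
#' truncated to per-gene expression levels \eqn{\{0, \dots, K-1\}}. State
#' indexing is mixed-radix with gene 1 as the leftmost Kronecker factor,
#' so gene N varies fastest along the state index.
#'
#' @slot Q sparse rate matrix (off-diagonals >= 0, zero row sums).
#' @slot K truncation level.
#' @slot N number of genes.
#' @slot geneNames gene identifiers in index order.
#' @slot semantics boundary semantics used ("blocking" or "classical").
#' @slot indexOrder human-readable record of the indexing convention.
#' @export
setClass("TruncatedGenerator",
  slots = c(
    Q          = "sparseMatrix",
    K          = "integer",
    N          = "integer",
    geneNames  = "character",
    semantics  = "character",
    indexOrder = "character"
  )
)

setValidity("TruncatedGenerator", function(object) {
  msg <- character(0)
  if (nrow(object@Q) != object@K^object@N)
    msg <- c(msg, "generator dimension must equal K^N")
  if (nrow(object@Q) != ncol(object@Q))
    msg <- c(msg, "generator must be square")
  if (length(msg)) msg else TRUE
})

#' PairProjector: marginalization operators for a gene pair
#'
#' The projector \eqn{C_{i,j}} (\eqn{K^N \times K^2}) marginalizes a global
#' state distribution onto the joint law of genes i and j; its companion
#' \eqn{C^*_{i,j}} (\eqn{K^2 \times K^N}) lifts a pair distribution to the
#' global space with the remaining genes uniform. They satisfy
#' \eqn{C^* C = K^{N-2} I_{K^2}} exactly.
#'
#' @slot C,Cstar the sparse projector matrices.
#' @slot i,j gene indices (1-based, in global order).
#' @slot N,K problem dimensions.
#' @export
setClass("PairProjector",
  slots = c(
    C     = "sparseMatrix",
    Cstar = "sparseMatrix",
    i     = "integer",
    j     = "integer",
    N     = "integer",
    K     = "integer"
  )
)

#' PairJointDistribution: joint pmf of a gene pair at one time point
#'
#' @slot P K x K matrix; entry (a+1, b+1) is P(x_i = a, x_j = b) at time t.
#'   Row index follows the gene earlier in the global ordering.
#' @slot i,j gene indices.
#' @slot t model time.
#' @export
setClass("PairJointDistribution",
  slots = c(
    P = "matrix",
    i = "integer",
    j = "integer",
    t = "numeric"
  )
)

setValidity("PairJointDistribution", function(object) {
  msg <- character(0)
  if (nrow(object@P) != ncol(object@P))
    msg <- c(msg, "joint table must be square")
  if (min(object@P) < -1e-12)
    msg <- c(msg, "joint probabilities must be >= -1e-12")
  if (abs(sum(object@P) - 1) > 1e-8)
    msg <- c(msg, "joint probabilities must sum to 1 within 1e-8")
  if (length(msg)) msg else TRUE
})

#' TrajectorySample: one simulated continuous-time path
#'
#' @slot times increasing event times (time 0 is the initial state).
#' @slot states (nEvents + 1) x N integer matrix of expression levels;
#'   row 1 is the initial state.
#' @slot events event labels ("ext_pos(i)", "ext_neg(i)", "depart(i)",
#'   "transfer_pos(i,j)", "transfer_neg(i,j)").
#' @slot seed RNG seed used.
#' @slot mode "unbounded" or "truncated".
#' @slot semantics boundary semantics ("blocking" or "classical").
#' @export
setClass("TrajectorySample",
  slots = c(
    times     = "numeric",
    states    = "matrix",
    events    = "character",
    seed      = "integer",
    mode      = "character",
    semantics = "character"
  )
)

#' EcdfResult: empirical CDF of one gene's level after a fixed event count
#'
#' @slot gene gene name.
#' @slot sample integer vector (length M) of the gene's level at the end of
#'   each replicate path.
#' @slot x evaluation points 0..max(sample).
#' @slot Fhat empirical CDF at x.
#' @slot nEvents events per replicate.
#' @slot M replicate count.
#' @export
setClass("EcdfResult",
  slots = c(
    gene    = "character",
    sample  = "integer",
    x       = "integer",
    Fhat    = "numeric",
    nEvents = "integer",
    M       = "integer"
  )
)
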