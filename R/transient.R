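## Matrix-exponential action by uniformization.
##
## For a generator Q with uniformization rate Lam >= max_i |Q[i,i]|, the
## stochastic matrix P = I + Q/Lam gives
##   v e^{Qt} = sum_{n>=0} e^{-a} a^n/n! (v P^n),  a = Lam t.
## Poisson weights are accumulated in log space so large a poses no
## under/overflow problem, and the series is truncated once past the Poisson
## mode with relative weight below `tol`. Probability vectors stay
## nonnegative because every term is a product of nonnegative quantities.
.uniformized <- function(Q) {
  lam <- max(-Matrix::diag(Q))
  if (lam <= 0) return(NULL)
  lam <- lam * (1 + 1e-12)
  P <- Q / lam
  Matrix::diag(P) <- Matrix::diag(P) + 1
  list(P = P, lam = lam)
}

.expActionLeft <- function(Q, v, t, tol = 1e-14, unif = NULL) {
  if (t < 0) stop("t must be nonnegative")
  if (t == 0) return(v)
  if (is.null(unif)) unif <- .uniformized(Q)
  if (is.null(unif)) return(v)           # Q == 0
  a <- unif$lam * t
  res <- v * exp(-a)
  term <- v
  lw <- -a
  nMax <- ceiling(a + 10 * sqrt(a + 1) + 30)
  for (n in seq_len(nMax)) {
    term <- as.vector(term %*% unif$P)
    lw <- lw + log(a) - log(n)
    w <- exp(lw)
    res <- res + term * w
    if (n > a && w < tol) break
  }
  res
}

## right action e^{Qt} W on the columns of a (dense) matrix W
.expActionRight <- function(Q, W, t, tol = 1e-14) {
  if (t < 0) stop("t must be nonnegative")
  W <- as.matrix(W)
  if (t == 0) return(W)
  unif <- .uniformized(Q)
  if (is.null(unif)) return(W)
  a <- unif$lam * t
  res <- W * exp(-a)
  term <- W
  lw <- -a
  nMax <- ceiling(a + 10 * sqrt(a + 1) + 30)
  for (n in seq_len(nMax)) {
    term <- as.matrix(unif$P %*% term)
    lw <- lw + log(a) - log(n)
    w <- exp(lw)
    res <- res + term * w
    if (n > a && w < tol) break
  }
  res
}

#' Transient state distribution pi(t) = pi(0) e^{Qt}
#'
#' Propagates a probability vector over the truncated state space by the
#' action of the matrix exponential (uniformization); the full K^N x K^N
#' exponential is never formed.
#'
#' @param gen a [TruncatedGenerator-class].
#' @param pi0 initial probability vector of length K^N (sums to 1).
#' @param t time (>= 0).
#' @return probability vector at time t.
#' @export
stateDistribution <- function(gen, pi0, t) {
  stopifnot(is(gen, "TruncatedGenerator"))
  if (length(pi0) != nrow(gen@Q)) stop("pi0 must have length K^N")
  if (abs(sum(pi0) - 1) > 1e-8) stop("pi0 must sum to 1")
  if (t < 0) stop("t must be nonnegative")
  .expActionLeft(gen@Q, pi0, t)
}

#' Pair projection operators C and C*
#'
#' \eqn{C_{i,j} = \bigotimes_n U_n} with \eqn{U_n = I_K} when n is i or j
#' and the all-ones column otherwise; \eqn{C^*_{i,j}} analogously with
#' all-ones rows. They satisfy \eqn{C^* C = K^{N-2} I_{K^2}} exactly. The
#' Kronecker position of each factor matches the global state indexing, so
#' the pair index runs with the earlier gene (in global order) as the major
#' index.
#'
#' @param N number of genes.
#' @param K truncation level.
#' @param i,j distinct gene indices in 1..N.
#' @return a [PairProjector-class].
#' @examples
#' pp <- pairProjectors(5, 7, 1, 2)
#' # crossprod identity: C* C = 7^3 I_49
#' @export
pairProjectors <- function(N, K, i, j) {
  if (i == j) stop("gene indices must be distinct")
  stopifnot(i >= 1, j <= N, j >= 1, i <= N, K >= 2)
  ones <- Matrix::Matrix(1, K, 1, sparse = TRUE)
  I <- Matrix::Diagonal(K)
  U <- lapply(seq_len(N), function(n) if (n == i || n == j) I else ones)
  V <- lapply(seq_len(N), function(n) if (n == i || n == j) I else t(ones))
  ## Class must be named: a bare new("PairProjector", C = ...) would let the
  ## argument "C" partially match new()'s formal "Class"
  new(Class = "PairProjector",
      C = .asSparse(.kronChain(U)), Cstar = .asSparse(.kronChain(V)),
      i = as.integer(min(i, j)), j = as.integer(max(i, j)),
      N = as.integer(N), K = as.integer(K))
}

#' Pairwise transient kernel
#'
#' The K^2 x K^2 kernel
#' \deqn{e^{Q_{i,j} t} := K^{-(N-2)} \, C^*_{i,j} \, e^{Qt} \, C_{i,j}}
#' mapping an initial joint pmf of genes (i, j) to the joint pmf at time t.
#' \eqn{e^{Qt} C} is computed by exponential action on the K^2 columns of C.
#' The kernel is row-stochastic and equals the identity at t = 0.
#'
#' @param gen a [TruncatedGenerator-class].
#' @param i,j distinct gene indices.
#' @param t time (>= 0).
#' @return a dense K^2 x K^2 matrix.
#' @export
jointKernel <- function(gen, i, j, t) {
  stopifnot(is(gen, "TruncatedGenerator"))
  if (i == j) stop("gene indices must be distinct")
  if (t < 0) stop("t must be nonnegative")
  pr <- pairProjectors(gen@N, gen@K, i, j)
  W <- .expActionRight(gen@Q, pr@C, t)
  as.matrix(pr@Cstar %*% W) / gen@K^(gen@N - 2)
}

## flatten a K x K pair pmf to the length-K^2 vector matching the
## projectors' index order (major index = earlier gene in global order)
.flattenPair <- function(P) as.vector(t(P))
.unflattenPair <- function(v, K) matrix(v, K, K, byrow = TRUE)

#' Propagate a pair joint distribution through a kernel
#'
#' @param pi0 K x K initial joint pmf of the gene pair (rows index the gene
#'   earlier in the global ordering).
#' @param kernel a K^2 x K^2 kernel from [jointKernel()].
#' @param i,j,t optional metadata recorded in the result.
#' @return a [PairJointDistribution-class].
#' @export
jointDistribution <- function(pi0, kernel, i = 1L, j = 2L, t = NA_real_) {
  pi0 <- as.matrix(pi0)
  K <- nrow(pi0)
  if (ncol(pi0) != K) stop("pi0 must be square")
  if (!all(dim(kernel) == K^2))
    stop(sprintf("kernel dimension %d does not match K^2 = %d", nrow(kernel), K^2))
  if (abs(sum(pi0) - 1) > 1e-8) stop("pi0 must sum to 1")
  out <- .unflattenPair(as.vector(.flattenPair(pi0) %*% kernel), K)
  new("PairJointDistribution", P = out, i = as.integer(i), j = as.integer(j),
      t = as.numeric(t))
}

#' Default initial joint pmf for a gene pair
#'
#' The "positive" variant puts weight 5 on the diagonal and 1 on the first
#' off-diagonals (for K = 7 this is the tridiagonal matrix with entries
#' 5/47 and 1/47), modelling a strongly positively correlated pair at time
#' zero. The "negative" variant applies the same band to the anti-diagonal,
#' a convention for a strongly negatively correlated start.
#'
#' @param K truncation level (>= 2).
#' @param sign "positive" or "negative".
#' @return a K x K pmf.
#' @export
defaultInitialPairPMF <- function(K = 7, sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  if (K < 2) stop("K must be at least 2")
  W <- diag(5, K)
  for (k in seq_len(K - 1)) W[k, k + 1] <- W[k + 1, k] <- 1
  if (sign == "negative") W <- W[, K:1]
  W / sum(W)
}

#' Pearson correlation of a pair joint pmf
#'
#' Moments are taken over the support values \{0, ..., K-1\} weighted by the
#' joint table.
#'
#' @param P a [PairJointDistribution-class] or a plain K x K pmf matrix.
#' @return the correlation coefficient.
#' @export
pearsonCorrelation <- function(P) {
  if (is(P, "PairJointDistribution")) P <- P@P
  P <- as.matrix(P)
  K <- nrow(P)
  s <- 0:(K - 1)
  mi <- rowSums(P); mj <- colSums(P)
  Ei <- sum(s * mi); Ej <- sum(s * mj)
  vi <- sum(s^2 * mi) - Ei^2; vj <- sum(s^2 * mj) - Ej^2
  if (vi <= 0 || vj <= 0) stop("degenerate marginal: zero variance")
  (sum(outer(s, s) * P) - Ei * Ej) / sqrt(vi * vj)
}

#' Pearson correlation trajectories of gene pairs
#'
#' For each requested pair and time point, computes the joint transient
#' distribution of the pair through the projection kernel and its Pearson
#' correlation. Internally the (mathematically identical) vector form is
#' used: the initial global vector \eqn{v_0 = \pi_{i,j}(0) C^* / K^{N-2}}
#' (pair pmf times uniform background) is propagated once by exponential
#' action and marginalized by C at each time, which avoids the K^2-column
#' kernel computation at every time point.
#'
#' @param net a valid [GeneNetwork-class].
#' @param K truncation level (default 7).
#' @param pairs gene pairs: a 2-column matrix of gene names or indices, a
#'   character vector like `"CEBPA:E2F1"`, or NULL for all pairs.
#' @param times nondecreasing time grid (default `seq(0, 1, by = 0.02)`).
#' @param pi0 K x K initial joint pmf applied to every pair (default the
#'   positive [defaultInitialPairPMF()]).
#' @param gen optionally a pre-assembled [TruncatedGenerator-class]
#'   (must match `net` and `K`).
#' @return a data.frame with columns `pair`, `gene_i`, `gene_j`, `time`,
#'   `rho`.
#' @export
correlationTrajectory <- function(net, K = 7, pairs = NULL,
                                  times = seq(0, 1, by = 0.02),
                                  pi0 = NULL, gen = NULL) {
  stopifnot(is(net, "GeneNetwork"))
  N <- nGenes(net)
  if (N < 2) stop("need at least two genes")
  if (any(diff(times) < 0)) stop("times must be nondecreasing")
  if (any(times < 0)) stop("times must be nonnegative")
  if (is.null(pi0)) pi0 <- defaultInitialPairPMF(K)
  pi0 <- as.matrix(pi0)
  if (nrow(pi0) != K) stop("pi0 must be K x K")
  pairIdx <- .resolvePairs(pairs, net@geneNames)
  if (is.null(gen)) gen <- assembleGenerator(net, K)
  stopifnot(gen@K == K, gen@N == N)
  unif <- .uniformized(gen@Q)
  lv <- .levelsMatrix(N, K)
  out <- vector("list", nrow(pairIdx))
  for (r in seq_len(nrow(pairIdx))) {
    i <- pairIdx[r, 1]; j <- pairIdx[r, 2]
    grp <- lv[, i] * K + lv[, j]
    v <- pi0[cbind(lv[, i] + 1, lv[, j] + 1)] / K^(N - 2)
    rho <- numeric(length(times))
    tPrev <- 0
    for (k in seq_along(times)) {
      v <- .expActionLeft(gen@Q, v, times[k] - tPrev, unif = unif)
      tPrev <- times[k]
      agg <- rowsum(v, grp)
      Pt <- matrix(agg[order(as.integer(rownames(agg)))], K, K, byrow = TRUE)
      rho[k] <- pearsonCorrelation(Pt)
    }
    out[[r]] <- data.frame(
      pair = paste(net@geneNames[i], net@geneNames[j], sep = ":"),
      gene_i = net@geneNames[i], gene_j = net@geneNames[j],
      time = times, rho = rho, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

## pairs -> 2-column index matrix (i < j), defaulting to all pairs
.resolvePairs <- function(pairs, geneNames) {
  N <- length(geneNames)
  if (is.null(pairs)) {
    cmb <- utils::combn(N, 2)
    return(t(cmb))
  }
  if (is.character(pairs)) {
    pieces <- strsplit(pairs, ":", fixed = TRUE)
    bad <- lengths(pieces) != 2
    if (any(bad)) stop("pair specifications must look like 'GENE1:GENE2'")
    pairs <- do.call(rbind, pieces)
  }
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2) stop("pairs must have two columns")
  toIdx <- function(v) {
    if (is.numeric(v)) return(as.integer(v))
    idx <- match(v, geneNames)
    if (anyNA(idx)) stop("unknown gene name(s): ",
                         paste(unique(v[is.na(idx)]), collapse = ", "))
    idx
  }
  i <- toIdx(pairs[, 1]); j <- toIdx(pairs[, 2])
  if (any(i < 1 | i > N | j < 1 | j > N)) stop("gene index out of range")
  if (any(i == j)) stop("pair members must be distinct")
  cbind(pmin(i, j), pmax(i, j))
}
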