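## state indexing: mixed-radix over levels {0..K-1}, gene 1 is the leftmost
## Kronecker factor (most significant digit); gene N varies fastest.
.INDEX_ORDER <- "mixed-radix state index: gene 1 leftmost Kronecker factor, gene N varies fastest"

.levelsMatrix <- function(N, K) {
  idx <- 0:(K^N - 1)
  vapply(seq_len(N), function(n) (idx %/% K^(N - n)) %% K, numeric(K^N))
}

.encodeState <- function(x, K) {
  N <- length(x)
  as.integer(sum(x * K^(N - seq_len(N))) + 1)
}

.asSparse <- function(M) as(as(as(M, "dMatrix"), "generalMatrix"), "CsparseMatrix")

#' Elementary K x K matrices of the SAN construction
#'
#' The building blocks of the local and synchronizing rate matrices:
#' `Upp` / `Low` carry ones on the first super- / sub-diagonal, `I10` is the
#' identity with its first diagonal entry zeroed, `IK0` the identity with
#' its last diagonal entry zeroed, and `I` the identity.
#'
#' @param K truncation level (at least 2).
#' @return a named list of sparse K x K matrices.
#' @export
elementaryMatrices <- function(K) {
  if (K < 2) stop("K must be at least 2")
  list(
    Upp = Matrix::sparseMatrix(i = 1:(K - 1), j = 2:K, x = 1, dims = c(K, K)),
    Low = Matrix::sparseMatrix(i = 2:K, j = 1:(K - 1), x = 1, dims = c(K, K)),
    I10 = Matrix::Diagonal(K, c(0, rep(1, K - 1))),
    IK0 = Matrix::Diagonal(K, c(rep(1, K - 1), 0)),
    I   = Matrix::Diagonal(K))
}

#' Local transition rate matrix of one gene
#'
#' \deqn{L_i = \lambda_i^+ (Upp - I_K^0) + \mu_i d_i (Low - I_1^0)
#'            + \lambda_i^- (Low - I_1^0)}
#' i.e. a birth-death generator on \{0..K-1\} with birth rate
#' \eqn{\lambda_i^+} (blocked at K-1) and death rate
#' \eqn{\mu_i d_i + \lambda_i^-} (inactive at 0).
#'
#' @param net a valid [GeneNetwork-class].
#' @param i gene index.
#' @param K truncation level.
#' @return a sparse K x K generator (zero row sums).
#' @export
localMatrix <- function(net, i, K) {
  stopifnot(is(net, "GeneNetwork"), i >= 1, i <= nGenes(net))
  e <- elementaryMatrices(K)
  net@lambdaPlus[[i]] * (e$Upp - e$IK0) +
    (net@mu[[i]] * net@d[[i]] + net@lambdaMinus[[i]]) * (e$Low - e$I10)
}

#' Synchronization matrices of one event
#'
#' For a synchronizing event (master m sends a customer to slave s with sign
#' +/-), returns the master transition-rate matrix
#' \eqn{D = \mu_m p (Low - I_1^0)}, its diagonal part `Dbar`, the slave
#' transition-probability matrix `E` (`Upp` for a positive customer, `Low`
#' for a negative one), and the slave factor of the normalizing tensor
#' (`IK0` for positive, `I10` for negative). The assembled synchronization
#' term places the off-diagonal part `D - Dbar` at the master slot and `E`
#' at the slave slot, and the normalizer places `Dbar` at the master slot
#' with the slave factor — the diagonal of `D` is used exactly once.
#'
#' @param net a valid [GeneNetwork-class].
#' @param event one row of [syncEvents()] (a list/data.frame row with
#'   `master`, `slave`, `sign`).
#' @param K truncation level.
#' @return a named list of sparse K x K matrices: `D`, `Dbar`, `E`,
#'   `Nslave`.
#' @export
syncMatrices <- function(net, event, K) {
  stopifnot(is(net, "GeneNetwork"))
  m <- event$master; s <- event$slave; sgn <- event$sign
  if (m == s) stop("master and slave must differ")
  p <- if (sgn == "+") net@pPlus[m, s] else net@pMinus[m, s]
  if (p <= 0) stop("event has zero routing probability")
  e <- elementaryMatrices(K)
  rate <- net@mu[[m]] * p
  list(D = rate * (e$Low - e$I10),
       Dbar = -rate * e$I10,
       E = if (sgn == "+") e$Upp else e$Low,
       Nslave = if (sgn == "+") e$IK0 else e$I10)
}

.kronChain <- function(mats) Reduce(function(a, b) kronecker(a, b), mats)

#' Assemble the truncated global generator by Kronecker structure
#'
#' Builds the \eqn{K^N \times K^N} infinitesimal generator
#' \deqn{Q = \bigoplus_i L_i + \sum_r \left(\bigotimes_i M_{r,i}
#'           + \bigotimes_i N_{r,i}\right)}
#' where the tensor-product term of event r has \eqn{D_r - \bar D_r} at the
#' master slot and \eqn{E_r} at the slave slot, and the normalizing term has
#' \eqn{\bar D_r} at the master slot and \eqn{I_K^0} (positive) or
#' \eqn{I_1^0} (negative) at the slave slot.
#'
#' Boundary semantics follow these matrices literally: a synchronized
#' transfer is disabled whenever the slave cannot move (slave at 0 for a
#' negative transfer, at K-1 for a positive one), and external positive
#' arrivals are blocked at level K-1 with no renormalization of lost mass.
#'
#' @param net a valid [GeneNetwork-class].
#' @param K truncation level.
#' @param sizeCap refuse to build generators larger than this dimension
#'   (default 2^21 states).
#' @return a [TruncatedGenerator-class] (semantics slot `"blocking"`).
#' @examples
#' gen <- assembleGenerator(builtinNetwork("normal"), K = 3)
#' max(abs(Matrix::rowSums(generatorMatrix(gen))))  # ~0
#' @export
assembleGenerator <- function(net, K, sizeCap = 2^21) {
  stopifnot(is(net, "GeneNetwork"), K >= 2)
  N <- nGenes(net)
  if (K^N > sizeCap)
    stop(sprintf("state space K^N = %g exceeds the size cap %g; use a smaller K",
                 K^N, sizeCap))
  e <- elementaryMatrices(K)
  S <- K^N
  Q <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(S, S))
  for (i in seq_len(N)) {
    mats <- rep(list(e$I), N)
    mats[[i]] <- localMatrix(net, i, K)
    Q <- Q + .kronChain(mats)
  }
  ev <- syncEvents(net)
  for (r in seq_len(nrow(ev))) {
    sm <- syncMatrices(net, ev[r, ], K)
    mats <- rep(list(e$I), N)
    mats[[ev$master[r]]] <- sm$D - sm$Dbar
    mats[[ev$slave[r]]] <- sm$E
    Q <- Q + .kronChain(mats)
    nrm <- rep(list(e$I), N)
    nrm[[ev$master[r]]] <- sm$Dbar
    nrm[[ev$slave[r]]] <- sm$Nslave
    Q <- Q + .kronChain(nrm)
  }
  new("TruncatedGenerator", Q = .asSparse(Q), K = as.integer(K),
      N = as.integer(N), geneNames = net@geneNames,
      semantics = "blocking", indexOrder = .INDEX_ORDER)
}

#' Build the truncated generator by brute-force state enumeration
#'
#' Independent construction of the same CTMC by looping over all K^N states
#' and listing transitions directly: per gene i with x_i > 0, departure at
#' rate \eqn{\mu_i d_i} and external negative arrival at rate
#' \eqn{\lambda_i^-} (both to \eqn{x_i - 1}); external positive arrival at
#' rate \eqn{\lambda_i^+} to \eqn{x_i + 1} when \eqn{x_i < K-1}; per
#' synchronizing event, rate \eqn{\mu_i p_{ij}^\pm} to the paired move.
#' Under `"blocking"` semantics a transfer is disabled when the slave is at its
#' boundary; under `"classical"` semantics the master still fires (the
#' transferred customer vanishes at the boundary), which is the dynamics for
#' which the product-form stationary law holds.
#'
#' Intended as a test oracle for [assembleGenerator()]; only usable for
#' small K^N.
#'
#' @param net a valid [GeneNetwork-class].
#' @param K truncation level.
#' @param semantics "blocking" or "classical".
#' @return a [TruncatedGenerator-class].
#' @export
enumerateGenerator <- function(net, K, semantics = c("blocking", "classical")) {
  semantics <- match.arg(semantics)
  stopifnot(is(net, "GeneNetwork"), K >= 2)
  N <- nGenes(net)
  S <- K^N
  if (S > 50000) stop("enumeration is only meant for small state spaces")
  lv <- .levelsMatrix(N, K)
  ev <- syncEvents(net)
  cap <- S * (2L * N + 2L * max(1L, nrow(syncEvents(net))))
  fromI <- integer(cap); toI <- integer(cap); rate <- numeric(cap)
  nT <- 0L
  add <- function(f, t, r) {
    nT <<- nT + 1L
    fromI[nT] <<- f; toI[nT] <<- t; rate[nT] <<- r
  }
  for (s in seq_len(S)) {
    x <- lv[s, ]
    for (i in seq_len(N)) {
      if (x[i] < K - 1)
        add(s, .encodeState(replace(x, i, x[i] + 1), K), net@lambdaPlus[[i]])
      if (x[i] > 0) {
        add(s, .encodeState(replace(x, i, x[i] - 1), K),
            net@mu[[i]] * net@d[[i]] + net@lambdaMinus[[i]])
      }
    }
    for (r in seq_len(nrow(ev))) {
      i <- ev$master[r]; j <- ev$slave[r]
      if (x[i] == 0) next
      xm <- replace(x, i, x[i] - 1)
      if (ev$sign[r] == "+") {
        if (x[j] < K - 1) add(s, .encodeState(replace(xm, j, x[j] + 1), K), ev$rate[r])
        else if (semantics == "classical") add(s, .encodeState(xm, K), ev$rate[r])
      } else {
        if (x[j] > 0) add(s, .encodeState(replace(xm, j, x[j] - 1), K), ev$rate[r])
        else if (semantics == "classical") add(s, .encodeState(xm, K), ev$rate[r])
      }
    }
  }
  Q <- Matrix::sparseMatrix(i = fromI[seq_len(nT)], j = toI[seq_len(nT)],
                            x = rate[seq_len(nT)], dims = c(S, S))
  Matrix::diag(Q) <- Matrix::diag(Q) - Matrix::rowSums(Q)
  new("TruncatedGenerator", Q = .asSparse(Q), K = as.integer(K),
      N = as.integer(N), geneNames = net@geneNames,
      semantics = semantics, indexOrder = .INDEX_ORDER)
}

#' Export a generator in Matrix Market format
#'
#' Writes `Q` in MatrixMarket coordinate format plus a JSON sidecar
#' recording K, N, the gene order, the semantics and the indexing
#' convention.
#'
#' @param gen a [TruncatedGenerator-class].
#' @param path output path for the `.mtx` file; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
writeGeneratorMTX <- function(gen, path) {
  stopifnot(is(gen, "TruncatedGenerator"))
  Matrix::writeMM(gen@Q, path)
  jsonlite::write_json(
    list(K = gen@K, N = gen@N, genes = gen@geneNames,
         semantics = gen@semantics, index_order = gen@indexOrder),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
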