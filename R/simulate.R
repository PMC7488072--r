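## Event table shared by the single-path and ensemble simulators.
## Types: per gene i, ext_pos(i) / ext_neg(i) / depart(i); per synchronizing
## event, transfer_pos(i,j) / transfer_neg(i,j). Rates follow the G-network
## movement rules: a gene must be non-empty to lose a customer; under
## "blocking" semantics a transfer additionally requires the slave to be able
## to move, under "classical" semantics the master fires regardless and the
## transferred customer vanishes at the slave's boundary.
.eventTable <- function(net) {
  N <- nGenes(net)
  ev <- syncEvents(net)
  data.frame(
    type = c(rep("ext_pos", N), rep("ext_neg", N), rep("depart", N),
             ifelse(ev$sign == "+", "transfer_pos", "transfer_neg")),
    i = c(seq_len(N), seq_len(N), seq_len(N), ev$master),
    j = c(rep(NA_integer_, 3 * N), ev$slave),
    rate = c(net@lambdaPlus, net@lambdaMinus, net@mu * net@d, ev$rate),
    stringsAsFactors = FALSE)
}

.eventLabel <- function(tab, k) {
  if (is.na(tab$j[k])) sprintf("%s(%d)", tab$type[k], tab$i[k])
  else sprintf("%s(%d,%d)", tab$type[k], tab$i[k], tab$j[k])
}

## active-rate vector at state x (single path)
.activeRates <- function(tab, x, K, mode, semantics) {
  r <- tab$rate
  up <- if (mode == "truncated") x < K - 1 else rep(TRUE, length(x))
  for (k in seq_len(nrow(tab))) {
    i <- tab$i[k]; j <- tab$j[k]
    ok <- switch(tab$type[k],
      ext_pos = up[i],
      ext_neg = x[i] > 0,
      depart = x[i] > 0,
      transfer_pos = x[i] > 0 && (semantics == "classical" || up[j]),
      transfer_neg = x[i] > 0 && (semantics == "classical" || x[j] > 0))
    if (!ok) r[k] <- 0
  }
  r
}

.applyEvent <- function(tab, k, x, K, mode, semantics) {
  i <- tab$i[k]; j <- tab$j[k]
  switch(tab$type[k],
    ext_pos = { x[i] <- x[i] + 1 },
    ext_neg = { x[i] <- x[i] - 1 },
    depart  = { x[i] <- x[i] - 1 },
    transfer_pos = {
      x[i] <- x[i] - 1
      if (mode != "truncated" || x[j] < K - 1) x[j] <- x[j] + 1
      # else: customer lost at the truncation boundary (classical only;
      # under blocking semantics the event was not active)
    },
    transfer_neg = {
      x[i] <- x[i] - 1
      if (x[j] > 0) x[j] <- x[j] - 1
    })
  x
}

#' Simulate one continuous-time path of the G-network
#'
#' Standard next-event (Gillespie) simulation of the network CTMC. Each
#' state change is one of the four G-network movements: a gene gains a
#' customer (external positive arrival), loses one (departure or external
#' negative arrival), or a synchronized transfer moves/removes customers at
#' a master-slave pair.
#'
#' @param net a valid [GeneNetwork-class].
#' @param x0 initial state (nonnegative integer vector of length N).
#' @param nEvents number of events to simulate.
#' @param seed RNG seed (paths are bit-reproducible given the seed).
#' @param mode "unbounded" (infinite state space, the regime of the
#'   product-form theory) or "truncated" (levels capped at K-1, matching the
#'   assembled generator).
#' @param K truncation level (required for mode = "truncated").
#' @param semantics "classical" (default: a transfer to a blocked slave
#'   still decrements the master, as in the G-network product-form theory)
#'   or "blocking" (the transfer is disabled, matching [assembleGenerator()]).
#' @return a [TrajectorySample-class].
#' @export
simulatePath <- function(net, x0 = NULL, nEvents = 100L, seed = 1L,
                         mode = c("unbounded", "truncated"), K = NULL,
                         semantics = c("classical", "blocking")) {
  mode <- match.arg(mode)
  semantics <- match.arg(semantics)
  stopifnot(is(net, "GeneNetwork"))
  N <- nGenes(net)
  if (is.null(x0)) x0 <- rep(0L, N)
  if (length(x0) != N || any(x0 < 0)) stop("x0 must be a nonnegative vector of length N")
  if (mode == "truncated") {
    if (is.null(K)) stop("mode = 'truncated' requires K")
    if (any(x0 > K - 1)) stop("x0 exceeds the truncation level")
  }
  set.seed(seed)
  tab <- .eventTable(net)
  x <- as.integer(x0)
  times <- numeric(nEvents)
  states <- matrix(0L, nEvents + 1L, N)
  states[1L, ] <- x
  events <- character(nEvents)
  tNow <- 0
  for (step in seq_len(nEvents)) {
    r <- .activeRates(tab, x, K, mode, semantics)
    tot <- sum(r)
    if (tot <= 0) stop("absorbing state reached at event ", step)
    tNow <- tNow + stats::rexp(1, tot)
    k <- sample.int(nrow(tab), 1L, prob = r)
    x <- .applyEvent(tab, k, x, K, mode, semantics)
    times[step] <- tNow
    states[step + 1L, ] <- x
    events[step] <- .eventLabel(tab, k)
  }
  colnames(states) <- net@geneNames
  new("TrajectorySample", times = c(0, times), states = states,
      events = events, seed = as.integer(seed), mode = mode,
      semantics = semantics)
}

## Lockstep ensemble of the *uniformized* chain: all M replicates advance one
## step at a time, vectorized across replicates. At each step an event is
## drawn with probability (active rate)/Lam, where Lam bounds the total rate
## in every state; otherwise the replicate self-loops. After n steps a
## replicate is distributed as the CTMC at an Erlang(n, Lam) time, so the
## step-indexed ensemble converges to the CTMC's stationary law (sampling at
## the n-th true event would instead converge to the jump-chain law, which
## over-weights high-activity states). Only final states are retained.
.simulateEnsembleFinal <- function(net, x0, nEvents, M, seed,
                                   mode = "unbounded", K = NULL,
                                   semantics = "classical") {
  N <- nGenes(net)
  tab <- .eventTable(net)
  nE <- nrow(tab)
  Lam <- sum(net@lambdaPlus + net@lambdaMinus + net@mu)  # total-rate bound
  if (Lam <= 0) stop("network has no positive rates")
  set.seed(seed)
  X <- matrix(rep(as.integer(x0), each = M), M, N)
  for (step in seq_len(nEvents)) {
    R <- matrix(tab$rate, M, nE, byrow = TRUE)
    for (k in seq_len(nE)) {
      i <- tab$i[k]; j <- tab$j[k]
      act <- switch(tab$type[k],
        ext_pos = if (mode == "truncated") X[, i] < K - 1 else TRUE,
        ext_neg = X[, i] > 0,
        depart  = X[, i] > 0,
        transfer_pos = X[, i] > 0 &
          (if (semantics == "blocking" && mode == "truncated") X[, j] < K - 1 else TRUE),
        transfer_neg = X[, i] > 0 &
          (if (semantics == "blocking") X[, j] > 0 else TRUE))
      R[, k] <- R[, k] * act
    }
    u <- stats::runif(M) * Lam
    cum <- R[, 1]
    pick <- rep(1L, M)
    for (k in 2:nE) {
      undecided <- u > cum
      pick[undecided] <- k
      cum <- cum + R[, k]
    }
    pick[u > cum] <- 0L          # self-loop of the uniformized chain
    for (k in setdiff(unique(pick), 0L)) {
      rows <- which(pick == k)
      i <- tab$i[k]; j <- tab$j[k]
      switch(tab$type[k],
        ext_pos = { X[rows, i] <- X[rows, i] + 1L },
        ext_neg = { X[rows, i] <- X[rows, i] - 1L },
        depart  = { X[rows, i] <- X[rows, i] - 1L },
        transfer_pos = {
          X[rows, i] <- X[rows, i] - 1L
          canUp <- if (mode == "truncated") X[rows, j] < K - 1 else rep(TRUE, length(rows))
          X[rows[canUp], j] <- X[rows[canUp], j] + 1L
        },
        transfer_neg = {
          X[rows, i] <- X[rows, i] - 1L
          canDn <- X[rows, j] > 0
          X[rows[canDn], j] <- X[rows[canDn], j] - 1L
        })
    }
  }
  X
}

#' Empirical CDF of a gene's level after a fixed number of events
#'
#' Runs M replicates of `nEvents` steps of the uniformized chain (all
#' replicates advance in lockstep from `x0`, vectorized across replicates;
#' the whole ensemble is reproducible from the single seed) and returns the
#' empirical CDF of the chosen gene's level at the end of each replicate.
#' A step of the uniformized chain performs an event with probability
#' proportional to its rate and otherwise leaves the state unchanged, so
#' after n steps a replicate is the CTMC observed at an Erlang(n, Lambda)
#' time; as `nEvents` grows the ECDF therefore approaches the stationary
#' geometric law, whose tail is [cdfTail()]. (Sampling at the n-th true jump
#' would instead converge to the jump-chain law, which over-weights
#' high-activity states.)
#'
#' @param net a valid [GeneNetwork-class].
#' @param gene gene name or index.
#' @param nEvents events per replicate.
#' @param M replicate count.
#' @param x0 initial state (default all zeros).
#' @param seed RNG seed.
#' @param mode,K,semantics as in [simulatePath()].
#' @return an [EcdfResult-class].
#' @export
ecdfAtStep <- function(net, gene, nEvents = 500L, M = 10000L, x0 = NULL,
                       seed = 1L, mode = c("unbounded", "truncated"),
                       K = NULL, semantics = c("classical", "blocking")) {
  mode <- match.arg(mode)
  semantics <- match.arg(semantics)
  stopifnot(is(net, "GeneNetwork"), M >= 1)
  N <- nGenes(net)
  gi <- if (is.numeric(gene)) as.integer(gene) else match(gene, net@geneNames)
  if (is.na(gi) || gi < 1 || gi > N) stop("unknown gene: ", gene)
  if (is.null(x0)) x0 <- rep(0L, N)
  X <- .simulateEnsembleFinal(net, x0, nEvents, M, seed, mode, K, semantics)
  smp <- as.integer(X[, gi])
  xs <- 0:max(smp)
  Fh <- vapply(xs, function(v) mean(smp <= v), numeric(1))
  new("EcdfResult", gene = as.character(net@geneNames[gi]), sample = smp,
      x = as.integer(xs), Fhat = Fh, nEvents = as.integer(nEvents),
      M = as.integer(M))
}

#' Sup distance between an empirical tail and the geometric tail
#'
#' \eqn{\max_x |(1 - \hat F(x)) - q^{x+1}|} over the ECDF's evaluation
#' points: how far the simulated law is from the product-form stationary
#' marginal with utilization q.
#'
#' @param ecdf an [EcdfResult-class].
#' @param q theoretical utilization in (0, 1).
#' @return the sup-norm distance.
#' @export
compareTail <- function(ecdf, q) {
  stopifnot(is(ecdf, "EcdfResult"))
  if (q <= 0 || q >= 1) stop("q must lie strictly in (0, 1)")
  max(abs((1 - ecdf@Fhat) - q^(ecdf@x + 1)))
}
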