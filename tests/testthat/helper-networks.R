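## Small fixtures and independent oracles shared across test files.

## isolated single gene: birth rate lambdaPlus, death rate mu*d + lambdaMinus
singleGene <- function(lambdaPlus = 1, lambdaMinus = 0, mu = 2) {
  GeneNetwork("g1", lambdaPlus, lambdaMinus, mu,
              matrix(0, 1, 1), matrix(0, 1, 1))
}

## two genes, one positive synchronizing edge g1 -> g2
twoGenePos <- function() {
  pp <- matrix(0, 2, 2); pp[1, 2] <- 0.4
  GeneNetwork(c("g1", "g2"), c(1, 0.8), c(0.2, 0.1), c(2, 1.5),
              pp, matrix(0, 2, 2))
}

## three genes with a positive, a negative and a cyclic edge
threeGeneMixed <- function() {
  pp <- matrix(0, 3, 3); pm <- matrix(0, 3, 3)
  pp[1, 2] <- 0.3; pm[2, 3] <- 0.25; pp[3, 1] <- 0.2
  GeneNetwork(c("g1", "g2", "g3"), c(1, 0.8, 1.2), c(0.3, 0.2, 0.4),
              c(2, 1.5, 1.8), pp, pm)
}

## dense truncated matrix exponential by the plain power series
## sum_{n<=terms} (At)^n / n!  -- an oracle independent of uniformization
expmSeries <- function(A, t, terms = 40) {
  A <- as.matrix(A)
  S <- diag(nrow(A))
  Tm <- diag(nrow(A))
  for (n in seq_len(terms)) {
    Tm <- Tm %*% (A * t) / n
    S <- S + Tm
  }
  S
}

## Pearson correlation of a K x K pmf by explicit double-loop moment sums
pearsonBruteForce <- function(P) {
  K <- nrow(P)
  Ei <- Ej <- Eii <- Ejj <- Eij <- 0
  for (a in 0:(K - 1)) for (b in 0:(K - 1)) {
    p <- P[a + 1, b + 1]
    Ei <- Ei + a * p; Ej <- Ej + b * p
    Eii <- Eii + a^2 * p; Ejj <- Ejj + b^2 * p
    Eij <- Eij + a * b * p
  }
  (Eij - Ei * Ej) / sqrt((Eii - Ei^2) * (Ejj - Ej^2))
}

## stationary vector of a small generator by direct linear solve of pi Q = 0
stationaryDirect <- function(Q) {
  Q <- as.matrix(Q)
  S <- nrow(Q)
  A <- t(Q)
  A[S, ] <- 1
  solve(A, c(rep(0, S - 1), 1))
}
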