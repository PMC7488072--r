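test_that("state distribution matches the truncated power-series exponential", {
  net <- twoGenePos()
  gen <- assembleGenerator(net, 2)
  pi0 <- c(1, 0, 0, 0)
  expect_identical(stateDistribution(gen, pi0, 0), pi0)
  for (t in c(0.1, 0.5, 1.5)) {
    pt <- stateDistribution(gen, pi0, t)
    oracle <- as.vector(pi0 %*% expmSeries(generatorMatrix(gen), t, terms = 60))
    expect_equal(pt, oracle, tolerance = 1e-10)
    expect_equal(sum(pt), 1, tolerance = 1e-10)
    expect_gte(min(pt), -1e-10)
  }
  expect_error(stateDistribution(gen, pi0, -1), "nonnegative")
  expect_error(stateDistribution(gen, c(1, 0, 0), 1), "length")
})

test_that("pair projectors satisfy C* C = K^(N-2) I exactly", {
  cases <- list(c(3, 2, 1, 2), c(3, 3, 1, 3), c(4, 2, 2, 4), c(5, 7, 1, 2),
                c(5, 7, 4, 5))
  for (cs in cases) {
    N <- cs[1]; K <- cs[2]; i <- cs[3]; j <- cs[4]
    pr <- pairProjectors(N, K, i, j)
    prod <- as.matrix(pr@Cstar %*% pr@C)
    expect_identical(prod, diag(K^(N - 2), K^2))
    ## each row of C is a unit indicator; each column holds K^(N-2) ones
    expect_true(all(Matrix::rowSums(pr@C) == 1))
    expect_true(all(Matrix::colSums(pr@C) == K^(N - 2)))
    expect_true(all(pr@C@x == 1))
  }
  ## N = 2: no marginalized genes, the projectors are identities
  pr2 <- pairProjectors(2, 3, 1, 2)
  expect_equal(as.matrix(pr2@C), diag(9))
  expect_equal(as.matrix(pr2@Cstar), diag(9))
  expect_error(pairProjectors(3, 2, 2, 2), "distinct")
})

test_that("the pairwise kernel is row-stochastic and the identity at t = 0", {
  net <- threeGeneMixed()
  gen <- assembleGenerator(net, 3)
  expect_equal(jointKernel(gen, 1, 3, 0), diag(9))
  for (t in c(0.2, 1)) {
    ker <- jointKernel(gen, 1, 2, t)
    expect_equal(unname(rowSums(ker)), rep(1, 9), tolerance = 1e-8)
    expect_gte(min(ker), -1e-10)
  }
})

test_that("for N = 2 the kernel is the full matrix exponential", {
  net <- twoGenePos()
  gen <- assembleGenerator(net, 2)
  ker <- jointKernel(gen, 1, 2, 0.7)
  expect_equal(ker, expmSeries(generatorMatrix(gen), 0.7, terms = 60),
               tolerance = 1e-10)
})

test_that("jointDistribution propagates and preserves mass", {
  K <- 3
  pi0 <- matrix(c(0.4, 0.1, 0, 0.1, 0.2, 0.1, 0, 0.05, 0.05), K, K, byrow = TRUE)
  gen <- assembleGenerator(threeGeneMixed(), K)
  ker0 <- jointKernel(gen, 1, 2, 0)
  jd0 <- jointDistribution(pi0, ker0, i = 1, j = 2, t = 0)
  expect_equal(jd0@P, pi0)
  jd <- jointDistribution(pi0, jointKernel(gen, 1, 2, 0.5), i = 1, j = 2, t = 0.5)
  expect_equal(sum(jd@P), 1, tolerance = 1e-8)
  expect_error(jointDistribution(pi0, diag(4)), "does not match")
})

test_that("the default initial pair pmf reproduces the tridiagonal 5/47 pattern", {
  P <- defaultInitialPairPMF(7, "positive")
  expect_equal(P[1, 1], 5 / 47)
  expect_equal(P[1, 2], 1 / 47)
  expect_equal(P[1, 3], 0)
  expect_equal(sum(P), 1)
  for (K in c(2, 4, 9)) expect_equal(sum(defaultInitialPairPMF(K)), 1)
  N7 <- defaultInitialPairPMF(7, "negative")
  expect_equal(sum(N7), 1)
  expect_equal(N7[1, 7], 5 / 47)
  expect_equal(pearsonCorrelation(N7), -pearsonCorrelation(P), tolerance = 1e-12)
  expect_lt(pearsonCorrelation(N7), -0.9)
  expect_error(defaultInitialPairPMF(1), "at least 2")
})

test_that("Pearson correlation matches brute-force moment sums", {
  ## independence: any outer product has correlation 0
  for (seed in 1:5) {
    set.seed(seed)
    a <- stats::runif(5); a <- a / sum(a)
    b <- stats::runif(5); b <- b / sum(b)
    expect_lt(abs(pearsonCorrelation(outer(a, b))), 1e-12)
  }
  ## perfect linear dependence: uniform mass on the diagonal
  expect_equal(pearsonCorrelation(diag(7) / 7), 1)
  ## the bundled initial pmf, against explicit double-loop sums
  P <- defaultInitialPairPMF(7)
  expect_equal(pearsonCorrelation(P), pearsonBruteForce(P), tolerance = 1e-14)
  expect_error(pearsonCorrelation(outer(c(1, 0, 0), c(0.2, 0.5, 0.3))),
               "degenerate")
})

test_that("the trajectory vector route equals the kernel route", {
  net <- threeGeneMixed()
  K <- 3
  pi0 <- defaultInitialPairPMF(K)
  gen <- assembleGenerator(net, K)
  tr <- correlationTrajectory(net, K = K, pairs = cbind(1, 3),
                              times = c(0, 0.4, 1), pi0 = pi0, gen = gen)
  for (t in c(0, 0.4, 1)) {
    jd <- jointDistribution(pi0, jointKernel(gen, 1, 3, t), i = 1, j = 3, t = t)
    expect_equal(tr$rho[tr$time == t], pearsonCorrelation(jd),
                 tolerance = 1e-9)
  }
})

test_that("projection equals marginalization of the full transient law for a uniform background", {
  net <- threeGeneMixed()
  K <- 3
  gen <- assembleGenerator(net, K)
  pi0pair <- defaultInitialPairPMF(K)
  lv <- sapply(1:3, function(n) ((0:(K^3 - 1)) %/% K^(3 - n)) %% K)
  ## full start: pair pmf on genes (1,2), gene 3 uniform
  full0 <- pi0pair[cbind(lv[, 1] + 1, lv[, 2] + 1)] / K
  fullT <- stateDistribution(gen, full0, 0.3)
  margFull <- matrix(0, K, K)
  for (a in 0:(K - 1)) for (b in 0:(K - 1))
    margFull[a + 1, b + 1] <- sum(fullT[lv[, 1] == a & lv[, 2] == b])
  proj <- jointDistribution(pi0pair, jointKernel(gen, 1, 2, 0.3))@P
  expect_equal(proj, margFull, tolerance = 1e-10)

  ## with a non-uniform background the projection identity no longer holds
  ## exactly; the deviation is small but nonzero and is documented behavior
  w <- 0.6^(0:(K - 1)); w <- w / sum(w)
  geo0 <- pi0pair[cbind(lv[, 1] + 1, lv[, 2] + 1)] * w[lv[, 3] + 1]
  geoT <- stateDistribution(gen, geo0, 0.3)
  margGeo <- matrix(0, K, K)
  for (a in 0:(K - 1)) for (b in 0:(K - 1))
    margGeo[a + 1, b + 1] <- sum(geoT[lv[, 1] == a & lv[, 2] == b])
  tv <- 0.5 * sum(abs(proj - margGeo))
  expect_lt(tv, 0.05)
})

test_that("at t = 0 every pair's correlation equals that of the initial pmf", {
  net <- builtinNetwork("normal")
  K <- 3
  pi0 <- defaultInitialPairPMF(K)
  tr <- correlationTrajectory(net, K = K, times = 0, pi0 = pi0)
  expect_identical(nrow(tr), 10L)
  expect_equal(tr$rho, rep(pearsonCorrelation(pi0), 10), tolerance = 1e-12)
})

test_that("pair resolution accepts names, indices and strings, and rejects unknowns", {
  net <- builtinNetwork("normal")
  a <- correlationTrajectory(net, K = 2, pairs = "CEBPA:E2F1", times = 0.1)
  b <- correlationTrajectory(net, K = 2, pairs = cbind(2, 1), times = 0.1)
  expect_equal(a$rho, b$rho)
  expect_error(correlationTrajectory(net, K = 2, pairs = "CEBPA:NOPE", times = 0.1),
               "unknown gene")
  expect_error(correlationTrajectory(net, K = 2, pairs = "CEBPA:CEBPA", times = 0.1),
               "distinct")
})
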