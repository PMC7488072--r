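test_that("elementary matrices match their definitions", {
  e <- elementaryMatrices(2)
  expect_equal(as.matrix(e$Upp), matrix(c(0, 0, 1, 0), 2, 2))
  expect_equal(as.matrix(e$Low), matrix(c(0, 1, 0, 0), 2, 2))
  expect_equal(as.matrix(e$I10), diag(c(0, 1)))
  expect_equal(as.matrix(e$IK0), diag(c(1, 0)))
  e3 <- elementaryMatrices(3)
  expect_equal(as.vector(Matrix::rowSums(e3$Low)), c(0, 1, 1))
  expect_equal(as.vector(Matrix::rowSums(e3$Upp)), c(1, 1, 0))
  expect_error(elementaryMatrices(1), "at least 2")
})

test_that("the local matrix is the truncated birth-death generator", {
  ## lambda+ = 1 up; mu*d + lambda- = 2*0.25 + 0.5 = 1 down
  pp <- matrix(0, 1, 1)
  net <- GeneNetwork("a", 1, 0.5, 2, pp, pp, d = 1, validate = FALSE)
  net@d[] <- 0.25  # force d without routing rows (boundary-case oracle)
  L <- localMatrix(net, 1, 2)
  expect_equal(as.matrix(L), matrix(c(-1, 1, 1, -1), 2, 2))

  ## K = 3 against a directly enumerated birth-death chain
  net2 <- singleGene(lambdaPlus = 1.3, lambdaMinus = 0.4, mu = 2.2)
  L3 <- as.matrix(localMatrix(net2, 1, 3))
  birth <- 1.3; death <- 2.2 * 1 + 0.4
  oracle <- matrix(0, 3, 3)
  oracle[1, 2] <- birth; oracle[2, 3] <- birth
  oracle[2, 1] <- death; oracle[3, 2] <- death
  diag(oracle) <- -rowSums(oracle)
  expect_equal(L3, oracle)
  expect_equal(max(abs(rowSums(L3))), 0)
})

test_that("synchronization matrices follow the master/slave recipes", {
  net <- twoGenePos()   # mu1 = 2, p12+ = 0.4 -> rate 0.8
  ev <- syncEvents(net)
  sm <- syncMatrices(net, ev[1, ], 2)
  offdiag <- as.matrix(sm$D - sm$Dbar)
  expect_equal(offdiag, matrix(c(0, 0.8, 0, 0), 2, 2))
  expect_equal(as.matrix(sm$E), matrix(c(0, 0, 1, 0), 2, 2))      # Upp
  expect_equal(as.matrix(sm$Nslave), diag(c(1, 0)))               # IK0

  pm <- matrix(0, 2, 2); pm[1, 2] <- 0.3
  netNeg <- GeneNetwork(c("a", "b"), c(1, 1), c(0, 0), c(2, 1),
                        matrix(0, 2, 2), pm)
  smNeg <- syncMatrices(netNeg, syncEvents(netNeg)[1, ], 3)
  expect_equal(as.matrix(smNeg$E), as.matrix(elementaryMatrices(3)$Low))
  expect_equal(as.matrix(smNeg$Nslave), diag(c(0, 1, 1)))         # I10
})

test_that("with no synchronizing events the generator is the Kronecker sum of locals", {
  net <- GeneNetwork(c("a", "b"), c(1, 2), c(0.5, 1), c(3, 4),
                     matrix(0, 2, 2), matrix(0, 2, 2))
  K <- 3
  gen <- assembleGenerator(net, K)
  L1 <- as.matrix(localMatrix(net, 1, K))
  L2 <- as.matrix(localMatrix(net, 2, K))
  kronSum <- kronecker(L1, diag(K)) + kronecker(diag(K), L2)
  expect_equal(as.matrix(generatorMatrix(gen)), kronSum)
})

test_that("Kronecker assembly agrees entrywise with brute-force enumeration", {
  ## the central correctness property, over a randomized family
  for (seed in 1:50) {
    N <- sample(2:3, 1)
    K <- sample(2:3, 1)
    net <- randomNetwork(N, density = 0.6, seed = seed, stable = FALSE)
    A <- generatorMatrix(assembleGenerator(net, K))
    B <- generatorMatrix(enumerateGenerator(net, K, semantics = "blocking"))
    expect_lt(max(abs(A - B)), 1e-12)
  }
  ## also on a hand-built two-gene network with one positive sync
  net <- twoGenePos()
  A <- generatorMatrix(assembleGenerator(net, 2))
  B <- generatorMatrix(enumerateGenerator(net, 2, semantics = "blocking"))
  expect_equal(as.matrix(A), as.matrix(B))
})

test_that("assembled generators are proper rate matrices", {
  for (cond in c("normal", "alt")) {
    gen <- assembleGenerator(builtinNetwork(cond), K = 4)
    Q <- generatorMatrix(gen)
    expect_lt(max(abs(Matrix::rowSums(Q))), 1e-9)
    offdiag <- Q; Matrix::diag(offdiag) <- 0
    expect_gte(min(offdiag@x, 0), 0)
    N <- nGenes(gen); R <- nrow(syncEvents(builtinNetwork(cond)))
    expect_lte(Matrix::nnzero(offdiag), 4^N * (2 * N + 2 * R))
  }
})

test_that("enumeration of a single gene reduces to the local birth-death matrix", {
  net <- singleGene(1.3, 0.4, 2.2)
  expect_equal(as.matrix(generatorMatrix(enumerateGenerator(net, 4))),
               as.matrix(localMatrix(net, 1, 4)))
})

test_that("the size cap refuses oversized state spaces with advice", {
  expect_error(assembleGenerator(builtinNetwork("normal"), K = 7, sizeCap = 100),
               "smaller K")
})

test_that("under classical semantics the truncated stationary law approaches the product form", {
  net <- threeGeneMixed()
  q <- unname(qValues(solveTraffic(net)))
  tv <- vapply(c(5, 7), function(K) {
    Q <- generatorMatrix(enumerateGenerator(net, K, semantics = "classical"))
    pi_ <- stationaryDirect(Q)
    lv <- sapply(1:3, function(n) ((0:(K^3 - 1)) %/% K^(3 - n)) %% K)
    pf <- rep(1, K^3)
    for (n in 1:3) {
      g <- q[n]^(0:(K - 1)); g <- g / sum(g)
      pf <- pf * g[lv[, n] + 1]
    }
    0.5 * sum(abs(pi_ - pf))
  }, numeric(1))
  expect_lt(tv[2], tv[1])     # truncation error shrinks with K
  expect_lt(tv[2], 0.01)
})

test_that("Matrix Market export round-trips with its JSON sidecar", {
  dir <- withr::local_tempdir()
  gen <- assembleGenerator(twoGenePos(), 3)
  p <- file.path(dir, "q.mtx")
  writeGeneratorMTX(gen, p)
  back <- Matrix::readMM(p)
  expect_equal(as.matrix(back), as.matrix(generatorMatrix(gen)))
  side <- jsonlite::read_json(paste0(p, ".json"))
  expect_identical(side$K, 3L)
  expect_identical(side$semantics, "blocking")
})
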