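# Scenario generators: reproducibility, PD contracts, truth encodings.

test_that("Erdős–Rényi precisions have the advertised support and weights", {
  withr::with_seed(1, g <- erdosRenyiPrecision(20, 0.1))
  expect_true(isSymmetric(g$precision))
  expect_gt(min(eigen(g$precision, symmetric = TRUE,
                      only.values = TRUE)$values), 0)
  off <- g$base[upper.tri(g$base)]
  w <- off[off != 0]
  expect_true(all(abs(w) >= 0.5 & abs(w) <= 1))
  expect_equal(g$support, g$support | t(g$support))
  expect_false(any(diag(g$support)))

  # expected edge count ~ connProb * choose(p, 2) over replicates
  counts <- vapply(1:200, function(s) {
    withr::with_seed(s, sum(erdosRenyiPrecision(33, 0.02)$support) / 2)
  }, numeric(1))
  expect_equal(mean(counts), 0.02 * choose(33, 2), tolerance = 0.1)
})

test_that("the PD shift adds 0.1 I the minimal number of times", {
  M <- diag(3)
  expect_identical(makePositiveDefinite(M), M)
  # min eigenvalue of this matrix is 1 - sqrt(2)*0.745 = -0.054
  M2 <- diag(3)
  M2[1, 2] <- M2[2, 1] <- 0.745
  M2[2, 3] <- M2[3, 2] <- 0.745
  out <- makePositiveDefinite(M2)
  expect_equal(diag(out), rep(1.1, 3))   # exactly one shift
  expect_equal(out - diag(0.1, 3), M2)   # off-diagonals untouched
  expect_error(makePositiveDefinite(matrix(c(1, 2, 0, 1), 2, 2)),
               "symmetric")
})

test_that("graph perturbation swaps exactly three edges in and out", {
  withr::with_seed(2, {
    g <- erdosRenyiPrecision(15, 0.2)
    g2 <- perturbGraph(g)
  })
  expect_equal(sum(g2$support), sum(g$support))          # 3 out, 3 in
  expect_equal(sum(xor(g$support, g2$support)) / 2, 6)   # symmetric diff
  withr::with_seed(3, a <- perturbGraph(g))
  withr::with_seed(3, b <- perturbGraph(g))
  expect_identical(a, b)
})

test_that("multi-category datasets match the benchmark geometry", {
  sim <- simulateMulticategory(seed = 4)
  expect_equal(dim(simFeatures(sim)), c(151, 33))
  expect_equal(dim(sim@X), c(151, 2))
  expect_equal(sim@params$groupSizes, c(76, 75))
  expect_equal(factorKinds(sim), c("indicator", "indicator"))
  expect_length(simTruth(sim), 2)
  s3 <- simulateMulticategory(groups = 3, seed = 4)
  expect_equal(s3@params$groupSizes, c(51, 50, 50))

  lowdim <- simulateMulticategory(n = 100, p = 20, connProb = 0.05,
                                  seed = 5)
  expect_equal(dim(simFeatures(lowdim)), c(100, 20))

  # per-group sample covariance inverse approaches the group precision
  big <- simulateMulticategory(n = 6000, p = 6, groups = 2,
                               connProb = 0.5, seed = 6)
  g1 <- simFeatures(big)[big@params$groupLabels == 1, ]
  est <- solve(cov(g1))
  expect_lt(max(abs(est - simPrecisions(big)[[1]])), 0.2)
})

test_that("continuous datasets satisfy the per-subject PD contract", {
  sim <- simulateContinuous(n = 40, p = 12, fracNonzero = 0.02, seed = 7)
  expect_equal(length(simPrecisions(sim)), 40)
  for (P in simPrecisions(sim)[1:10])
    expect_gt(min(eigen(P, symmetric = TRUE, only.values = TRUE)$values), 0)
  B <- simBeta(sim)
  expect_equal(simTruth(sim)[[1]], apply(B != 0, c(1, 2), any))
  # omega_ij = sum_l beta_ijl x_l for a spot check
  P1 <- simPrecisions(sim)[[1]]
  x1 <- sim@X[1, ]
  expect_equal(P1[2, 1], sum(B[2, 1, ] * x1))
  # the subject-resampling policy also keeps every subject PD
  sub <- simulateContinuous(n = 30, p = 10, seed = 8,
                            pdPolicy = "subject")
  for (P in simPrecisions(sub)[1:10])
    expect_gt(min(eigen(P, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("homogeneous datasets use an intercept-only factor", {
  sim <- simulateHomogeneous(n = 60, p = 10, connProb = 0.05, seed = 9)
  expect_equal(ncol(sim@X), 1)
  expect_true(all(sim@X == 1))
  expect_equal(factorKinds(sim), "intercept")
  expect_equal(simTruth(sim)[[1]],
               abs(simPrecisions(sim)[[1]]) > 0 & !diag(TRUE, 10))
})

test_that("dag datasets follow the sequential generation contract", {
  sim <- simulateDAG(n = 500, p = 10, q = 2, seed = 10)
  expect_equal(dim(simFeatures(sim)), c(500, 10))
  tr <- simTruth(sim)[[1]]
  expect_true(all(!tr[upper.tri(tr, diag = TRUE)]))   # strictly lower tri
  # all-null coefficients give i.i.d. standard-normal columns
  null <- simulateDAG(n = 2000, p = 6, q = 2, fracNonzero = 0, seed = 11)
  expect_lt(max(abs(colMeans(simFeatures(null)))), 0.1)
  expect_lt(max(abs(apply(simFeatures(null), 2, sd) - 1)), 0.1)
  # node means reproduce the generating formula on a fixed seed
  B <- simBeta(sim)
  Y <- simFeatures(sim)
  i <- which(rowSums(tr) > 0)[1]
  parents <- which(tr[i, ])
  mu_i <- rowSums(vapply(parents, function(j) {
    ytil <- (Y[, j] - mean(Y[, j])) / sd(Y[, j])
    as.numeric(sim@X %*% B[i, j, ]) * ytil
  }, numeric(500)))
  resid <- Y[, i] - mu_i
  expect_equal(sd(resid), 1, tolerance = 0.15)
  expect_lt(abs(cor(resid, mu_i)), 0.15)
  # discrete factors are Bernoulli(0.5)
  disc <- simulateDAG(n = 300, p = 5, q = 2, seed = 12,
                      factorKinds = c("discrete", "discrete"))
  expect_true(all(disc@X %in% c(0, 1)))
})

test_that("the Simpson design opposes the two group dependencies", {
  sim <- simulateSimpsons(seed = 13)
  expect_equal(dim(simFeatures(sim)), c(200, 3))
  O1 <- simPrecisions(sim)[[1]]
  O2 <- simPrecisions(sim)[[2]]
  pc <- function(O) -O[1, 2] / sqrt(O[1, 1] * O[2, 2])
  expect_lt(pc(O1), 0)    # omega_12 > 0 -> negative partial correlation
  expect_gt(pc(O2), 0)
  expect_equal(O1[2, 3], 0)
  expect_equal(O2[1, 3], 0)
  # pooled-covariance partial correlation is attenuated relative to the
  # stronger group dependence
  S <- solve(cov(simFeatures(sim)))
  pooled <- pc(S)
  expect_lt(abs(pooled), max(abs(pc(O1)), abs(pc(O2))))
})

test_that("generators are bit-reproducible and leave the RNG untouched", {
  a <- simulateMulticategory(n = 40, p = 8, seed = 17, connProb = 0.3)
  b <- simulateMulticategory(n = 40, p = 8, seed = 17, connProb = 0.3)
  expect_identical(simFeatures(a), simFeatures(b))
  expect_identical(simPrecisions(a), simPrecisions(b))
  set.seed(99)
  before <- .Random.seed
  invisible(simulateHomogeneous(n = 20, p = 5, connProb = 0.1, seed = 1))
  expect_identical(.Random.seed, before)
})
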