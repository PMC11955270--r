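# Variational engine: sweep behaviour, ELBO properties, oracle agreement.

test_that("a sweep shrinks the inclusion of a no-signal coefficient", {
  withr::with_seed(1, {
    n <- 80
    z <- rnorm(n)
    y <- rnorm(n)
    y <- y - z * sum(y * z) / sum(z * z)    # orthogonal to the regressor
    Y <- cbind(y, z)
  })
  d <- buildNodeDesign(Y, matrix(1, nrow(Y), 1), node = 1)
  hyper <- graphRegHyper(aPi = 1, bPi = 9)    # strong sparsity prior
  post <- graphreg:::.freshPosterior(d, hyper)
  a0 <- post@alpha[1]
  post <- caviSweep(d, post, hyper)
  expect_lt(post@alpha[1], a0)
})

test_that("a sweep at a converged fixed point leaves the posterior unchanged", {
  Y <- makeSignalData()
  d <- buildNodeDesign(standardizeColumns(Y)$values, matrix(1, nrow(Y), 1), 1)
  hyper <- graphRegHyper(elboTol = 1e-12, maxIter = 5000)
  post <- fitNode(d, hyper)
  # polish to a machine-precision fixed point before testing idempotence
  for (k in 1:50) post <- caviSweep(d, post, hyper)
  again <- caviSweep(d, post, hyper)
  expect_equal(again@alpha, post@alpha, tolerance = 1e-10)
  expect_equal(again@mu, post@mu, tolerance = 1e-10)
  expect_equal(again@omegaRate, post@omegaRate, tolerance = 1e-10)
})

test_that("the ELBO is non-decreasing across sweeps on random problems", {
  for (rep in 1:20) {
    withr::with_seed(1000 + rep, {
      n <- sample(20:60, 1)
      p <- sample(3:6, 1)
      q <- sample(1:2, 1)
      Y <- matrix(rnorm(n * p), n, p)
      if (rep %% 2 == 0) Y[, 1] <- Y[, 2] + rnorm(n, sd = 0.5)
      X <- matrix(rnorm(n * q), n, q)
    })
    d <- buildNodeDesign(standardizeColumns(Y)$values, X, 1)
    f <- fitNode(d, graphRegHyper())
    el <- f@elbo
    if (length(el) > 1)
      expect_true(all(diff(el) >= -1e-6 * (abs(el[-length(el)]) + 1)))
  }
})

test_that("VB inclusion probabilities rank like exact enumeration PIPs", {
  # fixed tau/omega/pi so the exact posterior is available by summing over
  # all spike/slab configurations
  withr::with_seed(42, {
    n <- 60; m <- 5
    Z <- matrix(rnorm(n * m), n, m)
    y <- as.numeric(Z %*% c(0.8, -0.5, 0.3, 0, 0) + rnorm(n))
  })
  y <- standardizeColumns(cbind(y))$values[, 1]
  ex <- exactSpikeSlab(y, Z, tau = 1, omega = 1, pi0 = 0.2)
  d <- buildNodeDesign(cbind(y, Z), matrix(1, n, 1), 1)
  f <- fitNode(d, graphRegHyper(elboTol = 1e-10, maxIter = 5000),
               fixed = list(tau = 1, omega = 1, pi = 0.2))
  expect_equal(cor(rank(ex$pip), rank(f@alpha), method = "spearman"), 1)
  expect_lt(max(abs(f@alpha - ex$pip)), 0.01)
})

test_that("the ELBO lower-bounds the exact log marginal likelihood", {
  withr::with_seed(7, {
    n <- 40; m <- 2
    Z <- matrix(rnorm(n * m), n, m)
    y <- as.numeric(Z %*% c(1, 0) + rnorm(n))
  })
  ex <- exactSpikeSlab(y, Z, tau = 2, omega = 1.5, pi0 = 0.3)
  d <- buildNodeDesign(cbind(y, Z), matrix(1, n, 1), 1)
  fixed <- list(tau = 2, omega = 1.5, pi = 0.3)
  f <- fitNode(d, graphRegHyper(elboTol = 1e-10, maxIter = 5000), fixed)
  expect_lte(tail(f@elbo, 1), ex$logMarginal + 1e-8)
})

test_that("the empty (dag node 1) design has the closed-form ELBO", {
  withr::with_seed(3, y <- rnorm(25))
  Y <- cbind(y, rnorm(25))
  d <- buildNodeDesign(Y, matrix(1, 25, 1), node = 1, mode = "dag")
  f <- fitNode(d, graphRegHyper())
  n <- 25
  cc <- n / 2 + 1
  dd <- sum(y^2) / 2
  closed <- -n / 2 * log(2 * pi) - cc * log(dd) + lgamma(cc)
  expect_equal(tail(f@elbo, 1), closed, tolerance = 1e-10)
  expect_true(f@converged)
})

test_that("node fits shrink under pure noise and detect strong effects", {
  withr::with_seed(11, Y <- matrix(rnorm(100 * 11), 100, 11))
  d <- buildNodeDesign(standardizeColumns(Y)$values, matrix(1, 100, 1), 1)
  f <- fitNode(d)
  expect_lt(mean(f@alpha), 0.2)

  Ysig <- makeSignalData(n = 200, p = 4, effect = 3)
  d2 <- buildNodeDesign(standardizeColumns(Ysig)$values,
                        matrix(1, 200, 1), 1)
  f2 <- fitNode(d2)
  k <- which(d2@indexMap$node == 2)
  expect_gt(f2@alpha[k], 0.95)
})

test_that("non-finite updates raise an error naming the coefficient", {
  Y <- matrix(c(1, -1, 1, -1, 2, -2, 2, -2), 4, 2)
  d <- buildNodeDesign(Y, matrix(1, 4, 1), 1)
  post <- graphreg:::.freshPosterior(d, graphRegHyper())
  expect_error(
    graphreg:::.caviCoefPass(d@design, colSums(d@design^2), post@alpha,
                             post@mu, post@sigma2, d@response, Inf,
                             1, 0, 0),
    "index")
})
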