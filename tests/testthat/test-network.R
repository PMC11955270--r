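# PIP weighting, partial-correlation formula, FDR selection, network
# assembly.

# a fit with hand-set posterior summaries for two nodes and two factors
makeToyFit <- function(alpha1, mu1, alpha2 = alpha1, mu2 = mu1,
                       omega = c(1, 1), q = 2) {
  hyper <- graphRegHyper()
  node <- function(i, alpha, mu, om) {
    m <- length(alpha)
    new("NodePosterior", alpha = alpha, mu = mu, sigma2 = rep(0.1, m),
        tauShape = rep(1, q), tauRate = rep(1, q),
        piA = rep(1, m), piB = rep(4, m),
        omegaShape = 10, omegaRate = 10 / om,
        elbo = c(-1), converged = TRUE,
        indexMap = data.frame(node = rep(setdiff(1:2, i), each = q),
                              factor = seq_len(q)),
        node = as.integer(i))
  }
  new("GraphRegFit",
      nodes = list(node(1, alpha1, mu1, omega[1]),
                   node(2, alpha2, mu2, omega[2])),
      mode = "undirected", hyper = hyper,
      featureNames = c("A", "B"), factorNames = paste0("X", seq_len(q)),
      factorKinds = rep("continuous", q),
      yCenter = c(0, 0), yScale = c(1, 1), n = 10L)
}

test_that("edge PIP is the squared-weight mean of inclusion probabilities", {
  # weights are (x_l E[b])^2 with E[b] = alpha * mu
  fit <- makeToyFit(alpha1 = c(0.9, 0.2), mu1 = c(0.3 / 0.9, 0))
  # E[b] = (0.3, 0); x = (1, 2) -> weights (0.09, 0) -> PIP = 0.9
  expect_equal(edgePIP(fit, 1, 2, c(1, 2)), 0.9)

  fit2 <- makeToyFit(alpha1 = c(0.8, 0.4), mu1 = c(0.5 / 0.8, 0.5 / 0.4))
  # E[b] = (0.5, 0.5), x = (1, 1): weighted mean = (0.8 + 0.4) / 2 = 0.6
  expect_equal(edgePIP(fit2, 1, 2, c(1, 1)), 0.6)

  fit3 <- makeToyFit(alpha1 = c(0.9, 0.9), mu1 = c(0, 0))
  expect_equal(edgePIP(fit3, 1, 2, c(1, 1)), 0)   # all-zero weights
})

test_that("partial correlation follows the precision-scale formula", {
  # -(sum_l x_l E[bs]) / E[omega] on the precision scale: with
  # E[bs]_prec = (0.2, 0.1) and E[omega] = 2 the regression-scale
  # coefficients are -E[bs]_prec / E[omega] = (-0.1, -0.05), and
  # x = (1, -1) gives -(0.2 - 0.1)/2 = -0.05
  fit <- makeToyFit(alpha1 = c(1, 1), mu1 = c(-0.1, -0.05),
                    omega = c(2, 2))
  expect_equal(edgePartialCor(fit, 1, 2, c(1, -1)), -0.05)
  # linearity: flipping x flips the sign
  expect_equal(edgePartialCor(fit, 1, 2, c(-1, 1)), 0.05)
  # all-zero coefficients give zero
  fit0 <- makeToyFit(alpha1 = c(0, 0), mu1 = c(0.4, 0.4))
  expect_equal(edgePartialCor(fit0, 1, 2, c(1, 1)), 0)
})

test_that("Bayesian FDR selection implements the prefix-mean rule", {
  out <- bayesFDRSelect(c(0.995, 0.99, 0.6), 0.01)
  # prefix means of (1 - PIP): 0.005, 0.0075, 0.135 -> 2 selected
  expect_equal(sum(out$selected), 2)
  expect_equal(out$threshold, 0.99)

  expect_equal(sum(bayesFDRSelect(rep(1, 5), 0.001)$selected), 5)
  none <- bayesFDRSelect(rep(0.9, 4), 0.05)
  expect_equal(sum(none$selected), 0)
  expect_true(is.na(none$threshold))
})

test_that("lowering the FDR level never adds selections", {
  withr::with_seed(8, pips <- runif(200)^0.3)
  prev <- rep(TRUE, 200)
  for (alpha in c(0.2, 0.1, 0.05, 0.01, 0.001)) {
    sel <- bayesFDRSelect(pips, alpha)$selected
    expect_true(all(prev | !sel))    # sel is a subset of prev
    prev <- sel
  }
})

test_that("realized Bayesian FDR of the selected set stays below the level", {
  withr::with_seed(9, pips <- c(runif(50, 0.9, 1), runif(200)))
  for (alpha in c(0.01, 0.05, 0.1)) {
    sel <- bayesFDRSelect(pips, alpha)$selected
    if (any(sel)) expect_lte(mean(1 - pips[sel]), alpha)
  }
})

test_that("undirected networks are symmetric and selection is coherent", {
  sim <- simulateHomogeneous(n = 80, p = 6, connProb = 0.2, seed = 13)
  fit <- fitGraphReg(simFeatures(sim), simFactors(sim))
  net <- buildNetwork(fit, matrix(1, 1, 1), fdrLevel = 0.05)
  e <- edgeRecords(net)
  expect_equal(nrow(e), choose(6, 2))
  expect_true(all(e$i < e$j))
  # the symmetrized PIP equals the mean of the two directed estimates
  for (r in sample(nrow(e), 5)) {
    pij <- edgePIP(fit, e$i[r], e$j[r], 1)
    pji <- edgePIP(fit, e$j[r], e$i[r], 1)
    expect_equal(e$pip[r], (pij + pji) / 2, tolerance = 1e-12)
  }
  # selected edges are exactly those at or above the realized threshold
  if (any(e$selected))
    expect_true(min(e$pip[e$selected]) >= max(c(0, e$pip[!e$selected])))
})

test_that("sign consistency holds for a single-factor model", {
  sim <- simulateHomogeneous(n = 100, p = 5, connProb = 0.3, seed = 14)
  fit <- fitGraphReg(simFeatures(sim), simFactors(sim))
  arr <- graphreg:::.coefArrays(fit)
  for (i in 1:5) for (j in setdiff(1:5, i)) {
    # on the precision scale E[bs]_prec = -E[omega] * c, so the sign of
    # the partial correlation is -sign(x * E[bs]_prec) = sign(x * c)
    cc <- arr$ebs[i, j, 1]
    ebsPrec <- -arr$eomega[i] * cc
    if (abs(cc) > 1e-10)
      expect_equal(sign(edgePartialCor(fit, i, j, 1)), -sign(ebsPrec))
  }
})

test_that("symmetrizing directed records averages them; dag is a no-op", {
  fit <- makeToyFit(alpha1 = c(1, 0), mu1 = c(0.8, 0),
                    alpha2 = c(1, 0), mu2 = c(0.6, 0))
  # build a directed table by hand from both node regressions
  e <- data.frame(i = c(1, 2), j = c(2, 1), covariate = 1,
                  pip = c(0.8, 0.6), pcor = c(0.3, -0.3),
                  selected = FALSE)
  tbl <- new("EdgeTable", edges = e, fdrLevel = 0.01, mode = "undirected",
             threshold = NA_real_, covariates = matrix(1, 1, 2),
             featureNames = c("A", "B"))
  sym <- symmetrizeEdges(tbl)
  es <- edgeRecords(sym)
  expect_equal(nrow(es), 1)
  expect_equal(es$pip, 0.7)
  expect_equal(es$pcor, 0)          # opposite directed estimates cancel

  dag <- new("EdgeTable",
             edges = data.frame(i = 2, j = 1, covariate = 1, pip = 0.5,
                                pcor = 0.1, selected = FALSE),
             fdrLevel = 0.01, mode = "dag", threshold = NA_real_,
             covariates = matrix(1, 1, 2), featureNames = c("A", "B"))
  expect_warning(out <- symmetrizeEdges(dag), "directed")
  expect_identical(edgeRecords(out), edgeRecords(dag))
})

test_that("group evaluation covariates yield one network per group", {
  sim <- simulateMulticategory(n = 90, p = 8, groups = 2, connProb = 0.3,
                               seed = 15)
  fit <- fitGraphReg(simFeatures(sim), simFactors(sim))
  net <- buildNetwork(fit, diag(2), fdrLevel = 0.01)
  e <- edgeRecords(net)
  expect_equal(nrow(e), 2 * choose(8, 2))
  expect_equal(sort(unique(e$covariate)), c(1, 2))
})

test_that("edge filters prune pairs by magnitude and selection fraction", {
  e <- data.frame(i = c(1, 1, 2, 2), j = c(2, 2, 3, 3),
                  covariate = c(1, 2, 1, 2),
                  pip = c(0.99, 0.99, 0.2, 0.3),
                  pcor = c(0.5, 0.45, 0.05, 0.02),
                  selected = c(TRUE, TRUE, FALSE, FALSE))
  tbl <- new("EdgeTable", edges = e, fdrLevel = 0.01, mode = "undirected",
             threshold = 0.99, covariates = matrix(0, 2, 1),
             featureNames = c("A", "B", "C"))
  kept <- filterEdges(tbl, minAbsPcor = 0.4, minFractionSelected = 0.5)
  expect_equal(unique(paste(edgeRecords(kept)$i, edgeRecords(kept)$j)),
               "1 2")
})
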