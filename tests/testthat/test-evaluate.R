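# Recovery metrics, AUC and the replication harness.

test_that("confusion counts follow set arithmetic over the universe", {
  expect_equal(confusionCounts(c(TRUE, FALSE), c(TRUE, FALSE)),
               c(tp = 1L, fp = 0L, tn = 1L, fn = 0L))
  uni <- rbind(c(1, 2), c(1, 3), c(2, 3))
  out <- confusionCounts(rbind(c(1, 2)), rbind(c(2, 3)), uni)
  expect_equal(out, c(tp = 0L, fp = 1L, tn = 1L, fn = 1L))
  # empty selection
  out0 <- confusionCounts(rbind(c(1, 2)), matrix(numeric(), 0, 2), uni)
  expect_equal(out0[["fp"]], 0L)
  expect_equal(out0[["tp"]], 0L)
  expect_error(confusionCounts(rbind(c(1, 4)), rbind(c(1, 2)), uni),
               "universe")
})

test_that("metric formulas agree with a brute-force implementation", {
  expect_equal(recoveryMetrics(c(tp = 5, fp = 0, tn = 20, fn = 0))[["mcc"]],
               1)
  expect_equal(recoveryMetrics(c(tp = 3, fp = 1, tn = 90, fn = 2))[["mcc"]],
               0.655, tolerance = 1e-3)
  expect_equal(recoveryMetrics(c(tp = 0, fp = 0, tn = 10, fn = 2))[["fdr"]],
               0)
  withr::with_seed(20, {
    for (k in 1:1000) {
      cts <- sample(0:30, 4, replace = TRUE)
      got <- recoveryMetrics(c(tp = cts[1], fp = cts[2],
                               tn = cts[3], fn = cts[4]))
      want <- bruteMetrics(cts[1], cts[2], cts[3], cts[4])
      expect_equal(got, want)
    }
  })
})

test_that("AUC equals the tie-aware rank statistic", {
  expect_equal(rocAUC(c(1, 0.9, 0.1, 0), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(rocAUC(rep(0.5, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)),
               0.5)
  expect_equal(rocAUC(c(0.9, 0.8, 0.3), c(TRUE, FALSE, TRUE)), 0.5)
  withr::with_seed(21, {
    for (k in 1:25) {
      s <- sample(seq(0, 1, by = 0.1), 30, replace = TRUE)
      lab <- runif(30) < 0.4
      if (any(lab) && !all(lab))
        expect_equal(rocAUC(s, lab), bruteAUC(s, lab))
    }
  })
  expect_error(rocAUC(c(1, 2), c(TRUE, TRUE)), "positive and one negative")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  withr::with_seed(22, {
    s <- runif(40)
    lab <- runif(40) < 0.3
  })
  base <- rocAUC(s, lab)
  expect_equal(rocAUC(qlogis(s * 0.98 + 0.01), lab), base)
  expect_equal(rocAUC(s^3, lab), base)
  expect_equal(rocAUC(rank(s), lab), base)
})

test_that("single-replicate studies are deterministic and self-consistent", {
  a <- replicateStudy("homogeneous", reps = 1, seed = 5, n = 60, p = 8,
                      connProb = 0.1)
  b <- replicateStudy("homogeneous", reps = 1, seed = 5, n = 60, p = 8,
                      connProb = 0.1)
  expect_identical(a$replicates, b$replicates)
  expect_equal(a$summary$sd, rep(NA_real_, nrow(a$summary)))

  # harness metrics equal metrics recomputed from the same fit's network
  repSeed <- withr::with_seed(5, sample.int(.Machine$integer.max - 1, 1))
  sim <- simulateHomogeneous(n = 60, p = 8, connProb = 0.1, seed = repSeed)
  fit <- fitGraphReg(simFeatures(sim), simFactors(sim))
  net <- buildNetwork(fit, matrix(1, 1, 1), fdrLevel = 0.01)
  e <- edgeRecords(net)
  truth <- simTruth(sim)[[1]][cbind(e$i, e$j)]
  met <- recoveryMetrics(confusionCounts(truth, e$selected))
  expect_equal(a$replicates$mcc, met[["mcc"]])
  expect_equal(a$replicates$auc, rocAUC(e$pip, truth))
})

test_that("continuous-scenario coefficient recovery separates signal from null", {
  # n large relative to p: true-support inclusion probabilities near 1,
  # null inclusion probabilities near 0 (averaged over replicates)
  onSupport <- c(); offSupport <- c()
  for (r in 1:20) {
    sim <- simulateContinuous(n = 1000, p = 10, q = 2, fracNonzero = 0.02,
                              seed = 400 + r)
    fit <- fitGraphReg(simFeatures(sim), simFactors(sim))
    B <- simBeta(sim)
    for (i in 1:10) {
      nd <- nodePosteriors(fit)[[i]]
      truth <- B[cbind(i, nd@indexMap$node, nd@indexMap$factor)] != 0
      onSupport <- c(onSupport, nd@alpha[truth])
      offSupport <- c(offSupport, nd@alpha[!truth])
    }
  }
  expect_gt(mean(onSupport), 0.9)
  expect_lt(mean(offSupport), 0.1)
})

test_that("failed replicates are reported, not dropped silently", {
  rs <- suppressWarnings(
    replicateStudy("continuous", reps = 2, seed = 1, n = 30, p = 8,
                   fracNonzero = 0.6, maxTries = 2))
  expect_equal(length(rs$failures), 2)
})
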