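# Independent oracles used across the suite.

# log density of N(0, S) at y
.mvnLogDens <- function(y, S) {
  L <- chol(S)
  -0.5 * length(y) * log(2 * pi) - sum(log(diag(L))) -
    0.5 * sum(backsolve(L, y, transpose = TRUE)^2)
}

# Exact spike-and-slab posterior by enumerating all 2^m configurations,
# with fixed slab precision tau, noise precision omega and inclusion
# probability pi0 (the slab coefficients are integrated analytically).
exactSpikeSlab <- function(y, Z, tau, omega, pi0) {
  m <- ncol(Z)
  configs <- as.matrix(expand.grid(rep(list(0:1), m)))
  logw <- apply(configs, 1, function(s) {
    S <- diag(length(y)) / omega
    act <- which(s == 1)
    if (length(act))
      S <- S + Z[, act, drop = FALSE] %*% t(Z[, act, drop = FALSE]) / tau
    sum(s * log(pi0) + (1 - s) * log(1 - pi0)) + .mvnLogDens(y, S)
  })
  mx <- max(logw)
  w <- exp(logw - mx)
  list(pip = colSums(configs * w) / sum(w),
       logMarginal = mx + log(sum(w)))
}

# brute-force metric formulas, written independently of recoveryMetrics()
bruteMetrics <- function(tp, fp, tn, fn) {
  tpr <- if (tp + fn > 0) tp / (tp + fn) else 0
  fpr <- if (fp + tn > 0) fp / (fp + tn) else 0
  fdr <- if (tp + fp > 0) fp / (fp + tp) else 0
  den <- prod(c(tp + fp, tp + fn, tn + fp, tn + fn))
  mcc <- if (den > 0) (tp * tn - fp * fn) / sqrt(den) else 0
  c(tpr = tpr, fpr = fpr, fdr = fdr, mcc = mcc)
}

# AUC by explicit pairwise comparison (ties count 1/2)
bruteAUC <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (a in pos) tot <- tot + sum(a > neg) + 0.5 * sum(a == neg)
  tot / (length(pos) * length(neg))
}

# small standardized dataset with one strong conditional dependence
makeSignalData <- function(n = 120, p = 4, effect = 2, seed = 99) {
  withr::with_seed(seed, {
    Y <- matrix(rnorm(n * p), n, p)
    Y[, 1] <- effect * Y[, 2] + rnorm(n)
    colnames(Y) <- paste0("V", seq_len(p))
    Y
  })
}
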