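# Structure-recovery metrics and the replication harness.

#' Confusion counts over a candidate universe
#'
#' Either supply \code{truth} and \code{selected} as logical vectors over
#' an implicit universe (same length), or as two-column index matrices of
#' edges together with an explicit \code{universe} matrix of candidate
#' pairs; edges outside the universe are an error.
#'
#' @param truth,selected logical vectors, or two-column matrices of pair
#'   indices.
#' @param universe two-column matrix of candidate pairs (required for the
#'   matrix form).
#' @return Named integer vector \code{c(tp, fp, tn, fn)}.
#' @examples
#' confusionCounts(c(TRUE, FALSE, TRUE), c(TRUE, TRUE, FALSE))
#' @export
confusionCounts <- function(truth, selected, universe = NULL) {
  if (!is.null(universe) || is.matrix(truth) || is.matrix(selected)) {
    if (is.null(universe)) stop("'universe' is required for edge-set input")
    key <- function(m) {
      m <- as.matrix(m)
      if (ncol(m) != 2) stop("edge sets must be two-column matrices")
      paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
    }
    uk <- key(universe)
    tk <- if (length(truth)) key(truth) else character()
    sk <- if (length(selected)) key(selected) else character()
    if (!all(tk %in% uk) || !all(sk %in% uk))
      stop("edges outside the candidate universe")
    truth <- uk %in% tk
    selected <- uk %in% sk
  }
  if (length(truth) != length(selected))
    stop("'truth' and 'selected' must have equal length")
  tp <- sum(truth & selected)
  fp <- sum(!truth & selected)
  fn <- sum(truth & !selected)
  tn <- sum(!truth & !selected)
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Binary-classification recovery metrics
#'
#' TPR = TP/(TP+FN), FPR = FP/(FP+TN), FDR = FP/(FP+TP) and the Matthews
#' correlation coefficient
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN) /
#'   \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}.}
#' Zero-denominator conventions: FDR is 0 when nothing is selected; MCC is
#' 0 when any factor of its denominator vanishes; TPR/FPR are 0 when their
#' denominators vanish.
#'
#' @param counts named vector from [confusionCounts()].
#' @return Named numeric vector \code{c(tpr, fpr, fdr, mcc)}.
#' @export
recoveryMetrics <- function(counts) {
  tp <- as.numeric(counts[["tp"]]); fp <- as.numeric(counts[["fp"]])
  tn <- as.numeric(counts[["tn"]]); fn <- as.numeric(counts[["fn"]])
  div <- function(num, den) if (den > 0) num / den else 0
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den > 0) (tp * tn - fp * fn) / sqrt(den) else 0
  c(tpr = div(tp, tp + fn), fpr = div(fp, fp + tn),
    fdr = div(fp, fp + tp), mcc = mcc)
}

#' Area under the ROC curve from PIP rankings
#'
#' Computed as the rank statistic: the probability that a randomly chosen
#' true edge outranks a randomly chosen non-edge, with ties counted 1/2.
#' This equals the area under the TPR-vs-FPR curve as the PIP threshold
#' sweeps (0, 1), without re-running selection over a threshold grid.
#'
#' @param scores numeric scores (PIPs).
#' @param labels logical truth flags.
#' @return AUC in \[0, 1\].
#' @examples
#' rocAUC(c(0.9, 0.8, 0.3), c(TRUE, FALSE, TRUE))
#' @export
rocAUC <- function(scores, labels) {
  labels <- as.logical(labels)
  nP <- sum(labels)
  nN <- sum(!labels)
  if (nP == 0 || nN == 0)
    stop("AUC requires at least one positive and one negative")
  r <- rank(scores)
  (sum(r[labels]) - nP * (nP + 1) / 2) / (nP * nN)
}

# ---- internal evaluation of one fitted replicate ------------------------

.upperTriVec <- function(M, pairs) M[cbind(pairs$i, pairs$j)]

# Vectorized MCC/TPR/FPR/FDR for a (pairs x E) selection matrix against a
# (pairs x E) truth matrix, column-wise; returns an E x 4 matrix.
.metricsByColumn <- function(truthMat, selMat) {
  tp <- as.numeric(colSums(truthMat & selMat))
  fp <- as.numeric(colSums(!truthMat & selMat))
  fn <- as.numeric(colSums(truthMat & !selMat))
  tn <- as.numeric(colSums(!truthMat & !selMat))
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- ifelse(den > 0, (tp * tn - fp * fn) / sqrt(den), 0)
  cbind(tpr = ifelse(tp + fn > 0, tp / (tp + fn), 0),
        fpr = ifelse(fp + tn > 0, fp / (fp + tn), 0),
        fdr = ifelse(tp + fp > 0, fp / (tp + fp), 0),
        mcc = mcc)
}

# per-column AUC; degenerate columns (no positives or no negatives, e.g.
# discrete-factor subjects whose loaded factors are all zero) yield NA
.aucByColumn <- function(truthMat, pipMat) {
  vapply(seq_len(ncol(pipMat)), function(e) {
    tr <- truthMat[, e]
    if (all(tr) || !any(tr)) return(NA_real_)
    rocAUC(pipMat[, e], tr)
  }, numeric(1))
}

# Evaluate one simulated dataset with a fitted model: returns the
# per-replicate metric row.  Selection always applies the Bayesian FDR
# rule jointly across all (pair, covariate) records.
.evaluateReplicate <- function(sim, fit, fdrLevel) {
  scen <- sim@scenario
  if (scen == "multicategory") {
    G <- sim@params$groups
    Xeval <- diag(G)
    if (sim@params$encoding == "intercept") {
      Xeval <- cbind(1, rbind(0, diag(G - 1)))
    }
    sc <- .networkScores(fit, Xeval)
    truthMat <- vapply(sim@truth, .upperTriVec, numeric(nrow(sc$pairs)),
                       pairs = sc$pairs) > 0
    sel <- bayesFDRSelect(as.numeric(sc$pip), fdrLevel)
    selMat <- matrix(sel$selected, ncol = G)
    pooled <- recoveryMetrics(confusionCounts(as.logical(truthMat),
                                              as.logical(selMat)))
    auc <- rocAUC(as.numeric(sc$pip), as.logical(truthMat))
    perGroup <- .metricsByColumn(truthMat, selMat)
    aucGroup <- .aucByColumn(truthMat, sc$pip)
    c(pooled, auc = auc,
      stats::setNames(colMeans(perGroup), paste0(colnames(perGroup),
                                                 "GroupMean")),
      aucGroupMean = mean(aucGroup))
  } else if (scen == "homogeneous") {
    sc <- .networkScores(fit, matrix(1, 1, 1))
    truth <- .upperTriVec(sim@truth[[1]], sc$pairs)
    sel <- bayesFDRSelect(as.numeric(sc$pip), fdrLevel)
    met <- recoveryMetrics(confusionCounts(truth, sel$selected))
    c(met, auc = rocAUC(as.numeric(sc$pip), truth))
  } else if (scen == "dag") {
    # variable-selection evaluation against the true coefficient support:
    # the candidate universe is every (ancestor pair j < i, factor)
    # coefficient, scored by its posterior inclusion probability E[s]
    B <- sim@beta
    truth <- logical(0)
    alph <- numeric(0)
    for (i in seq_along(fit@nodes)) {
      nd <- fit@nodes[[i]]
      if (!length(nd@alpha)) next
      im <- nd@indexMap
      truth <- c(truth, B[cbind(i, im$node, im$factor)] != 0)
      alph <- c(alph, nd@alpha)
    }
    sel <- bayesFDRSelect(alph, fdrLevel)
    met <- recoveryMetrics(confusionCounts(truth, sel$selected))
    c(met, auc = rocAUC(alph, truth))
  } else if (scen == "continuous") {
    sc <- .networkScores(fit, sim@X)
    sel <- bayesFDRSelect(as.numeric(sc$pip), fdrLevel)
    selMat <- matrix(sel$selected, ncol = nrow(sim@X))
    # per-subject truth: edge (i, j) exists for subject s iff
    # sum_l beta_ijl x_sl != 0.  With continuous factors this almost
    # surely equals the coefficient support; with discrete factors a
    # subject whose loaded factors are all 0 genuinely has no edge.
    if (length(sim@beta)) {
      q <- dim(sim@beta)[3]
      Bp <- vapply(seq_len(q), function(l)
        sim@beta[, , l][cbind(sc$pairs$i, sc$pairs$j)],
        numeric(nrow(sc$pairs)))
      truthMat <- abs(matrix(Bp, ncol = q) %*% t(sim@X)) > 1e-12
    } else {
      truth <- .upperTriVec(sim@truth[[1]], sc$pairs)
      truthMat <- matrix(truth, nrow(sc$pairs), nrow(sim@X))
    }
    perSubject <- .metricsByColumn(truthMat, selMat)
    aucSubject <- .aucByColumn(truthMat, sc$pip)
    c(colMeans(perSubject), auc = mean(aucSubject, na.rm = TRUE))
  } else {
    stop("scenario '", scen, "' has no replication metric")
  }
}

.simulateScenario <- function(scenario, seed, args) {
  gen <- switch(scenario,
                multicategory = simulateMulticategory,
                continuous = simulateContinuous,
                homogeneous = simulateHomogeneous,
                dag = simulateDAG)
  do.call(gen, c(args, list(seed = seed)))
}

#' Replicate a simulation benchmark
#'
#' For each replicate: simulate the scenario, fit the graphical
#' regression, build networks at the scenario's evaluation covariates
#' (group indicators, per-subject factors, or the intercept), select edges
#' with the Bayesian FDR rule applied jointly across all (pair, covariate)
#' records, and score structure recovery against the ground truth.
#' The continuous scenario scores each subject against its own edge set
#' (\eqn{\sum_l \beta_{ijl} x_l \ne 0}) and averages, matching the
#' per-subject reporting convention; the multi-category scenario reports
#' both pooled metrics (primary columns) and per-group averages
#' (\code{*GroupMean} columns); the DAG scenario scores
#' coefficient-level variable selection — every (ancestor pair, factor)
#' coefficient, ranked by its inclusion probability — against the true
#' coefficient support.
#'
#' @param scenario one of \code{"multicategory"}, \code{"continuous"},
#'   \code{"homogeneous"}, \code{"dag"}.
#' @param reps number of replicates.
#' @param fdrLevel Bayesian FDR level for edge selection.
#' @param hyper a [GraphRegHyper-class].
#' @param seed integer seed; per-replicate seeds are derived
#'   deterministically from it.
#' @param ... scenario parameters passed to the generator
#'   (e.g. \code{n}, \code{p}, \code{groups}, \code{connProb},
#'   \code{fracNonzero}, \code{factorKinds}).
#' @return A list with \code{summary} (data.frame of per-metric mean and
#'   sd), \code{replicates} (per-replicate metric rows), \code{scenario},
#'   \code{failures} (messages of failed replicates, reported rather than
#'   silently dropped).
#' @examples
#' \donttest{
#' rs <- replicateStudy("homogeneous", reps = 2, seed = 1, n = 60, p = 10,
#'                      connProb = 0.05)
#' rs$summary
#' }
#' @export
replicateStudy <- function(scenario = c("multicategory", "continuous",
                                        "homogeneous", "dag"),
                           reps = 50, fdrLevel = 0.01,
                           hyper = graphRegHyper(), seed = 1, ...) {
  scenario <- match.arg(scenario)
  args <- list(...)
  mode <- if (scenario == "dag") "dag" else "undirected"
  repSeeds <- .withSeed(seed, sample.int(.Machine$integer.max - 1, reps))
  rows <- vector("list", reps)
  failures <- character()
  for (r in seq_len(reps)) {
    res <- tryCatch({
      sim <- .simulateScenario(scenario, repSeeds[r], args)
      fit <- fitGraphReg(sim@Y, simFactors(sim), hyper, mode = mode)
      .evaluateReplicate(sim, fit, fdrLevel)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("replicate %d: %s", r,
                                      conditionMessage(res)))
    } else {
      rows[[r]] <- c(replicate = r, res)
    }
  }
  rep_df <- as.data.frame(do.call(rbind, rows))
  metrics <- setdiff(names(rep_df), "replicate")
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(mm) mean(rep_df[[mm]]), numeric(1)),
    sd = vapply(metrics, function(mm) stats::sd(rep_df[[mm]]), numeric(1)),
    row.names = NULL)
  list(summary = summary, replicates = rep_df, scenario = scenario,
       fdrLevel = fdrLevel, reps = reps, seed = seed, failures = failures)
}

#' Simpson's-paradox demonstration
#'
#' Fits the two-group dataset from [simulateSimpsons()] twice: with the
#' group indicators (heterogeneous fit) and with an intercept only
#' (pooled, homogeneous fit), and reports the A–B edge's partial
#' correlation under each.  In the generating design the two groups have
#' A–B conditional dependencies of opposite sign, which the pooled fit
#' averages away.
#'
#' @param seed integer seed passed to the generator.
#' @param hyper a [GraphRegHyper-class].
#' @param fdrLevel Bayesian FDR level used for the reported edge tables.
#' @return A list with \code{heterogeneous} (named vector of the two
#'   group-specific A–B partial correlations), \code{pooled} (scalar),
#'   \code{truePartialCor} (the generating \eqn{-\omega_{12}/
#'   \sqrt{\omega_{11}\omega_{22}}} per group), and the two fits.
#' @export
simpsonsAnalysis <- function(seed = 1, hyper = graphRegHyper(),
                             fdrLevel = 0.01) {
  sim <- simulateSimpsons(seed)
  het <- fitGraphReg(sim@Y, simFactors(sim), hyper)
  hom <- fitGraphReg(sim@Y, intrinsicFactors(sim@params$interceptX), hyper)
  hetNet <- buildNetwork(het, diag(2), fdrLevel)
  homNet <- buildNetwork(hom, matrix(1, 1, 1), fdrLevel)
  pcorOf <- function(net, cov) {
    e <- edgeRecords(net)
    e$pcor[e$i == 1 & e$j == 2 & e$covariate == cov]
  }
  truePC <- vapply(sim@precisions, function(O)
    -O[1, 2] / sqrt(O[1, 1] * O[2, 2]), numeric(1))
  list(heterogeneous = c(group1 = pcorOf(hetNet, 1),
                         group2 = pcorOf(hetNet, 2)),
       pooled = pcorOf(homNet, 1),
       truePartialCor = c(group1 = truePC[1], group2 = truePC[2]),
       heterogeneousFit = het, pooledFit = hom,
       heterogeneousNetwork = hetNet, pooledNetwork = homNet)
}
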