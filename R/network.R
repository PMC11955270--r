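# Network construction from a fitted model: weighted posterior inclusion
# probabilities, partial correlations, and Bayesian FDR edge selection.

# p x p x q arrays of posterior summaries; entry [i, j, l] refers to the
# coefficient of X_l * Y_j in node i's regression (NA where absent).
.coefArrays <- function(fit) {
  p <- length(fit@featureNames)
  q <- length(fit@factorNames)
  alpha <- array(NA_real_, c(p, p, q))
  mu <- array(NA_real_, c(p, p, q))
  eomega <- numeric(p)
  for (i in seq_len(p)) {
    nd <- fit@nodes[[i]]
    eomega[i] <- nd@omegaShape / nd@omegaRate
    if (length(nd@alpha)) {
      idx <- cbind(i, nd@indexMap$node, nd@indexMap$factor)
      alpha[idx] <- nd@alpha
      mu[idx] <- nd@mu
    }
  }
  list(alpha = alpha, mu = mu, ebs = alpha * mu, eomega = eomega,
       p = p, q = q)
}

.checkEvalCovariate <- function(x, q) {
  if (length(x) != q)
    stop("evaluation covariate must have length ", q)
  as.numeric(x)
}

#' Posterior inclusion probability of an edge
#'
#' For an individual with intrinsic-factor values \code{x}, the PIP of the
#' (directed) edge j -> i is the weighted mean of the per-factor inclusion
#' probabilities \eqn{E[s_{ijl}]} with weights \eqn{(x_l E[b_{ijl}])^2},
#' where \eqn{E[b] = \alpha \mu} is the marginal posterior mean of the
#' coefficient.  When all weights vanish the PIP is
#' defined as 0 (no evidence of an edge at that covariate value).
#'
#' @param fit a [GraphRegFit-class].
#' @param i response node; \code{j} regressor node.
#' @param j regressor node index.
#' @param x numeric q-vector of evaluation covariates.
#' @return A value in \[0, 1\].
#' @seealso [buildNetwork()] for whole-network construction including
#'   symmetrization across the two directed estimates.
#' @export
edgePIP <- function(fit, i, j, x) {
  arr <- .coefArrays(fit)
  x <- .checkEvalCovariate(x, arr$q)
  a <- arr$alpha[i, j, ]
  b <- arr$ebs[i, j, ]   # marginal posterior mean E[b] = alpha * mu
  if (anyNA(a))
    stop("node ", j, " is not a regressor in node ", i, "'s fit")
  w <- (x * b)^2
  if (sum(w) == 0) return(0)
  sum(w * a) / sum(w)
}

#' Partial correlation of an edge
#'
#' The edge's partial correlation at covariate value \code{x} is
#' \eqn{-\sum_l x_l E[\beta_{ijl}] / E[\omega_{ii}]}, where the
#' \eqn{\beta} parametrize the precision entry
#' \eqn{\omega_{ij}(x) = \sum_l \beta_{ijl} x_l}.  The node regression
#' estimates the coefficients \eqn{c_{ijl}} of
#' \eqn{\gamma_{ij}(x) = -\omega_{ij}(x) / \omega_{ii}}, i.e.
#' \eqn{\beta_{ijl} = -c_{ijl}\,\omega_{ii}}, so the noise precision
#' cancels and the estimate reduces to
#' \eqn{\hat\rho_{ij}(x) = \sum_l x_l E[b_{ijl} s_{ijl}]} with
#' \eqn{E[bs] = \alpha \mu} the posterior-mean regression coefficients.
#' Its sign agrees with the conditional association (positive for
#' positively partially-correlated nodes).  The raw value is returned;
#' clipping to \[-1, 1\] for reporting is left to the caller.
#'
#' @inheritParams edgePIP
#' @return A real number; sign flips with the sign of \code{x}.
#' @export
edgePartialCor <- function(fit, i, j, x) {
  arr <- .coefArrays(fit)
  x <- .checkEvalCovariate(x, arr$q)
  ebs <- arr$ebs[i, j, ]
  if (anyNA(ebs))
    stop("node ", j, " is not a regressor in node ", i, "'s fit")
  sum(x * ebs)
}

#' Bayesian FDR selection from posterior inclusion probabilities
#'
#' Sorts the PIPs in decreasing order and selects the largest prefix whose
#' mean posterior probability of being a false edge, \code{mean(1 - PIP)},
#' stays at or below \code{fdrLevel}.  The realized FDR of the selected
#' set is therefore bounded by \code{fdrLevel} by construction, and
#' lowering the level can only shrink the selection.
#'
#' @param pip numeric vector of PIPs in \[0, 1\].
#' @param fdrLevel target Bayesian FDR level in (0, 1).
#' @return A list with \code{selected} (logical, in input order) and
#'   \code{threshold} (smallest selected PIP; \code{NA} if none).
#' @examples
#' bayesFDRSelect(c(0.995, 0.99, 0.6), 0.01)
#' @export
bayesFDRSelect <- function(pip, fdrLevel = 0.01) {
  if (length(fdrLevel) != 1 || fdrLevel <= 0 || fdrLevel >= 1)
    stop("'fdrLevel' must lie in (0, 1)")
  if (any(pip < 0 | pip > 1)) stop("PIPs must lie in [0, 1]")
  o <- order(pip, decreasing = TRUE)
  cm <- cumsum(1 - pip[o]) / seq_along(o)
  k <- if (any(cm <= fdrLevel)) max(which(cm <= fdrLevel)) else 0L
  sel <- logical(length(pip))
  if (k > 0) sel[o[seq_len(k)]] <- TRUE
  list(selected = sel,
       threshold = if (k > 0) pip[o[k]] else NA_real_)
}

# Directed PIP and partial-correlation matrices for a whole evaluation
# grid, fully vectorized.  Returns flattened (p*p) x E matrices where row
# r corresponds to (i = (r-1) %% p + 1, j = (r-1) %/% p + 1).
.directedScores <- function(arr, Xeval) {
  p <- arr$p
  mu2 <- matrix(arr$ebs^2, p * p, arr$q)
  num <- matrix(arr$ebs^2 * arr$alpha, p * p, arr$q)
  X2 <- Xeval^2
  pipn <- num %*% t(X2)
  pipd <- mu2 %*% t(X2)
  pip <- pipn / pipd
  pip[!is.finite(pip)] <- 0        # all-zero-weight convention
  # regression-scale coefficients: the -1/omega_ii of the precision
  # parametrization cancels (see edgePartialCor)
  pcor <- matrix(arr$ebs, p * p, arr$q) %*% t(Xeval)
  list(pip = pip, pcor = pcor)
}

.pairIndices <- function(p, mode) {
  if (mode == "undirected") {
    idx <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
    data.frame(i = idx[, "row"], j = idx[, "col"])   # i < j
  } else {
    idx <- which(lower.tri(matrix(0, p, p)), arr.ind = TRUE)
    data.frame(i = idx[, "row"], j = idx[, "col"])   # j < i: edge j -> i
  }
}

# Core network computation shared by buildNetwork() and the replication
# harness: pair-by-covariate PIP and partial-correlation matrices.
.networkScores <- function(fit, Xeval, symmetrize = c("mean", "max")) {
  symmetrize <- match.arg(symmetrize)
  arr <- .coefArrays(fit)
  p <- arr$p
  Xeval <- as.matrix(Xeval)
  if (ncol(Xeval) != arr$q)
    stop("evaluation covariates must have ", arr$q, " columns")
  dir <- .directedScores(arr, Xeval)
  pr <- .pairIndices(p, fit@mode)
  lin1 <- pr$i + (pr$j - 1L) * p      # coefficient (j, .) in node i's fit
  if (fit@mode == "undirected") {
    lin2 <- pr$j + (pr$i - 1L) * p
    if (symmetrize == "mean") {
      pip <- (dir$pip[lin1, , drop = FALSE] + dir$pip[lin2, , drop = FALSE]) / 2
      pcor <- (dir$pcor[lin1, , drop = FALSE] + dir$pcor[lin2, , drop = FALSE]) / 2
    } else {
      pip <- pmax(dir$pip[lin1, , drop = FALSE], dir$pip[lin2, , drop = FALSE])
      keep <- abs(dir$pcor[lin1, , drop = FALSE]) >=
        abs(dir$pcor[lin2, , drop = FALSE])
      pcor <- ifelse(keep, dir$pcor[lin1, , drop = FALSE],
                     dir$pcor[lin2, , drop = FALSE])
    }
  } else {
    pip <- dir$pip[lin1, , drop = FALSE]
    pcor <- dir$pcor[lin1, , drop = FALSE]
  }
  list(pairs = pr, pip = pip, pcor = pcor)
}

#' Build sample- or group-specific networks
#'
#' Computes the PIP and partial correlation for every node pair at every
#' row of \code{Xeval} (one row per group, subject or spatial location),
#' symmetrizes the two directed estimates in undirected mode, and selects
#' edges with [bayesFDRSelect()] applied jointly across all
#' (pair, covariate) records.
#'
#' @param fit a [GraphRegFit-class].
#' @param Xeval evaluation covariates: an E x q matrix (or
#'   [IntrinsicFactors-class]), one row per network to construct.
#' @param fdrLevel target Bayesian FDR level.
#' @param symmetrize how to combine the two directed estimates in
#'   undirected mode: arithmetic \code{"mean"} (default) or \code{"max"}
#'   (largest PIP, partial correlation of larger magnitude).  Ignored with
#'   a warning in DAG mode, where estimates are inherently directed.
#' @return An [EdgeTable-class] with one record per pair per covariate row.
#' @examples
#' sim <- simulateHomogeneous(n = 80, p = 6, connProb = 0.2, seed = 2)
#' fit <- fitGraphReg(simFeatures(sim), simFactors(sim))
#' net <- buildNetwork(fit, matrix(1, 1, 1), fdrLevel = 0.01)
#' head(edgeRecords(net))
#' @export
buildNetwork <- function(fit, Xeval, fdrLevel = 0.01,
                         symmetrize = c("mean", "max")) {
  symmetrize <- match.arg(symmetrize)
  Xeval <- .factorValues(Xeval)
  if (anyNA(Xeval)) stop("evaluation covariates contain missing values")
  sc <- .networkScores(fit, Xeval, symmetrize)
  E <- nrow(Xeval)
  npair <- nrow(sc$pairs)
  pipVec <- as.numeric(sc$pip)
  sel <- bayesFDRSelect(pipVec, fdrLevel)
  edges <- data.frame(
    i = rep(sc$pairs$i, times = E),
    j = rep(sc$pairs$j, times = E),
    covariate = rep(seq_len(E), each = npair),
    pip = pipVec,
    pcor = as.numeric(sc$pcor),
    selected = sel$selected)
  rn <- rownames(Xeval)
  if (!is.null(rn)) edges$covariate <- rep(rn, each = npair)[seq_len(nrow(edges))]
  new("EdgeTable", edges = edges, fdrLevel = fdrLevel, mode = fit@mode,
      threshold = sel$threshold, covariates = Xeval,
      featureNames = fit@featureNames)
}

#' Symmetrize a directed edge table
#'
#' Replaces the PIP and partial correlation of each unordered pair by the
#' arithmetic mean of the two directed records and collapses them to a
#' single record.  [buildNetwork()] already symmetrizes in undirected
#' mode; this operation is exposed for tables of directed estimates built
#' manually.  In DAG mode the table is returned unchanged with a warning.
#'
#' @param x an [EdgeTable-class] whose \code{edges} contain both directed
#'   records per pair (i.e. unconstrained i, j).
#' @return An [EdgeTable-class] with one record per unordered pair.
#' @export
symmetrizeEdges <- function(x) {
  stopifnot(is(x, "EdgeTable"))
  if (x@mode == "dag") {
    warning("DAG edge tables are directed; returning the table unchanged")
    return(x)
  }
  e <- x@edges
  lo <- pmin(e$i, e$j)
  hi <- pmax(e$i, e$j)
  grp <- split(seq_len(nrow(e)), paste(lo, hi, e$covariate, sep = "\r"))
  out <- do.call(rbind, lapply(grp, function(ii)
    data.frame(i = lo[ii[1]], j = hi[ii[1]], covariate = e$covariate[ii[1]],
               pip = mean(e$pip[ii]), pcor = mean(e$pcor[ii]))))
  sel <- bayesFDRSelect(out$pip, x@fdrLevel)
  out$selected <- sel$selected
  out <- out[order(out$covariate, out$j, out$i), , drop = FALSE]
  rownames(out) <- NULL
  new("EdgeTable", edges = out, fdrLevel = x@fdrLevel, mode = x@mode,
      threshold = sel$threshold, covariates = x@covariates,
      featureNames = x@featureNames)
}

#' Post-filter an edge table
#'
#' Optional analysis filters applied after FDR selection, mirroring common
#' reporting choices: keep pairs whose partial correlation reaches
#' \code{minAbsPcor} for at least one covariate, and/or pairs selected in
#' more than \code{minFractionSelected} of the covariates.  Records of
#' pairs failing the filters are dropped.
#'
#' @param x an [EdgeTable-class].
#' @param minAbsPcor minimum \code{max |pcor|} across covariates, or NULL.
#' @param minFractionSelected minimum fraction of covariates in which the
#'   pair is selected (strict inequality), or NULL.
#' @return The filtered [EdgeTable-class].
#' @export
filterEdges <- function(x, minAbsPcor = NULL, minFractionSelected = NULL) {
  stopifnot(is(x, "EdgeTable"))
  e <- x@edges
  key <- paste(e$i, e$j, sep = "\r")
  keep <- rep(TRUE, length(unique(key)))
  names(keep) <- unique(key)
  if (!is.null(minAbsPcor)) {
    mx <- tapply(abs(e$pcor), key, max)
    keep[names(mx)] <- keep[names(mx)] & mx >= minAbsPcor
  }
  if (!is.null(minFractionSelected)) {
    fr <- tapply(e$selected, key, mean)
    keep[names(fr)] <- keep[names(fr)] & fr > minFractionSelected
  }
  e <- e[keep[key], , drop = FALSE]
  rownames(e) <- NULL
  new("EdgeTable", edges = e, fdrLevel = x@fdrLevel, mode = x@mode,
      threshold = x@threshold, covariates = x@covariates,
      featureNames = x@featureNames)
}
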