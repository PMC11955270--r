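#' @import methods
NULL

#' Hyperparameters for graphical regression
#'
#' Container for the prior and algorithmic settings of the node-wise
#' spike-and-slab variational fits.
#'
#' @slot aTau,bTau shape and rate of the Gamma prior on the slab precisions
#'   \eqn{\tau_{il}} (one precision per intrinsic factor within each node
#'   regression).
#' @slot aPi,bPi shapes of the Beta prior on the per-coefficient inclusion
#'   weights \eqn{\pi_{ijl}}.  The prior inclusion probability is
#'   \code{aPi / (aPi + bPi)}.
#' @slot elboTol relative ELBO change declaring convergence
#'   (\eqn{|\Delta ELBO| / (|ELBO| + 1) <} \code{elboTol}).
#' @slot maxIter maximum number of coordinate-ascent sweeps.
#' @slot seed optional integer seed recorded alongside the fit; the
#'   variational optimisation itself is deterministic and does not consume
#'   random numbers.
#'
#' @seealso [graphRegHyper()]
#' @exportClass GraphRegHyper
setClass("GraphRegHyper",
  representation(aTau = "numeric", bTau = "numeric",
                 aPi = "numeric", bPi = "numeric",
                 elboTol = "numeric", maxIter = "integer",
                 seed = "integer"),
  prototype(aTau = 0.005, bTau = 0.005, aPi = 1, bPi = 4,
            elboTol = 1e-4, maxIter = 1000L, seed = NA_integer_))

setValidity("GraphRegHyper", function(object) {
  msg <- character()
  for (s in c("aTau", "bTau", "aPi", "bPi"))
    if (length(slot(object, s)) != 1 || !is.finite(slot(object, s)) ||
        slot(object, s) <= 0)
      msg <- c(msg, sprintf("'%s' must be a single positive number", s))
  if (length(object@elboTol) != 1 || object@elboTol <= 0)
    msg <- c(msg, "'elboTol' must be > 0")
  if (length(object@maxIter) != 1 || is.na(object@maxIter) ||
      object@maxIter < 1)
    msg <- c(msg, "'maxIter' must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Intrinsic factors
#'
#' Sample-level covariates that modulate the conditional-dependence
#' structure: an intercept, group indicators, continuous indices or spatial
#' coordinates.  Each column carries a kind tag in
#' \code{c("intercept", "indicator", "continuous")}; intercept columns are
#' exempt from standardization and at most one is allowed.
#'
#' @slot values n x q numeric matrix (samples in rows).
#' @slot kinds character vector of per-column kinds.
#'
#' @seealso [intrinsicFactors()]
#' @exportClass IntrinsicFactors
setClass("IntrinsicFactors",
  representation(values = "matrix", kinds = "character"))

setValidity("IntrinsicFactors", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v)) msg <- c(msg, "'values' must be numeric")
  if (anyNA(v)) msg <- c(msg, "'values' must not contain missing entries")
  if (length(object@kinds) != ncol(v))
    msg <- c(msg, "one kind per column is required")
  if (!all(object@kinds %in% c("intercept", "indicator", "continuous")))
    msg <- c(msg, "kinds must be 'intercept', 'indicator' or 'continuous'")
  if (sum(object@kinds == "intercept") > 1)
    msg <- c(msg, "at most one intercept column is allowed")
  ind <- which(object@kinds == "indicator")
  if (length(ind) && !all(v[, ind] %in% c(0, 1)))
    msg <- c(msg, "indicator columns must take values in {0, 1}")
  if (length(msg)) msg else TRUE
})

#' Design of a single node regression
#'
#' The response is one (standardized) node; the regressors are element-wise
#' products of intrinsic-factor columns with the other node columns, in
#' node-major, factor-minor order.  In \code{"dag"} mode only predecessor
#' nodes (j < i under the supplied ordering) enter the design; node 1 has a
#' valid zero-column design.
#'
#' @slot response numeric n-vector.
#' @slot design n x m numeric matrix, m = (#regressor nodes) x q.
#' @slot indexMap data.frame with columns \code{node} and \code{factor}
#'   mapping each design column to its (node j, factor l) pair.
#' @slot node index of the response node.
#' @slot mode \code{"undirected"} or \code{"dag"}.
#'
#' @exportClass NodeDesign
setClass("NodeDesign",
  representation(response = "numeric", design = "matrix",
                 indexMap = "data.frame", node = "integer",
                 mode = "character"))

setValidity("NodeDesign", function(object) {
  msg <- character()
  if (nrow(object@design) != length(object@response) && ncol(object@design) > 0)
    msg <- c(msg, "design rows must match response length")
  if (nrow(object@indexMap) != ncol(object@design))
    msg <- c(msg, "indexMap must have one row per design column")
  if (!object@mode %in% c("undirected", "dag"))
    msg <- c(msg, "mode must be 'undirected' or 'dag'")
  if (ncol(object@design) > 0 && any(object@indexMap$node == object@node))
    msg <- c(msg, "response node must not appear as a regressor")
  if (length(msg)) msg else TRUE
})

#' Variational posterior of one node regression
#'
#' Mean-field posterior for a single node's covariate-modulated regression:
#' per-coefficient inclusion probabilities and slab moments, Gamma
#' posteriors for the per-factor slab precisions and the noise precision,
#' Beta posteriors for the inclusion weights, and the ELBO trace.
#'
#' @slot alpha,mu,sigma2 m-vectors: inclusion probability E[s], slab mean
#'   and slab variance of each coefficient.
#' @slot tauShape,tauRate q-vectors: Gamma posterior of each factor's slab
#'   precision.
#' @slot piA,piB m-vectors: Beta posterior of each coefficient's inclusion
#'   weight.
#' @slot omegaShape,omegaRate scalars: Gamma posterior of the noise
#'   precision \eqn{\omega_{ii}}.
#' @slot elbo numeric trace of the evidence lower bound, one entry per sweep.
#' @slot converged logical convergence flag.
#' @slot indexMap data.frame mapping coefficients to (node, factor) pairs.
#' @slot node response-node index.
#'
#' @exportClass NodePosterior
setClass("NodePosterior",
  representation(alpha = "numeric", mu = "numeric", sigma2 = "numeric",
                 tauShape = "numeric", tauRate = "numeric",
                 piA = "numeric", piB = "numeric",
                 omegaShape = "numeric", omegaRate = "numeric",
                 elbo = "numeric", converged = "logical",
                 indexMap = "data.frame", node = "integer"))

setValidity("NodePosterior", function(object) {
  msg <- character()
  m <- length(object@alpha)
  if (length(object@mu) != m || length(object@sigma2) != m ||
      length(object@piA) != m || length(object@piB) != m)
    msg <- c(msg, "alpha, mu, sigma2, piA, piB must share length m")
  if (m > 0 && (any(object@alpha < 0) || any(object@alpha > 1)))
    msg <- c(msg, "alpha must lie in [0, 1]")
  if (m > 0 && any(object@sigma2 <= 0))
    msg <- c(msg, "sigma2 must be positive")
  if (any(c(object@tauShape, object@tauRate, object@piA, object@piB,
            object@omegaShape, object@omegaRate) <= 0))
    msg <- c(msg, "all Gamma/Beta posterior parameters must be positive")
  if (length(object@elbo) > 1 &&
      any(diff(object@elbo) < -1e-6 * (abs(object@elbo[-length(object@elbo)]) + 1)))
    msg <- c(msg, "elbo trace must be non-decreasing within tolerance")
  if (length(msg)) msg else TRUE
})

#' Fitted graphical regression model
#'
#' Collection of the p node posteriors, the mode (undirected neighbourhood
#' regressions or DAG regressions on predecessors), the hyperparameters
#' used, and the feature standardization applied before fitting.
#'
#' @slot nodes list of [NodePosterior-class] objects, one per node.
#' @slot mode \code{"undirected"} or \code{"dag"}.
#' @slot hyper the [GraphRegHyper-class] used.
#' @slot featureNames,factorNames column labels of Y and X.
#' @slot factorKinds per-factor kind tags.
#' @slot yCenter,yScale per-feature standardization recorded for
#'   back-transformation and for standardizing evaluation covariates.
#' @slot n number of samples.
#'
#' @seealso [fitGraphReg()]
#' @exportClass GraphRegFit
setClass("GraphRegFit",
  representation(nodes = "list", mode = "character", hyper = "GraphRegHyper",
                 featureNames = "character", factorNames = "character",
                 factorKinds = "character",
                 yCenter = "numeric", yScale = "numeric", n = "integer"))

setValidity("GraphRegFit", function(object) {
  msg <- character()
  p <- length(object@featureNames)
  q <- length(object@factorNames)
  if (length(object@nodes) != p)
    msg <- c(msg, "exactly one node posterior per feature is required")
  if (!object@mode %in% c("undirected", "dag"))
    msg <- c(msg, "mode must be 'undirected' or 'dag'")
  # index maps must jointly cover each ordered pair (undirected) or each
  # j < i pair (dag) exactly once, for every factor
  ok <- TRUE
  for (i in seq_along(object@nodes)) {
    im <- object@nodes[[i]]@indexMap
    expect <- if (object@mode == "undirected") setdiff(seq_len(p), i)
              else seq_len(i - 1L)
    want <- expand.grid(factor = seq_len(q), node = expect)[, c("node", "factor")]
    if (!identical(as.integer(im$node), as.integer(want$node)) ||
        !identical(as.integer(im$factor), as.integer(want$factor))) {
      ok <- FALSE
      break
    }
  }
  if (!ok) msg <- c(msg, "node index maps do not cover the expected pairs")
  if (length(msg)) msg else TRUE
})

#' Edge table of sample- or group-specific networks
#'
#' One record per node pair per evaluation covariate: posterior inclusion
#' probability, partial correlation and the Bayesian-FDR selection flag.
#'
#' @slot edges data.frame with columns \code{i}, \code{j}, \code{covariate},
#'   \code{pip}, \code{pcor}, \code{selected}.
#' @slot fdrLevel target Bayesian FDR level used for selection.
#' @slot mode \code{"undirected"} or \code{"dag"}.
#' @slot threshold realized PIP threshold (NA when nothing was selected).
#' @slot covariates the evaluation-covariate matrix (one row per covariate
#'   id appearing in \code{edges}).
#' @slot featureNames node labels.
#'
#' @seealso [buildNetwork()]
#' @exportClass EdgeTable
setClass("EdgeTable",
  representation(edges = "data.frame", fdrLevel = "numeric",
                 mode = "character", threshold = "numeric",
                 covariates = "matrix", featureNames = "character"))

setValidity("EdgeTable", function(object) {
  msg <- character()
  need <- c("i", "j", "covariate", "pip", "pcor", "selected")
  if (!all(need %in% names(object@edges)))
    msg <- c(msg, paste("edges must contain columns:",
                        paste(need, collapse = ", ")))
  else {
    if (any(object@edges$pip < 0 | object@edges$pip > 1))
      msg <- c(msg, "pip must lie in [0, 1]")
    if (any(object@edges$i == object@edges$j))
      msg <- c(msg, "self-loops are not allowed")
    if (object@mode == "dag" && any(object@edges$j >= object@edges$i))
      msg <- c(msg, "dag records must satisfy j < i")
  }
  if (length(object@fdrLevel) != 1 || object@fdrLevel <= 0 ||
      object@fdrLevel >= 1)
    msg <- c(msg, "fdrLevel must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Simulated benchmark dataset
#'
#' Output of the scenario generators: a feature matrix, intrinsic factors,
#' the ground-truth edge supports, and the generating precision matrices
#' where applicable.
#'
#' @slot Y n x p feature matrix.
#' @slot X n x q intrinsic-factor matrix.
#' @slot factorKinds per-factor kind tags.
#' @slot truth list of logical p x p support matrices (one per group for the
#'   multi-category scenario, a single shared support otherwise; strictly
#'   lower-triangular in the DAG scenario).
#' @slot precisions list of generating precision matrices (empty for the
#'   DAG scenario, which is generated sequentially).
#' @slot beta p x p x q coefficient array for scenarios defined through
#'   covariate coefficients (continuous, DAG); otherwise an empty array.
#' @slot scenario scenario tag.
#' @slot seed seed the dataset was generated from.
#' @slot params generator parameters.
#'
#' @exportClass SimulatedGraphData
setClass("SimulatedGraphData",
  representation(Y = "matrix", X = "matrix", factorKinds = "character",
                 truth = "list", precisions = "list", beta = "array",
                 scenario = "character", seed = "integer", params = "list"))

setValidity("SimulatedGraphData", function(object) {
  msg <- character()
  if (nrow(object@Y) != nrow(object@X))
    msg <- c(msg, "Y and X must have the same number of samples")
  for (tr in object@truth) {
    if (!is.logical(tr) || nrow(tr) != ncol(object@Y))
      msg <- c(msg, "truth entries must be logical p x p matrices")
  }
  for (P in object@precisions) {
    if (max(abs(P - t(P))) > 1e-8) {
      msg <- c(msg, "stored precision matrices must be symmetric")
      break
    }
  }
  if (length(msg)) msg else TRUE
})
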