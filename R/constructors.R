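#' Create hyperparameters for graphical regression
#'
#' Defaults follow the recommended analysis settings: a diffuse
#' Gamma(0.005, 0.005) prior on the slab precisions and a Beta(1, 4) prior
#' on the inclusion weights (prior inclusion probability 0.2).  For
#' pathway-focused analyses that expect dense within-set connectivity a
#' Beta(0.05, 0.05) prior (\code{aPi = bPi = 0.05}) is the conventional
#' alternative.
#'
#' @param aTau,bTau Gamma shape and rate for the slab precisions.
#' @param aPi,bPi Beta shapes for the inclusion weights.
#' @param elboTol relative ELBO tolerance for convergence.
#' @param maxIter maximum number of CAVI sweeps.
#' @param seed optional integer seed recorded with the fit (the fit itself
#'   is deterministic).
#' @return A [GraphRegHyper-class] object.
#' @examples
#' graphRegHyper()
#' graphRegHyper(aPi = 0.05, bPi = 0.05)
#' @export
graphRegHyper <- function(aTau = 0.005, bTau = 0.005, aPi = 1, bPi = 4,
                        elboTol = 1e-4, maxIter = 1000L,
                        seed = NA_integer_) {
  new("GraphRegHyper", aTau = aTau, bTau = bTau, aPi = aPi, bPi = bPi,
      elboTol = elboTol, maxIter = as.integer(maxIter),
      seed = as.integer(seed))
}

#' Create an intrinsic-factor matrix
#'
#' Wraps an n x q covariate matrix together with per-column kind tags.
#' When \code{kinds} is omitted, each column is tagged automatically:
#' constant columns become \code{"intercept"}, \{0, 1\}-valued columns
#' become \code{"indicator"}, everything else \code{"continuous"}.
#'
#' No intercept column is ever added implicitly: the factor matrix is used
#' exactly as supplied, so group-indicator designs without a separate
#' intercept are expressed directly.
#'
#' @param values numeric matrix (or vector, treated as a single column).
#' @param kinds optional character vector of per-column kinds.
#' @return An [IntrinsicFactors-class] object.
#' @examples
#' intrinsicFactors(cbind(int = 1, grp = rep(0:1, 5)))
#' @export
intrinsicFactors <- function(values, kinds = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values)))
    colnames(values) <- paste0("X", seq_len(ncol(values)))
  if (is.null(kinds)) {
    kinds <- apply(values, 2, function(col) {
      if (all(col == col[1])) "intercept"
      else if (all(col %in% c(0, 1))) "indicator"
      else "continuous"
    })
  }
  new("IntrinsicFactors", values = values, kinds = unname(kinds))
}

#' @describeIn intrinsicFactors number of factor columns
#' @param x an \code{IntrinsicFactors} object.
#' @export
factorKinds <- function(x) {
  stopifnot(is(x, "IntrinsicFactors") || is(x, "GraphRegFit") ||
            is(x, "SimulatedGraphData"))
  if (is(x, "IntrinsicFactors")) x@kinds else x@factorKinds
}

.factorValues <- function(X) {
  if (is(X, "IntrinsicFactors")) X@values else as.matrix(X)
}

#' Accessors for fitted graphical regression models
#'
#' @param x a [GraphRegFit-class] object.
#' @return \code{nodePosteriors} returns the list of per-node variational
#'   posteriors; \code{fitMode} the \code{"undirected"}/\code{"dag"} flag;
#'   \code{hyperParams} the hyperparameters used.
#' @name fit-accessors
NULL

#' @rdname fit-accessors
#' @export
nodePosteriors <- function(x) { stopifnot(is(x, "GraphRegFit")); x@nodes }

#' @rdname fit-accessors
#' @export
fitMode <- function(x) { stopifnot(is(x, "GraphRegFit")); x@mode }

#' @rdname fit-accessors
#' @export
hyperParams <- function(x) { stopifnot(is(x, "GraphRegFit")); x@hyper }

#' Accessors for edge tables
#'
#' @param x an [EdgeTable-class] object.
#' @return \code{edgeRecords} returns the per (pair, covariate) data.frame;
#'   \code{fdrThreshold} the realized PIP cutoff.
#' @name edge-accessors
NULL

#' @rdname edge-accessors
#' @export
edgeRecords <- function(x) { stopifnot(is(x, "EdgeTable")); x@edges }

#' @rdname edge-accessors
#' @export
fdrThreshold <- function(x) { stopifnot(is(x, "EdgeTable")); x@threshold }

#' Accessors for simulated datasets
#'
#' @param x a [SimulatedGraphData-class] object.
#' @name sim-accessors
#' @return \code{simFeatures} the n x p feature matrix; \code{simFactors}
#'   the intrinsic factors as an [IntrinsicFactors-class] object;
#'   \code{simTruth} the list of ground-truth supports; \code{simPrecisions}
#'   the generating precision matrices; \code{simBeta} the coefficient
#'   array (where the scenario defines one).
NULL

#' @rdname sim-accessors
#' @export
simFeatures <- function(x) { stopifnot(is(x, "SimulatedGraphData")); x@Y }

#' @rdname sim-accessors
#' @export
simFactors <- function(x) {
  stopifnot(is(x, "SimulatedGraphData"))
  intrinsicFactors(x@X, x@factorKinds)
}

#' @rdname sim-accessors
#' @export
simTruth <- function(x) { stopifnot(is(x, "SimulatedGraphData")); x@truth }

#' @rdname sim-accessors
#' @export
simPrecisions <- function(x) {
  stopifnot(is(x, "SimulatedGraphData")); x@precisions
}

#' @rdname sim-accessors
#' @export
simBeta <- function(x) { stopifnot(is(x, "SimulatedGraphData")); x@beta }

setMethod("show", "GraphRegHyper", function(object) {
  cat("GraphRegHyper: aTau =", object@aTau, "bTau =", object@bTau,
      "aPi =", object@aPi, "bPi =", object@bPi, "\n")
  cat("  elboTol =", object@elboTol, " maxIter =", object@maxIter, "\n")
})

setMethod("show", "IntrinsicFactors", function(object) {
  cat("IntrinsicFactors:", nrow(object@values), "samples x",
      ncol(object@values), "factors\n")
  cat("  kinds:", paste(object@kinds, collapse = ", "), "\n")
})

setMethod("show", "NodePosterior", function(object) {
  cat("NodePosterior for node", object@node, "with",
      length(object@alpha), "coefficients\n")
  cat("  converged:", object@converged, "after", length(object@elbo),
      "sweeps; final ELBO:",
      if (length(object@elbo)) format(utils::tail(object@elbo, 1)) else "NA",
      "\n")
})

setMethod("show", "GraphRegFit", function(object) {
  cat("GraphRegFit (", object@mode, "): ", length(object@featureNames),
      " nodes, ", length(object@factorNames), " intrinsic factors, n = ",
      object@n, "\n", sep = "")
  conv <- vapply(object@nodes, function(nd) nd@converged, logical(1))
  cat("  converged node fits:", sum(conv), "/", length(conv), "\n")
})

setMethod("show", "EdgeTable", function(object) {
  cat("EdgeTable (", object@mode, "): ", nrow(object@edges),
      " records over ", nrow(object@covariates),
      " evaluation covariate(s)\n", sep = "")
  cat("  FDR level ", object@fdrLevel, "; selected: ",
      sum(object@edges$selected), "; PIP threshold: ",
      format(object@threshold), "\n", sep = "")
})

setMethod("show", "SimulatedGraphData", function(object) {
  cat("SimulatedGraphData [", object@scenario, "]: ",
      nrow(object@Y), " x ", ncol(object@Y), " features, ",
      ncol(object@X), " factor(s), seed ", object@seed, "\n", sep = "")
})
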