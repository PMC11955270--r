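#' Fit a covariate-dependent Gaussian graphical model
#'
#' Runs the node-wise spike-and-slab variational regressions: every node
#' is regressed on covariate-modulated versions of the other nodes
#' (\code{"undirected"}) or of its predecessors under the column ordering
#' of \code{Y} (\code{"dag"}).  Feature columns are standardized to mean 0
#' and unit sample variance once, and the centers/scales are recorded in
#' the fit.  The intrinsic-factor matrix is used exactly as supplied; no
#' intercept is added implicitly.
#'
#' The p node fits are independent, so results do not depend on the order
#' in which nodes are processed.
#'
#' @param Y n x p numeric feature matrix (n >= 3, p >= 2).
#' @param X intrinsic factors: an [IntrinsicFactors-class] or an n x q
#'   matrix (kinds are then auto-detected).
#' @param hyper a [GraphRegHyper-class]; see [graphRegHyper()] for defaults.
#' @param mode \code{"undirected"} or \code{"dag"}.
#' @return A [GraphRegFit-class] object.
#' @examples
#' sim <- simulateHomogeneous(n = 60, p = 8, connProb = 0.1, seed = 1)
#' fit <- fitGraphReg(simFeatures(sim), simFactors(sim))
#' fit
#' @export
fitGraphReg <- function(Y, X, hyper = graphRegHyper(),
                      mode = c("undirected", "dag")) {
  mode <- match.arg(mode)
  Y <- as.matrix(Y)
  if (anyNA(Y))
    stop("Y contains missing values; only complete cases are supported")
  if (nrow(Y) < 3) stop("at least 3 samples are required")
  if (ncol(Y) < 2) stop("at least 2 features are required")
  if (!is(X, "IntrinsicFactors")) X <- intrinsicFactors(X)
  Xv <- X@values
  if (nrow(Xv) != nrow(Y))
    stop("Y and X must have the same number of samples")
  featureNames <- colnames(Y)
  if (is.null(featureNames)) featureNames <- paste0("V", seq_len(ncol(Y)))

  std <- standardizeColumns(Y)
  p <- ncol(Y)
  nodes <- vector("list", p)
  for (i in seq_len(p)) {
    d <- buildNodeDesign(std$values, Xv, i, mode)
    nodes[[i]] <- tryCatch(fitNode(d, hyper),
                           error = function(e)
                             stop("node ", featureNames[i], " (", i, "): ",
                                  conditionMessage(e), call. = FALSE))
  }
  new("GraphRegFit", nodes = nodes, mode = mode, hyper = hyper,
      featureNames = featureNames, factorNames = colnames(Xv),
      factorKinds = X@kinds, yCenter = unname(std$center),
      yScale = unname(std$scale), n = nrow(Y))
}
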