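#' Build the regression design for one node
#'
#' For node i, the response is column i of \code{Y} and the regressors are
#' the element-wise products \eqn{X_l \odot Y_j} for every other node j and
#' every intrinsic factor l, in node-major, factor-minor order.  In
#' \code{"dag"} mode only predecessors (j < i under the column ordering of
#' \code{Y}) are used; node 1 yields a valid zero-regressor design.
#'
#' \code{Y} is used as supplied — standardize first (as [fitGraphReg()] does)
#' when fitting the model.
#'
#' @param Y n x p feature matrix.
#' @param X intrinsic factors: an [IntrinsicFactors-class] object or an
#'   n x q matrix.
#' @param node response-node index in 1..p.
#' @param mode \code{"undirected"} or \code{"dag"}.
#' @return A [NodeDesign-class] object with m = (p - 1) q (undirected) or
#'   (node - 1) q (dag) columns.
#' @examples
#' Y <- matrix(rnorm(30), 10, 3)
#' buildNodeDesign(Y, matrix(1, 10, 1), node = 1)
#' @export
buildNodeDesign <- function(Y, X, node, mode = c("undirected", "dag")) {
  mode <- match.arg(mode)
  Y <- as.matrix(Y)
  Xv <- .factorValues(X)
  p <- ncol(Y)
  q <- ncol(Xv)
  if (nrow(Y) != nrow(Xv))
    stop("Y and X must have the same number of samples")
  if (length(node) != 1 || node < 1 || node > p)
    stop("'node' must lie in 1..p")
  node <- as.integer(node)
  regs <- if (mode == "undirected") setdiff(seq_len(p), node)
          else seq_len(node - 1L)
  m <- length(regs) * q
  Z <- matrix(0, nrow(Y), m)
  col <- 0L
  for (j in regs)
    for (l in seq_len(q)) {
      col <- col + 1L
      Z[, col] <- Xv[, l] * Y[, j]
    }
  im <- if (m > 0)
    data.frame(node = rep(as.integer(regs), each = q),
               factor = rep(seq_len(q), times = length(regs)))
  else data.frame(node = integer(), factor = integer())
  new("NodeDesign", response = as.numeric(Y[, node]), design = Z,
      indexMap = im, node = node, mode = mode)
}
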