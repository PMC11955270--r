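# Downstream network summaries: hub detection, pathway connectivity,
# region-weighted spatial summaries.

.resolveNodes <- function(x, nodes) {
  if (is.character(nodes)) {
    idx <- match(nodes, x@featureNames)
    if (anyNA(idx)) stop("unknown node(s): ",
                         paste(nodes[is.na(idx)], collapse = ", "))
    idx
  } else {
    if (any(nodes < 1 | nodes > length(x@featureNames)))
      stop("unknown node index")
    as.integer(nodes)
  }
}

#' Connectivity degree of a node
#'
#' Sum of the magnitudes (absolute partial correlations) of the selected
#' edges incident to the node, the usual hub-detection statistic.
#'
#' @param x an [EdgeTable-class].
#' @param nodes node names or indices (default: all nodes).
#' @param covariate restrict to one covariate id (default: computed per
#'   covariate).
#' @return A nodes x covariates matrix of degrees (dropped to a vector for
#'   a single covariate).
#' @export
connectivityDegree <- function(x, nodes = NULL, covariate = NULL) {
  stopifnot(is(x, "EdgeTable"))
  e <- x@edges
  if (!is.null(covariate)) e <- e[e$covariate %in% covariate, , drop = FALSE]
  p <- length(x@featureNames)
  if (is.null(nodes)) nodes <- seq_len(p)
  idx <- .resolveNodes(x, nodes)
  covs <- unique(e$covariate)
  sel <- e[e$selected, , drop = FALSE]
  out <- matrix(0, length(idx), length(covs),
                dimnames = list(x@featureNames[idx], as.character(covs)))
  for (ci in seq_along(covs)) {
    ec <- sel[sel$covariate == covs[ci], , drop = FALSE]
    for (ni in seq_along(idx)) {
      inc <- ec$i == idx[ni] | ec$j == idx[ni]
      out[ni, ci] <- sum(abs(ec$pcor[inc]))
    }
  }
  drop(out)
}

#' Pathway connectivity score
#'
#' Ratio of the number of selected edges between pathway members to the
#' number of possible member pairs, in \[0, 1\].
#'
#' @param x an [EdgeTable-class].
#' @param members pathway member names or indices (at least 2).
#' @param covariate restrict to one covariate id.
#' @return Connectivity score(s), one per covariate.
#' @export
connectivityScore <- function(x, members, covariate = NULL) {
  stopifnot(is(x, "EdgeTable"))
  idx <- .resolveNodes(x, members)
  if (length(unique(idx)) < 2)
    stop("a pathway needs at least 2 members")
  e <- x@edges
  if (!is.null(covariate)) e <- e[e$covariate %in% covariate, , drop = FALSE]
  covs <- unique(e$covariate)
  total <- choose(length(unique(idx)), 2)
  out <- vapply(covs, function(cv) {
    ec <- e[e$selected & e$covariate == cv, , drop = FALSE]
    sum(ec$i %in% idx & ec$j %in% idx) / total
  }, numeric(1))
  names(out) <- as.character(covs)
  if (length(out) == 1) unname(out) else out
}

.regionOf <- function(x, regions) {
  covs <- unique(x@edges$covariate)
  if (is.null(names(regions)))
    stop("'regions' must be named by covariate (sample) id")
  miss <- setdiff(names(regions), as.character(covs))
  if (length(miss))
    stop("labeled sample(s) missing from the edge table: ",
         paste(miss, collapse = ", "))
  regions
}

#' Region-weighted partial correlation of a gene pair
#'
#' For spatial (per-sample) networks, the region summary of an edge is
#' \deqn{\hat\rho_{ij}^{region} = \sum_{s \in region} \rho_{ij}(s)
#'   PIP_{ij}(s) / n_{region},}
#' the PIP-weighted average of the per-sample partial correlations over
#' the samples of the region.
#'
#' @param x an [EdgeTable-class] with per-sample covariates.
#' @param regions named character vector: sample (covariate id) -> region.
#' @param i,j node names or indices of the pair.
#' @return Named numeric vector, one value per region.
#' @export
regionWeightedPartialCor <- function(x, regions, i, j) {
  stopifnot(is(x, "EdgeTable"))
  regions <- .regionOf(x, regions)
  ij <- sort(.resolveNodes(x, c(i, j)))
  e <- x@edges
  e <- e[e$i == ij[1] & e$j == ij[2], , drop = FALSE]
  e <- e[as.character(e$covariate) %in% names(regions), , drop = FALSE]
  lab <- regions[as.character(e$covariate)]
  if (!nrow(e)) stop("empty region")
  w <- e$pcor * e$pip
  out <- tapply(w, lab, sum) / tapply(w, lab, length)
  out <- as.numeric(out[unique(lab)])
  names(out) <- unique(lab)
  out
}

#' Region-weighted connectivity degree
#'
#' For each region, the weighted connectivity degree of node i is
#' \eqn{\sum_j |\hat\rho_{ij}^{region}|}, the sum over partners of the
#' magnitudes of the region-weighted partial correlations.  The rescaled
#' variant divides every degree by the maximum across nodes within the
#' region (all-zero degrees are returned as zeros).
#'
#' @param x an [EdgeTable-class] with per-sample covariates.
#' @param regions named character vector: sample id -> region.
#' @param nodes node names or indices (default: all).
#' @param rescale also return degrees rescaled to a maximum of 1.
#' @return A list with \code{degree} (nodes x regions matrix) and, when
#'   \code{rescale}, \code{rescaled}.
#' @export
weightedConnectivityDegree <- function(x, regions, nodes = NULL,
                                       rescale = TRUE) {
  stopifnot(is(x, "EdgeTable"))
  regions <- .regionOf(x, regions)
  p <- length(x@featureNames)
  allIdx <- seq_len(p)
  e <- x@edges
  e <- e[as.character(e$covariate) %in% names(regions), , drop = FALSE]
  lab <- regions[as.character(e$covariate)]
  regs <- unique(regions)
  deg <- matrix(0, p, length(regs),
                dimnames = list(x@featureNames, regs))
  nReg <- table(factor(regions, levels = regs))   # samples per region
  w <- e$pcor * e$pip
  key <- paste(e$i, e$j, lab, sep = "\r")
  sums <- tapply(w, key, sum)
  parts <- strsplit(names(sums), "\r")
  ii <- as.integer(vapply(parts, `[`, character(1), 1))
  jj <- as.integer(vapply(parts, `[`, character(1), 2))
  rr <- vapply(parts, `[`, character(1), 3)
  rho <- abs(sums / as.numeric(nReg[rr]))
  for (k in seq_along(rho)) {
    deg[ii[k], rr[k]] <- deg[ii[k], rr[k]] + rho[k]
    deg[jj[k], rr[k]] <- deg[jj[k], rr[k]] + rho[k]
  }
  out <- list(degree = deg)
  if (rescale) {
    mx <- apply(deg, 2, max)                      # max across all nodes
    out$rescaled <- sweep(deg, 2, ifelse(mx > 0, mx, 1), "/")
  }
  if (!is.null(nodes)) {
    keep <- .resolveNodes(x, nodes)
    out <- lapply(out, function(mm) mm[keep, , drop = FALSE])
  }
  out
}
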