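#' Standardize matrix columns
#'
#' Centers and scales every non-exempt column to mean 0 and unit sample
#' variance (the n - 1 denominator convention, fixed so that refits are
#' bit-reproducible).  Intercept-like columns listed in
#' \code{interceptCols} are passed through unchanged with center 0 and
#' scale 1 recorded.
#'
#' @param x numeric matrix.
#' @param interceptCols integer indices of columns to exempt.
#' @return A list with \code{values} (the standardized matrix),
#'   \code{center} and \code{scale} (per-column, recorded for
#'   back-transformation).
#' @examples
#' standardizeColumns(cbind(a = c(1, 2, 3)))
#' @export
standardizeColumns <- function(x, interceptCols = integer()) {
  x <- as.matrix(x)
  if (anyNA(x))
    stop("matrix contains missing values; only complete cases are supported")
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  cols <- colnames(x)
  if (is.null(cols)) cols <- paste0("V", seq_len(ncol(x)))
  exempt <- seq_len(ncol(x)) %in% interceptCols
  bad <- which(!exempt & (!is.finite(scl) | scl <= 0))
  if (length(bad))
    stop("degenerate input: zero-variance column(s) ",
         paste(cols[bad], collapse = ", "))
  ctr[exempt] <- 0
  scl[exempt] <- 1
  out <- sweep(sweep(x, 2, ctr, "-"), 2, scl, "/")
  list(values = out, center = ctr, scale = scl)
}
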