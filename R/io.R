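# Delimited-table, JSON and YAML input/output.  Tables are comma- or
# tab-delimited (auto-detected), header row = names, first column =
# sample ids.  Numbers are serialized at full precision.

.detectSep <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("\t", first)) "\t" else ","
}

.readTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = .detectSep(path),
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("table must have a sample-id column plus data")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m))
    stop("missing values in ", path,
         "; only complete cases are supported")
  rownames(m) <- ids
  m
}

#' Read a feature (expression) table
#'
#' Delimited text (comma or tab, auto-detected) with a header row of
#' feature names and sample ids in the first column.  Missing values are
#' an error: only complete cases are supported.
#'
#' @param path file path.
#' @return Numeric matrix with sample-id rownames.
#' @export
readFeatureTable <- function(path) .readTable(path)

#' Read an intrinsic-factor table
#'
#' Same format as [readFeatureTable()].  Column kinds are auto-detected
#' unless supplied.
#'
#' @param path file path.
#' @param kinds optional per-column kinds.
#' @return An [IntrinsicFactors-class]; sample ids are kept as rownames of
#'   its values.
#' @export
readFactorTable <- function(path, kinds = NULL) {
  m <- .readTable(path)
  intrinsicFactors(m, kinds)
}

#' Align a factor table to a feature table by sample id
#'
#' Reorders the factor rows to the feature order; a mismatch in the id
#' sets is an error that names the offending samples.
#'
#' @param Y feature matrix with sample-id rownames.
#' @param X an [IntrinsicFactors-class] with sample-id rownames.
#' @return The reordered [IntrinsicFactors-class].
#' @export
alignSamples <- function(Y, X) {
  stopifnot(is(X, "IntrinsicFactors"))
  yIds <- rownames(Y)
  xIds <- rownames(X@values)
  if (is.null(yIds) || is.null(xIds))
    stop("both tables need sample ids")
  onlyY <- setdiff(yIds, xIds)
  onlyX <- setdiff(xIds, yIds)
  if (length(onlyY) || length(onlyX))
    stop("sample ids do not match; only in features: [",
         paste(onlyY, collapse = ", "), "]; only in factors: [",
         paste(onlyX, collapse = ", "), "]")
  intrinsicFactors(X@values[match(yIds, xIds), , drop = FALSE], X@kinds)
}

#' Write a matrix as a delimited table
#'
#' @param m matrix with sample-id rownames.
#' @param path output path; the extension picks the delimiter
#'   (\code{.tsv} = tab, otherwise comma).
#' @param idColumn name of the sample-id column.
#' @return \code{path}, invisibly.
#' @export
writeMatrixTable <- function(m, path, idColumn = "sample") {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  ids <- rownames(m)
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(m)))
  df <- data.frame(ids, m, check.names = FALSE)
  names(df)[1] <- idColumn
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pathway membership map
#'
#' Two-column delimited file (pathway, member).  Pathways with fewer than
#' 2 members are rejected.
#'
#' @param path file path.
#' @return Named list: pathway -> character vector of members.
#' @export
readPathwayMap <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = .detectSep(path),
                          stringsAsFactors = FALSE)
  if (ncol(df) != 2) stop("pathway map must have exactly 2 columns")
  pw <- split(as.character(df[[2]]), df[[1]])
  small <- names(pw)[vapply(pw, function(x) length(unique(x)), 0L) < 2]
  if (length(small))
    stop("pathway(s) with fewer than 2 members: ",
         paste(small, collapse = ", "))
  pw
}

#' Read region labels
#'
#' Two-column delimited file (sample, region).
#'
#' @param path file path.
#' @return Named character vector: sample id -> region.
#' @export
readRegionLabels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = .detectSep(path),
                          stringsAsFactors = FALSE)
  if (ncol(df) != 2) stop("region labels must have exactly 2 columns")
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Write / read an edge table
#'
#' The records are written as a tab-delimited file with columns \code{i},
#' \code{j}, \code{covariate}, \code{pip}, \code{partial_correlation},
#' \code{selected}, and the selection metadata (FDR level, realized
#' threshold, mode, node labels, covariates) as a JSON sidecar at
#' \code{paste0(path, ".json")}.  The round trip is lossless at 15
#' significant digits.
#'
#' @param x an [EdgeTable-class].
#' @param path output path for the delimited records.
#' @return \code{writeEdgeTable}: \code{path}, invisibly;
#'   \code{readEdgeTable}: the reconstructed [EdgeTable-class].
#' @export
writeEdgeTable <- function(x, path) {
  stopifnot(is(x, "EdgeTable"))
  e <- x@edges
  names(e)[names(e) == "pcor"] <- "partial_correlation"
  utils::write.table(format(e, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(schema_version = 1L, fdr_level = x@fdrLevel, mode = x@mode,
               threshold = x@threshold, feature_names = x@featureNames,
               covariates = x@covariates)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeEdgeTable
#' @export
readEdgeTable <- function(path) {
  e <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  names(e)[names(e) == "partial_correlation"] <- "pcor"
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new("EdgeTable", edges = e, fdrLevel = meta$fdr_level, mode = meta$mode,
      threshold = if (is.null(meta$threshold)) NA_real_
                  else as.numeric(meta$threshold),
      covariates = as.matrix(meta$covariates),
      featureNames = as.character(meta$feature_names))
}

#' Write / read a fitted model as JSON
#'
#' Serializes the complete fit (mode, hyperparameters, standardization,
#' per-node variational posteriors with ELBO traces) to a versioned JSON
#' container, losslessly at full double precision.
#'
#' @param fit a [GraphRegFit-class].
#' @param path output path.
#' @return \code{writeGraphRegFit}: \code{path}, invisibly;
#'   \code{readGraphRegFit}: the reconstructed [GraphRegFit-class].
#' @export
writeGraphRegFit <- function(fit, path) {
  stopifnot(is(fit, "GraphRegFit"))
  nodeJson <- lapply(fit@nodes, function(nd) list(
    node = nd@node, alpha = nd@alpha, mu = nd@mu, sigma2 = nd@sigma2,
    tau_shape = nd@tauShape, tau_rate = nd@tauRate,
    pi_a = nd@piA, pi_b = nd@piB,
    omega_shape = nd@omegaShape, omega_rate = nd@omegaRate,
    elbo = nd@elbo, converged = nd@converged,
    map_node = nd@indexMap$node, map_factor = nd@indexMap$factor))
  hy <- fit@hyper
  obj <- list(schema_version = 1L, mode = fit@mode,
              hyper = list(a_tau = hy@aTau, b_tau = hy@bTau, a_pi = hy@aPi,
                           b_pi = hy@bPi, elbo_tol = hy@elboTol,
                           max_iter = hy@maxIter, seed = hy@seed),
              feature_names = fit@featureNames,
              factor_names = fit@factorNames,
              factor_kinds = fit@factorKinds,
              y_center = fit@yCenter, y_scale = fit@yScale, n = fit@n,
              nodes = nodeJson)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname writeGraphRegFit
#' @export
readGraphRegFit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version) || obj$schema_version != 1L)
    stop("unsupported fit schema version")
  hy <- graphRegHyper(aTau = obj$hyper$a_tau, bTau = obj$hyper$b_tau,
                    aPi = obj$hyper$a_pi, bPi = obj$hyper$b_pi,
                    elboTol = obj$hyper$elbo_tol,
                    maxIter = obj$hyper$max_iter,
                    seed = if (is.null(obj$hyper$seed)) NA_integer_
                           else obj$hyper$seed)
  nodes <- lapply(seq_len(nrow(obj$nodes)), function(i) {
    nd <- obj$nodes[i, ]
    unl <- function(v) as.numeric(unlist(v))
    new("NodePosterior",
        alpha = unl(nd$alpha), mu = unl(nd$mu), sigma2 = unl(nd$sigma2),
        tauShape = unl(nd$tau_shape), tauRate = unl(nd$tau_rate),
        piA = unl(nd$pi_a), piB = unl(nd$pi_b),
        omegaShape = nd$omega_shape, omegaRate = nd$omega_rate,
        elbo = unl(nd$elbo), converged = nd$converged,
        indexMap = data.frame(node = as.integer(unlist(nd$map_node)),
                              factor = as.integer(unlist(nd$map_factor))),
        node = as.integer(nd$node))
  })
  new("GraphRegFit", nodes = nodes, mode = obj$mode, hyper = hy,
      featureNames = as.character(obj$feature_names),
      factorNames = as.character(obj$factor_names),
      factorKinds = as.character(obj$factor_kinds),
      yCenter = as.numeric(obj$y_center),
      yScale = as.numeric(obj$y_scale), n = as.integer(obj$n))
}

#' Write / read a simulated dataset
#'
#' Writes the features and factors as delimited tables
#' (\code{<prefix>_features.csv}, \code{<prefix>_factors.csv}) and the
#' ground truth — supports, coefficient array, scenario parameters and
#' seed — as \code{<prefix>_truth.json}.
#'
#' @param sim a [SimulatedGraphData-class].
#' @param prefix path prefix for the three files.
#' @return \code{writeSimulatedData}: \code{prefix}, invisibly;
#'   \code{readSimulatedData}: the reconstructed
#'   [SimulatedGraphData-class] (generating precisions are not
#'   serialized).
#' @export
writeSimulatedData <- function(sim, prefix) {
  stopifnot(is(sim, "SimulatedGraphData"))
  rownames(sim@Y) <- rownames(sim@X) <- paste0("s", seq_len(nrow(sim@Y)))
  writeMatrixTable(sim@Y, paste0(prefix, "_features.csv"))
  writeMatrixTable(sim@X, paste0(prefix, "_factors.csv"))
  truth <- list(schema_version = 1L, scenario = sim@scenario,
                seed = sim@seed, factor_kinds = sim@factorKinds,
                supports = lapply(sim@truth, function(tr) {
                  idx <- which(tr, arr.ind = TRUE)
                  list(i = as.integer(idx[, 1]), j = as.integer(idx[, 2]))
                }),
                p = ncol(sim@Y),
                beta = if (length(sim@beta)) as.numeric(sim@beta) else NULL,
                beta_dim = if (length(sim@beta)) dim(sim@beta) else NULL,
                params = sim@params[!vapply(sim@params, is.matrix,
                                            logical(1))])
  jsonlite::write_json(truth, paste0(prefix, "_truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(prefix)
}

#' @rdname writeSimulatedData
#' @export
readSimulatedData <- function(prefix) {
  Y <- readFeatureTable(paste0(prefix, "_features.csv"))
  X <- .readTable(paste0(prefix, "_factors.csv"))
  tr <- jsonlite::read_json(paste0(prefix, "_truth.json"),
                            simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  p <- tr$p
  supports <- lapply(tr$supports, function(s) {
    m <- matrix(FALSE, p, p)
    if (length(s$i)) m[cbind(s$i, s$j)] <- TRUE
    m
  })
  beta <- if (length(tr$beta)) array(as.numeric(unlist(tr$beta)),
                                     as.integer(unlist(tr$beta_dim)))
          else array(numeric(), c(0, 0, 0))
  new("SimulatedGraphData", Y = Y, X = X,
      factorKinds = as.character(tr$factor_kinds), truth = supports,
      precisions = list(), beta = beta, scenario = tr$scenario,
      seed = as.integer(tr$seed), params = as.list(tr$params))
}

# ---- run configuration --------------------------------------------------

.configDefaults <- function() {
  list(features = NULL, factors = NULL, pathways = NULL, regions = NULL,
       mode = "undirected", a_tau = 0.005, b_tau = 0.005,
       a_pi = 1, b_pi = 4, elbo_tol = 1e-4, max_iter = 1000,
       fdr_level = 0.01, scenario = "homogeneous", reps = 50,
       seed = 1, out_dir = ".", log_level = "info")
}

#' Assemble a run configuration
#'
#' Precedence: explicit \code{overrides} > YAML file > defaults.  The
#' defaults carry the recommended hyperparameters (aTau = bTau = 0.005,
#' aPi = 1, bPi = 4) and FDR level 0.01.
#'
#' @param path optional YAML file.
#' @param overrides named list of explicit settings (e.g. parsed command
#'   flags).
#' @return Named list of settings, validated.
#' @export
readRunConfig <- function(path = NULL, overrides = list()) {
  cfg <- .configDefaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    fromFile <- yaml::read_yaml(path)
    unknown <- setdiff(names(fromFile), names(cfg))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg[names(fromFile)] <- fromFile
  }
  overrides <- overrides[!vapply(overrides, is.null, logical(1))]
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown))
    stop("unknown option(s): ", paste(unknown, collapse = ", "))
  cfg[names(overrides)] <- overrides
  if (cfg$fdr_level <= 0 || cfg$fdr_level >= 1)
    stop("fdr_level must lie in (0, 1)")
  if (!cfg$mode %in% c("undirected", "dag"))
    stop("mode must be 'undirected' or 'dag'")
  for (f in c("features", "factors", "pathways", "regions"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("referenced input file does not exist: ", cfg[[f]])
  cfg
}

#' @rdname readRunConfig
#' @param cfg a configuration list.
#' @return \code{hyperFromConfig}: the corresponding [GraphRegHyper-class].
#' @export
hyperFromConfig <- function(cfg) {
  graphRegHyper(aTau = cfg$a_tau, bTau = cfg$b_tau, aPi = cfg$a_pi,
              bPi = cfg$b_pi, elboTol = cfg$elbo_tol,
              maxIter = cfg$max_iter, seed = cfg$seed)
}
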