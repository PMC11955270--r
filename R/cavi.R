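# Coordinate-ascent mean-field variational inference for one node
# regression under the spike-and-slab model
#
#   y | b, s, omega ~ N(Z (b * s), omega^{-1} I)
#   b_k | tau_l(k)  ~ N(0, 1 / tau_l(k))
#   s_k | pi_k      ~ Bernoulli(pi_k)
#   pi_k ~ Beta(aPi, bPi),  tau_l ~ Gamma(aTau, bTau),  p(omega) propto 1
#
# with the structured factorization q(b, s) q(omega) q(pi) q(tau) and
# q(b_k | s_k = 0) fixed to the conditional prior, so the spike branch
# contributes nothing to the tau update and the per-coefficient update is
# the standard joint (b_k, s_k) form:
#   sigma2_k = 1 / (E[omega] z_k'z_k + E[tau])
#   mu_k     = sigma2_k E[omega] z_k' r_k             (partial residual r_k)
#   logit(alpha_k) = E[log pi/(1-pi)]
#                    + (E[log tau] + log sigma2_k) / 2 + mu_k^2 / (2 sigma2_k)

# Expectations under the current (or fixed) hyper-posterior factors.
# `fixed` may pin tau, omega and/or pi to known constants, which is used by
# the enumeration-oracle tests; the corresponding KL terms drop out of the
# (then conditional) ELBO.
.momentsOf <- function(post, hyper, fixed, lmap) {
  q <- length(post@tauShape)
  if (!is.null(fixed$tau)) {
    tau <- rep_len(fixed$tau, max(q, 1L))
    eTau <- tau
    elogTau <- log(tau)
  } else {
    eTau <- post@tauShape / post@tauRate
    elogTau <- digamma(post@tauShape) - log(post@tauRate)
  }
  if (!is.null(fixed$omega)) {
    eOmega <- fixed$omega
    elogOmega <- log(fixed$omega)
  } else {
    eOmega <- post@omegaShape / post@omegaRate
    elogOmega <- digamma(post@omegaShape) - log(post@omegaRate)
  }
  m <- length(post@alpha)
  if (!is.null(fixed$pi)) {
    elogPi <- rep(log(fixed$pi), m)
    elog1mPi <- rep(log1p(-fixed$pi), m)
  } else {
    elogPi <- digamma(post@piA) - digamma(post@piA + post@piB)
    elog1mPi <- digamma(post@piB) - digamma(post@piA + post@piB)
  }
  list(eTau = eTau, elogTau = elogTau, eOmega = eOmega,
       elogOmega = elogOmega, elogPi = elogPi, elog1mPi = elog1mPi,
       eTauCoef = if (m > 0) eTau[lmap] else numeric(),
       elogTauCoef = if (m > 0) elogTau[lmap] else numeric())
}

.freshPosterior <- function(design, hyper) {
  m <- ncol(design@design)
  q <- if (m > 0) max(design@indexMap$factor) else 0L
  n <- length(design@response)
  a0 <- hyper@aPi / (hyper@aPi + hyper@bPi)
  new("NodePosterior",
      alpha = rep(a0, m), mu = rep(0, m), sigma2 = rep(1, m),
      tauShape = rep(1, q), tauRate = rep(1, q),
      piA = rep(hyper@aPi, m), piB = rep(hyper@bPi, m),
      omegaShape = n / 2 + 1, omegaRate = n / 2 + 1,
      elbo = numeric(), converged = FALSE,
      indexMap = design@indexMap, node = design@node)
}

#' One CAVI sweep over a node posterior
#'
#' Performs a single full coordinate pass in fixed order: each
#' \eqn{(b_k, s_k)} pair jointly (in index-map order), then the slab
#' precisions \eqn{q(\tau_l)}, the inclusion weights \eqn{q(\pi_k)}, and the
#' noise precision \eqn{q(\omega)}.  Each block update is exact, so the
#' ELBO is non-decreasing from sweep to sweep.
#'
#' @param design a [NodeDesign-class].
#' @param post the current [NodePosterior-class] (e.g. from a previous
#'   sweep); internal initialization is used by [fitNode()].
#' @param hyper a [GraphRegHyper-class].
#' @param fixed optional list pinning \code{tau}, \code{omega} and/or
#'   \code{pi} to known constants (their updates are then skipped); used
#'   mainly for oracle comparisons.
#' @return The updated [NodePosterior-class].
#' @seealso [fitNode()], [computeELBO()]
#' @export
caviSweep <- function(design, post, hyper, fixed = NULL) {
  Z <- design@design
  y <- design@response
  n <- length(y)
  m <- ncol(Z)
  lmap <- design@indexMap$factor
  mom <- .momentsOf(post, hyper, fixed, lmap)

  if (m > 0) {
    ztz <- colSums(Z^2)
    resid <- y - as.numeric(Z %*% (post@alpha * post@mu))
    upd <- .caviCoefPass(Z, ztz, post@alpha, post@mu, post@sigma2, resid,
                         mom$eOmega, mom$eTauCoef, mom$elogTauCoef,
                         mom$elogPi - mom$elog1mPi)
    post@alpha <- upd$alpha
    post@mu <- upd$mu
    post@sigma2 <- upd$sigma2
    resid <- upd$resid

    if (is.null(fixed$tau) && length(post@tauShape)) {
      eb2 <- post@alpha * (post@mu^2 + post@sigma2)
      post@tauShape <- hyper@aTau +
        0.5 * as.numeric(tapply(post@alpha, lmap, sum))
      post@tauRate <- hyper@bTau + 0.5 * as.numeric(tapply(eb2, lmap, sum))
    }
    if (is.null(fixed$pi)) {
      post@piA <- hyper@aPi + post@alpha
      post@piB <- hyper@bPi + 1 - post@alpha
    }
    if (is.null(fixed$omega)) {
      sse <- sum(resid^2) +
        sum((post@alpha * (post@mu^2 + post@sigma2) -
             (post@alpha * post@mu)^2) * ztz)
      post@omegaShape <- n / 2 + 1
      post@omegaRate <- sse / 2
    }
  } else if (is.null(fixed$omega)) {
    post@omegaShape <- n / 2 + 1
    post@omegaRate <- sum(y^2) / 2
  }
  post
}

.xlogx <- function(x) ifelse(x > 0, x * log(x), 0)

#' Evidence lower bound of a node posterior
#'
#' Computes \eqn{E_q[\log p(\theta, y)] - E_q[\log q(\theta)]} for the
#' spike-and-slab node regression under the structured mean-field
#' factorization.  The flat (improper) prior on the noise precision
#' contributes no prior mass term, so the ELBO is defined up to the same
#' additive constant across sweeps and remains a valid monotone objective.
#'
#' @inheritParams caviSweep
#' @return A finite scalar.
#' @export
computeELBO <- function(design, post, hyper, fixed = NULL) {
  Z <- design@design
  y <- design@response
  n <- length(y)
  m <- ncol(Z)
  lmap <- design@indexMap$factor
  mom <- .momentsOf(post, hyper, fixed, lmap)

  if (m > 0) {
    ztz <- colSums(Z^2)
    resid <- y - as.numeric(Z %*% (post@alpha * post@mu))
    sse <- sum(resid^2) +
      sum((post@alpha * (post@mu^2 + post@sigma2) -
           (post@alpha * post@mu)^2) * ztz)
  } else {
    sse <- sum(y^2)
  }

  elbo <- 0.5 * n * (mom$elogOmega - log(2 * pi)) - 0.5 * mom$eOmega * sse

  if (m > 0) {
    a <- post@alpha
    # slab branch: prior-minus-entropy of q(b_k | s_k = 1); the spike
    # branch equals the conditional prior and cancels exactly
    elbo <- elbo + sum(a * (0.5 * mom$elogTauCoef -
                            0.5 * mom$eTauCoef * (post@mu^2 + post@sigma2) +
                            0.5 * log(post@sigma2) + 0.5))
    elbo <- elbo + sum(a * mom$elogPi + (1 - a) * mom$elog1mPi -
                       .xlogx(a) - .xlogx(1 - a))
    if (is.null(fixed$pi)) {
      elbo <- elbo + sum(lbeta(post@piA, post@piB) -
                         lbeta(hyper@aPi, hyper@bPi) +
                         (hyper@aPi - post@piA) * mom$elogPi +
                         (hyper@bPi - post@piB) * mom$elog1mPi)
    }
    if (is.null(fixed$tau) && length(post@tauShape)) {
      eTau <- post@tauShape / post@tauRate
      elogTau <- digamma(post@tauShape) - log(post@tauRate)
      elbo <- elbo + sum(hyper@aTau * log(hyper@bTau) - lgamma(hyper@aTau) -
                         (post@tauShape * log(post@tauRate) -
                          lgamma(post@tauShape)) +
                         (hyper@aTau - post@tauShape) * elogTau -
                         (hyper@bTau - post@tauRate) * eTau)
    }
  }

  if (is.null(fixed$omega)) {
    cc <- post@omegaShape
    dd <- post@omegaRate
    elbo <- elbo - (cc * log(dd) - lgamma(cc) +
                    (cc - 1) * mom$elogOmega - cc)
  }
  if (!is.finite(elbo)) stop("ELBO is not finite; invalid posterior state")
  elbo
}

#' Fit one node regression by CAVI
#'
#' Iterates [caviSweep()] from a deterministic initialization (inclusion
#' probabilities at the prior mean \code{aPi / (aPi + bPi)}, slab means 0,
#' slab precisions and noise precision at unit mean) until the relative
#' ELBO change falls below \code{elboTol} or \code{maxIter} sweeps have
#' run.  Non-convergence is reported through the \code{converged} flag,
#' not an error.  The fit is deterministic given its inputs.
#'
#' @inheritParams caviSweep
#' @return A converged (or capped) [NodePosterior-class] with the full
#'   ELBO trace.
#' @examples
#' Y <- matrix(rnorm(200), 50, 4)
#' d <- buildNodeDesign(Y, matrix(1, 50, 1), node = 1)
#' fitNode(d, graphRegHyper())
#' @export
fitNode <- function(design, hyper = graphRegHyper(), fixed = NULL) {
  post <- .freshPosterior(design, hyper)
  if (ncol(design@design) == 0) {
    post <- caviSweep(design, post, hyper, fixed)
    post@elbo <- computeELBO(design, post, hyper, fixed)
    post@converged <- TRUE
    return(post)
  }
  elbo <- numeric(hyper@maxIter)
  conv <- FALSE
  it <- 0L
  prev <- -Inf
  while (it < hyper@maxIter) {
    it <- it + 1L
    post <- caviSweep(design, post, hyper, fixed)
    elbo[it] <- computeELBO(design, post, hyper, fixed)
    if (it > 1 && abs(elbo[it] - prev) < hyper@elboTol * (abs(elbo[it]) + 1)) {
      conv <- TRUE
      break
    }
    prev <- elbo[it]
  }
  post@elbo <- elbo[seq_len(it)]
  post@converged <- conv
  post
}
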