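#' Adaptive-covariance MCMC
#'
#' Metropolis sampling with multivariate-normal proposals whose covariance
#' is adapted from the chain's running history (Haario-style adaptive
#' Metropolis with global acceptance-rate targeting). For an initial phase
#' of 200 iterations the proposal covariance is a fixed diagonal of
#' (1\% of each prior range)^2; afterwards the running empirical covariance
#' \eqn{\Sigma_t} and a global log-scale are updated every iteration with a
#' decaying learning rate, the scale steered towards an acceptance rate of
#' 0.25. The proposal is
#' \eqn{N(\theta,\; \eta_t \, s \, (\Sigma_t + 10^{-9} I))} with
#' \eqn{s = 2.38^2/d}. Out-of-support proposals (log-target \code{-Inf})
#' are rejected and counted in the acceptance rate. Given identical target,
#' starting point and seed the chain is bit-for-bit reproducible.
#'
#' @param target either a function returning the log-target density given a
#'   parameter vector, or a [FittingProblem-class] (whose log-posterior is
#'   then the target).
#' @param theta0 starting point; must have a finite log-target value.
#' @param numIters total number of iterations (> burn).
#' @param burn number of initial iterations discarded as burn-in (>= 0).
#' @param seed RNG seed.
#' @param lower,upper parameter bounds used to scale the initial proposal
#'   (and recorded in the result for identifiability diagnostics); required
#'   for a function target, taken from the prior box for a problem target.
#' @param ... passed through between methods.
#' @return A [PosteriorSample-class] holding the retained chain.
#' @examples
#' lt <- function(x) -sum(x^2) / 2        # standard 2-D Gaussian
#' s <- adaptiveMCMC(lt, c(0, 0), numIters = 2000, burn = 500, seed = 1,
#'                   lower = c(-10, -10), upper = c(10, 10))
#' colMeans(chain(s))
#' @export
setGeneric("adaptiveMCMC", function(target, theta0, numIters, burn, seed, ...)
  standardGeneric("adaptiveMCMC"))

#' @rdname adaptiveMCMC
#' @export
setMethod("adaptiveMCMC", "function",
  function(target, theta0, numIters, burn, seed, lower, upper, ...) {
    stopifnot(numIters > burn, burn >= 0,
              length(lower) == length(theta0),
              length(upper) == length(theta0), all(upper > lower))
    numIters <- as.integer(numIters); burn <- as.integer(burn)
    seed <- as.integer(seed)
    d <- length(theta0)
    theta <- as.numeric(theta0)
    lp <- target(theta)
    if (!is.finite(lp))
      stop("theta0 must have a finite log-target value", call. = FALSE)
    lp0 <- lp

    set.seed(seed)
    s <- 2.38^2 / d
    # per-coordinate characteristic scales: parameters spanning different
    # orders of magnitude (rate prefactors vs conductance) need proposals
    # proportional to their own size, not to the prior range, or the chain
    # crawls at the smallest parameter's scale and never mixes
    scale <- pmax(abs(theta), 1e-4 * (upper - lower))
    jitter <- 1e-9 * diag(scale^2, d)
    sigma0 <- diag((0.01 * scale)^2, d)
    adaptInit <- 200L
    mu <- theta
    Sigma <- sigma0
    logEta <- 0
    chainMat <- matrix(NA_real_, numIters, d)
    lps <- numeric(numIters)
    accepted <- 0L

    for (i in seq_len(numIters)) {
      S <- if (i <= adaptInit) s * (sigma0 + jitter)
           else exp(logEta) * s * (Sigma + jitter)
      R <- chol(S)
      prop <- theta + drop(stats::rnorm(d) %*% R)
      lpProp <- target(prop)
      acc <- is.finite(lpProp) && log(stats::runif(1)) < lpProp - lp
      if (acc) {
        theta <- prop; lp <- lpProp; accepted <- accepted + 1L
      }
      if (i > adaptInit) {
        g <- (i - adaptInit)^-0.6
        dev <- theta - mu
        mu <- mu + g * dev
        Sigma <- Sigma + g * (tcrossprod(theta - mu) - Sigma)
        logEta <- logEta + g * (as.numeric(acc) - 0.25)
      }
      chainMat[i, ] <- theta
      lps[i] <- lp
    }
    keep <- (burn + 1L):numIters
    if (!is.null(names(theta0))) colnames(chainMat) <- names(theta0)
    new("PosteriorSample",
        chain = chainMat[keep, , drop = FALSE], logPosteriors = lps[keep],
        acceptanceRate = accepted / numIters, seed = seed,
        arguments = list(numIters = numIters, burn = burn),
        theta0 = as.numeric(theta0), theta0LogPosterior = lp0,
        priorLower = as.numeric(lower), priorUpper = as.numeric(upper))
  })

#' @rdname adaptiveMCMC
#' @export
setMethod("adaptiveMCMC", "FittingProblem",
  function(target, theta0, numIters, burn, seed, ...) {
    problem <- target
    box <- priorBox(problem)
    res <- adaptiveMCMC(function(x) logPosterior(problem, x),
                        theta0 = as.numeric(theta0), numIters = numIters,
                        burn = burn, seed = seed,
                        lower = box$lower, upper = box$upper, ...)
    colnames(res@chain) <- problem@freeNames
    names(res@theta0) <- problem@freeNames
    names(res@priorLower) <- names(res@priorUpper) <- problem@freeNames
    res
  })

#' Run a complete fitting experiment
#'
#' The full AdaptiveMCMC pipeline of a bound fitting problem: multi-start
#' CMA-ES over the prior box to choose the chain's starting point
#' (\code{cmaOpt} restarts of \code{cmaMaxFevals} objective evaluations
#' each), then adaptive-covariance MCMC (\code{numIters} iterations,
#' \code{burn} discarded). Sub-seeds for the optimiser and the sampler are
#' derived deterministically from the master seed.
#'
#' @param problem a [FittingProblem-class] (see [bindProblem()]).
#' @param seed master RNG seed.
#' @return List with \code{theta0} (the CMA-ES start point),
#'   \code{posterior} (a [PosteriorSample-class]) and \code{map} (the
#'   maximum-posterior-density estimate, see [mapEstimate()]).
#' @export
runFitting <- function(problem, seed = 1) {
  stopifnot(is(problem, "FittingProblem"))
  args <- problem@spec@arguments
  set.seed(as.integer(seed))
  subSeeds <- sample.int(.Machine$integer.max - 1L, 2)
  theta0 <- cmaEsInitialize(problem, restarts = args$cmaOpt,
                            maxFevals = args$cmaMaxFevals, seed = subSeeds[1])
  post <- adaptiveMCMC(problem, theta0 = theta0, numIters = args$numIters,
                       burn = args$burn, seed = subSeeds[2])
  list(theta0 = theta0, posterior = post, map = mapEstimate(post))
}
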