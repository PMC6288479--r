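#' CMA-ES minimisation inside a box
#'
#' Covariance Matrix Adaptation Evolution Strategy (the standard
#' (mu/mu_w, lambda) formulation with cumulative step-size adaptation and
#' rank-one plus rank-mu covariance updates), used here as a derivative-free
#' global optimiser. Coordinates are internally rescaled to the unit box;
#' out-of-box proposals are evaluated at their projection onto the box with
#' a quadratic distance penalty, so the returned optimum always lies inside
#' \code{[lower, upper]}.
#'
#' @param fn objective to minimise, called with a vector on the original
#'   scale; may return non-finite values (treated as very bad).
#' @param lower,upper box bounds (equal-length numeric vectors).
#' @param maxFevals budget of objective evaluations.
#' @param x0 starting point (original scale); default the box midpoint.
#' @param sigma0 initial step size as a fraction of each coordinate range.
#' @param tolX stop when the search distribution's extent (step size times
#'   largest axis) falls below this fraction of the unit box.
#' @param popSize offspring population size lambda; the default
#'   \code{4 + floor(3 log d)} suits unimodal landscapes, larger values
#'   trade convergence speed for a better chance of locating the global
#'   basin on multimodal ones.
#' @param seed optional RNG seed for reproducibility.
#' @return List with \code{par} (best point found, original scale),
#'   \code{value} (its objective value) and \code{fevals} (evaluations used).
#' @examples
#' sphere <- function(x) sum((x - 0.3)^2)
#' cmaesMinimize(sphere, rep(0, 3), rep(1, 3), maxFevals = 2000, seed = 1)$par
#' @export
cmaesMinimize <- function(fn, lower, upper, maxFevals, x0 = NULL,
                          sigma0 = 1 / 6, tolX = 1e-12, seed = NULL,
                          popSize = NULL) {
  stopifnot(length(lower) == length(upper), all(upper > lower),
            maxFevals >= 1)
  if (!is.null(seed)) set.seed(seed)
  d <- length(lower)
  range <- upper - lower
  toX <- function(z) lower + z * range

  evalZ <- function(z) {
    zf <- pmin(pmax(z, 0), 1)
    f <- fn(toX(zf))
    if (!is.finite(f)) f <- 1e12
    f + 1e6 * sum((z - zf)^2)
  }

  # strategy parameters (Hansen's defaults, with active covariance update)
  lambda <- if (is.null(popSize)) 4L + floor(3 * log(d)) else as.integer(popSize)
  mu <- floor(lambda / 2)
  wPre <- log((lambda + 1) / 2) - log(seq_len(lambda))
  weights <- wPre[seq_len(mu)] / sum(wPre[seq_len(mu)])
  mueff <- 1 / sum(weights^2)
  cc <- (4 + mueff / d) / (d + 4 + 2 * mueff / d)
  cs <- (mueff + 2) / (d + mueff + 5)
  c1 <- 2 / ((d + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((d + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (d + 1)) - 1) + cs
  chiN <- sqrt(d) * (1 - 1 / (4 * d) + 1 / (21 * d^2))
  # negative ("active") recombination weights for the covariance update
  wNegPre <- wPre[(mu + 1):lambda]
  mueffNeg <- sum(wNegPre)^2 / sum(wNegPre^2)
  alphaNeg <- min(1 + c1 / cmu, 1 + 2 * mueffNeg / (mueff + 2),
                  (1 - c1 - cmu) / (d * cmu))
  wNeg <- alphaNeg * wNegPre / abs(sum(wNegPre))

  m <- if (is.null(x0)) rep(0.5, d) else (x0 - lower) / range
  m <- pmin(pmax(m, 0), 1)
  sigma <- sigma0
  pc <- ps <- numeric(d)
  C <- diag(d); B <- diag(d); D <- rep(1, d)
  eigenStale <- 0
  best <- list(z = m, f = evalZ(m))
  fevals <- 1

  while (fevals + lambda <= maxFevals) {
    arz <- matrix(stats::rnorm(d * lambda), d, lambda)
    ary <- B %*% (D * arz)
    arx <- m + sigma * ary
    fit <- apply(arx, 2, evalZ)
    fevals <- fevals + lambda
    ord <- order(fit)
    if (fit[ord[1]] < best$f)
      best <- list(z = pmin(pmax(arx[, ord[1]], 0), 1), f = fit[ord[1]])

    sel <- ord[seq_len(mu)]
    mOld <- m
    m <- drop(arx[, sel, drop = FALSE] %*% weights)
    yw <- (m - mOld) / sigma
    ps <- (1 - cs) * ps +
      sqrt(cs * (2 - cs) * mueff) * drop(B %*% ((1 / D) * crossprod(B, yw)))
    hsig <- sqrt(sum(ps^2)) /
      sqrt(1 - (1 - cs)^(2 * fevals / lambda)) / chiN < 1.4 + 2 / (d + 1)
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * yw
    artmp <- (arx[, sel, drop = FALSE] - mOld) / sigma
    # active update: the worst candidates push the distribution away from
    # themselves; their steps are normalised to preserve positive-definiteness
    selNeg <- ord[(mu + 1):lambda]
    yNeg <- (arx[, selNeg, drop = FALSE] - mOld) / sigma
    zNegNorm <- sqrt(colSums((((1 / D) * crossprod(B, yNeg)))^2))
    yNegScaled <- sweep(yNeg, 2, pmax(zNegNorm, 1e-12) / sqrt(d), "/")
    C <- (1 - c1 - cmu * (sum(weights) + sum(wNeg))) * C +
      c1 * (tcrossprod(pc) + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * (artmp %*% (weights * t(artmp)) +
               yNegScaled %*% (wNeg * t(yNegScaled)))
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))

    eigenStale <- eigenStale + lambda
    if (eigenStale > lambda / (c1 + cmu) / d / 10) {
      eigenStale <- 0
      C <- (C + t(C)) / 2
      eg <- eigen(C, symmetric = TRUE)
      if (any(eg$values <= 0)) {  # numerical degeneracy: restart the shape
        C <- diag(d); B <- diag(d); D <- rep(1, d)
      } else {
        B <- eg$vectors
        D <- sqrt(eg$values)
      }
    }
    if (sigma * max(D) < tolX) break
    if (!all(is.finite(m)) || !is.finite(sigma)) break
  }
  list(par = toX(best$z), value = best$f, fevals = fevals)
}

#' Multi-start CMA-ES
#'
#' Runs [cmaesMinimize()] from independent uniform starting points inside
#' the box, splitting the evaluation budget equally across restarts, and
#' returns the best result overall. Restart seeds are derived
#' deterministically from the master seed.
#'
#' @inheritParams cmaesMinimize
#' @param restarts number of independent restarts (>= 1).
#' @param seed master RNG seed.
#' @return As [cmaesMinimize()], plus \code{restartValues} (best objective
#'   value per restart).
#' @export
cmaesMultistart <- function(fn, lower, upper, restarts, maxFevals, seed,
                            sigma0 = 1 / 6, popSize = NULL) {
  stopifnot(restarts >= 1)
  set.seed(seed)
  subSeeds <- sample.int(.Machine$integer.max - 1L, restarts)
  budget <- max(1L, floor(maxFevals / restarts))
  best <- NULL
  vals <- numeric(restarts)
  for (r in seq_len(restarts)) {
    set.seed(subSeeds[r])
    x0 <- lower + stats::runif(length(lower)) * (upper - lower)
    res <- cmaesMinimize(fn, lower, upper, maxFevals = budget, x0 = x0,
                         sigma0 = sigma0, popSize = popSize)
    vals[r] <- res$value
    if (is.null(best) || res$value < best$value) best <- res
  }
  best$restartValues <- vals
  best
}

#' Choose an MCMC starting point by multi-start CMA-ES
#'
#' Minimises the negative log-posterior of a bound fitting problem with
#' \code{restarts} independent CMA-ES searches and returns the best
#' parameter vector found overall. Each restart spends the first part of
#' its evaluation budget screening independent uniform draws from the
#' prior box and starts CMA-ES from the best draw; screening evaluations
#' count against the budget.
#'
#' Three pieces of search geometry help the optimiser without touching
#' the posterior itself: the search runs in log-transformed coordinates
#' (the natural scale for rate constants whose prior spans six orders of
#' magnitude); parameter sets rejected by the physiological rate window —
#' which have log-posterior \code{-Inf} and would otherwise form a flat,
#' uninformative plateau — are scored by a penalty growing with the size
#' of the violation; and the prior-draw screening avoids starting inside
#' the large "silent channel" region of parameter space where the model
#' carries no current and the least-squares surface is flat.
#'
#' @param problem a [FittingProblem-class].
#' @param restarts number of CMA-ES restarts (the spec argument
#'   \code{cmaOpt}).
#' @param maxFevals objective-evaluation budget (the spec argument
#'   \code{cmaMaxFevals}); by default the budget of each restart, see
#'   \code{budgetSplit}.
#' @param seed master RNG seed; each restart's sub-seed derives from it.
#' @param sigma0 initial step size(s), as a fraction of each (transformed)
#'   coordinate range; a vector is recycled across restarts.
#' @param popSize CMA-ES population size(s) per generation; a vector is
#'   recycled across restarts.
#' @param logScale search in log-transformed coordinates (default TRUE).
#' @param screenFraction fraction of each restart's budget spent screening
#'   uniform prior draws for the starting point.
#' @param budgetSplit "perRestart" (default) treats \code{maxFevals} as
#'   the budget of each restart; "total" divides it equally across
#'   restarts.
#' @return Named free-parameter vector with attributes \code{logPosterior}
#'   and \code{fevals} (total evaluations spent, all restarts).
#' @export
cmaEsInitialize <- function(problem, restarts = 5, maxFevals = 20000,
                            seed = 1, sigma0 = 0.15, popSize = 8,
                            logScale = TRUE, screenFraction = 0.05,
                            budgetSplit = c("perRestart", "total")) {
  budgetSplit <- match.arg(budgetSplit)
  box <- priorBox(problem)
  cons <- problem@constraint
  freeNames <- problem@freeNames
  d <- length(freeNames)
  rateWindowPenalty <- function(x) {
    m <- tryCatch(
      pmax(evaluateRates(assembleParameters(problem, x)$params, cons@vLow),
           evaluateRates(assembleParameters(problem, x)$params, cons@vHigh)),
      error = function(e) NULL)
    if (is.null(m)) return(1)
    sum(pmax(0, log(m / cons@rateMax))^2 +
          pmax(0, log(cons@rateMin / m))^2)
  }
  fn <- function(x) {
    lp <- logPosterior(problem, x)
    if (is.finite(lp)) return(-lp)
    # zero-probability region: a finite, violation-graded score that ranks
    # above every attainable finite negative log-posterior
    1e14 * (1 + rateWindowPenalty(x))
  }
  if (logScale) {
    obj <- function(y) fn(exp(y))
    lower <- log(box$lower); upper <- log(box$upper)
    toSearch <- log; fromSearch <- exp
  } else {
    obj <- fn
    lower <- box$lower; upper <- box$upper
    toSearch <- identity; fromSearch <- identity
  }

  budget <- if (budgetSplit == "total")
    max(1L, floor(maxFevals / restarts)) else as.integer(maxFevals)
  set.seed(as.integer(seed))
  subSeeds <- sample.int(.Machine$integer.max - 1L, restarts)
  best <- NULL
  fevals <- 0L
  for (r in seq_len(restarts)) {
    set.seed(subSeeds[r])
    nScreen <- max(1L, min(200L, floor(screenFraction * budget)))
    draws <- matrix(stats::runif(d * nScreen, box$lower, box$upper),
                    ncol = d, byrow = TRUE)
    vals <- apply(draws, 1, fn)
    x0 <- draws[which.min(vals), ]
    res <- cmaesMinimize(obj, lower, upper, maxFevals = budget - nScreen,
                         x0 = toSearch(x0),
                         sigma0 = sigma0[(r - 1) %% length(sigma0) + 1],
                         popSize = popSize[(r - 1) %% length(popSize) + 1])
    fevals <- fevals + nScreen + res$fevals
    if (min(vals) < res$value) res <- list(par = toSearch(x0),
                                           value = min(vals))
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (best$value >= 1e14)
    stop("every CMA-ES restart ended at zero posterior probability; ",
         "review the prior bounds and rate constraint", call. = FALSE)
  theta <- stats::setNames(fromSearch(best$par), freeNames)
  attr(theta, "logPosterior") <- -best$value
  attr(theta, "fevals") <- fevals
  theta
}
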