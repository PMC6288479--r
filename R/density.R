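#' Gaussian log-likelihood of a parameter vector
#'
#' Whole-trace Gaussian likelihood: the observed currents are modelled as
#' the simulated trace plus i.i.d. N(0, sigma^2) noise, giving
#' \deqn{\log L = -\tfrac{n}{2}\log(2\pi\sigma^2)
#'   - \sum_i (y_i - \hat y_i(\theta))^2 / (2\sigma^2).}
#' The trace is simulated at exactly the bound sample times. A simulation
#' failure yields \code{-Inf} (the sampler treats it as a rejection).
#'
#' @param problem a [FittingProblem-class].
#' @param theta free-parameter vector in declaration order.
#' @return The log-likelihood (finite, or -Inf on simulation failure).
#' @export
logLikelihood <- function(problem, theta) {
  ap <- assembleParameters(problem, theta)
  pred <- tryCatch(
    simulateCurrent(ap$params, problem@constants, problem@protocol,
                    problem@times),
    hergfit_simulation_error = function(e) NULL,
    error = function(e) NULL)
  if (is.null(pred)) return(-Inf)
  r <- problem@observed - pred@currents
  n <- length(r)
  -n / 2 * log(2 * pi * ap$sigma^2) - sum(r^2) / (2 * ap$sigma^2)
}

.rateMaxOverRange <- function(params, constraint) {
  rLow <- evaluateRates(params, constraint@vLow)
  rHigh <- evaluateRates(params, constraint@vHigh)
  pmax(rLow, rHigh)
}

#' Check the physiological rate constraint
#'
#' @param params a [RateParameters-class].
#' @param constraint a [RateConstraint-class].
#' @return TRUE when every rate's maximum over the voltage range lies
#'   within \code{[rateMin, rateMax]}.
#' @export
satisfiesRateConstraint <- function(params, constraint = rateConstraint()) {
  m <- tryCatch(.rateMaxOverRange(asRateParameters(params), constraint),
                error = function(e) NULL)
  !is.null(m) && all(m >= constraint@rateMin) && all(m <= constraint@rateMax)
}

#' Log-prior density of a parameter vector
#'
#' Box-uniform priors with physiological-rate assertions: the density is
#' \code{-Inf} if any free component leaves its uniform bounds, or if any of
#' the four transition rates (assembled from free and point-fixed entries)
#' violates the rate constraint; otherwise it is the normalising constant
#' \code{-sum(log(upper - lower))} over the uniform entries.
#'
#' @param prior ordered named prior list (as in [FittingSpec-class]).
#' @param constraint a [RateConstraint-class].
#' @param theta free-parameter vector, ordered as the uniform prior entries.
#' @return Log-density (a finite constant inside the support, else -Inf).
#' @export
logPrior <- function(prior, constraint, theta) {
  isFree <- vapply(prior, function(p) p$type == "uniform", logical(1))
  freeEntries <- prior[isFree]
  stopifnot(length(theta) == length(freeEntries))
  lower <- vapply(freeEntries, `[[`, numeric(1), "lower")
  upper <- vapply(freeEntries, `[[`, numeric(1), "upper")
  if (any(!is.finite(theta)) || any(theta < lower) || any(theta > upper))
    return(-Inf)
  full <- c(stats::setNames(as.numeric(theta), names(freeEntries)),
            vapply(prior[!isFree], `[[`, numeric(1), "value"))
  params <- asRateParameters(full[.RATE_PARAM_NAMES])
  if (!satisfiesRateConstraint(params, constraint)) return(-Inf)
  -sum(log(upper - lower))
}

#' Log-posterior density of a parameter vector
#'
#' \code{logPrior + logLikelihood}. An out-of-support point short-circuits:
#' no simulation is run when the prior is \code{-Inf}.
#'
#' @param problem a [FittingProblem-class].
#' @param theta free-parameter vector in declaration order.
#' @return The unnormalised log-posterior.
#' @export
logPosterior <- function(problem, theta) {
  lp <- logPrior(problem@prior, problem@constraint, theta)
  if (!is.finite(lp)) return(-Inf)
  lp + logLikelihood(problem, theta)
}

#' Free-parameter prior box of a problem
#'
#' @param problem a [FittingProblem-class].
#' @return List with named \code{lower} and \code{upper} vectors over the
#'   free parameters, in declaration order.
#' @export
priorBox <- function(problem) {
  free <- problem@prior[problem@freeNames]
  list(lower = vapply(free, `[[`, numeric(1), "lower"),
       upper = vapply(free, `[[`, numeric(1), "upper"))
}
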