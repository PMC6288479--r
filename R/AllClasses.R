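#' @import methods
NULL

.RATE_PARAM_NAMES <- c("kO1", "kO2", "kC1", "kC2", "kI1", "kI2", "kA1", "kA2", "GKr")
.KINETIC_PARAM_NAMES <- .RATE_PARAM_NAMES[1:8]
.STATE_NAMES <- c("O", "C", "IO")

#' Rate parameters of the hERG Markov model
#'
#' The nine free scalars of the four-state hERG gating model: four
#' voltage-dependent transition rates, each of the form
#' \eqn{k(V) = k_1 \exp(\pm k_2 V)} with prefactor \eqn{k_1} (ms\eqn{^{-1}})
#' and voltage sensitivity \eqn{k_2} (mV\eqn{^{-1}}), plus the maximal
#' conductance \code{GKr} (microsiemens). All nine values must be strictly
#' positive and finite.
#'
#' @slot .Data named numeric vector of length 9 with names
#'   \code{kO1, kO2, kC1, kC2, kI1, kI2, kA1, kA2, GKr}.
#' @export
setClass("RateParameters", contains = "numeric", validity = function(object) {
  v <- unclass(object)
  if (length(v) != 9L)
    return("must contain exactly 9 values")
  if (!identical(names(v), .RATE_PARAM_NAMES))
    return(sprintf("names must be exactly: %s", paste(.RATE_PARAM_NAMES, collapse = ", ")))
  if (any(!is.finite(v)))
    return("all values must be finite")
  if (any(v <= 0))
    return("all values must be strictly positive")
  TRUE
})

#' Construct hERG rate parameters
#'
#' @param kO1,kO2,kC1,kC2,kI1,kI2,kA1,kA2 kinetic parameters: prefactors in
#'   ms^-1, voltage sensitivities in mV^-1, all strictly positive.
#' @param GKr maximal conductance (uS), strictly positive.
#' @return A [RateParameters-class] object.
#' @examples
#' p <- rateParameters(kO1 = 2.5e-4, kO2 = 0.07, kC1 = 4e-5, kC2 = 0.055,
#'                     kI1 = 0.09, kI2 = 0.009, kA1 = 5e-3, kA2 = 0.03,
#'                     GKr = 0.15)
#' @export
rateParameters <- function(kO1, kO2, kC1, kC2, kI1, kI2, kA1, kA2, GKr) {
  v <- c(kO1 = kO1, kO2 = kO2, kC1 = kC1, kC2 = kC2,
         kI1 = kI1, kI2 = kI2, kA1 = kA1, kA2 = kA2, GKr = GKr)
  new("RateParameters", v)
}

#' Coerce a named vector to RateParameters
#'
#' @param x named numeric vector containing the nine parameter names.
#' @return A [RateParameters-class] object.
#' @export
asRateParameters <- function(x) {
  if (is(x, "RateParameters")) return(x)
  if (is.null(names(x)) || !all(.RATE_PARAM_NAMES %in% names(x)))
    stop("'x' must be a named vector with entries ",
         paste(.RATE_PARAM_NAMES, collapse = ", "))
  new("RateParameters", unclass(x)[.RATE_PARAM_NAMES])
}

setMethod("show", "RateParameters", function(object) {
  cat("RateParameters (4-state hERG Markov model)\n")
  print(unclass(object))
})

#' Physical constants of the model
#'
#' @slot EK potassium reversal potential (mV). The driving force on the
#'   current is \code{Vm - EK}.
#' @slot timeUnit internal time unit, always "ms".
#' @slot voltageUnit internal voltage unit, always "mV".
#' @export
setClass("ModelConstants",
  representation(EK = "numeric", timeUnit = "character", voltageUnit = "character"),
  prototype(EK = -88.4, timeUnit = "ms", voltageUnit = "mV"),
  validity = function(object) {
    if (length(object@EK) != 1L || !is.finite(object@EK))
      return("EK must be a single finite value (mV)")
    if (!identical(object@timeUnit, "ms") || !identical(object@voltageUnit, "mV"))
      return("internal units are fixed to ms and mV")
    TRUE
  })

#' Construct model constants
#'
#' @param EK reversal potential in mV. Default -88.4 mV, a typical potassium
#'   Nernst potential for whole-cell patch-clamp solutions near room
#'   temperature.
#' @return A [ModelConstants-class] object.
#' @export
modelConstants <- function(EK = -88.4) new("ModelConstants", EK = EK)

setMethod("show", "ModelConstants", function(object) {
  cat(sprintf("ModelConstants: EK = %g mV (time in ms, voltage in mV)\n", object@EK))
})

#' Gating-state occupancies
#'
#' Occupancies of the open (O), closed (C) and inactivated-open (IO) states.
#' The inactivated-closed occupancy is derived as
#' \code{IC = 1 - (O + C + IO)}, so conservation of probability is structural.
#'
#' @slot .Data named numeric vector (O, C, IO).
#' @export
setClass("GatingState", contains = "numeric", validity = function(object) {
  v <- unclass(object)
  if (length(v) != 3L || !identical(names(v), .STATE_NAMES))
    return("must be a named vector (O, C, IO)")
  tol <- 1e-8
  ic <- 1 - sum(v)
  if (any(v < -tol) || any(v > 1 + tol) || ic < -tol || ic > 1 + tol)
    return("occupancies (including derived IC) must lie in [0, 1]")
  TRUE
})

#' Construct a gating state
#'
#' @param O,C,IO occupancies in \[0, 1\] with \code{O + C + IO <= 1}.
#' @return A [GatingState-class] object.
#' @export
gatingState <- function(O, C, IO)
  new("GatingState", c(O = unname(O), C = unname(C), IO = unname(IO)))

#' Full occupancy vector including the derived IC state
#'
#' @param state a [GatingState-class] object.
#' @return Named numeric of length 4 (O, C, IO, IC) summing to 1 exactly.
#' @export
occupancies <- function(state) {
  v <- unclass(state)
  c(v, IC = unname(1 - sum(v)))
}

setMethod("show", "GatingState", function(object) {
  cat("GatingState:\n")
  print(occupancies(object))
})

#' Voltage-clamp protocol
#'
#' An ordered, contiguous list of segments starting at t = 0. Each segment is
#' a list with \code{kind} ("hold", "ramp" or "sine"), \code{duration} (ms)
#' and kind-specific fields: \code{v} for holds; \code{vStart}, \code{vEnd}
#' for ramps; \code{vOffset}, \code{amplitude}, \code{period}, \code{phase}
#' for sines. Segments are left-closed/right-open, so at an internal boundary
#' the later segment's voltage applies.
#'
#' @slot segments list of segment descriptions.
#' @export
setClass("VoltageProtocol", representation(segments = "list"),
  validity = function(object) {
    segs <- object@segments
    if (length(segs) == 0L) return("protocol must contain at least one segment")
    for (i in seq_along(segs)) {
      s <- segs[[i]]
      if (!is.list(s) || is.null(s$kind) || is.null(s$duration))
        return(sprintf("segment %d must have 'kind' and 'duration'", i))
      if (!s$kind %in% c("hold", "ramp", "sine"))
        return(sprintf("segment %d: unknown kind '%s'", i, s$kind))
      if (!is.finite(s$duration) || s$duration <= 0)
        return(sprintf("segment %d: duration must be > 0", i))
      need <- switch(s$kind,
        hold = "v", ramp = c("vStart", "vEnd"),
        sine = c("vOffset", "amplitude", "period", "phase"))
      miss <- setdiff(need, names(s))
      if (length(miss))
        return(sprintf("segment %d (%s): missing field(s) %s", i, s$kind,
                       paste(miss, collapse = ", ")))
      bad <- !vapply(s[need], function(x) is.numeric(x) && is.finite(x), logical(1))
      if (any(bad))
        return(sprintf("segment %d: non-finite field(s)", i))
      if (s$kind == "sine" && s$period <= 0)
        return(sprintf("segment %d: sine period must be > 0", i))
    }
    TRUE
  })

setMethod("show", "VoltageProtocol", function(object) {
  segs <- object@segments
  cat(sprintf("VoltageProtocol: %d segment(s), total duration %g ms\n",
              length(segs), protocolDuration(object)))
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    desc <- switch(s$kind,
      hold = sprintf("hold %g mV", s$v),
      ramp = sprintf("ramp %g -> %g mV", s$vStart, s$vEnd),
      sine = sprintf("sine offset %g, amp %g mV, period %g ms", s$vOffset,
                     s$amplitude, s$period))
    cat(sprintf("  [%2d] %8g ms  %s\n", i, s$duration, desc))
  }
})

#' Simulated current trace
#'
#' @slot times sample times (ms, strictly increasing).
#' @slot currents IKr at each sample (nA).
#' @slot states matrix of (O, C, IO) occupancies per sample (may have 0 rows
#'   when state output was not requested).
#' @export
setClass("CurrentTrace",
  representation(times = "numeric", currents = "numeric", states = "matrix"),
  validity = function(object) {
    if (length(object@times) != length(object@currents))
      return("times and currents must have equal length")
    if (length(object@times) > 1L && any(diff(object@times) <= 0))
      return("times must be strictly increasing")
    if (nrow(object@states) > 0L && nrow(object@states) != length(object@times))
      return("states must have one row per sample")
    TRUE
  })

setMethod("show", "CurrentTrace", function(object) {
  n <- length(object@times)
  cat(sprintf("CurrentTrace: %d samples over [%g, %g] ms, IKr range [%.4g, %.4g] nA\n",
              n, object@times[1], object@times[n],
              min(object@currents), max(object@currents)))
})

#' @describeIn CurrentTrace-class coerce to a data.frame with columns
#'   \code{t} (ms), \code{IKr} (nA) and, when present, the state occupancies.
#' @param x a \code{CurrentTrace}.
#' @param ... unused.
#' @export
setMethod("as.data.frame", "CurrentTrace", function(x, ...) {
  df <- data.frame(t = x@times, IKr = x@currents)
  if (nrow(x@states) > 0L) df <- cbind(df, as.data.frame(x@states))
  df
})

#' Parsed fitting specification
#'
#' The machine-readable JSON document binding a fitting algorithm, its
#' arguments, data-to-model name maps and a prior. Field names mirror the
#' JSON keys: \code{algorithm}, \code{arguments}, \code{output},
#' \code{input}, \code{prior}.
#'
#' @slot algorithm algorithm identifier (currently only "AdaptiveMCMC").
#' @slot arguments named list of numeric algorithm arguments.
#' @slot outputMap named character: data-column name -> model-output name.
#' @slot inputMap named character: simulation-input name -> data-column name.
#' @slot prior ordered named list of prior entries, each
#'   \code{list(type = "uniform", lower =, upper =)} or
#'   \code{list(type = "point", value =)}.
#' @slot units named character of declared data-column units (sidecar; may be
#'   empty, in which case defaults apply at binding time).
#' @export
setClass("FittingSpec",
  representation(algorithm = "character", arguments = "list",
                 outputMap = "character", inputMap = "character",
                 prior = "list", units = "character"),
  validity = function(object) {
    if (length(object@algorithm) != 1L || !nzchar(object@algorithm))
      return("algorithm must be a non-empty string")
    if (length(object@outputMap) == 0L || length(object@inputMap) == 0L)
      return("input and output maps must be non-empty")
    if (length(object@prior) == 0L)
      return("prior must be non-empty")
    ok <- vapply(object@arguments, function(a)
      is.numeric(a) && length(a) == 1L && is.finite(a), logical(1))
    if (!all(ok)) return("every argument value must be a finite number")
    TRUE
  })

setMethod("show", "FittingSpec", function(object) {
  cat(sprintf("FittingSpec: algorithm %s\n", object@algorithm))
  cat("  arguments:", paste(sprintf("%s = %g", names(object@arguments),
                                    unlist(object@arguments)), collapse = ", "), "\n")
  cat("  output:   ", paste(sprintf("%s = %s", names(object@outputMap),
                                    object@outputMap), collapse = ", "), "\n")
  cat("  input:    ", paste(sprintf("%s = %s", names(object@inputMap),
                                    object@inputMap), collapse = ", "), "\n")
  nfree <- sum(vapply(object@prior, function(p) p$type == "uniform", logical(1)))
  cat(sprintf("  prior:     %d entries (%d free, %d fixed)\n",
              length(object@prior), nfree, length(object@prior) - nfree))
})

#' Named-column numeric data table
#'
#' In-memory form of the CSV data file: uniquely named numeric columns of
#' equal length, with a per-column unit label.
#'
#' @slot columns data.frame of numeric columns.
#' @slot units named character of per-column unit labels ("" = undeclared).
#' @export
setClass("DataTable",
  representation(columns = "data.frame", units = "character"),
  validity = function(object) {
    df <- object@columns
    if (ncol(df) == 0L) return("table must have at least one column")
    if (anyDuplicated(names(df))) return("column names must be unique")
    if (!all(vapply(df, is.numeric, logical(1))))
      return("all columns must be numeric")
    if (!all(vapply(df, function(x) all(is.finite(x)), logical(1))))
      return("all values must be finite")
    if (!identical(sort(names(object@units)), sort(names(df))))
      return("units must be named after the columns")
    TRUE
  })

setMethod("show", "DataTable", function(object) {
  df <- object@columns
  u <- object@units[names(df)]
  lab <- ifelse(nzchar(u), sprintf("%s [%s]", names(df), u), names(df))
  cat(sprintf("DataTable: %d rows x %d columns (%s)\n", nrow(df), ncol(df),
              paste(lab, collapse = ", ")))
})

#' Physiological rate constraint
#'
#' Parameterisations whose transition rates leave a physiological window are
#' assigned zero prior probability. For each of the four rates the maximum
#' over the voltage range \code{[vLow, vHigh]} (attained at an endpoint,
#' since each rate is monotone in voltage) must lie within
#' \code{[rateMin, rateMax]}: the rate may neither explode anywhere in the
#' range nor stay negligibly small across all of it.
#'
#' @slot vLow,vHigh voltage range (mV).
#' @slot rateMin,rateMax admissible window for each rate's maximum (ms^-1).
#' @export
setClass("RateConstraint",
  representation(vLow = "numeric", vHigh = "numeric",
                 rateMin = "numeric", rateMax = "numeric"),
  validity = function(object) {
    if (object@vLow >= object@vHigh) return("vLow must be < vHigh")
    if (!(object@rateMin > 0 && object@rateMin < object@rateMax))
      return("need 0 < rateMin < rateMax")
    TRUE
  })

#' Construct a rate constraint
#'
#' Defaults follow the physiological-range convention used in hERG
#' whole-trace fitting: rates within \[1.67e-5, 1000\] ms^-1 over
#' \[-120, 60\] mV.
#'
#' @param vLow,vHigh voltage range (mV).
#' @param rateMin,rateMax rate window (ms^-1).
#' @return A [RateConstraint-class] object.
#' @export
rateConstraint <- function(vLow = -120, vHigh = 60,
                           rateMin = 1.67e-5, rateMax = 1000) {
  new("RateConstraint", vLow = vLow, vHigh = vHigh,
      rateMin = rateMin, rateMax = rateMax)
}

setMethod("show", "RateConstraint", function(object) {
  cat(sprintf("RateConstraint: rates within [%g, %g] ms^-1 over [%g, %g] mV\n",
              object@rateMin, object@rateMax, object@vLow, object@vHigh))
})

#' A bound, runnable fitting problem
#'
#' The result of binding a fitting specification and a data table to the
#' model and a protocol: resolved sample times, observed currents, prior,
#' noise model and rate constraint.
#'
#' @slot constants a [ModelConstants-class].
#' @slot protocol a [VoltageProtocol-class].
#' @slot times resolved simulation sample times (ms, strictly increasing).
#' @slot observed observed currents at those times (nA).
#' @slot prior the ordered prior (as in [FittingSpec-class]).
#' @slot freeNames names of the free (uniform-prior) parameters, in
#'   declaration order; this fixes the parameter-vector layout.
#' @slot fixed named numeric of point-prior (fixed) values.
#' @slot sigmaFree TRUE when the noise standard deviation "obj:std" is a free
#'   parameter rather than fixed.
#' @slot constraint a [RateConstraint-class].
#' @slot spec the originating [FittingSpec-class] (echo).
#' @slot conversionLog character log of unit conversions applied at binding.
#' @export
setClass("FittingProblem",
  representation(constants = "ModelConstants", protocol = "VoltageProtocol",
                 times = "numeric", observed = "numeric", prior = "list",
                 freeNames = "character", fixed = "numeric",
                 sigmaFree = "logical", constraint = "RateConstraint",
                 spec = "FittingSpec", conversionLog = "character"),
  validity = function(object) {
    if (length(object@times) != length(object@observed))
      return("observed array length must equal sample-time length")
    if (length(object@times) > 1L && any(diff(object@times) <= 0))
      return("sample times must be strictly increasing")
    TRUE
  })

setMethod("show", "FittingProblem", function(object) {
  cat(sprintf("FittingProblem: %d samples over [%g, %g] ms\n",
              length(object@times), min(object@times), max(object@times)))
  cat(sprintf("  %d free parameter(s): %s\n", length(object@freeNames),
              paste(object@freeNames, collapse = ", ")))
  cat(sprintf("  noise sigma: %s\n",
              if (object@sigmaFree) "free (uniform prior)"
              else sprintf("fixed at %g", object@fixed[["obj:std"]])))
  if (length(object@conversionLog))
    cat("  conversions:", paste(object@conversionLog, collapse = "; "), "\n")
})

#' Posterior sample from adaptive-covariance MCMC
#'
#' @slot chain retained (post burn-in) iteration x free-parameter matrix.
#' @slot logPosteriors log-posterior of each retained iteration.
#' @slot acceptanceRate overall acceptance rate of the chain.
#' @slot seed the RNG seed used.
#' @slot arguments echo of the algorithm arguments.
#' @slot theta0 the chain's starting point.
#' @slot theta0LogPosterior log-posterior at theta0.
#' @slot priorLower,priorUpper per-free-parameter prior bounds (used by the
#'   identifiability flags to relate marginal width to prior width).
#' @export
setClass("PosteriorSample",
  representation(chain = "matrix", logPosteriors = "numeric",
                 acceptanceRate = "numeric", seed = "integer",
                 arguments = "list", theta0 = "numeric",
                 theta0LogPosterior = "numeric",
                 priorLower = "numeric", priorUpper = "numeric"),
  validity = function(object) {
    if (nrow(object@chain) != length(object@logPosteriors))
      return("one log-posterior per retained iteration required")
    if (any(!is.finite(object@logPosteriors)))
      return("every retained iteration must have a finite log-posterior")
    if (object@acceptanceRate <= 0 || object@acceptanceRate >= 1)
      return("acceptance rate must lie in (0, 1)")
    TRUE
  })

setMethod("show", "PosteriorSample", function(object) {
  cat(sprintf("PosteriorSample: %d retained iterations, %d parameter(s)\n",
              nrow(object@chain), ncol(object@chain)))
  cat(sprintf("  acceptance rate %.3f, max log-posterior %.4f, seed %d\n",
              object@acceptanceRate, max(object@logPosteriors), object@seed))
})

#' @describeIn PosteriorSample-class the retained chain matrix.
#' @param sample a \code{PosteriorSample}.
#' @export
chain <- function(sample) sample@chain

#' @describeIn PosteriorSample-class per-iteration log-posteriors.
#' @export
logPosteriors <- function(sample) sample@logPosteriors

#' @describeIn PosteriorSample-class overall acceptance rate.
#' @export
acceptanceRate <- function(sample) sample@acceptanceRate

#' Marginal posterior summary for one parameter
#'
#' @slot parameter parameter name.
#' @slot breaks histogram bin edges.
#' @slot counts histogram counts (sum equals retained-chain length).
#' @slot mean,sd sample mean and standard deviation.
#' @slot ciLevel,ciLower,ciUpper equal-tailed credible interval.
#' @slot mode midpoint of the highest smoothed histogram bin.
#' @slot flags list(multimodal =, flat =) identifiability flags.
#' @export
setClass("MarginalSummary",
  representation(parameter = "character", breaks = "numeric", counts = "numeric",
                 mean = "numeric", sd = "numeric", ciLevel = "numeric",
                 ciLower = "numeric", ciUpper = "numeric", mode = "numeric",
                 flags = "list"),
  validity = function(object) {
    if (length(object@breaks) != length(object@counts) + 1L)
      return("breaks must have length(counts) + 1")
    if (object@ciLevel <= 0 || object@ciLevel >= 1)
      return("ciLevel must lie in (0, 1)")
    if (object@ciLower > object@ciUpper)
      return("ciLower must be <= ciUpper")
    TRUE
  })

setMethod("show", "MarginalSummary", function(object) {
  cat(sprintf("MarginalSummary for %s: mean %.6g, sd %.3g, %d%% CI [%.6g, %.6g]\n",
              object@parameter, object@mean, object@sd,
              round(100 * object@ciLevel), object@ciLower, object@ciUpper))
  cat(sprintf("  mode ~ %.6g; flags: multimodal = %s, flat = %s\n", object@mode,
              object@flags$multimodal, object@flags$flat))
})

#' Ground truth record for synthetic data
#'
#' Everything needed to generate a synthetic voltage-clamp recording and
#' later check parameter recovery against it: true parameters, constants,
#' protocol, observation-noise standard deviation, sampling interval and
#' RNG seed.
#'
#' @slot params true [RateParameters-class].
#' @slot constants a [ModelConstants-class].
#' @slot protocol a [VoltageProtocol-class].
#' @slot sigma observation-noise standard deviation (nA), >= 0 (0 gives a
#'   noise-free dataset).
#' @slot seed RNG seed for the noise draw.
#' @slot dt sampling interval (ms), > 0.
#' @export
setClass("TruthRecord",
  representation(params = "RateParameters", constants = "ModelConstants",
                 protocol = "VoltageProtocol", sigma = "numeric",
                 seed = "integer", dt = "numeric"),
  validity = function(object) {
    if (object@sigma < 0) return("sigma must be >= 0")
    if (object@dt <= 0) return("dt must be > 0")
    TRUE
  })

setMethod("show", "TruthRecord", function(object) {
  cat(sprintf("TruthRecord: sigma = %g nA, dt = %g ms, seed = %d\n",
              object@sigma, object@dt, object@seed))
  show(object@params)
})
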