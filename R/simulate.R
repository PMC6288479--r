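.SEG_KIND_CODE <- c(hold = 1, ramp = 2, sine = 3)

.simError <- function(msg) {
  stop(structure(list(message = msg, call = NULL),
                 class = c("hergfit_simulation_error", "error", "condition")))
}

.segParms <- function(kinetics, seg, t0) {
  q <- switch(seg$kind,
    hold = c(seg$v, 0, 0, 0),
    ramp = c(seg$vStart, seg$vEnd, seg$duration, 0),
    sine = c(seg$vOffset, seg$amplitude, seg$period, seg$phase))
  c(kinetics, .SEG_KIND_CODE[[seg$kind]], q, t0)
}

#' Integrate the gating ODEs over a protocol
#'
#' Returns the (O, C, IO) occupancy matrix at the requested times. The
#' integration restarts at every protocol segment boundary so that voltage
#' discontinuities are never smoothed over by the step-size controller; the
#' right-hand side is compiled C code driven through deSolve's lsoda.
#'
#' @noRd
.integrateStates <- function(params, protocol, times, rtol, atol) {
  kin <- unclass(params)[.KINETIC_PARAM_NAMES]
  bounds <- .segmentBounds(protocol)
  nseg <- length(protocol@segments)
  state <- unclass(steadyState(evaluateRates(params, voltageAt(protocol, 0))))
  out <- matrix(NA_real_, length(times), 3,
                dimnames = list(NULL, .STATE_NAMES))
  for (i in seq_len(nseg)) {
    t0 <- bounds[i]; t1 <- bounds[i + 1]
    sel <- if (i < nseg) which(times >= t0 & times < t1)
           else which(times >= t0 & times <= t1)
    tt <- sort(unique(c(t0, times[sel], t1)))
    sol <- suppressWarnings(
      deSolve::lsoda(y = state, times = tt, func = "hergfit_derivs",
                     parms = .segParms(kin, protocol@segments[[i]], t0),
                     dllname = "hergfit", initfunc = "hergfit_initmod",
                     rtol = rtol, atol = atol, maxsteps = 50000))
    if (attr(sol, "istate")[1] < 0 || anyNA(sol))
      .simError(sprintf(
        "ODE integration failed in segment %d (params: %s)", i,
        paste(sprintf("%s=%.6g", names(params), unclass(params)),
              collapse = ", ")))
    if (length(sel))
      out[sel, ] <- sol[match(times[sel], tt), 2:4, drop = FALSE]
    state <- sol[nrow(sol), 2:4]
    names(state) <- .STATE_NAMES
  }
  out
}

#' Simulate the IKr current under a voltage-clamp protocol
#'
#' Integrates the four-state Markov model from the steady state at the
#' protocol's initial holding voltage and reports
#' \eqn{I_{Kr} = G_{Kr} \, O(V_m, t) \, (V_m - E_K)} at exactly the
#' requested sample times.
#'
#' @param params a [RateParameters-class] (or coercible named vector).
#' @param constants a [ModelConstants-class] (reversal potential EK).
#' @param protocol a [VoltageProtocol-class].
#' @param times sample times (ms), strictly increasing, within
#'   \[0, protocol duration\].
#' @param rtol,atol relative and absolute integration tolerances. The
#'   defaults are tight enough that the accumulated global error over a
#'   multi-second protocol stays well below 1e-6 in every occupancy.
#' @param states if TRUE, include per-sample occupancies in the result.
#' @return A [CurrentTrace-class].
#' @examples
#' tr <- simulateCurrent(defaultTruth()@params, modelConstants(),
#'                       defaultFixtureProtocol(), times = seq(0, 12000, 10))
#' @export
simulateCurrent <- function(params, constants, protocol, times,
                            rtol = 1e-8, atol = 1e-10, states = FALSE) {
  params <- asRateParameters(params)
  stopifnot(is(constants, "ModelConstants"), is(protocol, "VoltageProtocol"),
            is.numeric(times), length(times) >= 1L, all(is.finite(times)))
  if (any(diff(times) <= 0))
    stop("sample times must be strictly increasing", call. = FALSE)
  total <- protocolDuration(protocol)
  if (times[1] < 0 || times[length(times)] > total)
    stop("sample times must lie within the protocol duration [0, ", total,
         "] ms", call. = FALSE)
  st <- .integrateStates(params, protocol, times, rtol, atol)
  # occupancies may leave [0,1] by no more than the solver tolerance
  if (any(st < -1e-6) || any(st > 1 + 1e-6))
    .simError("integration produced occupancies far outside [0, 1]")
  stOut <- pmin(pmax(st, 0), 1)
  v <- voltageAt(protocol, times)
  ikr <- unclass(params)[["GKr"]] * stOut[, "O"] * (v - constants@EK)
  new("CurrentTrace", times = as.numeric(times), currents = unname(ikr),
      states = if (states) stOut else matrix(numeric(0), 0, 3,
                                             dimnames = list(NULL, .STATE_NAMES)))
}

#' Write a current trace to CSV
#'
#' @param trace a [CurrentTrace-class].
#' @param path output file path.
#' @param names column names for time and current (default \code{t},
#'   \code{IKr}, matching the bound output names of the fitting spec).
#' @return \code{path}, invisibly.
#' @export
writeTrace <- function(trace, path, names = c("t", "IKr")) {
  df <- data.frame(trace@times, trace@currents)
  colnames(df) <- names
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
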