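#' Evaluate the four voltage-dependent transition rates
#'
#' The four rates of the hERG Markov model at a membrane potential \code{v}:
#' \deqn{kO = kO1 e^{kO2 v},\quad kC = kC1 e^{-kC2 v},\quad
#'       kI = kI1 e^{kI2 v},\quad kA = kA1 e^{-kA2 v}.}
#' Exponent arguments beyond +/-700 would overflow the double range; such a
#' parameter/voltage combination is rejected as invalid rather than clipped
#' silently.
#'
#' @param params a [RateParameters-class] (or coercible named vector).
#' @param v membrane potential (mV), a single finite value.
#' @return Named numeric (kO, kC, kI, kA) in ms^-1, all strictly positive.
#' @examples
#' p <- defaultTruth()@params
#' evaluateRates(p, 0)   # at 0 mV the rates equal the prefactors
#' @export
evaluateRates <- function(params, v) {
  params <- asRateParameters(params)
  stopifnot(length(v) == 1L, is.finite(v))
  p <- unclass(params)
  expo <- c(kO = p[["kO2"]] * v, kC = -p[["kC2"]] * v,
            kI = p[["kI2"]] * v, kA = -p[["kA2"]] * v)
  if (any(abs(expo) > 700))
    stop("invalid parameter/voltage combination: rate exponent exceeds +/-700 at v = ",
         v, " mV", call. = FALSE)
  r <- c(p[["kO1"]], p[["kC1"]], p[["kI1"]], p[["kA1"]]) * exp(expo)
  if (any(!is.finite(r)))
    stop("non-finite transition rate at v = ", v, " mV", call. = FALSE)
  r
}

.checkRateSet <- function(rates) {
  stopifnot(is.numeric(rates), length(rates) == 4L,
            all(c("kO", "kC", "kI", "kA") %in% names(rates)),
            all(is.finite(rates)), all(rates > 0))
  rates[c("kO", "kC", "kI", "kA")]
}

#' Time derivatives of the gating-state occupancies
#'
#' Right-hand side of the four-state Markov model at fixed transition rates,
#' with IC substituted by conservation. The implied dIC/dt is
#' \code{-(dO + dC + dIO)/dt}.
#'
#' @param state a [GatingState-class].
#' @param rates named numeric (kO, kC, kI, kA) as from [evaluateRates()].
#' @return Named numeric (dO, dC, dIO) in ms^-1.
#' @export
stateDerivatives <- function(state, rates) {
  stopifnot(is(state, "GatingState"))
  r <- .checkRateSet(rates)
  s <- occupancies(state)
  O <- s[["O"]]; C <- s[["C"]]; IO <- s[["IO"]]; IC <- s[["IC"]]
  c(dO  = r[["kO"]] * C + r[["kA"]] * IO - (r[["kC"]] + r[["kI"]]) * O,
    dC  = r[["kC"]] * O + r[["kA"]] * IC - (r[["kO"]] + r[["kI"]]) * C,
    dIO = r[["kI"]] * O + r[["kO"]] * IC - (r[["kA"]] + r[["kC"]]) * IO)
}

#' Steady state of the gating system at fixed rates
#'
#' The model factorises into an activation gate (C <-> O, rates kO/kC) and an
#' inactivation-recovery gate (I <-> not-I, rates kI/kA), so the fixed point
#' is the product of the two gates' equilibria:
#' \code{O = a_inf * r_inf}, \code{C = (1 - a_inf) * r_inf},
#' \code{IO = a_inf * (1 - r_inf)} with \code{a_inf = kO/(kO+kC)} and
#' \code{r_inf = kA/(kA+kI)}.
#'
#' @param rates named numeric (kO, kC, kI, kA), all strictly positive.
#' @return A [GatingState-class] at which [stateDerivatives()] vanishes.
#' @export
steadyState <- function(rates) {
  r <- .checkRateSet(rates)
  aInf <- r[["kO"]] / (r[["kO"]] + r[["kC"]])
  rInf <- r[["kA"]] / (r[["kA"]] + r[["kI"]])
  gatingState(O = aInf * rInf, C = (1 - aInf) * rInf, IO = aInf * (1 - rInf))
}

#' Hodgkin-Huxley gate summary at constant voltage
#'
#' Steady-state values and time constants of the two independent gates into
#' which the four-state model factorises: activation \code{a} and
#' non-inactivation \code{r}. These give closed-form relaxation solutions at
#' constant voltage, used as the analytic oracle for the numerical
#' integrator.
#'
#' @param params a [RateParameters-class].
#' @param v membrane potential (mV).
#' @return List with \code{aInf}, \code{rInf} (dimensionless, in (0,1)) and
#'   \code{tauA}, \code{tauR} (ms, > 0).
#' @export
analyticGateSolution <- function(params, v) {
  r <- evaluateRates(params, v)
  list(aInf = r[["kO"]] / (r[["kO"]] + r[["kC"]]),
       rInf = r[["kA"]] / (r[["kA"]] + r[["kI"]]),
       tauA = 1 / (r[["kO"]] + r[["kC"]]),
       tauR = 1 / (r[["kA"]] + r[["kI"]]))
}

.factorizeState <- function(state, tol = 1e-8) {
  s <- occupancies(state)
  rGate <- s[["O"]] + s[["C"]]              # P(not inactivated)
  aGate <- if (rGate > tol) s[["O"]] / rGate else s[["O"]] + s[["IO"]]
  # the state must be an outer product of the two gates
  if (abs(aGate * rGate - s[["O"]]) > tol ||
      abs(aGate * (1 - rGate) - s[["IO"]]) > tol)
    stop("analytic oracle inapplicable: initial state does not factorise ",
         "into independent activation and inactivation gates", call. = FALSE)
  c(a = aGate, r = rGate)
}

#' Closed-form gating solution at constant voltage
#'
#' Exact solution of the gating ODEs when the voltage is held constant and
#' the initial state factorises into the two Hodgkin-Huxley gates (always
#' true for a steady state). Each gate relaxes exponentially,
#' \eqn{a(t) = a_\infty + (a_0 - a_\infty) e^{-t/\tau_a}}, and the Markov
#' states are reassembled as products of the gates.
#'
#' @param params a [RateParameters-class].
#' @param v constant membrane potential (mV).
#' @param initial initial [GatingState-class]; must factorise (see Details).
#' @param times evaluation times (ms, non-negative).
#' @return Matrix with one row per time and columns O, C, IO, IC.
#' @export
analyticConstantVoltageSolution <- function(params, v, initial, times) {
  stopifnot(is.numeric(times), all(is.finite(times)), all(times >= 0))
  g <- analyticGateSolution(params, v)
  g0 <- .factorizeState(initial)
  a <- g$aInf + (g0[["a"]] - g$aInf) * exp(-times / g$tauA)
  r <- g$rInf + (g0[["r"]] - g$rInf) * exp(-times / g$tauR)
  cbind(O = a * r, C = (1 - a) * r, IO = a * (1 - r), IC = (1 - a) * (1 - r))
}
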