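#' Construct a ground-truth record
#'
#' @param params true [RateParameters-class].
#' @param constants a [ModelConstants-class].
#' @param protocol a [VoltageProtocol-class].
#' @param sigma observation-noise standard deviation (nA), > 0.
#' @param seed RNG seed for the noise draw.
#' @param dt sampling interval (ms), > 0.
#' @return A [TruthRecord-class].
#' @export
truthRecord <- function(params, constants = modelConstants(),
                        protocol = defaultFixtureProtocol(),
                        sigma = 0.00463, seed = 20260101L, dt = 0.1) {
  new("TruthRecord", params = asRateParameters(params), constants = constants,
      protocol = protocol, sigma = sigma, seed = as.integer(seed), dt = dt)
}

#' The package's default synthetic ground truth
#'
#' A fixed, documented parameter set used to generate synthetic recordings
#' for recovery testing. The values are synthetic constants chosen in the
#' physiological ballpark of published hERG gating kinetics at room
#' temperature (activation time constants of hundreds of ms, inactivation
#' of tens of ms): they lie strictly inside the reference prior box of
#' [hergFittingSpec()], satisfy the default physiological rate constraint
#' over \[-120, 60\] mV, and yield a signal-to-noise ratio far above 20
#' under the reference noise level sigma = 0.00463 with the built-in
#' fixture protocol. They are not estimates from any recorded cell.
#'
#' @return A [TruthRecord-class].
#' @examples
#' truth <- defaultTruth()
#' satisfiesRateConstraint(truth@params)
#' @export
defaultTruth <- function() {
  truthRecord(rateParameters(
    kO1 = 2.5e-4, kO2 = 0.07, kC1 = 4e-5, kC2 = 0.055,
    kI1 = 0.09, kI2 = 0.009, kA1 = 5e-3, kA2 = 0.03, GKr = 0.15))
}

.checkTruthAdmissible <- function(truth) {
  spec <- hergFittingSpec()
  p <- unclass(truth@params)
  for (nm in .RATE_PARAM_NAMES) {
    pr <- spec@prior[[nm]]
    if (p[[nm]] <= pr$lower || p[[nm]] >= pr$upper)
      stop("truth parameter ", nm, " = ", p[[nm]],
           " is not strictly inside the prior box [", pr$lower, ", ",
           pr$upper, "]; recovery tests against it would be meaningless",
           call. = FALSE)
  }
  if (!satisfiesRateConstraint(truth@params))
    stop("truth parameters violate the physiological rate constraint",
         call. = FALSE)
  invisible(TRUE)
}

#' Generate a synthetic voltage-clamp dataset
#'
#' Simulates the protocol on a regular time grid at the truth's sampling
#' interval and adds i.i.d. N(0, sigma^2) observation noise, emulating a
#' digitised whole-cell recording after leak/capacitance pre-processing.
#' Times are reported in seconds (the convention of the CSV data files);
#' the binder converts them back to ms. The truth must lie strictly inside
#' the reference prior box and satisfy the rate constraint, so that
#' recovery checks against it are meaningful. The same truth record (same
#' seed) always yields an identical dataset.
#'
#' @param truth a [TruthRecord-class].
#' @return List with \code{data} (a [DataTable-class] with columns \code{t}
#'   in s and \code{exp_IKr} in nA) and \code{truth} (the record, echoed).
#' @export
generateDataset <- function(truth) {
  stopifnot(is(truth, "TruthRecord"))
  .checkTruthAdmissible(truth)
  total <- protocolDuration(truth@protocol)
  times <- seq(0, total, by = truth@dt)
  clean <- simulateCurrent(truth@params, truth@constants, truth@protocol,
                           times)
  set.seed(truth@seed)
  noisy <- clean@currents + stats::rnorm(length(times), 0, truth@sigma)
  list(data = dataTable(t = times / 1000, exp_IKr = noisy,
                        units = c(t = "s", exp_IKr = "nA")),
       truth = truth)
}

#' Write a complete self-contained fixture to disk
#'
#' Writes \code{data.csv} (the synthetic recording), \code{spec.json} (the
#' fitting specification), \code{protocol.json} (the voltage protocol) and
#' \code{truth.json} (the generating parameters, noise level and seed;
#' synthetic ground truth, not experimental estimates). Re-reading each
#' file reproduces the in-memory object.
#'
#' @param table a [DataTable-class].
#' @param spec a [FittingSpec-class].
#' @param protocol a [VoltageProtocol-class].
#' @param outDir output directory (created if needed).
#' @param truth optional [TruthRecord-class] to record alongside.
#' @return Named character vector of the files written, invisibly.
#' @export
writeFixture <- function(table, spec, protocol, outDir, truth = NULL) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  files <- c(data = file.path(outDir, "data.csv"),
             spec = file.path(outDir, "spec.json"),
             protocol = file.path(outDir, "protocol.json"))
  writeDataTable(table, files[["data"]])
  writeFittingSpec(spec, files[["spec"]])
  writeProtocol(protocol, files[["protocol"]])
  if (!is.null(truth)) {
    files <- c(files, truth = file.path(outDir, "truth.json"))
    jsonlite::write_json(
      list(note = "synthetic ground truth used to generate data.csv",
           params = as.list(unclass(truth@params)), EK = truth@constants@EK,
           sigma = truth@sigma, seed = truth@seed, dt_ms = truth@dt),
      files[["truth"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(files)
}

#' A reduced-budget fitting specification for continuous testing
#'
#' The reference specification of [hergFittingSpec()] with smaller
#' optimiser and sampler budgets, suitable for scaled-down recovery runs:
#' \code{cmaOpt = 2}, \code{cmaMaxFevals = 4000}, \code{burn = 10000},
#' \code{numIters = 20000}.
#'
#' @return A [FittingSpec-class].
#' @export
reducedFittingSpec <- function() {
  spec <- hergFittingSpec()
  spec@arguments <- list(cmaOpt = 2, cmaMaxFevals = 4000,
                         burn = 10000, numIters = 20000)
  spec
}
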