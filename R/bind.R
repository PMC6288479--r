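.MODEL_OUTPUTS <- "IKr"      # named simulation outputs the model exposes
.MODEL_INPUTS <- "exp_times" # named simulation inputs (sample-time grid)
.DEFAULT_UNITS <- c(t = "s") # undeclared current columns default to nA

.resolveUnits <- function(spec, data, cols) {
  u <- tableUnits(data)[cols]
  declared <- spec@units
  u[cols %in% names(declared)] <- declared[cols[cols %in% names(declared)]]
  blank <- !nzchar(u)
  u[blank] <- ifelse(cols[blank] %in% names(.DEFAULT_UNITS),
                     .DEFAULT_UNITS[cols[blank]], "nA")
  stats::setNames(u, cols)
}

#' Bind a fitting specification and data to the model and a protocol
#'
#' Resolves the specification's name maps against the data table: the input
#' map selects the data column providing the simulation sample times
#' (honouring the contract that outputs are generated at exactly the times
#' in the data file), and the output map selects the observed-current
#' column compared against the model output \code{IKr}. Because binding is
#' purely name-based, reordering data columns, or renaming them together
#' with the maps, never changes the bound problem.
#'
#' Units must match the model's internal units, with one narrow exception:
#' a time column declared in seconds is converted to milliseconds (and the
#' conversion logged). Any other unit mismatch is an error.
#'
#' @param spec a [FittingSpec-class].
#' @param data a [DataTable-class].
#' @param constants a [ModelConstants-class].
#' @param protocol a [VoltageProtocol-class].
#' @param constraint a [RateConstraint-class]; default physiological window.
#' @return A [FittingProblem-class].
#' @export
bindProblem <- function(spec, data, constants = modelConstants(),
                        protocol = defaultFixtureProtocol(),
                        constraint = rateConstraint()) {
  stopifnot(is(spec, "FittingSpec"), is(data, "DataTable"),
            is(constants, "ModelConstants"), is(protocol, "VoltageProtocol"))
  df <- tableColumns(data)
  log <- character(0)

  # --- input map: simulation-input name -> data-column name -----------------
  unknownIn <- setdiff(names(spec@inputMap), .MODEL_INPUTS)
  if (length(unknownIn))
    stop("input map names unknown simulation input(s): ",
         paste(unknownIn, collapse = ", "), "; available: ",
         paste(.MODEL_INPUTS, collapse = ", "), call. = FALSE)
  timeCol <- spec@inputMap[["exp_times"]]
  if (!timeCol %in% names(df))
    stop("input map requires data column '", timeCol,
         "' which is absent; available columns: ",
         paste(names(df), collapse = ", "), call. = FALSE)

  # --- output map: data-column name -> model-output name --------------------
  unknownOut <- setdiff(unname(spec@outputMap), .MODEL_OUTPUTS)
  if (length(unknownOut))
    stop("output map names unknown model output(s): ",
         paste(unknownOut, collapse = ", "), "; available: ",
         paste(.MODEL_OUTPUTS, collapse = ", "), call. = FALSE)
  obsCol <- names(spec@outputMap)[spec@outputMap == "IKr"]
  if (length(obsCol) != 1L)
    stop("output map must bind exactly one data column to IKr", call. = FALSE)
  if (!obsCol %in% names(df))
    stop("output map requires data column '", obsCol,
         "' which is absent; available columns: ",
         paste(names(df), collapse = ", "), call. = FALSE)

  units <- .resolveUnits(spec, data, c(timeCol, obsCol))
  times <- df[[timeCol]]
  if (units[[timeCol]] == "s") {
    times <- times * 1000
    log <- c(log, sprintf("time column '%s' converted from s to ms", timeCol))
  } else if (units[[timeCol]] != "ms") {
    stop("unsupported time unit '", units[[timeCol]], "' for column '",
         timeCol, "' (only s and ms are recognised)", call. = FALSE)
  }
  if (units[[obsCol]] != "nA")
    stop("unit mismatch for column '", obsCol, "': data in '", units[[obsCol]],
         "' but the model current is in nA; only the time column is ",
         "auto-converted", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("time column '", timeCol, "' must be strictly increasing",
         call. = FALSE)

  prior <- spec@prior
  pn <- names(prior)
  missPar <- setdiff(c(.RATE_PARAM_NAMES, "obj:std"), pn)
  if (length(missPar))
    stop("prior is missing entr", if (length(missPar) > 1) "ies" else "y",
         " for: ", paste(missPar, collapse = ", "), call. = FALSE)
  unknownPar <- setdiff(pn, c(.RATE_PARAM_NAMES, "obj:std"))
  if (length(unknownPar))
    stop("prior names unknown parameter(s): ",
         paste(unknownPar, collapse = ", "), call. = FALSE)
  isFree <- vapply(prior, function(p) p$type == "uniform", logical(1))
  fixed <- vapply(prior[!isFree], `[[`, numeric(1), "value")
  if (length(fixed) == 0L) fixed <- stats::setNames(numeric(0), character(0))
  if (!any(isFree))
    stop("at least one non-point prior entry is required for inference",
         call. = FALSE)

  new("FittingProblem", constants = constants, protocol = protocol,
      times = as.numeric(times), observed = as.numeric(df[[obsCol]]),
      prior = prior, freeNames = pn[isFree], fixed = fixed,
      sigmaFree = isFree[["obj:std"]], constraint = constraint,
      spec = spec, conversionLog = log)
}

#' Assemble the full model parameter set from a free-parameter vector
#'
#' Combines the free values in \code{theta} (ordered as
#' \code{problem@freeNames}) with the problem's fixed (point-prior) values.
#'
#' @param problem a [FittingProblem-class].
#' @param theta numeric vector of free-parameter values in declaration
#'   order (names optional).
#' @return List with \code{params} (a [RateParameters-class]) and
#'   \code{sigma} (the noise standard deviation).
#' @export
assembleParameters <- function(problem, theta) {
  stopifnot(length(theta) == length(problem@freeNames))
  full <- c(stats::setNames(as.numeric(theta), problem@freeNames),
            problem@fixed)
  list(params = asRateParameters(full[.RATE_PARAM_NAMES]),
       sigma = full[["obj:std"]])
}
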