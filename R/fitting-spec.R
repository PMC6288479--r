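.SUPPORTED_ALGORITHMS <- "AdaptiveMCMC"
.SPEC_REQUIRED_KEYS <- c("algorithm", "arguments", "output", "input", "prior")
.SPEC_OPTIONAL_KEYS <- c("units", "objective")

.parsePriorEntry <- function(name, entry) {
  if (is.numeric(entry) && length(entry) == 1L && is.finite(entry))
    return(list(type = "point", value = as.numeric(entry)))
  if (is.list(entry)) entry <- unlist(entry)
  if (is.numeric(entry) && length(entry) == 2L && all(is.finite(entry))) {
    if (entry[1] >= entry[2])
      stop("prior entry '", name, "': lower bound ", entry[1],
           " is not below upper bound ", entry[2], call. = FALSE)
    return(list(type = "uniform", lower = as.numeric(entry[1]),
                upper = as.numeric(entry[2])))
  }
  stop("prior entry '", name, "' must be a single fixed value (point ",
       "distribution) or a two-membered [lower, upper] list (uniform)",
       call. = FALSE)
}

.checkNameMap <- function(m, what) {
  if (!is.list(m) || length(m) == 0L || is.null(names(m)) ||
      any(!nzchar(names(m))))
    stop("'", what, "' must be a non-empty map of named entries", call. = FALSE)
  vals <- vapply(m, function(x) {
    if (!is.character(x) || length(x) != 1L || !nzchar(x))
      stop("'", what, "' entries must be single non-empty names", call. = FALSE)
    x
  }, character(1))
  vals
}

.validateArguments <- function(algorithm, args) {
  if (identical(algorithm, "AdaptiveMCMC")) {
    need <- c("cmaOpt", "cmaMaxFevals", "burn", "numIters")
    miss <- setdiff(need, names(args))
    if (length(miss))
      stop("AdaptiveMCMC requires argument(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    if (args$burn < 0 || args$numIters <= args$burn)
      stop("AdaptiveMCMC requires numIters > burn >= 0", call. = FALSE)
    if (args$cmaOpt < 1)
      stop("AdaptiveMCMC requires cmaOpt >= 1", call. = FALSE)
    if (args$cmaMaxFevals < 100)
      stop("AdaptiveMCMC requires cmaMaxFevals >= 100", call. = FALSE)
  }
  invisible(TRUE)
}

#' Parse a fitting specification from JSON text
#'
#' The fitting specification is a JSON document with five required entries:
#' \code{algorithm} (an identifier naming the fitting algorithm),
#' \code{arguments} (a map of numeric algorithm arguments), \code{output}
#' (map from data-column names to model-output names), \code{input} (map
#' from simulation-input names to data-column names) and \code{prior} (per
#' parameter, either a two-membered \code{[lower, upper]} list for a uniform
#' prior or a single number for a point distribution). An optional
#' \code{units} entry declares data-column units; an \code{objective} entry
#' is reserved and must be "gaussian" if present. Unknown top-level keys and
#' unknown algorithm identifiers are rejected.
#'
#' @param text a JSON string (or a character vector of lines).
#' @return A validated [FittingSpec-class].
#' @seealso [readFittingSpec()] to parse from a file path.
#' @export
parseFittingSpec <- function(text) {
  doc <- tryCatch(
    jsonlite::fromJSON(paste(text, collapse = "\n"), simplifyVector = FALSE),
    error = function(e) stop("malformed JSON in fitting specification: ",
                             conditionMessage(e), call. = FALSE))
  if (!is.list(doc) || is.null(names(doc)))
    stop("fitting specification must be a JSON object", call. = FALSE)
  miss <- setdiff(.SPEC_REQUIRED_KEYS, names(doc))
  if (length(miss))
    stop("fitting specification is missing required entr",
         if (length(miss) > 1) "ies: " else "y: ",
         paste(miss, collapse = ", "), call. = FALSE)
  unknown <- setdiff(names(doc), c(.SPEC_REQUIRED_KEYS, .SPEC_OPTIONAL_KEYS))
  if (length(unknown))
    stop("unknown top-level entr", if (length(unknown) > 1) "ies: " else "y: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (!is.null(doc$objective) && !identical(doc$objective, "gaussian"))
    stop("'objective' is reserved; only \"gaussian\" is supported",
         call. = FALSE)

  alg <- doc$algorithm
  if (!is.character(alg) || length(alg) != 1L || !nzchar(alg))
    stop("'algorithm' must be a non-empty string", call. = FALSE)
  if (!alg %in% .SUPPORTED_ALGORITHMS)
    stop("unknown algorithm '", alg, "'; supported: ",
         paste(.SUPPORTED_ALGORITHMS, collapse = ", "), call. = FALSE)

  if (!is.list(doc$arguments) || length(doc$arguments) == 0L)
    stop("'arguments' must be a non-empty map", call. = FALSE)
  args <- lapply(doc$arguments, function(a) {
    if (!is.numeric(a) || length(a) != 1L || !is.finite(a))
      stop("every argument value must be a finite number", call. = FALSE)
    as.numeric(a)
  })
  .validateArguments(alg, args)

  outputMap <- .checkNameMap(doc$output, "output")
  inputMap <- .checkNameMap(doc$input, "input")

  if (!is.list(doc$prior) || is.null(names(doc$prior)))
    stop("'prior' must be a map of per-parameter entries", call. = FALSE)
  prior <- mapply(.parsePriorEntry, names(doc$prior), doc$prior,
                  SIMPLIFY = FALSE)

  units <- character(0)
  if (!is.null(doc$units)) units <- .checkNameMap(doc$units, "units")

  new("FittingSpec", algorithm = alg, arguments = args,
      outputMap = outputMap, inputMap = inputMap, prior = prior,
      units = units)
}

#' Read a fitting specification from a JSON file
#'
#' @param path path to the JSON fitting-specification file.
#' @return A validated [FittingSpec-class].
#' @export
readFittingSpec <- function(path)
  parseFittingSpec(readLines(path, warn = FALSE))

#' Serialize a fitting specification back to JSON
#'
#' Writing and re-parsing reproduces the specification field-by-field.
#'
#' @param spec a [FittingSpec-class].
#' @param path optional output file path; when NULL the JSON text is
#'   returned instead.
#' @return \code{path} invisibly, or the JSON text when \code{path} is NULL.
#' @export
writeFittingSpec <- function(spec, path = NULL) {
  stopifnot(is(spec, "FittingSpec"))
  prior <- lapply(spec@prior, function(p)
    if (p$type == "point") p$value else c(p$lower, p$upper))
  doc <- list(algorithm = spec@algorithm, arguments = spec@arguments,
              output = as.list(spec@outputMap), input = as.list(spec@inputMap),
              prior = prior)
  if (length(spec@units)) doc$units <- as.list(spec@units)
  if (is.null(path))
    return(as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                         pretty = TRUE)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Number of free parameters declared by a fitting specification
#'
#' Free parameters are those with a uniform (non-point) prior entry; point
#' entries are fixed constants during fitting.
#'
#' @param spec a [FittingSpec-class].
#' @return Integer count of uniform prior entries.
#' @export
countFreeParameters <- function(spec) {
  stopifnot(is(spec, "FittingSpec"))
  sum(vapply(spec@prior, function(p) identical(p$type, "uniform"), logical(1)))
}

#' The built-in hERG fitting specification
#'
#' The reference fitting document for the nine-parameter hERG model:
#' algorithm "AdaptiveMCMC" with 5 CMA-ES restarts of 20,000 objective
#' evaluations each, 100,000 MCMC iterations with a 50,000-iteration burn-in,
#' output map \code{exp_IKr = IKr}, input map \code{exp_times = t}, uniform
#' priors Uniform(1e-7, 0.1) on the eight kinetic parameters,
#' Uniform(0.0612, 0.612) on GKr, and the observation-noise standard
#' deviation \code{obj:std} fixed at 0.00463.
#'
#' A copy ships as \code{system.file("extdata", "herg_fitting_spec.json",
#' package = "hergfit")}.
#'
#' @return A [FittingSpec-class].
#' @export
hergFittingSpec <- function() {
  prior <- c(
    lapply(stats::setNames(.KINETIC_PARAM_NAMES, .KINETIC_PARAM_NAMES),
           function(nm) list(type = "uniform", lower = 1e-7, upper = 0.1)),
    list(GKr = list(type = "uniform", lower = 0.0612, upper = 0.612),
         "obj:std" = list(type = "point", value = 0.00463)))
  new("FittingSpec", algorithm = "AdaptiveMCMC",
      arguments = list(cmaOpt = 5, cmaMaxFevals = 20000,
                       burn = 50000, numIters = 100000),
      outputMap = c(exp_IKr = "IKr"), inputMap = c(exp_times = "t"),
      prior = prior, units = c(t = "s", exp_IKr = "nA"))
}
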