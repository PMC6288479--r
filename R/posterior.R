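.chainColumn <- function(sample, parameter) {
  cn <- colnames(sample@chain)
  if (is.character(parameter)) {
    if (is.null(cn) || !parameter %in% cn)
      stop("unknown parameter '", parameter, "'",
           if (!is.null(cn)) paste0("; available: ", paste(cn, collapse = ", ")),
           call. = FALSE)
    j <- match(parameter, cn)
  } else j <- as.integer(parameter)
  list(x = sample@chain[, j], j = j,
       name = if (!is.null(cn)) cn[j] else paste0("p", j))
}

#' Maximum posterior density estimate
#'
#' The argmax of the log-posterior over the chain's starting point and
#' every retained iteration; ties are broken by earliest occurrence (the
#' starting point first).
#'
#' @param sample a [PosteriorSample-class].
#' @param theta0 optional starting point overriding the one stored in
#'   \code{sample} (with its log-posterior as attribute
#'   \code{"logPosterior"}; otherwise the stored value is used).
#' @return Named parameter vector with attribute \code{logPosterior}.
#' @export
mapEstimate <- function(sample, theta0 = NULL) {
  stopifnot(is(sample, "PosteriorSample"), nrow(sample@chain) >= 1L)
  if (is.null(theta0)) {
    theta0 <- sample@theta0
    lp0 <- sample@theta0LogPosterior
  } else {
    lp0 <- attr(theta0, "logPosterior")
    if (is.null(lp0)) lp0 <- -Inf
  }
  iBest <- which.max(sample@logPosteriors)   # which.max takes the earliest tie
  lpBest <- sample@logPosteriors[iBest]
  if (length(lp0) == 1L && is.finite(lp0) && lp0 >= lpBest) {
    out <- stats::setNames(as.numeric(theta0), colnames(sample@chain))
    attr(out, "logPosterior") <- lp0
  } else {
    out <- sample@chain[iBest, ]
    attr(out, "logPosterior") <- lpBest
  }
  out
}

#' Equal-tailed credible interval from the retained chain
#'
#' Empirical quantiles at (1 - level)/2 and 1 - (1 - level)/2, using linear
#' interpolation between order statistics (R quantile type 7).
#'
#' @param sample a [PosteriorSample-class].
#' @param parameter parameter name (or column index).
#' @param level interval mass in (0, 1).
#' @return Numeric \code{c(lo, hi)}.
#' @export
credibleInterval <- function(sample, parameter, level = 0.95) {
  stopifnot(level > 0, level < 1)
  col <- .chainColumn(sample, parameter)
  a <- (1 - level) / 2
  unname(stats::quantile(col$x, c(a, 1 - a), type = 7, names = FALSE))
}

.smoothCounts <- function(counts) {
  # moving average over 3 bins, shrinking to the available window at edges
  n <- length(counts)
  vapply(seq_len(n), function(i) {
    w <- max(1, i - 1):min(n, i + 1)
    mean(counts[w])
  }, numeric(1))
}

.histogramOn <- function(x, bins) {
  rng <- range(x)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)  # degenerate column
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE, right = FALSE,
                      include.lowest = TRUE)
  # with right = FALSE the last bin is closed on both sides, so every
  # sample (including the maximum) is counted exactly once
  list(breaks = h$breaks, counts = h$counts)
}

.modalityFlags <- function(x, counts, breaks, priorLo, priorHi,
                           ciLo, ciHi, flatFraction, modeFraction) {
  sm <- .smoothCounts(counts)
  n <- length(sm)
  isPeak <- vapply(seq_len(n), function(i) {
    left <- if (i > 1) sm[i] > sm[i - 1] else sm[i] > 0
    right <- if (i < n) sm[i] >= sm[i + 1] else TRUE
    if (i > 1 && sm[i] == sm[i - 1]) left <- FALSE  # plateaus count once
    left && right
  }, logical(1))
  cand <- which(isPeak & sm > modeFraction * max(sm))
  # distinct modes must be separated by a real valley: merge candidate
  # peaks whose intervening minimum stays above half the smaller peak
  # (sampling noise puts shallow wiggles on any finite-chain histogram)
  while (length(cand) > 1L) {
    merged <- FALSE
    for (j in seq_len(length(cand) - 1L)) {
      a <- cand[j]; b <- cand[j + 1L]
      valley <- min(sm[a:b])
      if (valley > 0.5 * min(sm[a], sm[b])) {
        cand <- cand[-(if (sm[a] >= sm[b]) j + 1L else j)]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  multimodal <- length(cand) > 1L
  flat <- if (is.finite(priorLo) && is.finite(priorHi) && priorHi > priorLo)
    (ciHi - ciLo) > flatFraction * (priorHi - priorLo)
  else FALSE
  list(multimodal = multimodal, flat = flat,
       mode = mean(breaks[which.max(sm) + 0:1]))
}

#' Marginal posterior histogram and summary for one parameter
#'
#' Histogram over the retained samples (default 50 equal-width bins over
#' the sample range), together with the sample mean, standard deviation,
#' equal-tailed credible interval, a smoothed-histogram mode estimate, and
#' the identifiability flags of [identifiabilityFlags()].
#'
#' @param sample a [PosteriorSample-class].
#' @param parameter parameter name (or column index).
#' @param bins number of histogram bins (>= 2).
#' @param ciLevel credible-interval mass.
#' @param flatFraction,modeFraction flag thresholds, see
#'   [identifiabilityFlags()].
#' @return A [MarginalSummary-class].
#' @export
marginalHistogram <- function(sample, parameter, bins = 50, ciLevel = 0.95,
                              flatFraction = 0.8, modeFraction = 0.2) {
  stopifnot(bins >= 2)
  col <- .chainColumn(sample, parameter)
  h <- .histogramOn(col$x, bins)
  ci <- credibleInterval(sample, parameter, ciLevel)
  pLo <- if (length(sample@priorLower)) sample@priorLower[col$j] else NA_real_
  pHi <- if (length(sample@priorUpper)) sample@priorUpper[col$j] else NA_real_
  fl <- .modalityFlags(col$x, h$counts, h$breaks, pLo, pHi, ci[1], ci[2],
                       flatFraction, modeFraction)
  new("MarginalSummary", parameter = col$name, breaks = h$breaks,
      counts = as.numeric(h$counts), mean = mean(col$x),
      sd = stats::sd(col$x), ciLevel = ciLevel, ciLower = ci[1],
      ciUpper = ci[2], mode = fl$mode,
      flags = list(multimodal = fl$multimodal, flat = fl$flat))
}

#' Per-parameter identifiability flags
#'
#' Operational versions of the qualitative criteria used to judge whether
#' the data constrain each parameter: \code{flat} when the 95\% credible
#' interval is wider than \code{flatFraction} (default 80\%) of the prior
#' range, and \code{multimodal} when the 3-bin-smoothed histogram has more
#' than one local maximum exceeding \code{modeFraction} (default 20\%) of
#' the global maximum, with distinct maxima required to be separated by a
#' valley dropping below half the smaller peak (so the sampling wiggle of
#' a finite chain's histogram does not count as extra modes). Either flag
#' suggests the experiment does not provide
#' enough information to uniquely constrain that parameter. Thresholds are
#' heuristics and are reported alongside the raw marginals.
#'
#' @param sample a [PosteriorSample-class] with at least 1000 retained
#'   iterations.
#' @param bins histogram bins used for mode counting.
#' @param ciLevel credible-interval mass for the flatness rule.
#' @param flatFraction,modeFraction flag thresholds.
#' @return data.frame with one row per parameter: \code{parameter},
#'   \code{multimodal}, \code{flat}, \code{ciWidth}, \code{priorWidth}.
#' @export
identifiabilityFlags <- function(sample, bins = 50, ciLevel = 0.95,
                                 flatFraction = 0.8, modeFraction = 0.2) {
  stopifnot(is(sample, "PosteriorSample"))
  if (nrow(sample@chain) < 1000L)
    stop("retained chain too short for identifiability flags ",
         "(need >= 1000 iterations)", call. = FALSE)
  d <- ncol(sample@chain)
  rows <- lapply(seq_len(d), function(j) {
    ms <- marginalHistogram(sample, j, bins = bins, ciLevel = ciLevel,
                            flatFraction = flatFraction,
                            modeFraction = modeFraction)
    pw <- if (length(sample@priorUpper))
      sample@priorUpper[j] - sample@priorLower[j] else NA_real_
    data.frame(parameter = ms@parameter, multimodal = ms@flags$multimodal,
               flat = ms@flags$flat, ciWidth = ms@ciUpper - ms@ciLower,
               priorWidth = pw)
  })
  do.call(rbind, rows)
}

#' Overlay of observed and model-predicted currents
#'
#' Simulates the model at the problem's bound sample times under a given
#' parameter vector and aligns prediction with observation, the standard
#' visual check that a maximum-posterior-density fit captures the recorded
#' trace.
#'
#' @param problem a [FittingProblem-class].
#' @param theta free-parameter vector.
#' @return data.frame with columns \code{time} (ms), \code{observed} and
#'   \code{predicted} (nA), with attributes \code{rmse} and
#'   \code{residualSummary}.
#' @export
predictionOverlay <- function(problem, theta) {
  ap <- assembleParameters(problem, theta)
  pred <- simulateCurrent(ap$params, problem@constants, problem@protocol,
                          problem@times)
  out <- data.frame(time = problem@times, observed = problem@observed,
                    predicted = pred@currents)
  r <- out$observed - out$predicted
  attr(out, "rmse") <- sqrt(mean(r^2))
  attr(out, "residualSummary") <- summary(r)
  out
}
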