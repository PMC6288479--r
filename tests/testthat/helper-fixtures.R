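# Shared fixtures and small oracles used across the suite.

# Draw n parameter sets uniformly from the reference prior box.
drawPriorParams <- function(n, seed) {
  spec <- hergFittingSpec()
  lo <- vapply(spec@prior[hergfit:::.RATE_PARAM_NAMES], `[[`, numeric(1), "lower")
  hi <- vapply(spec@prior[hergfit:::.RATE_PARAM_NAMES], `[[`, numeric(1), "upper")
  set.seed(seed)
  m <- matrix(runif(n * 9, lo, hi), ncol = 9, byrow = TRUE)
  colnames(m) <- names(lo)
  m
}

# A small bound problem on synthetic data at a coarse sampling interval.
makeToyProblem <- function(dt = 10, sigma = 0.00463, seed = 101,
                           protocol = defaultFixtureProtocol()) {
  truth <- truthRecord(defaultTruth()@params, protocol = protocol,
                       sigma = sigma, seed = seed, dt = dt)
  ds <- generateDataset(truth)
  spec <- reducedFittingSpec()
  problem <- bindProblem(spec, ds$data, protocol = protocol)
  list(problem = problem, truth = truth,
       truthTheta = unclass(truth@params)[problem@freeNames])
}

# Effective sample size from the empirical autocorrelation (initial positive
# sequence): n / (1 + 2 * sum of positive-lag autocorrelations).
effectiveSize <- function(x) {
  n <- length(x)
  rho <- stats::acf(x, lag.max = min(n - 1, 1000), plot = FALSE)$acf[-1]
  upto <- which(rho < 0)[1]
  if (!is.na(upto)) rho <- rho[seq_len(upto - 1)]
  n / (1 + 2 * sum(rho))
}

tableSpecJSON <- function() {
  readLines(system.file("extdata", "herg_fitting_spec.json", package = "hergfit"))
}
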