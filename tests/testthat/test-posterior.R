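# build a PosteriorSample directly for summary-level tests
fakeSample <- function(chain, lps = NULL, theta0 = NULL, lp0 = -Inf,
                       lower = NULL, upper = NULL) {
  chain <- as.matrix(chain)
  if (is.null(lps)) lps <- rep(0, nrow(chain))
  if (is.null(theta0)) theta0 <- chain[1, ]
  if (is.null(lower)) lower <- rep(-Inf, ncol(chain))
  if (is.null(upper)) upper <- rep(Inf, ncol(chain))
  new("PosteriorSample", chain = chain, logPosteriors = lps,
      acceptanceRate = 0.3, seed = 1L, arguments = list(),
      theta0 = as.numeric(theta0), theta0LogPosterior = lp0,
      priorLower = lower, priorUpper = upper)
}

test_that("the MAP estimate is the argmax over start point and chain", {
  ch <- matrix(c(1, 2, 3), ncol = 1, dimnames = list(NULL, "a"))
  s <- fakeSample(ch, lps = c(-5, -2, -9), theta0 = 0, lp0 = -4)
  expect_equal(as.numeric(mapEstimate(s)), 2)
  expect_equal(attr(mapEstimate(s), "logPosterior"), -2)
  # theta0 better than every chain point
  s2 <- fakeSample(ch, lps = c(-5, -2, -9), theta0 = 0, lp0 = -1)
  expect_equal(as.numeric(mapEstimate(s2)), 0)
  # brute-force scan oracle on a random chain
  set.seed(9)
  lps <- rnorm(200)
  s3 <- fakeSample(matrix(rnorm(200), ncol = 1), lps = lps, lp0 = -Inf)
  expect_equal(attr(mapEstimate(s3), "logPosterior"), max(lps))
  expect_equal(as.numeric(mapEstimate(s3)), unname(chain(s3)[which.max(lps), 1]))
  # ties break to the earliest occurrence
  s4 <- fakeSample(ch, lps = c(-2, -2, -9), theta0 = 0, lp0 = -7)
  expect_equal(as.numeric(mapEstimate(s4)), 1)
})

test_that("credible intervals follow the interpolated-quantile rule", {
  s <- fakeSample(matrix(1:100, ncol = 1, dimnames = list(NULL, "x")))
  ci <- credibleInterval(s, "x", 0.9)
  expect_equal(ci, c(5.95, 95.05))   # type-7 quantiles of 1..100
  # degenerate column collapses to a point
  sd <- fakeSample(matrix(rep(3.2, 50), ncol = 1, dimnames = list(NULL, "x")))
  expect_equal(credibleInterval(sd, "x", 0.9), c(3.2, 3.2))
  # widening the level widens the interval
  set.seed(4)
  sr <- fakeSample(matrix(rnorm(5000), ncol = 1, dimnames = list(NULL, "x")))
  w <- vapply(c(0.5, 0.9, 0.99), function(l)
    diff(credibleInterval(sr, "x", l)), numeric(1))
  expect_true(all(diff(w) > 0))
  expect_error(credibleInterval(sr, "nope"), "unknown parameter")
})

test_that("marginal histograms conserve counts and summarise correctly", {
  set.seed(8)
  n <- 1e5
  u <- matrix(runif(n), ncol = 1, dimnames = list(NULL, "u"))
  s <- fakeSample(u, lower = 0, upper = 1)
  for (bins in c(10, 50)) {
    ms <- marginalHistogram(s, "u", bins = bins)
    expect_length(ms@counts, bins)
    expect_equal(sum(ms@counts), n)
  }
  # uniform column: each of 10 bins within 5 binomial SD of n/10
  ms <- marginalHistogram(s, "u", bins = 10)
  sdBin <- sqrt(n * 0.1 * 0.9)
  expect_true(all(abs(ms@counts - n / 10) < 5 * sdBin))
  # degenerate column: single occupied bin, zero spread
  sd <- fakeSample(matrix(rep(2.5, 2000), ncol = 1,
                          dimnames = list(NULL, "c")))
  msd <- marginalHistogram(sd, "c")
  expect_equal(sum(msd@counts > 0), 1)
  expect_equal(msd@sd, 0)
  expect_equal(c(msd@ciLower, msd@ciUpper), c(2.5, 2.5))
})

test_that("identifiability flags implement the flat and multimodal rules", {
  set.seed(15)
  n <- 20000
  # spread over the whole prior range: flat
  flat <- fakeSample(matrix(runif(n), ncol = 1, dimnames = list(NULL, "p")),
                     lower = 0, upper = 1)
  expect_true(identifiabilityFlags(flat)$flat)
  # tight unimodal Gaussian well inside the prior: neither flag
  tight <- fakeSample(matrix(rnorm(n, 0.5, 0.01), ncol = 1,
                             dimnames = list(NULL, "p")),
                      lower = 0, upper = 1)
  fl <- identifiabilityFlags(tight)
  expect_false(fl$flat); expect_false(fl$multimodal)
  # balanced, well-separated mixture: multimodal
  mix <- fakeSample(matrix(c(rnorm(n / 2, 0.2, 0.02),
                             rnorm(n / 2, 0.8, 0.02)), ncol = 1,
                           dimnames = list(NULL, "p")),
                    lower = 0, upper = 1)
  expect_true(identifiabilityFlags(mix)$multimodal)
  # chains shorter than 1000 are refused
  short <- fakeSample(matrix(rnorm(500), ncol = 1, dimnames = list(NULL, "p")))
  expect_error(identifiabilityFlags(short), "1000")
})

test_that("prediction overlays align and quantify fit quality", {
  # noise-free data at the truth: RMSE exactly 0
  tp0 <- makeToyProblem(dt = 10, sigma = 1e-12)
  ov0 <- predictionOverlay(tp0$problem, tp0$truthTheta)
  expect_equal(nrow(ov0), length(tp0$problem@times))
  expect_lt(attr(ov0, "rmse"), 1e-9)
  # noisy data at the truth: RMSE concentrates near sigma (chi-square)
  tp <- makeToyProblem(dt = 1.2, sigma = 0.00463)   # ~1e4 samples
  ov <- predictionOverlay(tp$problem, tp$truthTheta)
  expect_lt(abs(attr(ov, "rmse") - 0.00463) / 0.00463, 0.1)
  expect_identical(ov$observed, tp$problem@observed)
})
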