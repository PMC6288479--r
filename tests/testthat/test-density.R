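threePointProblem <- function(residuals = c(0.01, -0.02, 0)) {
  prot <- voltageProtocol(holdSegment(-80, 10))
  truth <- defaultTruth()@params
  tt <- c(1, 2, 3)
  clean <- simulateCurrent(truth, modelConstants(), prot, tt)
  tbl <- dataTable(t = tt / 1000, exp_IKr = clean@currents + residuals,
                   units = c(t = "s", exp_IKr = "nA"))
  list(problem = bindProblem(hergFittingSpec(), tbl, protocol = prot),
       theta = unclass(truth))
}

test_that("the Gaussian log-likelihood matches its closed form", {
  s <- 0.00463
  tp <- threePointProblem(residuals = c(0, 0, 0))
  theta <- tp$theta[tp$problem@freeNames]
  # zero residuals: only the normalisation term remains
  expect_equal(logLikelihood(tp$problem, theta), -3 / 2 * log(2 * pi * s^2),
               tolerance = 1e-12)
  # hand-evaluated toy case, cross-checked against dnorm as the oracle
  r <- c(0.01, -0.02, 0)
  tp2 <- threePointProblem(residuals = r)
  expected <- sum(stats::dnorm(r, mean = 0, sd = s, log = TRUE))
  expect_equal(logLikelihood(tp2$problem, theta), expected, tolerance = 1e-12)
})

test_that("log-likelihood decreases when sigma shrinks under large residuals", {
  # residual sum of squares far above n*sigma^2: smaller sigma is worse
  tp <- threePointProblem(residuals = c(0.1, -0.1, 0.1))
  spec <- hergFittingSpec()
  spec@prior[["obj:std"]] <- list(type = "uniform", lower = 1e-4, upper = 0.1)
  prot <- tp$problem@protocol
  tbl <- dataTable(t = tp$problem@times / 1000, exp_IKr = tp$problem@observed,
                   units = c(t = "s", exp_IKr = "nA"))
  prob <- bindProblem(spec, tbl, protocol = prot)
  sigmas <- c(0.05, 0.02, 0.01, 0.005)
  lls <- vapply(sigmas, function(s)
    logLikelihood(prob, c(tp$theta[hergfit:::.RATE_PARAM_NAMES], s)),
    numeric(1))
  expect_true(all(diff(lls) < 0))
})

test_that("the uniform prior is constant inside the box and -Inf outside", {
  spec <- hergFittingSpec()
  cons <- rateConstraint()
  theta <- unclass(defaultTruth()@params)
  widths <- c(rep(0.1 - 1e-7, 8), 0.612 - 0.0612)
  expect_equal(logPrior(spec@prior, cons, theta), -sum(log(widths)))
  thetaHigh <- theta; thetaHigh[["GKr"]] <- 0.7      # above the 0.612 bound
  expect_identical(logPrior(spec@prior, cons, thetaHigh), -Inf)
  thetaLow <- theta; thetaLow[["kO1"]] <- 0          # at/below the lower bound
  expect_identical(logPrior(spec@prior, cons, thetaLow), -Inf)
})

test_that("non-physiological rates get zero prior probability", {
  spec <- hergFittingSpec()
  cons <- rateConstraint()
  theta <- unclass(defaultTruth()@params)
  # kC explodes at -120 mV: 0.09 * exp(0.1 * 120) > 1000 ms^-1, box-bounds hold
  thetaFast <- theta; thetaFast[["kC1"]] <- 0.09; thetaFast[["kC2"]] <- 0.1
  expect_gt(0.09 * exp(0.1 * 120), 1000)
  expect_identical(logPrior(spec@prior, cons, thetaFast), -Inf)
  expect_false(satisfiesRateConstraint(asRateParameters(thetaFast), cons))
  # kO negligible everywhere in the range: below the minimum-rate floor
  thetaSlow <- theta; thetaSlow[["kO1"]] <- 2e-7; thetaSlow[["kO2"]] <- 1e-6
  expect_lt(2e-7 * exp(1e-6 * 60), 1.67e-5)
  expect_identical(logPrior(spec@prior, cons, thetaSlow), -Inf)
  # the default truth satisfies the constraint
  expect_true(satisfiesRateConstraint(defaultTruth()@params, cons))
})

test_that("log-posterior is prior + likelihood and short-circuits off-support", {
  tp <- threePointProblem()
  prob <- tp$problem
  box <- priorBox(prob)
  set.seed(42)
  for (i in 1:10) {
    theta <- box$lower + runif(9) * (box$upper - box$lower)
    lp <- logPrior(prob@prior, prob@constraint, theta)
    expected <- if (is.finite(lp)) lp + logLikelihood(prob, theta) else -Inf
    expect_equal(logPosterior(prob, theta), expected)
  }
  # off-support points never reach the simulator
  calls <- 0L
  local_mocked_bindings(
    simulateCurrent = function(...) { calls <<- calls + 1L;
      stop("should not simulate") },
    .package = "hergfit")
  bad <- box$upper * 2
  expect_identical(logPosterior(prob, bad), -Inf)
  expect_identical(calls, 0L)
})
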