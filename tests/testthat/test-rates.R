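test_that("rate evaluation follows the exponential voltage dependence", {
  p <- rateParameters(kO1 = 2e-3, kO2 = 0.05, kC1 = 1e-2, kC2 = 0.03,
                      kI1 = 3e-2, kI2 = 0.01, kA1 = 4e-3, kA2 = 0.02,
                      GKr = 0.2)
  # at 0 mV every rate equals its prefactor
  expect_equal(evaluateRates(p, 0),
               c(kO = 2e-3, kC = 1e-2, kI = 3e-2, kA = 4e-3))
  # scalar-arithmetic oracles at nonzero voltage
  r20 <- evaluateRates(p, 20)
  expect_equal(r20[["kO"]], 2e-3 * exp(1), tolerance = 1e-12)
  rm40 <- evaluateRates(p, -40)
  expect_equal(rm40[["kC"]], 1e-2 * exp(1.2), tolerance = 1e-12)
  # backward rates decrease with voltage, forward rates increase
  expect_true(r20[["kC"]] < 1e-2 && r20[["kA"]] < 4e-3)
  expect_true(r20[["kO"]] > 2e-3 && r20[["kI"]] > 3e-2)
})

test_that("overflowing exponents are rejected as invalid combinations", {
  p <- defaultTruth()@params
  expect_error(evaluateRates(p, 1e6), "exponent")
})

test_that("rate parameters enforce positivity, finiteness and naming", {
  expect_error(rateParameters(0, 1, 1, 1, 1, 1, 1, 1, 1), "positive")
  expect_error(rateParameters(Inf, 1, 1, 1, 1, 1, 1, 1, 1), "finite")
  expect_error(asRateParameters(c(a = 1)), "named vector")
  # coercion reorders a permuted named vector correctly
  v <- unclass(defaultTruth()@params)
  p2 <- asRateParameters(rev(v))
  expect_equal(unclass(p2), v)
})

test_that("state derivatives match the Markov transition equations", {
  rates <- c(kO = 0.7, kC = 0.3, kI = 0.2, kA = 0.9)
  # hand substitution with O = 1, all rates equal k
  k <- 0.25
  d <- stateDerivatives(gatingState(1, 0, 0),
                        c(kO = k, kC = k, kI = k, kA = k))
  expect_equal(d, c(dO = -2 * k, dC = k, dIO = k))
  # derivatives vanish at the analytic steady state
  ss <- steadyState(rates)
  expect_lt(max(abs(stateDerivatives(ss, rates))), 1e-12)
  # total occupancy is conserved for arbitrary states
  set.seed(7)
  for (i in 1:20) {
    x <- runif(3); x <- x / sum(x) * runif(1)
    st <- gatingState(x[1], x[2], x[3])
    r <- stats::setNames(runif(4, 0.01, 2), c("kO", "kC", "kI", "kA"))
    dv <- stateDerivatives(st, r)
    # conservation: the implied dIC/dt (from the IC transition balance)
    # must cancel the sum of the three explicit derivatives
    s <- occupancies(st)
    dIC <- r[["kI"]] * s[["C"]] + r[["kC"]] * s[["IO"]] -
      (r[["kO"]] + r[["kA"]]) * s[["IC"]]
    expect_equal(unname(sum(dv) + dIC), 0, tolerance = 1e-14)
  }
})

test_that("steady state is the fixed point of the gating dynamics", {
  # symmetric rates occupy all four states equally
  ss <- steadyState(c(kO = 0.4, kC = 0.4, kI = 0.8, kA = 0.8))
  expect_equal(unname(occupancies(ss)), rep(0.25, 4))
  # strongly activated and recovered: everything open
  ss2 <- steadyState(c(kO = 100, kC = 1e-4, kI = 1e-4, kA = 100))
  expect_gt(occupancies(ss2)[["O"]], 0.999)
  # random positive rates: derivative sup-norm < 1e-12 at the fixed point
  set.seed(11)
  for (i in 1:50) {
    r <- stats::setNames(exp(runif(4, -8, 4)), c("kO", "kC", "kI", "kA"))
    expect_lt(max(abs(stateDerivatives(steadyState(r), r))), 1e-12)
  }
})

test_that("closed-form constant-voltage solution has the right endpoints", {
  p <- defaultTruth()@params
  init <- steadyState(evaluateRates(p, -80))
  sol0 <- analyticConstantVoltageSolution(p, 20, init, 0)
  expect_equal(as.numeric(sol0[1, 1:3]), as.numeric(occupancies(init)[1:3]),
               tolerance = 1e-12)
  solInf <- analyticConstantVoltageSolution(p, 20, init, 1e7)
  ssTarget <- occupancies(steadyState(evaluateRates(p, 20)))
  expect_equal(as.numeric(solInf[1, ]), as.numeric(ssTarget),
               tolerance = 1e-10)
})

test_that("closed form agrees with independent numerical ODE integration", {
  # generic (non-compiled) ODE of the full 4-state system as the oracle
  p <- defaultTruth()@params
  v <- 0
  rates <- evaluateRates(p, v)
  rhs <- function(t, y, parms) {
    d <- stateDerivatives(gatingState(y[1], y[2], y[3]), rates)
    list(unname(d))
  }
  init <- steadyState(evaluateRates(p, -80))
  tt <- seq(0, 300, 1)
  num <- deSolve::lsoda(unclass(init), tt, rhs, NULL,
                        rtol = 1e-10, atol = 1e-12)
  ana <- analyticConstantVoltageSolution(p, v, init, tt)
  expect_lt(max(abs(num[, 2:4] - ana[, 1:3])), 1e-6)
})

test_that("non-factorisable initial states are rejected by the oracle", {
  bad <- gatingState(0.5, 0.1, 0.4)  # O*IC != C*IO
  expect_error(analyticConstantVoltageSolution(defaultTruth()@params, 0,
                                               bad, 0:10),
               "inapplicable")
})
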