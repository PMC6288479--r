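test_that("the default truth is admissible for recovery studies", {
  truth <- defaultTruth()
  spec <- hergFittingSpec()
  p <- unclass(truth@params)
  for (nm in names(p)) {
    pr <- spec@prior[[nm]]
    expect_gt(p[[nm]], pr$lower)
    expect_lt(p[[nm]], pr$upper)
  }
  expect_true(satisfiesRateConstraint(truth@params))
  # each rate's maximum over the voltage range is inside the window
  cons <- rateConstraint()
  mx <- pmax(evaluateRates(truth@params, cons@vLow),
             evaluateRates(truth@params, cons@vHigh))
  expect_true(all(mx >= cons@rateMin & mx <= cons@rateMax))
  # prior density at the truth is finite
  expect_true(is.finite(logPrior(spec@prior, cons, p)))
  # signal-to-noise of the noise-free fixture trace is comfortably high
  tr <- simulateCurrent(truth@params, truth@constants, truth@protocol,
                        seq(0, 12000, 10))
  expect_gt(stats::sd(tr@currents) / truth@sigma, 20)
})

test_that("synthetic data is the clean trace plus the declared noise", {
  truth <- defaultTruth()
  # noise-free generation equals the simulation exactly
  t0 <- truthRecord(truth@params, sigma = 0, dt = 20)
  ds0 <- generateDataset(t0)
  clean <- simulateCurrent(truth@params, truth@constants, truth@protocol,
                           seq(0, 12000, 20))
  expect_identical(tableColumns(ds0$data)$exp_IKr, clean@currents)
  expect_equal(tableColumns(ds0$data)$t, seq(0, 12000, 20) / 1000)
  # with noise: empirical residual moments match sigma (n > 1e5)
  t1 <- defaultTruth()   # dt = 0.1 ms -> 120001 rows
  ds1 <- generateDataset(t1)
  df <- tableColumns(ds1$data)
  expect_equal(nrow(df), 120001)
  clean1 <- simulateCurrent(t1@params, t1@constants, t1@protocol,
                            seq(0, 12000, 0.1))
  resid <- df$exp_IKr - clean1@currents
  n <- length(resid)
  expect_lt(abs(mean(resid)), 4 * t1@sigma / sqrt(n))
  expect_lt(abs(sd(resid) - t1@sigma) / t1@sigma, 0.05)
  expect_lt(abs(var(resid) - t1@sigma^2) / t1@sigma^2, 0.05)
})

test_that("generation is deterministic in the seed and binder-compatible", {
  a <- generateDataset(defaultTruth())
  b <- generateDataset(defaultTruth())
  expect_identical(tableColumns(a$data), tableColumns(b$data))
  other <- truthRecord(defaultTruth()@params, seed = 999)
  c3 <- generateDataset(other)
  expect_false(identical(tableColumns(a$data)$exp_IKr,
                         tableColumns(c3$data)$exp_IKr))
  # generated data always satisfies the binder's preconditions
  prob <- bindProblem(hergFittingSpec(), a$data)
  expect_equal(length(prob@times), 120001)
  expect_true(all(diff(prob@times) > 0))
})

test_that("inadmissible truths are refused", {
  bad <- defaultTruth()
  p <- unclass(bad@params)
  p[["GKr"]] <- 0.7                      # outside the prior box
  expect_error(generateDataset(truthRecord(p)), "prior box")
  p2 <- unclass(defaultTruth()@params)
  p2[["kC1"]] <- 0.09; p2[["kC2"]] <- 0.099   # kC explodes at -120 mV
  expect_error(generateDataset(truthRecord(p2)), "rate constraint")
})

test_that("fixture files round-trip and use the documented layout", {
  dir <- withr::local_tempdir()
  truth <- truthRecord(defaultTruth()@params, dt = 50)
  ds <- generateDataset(truth)
  spec <- reducedFittingSpec()
  files <- writeFixture(ds$data, spec, truth@protocol, dir, truth = truth)
  expect_true(all(file.exists(files)))
  expect_identical(readLines(files[["data"]], n = 1), "t,exp_IKr")
  backSpec <- readFittingSpec(files[["spec"]])
  expect_equal(backSpec, spec)
  backData <- readDataTable(files[["data"]],
                            units = c(t = "s", exp_IKr = "nA"))
  expect_equal(tableColumns(backData), tableColumns(ds$data))
  backProt <- readProtocol(files[["protocol"]])
  grid <- seq(0, 12000, 0.5)
  expect_identical(voltageAt(backProt, grid), voltageAt(truth@protocol, grid))
  # same seed, same bytes
  dir2 <- withr::local_tempdir()
  files2 <- writeFixture(ds$data, spec, truth@protocol, dir2, truth = truth)
  for (k in names(files))
    expect_identical(readLines(files[[k]]), readLines(files2[[k]]))
  # the emitted spec passes validation (parse implies validity)
  expect_s4_class(backSpec, "FittingSpec")
})
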