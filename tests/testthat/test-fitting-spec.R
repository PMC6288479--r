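test_that("the reference hERG fitting document parses to the expected spec", {
  spec <- parseFittingSpec(tableSpecJSON())
  expect_s4_class(spec, "FittingSpec")
  expect_identical(spec@algorithm, "AdaptiveMCMC")
  expect_equal(spec@arguments,
               list(cmaOpt = 5, cmaMaxFevals = 20000,
                    burn = 50000, numIters = 100000))
  expect_identical(spec@outputMap, c(exp_IKr = "IKr"))
  expect_identical(spec@inputMap, c(exp_times = "t"))
  expect_equal(countFreeParameters(spec), 9)
  expect_equal(spec@prior[["obj:std"]], list(type = "point", value = 0.00463))
  expect_equal(spec@prior[["GKr"]],
               list(type = "uniform", lower = 0.0612, upper = 0.612))
  for (nm in c("kO1", "kO2", "kC1", "kC2", "kI1", "kI2", "kA1", "kA2"))
    expect_equal(spec@prior[[nm]],
                 list(type = "uniform", lower = 1e-7, upper = 0.1))
  # the file and the built-in constructor agree
  expect_equal(spec, hergFittingSpec())
})

test_that("malformed fitting documents are rejected with clear messages", {
  ok <- jsonlite::fromJSON(paste(tableSpecJSON(), collapse = "\n"),
                           simplifyVector = FALSE)
  noPrior <- ok; noPrior$prior <- NULL
  expect_error(parseFittingSpec(jsonlite::toJSON(noPrior, auto_unbox = TRUE)),
               "prior")
  badBounds <- ok; badBounds$prior$kO1 <- list(0.1, 1e-7)
  expect_error(parseFittingSpec(jsonlite::toJSON(badBounds, auto_unbox = TRUE)),
               "lower bound")
  badEntry <- ok; badEntry$prior$kO1 <- list(1, 2, 3)
  expect_error(parseFittingSpec(jsonlite::toJSON(badEntry, auto_unbox = TRUE)),
               "two-membered")
  unknownKey <- ok; unknownKey$extra <- 1
  expect_error(parseFittingSpec(jsonlite::toJSON(unknownKey, auto_unbox = TRUE)),
               "unknown top-level")
  badAlg <- ok; badAlg$algorithm <- "NestedSampling"
  expect_error(parseFittingSpec(jsonlite::toJSON(badAlg, auto_unbox = TRUE)),
               "AdaptiveMCMC")  # error lists the supported algorithms
  badObj <- ok; badObj$objective <- "huber"
  expect_error(parseFittingSpec(jsonlite::toJSON(badObj, auto_unbox = TRUE)),
               "gaussian")
  expect_error(parseFittingSpec("{not json"), "malformed")
})

test_that("algorithm arguments are validated per algorithm", {
  ok <- jsonlite::fromJSON(paste(tableSpecJSON(), collapse = "\n"),
                           simplifyVector = FALSE)
  bad <- ok; bad$arguments$burn <- 200000
  expect_error(parseFittingSpec(jsonlite::toJSON(bad, auto_unbox = TRUE)),
               "numIters > burn")
  bad <- ok; bad$arguments$cmaOpt <- 0
  expect_error(parseFittingSpec(jsonlite::toJSON(bad, auto_unbox = TRUE)),
               "cmaOpt")
  bad <- ok; bad$arguments$cmaMaxFevals <- 10
  expect_error(parseFittingSpec(jsonlite::toJSON(bad, auto_unbox = TRUE)),
               "cmaMaxFevals")
  bad <- ok; bad$arguments$numIters <- NULL
  expect_error(parseFittingSpec(jsonlite::toJSON(bad, auto_unbox = TRUE)),
               "numIters")
})

test_that("free-parameter counting distinguishes uniform from point priors", {
  spec <- hergFittingSpec()
  expect_equal(countFreeParameters(spec), 9)
  allPoint <- spec
  allPoint@prior <- lapply(spec@prior, function(p)
    if (p$type == "point") p else list(type = "point", value = p$lower))
  expect_equal(countFreeParameters(allPoint), 0)
  freeSigma <- spec
  freeSigma@prior[["obj:std"]] <- list(type = "uniform",
                                       lower = 1e-4, upper = 1e-2)
  expect_equal(countFreeParameters(freeSigma), 10)
})

test_that("serialising and re-parsing a spec is the identity", {
  spec <- hergFittingSpec()
  expect_equal(parseFittingSpec(writeFittingSpec(spec)), spec)
  f <- withr::local_tempfile(fileext = ".json")
  writeFittingSpec(spec, f)
  expect_equal(readFittingSpec(f), spec)
})
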