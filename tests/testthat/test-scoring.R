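canonical_registry <- defaultRegistry()

test_that("MMS is the signed sum of indicators", {
  reg <- canonical_registry
  nm <- parameterNames(reg)
  zero <- setNames(rep(0, 18), nm)
  expect_identical(unname(computeMMS(zero, reg)), 0L)
  # only the conserved-substitution indicator: -1, clamped to 0
  onlyCons <- zero; onlyCons["conserved_substitution"] <- 1
  expect_identical(unname(computeMMS(onlyCons, reg)), -1L)
  expect_identical(unname(computeMMS(onlyCons, reg, clamp = TRUE)), 0L)
  # all 17 positive parameters
  allPos <- setNames(rep(1, 18), nm); allPos["conserved_substitution"] <- 0
  expect_identical(unname(computeMMS(allPos, reg)), 17L)
  # incomplete vectors are rejected
  expect_error(computeMMS(zero[-1], reg), "missing")
  expect_error(computeMMS(replace(zero, 1, 2), reg), "binary")
})

test_that("WMMS with unit weights reduces to MMS", {
  reg <- canonical_registry
  for (seed in 1:5) {
    X <- withr::with_seed(seed, {
      matrix(rbinom(10 * 18, 1, 0.3), nrow = 10,
             dimnames = list(paste0("A", 36:45, "V"), parameterNames(reg)))
    })
    w <- weightSet(parameterSigns(reg))
    expect_equal(unname(computeWMMS(X, w)),
                 as.numeric(computeMMS(X, reg)), tolerance = 1e-12)
  }
})

test_that("weight training recovers an exact single-predictor fit", {
  X <- matrix(c(1, 1, 0, 0, 1, 0), ncol = 1,
              dimnames = list(NULL, "only"))
  y <- 3.5 * X[, 1]
  ws <- trainWeights(X, y)
  expect_equal(unname(weights(ws)), 3.5, tolerance = 1e-10)
  expect_equal(intercept(ws), 0, tolerance = 1e-10)
})

test_that("planted weights are recovered exactly at zero noise", {
  fx <- generateFixture(seed = 42, nMutations = 40, kParameters = 18,
                        noiseSd = 0)
  y <- as.numeric(fx$parameters %*% fx$plantedWeights)
  ws <- trainWeights(fx$parameters, y)
  expect_equal(weights(ws), fx$plantedWeights, tolerance = 1e-8)
  expect_equal(intercept(ws), 0, tolerance = 1e-8)
  # matches the closed-form normal-equations oracle
  oracle <- oracle_ols(fx$parameters, y)
  expect_equal(unname(c(intercept(ws), weights(ws))), oracle,
               tolerance = 1e-8)
})

test_that("training is invariant to row order and matches the oracle with noise", {
  fx <- generateFixture(seed = 9, nMutations = 60, kParameters = 10,
                        noiseSd = 0)
  y <- withr::with_seed(10, as.numeric(fx$parameters %*% fx$plantedWeights) +
                          rnorm(60, 0, 0.5))
  ws <- trainWeights(fx$parameters, y)
  oracle <- oracle_ols(fx$parameters, y)
  expect_equal(unname(c(intercept(ws), weights(ws))), oracle,
               tolerance = 1e-8)
  perm <- withr::with_seed(11, sample(60))
  ws2 <- trainWeights(fx$parameters[perm, ], y[perm])
  expect_equal(weights(ws2), weights(ws), tolerance = 1e-10)
})

test_that("noisy recovery lands within 3 standard errors almost always", {
  fx <- generateFixture(seed = 1, nMutations = 40, kParameters = 18,
                        noiseSd = 0)
  hits <- 0L; total <- 0L
  for (seed in 1:200) {
    y <- withr::with_seed(seed, {
      as.numeric(fx$parameters %*% fx$plantedWeights) + rnorm(40, 0, 0.5)
    })
    ws <- trainWeights(fx$parameters, y)
    inside <- abs(weights(ws) - fx$plantedWeights) <= 3 * ws@details$se
    hits <- hits + sum(inside)
    total <- total + length(inside)
  }
  expect_gte(hits / total, 0.95)
})

test_that("exact collinearity is reported with the offending columns", {
  X <- withr::with_seed(2, matrix(rbinom(60, 1, 0.5), ncol = 3,
                                  dimnames = list(NULL, c("a", "b", "dup"))))
  X[, "dup"] <- X[, "a"]
  expect_error(trainWeights(X, rnorm(20)), "dup")
  expect_error(trainWeights(X[1:2, ], rnorm(2)), "more observations")
})

test_that("MMS severity bands count correctly", {
  expect_identical(unname(binMMS(c(0, 1, 2, 3, 4, 5))), c(1L, 2L, 2L, 1L))
  expect_identical(unname(binMMS(integer(0))), c(0L, 0L, 0L, 0L))
  expect_identical(sum(binMMS(0:17)), 18L)
  expect_error(binMMS(c(1.5)), "integer")
  expect_error(binMMS(-1), "clamp")
})

test_that("score concordance counts exact matches at 2-decimal rounding", {
  expect_identical(scoreConcordance(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_identical(scoreConcordance(c(1, 2), c(1, 3)), 0.5)
  # sub-rounding differences still count as exact correspondence
  expect_identical(scoreConcordance(1.001, 1.0), 1)
  expect_identical(scoreConcordance(1.01, 1.0), 0)
  expect_error(scoreConcordance(1:3, 1:2), "length")
})
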