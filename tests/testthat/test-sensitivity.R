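test_that("sensitivity ranges are centered on the optimum", {
  expect_equal(makeRanges(c(a = 10))$a, c(8, 12))
  expect_equal(makeRanges(c(r_prime = 0.062))$r_prime, c(0.0496, 0.0744))
  expect_equal(makeRanges(c(z = 0), zero_scale = 5)$z, c(0, 1))
  expect_error(makeRanges(c(a = 1), fraction = 0), "degenerate")
  # negative optimum: interval still ordered
  expect_equal(makeRanges(c(a = -10))$a, c(-12, -8))
})

test_that("pooled ranges span both material optima", {
  r <- pooledRanges(list(c(r_prime = 1.104, d_prime = 0.040),
                         c(r_prime = 0.062, d_prime = 0.068)))
  expect_equal(r$r_prime, c(0.062 * 0.8, 1.104 * 1.2))
  expect_equal(r$d_prime, c(0.040 * 0.8, 0.068 * 1.2))
})

test_that("Sobol sequence reproduces the reference low-discrepancy points", {
  # first points of the standard (Joe-Kuo) sequence
  x <- sobolSequence(8, 3)
  expect_equal(x[, 1], c(0, 0.5, 0.75, 0.25, 0.375, 0.875, 0.625, 0.125))
  expect_equal(x[, 2], c(0, 0.5, 0.25, 0.75, 0.375, 0.875, 0.125, 0.625))
  expect_equal(x[, 3], c(0, 0.5, 0.25, 0.75, 0.625, 0.125, 0.875, 0.375))
  # dyadic balance: each half of [0,1) gets exactly half the points
  y <- sobolSequence(256, 10)
  expect_true(all(colSums(y < 0.5) == 128))
})

test_that("Saltelli design has the cross-sampling structure", {
  rng <- list(a = c(0, 1), b = c(10, 20))
  X <- saltelliSample(rng, 4, seed = 1)
  expect_equal(nrow(X), 4 * (2 + 2))
  expect_true(all(X[, "a"] >= 0 & X[, "a"] <= 1))
  expect_true(all(X[, "b"] >= 10 & X[, "b"] <= 20))
  # AB1 block: column a from B, column b from A
  A <- X[1:4, ]; B <- X[5:8, ]; AB1 <- X[9:12, ]; AB2 <- X[13:16, ]
  expect_equal(AB1[, "a"], B[, "a"])
  expect_equal(AB1[, "b"], A[, "b"])
  expect_equal(AB2[, "b"], B[, "b"])
  expect_identical(X, saltelliSample(rng, 4, seed = 1))
  expect_false(identical(X, saltelliSample(rng, 4, seed = 2)))
  expect_error(saltelliSample(list(a = c(1, 1)), 4), "degenerate")
})

test_that("estimators recognize single-factor and additive models", {
  rng <- list(x1 = c(0, 1), x2 = c(0, 1))
  r1 <- sobolAnalysis(rng, function(x) x[1], n_base = 512L, seed = 1)
  expect_equal(r1$Si[1], 1, tolerance = 0.05)
  expect_equal(r1$Si[2], 0, tolerance = 0.02)
  expect_equal(r1$STi[2], 0, tolerance = 0.02)
  radd <- sobolAnalysis(rng, function(x) x[1] + x[2], n_base = 512L,
                        seed = 1)
  expect_equal(sum(radd$Si), 1, tolerance = 0.05)
  expect_equal(radd$Si, radd$STi, tolerance = 0.05)
  # totals dominate first-order up to estimator noise
  expect_true(all(radd$STi >= radd$Si - 0.05))
  X <- saltelliSample(rng, 64, seed = 1)
  expect_error(sobolIndices(X, rep(1, nrow(X))), "variance")
})

test_that("influence flags follow the dual thresholds", {
  r <- data.frame(parameter = c("a", "b", "c"),
                  Si = c(0.06, 0.01, 0.01), STi = c(0.06, 0.05, 0.2))
  expect_equal(unname(classifyInfluential(r)), c(TRUE, FALSE, TRUE))
})

test_that("trajectory scalarization supports mean, final and l2 summaries", {
  scen <- list(variable = "vloss", degradation = degMg10(),
               times = c(28, 56, 84))
  V <- volumeLoss(degMg10(), c(28, 56, 84))
  expect_equal(modelOutputScalar(c(r_prime = 0.062, d_prime = 0.068),
                                 scen), mean(V))
  expect_equal(modelOutputScalar(c(r_prime = 0.062, d_prime = 0.068),
                                 scen, summary = "final"), V[3])
  expect_equal(modelOutputScalar(c(r_prime = 0.062, d_prime = 0.068),
                                 scen, summary = "l2"), sqrt(sum(V^2)))
  # overriding a parameter changes the output accordingly
  V2 <- modelOutputScalar(c(r_prime = 0.1, d_prime = 0.068), scen)
  expect_gt(V2, mean(V))
})

test_that("bootstrap intervals bracket the point estimates", {
  rng <- list(x1 = c(0, 1), x2 = c(0, 1))
  r <- sobolAnalysis(rng, function(x) x[1] + 0.3 * x[2], n_base = 256L,
                     seed = 2, n_boot = 100)
  expect_true(all(r$Si_lo <= r$Si + 1e-9 & r$Si <= r$Si_hi + 1e-9))
  expect_true(all(r$STi_lo <= r$STi + 1e-9))
})
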