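test_that("loss functions reproduce hand-computed values", {
  # single BV/TV residual of 2 with unit weight: loss 4
  ds1 <- data.frame(material = "Ti", variable = "bvtv", time_days = 28,
                    median = 2, sd = 0, n = 1)
  rem <- tiParams()$remodelling
  tr <- simulateModel(rem, times = c(0, 28))
  h28 <- tr$H[2]
  l <- lossBvtvCwidth(rem, NULL, NULL,
                      transform(ds1, median = h28 + 2),
                      lossSpec(0, 0, NULL), material = "Ti")
  expect_equal(l, 4, tolerance = 1e-8)
  # model identical to data with zero regularization: loss 0
  l0 <- lossBvtvCwidth(rem, NULL, NULL, transform(ds1, median = h28),
                       lossSpec(0, 0, NULL), material = "Ti")
  expect_equal(l0, 0, tolerance = 1e-12)
  # zero residuals, k3 = 10, v1 = 1: pure regularization 0.11
  remR <- remodellingParams(k1 = 0.388, v1 = 1, r1 = 0.4915,
                            r2 = 23.1846, k3 = 10)
  trR <- simulateModel(remR, times = c(0, 28))
  lR <- lossBvtvCwidth(remR, NULL, NULL, transform(ds1, median = trR$H[2]),
                       lossSpec(0.001, 0.01, NULL), material = "Ti")
  expect_equal(lR, 0.001 * 100 + 0.01 * 1, tolerance = 1e-10)
})

test_that("volume and lattice losses are mean squared residuals", {
  p <- degMg10()
  tt <- c(28, 70, 140)
  ds <- data.frame(material = "Mg-10Gd", variable = "vloss",
                   time_days = tt, median = volumeLoss(p, tt),
                   sd = 0, n = 6)
  expect_equal(lossVolume(p, ds), 0, tolerance = 1e-14)
  ds$median <- ds$median + c(0.1, -0.1, 0.1)
  expect_equal(lossVolume(p, ds), 0.01, tolerance = 1e-12)
  expect_error(lossVolume(p, ds[0, ]), "no volume-loss rows")

  u <- mg10Params()$ultrastructure[["002"]]
  L <- latticeClosedForm(u, p, tt)
  dsl <- data.frame(material = "Mg-10Gd", variable = "lattice_002",
                    time_days = tt, median = L + 0.002, sd = 0, n = 6)
  expect_equal(lossLattice(u, p, dsl), 4e-6, tolerance = 1e-8)
})

test_that("artificial data points are appended to the BV/TV residual set", {
  rem <- tiParams()$remodelling
  tr <- simulateModel(rem, times = c(0, 3, 28))
  ds <- data.frame(material = "Ti", variable = "bvtv", time_days = 28,
                   median = tr$H[3], sd = 0, n = 1)
  spec <- lossSpec(0, 0, data.frame(time_days = 3, value = 0))
  # residual set becomes {0, H(3) - 0}; mean square = H(3)^2 / 2
  expect_equal(lossBvtvCwidth(rem, NULL, NULL, ds, spec, material = "Ti"),
               tr$H[2]^2 / 2, tolerance = 1e-8)
})

test_that("latin hypercube starts are stratified, bounded and reproducible", {
  b <- parameterBounds("Mg")[c("r_prime", "d_prime", "m2")]
  x1 <- lhsInit(b, 1, seed = 3)
  expect_equal(dim(x1), c(1L, 3L))
  for (j in seq_len(3))
    expect_true(x1[1, j] >= b[[j]][1] && x1[1, j] <= b[[j]][2])
  x <- lhsInit(b, 10, seed = 3)
  # one sample in each of the 10 equal-probability bins per dimension
  for (j in seq_len(3)) {
    u <- (x[, j] - b[[j]][1]) / diff(b[[j]])
    expect_equal(sort(findInterval(u, seq(0, 1, by = 0.1),
                                   rightmost.closed = TRUE)), 1:10)
  }
  expect_identical(x, lhsInit(b, 10, seed = 3))
  expect_false(identical(x, lhsInit(b, 10, seed = 4)))
  expect_error(lhsInit(list(a = c(1, 1)), 5), "degenerate")
})

test_that("CMA-ES minimizes standard test functions inside a box", {
  set.seed(1)
  quad <- cmaes(function(x) sum((x - c(0.3, 0.7))^2), c(0.5, 0.5),
                sigma = 0.3, lower = 0, upper = 1)
  expect_lt(max(abs(quad$par - c(0.3, 0.7))), 1e-3)
  set.seed(2)
  rosen <- cmaes(function(x) 100 * (x[2] - x[1]^2)^2 + (1 - x[1])^2,
                 c(-1, 1), sigma = 0.5, lower = -2, upper = 2,
                 max_iter = 2000)
  expect_lt(max(abs(rosen$par - c(1, 1))), 1e-2)
  # solutions respect the box even when the unconstrained optimum is outside
  set.seed(3)
  edge <- cmaes(function(x) sum((x - 2)^2), c(0.5, 0.5), sigma = 0.3,
                lower = 0, upper = 1)
  expect_true(all(edge$par <= 1 + 1e-12))
  expect_lt(max(abs(edge$par - 1)), 1e-6)
})

test_that("multi-start optimization is deterministic under a fixed seed", {
  b <- parameterBounds("Mg")[c("r_prime", "d_prime")]
  target <- function(th) (th[["r_prime"]] - 0.5)^2 +
    (th[["d_prime"]] - 0.25)^2
  f1 <- optimizeLoss(target, b, n_starts = 2, seed = 11, max_iter = 80)
  f2 <- optimizeLoss(target, b, n_starts = 2, seed = 11, max_iter = 80)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$starts$loss, f2$starts$loss)
  expect_equal(f1$value, min(f1$starts$loss))
  expect_lt(max(abs(f1$par - c(0.5, 0.25))), 1e-4)
})

test_that("degradation parameters are recovered from noise-free synthetic data", {
  ds <- generateStudy(studyDesign("study1", materials = "Mg-10Gd", cv = 0,
                                  seed = 8))
  fit <- optimizeLoss(
    function(th) lossVolume(buildDeg <- degradationParams(
      "surface_rate", r_prime = th[["r_prime"]], d_prime = th[["d_prime"]]),
      ds, material = "Mg-10Gd"),
    parameterBounds("Mg")[c("r_prime", "d_prime")],
    n_starts = 3, seed = 21, max_iter = 200)
  expect_lt(abs(fit$par[["r_prime"]] / 0.062 - 1), 0.01)
  expect_lt(abs(fit$par[["d_prime"]] / 0.068 - 1), 0.01)
})

test_that("staged workflow degrades gracefully with missing materials", {
  dsTi <- generateStudy(studyDesign("study1", materials = "Ti", cv = 0,
                                    seed = 9))
  expect_warning(
    wf <- stagedWorkflow(dsTi, control = workflowControl(n_starts = 1,
                                                         max_iter = 20)),
    "skipped")
  expect_s3_class(wf, "osteo_staged")
  expect_null(wf$`Mg-5Gd`)
  expect_true(is.numeric(wf$Ti$value))
})

test_that("the initial-mineral parameter study reports errors per H(0)", {
  ds <- generateStudy(studyDesign("study1", materials = "Ti", cv = 0,
                                  seed = 13))
  res <- h0ParameterStudy(ds, H0_grid = c(0, 0.2),
                          control = workflowControl(n_starts = 1,
                                                    max_iter = 25))
  expect_equal(res$H0, c(0, 0.2))
  expect_true(all(is.finite(res$loss)))
  expect_true(all(res$mae_bvtv >= 0) && all(res$mae_cwidth >= 0))
})
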