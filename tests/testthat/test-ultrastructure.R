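test_that("plane presets and parameter validation", {
  u002 <- ultrastructureParams(k4 = 1, k6 = 1, k7 = 1, k8 = 0.01,
                               plane = "002")
  expect_equal(c(u002$L_min, u002$L_max), c(3.403, 3.447))
  u310 <- ultrastructureParams(k4 = 1, k6 = 1, k7 = 1, k8 = 0.01,
                               plane = "310")
  expect_equal(c(u310$L_min, u310$L_max), c(2.243, 2.281))
  expect_equal(u002$C_hat, 15)
  expect_error(ultrastructureParams(k4 = 1, k6 = 0.5, k7 = 1, k8 = 0.01))
  expect_error(ultrastructureParams(k4 = -1, k6 = 1, k7 = 1, k8 = 0.01))
  expect_error(ultrastructureParams(k4 = 1, k6 = 1, k7 = 1, k8 = 0.01,
                                    C0 = 0))
  expect_error(ultrastructureParams(k4 = 1, k6 = 1, k7 = 1, k8 = 0.01,
                                    L_min = 3.5, L_max = 3.4))
})

test_that("ultrastructure right-hand side fixed points", {
  u <- ultrastructureParams(k4 = 38, k6 = 1.27, k7 = 2.3, k8 = 0.0092)
  dH1 <- function(t) 0.01
  # zero width is absorbing for the multiplicative growth law
  d <- ultrastructureRHS(0, u$L_max, 5, u, dH1)
  expect_equal(unname(d[["dCw"]]), 0)
  # healthy lattice with no corrosion is an equilibrium
  d <- ultrastructureRHS(0.1, u$L_max, 5, u, dH1, function(t) 0)
  expect_equal(unname(d[["dL"]]), 0)
  # the lower lattice bound repels
  d <- ultrastructureRHS(0.1, u$L_min, 5, u, dH1, function(t) 0)
  expect_equal(unname(d[["dL"]]), u$k8 * (u$L_max - u$L_min))
  expect_error(ultrastructureRHS(0.1, u$L_max + 1, 5, u, dH1))
})

test_that("crystal-width closed form reduces to the exact exponentials", {
  u <- ultrastructureParams(k4 = 2, k6 = 1, k7 = 1, k8 = 0.01, C0 = 1e-3)
  # no mineralization: width stays at its seed
  expect_equal(crystalWidthClosedForm(u, function(t) 0, c(0, 10, 100)),
               rep(1e-3, 3))
  # constant rate and first-order kinetics: pure exponential growth
  cw <- crystalWidthClosedForm(u, function(t) 0.05, c(0, 5, 20))
  expect_lt(relErr(cw, 1e-3 * exp(2 * 0.05 * c(0, 5, 20))), 1e-8)
})

test_that("crystal width is exactly linear in its seed", {
  tp <- mg10Params()
  tt <- seq(0, 230, by = 1)
  u1 <- tp$ultrastructure[["002"]]
  u3 <- ultrastructureParams(k4 = u1$k4, k6 = u1$k6, k7 = u1$k7,
                             k8 = u1$k8, plane = "002", C0 = 3 * u1$C0)
  dH <- local({
    tr <- simulateModel(tp$remodelling, tp$degradation, u1, times = tt)
    stats::splinefun(tr$time, tr$dHdt, method = "natural")
  })
  ts <- c(28, 84, 224)
  expect_equal(crystalWidthClosedForm(u3, dH, ts),
               3 * crystalWidthClosedForm(u1, dH, ts), tolerance = 1e-12)
})

test_that("lattice closed form has the linear-ODE limits", {
  u <- ultrastructureParams(k4 = 1, k6 = 1, k7 = 2.3037, k8 = 0.0092,
                            plane = "002")
  # no corrosion: lattice stays healthy
  expect_equal(latticeClosedForm(u, NULL, c(0, 50, 200)),
               rep(u$L_max, 3))
  # constant corrosion rate: stationary value of the linear ODE
  v <- 0.01
  Linf <- (u$k7 * v * u$L_min + u$k8 * u$L_max) / (u$k7 * v + u$k8)
  L <- latticeClosedForm(u, function(t) rep(v, length(t)), 3000)
  expect_lt(abs(L - Linf), 1e-6)
})

test_that("Mg-10Gd lattice dips and then recovers toward the healthy spacing", {
  u <- mg10Params()$ultrastructure[["002"]]
  tt <- c(0, 5, 20, 50, 100, 224, 1000)
  L <- latticeClosedForm(u, degMg10(), tt)
  expect_true(all(L >= u$L_min & L <= u$L_max))
  expect_lt(min(L), u$L_max - 0.005)          # substitution dip
  expect_gt(L[length(L)], L[which.min(L)])    # recovery phase
})
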