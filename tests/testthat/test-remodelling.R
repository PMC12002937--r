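test_that("right-hand side matches direct substitution", {
  p <- tiParams()$remodelling
  s0 <- c(x1 = 1, x2 = 0, I = 1, N = 0, H = 0)
  d <- remodellingRHS(s0, 0, p)
  # at the initial condition no mineral forms and nucleation starts at k1
  expect_equal(unname(d[["dH"]]), 0)
  expect_equal(unname(d[["dN"]]), p$k2 * p$k1)
  expect_equal(unname(d[["dx1"]]), -p$k1)
  expect_equal(unname(d[["dx2"]]), p$k1)

  # decayed matrix: only the Mg source moves the inhibitor
  pMg <- mg10Params()$remodelling
  vr <- volumeLossRateFunction(degMg10())
  sLate <- c(x1 = 0, x2 = 1, I = 0, N = 0.5, H = 0.3)
  dLate <- remodellingRHS(sLate, 10, pMg, vr)
  expect_equal(unname(dLate[["dx1"]]), 0)
  expect_equal(unname(dLate[["dx2"]]), 0)
  expect_equal(unname(dLate[["dI"]]), pMg$m2 * vr(10))

  expect_error(remodellingRHS(c(x1 = NaN, x2 = 0, I = 1, N = 0, H = 0),
                              0, p))
})

test_that("Hill gate is bounded in (0, 1] and equals 1 only at zero inhibitor", {
  expect_equal(hillGate(1), 0.000999000999000999, tolerance = 1e-15)
  expect_equal(hillGate(0), 1)
  I <- c(0, 10^seq(-3, 2, length.out = 40))
  g <- hillGate(I)
  expect_true(all(g > 0 & g <= 1))
  # strict inequality where I^a is resolvable above double precision
  Is <- 10^seq(-1.5, 2, length.out = 40)
  gs <- hillGate(Is)
  expect_true(all(gs < 1))
  expect_true(all(diff(gs) < 0))
})

test_that("matrix maturation follows the analytic exponential", {
  p <- tiParams()
  tt <- seq(0, 20, by = 0.25)
  tr <- simulateRemodelling(p$remodelling, NULL, tt,
                            rtol = 1e-10, atol = 1e-14)
  expect_lt(relErr(tr$x1, exp(-p$remodelling$k1 * tt)), 1e-6)
  expect_lt(relErr(tr$x2[-1], 1 - exp(-p$remodelling$k1 * tt[-1])), 1e-6)
  expect_lt(max(abs(tr$x1 + tr$x2 - 1)), 1e-8)
})

test_that("Mg degradation delays mineralization relative to Ti", {
  tt <- seq(0, 230, by = 1)
  pTi <- tiParams()
  trTi <- simulateRemodelling(pTi$remodelling, NULL, tt)
  # same bone parameters, Mg coupling switched on
  pM <- remodellingParams(k1 = 0.3880, v1 = 0.0164, r1 = 0.4915,
                          r2 = 23.1846, k3 = 0.5744, m2 = 84.0455)
  trMg <- simulateRemodelling(pM, degMg10(), tt)
  expect_gt(computeLag(trMg), computeLag(trTi))
  # early mineral is suppressed by the inhibitor spike
  expect_lt(trMg$H[tt == 14], trTi$H[tt == 14])
  # but mineralization does eventually proceed
  expect_gt(max(trMg$H), 0.1)
})

test_that("raising the Mg-inhibition rate never increases mineral content", {
  tt <- seq(0, 230, by = 2)
  base <- mg10Params()$remodelling
  prev <- NULL
  for (m2 in c(0, 20, 84.0455, 150)) {
    p <- remodellingParams(k1 = base$k1, v1 = base$v1, r1 = base$r1,
                           k3 = base$k3, r2 = base$r2, m2 = m2)
    tr <- simulateRemodelling(p, degMg10(), tt)
    if (!is.null(prev)) expect_true(all(tr$H <= prev + 1e-8))
    prev <- tr$H
  }
})

test_that("the maturation-event removal variant freezes the inhibitor after maturation", {
  tt <- seq(0, 230, by = 1)
  base <- mg10Params()$remodelling
  alt <- remodellingParams(k1 = base$k1, v1 = base$v1, r1 = base$r1,
                           k3 = base$k3, r2 = base$r2, m2 = base$m2,
                           inhibitor_removal = "maturation_rate")
  trAlt <- simulateRemodelling(alt, degMg10(), tt)
  trDef <- simulateRemodelling(base, degMg10(), tt)
  # without persistent removal the Mg-driven inhibitor stays high and
  # blocks mineralization; the default variant lets bone form
  expect_gt(min(trAlt$I[tt > 100]), 1)
  expect_lt(max(trAlt$H), 1e-3)
  expect_lt(min(trDef$I[tt > 100]), 0.1)
  expect_gt(max(trDef$H), 0.1)
})

test_that("lag time is the tangent construction at maximum growth rate", {
  # logistic growth: inflection at t = 10, slope 1/4, H(0) ~ 0
  tt <- seq(0, 30, by = 0.01)
  H <- 1 / (1 + exp(-(tt - 10)))
  tlag <- computeLag(data.frame(time = tt, H = H))
  expect_equal(tlag, 10 - (0.5 - H[1]) / 0.25, tolerance = 1e-3)
  expect_error(computeLag(data.frame(time = tt, H = rep(2, length(tt)))),
               "flat")
  # calibrated Ti model: lag in the single-digit-to-low-teens range
  pTi <- tiParams()
  trTi <- simulateRemodelling(pTi$remodelling, NULL, seq(0, 230, by = 0.25))
  expect_gt(computeLag(trTi), 1)
  expect_lt(computeLag(trTi), 15)
})

test_that("solver input validation rejects malformed grids and states", {
  p <- tiParams()$remodelling
  expect_error(simulateRemodelling(p, NULL, c(0, 2, 1)))
  expect_error(simulateRemodelling(p, NULL, c(1, 2, 3)))
  expect_error(simulateRemodelling(p, NULL, seq(0, 10), H0 = -1))
  expect_error(simulateModel(p, times = seq(0, 10),
                             init = c(bogus = 1)), "unknown state")
})
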