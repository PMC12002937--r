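test_that("study designs encode the two sampling schemes", {
  d1 <- studyDesign("study1")
  expect_equal(d1$grids$bvtv, c(28, 56, 70, 84, 140, 224))
  expect_equal(d1$grids$cwidth, c(28, 56, 84))
  expect_equal(d1$grids$lattice_002, c(70, 140, 224))
  expect_equal(d1$H0, 0)
  d2 <- studyDesign("study2")
  expect_equal(d2$grids$bvtv, c(3, 7, 14, 28, 90))
  expect_equal(d2$materials, "Ti")
  expect_equal(d2$H0, 42.47)
  expect_error(studyDesign("study1", animals = 0))
  expect_error(defaultParameters("Mg-10Gd", study = "study2"), "Ti")
})

test_that("noise-free medians equal the forward trajectories exactly", {
  ds <- generateStudy(studyDesign("study1", cv = 0, lattice_sd = 0,
                                  seed = 2))
  tp <- mg10Params()
  tt <- sort(unique(c(0, ds$time_days)))
  tr <- simulateModel(tp$remodelling, tp$degradation,
                      tp$ultrastructure[["002"]], times = tt)
  rows <- ds[ds$material == "Mg-10Gd" & ds$variable == "bvtv", ]
  expect_equal(rows$median, tr$H[match(rows$time_days, tr$time)],
               tolerance = 1e-12)
  rowsV <- ds[ds$material == "Mg-10Gd" & ds$variable == "vloss", ]
  expect_equal(rowsV$median, volumeLoss(tp$degradation, rowsV$time_days),
               tolerance = 1e-8)
  expect_true(all(ds$sd == 0))
})

test_that("generation is deterministic under the design seed", {
  d <- studyDesign("study1", cv = 0.1, seed = 77)
  ds1 <- generateStudy(d)
  ds2 <- generateStudy(d)
  expect_identical(as.data.frame(ds1), as.data.frame(ds2))
  ds3 <- generateStudy(studyDesign("study1", cv = 0.1, seed = 78))
  expect_false(identical(ds1$median, ds3$median))
  # the caller's RNG stream is not consumed
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(generateStudy(d)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("median summaries are unbiased under symmetric multiplicative noise", {
  des <- studyDesign("study1", materials = "Ti", cv = 0.1)
  tp <- tiParams()
  tr <- simulateModel(tp$remodelling, times = c(0, des$grids$bvtv))
  truthH <- tr$H[match(des$grids$bvtv, tr$time)]
  meds <- matrix(0, 400, length(des$grids$bvtv))
  for (r in seq_len(400)) {
    des$seed <- 1000L + r
    ds <- generateStudy(des)
    meds[r, ] <- ds$median[ds$variable == "bvtv"]
  }
  expect_lt(max(abs(colMeans(meds) / truthH - 1)), 0.02)
})

test_that("physically inadmissible truth parameters are rejected", {
  truth <- list(Ti = tiParams())
  truth$Ti$remodelling$k1 <- 100  # outside the calibration box
  expect_error(generateStudy(studyDesign("study1", materials = "Ti"),
                             truth), "outside its calibration bounds")
})

test_that("fixture bundles round-trip through CSV", {
  dir <- withr::local_tempdir()
  path <- fixtureBundle("study1", dir, seed = 123L, cv = 0.05)
  expect_true(file.exists(path))
  ds <- readStudyDataset(path)
  expect_s3_class(ds, "osteo_dataset")
  expect_true(all(c("Ti", "Mg-5Gd", "Mg-10Gd") %in% ds$material))
  expect_true(all(ds$sd >= 0) && all(ds$n == 6))
  vl <- ds[ds$variable == "vloss", ]
  expect_true(all(vl$median >= 0 & vl$median <= 1))
})
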