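#' Calibration bounds for all model parameters
#'
#' Box constraints used for latin-hypercube initialization and CMA-ES
#' search. Three bounds are material-conditional: the bone growth rate
#' `k3`, the crystal-growth prefactor `k4` and the precipitation order
#' `k6` use wider ranges for Mg-based materials than for Ti.
#'
#' @param material `"Ti"` or `"Mg"` (either Mg-xGd alloy).
#' @return Named list of `c(lo, hi)` intervals.
#' @export
parameterBounds <- function(material = c("Ti", "Mg")) {
  material <- match.arg(material)
  b <- list(
    m1 = c(0, 1),
    r_prime = c(1e-4, 1.2),
    d_prime = c(1e-4, 1),
    k1 = c(0.01, 10),
    v1 = c(0.001, 10),
    r1 = c(0.02, 20),
    m2 = c(1, 150),
    r2 = c(1, 100),
    k7 = c(0, 10),
    k8 = c(0, 1)
  )
  if (material == "Ti") {
    b$k3 <- c(0.1, 10); b$k4 <- c(0.1, 100); b$k6 <- c(1, 3)
  } else {
    b$k3 <- c(1, 30); b$k4 <- c(0.001, 300); b$k6 <- c(1, 5)
  }
  b
}

#' Loss configuration
#'
#' Weights and regularization for the scalarized least-squares losses.
#' Each included variable contributes its mean squared residual (`1/n`
#' weighting). For the Ti calibration two ridge penalties
#' (`lambda_k * k3^2`, `lambda_v * v1^2`) prevent unrealistically large
#' growth/production rates, and an artificial early BV/TV point (default
#' `t = 3` days at the initial value `H(0)`) anchors the lag phase that
#' the sparse experimental grid does not constrain.
#'
#' @param lambda_k ridge weight on `k3^2` (default 0.001).
#' @param lambda_v ridge weight on `v1^2` (default 0.01).
#' @param artificial_points data frame with columns `time_days`, `value`
#'   appended to the BV/TV residual set, or `NULL` for none.
#' @return An object of class `osteo_loss_spec`.
#' @export
lossSpec <- function(lambda_k = 0.001, lambda_v = 0.01,
                     artificial_points = data.frame(time_days = 3,
                                                    value = 0)) {
  stopifnot(lambda_k >= 0, lambda_v >= 0)
  if (!is.null(artificial_points))
    stopifnot(is.data.frame(artificial_points),
              all(c("time_days", "value") %in% names(artificial_points)))
  structure(list(lambda_k = lambda_k, lambda_v = lambda_v,
                 artificial_points = artificial_points),
            class = "osteo_loss_spec")
}

datasetRows <- function(dataset, variable, material = NULL) {
  stopifnot(is.data.frame(dataset),
            all(c("variable", "time_days", "median") %in% names(dataset)))
  d <- dataset[dataset$variable == variable, , drop = FALSE]
  if (!is.null(material) && "material" %in% names(dataset))
    d <- d[d$material == material, , drop = FALSE]
  d
}

#' Volume-loss calibration loss
#'
#' Mean squared residual between the closed-form cumulative volume loss
#' and the observed medians (`variable == "vloss"`, fractions).
#'
#' @param params an [degradationParams()] object.
#' @param dataset study data frame (`material`, `variable`, `time_days`,
#'   `median`, ...).
#' @param material optional material filter.
#' @return Scalar loss.
#' @export
lossVolume <- function(params, dataset, material = NULL) {
  d <- datasetRows(dataset, "vloss", material)
  if (nrow(d) == 0L) stop("no volume-loss rows in dataset")
  mean((d$median - volumeLoss(params, d$time_days))^2)
}

#' Joint BV/TV and crystal-width calibration loss
#'
#' The scalarized multi-objective loss: mean squared BV/TV residual
#' (including any artificial points) plus mean squared crystal-width
#' residual plus the ridge terms of the [lossSpec()]. Variables missing
#' from the dataset simply contribute nothing.
#'
#' @param remodelling an [remodellingParams()] object.
#' @param ultrastructure an [ultrastructureParams()] object or `NULL`
#'   (BV/TV-only fit).
#' @param degradation an [degradationParams()] object or `NULL`.
#' @param dataset study data frame.
#' @param spec an [lossSpec()] object.
#' @param material optional material filter.
#' @param H0 initial mineral content used in the simulation.
#' @param rtol,atol solver tolerances.
#' @return Scalar loss.
#' @export
lossBvtvCwidth <- function(remodelling, ultrastructure = NULL,
                           degradation = NULL, dataset,
                           spec = lossSpec(), material = NULL,
                           H0 = 0, rtol = 1e-8, atol = 1e-10) {
  db <- datasetRows(dataset, "bvtv", material)
  dc <- if (is.null(ultrastructure)) db[0, ] else
    datasetRows(dataset, "cwidth", material)
  if (nrow(db) == 0L && nrow(dc) == 0L)
    stop("no BV/TV or crystal-width rows in dataset")
  tb <- db$time_days; yb <- db$median
  if (!is.null(spec$artificial_points)) {
    tb <- c(tb, spec$artificial_points$time_days)
    yb <- c(yb, spec$artificial_points$value)
  }
  tgrid <- sort(unique(c(0, tb, dc$time_days)))
  traj <- simulateModel(remodelling, degradation, ultrastructure,
                        times = tgrid, H0 = H0, rtol = rtol, atol = atol)
  loss <- 0
  if (length(tb))
    loss <- loss + mean((yb - traj$H[match(tb, traj$time)])^2)
  if (nrow(dc))
    loss <- loss +
      mean((dc$median - traj$Cwidth[match(dc$time_days, traj$time)])^2)
  loss + spec$lambda_k * remodelling$k3^2 + spec$lambda_v * remodelling$v1^2
}

#' Lattice-spacing calibration loss
#'
#' Mean squared residual between the closed-form lattice trajectory and
#' the observed medians for one crystallographic plane
#' (`variable == "lattice_310"` or `"lattice_002"`, Angstrom).
#'
#' @param params an [ultrastructureParams()] object (its `plane` selects
#'   the variable unless `plane` is given).
#' @param degradation an [degradationParams()] object.
#' @param dataset study data frame.
#' @param plane `"310"` or `"002"`; defaults to `params$plane`.
#' @param material optional material filter.
#' @return Scalar loss.
#' @export
lossLattice <- function(params, degradation, dataset, plane = NULL,
                        material = NULL) {
  if (is.null(plane)) plane <- params$plane
  d <- datasetRows(dataset, paste0("lattice_", plane), material)
  if (nrow(d) == 0L) stop("no lattice rows for plane ", plane)
  mean((d$median - latticeClosedForm(params, degradation, d$time_days))^2)
}

#' Latin hypercube initialization
#'
#' Stratified starting points for the multi-start optimization: each
#' dimension is divided into `n_samples` equal-probability bins with
#' exactly one sample per bin. Deterministic under a fixed seed; the
#' caller's RNG state is restored afterwards.
#'
#' @param bounds named list of `c(lo, hi)` intervals.
#' @param n_samples number of points (>= 1).
#' @param seed optional integer seed.
#' @return Matrix `n_samples x d` with parameter names as columns.
#' @export
lhsInit <- function(bounds, n_samples, seed = NULL) {
  stopifnot(is.list(bounds), length(bounds) >= 1L, n_samples >= 1L)
  lo <- vapply(bounds, `[`, numeric(1), 1)
  hi <- vapply(bounds, `[`, numeric(1), 2)
  if (any(!is.finite(lo)) || any(!is.finite(hi)) || any(lo >= hi))
    stop("degenerate bounds: need finite lo < hi in every dimension")
  u <- withSeed(seed, lhs::randomLHS(n_samples, length(bounds)))
  x <- sweep(sweep(u, 2, hi - lo, `*`), 2, lo, `+`)
  colnames(x) <- names(bounds)
  x
}

withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Multi-start bounded CMA-ES minimization
#'
#' Minimizes a loss over a box using [cmaes()] in a `[0, 1]`-rescaled
#' parameter space, starting from latin-hypercube points (or supplied
#' starts). Every start uses a seed derived deterministically from
#' `seed`, so results are reproducible bit-for-bit.
#'
#' @param loss function of a named parameter vector returning a scalar;
#'   non-finite or error results are treated as very large.
#' @param bounds named list of `c(lo, hi)` intervals for the free
#'   parameters.
#' @param n_starts number of LHS starts (ignored if `inits` given).
#' @param inits optional matrix of starting points (columns = parameters).
#' @param seed integer seed controlling initialization and CMA-ES.
#' @param max_iter,tol_fun,popsize,sigma CMA-ES controls (see [cmaes()]).
#' @return An object of class `osteo_fit`: `par` (best parameters),
#'   `value`, `starts` (per-start summary data frame), `par_per_start`,
#'   `bounds`.
#' @export
optimizeLoss <- function(loss, bounds, n_starts = 10, inits = NULL,
                         seed = 1, max_iter = 500, tol_fun = 1e-10,
                         popsize = NULL, sigma = 0.25) {
  lo <- vapply(bounds, `[`, numeric(1), 1)
  hi <- vapply(bounds, `[`, numeric(1), 2)
  nm <- names(bounds)
  if (is.null(inits)) inits <- lhsInit(bounds, n_starts, seed)
  inits <- inits[, nm, drop = FALSE]
  n_starts <- nrow(inits)
  safeLoss <- function(u) {
    x <- lo + u * (hi - lo)
    names(x) <- nm
    v <- tryCatch(loss(x), error = function(e) Inf)
    if (!is.finite(v)) .Machine$double.xmax / 2 else v
  }
  runs <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    u0 <- (inits[i, ] - lo) / (hi - lo)
    runs[[i]] <- withSeed(seed + i, {
      r <- cmaes(safeLoss, u0, sigma = sigma, lower = 0, upper = 1,
                 popsize = popsize, max_iter = max_iter, tol_fun = tol_fun)
      r$par_phys <- stats::setNames(lo + r$par * (hi - lo), nm)
      r
    })
  }
  vals <- vapply(runs, `[[`, numeric(1), "value")
  best <- which.min(vals)
  structure(
    list(par = runs[[best]]$par_phys,
         value = vals[best],
         starts = data.frame(
           start = seq_len(n_starts), seed = seed + seq_len(n_starts),
           loss = vals,
           iterations = vapply(runs, `[[`, integer(1), "iterations"),
           evals = vapply(runs, function(r) as.integer(r$counts),
                          integer(1)),
           converged = vapply(runs, `[[`, logical(1), "converged")),
         par_per_start = do.call(rbind, lapply(runs, `[[`, "par_phys")),
         bounds = bounds),
    class = "osteo_fit"
  )
}

#' @export
print.osteo_fit <- function(x, ...) {
  cat("Calibration result (", nrow(x$starts), " start(s)):\n", sep = "")
  cat("  best loss:", format(x$value, digits = 6), "\n  parameters:\n")
  print(round(x$par, 5))
  invisible(x)
}

buildRemodelling <- function(theta, fixed = list(),
                             inhibitor_removal = "mature_matrix") {
  g <- function(nm, default = NULL) {
    if (nm %in% names(theta)) theta[[nm]]
    else if (nm %in% names(fixed)) fixed[[nm]]
    else default
  }
  remodellingParams(k1 = g("k1"), v1 = g("v1"), r1 = g("r1"),
                    k3 = g("k3"), r2 = g("r2"), m2 = g("m2", 0),
                    inhibitor_removal = inhibitor_removal)
}

buildUltrastructure <- function(theta, fixed = list(), plane = "002",
                                C0 = 1e-3) {
  g <- function(nm, default = NULL) {
    if (nm %in% names(theta)) theta[[nm]]
    else if (nm %in% names(fixed)) fixed[[nm]]
    else default
  }
  ultrastructureParams(k4 = g("k4"), k6 = g("k6"),
                       k7 = g("k7", 1), k8 = g("k8", 0.01),
                       plane = plane, C0 = C0)
}

buildDegradation <- function(theta, model) {
  if (model == "power_law") degradationParams("power_law", m1 = theta[["m1"]])
  else degradationParams("surface_rate", r_prime = theta[["r_prime"]],
                         d_prime = theta[["d_prime"]])
}

#' Workflow control settings
#'
#' @param n_starts LHS starts for the Ti and Mg-10Gd calibrations
#'   (default 10).
#' @param refit_starts starts for single-material refits (default 1).
#' @param max_iter CMA-ES generations per start (default 500).
#' @param seed master seed; all stage seeds derive from it.
#' @param H0 initial mineral content (also the artificial-point value).
#' @param artificial_time time (days) of the artificial early BV/TV point.
#' @param lambda_k,lambda_v Ti ridge weights.
#' @param C0 crystal-width seed.
#' @param refit_lattice_mg5gd refit `k7`, `k8` per plane on Mg-5Gd data in
#'   stage 3 (material-specific ion-exchange rates) instead of pure
#'   prediction.
#' @param inhibitor_removal passed to [remodellingParams()].
#' @param rtol,atol solver tolerances used inside losses.
#' @return A list of settings.
#' @export
workflowControl <- function(n_starts = 10, refit_starts = 1, max_iter = 500,
                            seed = 1, H0 = 0, artificial_time = 3,
                            lambda_k = 0.001, lambda_v = 0.01, C0 = 1e-3,
                            refit_lattice_mg5gd = FALSE,
                            inhibitor_removal = "mature_matrix",
                            rtol = 1e-8, atol = 1e-10) {
  as.list(environment())
}

#' Staged material-transfer calibration workflow
#'
#' Three-stage calibration mirroring the transfer logic of the study
#' design:
#' \enumerate{
#'   \item Ti: all bone/ultrastructure parameters
#'     (`k1, v1, r1, r2, k3, k4, k6`) are fitted jointly on BV/TV and
#'     crystal width with `m2 = 0`, ridge regularization and the
#'     artificial early point. In parallel the degradation parameters are
#'     fitted per Mg material on volume loss.
#'   \item Mg-10Gd: `k1, v1, r1, r2` are frozen at the Ti values;
#'     `m2, k3, k4, k6` are refitted jointly on BV/TV and crystal width,
#'     and `k7, k8` are fitted per crystallographic plane on the lattice
#'     data.
#'   \item Mg-5Gd: all parameters are fixed and the model is applied as a
#'     pure prediction (optionally refitting `k7, k8` per plane).
#' }
#'
#' @param dataset study data frame with materials `"Ti"`, `"Mg-10Gd"`,
#'   `"Mg-5Gd"` (missing materials skip their stages with a warning).
#' @param degradation_model `"surface_rate"` or `"power_law"`.
#' @param control see [workflowControl()].
#' @return An object of class `osteo_staged`: per-stage fits, fixed
#'   parameter sets per material, stage-3 prediction trajectories and
#'   metric reports.
#' @export
stagedWorkflow <- function(dataset, degradation_model = "surface_rate",
                           control = workflowControl()) {
  ctl <- control
  mats <- unique(dataset$material)
  out <- list(control = ctl, degradation_model = degradation_model)

  degBounds <- if (degradation_model == "power_law")
    parameterBounds("Mg")["m1"] else parameterBounds("Mg")[c("r_prime",
                                                             "d_prime")]

  ## Stage 1: degradation per Mg material + full Ti calibration
  out$degradation <- list()
  for (m in intersect(c("Mg-5Gd", "Mg-10Gd"), mats)) {
    if (nrow(datasetRows(dataset, "vloss", m)) == 0L) next
    fit <- optimizeLoss(
      function(th) lossVolume(buildDegradation(th, degradation_model),
                              dataset, material = m),
      degBounds, n_starts = ctl$n_starts,
      seed = ctl$seed + 1000L * match(m, c("Mg-5Gd", "Mg-10Gd")),
      max_iter = ctl$max_iter)
    fit$params <- buildDegradation(fit$par, degradation_model)
    out$degradation[[m]] <- fit
  }

  if (!"Ti" %in% mats) {
    warning("no Ti data: stages 1b-3 skipped")
    class(out) <- "osteo_staged"
    return(out)
  }

  tiBounds <- parameterBounds("Ti")
  haveCwTi <- nrow(datasetRows(dataset, "cwidth", "Ti")) > 0L
  freeTi <- c("k1", "v1", "r1", "r2", "k3", if (haveCwTi) c("k4", "k6"))
  specTi <- lossSpec(ctl$lambda_k, ctl$lambda_v,
                     data.frame(time_days = ctl$artificial_time,
                                value = ctl$H0))
  tiLoss <- function(th) {
    rem <- buildRemodelling(th, inhibitor_removal = ctl$inhibitor_removal)
    ult <- if (haveCwTi) buildUltrastructure(th, C0 = ctl$C0) else NULL
    lossBvtvCwidth(rem, ult, NULL, dataset, specTi, material = "Ti",
                   H0 = ctl$H0, rtol = ctl$rtol, atol = ctl$atol)
  }
  out$Ti <- optimizeLoss(tiLoss, tiBounds[freeTi], n_starts = ctl$n_starts,
                         seed = ctl$seed + 10L, max_iter = ctl$max_iter)

  ## Stage 2: Mg-10Gd bone + lattice calibration
  if ("Mg-10Gd" %in% mats &&
      nrow(datasetRows(dataset, "bvtv", "Mg-10Gd")) > 0L) {
    mgBounds <- parameterBounds("Mg")
    deg10 <- out$degradation[["Mg-10Gd"]]$params
    fixed <- as.list(out$Ti$par[c("k1", "v1", "r1", "r2")])
    haveCwMg <- nrow(datasetRows(dataset, "cwidth", "Mg-10Gd")) > 0L
    freeMg <- c("m2", "k3", if (haveCwMg) c("k4", "k6"))
    mgLoss <- function(th) {
      rem <- buildRemodelling(th, fixed, ctl$inhibitor_removal)
      ult <- if (haveCwMg) buildUltrastructure(th, C0 = ctl$C0) else NULL
      lossBvtvCwidth(rem, ult, deg10, dataset, lossSpec(0, 0, NULL),
                     material = "Mg-10Gd", H0 = ctl$H0,
                     rtol = ctl$rtol, atol = ctl$atol)
    }
    out$`Mg-10Gd` <- optimizeLoss(mgLoss, mgBounds[freeMg],
                                  n_starts = ctl$n_starts,
                                  seed = ctl$seed + 20L,
                                  max_iter = ctl$max_iter)
    out$bone_par <- c(unlist(fixed), out$`Mg-10Gd`$par)

    out$lattice <- list()
    for (pl in c("310", "002")) {
      if (nrow(datasetRows(dataset, paste0("lattice_", pl),
                           "Mg-10Gd")) == 0L) next
      base <- out$bone_par
      latLoss <- function(th) {
        ult <- ultrastructureParams(
          k4 = getOr(base, "k4", 1), k6 = getOr(base, "k6", 1),
          k7 = th[["k7"]], k8 = th[["k8"]], plane = pl, C0 = ctl$C0)
        lossLattice(ult, deg10, dataset, plane = pl, material = "Mg-10Gd")
      }
      out$lattice[[pl]] <- optimizeLoss(
        latLoss, parameterBounds("Mg")[c("k7", "k8")],
        n_starts = ctl$n_starts, seed = ctl$seed + 30L + as.integer(pl),
        max_iter = ctl$max_iter)
    }
  } else {
    warning("no Mg-10Gd BV/TV data: stage 2 (and stage 3) skipped")
    class(out) <- "osteo_staged"
    return(out)
  }

  ## Stage 3: Mg-5Gd prediction with all parameters fixed
  if ("Mg-5Gd" %in% mats && !is.null(out$degradation[["Mg-5Gd"]])) {
    deg5 <- out$degradation[["Mg-5Gd"]]$params
    bp <- out$bone_par
    rem5 <- buildRemodelling(bp, inhibitor_removal = ctl$inhibitor_removal)
    pred <- list(remodelling = rem5, degradation = deg5)
    d5 <- dataset[dataset$material == "Mg-5Gd", , drop = FALSE]
    tgrid <- sort(unique(c(0, d5$time_days, seq(0, max(d5$time_days),
                                                length.out = 116L))))
    metrics <- list(); trajs <- list()
    for (pl in names(out$lattice)) {
      k78 <- out$lattice[[pl]]$par
      if (ctl$refit_lattice_mg5gd &&
          nrow(datasetRows(dataset, paste0("lattice_", pl),
                           "Mg-5Gd")) > 0L) {
        refit <- optimizeLoss(
          function(th) {
            ult <- ultrastructureParams(
              k4 = getOr(bp, "k4", 1), k6 = getOr(bp, "k6", 1),
              k7 = th[["k7"]], k8 = th[["k8"]], plane = pl, C0 = ctl$C0)
            lossLattice(ult, deg5, dataset, plane = pl, material = "Mg-5Gd")
          },
          parameterBounds("Mg")[c("k7", "k8")],
          n_starts = ctl$refit_starts,
          seed = ctl$seed + 50L + as.integer(pl), max_iter = ctl$max_iter)
        k78 <- refit$par
        out$lattice_mg5gd_refit[[pl]] <- refit
      }
      ult <- ultrastructureParams(
        k4 = getOr(bp, "k4", 1), k6 = getOr(bp, "k6", 1),
        k7 = k78[["k7"]], k8 = k78[["k8"]], plane = pl, C0 = ctl$C0)
      tr <- simulateModel(rem5, deg5, ult, times = tgrid, H0 = ctl$H0,
                          rtol = ctl$rtol, atol = ctl$atol)
      trajs[[pl]] <- tr
      dl <- datasetRows(dataset, paste0("lattice_", pl), "Mg-5Gd")
      if (nrow(dl))
        metrics[[paste0("lattice_", pl)]] <-
          metricReport(tr$L[match(dl$time_days, tr$time)], dl$median)
    }
    if (length(trajs) == 0L) {
      tr <- simulateModel(rem5, deg5, NULL, times = tgrid, H0 = ctl$H0,
                          rtol = ctl$rtol, atol = ctl$atol)
      trajs[["bone"]] <- tr
    }
    tr1 <- trajs[[1]]
    for (v in c("bvtv", "cwidth", "vloss")) {
      dv <- datasetRows(dataset, v, "Mg-5Gd")
      if (nrow(dv) == 0L) next
      col <- c(bvtv = "H", cwidth = "Cwidth", vloss = "Vloss")[[v]]
      if (!col %in% names(tr1)) next
      metrics[[v]] <- metricReport(tr1[[col]][match(dv$time_days,
                                                    tr1$time)], dv$median)
    }
    out$`Mg-5Gd` <- list(remodelling = rem5, degradation = deg5,
                         trajectories = trajs, metrics = metrics)
  }
  class(out) <- "osteo_staged"
  out
}

getOr <- function(v, nm, default) if (nm %in% names(v)) v[[nm]] else default

#' @export
print.osteo_staged <- function(x, ...) {
  cat("Staged calibration workflow (degradation model:",
      x$degradation_model, ")\n")
  for (m in names(x$degradation))
    cat("  ", m, "degradation loss:",
        format(x$degradation[[m]]$value, digits = 4), "\n")
  if (!is.null(x$Ti)) cat("  Ti bone fit loss:",
                          format(x$Ti$value, digits = 4), "\n")
  if (!is.null(x$`Mg-10Gd`)) cat("  Mg-10Gd bone fit loss:",
                                 format(x$`Mg-10Gd`$value, digits = 4), "\n")
  if (!is.null(x$`Mg-5Gd`)) {
    cat("  Mg-5Gd prediction MAE:\n")
    for (v in names(x$`Mg-5Gd`$metrics))
      cat("    ", v, ":", format(x$`Mg-5Gd`$metrics[[v]]$mae, digits = 4),
          "\n")
  }
  invisible(x)
}

#' Parameter study over the initial mineral content H(0)
#'
#' Recalibrates the Ti model for each value of `H(0)` on a grid, moving
#' the artificial-point value along with it, and reports the attained
#' loss and per-variable MAE as a function of the initial value.
#'
#' @param dataset study data frame containing Ti rows.
#' @param H0_grid numeric vector of initial values to test.
#' @param control see [workflowControl()]; `n_starts`/`max_iter` bound the
#'   per-value optimization budget.
#' @return Data frame with columns `H0`, `loss`, `mae_bvtv`
#'   (and `mae_cwidth` when crystal-width data are present).
#' @export
h0ParameterStudy <- function(dataset, H0_grid,
                             control = workflowControl(n_starts = 3,
                                                       max_iter = 150)) {
  res <- lapply(H0_grid, function(h0) {
    ctl <- control; ctl$H0 <- h0
    wf <- suppressWarnings(
      stagedWorkflow(dataset[dataset$material == "Ti", , drop = FALSE],
                     control = ctl))
    th <- wf$Ti$par
    rem <- buildRemodelling(th, inhibitor_removal = ctl$inhibitor_removal)
    haveCw <- nrow(datasetRows(dataset, "cwidth", "Ti")) > 0L
    ult <- if (haveCw) buildUltrastructure(th, C0 = ctl$C0) else NULL
    db <- datasetRows(dataset, "bvtv", "Ti")
    dc <- datasetRows(dataset, "cwidth", "Ti")
    tr <- simulateModel(rem, NULL, ult,
                        times = sort(unique(c(0, db$time_days,
                                              dc$time_days))),
                        H0 = h0, rtol = ctl$rtol, atol = ctl$atol)
    row <- data.frame(H0 = h0, loss = wf$Ti$value,
                      mae_bvtv = mae(tr$H[match(db$time_days, tr$time)],
                                     db$median))
    if (haveCw)
      row$mae_cwidth <- mae(tr$Cwidth[match(dc$time_days, tr$time)],
                            dc$median)
    row
  })
  do.call(rbind, res)
}
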