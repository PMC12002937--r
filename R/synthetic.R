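#' Default calibrated parameter sets per material
#'
#' The forward-model truth used by the synthetic-study generator:
#' degradation constants per Mg alloy (surface-rate law `r'`, `d'` and
#' power-law `m1`), bone remodelling rates, and ultrastructure constants
#' per crystallographic plane. The Mg-5Gd bone/ultrastructure values are
#' those calibrated for Mg-10Gd (the transfer assumption of the staged
#' workflow); parameters not refitted for Mg keep their Ti values. A
#' second-study Ti variant (press-fit pins, nonzero initial mineral
#' content) carries its own remodelling rates and `H0 = 42.47`.
#'
#' @param material `"Ti"`, `"Mg-5Gd"` or `"Mg-10Gd"`.
#' @param study `"study1"` (screws, 4-32 weeks) or `"study2"` (Ti pins,
#'   3-90 days).
#' @param degradation_model `"surface_rate"` or `"power_law"`.
#' @param inhibitor_removal passed to [remodellingParams()].
#' @param C0 crystal-width seed passed to [ultrastructureParams()].
#' @return List with elements `remodelling`, `degradation` (or `NULL`),
#'   `ultrastructure` (list by plane, or `NULL`), `H0`.
#' @export
defaultParameters <- function(material = c("Ti", "Mg-5Gd", "Mg-10Gd"),
                              study = c("study1", "study2"),
                              degradation_model = c("surface_rate",
                                                    "power_law"),
                              inhibitor_removal = "mature_matrix",
                              C0 = 1e-3) {
  material <- match.arg(material)
  study <- match.arg(study)
  degradation_model <- match.arg(degradation_model)

  if (study == "study2") {
    if (material != "Ti")
      stop("the second study design contains Ti pins only")
    rem <- remodellingParams(k1 = 18.5965, v1 = 0.3474, r1 = 9.6068,
                             r2 = 0.8024, k3 = 0.6029,
                             inhibitor_removal = inhibitor_removal)
    return(list(remodelling = rem, degradation = NULL,
                ultrastructure = NULL, H0 = 42.47))
  }

  bone <- switch(material,
    "Ti" = list(k1 = 0.3880, v1 = 0.0164, r1 = 0.4915, r2 = 23.1846,
                k3 = 0.5744, m2 = 0),
    list(k1 = 0.3880, v1 = 0.0164, r1 = 0.4915, r2 = 23.1846,
         k3 = 6.9291, m2 = 84.0455))
  rem <- remodellingParams(k1 = bone$k1, v1 = bone$v1, r1 = bone$r1,
                           k3 = bone$k3, r2 = bone$r2, m2 = bone$m2,
                           inhibitor_removal = inhibitor_removal)
  deg <- switch(material,
    "Ti" = NULL,
    "Mg-5Gd" = if (degradation_model == "surface_rate")
      degradationParams("surface_rate", r_prime = 1.104, d_prime = 0.040)
    else degradationParams("power_law", m1 = 0.015),
    "Mg-10Gd" = if (degradation_model == "surface_rate")
      degradationParams("surface_rate", r_prime = 0.062, d_prime = 0.068)
    else degradationParams("power_law", m1 = 0.015))
  kc <- if (material == "Ti") c(k4 = 38.1357, k6 = 1.2694)
        else c(k4 = 115.0688, k6 = 1.4712)
  ult <- list(
    `310` = ultrastructureParams(k4 = kc[["k4"]], k6 = kc[["k6"]],
                                 k7 = 6.2619, k8 = 0.0109,
                                 plane = "310", C0 = C0),
    `002` = ultrastructureParams(k4 = kc[["k4"]], k6 = kc[["k6"]],
                                 k7 = 2.3037, k8 = 0.0092,
                                 plane = "002", C0 = C0))
  list(remodelling = rem, degradation = deg, ultrastructure = ult, H0 = 0)
}

#' Synthetic study design
#'
#' Describes the sparse animal-study sampling the generator emulates.
#' The first study measures BV/TV and implant volume loss at 4, 8, 10,
#' 12, 20 and 32 weeks (28-224 days), crystal width and (310) lattice
#' spacing at 4, 8 and 12 weeks, and (002) quantities at 10, 20 and 32
#' weeks. The second study measures BV/TV of Ti pins at 3, 7, 14, 28 and
#' 90 days. Per-animal scatter is multiplicative Gaussian with
#' coefficient of variation `cv`, except lattice spacings whose dynamic
#' range is tiny and which receive additive Gaussian noise of SD
#' `lattice_sd` Angstrom.
#'
#' @param study `"study1"` or `"study2"`.
#' @param materials materials to include; defaults to all three for
#'   study 1, Ti only for study 2.
#' @param animals animals per time point (default 6).
#' @param cv coefficient of variation of multiplicative noise
#'   (default 0.10).
#' @param lattice_sd additive noise SD for lattice spacings (Angstrom).
#' @param H0 initial mineral content; defaults 0 (study 1) or 42.47
#'   (study 2).
#' @param seed integer seed for dataset generation.
#' @return An object of class `osteo_design`.
#' @export
studyDesign <- function(study = c("study1", "study2"), materials = NULL,
                        animals = 6L, cv = 0.10, lattice_sd = 0.005,
                        H0 = NULL, seed = 1L) {
  study <- match.arg(study)
  stopifnot(animals >= 1L, cv >= 0, lattice_sd >= 0)
  if (is.null(materials))
    materials <- if (study == "study1") c("Ti", "Mg-5Gd", "Mg-10Gd")
                 else "Ti"
  if (is.null(H0)) H0 <- if (study == "study1") 0 else 42.47
  grids <- if (study == "study1") {
    list(bvtv = c(28, 56, 70, 84, 140, 224),
         vloss = c(28, 56, 70, 84, 140, 224),
         cwidth = c(28, 56, 84),
         lattice_310 = c(28, 56, 84),
         lattice_002 = c(70, 140, 224))
  } else {
    list(bvtv = c(3, 7, 14, 28, 90))
  }
  for (g in grids) stopifnot(all(diff(g) > 0))
  structure(list(study = study, materials = materials, grids = grids,
                 animals = as.integer(animals), cv = cv,
                 lattice_sd = lattice_sd, H0 = H0, seed = as.integer(seed)),
            class = "osteo_design")
}

#' @export
print.osteo_design <- function(x, ...) {
  cat("Synthetic study design (", x$study, "): ",
      paste(x$materials, collapse = ", "), "\n", sep = "")
  cat("  animals/time point:", x$animals, " CV:", x$cv,
      " lattice SD:", x$lattice_sd, "A  H0:", x$H0, "\n")
  cat("  variables:", paste(names(x$grids), collapse = ", "), "\n")
  invisible(x)
}

checkTruthBounds <- function(truth, material) {
  b <- parameterBounds(if (material == "Ti") "Ti" else "Mg")
  chk <- function(nm, val) {
    if (is.null(val)) return()
    if (val < b[[nm]][1] - 1e-12 || val > b[[nm]][2] + 1e-12)
      stop("truth parameter '", nm, "' = ", val, " for ", material,
           " outside its calibration bounds [", b[[nm]][1], ", ",
           b[[nm]][2], "]")
  }
  rem <- truth$remodelling
  for (nm in c("k1", "v1", "r1", "r2", "k3")) chk(nm, rem[[nm]])
  if (rem$m2 > 0) chk("m2", rem$m2)
  deg <- truth$degradation
  if (!is.null(deg)) {
    if (deg$model == "power_law") chk("m1", deg$m1)
    else { chk("r_prime", deg$r_prime); chk("d_prime", deg$d_prime) }
  }
  if (!is.null(truth$ultrastructure))
    for (u in truth$ultrastructure)
      for (nm in c("k4", "k6", "k7", "k8")) chk(nm, u[[nm]])
  invisible(TRUE)
}

#' Generate a synthetic study dataset
#'
#' Simulates the coupled forward model per material under the truth
#' parameters, draws `animals` noisy per-animal observations at each
#' design time, and summarizes them as median and standard deviation —
#' the same summary shape as the animal-study tables the model is
#' calibrated against. Deterministic under the design's seed; the
#' caller's RNG state is untouched.
#'
#' @param design an [studyDesign()] object.
#' @param truth named list of per-material truth parameter lists (as from
#'   [defaultParameters()]); defaults to the calibrated values.
#' @return Data frame of class `osteo_dataset` with columns `material`,
#'   `variable`, `time_days`, `median`, `sd`, `n`, and a `"provenance"`
#'   attribute recording truth and seed.
#' @examples
#' d <- studyDesign("study1", cv = 0)
#' head(generateStudy(d))
#' @export
generateStudy <- function(design, truth = NULL) {
  stopifnot(inherits(design, "osteo_design"))
  if (is.null(truth))
    truth <- stats::setNames(
      lapply(design$materials, defaultParameters, study = design$study),
      design$materials)
  for (m in design$materials) {
    if (is.null(truth[[m]]))
      stop("no truth parameters supplied for material ", m)
    checkTruthBounds(truth[[m]], m)
  }
  rows <- withSeed(design$seed, {
    acc <- list()
    for (m in design$materials) {
      tp <- truth[[m]]
      tt <- sort(unique(c(0, unlist(design$grids))))
      # lattice planes are simulated separately (one L state per solve)
      planes <- intersect(c("310", "002"),
                          sub("lattice_", "",
                              grep("lattice_", names(design$grids),
                                   value = TRUE)))
      trajs <- list()
      if (is.null(tp$ultrastructure) || length(planes) == 0L) {
        trajs[["base"]] <- simulateModel(tp$remodelling, tp$degradation,
                                         NULL, times = tt, H0 = tp$H0)
      } else {
        for (pl in planes)
          trajs[[pl]] <- simulateModel(tp$remodelling, tp$degradation,
                                       tp$ultrastructure[[pl]],
                                       times = tt, H0 = tp$H0)
      }
      tr1 <- trajs[[1]]
      valueAt <- function(variable, t) {
        switch(variable,
          bvtv = tr1$H[match(t, tr1$time)],
          vloss = tr1$Vloss[match(t, tr1$time)],
          cwidth = tr1$Cwidth[match(t, tr1$time)],
          lattice_310 = trajs[["310"]]$L[match(t, trajs[["310"]]$time)],
          lattice_002 = trajs[["002"]]$L[match(t, trajs[["002"]]$time)])
      }
      for (v in names(design$grids)) {
        if (v == "vloss" && is.null(tp$degradation)) next
        if (startsWith(v, "lattice") &&
            (is.null(tp$ultrastructure) || is.null(tp$degradation))) next
        if (v == "cwidth" && is.null(tp$ultrastructure)) next
        for (t in design$grids[[v]]) {
          mu <- valueAt(v, t)
          if (is.null(mu) || !is.finite(mu)) next
          obs <- if (startsWith(v, "lattice"))
            mu + stats::rnorm(design$animals, 0, design$lattice_sd)
          else mu * (1 + stats::rnorm(design$animals, 0, design$cv))
          acc[[length(acc) + 1L]] <-
            data.frame(material = m, variable = v, time_days = t,
                       median = stats::median(obs),
                       sd = if (design$animals > 1L) stats::sd(obs) else 0,
                       n = design$animals)
        }
      }
    }
    do.call(rbind, acc)
  })
  rownames(rows) <- NULL
  attr(rows, "provenance") <- list(truth = truth, seed = design$seed,
                                   design = design)
  class(rows) <- c("osteo_dataset", "data.frame")
  rows
}

#' Write frozen synthetic fixtures
#'
#' Generates the study dataset under a fixed seed and writes it as a
#' versioned CSV (schema: material, variable, time_days, median, sd, n),
#' the plain-text fixture format used by the calibration and sensitivity
#' tests.
#'
#' @param study `"study1"` or `"study2"`.
#' @param dir output directory (created if needed).
#' @param seed integer seed (default 20260101).
#' @param cv noise level (default 0.10).
#' @return Invisibly, the written file path.
#' @export
fixtureBundle <- function(study = c("study1", "study2"), dir,
                          seed = 20260101L, cv = 0.10) {
  study <- match.arg(study)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ds <- generateStudy(studyDesign(study, cv = cv, seed = seed))
  path <- file.path(dir, paste0("synthetic_", study, "_seed", seed,
                                ".csv"))
  utils::write.csv(as.data.frame(ds), path, row.names = FALSE)
  invisible(path)
}
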