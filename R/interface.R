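#' Read and validate a run configuration
#'
#' Configurations are flat JSON objects. Unknown keys are rejected so a
#' typo cannot silently fall back to a default; value types are checked
#' before any computation starts.
#'
#' @param path path to a JSON file, or a named list already in memory.
#' @return Validated configuration list of class `osteo_config`.
#' @export
readRunConfig <- function(path) {
  cfg <- if (is.character(path)) jsonlite::fromJSON(path) else path
  validateRunConfig(cfg)
}

configSchema <- function() {
  list(
    command = "character", material = "character", study = "character",
    degradation_model = "character", time_unit = "character",
    seed = "numeric", out_dir = "character",
    rtol = "numeric", atol = "numeric",
    H0 = "numeric", C0 = "numeric",
    n_starts = "numeric", max_iter = "numeric", popsize = "numeric",
    refit_lattice_mg5gd = "logical", inhibitor_removal = "character",
    animals = "numeric", cv = "numeric", lattice_sd = "numeric",
    variable = "character", n_base = "numeric", fraction = "numeric",
    summary = "character", dataset = "character", times_max = "numeric",
    times_step = "numeric"
  )
}

#' @rdname readRunConfig
#' @param cfg named list to validate.
#' @export
validateRunConfig <- function(cfg) {
  schema <- configSchema()
  if (!is.list(cfg) || is.null(names(cfg)) || any(names(cfg) == ""))
    stop("configuration must be a named list / JSON object")
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (k in names(cfg)) {
    ok <- switch(schema[[k]],
                 character = is.character(cfg[[k]]),
                 numeric = is.numeric(cfg[[k]]),
                 logical = is.logical(cfg[[k]]))
    if (!ok || length(cfg[[k]]) != 1L)
      stop("configuration key '", k, "' must be a single ", schema[[k]])
  }
  if (!is.null(cfg$time_unit) && cfg$time_unit != "days")
    stop("only 'days' is supported as time_unit")
  class(cfg) <- c("osteo_config", "list")
  cfg
}

#' Write a trajectory as CSV
#'
#' One column per state variable plus `time` (days); volume loss is also
#' written in percent at this I/O boundary.
#'
#' @param trajectory an `osteo_trajectory`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
writeTrajectory <- function(trajectory, path) {
  df <- as.data.frame(trajectory)
  if ("Vloss" %in% names(df)) df$vloss_percent <- 100 * df$Vloss
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write study datasets
#'
#' CSV schema: `material`, `variable`, `time_days`, `median`, `sd`, `n`.
#'
#' @param path CSV file.
#' @return For `readStudyDataset`, an `osteo_dataset` data frame.
#' @export
readStudyDataset <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("material", "variable", "time_days", "median", "sd", "n")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("dataset is missing column(s): ", paste(missing, collapse = ", "))
  class(d) <- c("osteo_dataset", "data.frame")
  d
}

#' @rdname readStudyDataset
#' @param dataset an `osteo_dataset`.
#' @export
writeStudyDataset <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Every run writes a manifest beside its outputs: the configuration, an
#' md5 hash of its canonical JSON serialization, the seed and the package
#' version, so outputs can be traced to the exact settings that produced
#' them.
#'
#' @param config validated configuration list.
#' @param out_dir output directory.
#' @return Invisibly, the manifest path.
#' @export
writeManifest <- function(config, out_dir) {
  canon <- jsonlite::toJSON(config[order(names(config))],
                            auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(canon, tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  manifest <- list(config = config, config_md5 = hash,
                   seed = config$seed,
                   package_version =
                     as.character(utils::packageVersion("osteomg")))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Execute a pipeline command
#'
#' Programmatic entry point binding the stages into reproducible runs;
#' the thin command-line wrapper in `inst/cli/osteomg.R` forwards to this
#' function. Every run writes its artifacts plus a manifest into
#' `out_dir`.
#'
#' Commands: `"simulate"` (forward model for one material, trajectory
#' CSV), `"synthesize"` (synthetic study dataset CSV), `"calibrate"`
#' (staged workflow on a dataset CSV, fitted parameters JSON + metric
#' summary CSV), `"sensitivity"` (Sobol indices of the volume-loss
#' scalar, CSV), `"evaluate"` (metric summary of a calibration re-run).
#'
#' @param command one of the commands above.
#' @param config an `osteo_config` (or path/list accepted by
#'   [readRunConfig()]).
#' @return Invisibly, a list of written artifact paths.
#' @export
runCommand <- function(command = c("simulate", "synthesize", "calibrate",
                                   "sensitivity", "evaluate"),
                       config) {
  command <- match.arg(command)
  cfg <- readRunConfig(config)
  cfg$command <- command
  out_dir <- cfg$out_dir %||here% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(cfg$seed %||here% 1L)
  paths <- list()

  if (command == "simulate") {
    p <- defaultParameters(cfg$material %||here% "Ti",
                           study = cfg$study %||here% "study1",
                           degradation_model =
                             cfg$degradation_model %||here% "surface_rate")
    tt <- seq(0, cfg$times_max %||here% 230,
              by = cfg$times_step %||here% 1)
    ult <- if (!is.null(p$ultrastructure)) p$ultrastructure[["002"]]
    tr <- simulateModel(p$remodelling, p$degradation, ult, times = tt,
                        H0 = cfg$H0 %||here% p$H0,
                        rtol = cfg$rtol %||here% 1e-8,
                        atol = cfg$atol %||here% 1e-10)
    paths$trajectory <- writeTrajectory(
      tr, file.path(out_dir, paste0("trajectory_",
                                    cfg$material %||here% "Ti", ".csv")))
  } else if (command == "synthesize") {
    des <- studyDesign(cfg$study %||here% "study1",
                       animals = cfg$animals %||here% 6L,
                       cv = cfg$cv %||here% 0.10,
                       lattice_sd = cfg$lattice_sd %||here% 0.005,
                       seed = seed)
    ds <- generateStudy(des)
    paths$dataset <- writeStudyDataset(
      ds, file.path(out_dir, paste0("synthetic_", des$study, ".csv")))
  } else if (command %in% c("calibrate", "evaluate")) {
    if (is.null(cfg$dataset)) stop("'dataset' path required")
    ds <- readStudyDataset(cfg$dataset)
    ctl <- workflowControl(
      n_starts = cfg$n_starts %||here% 10L,
      max_iter = cfg$max_iter %||here% 500L,
      seed = seed, H0 = cfg$H0 %||here% 0,
      refit_lattice_mg5gd = isTRUE(cfg$refit_lattice_mg5gd))
    wf <- stagedWorkflow(ds, cfg$degradation_model %||here% "surface_rate",
                         control = ctl)
    fitted <- list(
      Ti = as.list(wf$Ti$par),
      `Mg-10Gd` = if (!is.null(wf$`Mg-10Gd`)) as.list(wf$`Mg-10Gd`$par),
      degradation = lapply(wf$degradation, function(f) as.list(f$par)),
      lattice = lapply(wf$lattice, function(f) as.list(f$par)))
    paths$fit <- file.path(out_dir, "fit_result.json")
    jsonlite::write_json(fitted, paths$fit, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    ms <- metricSummary(wf)
    paths$metrics <- file.path(out_dir, "metric_summary.csv")
    utils::write.csv(ms, paths$metrics, row.names = FALSE)
  } else if (command == "sensitivity") {
    opt5 <- c(r_prime = 1.104, d_prime = 0.040)
    opt10 <- c(r_prime = 0.062, d_prime = 0.068)
    ranges <- pooledRanges(list(opt5, opt10),
                           fraction = cfg$fraction %||here% 0.2)
    scen <- list(variable = "vloss",
                 degradation = degradationParams("surface_rate",
                                                 r_prime = 0.062,
                                                 d_prime = 0.068),
                 times = c(28, 56, 70, 84, 140, 224),
                 summary = cfg$summary %||here% "mean")
    res <- sobolAnalysis(ranges, scen,
                         n_base = as.integer(cfg$n_base %||here% 1024L),
                         seed = seed)
    paths$sobol <- file.path(out_dir, "sobol_indices.csv")
    utils::write.csv(as.data.frame(res), paths$sobol, row.names = FALSE)
  }
  paths$manifest <- writeManifest(cfg, out_dir)
  invisible(paths)
}
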