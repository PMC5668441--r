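# Configuration and end-to-end pipeline: sample -> simulate -> calibrate ->
# transfect -> classify -> drug trials -> reports, with a manifest tying
# every output to the config and seed.

#' Build a run configuration
#'
#' A fully serialisable description of one population run. A persisted
#' config plus its seed reproduces the run exactly (all randomness flows
#' from the single seed).
#'
#' @param seed integer master seed.
#' @param n number of sampled models.
#' @param interval conductance sampling interval.
#' @param scheme `"uniform"` or `"lhs"`.
#' @param duration_s,window_s solver durations (see [solver_settings()]).
#' @param ranges_file CSV of biomarker ranges (`NULL`: package synthetic
#'   control ranges).
#' @param drug_files named character vector of drug-spec CSVs.
#' @param doses_uM dose list for every trial.
#' @param classification list(biomarker, threshold) for [classify()].
#' @param out_dir output directory.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1, n = 100, interval = c(0.5, 2),
                       scheme = "uniform", duration_s = 800, window_s = 30,
                       ranges_file = NULL, drug_files = character(),
                       doses_uM = c(5, 10, 20),
                       classification = list(biomarker = "APD90",
                                             threshold = NULL),
                       out_dir = "run_output") {
  structure(list(seed = seed, n = n, interval = interval, scheme = scheme,
                 duration_s = duration_s, window_s = window_s,
                 ranges_file = ranges_file, drug_files = drug_files,
                 doses_uM = doses_uM, classification = classification,
                 out_dir = out_dir),
            class = "run_config")
}

#' Read / write a run configuration as JSON
#' @param config a [run_config].
#' @param path JSON file.
#' @export
write_config_json <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, cfg[!vapply(cfg, is.null, logical(1))])
}

#' Default synthetic control calibration ranges
#'
#' The package's stand-in for experimentally derived biomarker windows of
#' control hiPSC-CMs: plausible spans of spontaneous rate, diastolic and
#' peak voltage, amplitude, upstroke velocity and APD, labelled synthetic.
#'
#' @return a [biomarker_ranges] object.
#' @export
default_control_ranges <- function() {
  read_ranges_csv(system.file("extdata", "ranges_synthetic_control.csv",
                              package = "hipscpop", mustWork = TRUE))
}

#' Run the full population pipeline
#'
#' Executes sample, simulate, calibrate, transfect, classify, the drug
#' trials, and the report stage, writing population CSVs, trial tables and a
#' JSON manifest (config, per-stage counts and timings) under
#' `config$out_dir`. A stage failure aborts with the manifest recording the
#' completed stages.
#'
#' @param config a [run_config].
#' @param progress print per-stage progress.
#' @return invisibly, a list with the control and mutant populations, the
#'   trials, and the manifest.
#' @export
run_pipeline <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(config),
                   package_version = as.character(utils::packageVersion("hipscpop")),
                   stages = list())
  t_stage <- function(nm, expr) {
    t0 <- Sys.time()
    val <- tryCatch(force(expr), error = function(e) {
      manifest$stages[[nm]] <<- list(status = "failed",
                                     error = conditionMessage(e))
      .write_manifest(manifest, config$out_dir)
      stop("pipeline stage '", nm, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[nm]] <<- list(
      status = "ok",
      seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 2))
    val
  }

  settings <- solver_settings(duration_s = config$duration_s,
                              window_s = config$window_s)
  samples <- t_stage("sample", sample_population(config$n, config$interval,
                                                 seed = config$seed,
                                                 scheme = config$scheme))
  cand <- t_stage("simulate", simulate_candidates(samples,
                                                  settings = settings,
                                                  progress = progress))
  ranges <- t_stage("ranges", if (is.null(config$ranges_file))
    default_control_ranges() else read_ranges_csv(config$ranges_file))
  control <- t_stage("calibrate", {
    pop <- calibrate(cand, ranges)
    if (!nrow(pop)) stop("no models accepted by calibration")
    pop
  })
  mutant <- t_stage("transfect", transfect(control, settings = settings,
                                           progress = progress))
  mutant <- t_stage("classify", classify(mutant, config$classification))

  trials <- list()
  for (nm in names(config$drug_files)) {
    drug <- read_drug_csv(config$drug_files[[nm]], doses = config$doses_uM)
    trials[[nm]] <- t_stage(paste0("trial_", nm),
                            drug_trial(mutant, drug,
                                       doses = config$doses_uM,
                                       settings = settings,
                                       progress = progress))
  }

  write_population_csv(control, file.path(config$out_dir,
                                          "population_control.csv"))
  write_population_csv(mutant, file.path(config$out_dir,
                                         "population_mutant.csv"))
  counts <- t_stage("report", write_report(control, mutant, trials,
                                           dir = config$out_dir))
  manifest$counts <- counts
  manifest$counts$sampled <- config$n
  manifest$counts$mutant_quiescent_ids <- attr(mutant, "quiescent_ids")
  .write_manifest(manifest, config$out_dir)
  invisible(list(control = control, mutant = mutant, trials = trials,
                 manifest = manifest))
}

.write_manifest <- function(manifest, dir) {
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA, force = TRUE)
}
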