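# Population-of-models machinery: conductance sampling, experimental-range
# calibration, in-silico transfection of the V1763M mutation, phenotype
# classification.

.biomarker_cols <- c("rate", "MDP", "Peak", "APA", "Vmax",
                     "APD30", "APD50", "APD90")

# run a seeded expression without disturbing the caller's RNG stream
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
  }
  force(expr)
}

#' Sample random conductance scale factors
#'
#' Draws one dimensionless multiplicative scale factor per sampled maximal
#' conductance/permeability (the 11 sarcolemmal maxima) and per model, either
#' uniformly or by Latin hypercube stratification.
#'
#' @param n number of models (>= 0).
#' @param interval sampling interval `c(lo, hi)`, `lo < hi`.
#' @param seed integer seed; identical seeds give identical samples.
#' @param scheme `"uniform"` or `"lhs"` (Latin hypercube: each dimension
#'   stratified into `n` equal bins).
#' @return data.frame: `id` plus one column per sampled parameter.
#' @export
sample_population <- function(n, interval = c(0.5, 2), seed = 1,
                              scheme = c("uniform", "lhs")) {
  scheme <- match.arg(scheme)
  if (n < 0) stop("n must be >= 0")
  if (length(interval) != 2 || !all(is.finite(interval)) ||
      interval[1] >= interval[2])
    stop("invalid sampling interval: need finite lo < hi")
  k <- length(.sampled_names)
  if (n == 0) {
    m <- matrix(numeric(0), 0, k, dimnames = list(NULL, .sampled_names))
    return(cbind(data.frame(id = integer(0)), as.data.frame(m)))
  }
  m <- .with_seed(seed, {
    if (scheme == "uniform") {
      matrix(stats::runif(n * k, interval[1], interval[2]), n, k)
    } else {
      vapply(seq_len(k), function(j) {
        strata <- (sample.int(n) - 1 + stats::runif(n)) / n
        interval[1] + strata * (interval[2] - interval[1])
      }, numeric(n))
    }
  })
  m <- matrix(m, n, k, dimnames = list(NULL, .sampled_names))
  cbind(data.frame(id = seq_len(n)), as.data.frame(m))
}

#' Simulate candidates: biomarkers for each sampled model
#'
#' Runs every conductance sample to its quasi-steady beating regime and
#' extracts biomarkers. Quiescent and numerically failed models are retained
#' with their status so that calibration can reject them explicitly.
#'
#' @param samples data.frame from [sample_population()].
#' @param genotype `"control"` or `"V1763M"`.
#' @param settings [solver_settings()].
#' @param blocks optional [block_factors] applied to every model.
#' @param progress print a dot every 25 models.
#' @return data.frame `candidates`: id, scale factors, `status`
#'   (spontaneous/quiescent/failed), `converged`, and biomarker columns.
#' @export
simulate_candidates <- function(samples, genotype = "control",
                                settings = solver_settings(), blocks = NULL,
                                progress = FALSE) {
  stopifnot(is.data.frame(samples), all(.sampled_names %in% names(samples)))
  if (nrow(samples) == 0) {
    out <- cbind(samples[, c("id", .sampled_names), drop = FALSE],
                 data.frame(status = character(0), converged = logical(0)),
                 stats::setNames(as.data.frame(matrix(numeric(0), 0,
                                                      length(.biomarker_cols))),
                                 .biomarker_cols))
    attr(out, "genotype") <- genotype
    return(out)
  }
  rows <- lapply(seq_len(nrow(samples)), function(i) {
    sc <- unlist(samples[i, .sampled_names])
    par <- cell_parameters(genotype = genotype, scale = sc)
    sim <- run_to_steady_state(par, blocks = blocks, settings = settings)
    bm <- .result_biomarkers(sim)
    if (progress && i %% 25 == 0) cat(".")
    cbind(samples[i, , drop = FALSE],
          data.frame(status = sim$status, converged = sim$converged),
          as.data.frame(t(bm$summary)))
  })
  if (progress) cat("\n")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "genotype") <- genotype
  out
}

#' Biomarker acceptance ranges
#'
#' @param df data.frame with columns `biomarker`, `lower`, `upper` (and
#'   optionally `source`), or `NULL` to build from `...`.
#' @param ... named `c(lower, upper)` pairs, e.g. `APD90 = c(200, 600)`.
#' @return object of class `biomarker_ranges` (a data.frame).
#' @export
biomarker_ranges <- function(df = NULL, ...) {
  if (is.null(df)) {
    args <- list(...)
    df <- data.frame(biomarker = names(args),
                     lower = vapply(args, `[`, numeric(1), 1),
                     upper = vapply(args, `[`, numeric(1), 2))
  }
  stopifnot(all(c("biomarker", "lower", "upper") %in% names(df)))
  if (any(df$lower > df$upper))
    stop("invalid ranges: lower > upper for ",
         paste(df$biomarker[df$lower > df$upper], collapse = ", "))
  rownames(df) <- NULL
  class(df) <- c("biomarker_ranges", "data.frame")
  df
}

#' Read / write biomarker ranges as CSV
#' @param path CSV file with columns biomarker, lower, upper (, source).
#' @export
read_ranges_csv <- function(path) {
  biomarker_ranges(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_ranges_csv
#' @param ranges a `biomarker_ranges` object.
#' @export
write_ranges_csv <- function(ranges, path) {
  utils::write.csv(as.data.frame(ranges), path, row.names = FALSE)
  invisible(path)
}

#' Calibrate candidates against experimental biomarker ranges
#'
#' A candidate is accepted iff it beats spontaneously and every biomarker
#' named in `ranges` lies inside its `[lower, upper]` interval (inclusive
#' bounds, so borderline models do not flip under round-off). Quiescent and
#' failed candidates are always rejected. Idempotent: re-calibrating an
#' accepted population with the same ranges changes nothing.
#'
#' @param candidates data.frame from [simulate_candidates()] (or a
#'   population).
#' @param ranges a [biomarker_ranges] object.
#' @return object of class `population`: the accepted rows, with attributes
#'   `ranges`, `genotype`, `rejected_ids`.
#' @export
calibrate <- function(candidates, ranges) {
  stopifnot(is.data.frame(candidates), inherits(ranges, "biomarker_ranges"))
  missing_bm <- setdiff(ranges$biomarker, names(candidates))
  if (length(missing_bm))
    stop("candidates lack biomarker(s) required by the ranges: ",
         paste(missing_bm, collapse = ", "))
  spont <- if ("status" %in% names(candidates))
    candidates$status == "spontaneous" else rep(TRUE, nrow(candidates))
  ok <- spont
  for (i in seq_len(nrow(ranges))) {
    b <- ranges$biomarker[i]
    val <- candidates[[b]]
    ok <- ok & !is.na(val) & val >= ranges$lower[i] & val <= ranges$upper[i]
  }
  pop <- candidates[ok, , drop = FALSE]
  rownames(pop) <- NULL
  structure(pop,
            class = c("population", "data.frame"),
            genotype = attr(candidates, "genotype") %||% "control",
            ranges = ranges,
            rejected_ids = candidates$id[!ok])
}

#' @export
print.population <- function(x, ...) {
  cat("population of", nrow(x), attr(x, "genotype"), "models")
  q <- attr(x, "quiescent_ids")
  if (!is.null(q)) cat(" (", length(q), " quiescent excluded)", sep = "")
  cat("\n")
  if (nrow(x)) print(utils::head(as.data.frame(x)[, c("id", "rate", "MDP",
                                                      "APD90")], 5))
  invisible(x)
}

#' @export
summary.population <- function(object, ...) {
  df <- as.data.frame(object)
  cat("population:", nrow(df), "models, genotype",
      attr(object, "genotype"), "\n")
  print(vapply(df[intersect(.biomarker_cols, names(df))],
               stats::quantile, numeric(5), probs = c(0, .25, .5, .75, 1),
               na.rm = TRUE))
  invisible(object)
}

#' Transfect the V1763M mutation into a calibrated control population
#'
#' Re-simulates every member with the mutant late-sodium formulation and
#' identical conductance scale factors (ids preserved; no re-calibration, as
#' in the in-vitro transfection it mirrors). Members that stop beating under
#' the mutation are excluded from the returned population and logged in
#' `attr(, "quiescent_ids")`; numerical failures in `attr(, "failed_ids")`.
#'
#' @param control a control `population`.
#' @param settings [solver_settings()] used for the mutant simulations.
#' @param progress print progress dots.
#' @return mutant `population` with columns as the control one plus
#'   `APD90_control` and `dAPD90_pct` (paired prolongation per model).
#' @export
transfect <- function(control, settings = solver_settings(),
                      progress = FALSE) {
  stopifnot(inherits(control, "population"))
  if (!identical(attr(control, "genotype"), "control"))
    stop("transfect() expects a control-genotype population")
  cand <- simulate_candidates(as.data.frame(control)[, c("id", .sampled_names)],
                              genotype = "V1763M", settings = settings,
                              progress = progress)
  quiescent <- cand$id[cand$status == "quiescent"]
  failed <- cand$id[cand$status == "failed"]
  keep <- cand$status == "spontaneous"
  mut <- cand[keep, , drop = FALSE]
  mut$APD90_control <- control$APD90[match(mut$id, control$id)]
  mut$dAPD90_pct <- 100 * (mut$APD90 / mut$APD90_control - 1)
  rownames(mut) <- NULL
  structure(mut,
            class = c("population", "data.frame"),
            genotype = "V1763M",
            ranges = attr(control, "ranges"),
            quiescent_ids = quiescent,
            failed_ids = failed)
}

#' Classify mutant models as symptomatic or asymptomatic
#'
#' Default rule: a mutant model is symptomatic iff its APD90 exceeds the
#' upper APD90 bound used to calibrate the control population (models whose
#' repolarisation leaves the normal range), matching the split of the mutant
#' population into a prolonged-APD and a normal-APD group.
#'
#' @param mutant a mutant `population` (from [transfect()]).
#' @param rule list with `biomarker` (default `"APD90"`) and `threshold`
#'   (ms); when `threshold` is `NULL` the upper calibration bound of that
#'   biomarker is used.
#' @return the population with a `label` column
#'   (`"symptomatic"`/`"asymptomatic"`).
#' @export
classify <- function(mutant, rule = list(biomarker = "APD90",
                                         threshold = NULL)) {
  stopifnot(inherits(mutant, "population"))
  b <- rule$biomarker %||% "APD90"
  if (!b %in% names(mutant))
    stop("classification rule references absent biomarker: ", b)
  thr <- rule$threshold
  if (is.null(thr)) {
    rg <- attr(mutant, "ranges")
    if (is.null(rg) || !b %in% rg$biomarker)
      stop("no threshold given and no calibration range available for ", b)
    thr <- rg$upper[rg$biomarker == b]
  }
  lab <- ifelse(mutant[[b]] > thr, "symptomatic", "asymptomatic")
  mutant$label <- lab
  attr(mutant, "classification") <- list(biomarker = b, threshold = thr)
  mutant
}

#' Write / read a population as CSV
#'
#' One row per model: id, the 11 scale factors, genotype, status, biomarkers
#' and (if present) label. Attributes required to rebuild the object are not
#' serialised beyond the genotype column.
#'
#' @param pop a `population`.
#' @param path CSV file.
#' @export
write_population_csv <- function(pop, path) {
  df <- as.data.frame(pop)
  df$genotype <- attr(pop, "genotype") %||% "control"
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_population_csv
#' @export
read_population_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  geno <- unique(df$genotype) %||% "control"
  if (length(geno) > 1) stop("population file mixes genotypes")
  df$genotype <- NULL
  structure(df, class = c("population", "data.frame"), genotype = geno)
}
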