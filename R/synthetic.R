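# Synthetic fixtures: analytic waveforms with closed-form biomarkers,
# range tables around a reference, toy populations with planted group
# differences. Everything is seed-deterministic and emits the same objects
# as the real pipeline, so fixtures are drop-in.

#' Generate a parametric AP-like waveform with known biomarkers
#'
#' Each beat: a hold at `mdp_mV`, a linear upstroke of `upstroke_ms`, then
#' repolarisation back to `mdp_mV` -- linear over `repol_ms`, or exponential
#' decay with time constant `tau_ms` (APD90 is then `tau_ms * ln 10` after
#' the peak, by construction).
#'
#' @param mdp_mV,peak_mV diastolic and peak voltage (mV).
#' @param upstroke_ms upstroke duration (ms).
#' @param shape `"linear"` or `"exponential"` repolarisation.
#' @param repol_ms linear repolarisation duration (ms).
#' @param tau_ms exponential repolarisation time constant (ms).
#' @param cycle_ms cycle length (ms).
#' @param beats number of beats.
#' @param dt_ms sampling interval (ms).
#' @param lead_ms diastolic lead-in before the first upstroke (ms).
#' @return an [ap_trace] (dVdt from finite differences).
#' @export
make_waveform <- function(mdp_mV = -80, peak_mV = 40, upstroke_ms = 2,
                          shape = c("linear", "exponential"), repol_ms = 300,
                          tau_ms = 100, cycle_ms = 1000, beats = 5,
                          dt_ms = 1, lead_ms = 100) {
  shape <- match.arg(shape)
  if (peak_mV <= mdp_mV) stop("peak must exceed MDP")
  if (any(c(upstroke_ms, repol_ms, tau_ms, cycle_ms, dt_ms) <= 0))
    stop("durations must be > 0")
  apa <- peak_mV - mdp_mV
  one_ms <- seq(0, cycle_ms - dt_ms, by = dt_ms)
  vbeat <- vapply(one_ms, function(tm) {
    if (tm < upstroke_ms) return(mdp_mV + apa * tm / upstroke_ms)
    te <- tm - upstroke_ms
    if (shape == "linear") {
      if (te >= repol_ms) mdp_mV else peak_mV - apa * te / repol_ms
    } else {
      mdp_mV + apa * exp(-te / tau_ms)
    }
  }, numeric(1))
  v <- c(rep(mdp_mV, round(lead_ms / dt_ms)), rep(vbeat, beats), mdp_mV)
  t <- (seq_along(v) - 1) * dt_ms / 1000
  dv <- c(diff(v) / diff(t) / 1000, 0)  # V/s
  .new_trace(t, v, dv, rep(0, length(v)),
             meta = list(synthetic = TRUE, shape = shape))
}

#' Build a biomarker-range table around a reference
#'
#' Stand-in for an experimental calibration table: each biomarker's window
#' is `reference +/- tightness * |reference|`.
#'
#' @param reference an `ap_biomarkers` object or named numeric vector of
#'   biomarker values.
#' @param tightness positive fraction; larger accepts more.
#' @param biomarkers which biomarkers to constrain.
#' @param seed accepted for interface uniformity (the construction is
#'   deterministic).
#' @return a [biomarker_ranges] object.
#' @export
make_range_table <- function(reference, tightness = 0.3,
                             biomarkers = c("rate", "MDP", "Peak", "APA",
                                            "Vmax", "APD90"),
                             seed = NULL) {
  if (inherits(reference, "ap_biomarkers")) reference <- reference$summary
  if (tightness <= 0) stop("tightness must be > 0")
  ref <- reference[biomarkers]
  if (any(is.na(ref))) stop("reference lacks biomarker(s): ",
                            paste(biomarkers[is.na(ref)], collapse = ", "))
  half <- tightness * abs(ref)
  biomarker_ranges(data.frame(biomarker = biomarkers,
                              lower = unname(ref - half),
                              upper = unname(ref + half),
                              source = "synthetic"))
}

#' Build a toy population with planted group differences
#'
#' Constructs a labelled population-shaped object in which the labelled
#' subgroup's conductance scale factors differ from the reference group by
#' exact multiplicative offsets, so that [compare_groups()] recovers the
#' planted percent differences exactly (same base draw in both groups).
#'
#' @param n total number of models (>= 2; split evenly).
#' @param planted named numeric vector of percent median differences to
#'   plant, in percent (e.g. `c(g_NaL = 41)` plants +41 percent in group A).
#' @param seed RNG seed.
#' @param labels the two group labels (A = planted group first).
#' @return a labelled `population` with known group structure.
#' @export
make_toy_population <- function(n = 40, planted = c(g_NaL = 41), seed = 1,
                                labels = c("symptomatic", "asymptomatic")) {
  if (n < 2) stop("n must be >= 2")
  bad <- setdiff(names(planted), .sampled_names)
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  nb <- n %/% 2
  na <- n - nb
  base <- .with_seed(seed, matrix(stats::rlnorm(nb * length(.sampled_names),
                                                0, 0.25),
                                  nb, length(.sampled_names),
                                  dimnames = list(NULL, .sampled_names)))
  # group A re-uses group B's draws so planted median ratios are exact
  a <- base[rep_len(seq_len(nb), na), , drop = FALSE]
  for (nm in names(planted)) a[, nm] <- a[, nm] * (1 + planted[[nm]] / 100)
  df <- as.data.frame(rbind(a, base))
  df <- cbind(data.frame(id = seq_len(n)), df)
  df$status <- "spontaneous"
  df$label <- rep(labels, c(na, nb))
  # plausible biomarkers, deterministic in the scales
  df$APD90 <- 420 * df$g_NaL / 1
  df$rate <- 40 / df$g_K1^0.1
  df$MDP <- -76; df$Peak <- 22; df$APA <- 98; df$Vmax <- 22
  df$APD50 <- 0.8 * df$APD90; df$APD30 <- 0.6 * df$APD90
  structure(df, class = c("population", "data.frame"),
            genotype = "V1763M", seed = seed, planted = planted)
}

#' Write a complete toy workspace of fixtures
#'
#' Emits a synthetic range table, a fictitious test-drug spec (its 20 uM dose
#' halves I_NaL) and a small toy population, in the same file formats the
#' real pipeline reads.
#'
#' @param dir output directory.
#' @param seed RNG seed.
#' @return invisibly, the written file paths.
#' @export
make_fixtures <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- c(rate = 39, MDP = -76, Peak = 22, APA = 98, Vmax = 22,
           APD30 = 300, APD50 = 360, APD90 = 420)
  f1 <- file.path(dir, "ranges_toy.csv")
  write_ranges_csv(make_range_table(ref, tightness = 0.4), f1)
  f2 <- file.path(dir, "drug_testdrug.csv")
  utils::write.csv(data.frame(drug = "testdrug", channel = "I_NaL",
                              genotype = "any", IC50_uM = 20, hill = 1),
                   f2, row.names = FALSE)
  f3 <- file.path(dir, "population_toy.csv")
  write_population_csv(make_toy_population(seed = seed), f3)
  invisible(c(f1, f2, f3))
}
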