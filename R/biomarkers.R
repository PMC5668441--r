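# Biomarker extraction: the calibration and reporting currency of the
# population method.

#' Extract action-potential biomarkers from detected cycles
#'
#' Per beat: `MDP` = minimum Vm of the cycle (mV); `Peak` = maximum Vm (mV);
#' `APA` = Peak - MDP (mV); `Vmax` = maximum upstroke velocity (V/s);
#' `APDx` = time (ms) from the instant of maximum upstroke velocity to the
#' downward crossing of `Peak - x/100 * APA` (levels interpolated linearly
#' between samples). `rate` (beats/min) is 60 over the mean upstroke-to-
#' upstroke interval and requires at least two cycles. The per-model summary
#' is the mean over the last `last_n` complete beats.
#'
#' @param cycles cycle table from [detect_cycles()].
#' @param trace the [ap_trace] the cycles were detected in.
#' @param apd_levels repolarisation percentages for APD measurement.
#' @param last_n number of final beats averaged into the summary.
#' @return object of class `ap_biomarkers`: list with `summary` (named
#'   vector: rate, MDP, Peak, APA, Vmax, APD30, APD50, APD90, ...),
#'   `per_beat` (data.frame), `n_beats`, and `defined`. When no complete
#'   cycle is available the object has `defined = FALSE` and an all-`NA`
#'   summary -- the undefined-biomarkers signal, distinct from numeric zero.
#' @export
extract_biomarkers <- function(cycles, trace, apd_levels = c(30, 50, 90),
                               last_n = 3) {
  stopifnot(inherits(trace, "ap_trace"))
  apd_levels <- sort(apd_levels)
  apd_names <- paste0("APD", apd_levels)
  cols <- c("rate", "MDP", "Peak", "APA", "Vmax", apd_names)

  undefined <- structure(list(
    summary = stats::setNames(rep(NA_real_, length(cols)), cols),
    per_beat = NULL, n_beats = 0L, defined = FALSE),
    class = "ap_biomarkers")
  if (is.null(cycles) || nrow(cycles) == 0) return(undefined)

  t <- trace$time; v <- trace$Vm
  beats <- lapply(seq_len(nrow(cycles)), function(k) {
    cy <- cycles[k, ]
    seg <- cy$i_start:cy$i_end
    pk <- max(v[seg]); mdp <- min(v[seg]); apa <- pk - mdp
    iu <- cy$i_upstroke
    vmax <- trace$dVdt[iu]
    tu <- t[iu]
    post <- seg[t[seg] >= tu]
    apd <- vapply(apd_levels, function(x) {
      lev <- pk - x / 100 * apa
      # first downward crossing of lev after the peak
      ipk <- post[which.max(v[post])]
      after <- post[post >= ipk]
      below <- which(v[after] <= lev)
      if (!length(below)) return(NA_real_)
      i2 <- after[below[1]]
      if (below[1] == 1) return((t[i2] - tu) * 1000)
      i1 <- after[below[1] - 1]
      tc <- t[i1] + (lev - v[i1]) * (t[i2] - t[i1]) / (v[i2] - v[i1])
      (tc - tu) * 1000
    }, numeric(1))
    c(t_upstroke = tu, MDP = mdp, Peak = pk, APA = apa, Vmax = vmax,
      stats::setNames(apd, apd_names))
  })
  pb <- as.data.frame(do.call(rbind, beats))

  rate <- if (nrow(cycles) >= 2) 60 / mean(diff(cycles$t_upstroke)) else 0
  keep <- utils::tail(seq_len(nrow(pb)), last_n)
  summ <- c(rate = rate,
            colMeans(pb[keep, c("MDP", "Peak", "APA", "Vmax", apd_names),
                        drop = FALSE], na.rm = TRUE))
  structure(list(summary = summ, per_beat = pb, n_beats = nrow(pb),
                 defined = TRUE),
            class = "ap_biomarkers")
}

#' @export
print.ap_biomarkers <- function(x, ...) {
  if (!x$defined) {
    cat("ap_biomarkers: undefined (no complete AP cycle)\n")
  } else {
    cat("ap_biomarkers over", x$n_beats, "beats:\n")
    print(round(x$summary, 2))
  }
  invisible(x)
}

# biomarkers of a simulation_result, or undefined signal if not spontaneous
.result_biomarkers <- function(result, apd_levels = c(30, 50, 90)) {
  if (!inherits(result, "simulation_result") || !result$spontaneous)
    return(extract_biomarkers(NULL, .new_trace(numeric(0), numeric(0),
                                               numeric(0), numeric(0)),
                              apd_levels = apd_levels))
  s <- result$settings
  cyc <- detect_cycles(result$trace, threshold_mV = s$threshold_mV,
                       min_amplitude_mV = s$min_amplitude_mV)
  extract_biomarkers(cyc, result$trace, apd_levels = apd_levels,
                     last_n = s$steady_beats)
}

#' Persistent late sodium current of a steady-state spontaneous AP
#'
#' The gain-of-function quantification point: I_NaL sampled a fixed delay
#' after the instant of maximum upstroke velocity (default 200 ms), averaged
#' over the last complete beats of the analysis window.
#'
#' @param result a spontaneous [run_to_steady_state()] result.
#' @param delay_ms measurement delay after the upstroke (ms).
#' @param last_n number of final beats averaged.
#' @return persistent I_NaL in A/F (negative = inward).
#' @export
persistent_inal <- function(result, delay_ms = 200, last_n = 3) {
  stopifnot(inherits(result, "simulation_result"))
  if (!result$spontaneous) stop("persistent I_NaL undefined: no spontaneous APs")
  s <- result$settings
  cyc <- detect_cycles(result$trace, threshold_mV = s$threshold_mV,
                       min_amplitude_mV = s$min_amplitude_mV)
  tu <- utils::tail(cyc$t_upstroke, last_n + 1)
  tu <- tu[tu + delay_ms / 1000 <= max(result$trace$time)]
  tu <- utils::tail(tu, last_n)
  if (!length(tu)) stop("analysis window too short for the measurement delay")
  vals <- stats::approx(result$trace$time, result$trace$INaL,
                        xout = tu + delay_ms / 1000)$y
  mean(vals)
}

#' Write a biomarker table as CSV
#'
#' One row per model; columns `id, rate, MDP, Peak, APA, Vmax, APD30, APD50,
#' APD90` (plus any extra APD levels present).
#'
#' @param x data.frame with an `id` column and biomarker columns (e.g. the
#'   core of a population object), or a single `ap_biomarkers`.
#' @param path output file.
#' @export
write_biomarkers_csv <- function(x, path) {
  if (inherits(x, "ap_biomarkers"))
    x <- cbind(data.frame(id = 1L), as.data.frame(t(x$summary)))
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
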