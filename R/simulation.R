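# Simulation layer: integration to a stable spontaneous-beating regime,
# AP cycle detection, trace export.

#' Solver and analysis settings
#'
#' @param duration_s total simulated time (s). The paper-scale default is a
#'   long pre-run so that every population member reaches a quasi-steady
#'   beating regime before biomarkers are read.
#' @param window_s length of the final analysis window (s) that is recorded
#'   and used for biomarker extraction.
#' @param dt_out_s output sampling interval of the recorded window (s).
#' @param rtol,atol relative/absolute tolerance of the adaptive integrator
#'   (absolute tolerances are scaled per state by typical magnitudes).
#' @param max_step_s maximum integration step (s).
#' @param threshold_mV upward-crossing level defining an action potential.
#' @param min_amplitude_mV minimum Vm excursion for a cycle to count as an AP
#'   (rejects sub-threshold oscillations).
#' @param steady_tol_ms steady state is declared when consecutive-beat APD90
#'   spreads less than this over the last `steady_beats` beats.
#' @param steady_beats number of final beats used for the steady-state check
#'   and for biomarker averaging.
#' @param record_currents record all 13 membrane currents in the trace
#'   (I_NaL is always recorded).
#' @param initial_state starting state; default [initial_state()].
#' @return list of class `solver_settings`.
#' @export
solver_settings <- function(duration_s = 800, window_s = 30, dt_out_s = 5e-4,
                            rtol = 1e-5, atol = 1e-5, max_step_s = 1e-3,
                            threshold_mV = 0, min_amplitude_mV = 40,
                            steady_tol_ms = 5, steady_beats = 3,
                            record_currents = FALSE, initial_state = NULL) {
  if (duration_s < 0) stop("duration_s must be >= 0")
  if (window_s < 0 || dt_out_s <= 0) stop("invalid window/output settings")
  structure(list(duration_s = duration_s, window_s = min(window_s, duration_s),
                 dt_out_s = dt_out_s, rtol = rtol, atol = atol,
                 max_step_s = max_step_s, threshold_mV = threshold_mV,
                 min_amplitude_mV = min_amplitude_mV,
                 steady_tol_ms = steady_tol_ms, steady_beats = steady_beats,
                 record_currents = record_currents,
                 initial_state = initial_state),
            class = "solver_settings")
}

.new_trace <- function(time, Vm, dVdt, INaL, currents = NULL, meta = list()) {
  structure(list(time = time, Vm = Vm, dVdt = dVdt, INaL = INaL,
                 currents = currents, meta = meta),
            class = "ap_trace")
}

#' @export
print.ap_trace <- function(x, ...) {
  cat("AP trace: ", length(x$time), " samples, t = [",
      round(min(x$time), 3), ", ", round(max(x$time), 3), "] s, Vm = [",
      round(min(x$Vm), 1), ", ", round(max(x$Vm), 1), "] mV\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.ap_trace <- function(x, ...) {
  df <- data.frame(time_s = x$time, Vm_mV = x$Vm, dVdt_V_per_s = x$dVdt,
                   I_NaL_A_per_F = x$INaL)
  if (!is.null(x$currents)) df <- cbind(df, as.data.frame(x$currents))
  df
}

#' @export
plot.ap_trace <- function(x, ...) {
  plot(x$time, x$Vm, type = "l", xlab = "time (s)", ylab = "Vm (mV)", ...)
  invisible(x)
}

#' Write a trace as CSV
#' @param trace an `ap_trace`.
#' @param path output file.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' Integrate a cell model to a stable spontaneous-beating regime
#'
#' Runs the stiff Hodgkin-Huxley system with an adaptive Rush-Larsen
#' integrator for `duration_s` simulated seconds and records the final
#' `window_s` for analysis. The result is classified as exactly one of
#' `spontaneous` (action potentials detected in the window), `quiescent`
#' (no AP-sized Vm excursion), or `failed` (numerical breakdown).
#'
#' @param params a [cell_parameters] object.
#' @param blocks optional [block_factors] (drug block), default none.
#' @param settings a [solver_settings] object.
#' @return object of class `simulation_result`: list with `trace`
#'   ([ap_trace] of the analysis window), `status`, `spontaneous`,
#'   `converged` (steady-state APD90 criterion met) and `diagnostics`.
#' @export
run_to_steady_state <- function(params, blocks = NULL,
                                settings = solver_settings()) {
  stopifnot(inherits(params, "cell_parameters"),
            inherits(settings, "solver_settings"))
  y0 <- settings$initial_state %||% .baseline_initial_state
  y0 <- .check_state(y0)

  if (settings$duration_s == 0) {
    tr <- .new_trace(0, 1000 * y0[1], NA_real_, NA_real_)
    return(structure(list(trace = tr, status = "quiescent",
                          spontaneous = FALSE, converged = FALSE,
                          diagnostics = list(beats = 0L, apd_drift_ms = NA,
                                             n_steps = 0),
                          params = params, settings = settings),
                     class = "simulation_result"))
  }

  res <- .integrate_model(y0, .params_vec(params), .blocks_vec(blocks),
                          t_end = settings$duration_s,
                          record_from = settings$duration_s - settings$window_s,
                          dt_out = settings$dt_out_s,
                          rtol = settings$rtol, atol = settings$atol,
                          max_step = settings$max_step_s,
                          record_currents = settings$record_currents)

  cur <- NULL
  if (settings$record_currents && !is.null(res$currents)) {
    cur <- t(res$currents)
    colnames(cur) <- .current_names
  }
  tr <- .new_trace(res$time, res$Vm, res$dVdt, res$INaL, cur,
                   meta = list(settings = settings,
                               final_state = stats::setNames(res$final_state,
                                                             .state_names)))

  if (res$status != 0 || any(!is.finite(res$Vm))) {
    return(structure(list(trace = tr, status = "failed", spontaneous = FALSE,
                          converged = FALSE,
                          diagnostics = list(beats = NA_integer_,
                                             apd_drift_ms = NA,
                                             n_steps = res$n_steps,
                                             t_reached = res$t_reached),
                          params = params, settings = settings),
                     class = "simulation_result"))
  }

  cyc <- detect_cycles(tr, threshold_mV = settings$threshold_mV,
                       min_amplitude_mV = settings$min_amplitude_mV)
  spont <- nrow(cyc) >= 2
  conv <- FALSE
  drift <- NA_real_
  if (spont) {
    bm <- extract_biomarkers(cyc, tr, last_n = settings$steady_beats)
    ap <- bm$per_beat$APD90
    ap <- ap[!is.na(ap)]
    if (length(ap) >= settings$steady_beats) {
      last <- utils::tail(ap, settings$steady_beats)
      drift <- max(last) - min(last)
      conv <- drift < settings$steady_tol_ms
    }
  }
  structure(list(trace = tr, status = if (spont) "spontaneous" else "quiescent",
                 spontaneous = spont, converged = conv,
                 diagnostics = list(beats = nrow(cyc), apd_drift_ms = drift,
                                    n_steps = res$n_steps,
                                    n_reject = res$n_reject),
                 params = params, settings = settings),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("simulation_result: status =", x$status,
      "| beats =", x$diagnostics$beats,
      "| converged =", x$converged, "\n")
  invisible(x)
}

#' Detect spontaneous AP cycles in a voltage trace
#'
#' An AP is an upward crossing of `threshold_mV` whose enclosing cycle has a
#' Vm excursion of at least `min_amplitude_mV`. Cycles span from one maximum
#' diastolic potential to the next (trace edges serve as the outer
#' boundaries), so a trace with k detected upstrokes yields k cycles.
#'
#' @param trace an [ap_trace].
#' @param threshold_mV AP detection level (upward crossing, positive slope).
#' @param min_amplitude_mV minimum excursion; smaller oscillations are not
#'   APs.
#' @return data.frame with one row per cycle: sample indices
#'   (`i_start`, `i_end`, `i_upstroke`), times (`t_start`, `t_end`,
#'   `t_upstroke` = time of maximum upstroke velocity). Empty (0 rows) for a
#'   quiescent trace.
#' @export
detect_cycles <- function(trace, threshold_mV = 0, min_amplitude_mV = 40) {
  stopifnot(inherits(trace, "ap_trace"))
  v <- trace$Vm
  t <- trace$time
  n <- length(v)
  empty <- data.frame(i_start = integer(0), i_end = integer(0),
                      i_upstroke = integer(0), t_start = numeric(0),
                      t_end = numeric(0), t_upstroke = numeric(0))
  if (n < 3) return(empty)
  above <- v > threshold_mV
  cross <- which(!above[-n] & above[-1]) + 1L  # first index above threshold
  if (!length(cross)) return(empty)

  # cycle boundaries: trace start, diastolic minimum between consecutive
  # upstrokes, trace end
  bounds <- c(1L, vapply(seq_len(length(cross) - 1), function(k) {
    seg <- cross[k]:cross[k + 1]
    seg[which.min(v[seg])]
  }, integer(1)), n)

  out <- lapply(seq_along(cross), function(k) {
    i0 <- bounds[k]; i1 <- bounds[k + 1]
    seg <- i0:i1
    if (max(v[seg]) - min(v[seg]) < min_amplitude_mV) return(NULL)
    # exclude the closing boundary sample: it can carry the next beat's
    # upstroke slope and must not win the max-dV/dt search
    sseg <- seg[-length(seg)]
    dv <- trace$dVdt[sseg]
    iu <- if (all(is.na(dv))) seg[1] else sseg[which.max(dv)]
    data.frame(i_start = i0, i_end = i1, i_upstroke = iu,
               t_start = t[i0], t_end = t[i1], t_upstroke = t[iu])
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) empty else out
}
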