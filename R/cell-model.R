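# Cell model layer: parameters, state, currents, mutation.
#
# Internal convention: membrane voltage in VOLTS inside the state vector and
# ODE core (as in the source model family); traces and biomarkers are in mV
# and ms at the user-facing boundary.

# Names/order must match the enums in src/model.cpp.
.state_names <- c("Vm", "m", "h", "j", "d", "f1", "f2", "fCa",
                  "Xr1", "Xr2", "Xs", "Xf", "q", "r", "g",
                  "mL", "hL", "Nai", "Cai", "CaSR")
.param_names <- c("g_Na", "g_NaL", "P_CaL", "g_Kr", "g_Ks", "g_K1", "g_f",
                  "g_to", "k_NCX", "P_NaK", "g_pCa",
                  "mut_gNaL_scale", "mut_hL_shift_mV", "mut_tau_hL_factor",
                  "genotype_flag")
.current_names <- c("I_Na", "I_NaL", "I_CaL", "I_Kr", "I_Ks", "I_K1", "I_f",
                    "I_to", "I_NCX", "I_NaK", "I_pCa", "I_bNa", "I_bCa")
.sampled_names <- .param_names[1:11]
.blocked_channels <- c("I_Na", "I_NaL", "I_Kr", "I_CaL")

# Baseline maximal conductances/permeabilities (S/F; P_CaL in m^3/(F*s),
# k_NCX and P_NaK and g_pCa in A/F), ventricular-like hiPSC-CM baseline.
# g_NaL and the V1763M gain-of-function knobs are calibrated against the
# observable constraints of the modelled mutation (persistent-I_NaL ratio
# 4.86 at 200 ms post-upstroke; +43% APD90); see the methods vignette.
.baseline_maxima <- c(
  g_Na  = 3671.2302,
  g_NaL = 58.0,
  P_CaL = 8.635702e-5,
  g_Kr  = 29.8667,
  g_Ks  = 2.041,
  g_K1  = 28.1492,
  g_f   = 30.10312,
  g_to  = 29.9038,
  k_NCX = 4872.9136,
  P_NaK = 1.841424,
  g_pCa = 0.4125
)

# Calibrated V1763M late-Na gain-of-function knobs (see vignette).
.mutant_defaults <- c(mut_gNaL_scale = 1.33, mut_hL_shift_mV = 2.0,
                      mut_tau_hL_factor = 10.0)

# Fixed physical constants (duplicated from the C++ core for user inspection).
.fixed_constants <- c(
  C_m = 9.87109e-11, T_kelvin = 310, F = 96485.3415, R_gas = 8.314472,
  V_cytosol_um3 = 8800, V_SR_um3 = 583.73,
  Na_o = 151, K_o = 5.4, Ca_o = 1.8, K_i = 150,
  g_b_Na = 0.9, g_b_Ca = 0.69264
)

#' Construct a set of cell parameters
#'
#' Builds the maximal conductances/permeabilities of the eleven sarcolemmal
#' currents of the spontaneous hiPSC-CM action-potential model, optionally
#' scaled per current, together with the genotype of the late sodium current
#' (`"control"` or the LQT3 gain-of-function variant `"V1763M"`).
#'
#' @param genotype `"control"` or `"V1763M"`.
#' @param scale named numeric vector of dimensionless multiplicative scale
#'   factors applied to the baseline maxima; names must be a subset of
#'   `c("g_Na","g_NaL","P_CaL","g_Kr","g_Ks","g_K1","g_f","g_to","k_NCX",
#'   "P_NaK","g_pCa")`. Unnamed entries of length 11 are matched positionally.
#' @param mut_gNaL_scale,mut_hL_shift_mV,mut_tau_hL_factor calibration of the
#'   V1763M variant: conductance scale, depolarising shift (mV) of the
#'   slow-inactivation steady state, and slowing factor on its time constant.
#'   Defaults are the package's calibrated values (persistent-current ratio
#'   4.86 at 200 ms post-upstroke, +43% APD90); no effect for the control
#'   genotype.
#' @return An object of class `cell_parameters`: a list with the absolute
#'   maxima (`maxima`), `genotype`, the mutant knobs, and the fixed physical
#'   constants (`constants`, immutable).
#' @examples
#' p <- cell_parameters()
#' pm <- apply_mutation(p)
#' pm$genotype
#' @export
cell_parameters <- function(genotype = c("control", "V1763M"), scale = NULL,
                            mut_gNaL_scale = .mutant_defaults[["mut_gNaL_scale"]],
                            mut_hL_shift_mV = .mutant_defaults[["mut_hL_shift_mV"]],
                            mut_tau_hL_factor = .mutant_defaults[["mut_tau_hL_factor"]]) {
  genotype <- match.arg(genotype)
  maxima <- .baseline_maxima
  if (!is.null(scale)) {
    scale <- unlist(scale)
    if (is.null(names(scale))) {
      if (length(scale) != length(.sampled_names))
        stop("unnamed `scale` must have length ", length(.sampled_names))
      names(scale) <- .sampled_names
    }
    unknown <- setdiff(names(scale), .sampled_names)
    if (length(unknown))
      stop("unknown parameter(s) in `scale`: ", paste(unknown, collapse = ", "))
    if (any(!is.finite(scale)) || any(scale < 0))
      stop("scale factors must be finite and >= 0")
    maxima[names(scale)] <- maxima[names(scale)] * scale
  }
  structure(list(maxima = maxima, genotype = genotype,
                 mut_gNaL_scale = mut_gNaL_scale,
                 mut_hL_shift_mV = mut_hL_shift_mV,
                 mut_tau_hL_factor = mut_tau_hL_factor,
                 constants = .fixed_constants),
            class = "cell_parameters")
}

#' @export
print.cell_parameters <- function(x, ...) {
  cat("hiPSC-CM cell parameters (genotype: ", x$genotype, ")\n", sep = "")
  print(signif(x$maxima, 6))
  if (x$genotype == "V1763M")
    cat("V1763M I_NaL: conductance x", x$mut_gNaL_scale,
        ", hL_inf shift +", x$mut_hL_shift_mV, " mV, tau_hL x",
        x$mut_tau_hL_factor, "\n", sep = "")
  invisible(x)
}

# flatten to the numeric vector the C++ core expects
.params_vec <- function(params) {
  stopifnot(inherits(params, "cell_parameters"))
  c(unname(params$maxima),
    params$mut_gNaL_scale, params$mut_hL_shift_mV, params$mut_tau_hL_factor,
    as.numeric(params$genotype == "V1763M"))
}

#' Express the V1763M late-sodium mutation in a parameter set
#'
#' Switches the genotype to `V1763M`, leaving every sampled conductance scale
#' untouched (the in-silico analogue of transfecting the mutant channel).
#' Idempotent.
#'
#' @param params a [cell_parameters] object.
#' @return the same parameters with `genotype = "V1763M"`.
#' @export
apply_mutation <- function(params) {
  stopifnot(inherits(params, "cell_parameters"))
  params$genotype <- "V1763M"
  params
}

#' Pore-block factors for the drug-targeted channels
#'
#' @param I_Na,I_NaL,I_Kr,I_CaL multiplicative conductance factors in
#'   `[0, 1]`; 1 means no block.
#' @return a named numeric vector of class `block_factors`.
#' @export
block_factors <- function(I_Na = 1, I_NaL = 1, I_Kr = 1, I_CaL = 1) {
  b <- c(I_Na = I_Na, I_NaL = I_NaL, I_Kr = I_Kr, I_CaL = I_CaL)
  if (any(!is.finite(b)) || any(b < 0) || any(b > 1))
    stop("block factors must lie in [0, 1]")
  structure(b, class = "block_factors")
}

.blocks_vec <- function(blocks) {
  if (is.null(blocks)) return(rep(1, 4))
  stopifnot(inherits(blocks, "block_factors"))
  unname(blocks[c("I_Na", "I_NaL", "I_Kr", "I_CaL")])
}

#' Default initial state of the cell model
#'
#' The quasi-steady diastolic state of the baseline control model (obtained
#' from a long drug-free pre-simulation), used as the starting point for all
#' population members. Voltage in volts, concentrations in mM, gates
#' dimensionless.
#'
#' @return named numeric vector of the 20 state variables.
#' @export
initial_state <- function() {
  .baseline_initial_state
}

.check_state <- function(state) {
  if (length(state) != length(.state_names))
    stop("state must have ", length(.state_names), " entries")
  if (any(!is.finite(state)))
    stop("non-finite state: numerical breakdown")
  if (!is.null(names(state)) && !identical(names(state), .state_names))
    state <- state[.state_names]
  gates <- state[2:17]
  if (any(gates < 0 | gates > 1)) stop("gating variables must lie in [0, 1]")
  if (any(state[c("Nai", "Cai", "CaSR")] <= 0))
    stop("ionic concentrations must be positive")
  unname(state)
}

#' Evaluate all sarcolemmal currents at a given state
#'
#' @param state named numeric state vector (see [initial_state()]).
#' @param params a [cell_parameters] object.
#' @param blocks optional [block_factors]; default no block.
#' @return named numeric vector of the 13 membrane currents in A/F
#'   (inward negative).
#' @export
compute_currents <- function(state, params, blocks = NULL) {
  y <- .check_state(state)
  out <- .model_rhs(y, .params_vec(params), .blocks_vec(blocks))
  stats::setNames(out$currents, .current_names)
}

#' Time derivative of the full state
#'
#' The membrane equation `dVm/dt = -(sum of currents)` (A/F, so per unit
#' capacitance), Hodgkin-Huxley gate kinetics, and ionic mass balances.
#'
#' @inheritParams compute_currents
#' @param t time (s); the model is autonomous, `t` is accepted for
#'   solver-interface compatibility.
#' @return named numeric vector of d(state)/dt in (V, dimensionless, mM)/s.
#' @export
derivatives <- function(t, state, params, blocks = NULL) {
  y <- .check_state(state)
  out <- .model_rhs(y, .params_vec(params), .blocks_vec(blocks))
  stats::setNames(out$dydt, .state_names)
}

# gate steady states / taus at a given state (internal; used by tests)
.gate_kinetics <- function(state, params, blocks = NULL) {
  y <- .check_state(state)
  out <- .model_rhs(y, .params_vec(params), .blocks_vec(blocks))
  data.frame(gate = .state_names, inf = out$gate_inf, tau = out$gate_tau)
}

#' Serialize cell parameters to a flat key-value list
#'
#' @param params a [cell_parameters] object.
#' @return named list (conductances, mutant knobs, genotype string) suitable
#'   for `jsonlite::write_json()`.
#' @export
as_config <- function(params) {
  c(as.list(params$maxima),
    list(mut_gNaL_scale = params$mut_gNaL_scale,
         mut_hL_shift_mV = params$mut_hL_shift_mV,
         mut_tau_hL_factor = params$mut_tau_hL_factor,
         genotype = params$genotype))
}

#' Rebuild cell parameters from a flat key-value list
#'
#' @param config named list as produced by [as_config()] (absolute maxima).
#' @return a [cell_parameters] object.
#' @export
parameters_from_config <- function(config) {
  p <- cell_parameters(genotype = config$genotype,
                       mut_gNaL_scale = config$mut_gNaL_scale %||% .mutant_defaults[["mut_gNaL_scale"]],
                       mut_hL_shift_mV = config$mut_hL_shift_mV %||% .mutant_defaults[["mut_hL_shift_mV"]],
                       mut_tau_hL_factor = config$mut_tau_hL_factor %||% .mutant_defaults[["mut_tau_hL_factor"]])
  for (nm in .sampled_names)
    if (!is.null(config[[nm]])) p$maxima[[nm]] <- as.numeric(config[[nm]])
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
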