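test_that("zeroing all sampled maxima silences their currents", {
  p0 <- cell_parameters(scale = rep(0, 11))
  cur <- compute_currents(depolarised_state(), p0)
  zeroed <- c("I_Na", "I_NaL", "I_CaL", "I_Kr", "I_Ks", "I_K1", "I_f",
              "I_to", "I_NCX", "I_NaK", "I_pCa")
  expect_true(all(abs(cur[zeroed]) == 0))
})

test_that("I_K1 vanishes at the potassium reversal potential", {
  cst <- cell_parameters()$constants
  E_K <- cst[["R_gas"]] * cst[["T_kelvin"]] / cst[["F"]] *
    log(cst[["K_o"]] / cst[["K_i"]])
  st <- initial_state()
  st[["Vm"]] <- E_K
  cur <- compute_currents(st, cell_parameters())
  expect_equal(unname(cur[["I_K1"]]), 0, tolerance = 1e-12)
})

test_that("membrane equation: dVm/dt equals minus the current sum, exactly", {
  p <- cell_parameters()
  for (vm in c(-0.08, -0.04, 0.0, 0.02)) {
    st <- depolarised_state(vm)
    cur <- compute_currents(st, p)
    dy <- derivatives(0, st, p)
    # equality up to summation round-off (C++ and R sum in different orders)
    expect_equal(dy[["Vm"]], -sum(cur), tolerance = 1e-12)
  }
})

test_that("pore block scales each targeted current linearly", {
  p <- cell_parameters()
  st <- depolarised_state()
  free <- compute_currents(st, p)
  for (ch in c("I_Na", "I_NaL", "I_Kr", "I_CaL")) {
    for (b in c(0, 0.25, 0.7)) {
      args <- stats::setNames(list(b), ch)
      blk <- do.call(block_factors, args)
      blocked <- compute_currents(st, p, blk)
      expect_equal(unname(blocked[[ch]]), unname(b * free[[ch]]),
                   tolerance = 1e-14)
      others <- setdiff(names(free), ch)
      expect_equal(blocked[others], free[others], tolerance = 1e-14)
    }
  }
})

test_that("mutant late sodium current dominates control at identical state", {
  pc <- cell_parameters()
  pm <- apply_mutation(pc)
  for (vm in seq(-0.09, 0.03, by = 0.02)) {
    st <- depolarised_state(vm)
    ic <- compute_currents(st, pc)[["I_NaL"]]
    im <- compute_currents(st, pm)[["I_NaL"]]
    expect_gte(abs(im), abs(ic))
  }
})

test_that("apply_mutation is idempotent and preserves sampled maxima", {
  p <- cell_parameters(scale = c(g_Kr = 1.3, g_NaL = 0.7))
  m1 <- apply_mutation(p)
  m2 <- apply_mutation(m1)
  expect_identical(m1, m2)
  expect_identical(m1$maxima, p$maxima)
  expect_identical(m1$genotype, "V1763M")
})

test_that("gates sit at their fixed point when set to the steady-state value", {
  p <- cell_parameters()
  st <- initial_state()
  st[["Vm"]] <- -0.05
  kin <- hipscpop:::.gate_kinetics(st, p)
  gate_rows <- kin$tau > 0
  st[kin$gate[gate_rows]] <- kin$inf[gate_rows]
  dy <- derivatives(0, st, p)
  expect_true(all(abs(dy[kin$gate[gate_rows]]) < 1e-12))
})

test_that("integration keeps gates in [0, 1] across parameter draws", {
  samples <- sample_population(3, seed = 11)
  for (i in seq_len(nrow(samples))) {
    p <- cell_parameters(scale = unlist(samples[i, hipscpop:::.sampled_names]))
    r <- run_to_steady_state(p, settings = solver_settings(duration_s = 10,
                                                           window_s = 5))
    gates <- r$trace$meta$final_state[2:17]
    expect_true(all(gates >= 0 & gates <= 1))
    expect_true(all(is.finite(r$trace$Vm)))
  }
})

test_that("non-finite states are rejected as numerical breakdown", {
  st <- initial_state()
  st[["Cai"]] <- NaN
  expect_error(compute_currents(st, cell_parameters()), "non-finite")
  expect_error(derivatives(0, st, cell_parameters()), "non-finite")
})

test_that("parameter config round-trips through the flat key-value form", {
  p <- apply_mutation(cell_parameters(scale = c(g_Na = 1.2, g_pCa = 0.8)))
  q <- parameters_from_config(as_config(p))
  expect_equal(q$maxima, p$maxima)
  expect_identical(q$genotype, p$genotype)
  expect_equal(q$mut_tau_hL_factor, p$mut_tau_hL_factor)
})

test_that("block factors outside [0,1] and negative scales are refused", {
  expect_error(block_factors(I_Na = 1.2), "\\[0, 1\\]")
  expect_error(block_factors(I_Kr = -0.1), "\\[0, 1\\]")
  expect_error(cell_parameters(scale = c(g_Na = -1)), "finite and >= 0")
  expect_error(cell_parameters(scale = c(nonsense = 1)), "unknown parameter")
})
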