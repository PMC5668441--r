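test_that("analytic triangle waveform yields its closed-form biomarkers", {
  tr <- make_waveform(mdp_mV = -80, peak_mV = 40, upstroke_ms = 1,
                      repol_ms = 300, cycle_ms = 1000, beats = 3,
                      dt_ms = 0.5)
  bm <- extract_biomarkers(detect_cycles(tr), tr)
  s <- bm$summary
  expect_equal(s[["APA"]], 120, tolerance = 1e-9)
  expect_equal(s[["MDP"]], -80, tolerance = 1e-9)
  expect_equal(s[["Peak"]], 40, tolerance = 1e-9)
  expect_equal(s[["rate"]], 60, tolerance = 1e-6)
  expect_lt(abs(s[["APD90"]] - 270), 2)   # 0.9 * 300 ms, upstroke offset < 2
  expect_lt(abs(s[["APD50"]] - 150), 2)
  expect_lt(abs(s[["APD30"]] - 90), 2)
})

test_that("exponential repolarisation gives APD90 = tau * ln(10) past peak", {
  tau <- 120
  tr <- make_waveform(shape = "exponential", tau_ms = tau, upstroke_ms = 1,
                      cycle_ms = 1500, beats = 3, dt_ms = 0.5)
  bm <- extract_biomarkers(detect_cycles(tr), tr)
  expect_lt(abs(bm$summary[["APD90"]] - tau * log(10)), 3)
  expect_lt(abs(bm$summary[["APD50"]] - tau * log(2)), 3)
})

test_that("APD levels are ordered within every beat", {
  r <- fixture("baseline_control_sim")
  bm <- extract_biomarkers(detect_cycles(r$trace), r$trace)
  pb <- bm$per_beat
  ok <- stats::complete.cases(pb[, c("APD30", "APD50", "APD90")])
  expect_true(all(pb$APD30[ok] <= pb$APD50[ok]))
  expect_true(all(pb$APD50[ok] <= pb$APD90[ok]))
  expect_true(all(pb$MDP < pb$Peak))
  expect_equal(pb$APA, pb$Peak - pb$MDP, tolerance = 1e-12)
})

test_that("biomarkers are invariant under time translation", {
  tr <- make_waveform(beats = 4)
  shifted <- tr
  shifted$time <- tr$time + 123.456
  b1 <- extract_biomarkers(detect_cycles(tr), tr)
  b2 <- extract_biomarkers(detect_cycles(shifted), shifted)
  expect_equal(b1$summary, b2$summary, tolerance = 1e-9)
})

test_that("halving the sampling interval moves biomarkers by < 0.5%", {
  b <- lapply(c(1, 0.5), function(dt) {
    tr <- make_waveform(upstroke_ms = 2, repol_ms = 300, beats = 3,
                        dt_ms = dt)
    extract_biomarkers(detect_cycles(tr), tr)$summary
  })
  rel <- abs(b[[2]] - b[[1]]) / abs(b[[1]])
  expect_true(all(rel < 0.005))
})

test_that("absence of complete cycles yields the undefined signal, not zero", {
  tr <- hipscpop:::.new_trace(seq(0, 2, 0.001), rep(-75, 2001),
                              rep(0, 2001), rep(0, 2001))
  bm <- extract_biomarkers(detect_cycles(tr), tr)
  expect_false(bm$defined)
  expect_true(all(is.na(bm$summary)))
  expect_identical(bm$n_beats, 0L)
})

test_that("rate is positive iff at least two cycles were detected", {
  one <- make_waveform(beats = 1)
  b1 <- extract_biomarkers(detect_cycles(one), one)
  expect_identical(b1$summary[["rate"]], 0)
  two <- make_waveform(beats = 2)
  b2 <- extract_biomarkers(detect_cycles(two), two)
  expect_gt(b2$summary[["rate"]], 0)
})
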