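test_that("conductance sampling respects bounds, seed and edge cases", {
  s <- sample_population(50, interval = c(0.5, 2), seed = 3)
  m <- as.matrix(s[, hipscpop:::.sampled_names])
  expect_true(all(m >= 0.5 & m <= 2))
  expect_identical(s, sample_population(50, interval = c(0.5, 2), seed = 3))
  expect_false(identical(s, sample_population(50, c(0.5, 2), seed = 4)))
  expect_identical(nrow(sample_population(0, seed = 1)), 0L)
  expect_error(sample_population(5, interval = c(2, 0.5)), "interval")
  expect_identical(anyDuplicated(s$id), 0L)
})

test_that("latin hypercube sampling stratifies every dimension", {
  n <- 16
  s <- sample_population(n, interval = c(0.5, 2), seed = 9, scheme = "lhs")
  for (nm in hipscpop:::.sampled_names) {
    bins <- floor((s[[nm]] - 0.5) / 1.5 * n)
    expect_setequal(bins, 0:(n - 1))
  }
})

test_that("calibration matches a brute-force per-candidate oracle", {
  set.seed(101)
  n <- 200
  cand <- data.frame(id = 1:n,
                     rate = runif(n, 5, 120), MDP = runif(n, -95, -50),
                     APD90 = runif(n, 100, 800))
  cand$status <- sample(c("spontaneous", "quiescent"), n, TRUE, c(.8, .2))
  rg <- biomarker_ranges(rate = c(20, 80), MDP = c(-86, -60),
                         APD90 = c(150, 600))
  # independent oracle: explicit loop over candidates and biomarkers
  oracle <- vapply(seq_len(n), function(i) {
    cand$status[i] == "spontaneous" &&
      all(vapply(seq_len(nrow(rg)), function(j) {
        v <- cand[[rg$biomarker[j]]][i]
        v >= rg$lower[j] && v <= rg$upper[j]
      }, logical(1)))
  }, logical(1))
  pop <- calibrate(cand, rg)
  expect_setequal(pop$id, cand$id[oracle])
  expect_setequal(attr(pop, "rejected_ids"), cand$id[!oracle])
  # inclusive bounds: a candidate sitting exactly on a bound is accepted
  edge <- data.frame(id = 1L, rate = 20, MDP = -60, APD90 = 600,
                     status = "spontaneous")
  expect_identical(nrow(calibrate(edge, rg)), 1L)
  # idempotence
  expect_setequal(calibrate(pop, rg)$id, pop$id)
})

test_that("quiescent candidates are always rejected, even by infinite ranges", {
  cand <- data.frame(id = 1:4, APD90 = c(300, 300, 300, 300),
                     status = c("spontaneous", "quiescent", "failed",
                                "spontaneous"))
  rg <- biomarker_ranges(APD90 = c(-Inf, Inf))
  expect_setequal(calibrate(cand, rg)$id, c(1L, 4L))
})

test_that("shrinking any range never enlarges the accepted set", {
  set.seed(77)
  n <- 120
  cand <- data.frame(id = 1:n, rate = runif(n, 5, 120),
                     APD90 = runif(n, 100, 800), status = "spontaneous")
  rg <- biomarker_ranges(rate = c(20, 80), APD90 = c(150, 600))
  base <- calibrate(cand, rg)$id
  for (j in seq_len(nrow(rg))) for (delta in c(5, 20, 60)) {
    shrunk <- rg
    shrunk$lower[j] <- shrunk$lower[j] + delta
    shrunk$upper[j] <- shrunk$upper[j] - delta
    expect_true(all(calibrate(cand, shrunk)$id %in% base))
  }
})

test_that("calibration names the missing biomarker in its error", {
  cand <- data.frame(id = 1, rate = 40, status = "spontaneous")
  expect_error(calibrate(cand, biomarker_ranges(APD90 = c(100, 500))),
               "APD90")
})

test_that("transfection preserves ids, scales, and cardinality bookkeeping", {
  ctrl <- fixture("control_pop")
  mut <- fixture("mutant_pop")
  expect_gte(nrow(ctrl), 3)  # the fixture protocol must accept some models
  expect_identical(attr(mut, "genotype"), "V1763M")
  expect_identical(anyDuplicated(mut$id), 0L)
  expect_true(all(mut$id %in% ctrl$id))
  expect_identical(nrow(ctrl),
                   nrow(mut) + length(attr(mut, "quiescent_ids")) +
                     length(attr(mut, "failed_ids")))
  for (nm in hipscpop:::.sampled_names)
    expect_equal(mut[[nm]], ctrl[[nm]][match(mut$id, ctrl$id)],
                 tolerance = 1e-12)
  expect_error(transfect(mut), "control-genotype")
})

test_that("classification partitions the population by the APD90 rule", {
  mut <- fixture("mutant_classified")
  expect_true(all(mut$label %in% c("symptomatic", "asymptomatic")))
  thr <- attr(mut, "classification")$threshold
  expect_identical(mut$label == "symptomatic", mut$APD90 > thr)
  # explicit threshold overrides; absurdly high threshold: all asymptomatic
  all_asym <- classify(fixture("mutant_pop"),
                       rule = list(biomarker = "APD90", threshold = 1e6))
  expect_true(all(all_asym$label == "asymptomatic"))
  expect_error(classify(fixture("mutant_pop"),
                        rule = list(biomarker = "nope", threshold = 1)),
               "absent biomarker")
})

test_that("population CSV round-trips rows and genotype", {
  mut <- fixture("mutant_classified")
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write_population_csv(mut, f)
  back <- read_population_csv(f)
  expect_identical(attr(back, "genotype"), "V1763M")
  expect_equal(back$APD90, mut$APD90, tolerance = 1e-9)
  expect_identical(back$label, mut$label)
})
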