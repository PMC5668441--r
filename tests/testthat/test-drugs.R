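test_that("pore-block factor matches its closed forms", {
  expect_identical(block_factor(0, 10, 1), 1)
  for (h in c(0.5, 1, 2.4)) expect_equal(block_factor(10, 10, h), 0.5)
  expect_equal(block_factor(20, 10, 1), 1 / 3)
  expect_equal(block_factor(30, 10, 2), 1 / 10)
  expect_error(block_factor(-1, 10), ">= 0")
  expect_error(block_factor(5, -3), "> 0")
})

test_that("block factors are monotone non-increasing in dose", {
  doses <- seq(0, 100, by = 2.5)
  for (h in c(0.7, 1, 1.8)) {
    f <- block_factor(doses, ic50 = 12, h = h)
    expect_true(all(diff(f) <= 0))
    expect_true(all(f > 0 & f <= 1))
  }
})

test_that("apply_drug resolves channels, genotypes and zero dose", {
  spec <- drug_spec("fixture", data.frame(
    channel = c("I_Na", "I_Na", "I_NaL"),
    genotype = c("control", "V1763M", "any"),
    IC50_uM = c(40, 10, 8), hill = c(1, 1, 1)))
  z <- apply_drug(spec, 0, "control")
  expect_equal(unclass(z), stats::setNames(rep(1, 4), names(z)),
               ignore_attr = TRUE)
  # genotype-matched IC50 lookup (oracle: direct table evaluation)
  fc <- apply_drug(spec, 20, "control")
  fm <- apply_drug(spec, 20, "V1763M")
  expect_equal(fc[["I_Na"]], 1 / (1 + 20 / 40))
  expect_equal(fm[["I_Na"]], 1 / (1 + 20 / 10))
  expect_equal(fm[["I_NaL"]], 1 / (1 + 20 / 8))
  # channels absent from the spec stay unblocked
  expect_identical(fc[["I_Kr"]], 1)
  expect_identical(fc[["I_CaL"]], 1)
  expect_error(drug_spec("bad", data.frame(channel = "I_Ks", IC50_uM = 1)),
               "unknown channel")
})

test_that("shipped drug specifications load and behave sensibly", {
  mex <- read_drug_csv(system.file("extdata", "drug_mexiletine_synthetic.csv",
                                   package = "hipscpop"))
  ran <- read_drug_csv(system.file("extdata", "drug_ranolazine_synthetic.csv",
                                   package = "hipscpop"))
  # mexiletine-like spec blocks mutant I_Na harder than control I_Na
  expect_lt(apply_drug(mex, 20, "V1763M")[["I_Na"]],
            apply_drug(mex, 20, "control")[["I_Na"]])
  # ranolazine-like spec touches I_Na less than mexiletine at equal dose
  expect_gt(apply_drug(ran, 20, "V1763M")[["I_Na"]],
            apply_drug(mex, 20, "V1763M")[["I_Na"]])
  # both are strong late-Na blockers
  expect_lt(apply_drug(ran, 20, "V1763M")[["I_NaL"]], 0.5)
})

test_that("zero-dose trial reproduces drug-free biomarkers exactly", {
  mut <- fixture("mutant_pop")
  small <- mut[seq_len(min(4, nrow(mut))), , drop = FALSE]
  attributes(small)[c("genotype", "ranges")] <-
    attributes(mut)[c("genotype", "ranges")]
  class(small) <- class(mut)
  td <- read_drug_csv(system.file("extdata", "drug_testdrug.csv",
                                  package = "hipscpop"))
  tr <- drug_trial(small, td, doses = 0, settings = fixture("settings_small"))
  expect_true(all(tr$per_model$status == "spontaneous"))
  expect_identical(unname(tr$per_model$dAPD90_ms), rep(0, nrow(small)))
  expect_identical(unname(tr$per_model$APD90), unname(small$APD90))
  expect_false(any(tr$per_model$prolonged))
})

test_that("a pure late-Na blocker shortens mutant APs dose-dependently", {
  mut <- fixture("mutant_pop")
  td <- read_drug_csv(system.file("extdata", "drug_testdrug.csv",
                                  package = "hipscpop"))
  tr <- drug_trial(mut, td, doses = c(10, 20),
                   settings = fixture("settings_small"))
  agg <- tr$aggregates
  expect_lt(agg$mean_dAPD90_ms[agg$dose_uM == 10], 0)
  expect_lt(agg$mean_dAPD90_ms[agg$dose_uM == 20],
            agg$mean_dAPD90_ms[agg$dose_uM == 10])
  # stopped implies no recorded APD change
  stopped <- tr$per_model$status == "quiescent"
  expect_true(all(is.na(tr$per_model$dAPD90_ms[stopped])))
  # reproducibility of the stopped count under identical config
  tr2 <- drug_trial(mut, td, doses = c(10, 20),
                    settings = fixture("settings_small"))
  expect_identical(tr$aggregates$stopped, tr2$aggregates$stopped)
  expect_identical(tr$per_model$dAPD90_ms, tr2$per_model$dAPD90_ms)
})
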