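test_that("a group contrasted with itself shows zero percent differences", {
  toy <- make_toy_population(n = 20, seed = 5)
  gc <- compare_groups(toy, toy)
  expect_true(all(gc$pct_diff == 0))
})

test_that("contrasts equal brute-force medians on hand-built groups", {
  a <- data.frame(g_NaL = c(1, 2, 3), g_Kr = c(2, 2, 2))
  b <- data.frame(g_NaL = c(1, 1, 1), g_Kr = c(4, 4, 4))
  for (nm in setdiff(hipscpop:::.sampled_names, names(a))) {
    a[[nm]] <- 1; b[[nm]] <- 1
  }
  gc <- compare_groups(a, b, quantities = c("g_NaL", "g_Kr"))
  base <- hipscpop:::.baseline_maxima
  expect_equal(gc$median_A[1], 2 * base[["g_NaL"]])
  expect_equal(gc$pct_diff[1], 100 * (2 - 1) / 1)
  expect_equal(gc$pct_diff[2], 100 * (2 - 4) / 4)
  # antisymmetry: swapping groups inverts the ratio consistently
  rev <- compare_groups(b, a, quantities = c("g_NaL", "g_Kr"))
  expect_equal((1 + gc$pct_diff / 100) * (1 + rev$pct_diff / 100),
               rep(1, 2), tolerance = 1e-12)
  expect_error(compare_groups(a[0, ], b), "empty group")
})

test_that("planted toy-population differences are recovered exactly", {
  toy <- make_toy_population(n = 60, planted = c(g_NaL = 41, g_Kr = -17.7),
                             seed = 8)
  A <- toy[toy$label == "symptomatic", ]
  B <- toy[toy$label == "asymptomatic", ]
  gc <- compare_groups(A, B, quantities = c("g_NaL", "g_Kr", "g_K1"))
  expect_equal(gc$pct_diff[gc$quantity == "g_NaL"], 41, tolerance = 1e-9)
  expect_equal(gc$pct_diff[gc$quantity == "g_Kr"], -17.7, tolerance = 1e-9)
  expect_equal(gc$pct_diff[gc$quantity == "g_K1"], 0, tolerance = 1e-9)
})

test_that("ancestor contrast follows the id mapping exactly", {
  ctrl <- make_toy_population(n = 10, planted = c(g_NaL = 0), seed = 2)
  ctrl$label <- NULL
  attr(ctrl, "genotype") <- "control"
  ctrl$APD90 <- seq(300, 480, length.out = 10)
  ctrl$rate <- seq(50, 32, length.out = 10)
  labels <- stats::setNames(rep(c("symptomatic", "asymptomatic"), each = 5),
                            ctrl$id)
  gc <- ancestor_contrast(ctrl, labels, quantities = c("APD90", "rate"))
  manual_sym <- stats::median(ctrl$APD90[1:5])
  manual_asym <- stats::median(ctrl$APD90[6:10])
  expect_equal(gc$median_A[gc$quantity == "APD90"], manual_sym)
  expect_equal(gc$pct_diff[gc$quantity == "APD90"],
               100 * (manual_sym - manual_asym) / manual_asym)
  # one-label mapping -> empty group error
  expect_error(ancestor_contrast(ctrl, stats::setNames(
    rep("symptomatic", 10), ctrl$id)), "empty group")
  # broken mapping -> error
  expect_error(ancestor_contrast(ctrl, stats::setNames("symptomatic", 999)),
               "mapping")
})

test_that("stopped-vs-beating contrast matches manual medians", {
  pop <- make_toy_population(n = 8, planted = c(g_K1 = 0), seed = 3)
  trial <- structure(list(per_model = data.frame(
    id = pop$id, dose_uM = 20,
    status = rep(c("quiescent", "spontaneous"), each = 4))),
    class = "drug_trial")
  gc <- stopped_vs_beating_contrast(trial, pop, 20, quantities = "g_K1")
  base <- hipscpop:::.baseline_maxima[["g_K1"]]
  expect_equal(gc$median_A, stats::median(pop$g_K1[1:4]) * base)
  expect_equal(gc$median_B, stats::median(pop$g_K1[5:8]) * base)
  allbeat <- structure(list(per_model = data.frame(
    id = pop$id, dose_uM = 20, status = "spontaneous")),
    class = "drug_trial")
  expect_error(stopped_vs_beating_contrast(allbeat, pop, 20), "stopped")
})
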