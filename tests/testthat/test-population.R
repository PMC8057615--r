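test_that("zero variation gives identical cells and reduces to the model", {
  m <- default_model()
  pop <- draw_population(m$params, population_spec(3, 0, seed = 9))
  expect_equal(pop[[1]], pop[[2]])
  expect_equal(unclass(pop[[1]]), unclass(m$params))
  pr <- population_timecourse(m, pop[1], lps_step_protocol(24),
                              times = seq(0, 24, 4))
  expect_equal(unname(pr$trajectories[, 1]), unname(pr$reference),
               tolerance = 1e-4)
})

test_that("draws are reproducible from the seed and respect the range", {
  m <- default_model()
  a <- draw_population(m$params, population_spec(5, 0.2, seed = 42))
  b <- draw_population(m$params, population_spec(5, 0.2, seed = 42))
  expect_identical(a, b)
  c2 <- draw_population(m$params, population_spec(5, 0.2, seed = 43))
  expect_false(identical(a, c2))
  pos <- unclass(m$params) > 0
  fac <- unclass(a[[3]])[pos] / unclass(m$params)[pos]
  expect_true(all(fac >= 0.8 - 1e-12 & fac <= 1.2 + 1e-12))
})

test_that("uniform draws average to the reference parameters", {
  # law-of-large-numbers check on a handful of parameters at n = 10,000
  m <- default_model()
  p <- m$params
  pop <- draw_population(p, population_spec(10000, 0.2, seed = 1))
  pick <- c("v0_STAT1", "kdm_IRF8", "ka_r1", "protein_mrna_ratio")
  draws <- sapply(pop, function(q) q[pick])
  rel <- rowMeans(draws) / unclass(p)[pick]
  expect_true(all(abs(rel - 1) < 0.02))
})

test_that("population summaries are consistent with stored per-cell values", {
  m <- default_model()
  pop <- draw_population(m$params, population_spec(12, 0.1, seed = 3))
  pr <- population_timecourse(m, pop, lps_step_protocol(24),
                              times = seq(0, 24, 6))
  e <- pr$endpoint
  expect_equal(unname(pr$summary["mean"]), mean(e))
  expect_equal(unname(pr$summary["sd"]), stats::sd(e))
  expect_equal(unname(pr$summary["sem"]), stats::sd(e) / sqrt(length(e)))
})

test_that("endpoint spread grows with the variation level", {
  m <- default_model()
  sds <- sapply(c(0.1, 0.2, 0.4), function(a) {
    pop <- draw_population(m$params, population_spec(40, a, seed = 11))
    pr <- population_timecourse(m, pop, lps_step_protocol(48),
                                times = c(0, 24, 48))
    pr$summary["sd"]
  })
  expect_true(all(diff(sds) > 0))
})

test_that("population steady states reduce to the deterministic diagram", {
  m <- default_model()
  pop <- draw_population(m$params, population_spec(2, 0, seed = 1))
  ps <- population_steady_states(m, pop, lps_grid = c(0, 1),
                                 initial = "low", dwell_h = 250)
  v0 <- ps$value[ps$lps == 0]
  v1 <- ps$value[ps$lps == 1]
  expect_equal(v0, rep(basal_state(m)[["mrna_STAT1"]], 2), tolerance = 0.02)
  high1 <- csfgrn:::settle(m, 400, lps = 1, state = basal_state(m))
  expect_equal(v1, rep(high1[["mrna_STAT1"]], 2), tolerance = 0.05)
})

test_that("cells started high stay activated regardless of LPS", {
  m <- default_model()
  pop <- draw_population(m$params, population_spec(25, 0.2, seed = 8))
  ps <- population_steady_states(m, pop, lps_grid = c(0, 0.5),
                                 initial = "high", dwell_h = 200)
  expect_true(all(ps$above))
})

test_that("from low starts two states coexist at low LPS only", {
  m <- default_model()
  pop <- draw_population(m$params, population_spec(40, 0.2, seed = 15))
  ps <- population_steady_states(m, pop, lps_grid = c(0.05, 1),
                                 initial = "low", dwell_h = 200)
  fr_low <- mean(ps$above[ps$lps == 0.05])
  fr_high <- mean(ps$above[ps$lps == 1])
  expect_gt(fr_low, 0.02)
  expect_lt(fr_low, 0.98)      # genuinely split population
  expect_equal(fr_high, 1)     # everyone activates at full stimulation
})
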