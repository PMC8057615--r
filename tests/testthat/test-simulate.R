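test_that("the basal protocol holds the basal steady state", {
  m <- default_model()
  tc <- run_protocol(m, basal_protocol(48))
  m0 <- mrna_values(tc)
  ref <- m0[1, ]
  dev <- apply(abs(sweep(m0, 2, ref, "/") - 1), 2, max)
  expect_true(all(dev < 0.05))
})

test_that("a zero-duration protocol returns the initial state", {
  m <- default_model()
  prot <- grn_protocol(list(list(start_h = 0, end_h = 0, lps = 1)))
  tc <- run_protocol(m, prot, times = 0)
  expect_equal(nrow(tc$values), 1)
  expect_equal(unname(tc$values[1, ]), unname(basal_state(m)))
})

test_that("protocols compose: restart equals one continuous run", {
  m <- default_model()
  full <- run_protocol(m, lps_step_protocol(30), times = seq(0, 30, 2))
  first <- run_protocol(m, lps_step_protocol(16), times = seq(0, 16, 2))
  mid <- first$values[nrow(first$values), ]
  second <- run_protocol(m, grn_protocol(list(
    list(start_h = 0, end_h = 14, lps = 1)), initial = mid),
    times = seq(0, 14, 2))
  glued <- second$values[nrow(second$values), ]
  expect_equal(unname(glued), unname(full$values[nrow(full$values), ]),
               tolerance = 1e-6)
})

test_that("halving solver tolerances leaves 48 h values unchanged to 0.1%", {
  m <- default_model()
  a <- run_protocol(m, lps_step_protocol(48), times = c(0, 48),
                    rtol = 1e-8, atol = 1e-10)
  b <- run_protocol(m, lps_step_protocol(48), times = c(0, 48),
                    rtol = 5e-9, atol = 5e-11)
  ra <- mrna_values(a)[2, ]; rb <- mrna_values(b)[2, ]
  expect_true(all(abs(ra / rb - 1) < 1e-3))
})

test_that("LPS step reproduces the qualitative response classes", {
  rep <- qualitative_fit_report(default_model())
  rep <- rep[!is.na(rep$expected), ]
  expect_true(all(rep$match),
              info = paste(rep$component, rep$class, collapse = "; "))
})

test_that("washout: monostable toy decays with its half-life", {
  m <- toy_model(v0 = 0.2, kdm = 0.1)
  # raise the gene, then watch free decay toward the basal level
  hi <- c(mrna_GENE = 6)
  out <- csfgrn:::integrate_segment(m, hi, c(0, log(2) / 0.1), lps = 0)
  # after one half-life the excess over steady state halves
  excess0 <- 6 - 2
  excess1 <- unname(out[2, "mrna_GENE"]) - 2
  expect_equal(excess1 / excess0, 0.5, tolerance = 1e-4)
})

test_that("washout arms coincide when LPS is never removed early", {
  m <- default_model()
  w <- washout_experiment(m, t_on = 20, t_total = 20)
  expect_equal(w$maintained$values, w$removed$values, tolerance = 1e-10)
})

test_that("Irf8 and Csf1 stay high after the 36 h + 12 h washout", {
  w <- washout_experiment(default_model(), t_on = 36, t_total = 48)
  expect_lt(w$relative_difference[["IRF8"]], 0.2)
  expect_lt(w$relative_difference[["CSF1"]], 0.2)
  # both arms remain far above the basal level
  m <- default_model()
  b <- mrna_values(run_protocol(m, basal_protocol(1), times = c(0, 1)))[1, ]
  off48 <- mrna_values(w$removed)[nrow(w$removed$values), ]
  expect_gt(off48[["IRF8"]] / b[["IRF8"]], 1.2)
  expect_gt(off48[["CSF1"]] / b[["CSF1"]], 1.2)
})

test_that("knockdown calibration hits the requested residual fraction", {
  m <- default_model()
  kd <- knockdown_prediction(m, "STAT1", 0.5, horizon_h = 48)
  ctrl <- kd$control[["mrna_STAT1"]]
  pert <- kd$perturbed[["mrna_STAT1"]]
  expect_equal(pert / ctrl, 0.5, tolerance = 1e-3)
  expect_true(all(kd$ratios < 1))
})

test_that("knockdown effects vanish continuously as the fraction shrinks", {
  m <- default_model()
  kd <- knockdown_prediction(m, "STAT1", 0.02, horizon_h = 24)
  expect_true(all(abs(kd$ratios - 1) < 0.05))
})

test_that("Irf8 knockdown leaves the other components near control", {
  kd <- knockdown_prediction(default_model(), "IRF8", 0.5, horizon_h = 24)
  expect_true(all(abs(kd$ratios - 1) < 0.1))
})

test_that("screen with unit folds returns a matrix of ones", {
  m <- default_model()
  s <- expression_screen(m, fold_low = 1, fold_high = 1, horizon_h = 12)
  expect_true(all(abs(s$ratios - 1) < 1e-6))
})

test_that("perturbing a component with no outgoing edges leaves others flat", {
  m <- chain_model()
  s <- expression_screen(m, fold_low = 0.2, fold_high = 5, horizon_h = 60)
  expect_lt(abs(s$ratios["B", "A", "high"] - 1), 1e-6)
  expect_lt(abs(s$ratios["B", "A", "low"] - 1), 1e-6)
  expect_gt(s$ratios["A", "B", "high"], 1)   # upstream does act downstream
})

test_that("influence screen ranks the documented top and bottom components", {
  s <- expression_screen(default_model())
  infl <- s$influence
  expect_setequal(names(infl)[1:3], c("STAT1", "STAT3", "CEBPA"))
  ranks <- match(c("IRF8", "CSF1R"), names(infl))
  expect_true(all(ranks >= 7))
  expect_true(all(infl[c("IRF8", "CSF1R")] < infl[3] / 2))
})

test_that("time courses export as tidy tables", {
  m <- toy_model()
  tc <- run_protocol(m, basal_protocol(4), times = 0:4)
  d <- as.data.frame(tc)
  expect_named(d, c("time_h", "variable", "value"))
  expect_equal(nrow(d), 5)
  f <- tempfile(fileext = ".csv")
  write_timecourse(tc, f)
  expect_equal(nrow(utils::read.csv(f)), 5)
})
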