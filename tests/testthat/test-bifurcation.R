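test_that("a linear decay model has exactly one steady state at v0/kdm", {
  m <- toy_model(v0 = 0.3, kdm = 0.1)
  for (l in c(0, 0.5)) {
    ss <- find_steady_states(m, lps = l, n_starts = 5, seed = 2)
    expect_equal(nrow(ss), 1)
    expect_equal(ss$stability, "stable")
    expect_equal(ss$mrna_GENE, 3, tolerance = 1e-6)
  }
})

test_that("the default model is bistable at LPS 0 and monostable at LPS 1", {
  m <- default_model()
  ss0 <- find_steady_states(m, lps = 0, n_starts = 12, seed = 5)
  stable0 <- ss0[ss0$stability == "stable", ]
  expect_gte(nrow(stable0), 2)
  expect_gt(max(stable0$mrna_STAT1) / min(stable0$mrna_STAT1), 3)
  ss1 <- find_steady_states(m, lps = 1, n_starts = 12, seed = 5)
  expect_equal(sum(ss1$stability == "stable"), 1)
})

test_that("continuation on a monostable toy yields a single fold-free branch", {
  m <- toy_model(v0 = 0.3, kdm = 0.1)
  b <- continue_branch(m, c(mrna_GENE = 3), lps_start = 0,
                       lps_range = c(0, 1), ds = 0.05)
  expect_false(b$truncated)
  expect_equal(nrow(b$folds), 0)
  expect_true(all(b$points$stability == "stable"))
  expect_true(all(abs(b$points$mrna_GENE - 3) < 1e-6))
})

test_that("continuation finds the lower fold and the negative-LPS saddle-node", {
  m <- default_model()
  bd <- bifurcation_diagram(m, lps_range = c(-0.4, 1))
  expect_gt(nrow(bd$folds), 0)
  pos_folds <- bd$folds$lps[bd$folds$lps > 0]
  neg_folds <- bd$folds$lps[bd$folds$lps < 0]
  # one fold at small positive LPS terminates the basal branch
  expect_gte(length(pos_folds), 1)
  expect_true(all(pos_folds < 0.5))
  # the middle and upper branches connect at negative LPS
  expect_gte(length(neg_folds), 1)
  # the branch through the activated state has no fold at LPS >= 0
  expect_true(all(bd$branches$upper$folds$lps < 0 |
                    !nrow(bd$branches$upper$folds)))
})

test_that("unstable continuation points lie between stable branches", {
  m <- default_model()
  bd <- bifurcation_diagram(m, lps_range = c(-0.4, 1))
  p <- do.call(rbind, lapply(bd$branches, function(b) b$points))
  uns <- p[p$stability == "unstable" & p$lps >= 0, ]
  stb <- p[p$stability == "stable", ]
  expect_gt(nrow(uns), 0)   # the middle branch is actually traversed
  set.seed(1)
  for (i in sample(seq_len(nrow(uns)), min(5, nrow(uns)))) {
    l <- uns$lps[i]
    near <- stb[abs(stb$lps - l) < 0.03, ]
    expect_gte(nrow(near), 2)
    expect_true(min(near$mrna_STAT1) < uns$mrna_STAT1[i] &&
                  uns$mrna_STAT1[i] < max(near$mrna_STAT1))
  }
})

test_that("hysteresis: the up-sweep activates and the down-sweep stays high", {
  m <- default_model()
  h <- hysteresis_sweep(m, lps_up = c(0, 0.2, 0.5, 1), dwell_h = 200)
  up0 <- h$mrna_STAT1[h$direction == "up" & h$lps == 0]
  dn0 <- h$mrna_STAT1[h$direction == "down" & h$lps == 0]
  up1 <- h$mrna_STAT1[h$direction == "up" & h$lps == 1]
  expect_gt(up1 / up0, 3)      # the sweep switches on
  expect_gt(dn0 / up0, 3)      # and never switches back (irreversible)
  expect_equal(dn0, h$mrna_STAT1[h$direction == "down" & h$lps == 1],
               tolerance = 0.35)
})

test_that("hysteresis on a monostable toy retraces itself", {
  m <- toy_model(v0 = 0.3, kdm = 0.1)
  h <- hysteresis_sweep(m, lps_up = c(0, 0.5, 1), dwell_h = 100)
  up <- h[h$direction == "up", ]
  dn <- h[h$direction == "down", ]
  dn <- dn[match(up$lps, dn$lps), ]
  expect_equal(up$mrna_GENE, dn$mrna_GENE, tolerance = 1e-6)
})

test_that("a 50% Stat1 knockdown lowers expression but keeps bistability", {
  m <- default_model()
  kd <- knockdown_prediction(m, "STAT1", 0.5, horizon_h = 48)
  sc <- stats::setNames(kd$scale, "STAT1")
  lo <- csfgrn:::settle(m, 600, lps = 0, state = basal_state(m),
                        synthesis_scale = sc)
  hi <- csfgrn:::settle(m, 600, lps = 0, state = activated_state(m),
                        synthesis_scale = sc)
  expect_gt(hi[["mrna_STAT1"]] / lo[["mrna_STAT1"]], 3)  # still two states
  hi0 <- activated_state(m)
  expect_lt(hi[["mrna_STAT1"]], hi0[["mrna_STAT1"]])     # but lowered
})

test_that("bifurcation diagrams export to CSV with fold metadata", {
  m <- toy_model(v0 = 0.3, kdm = 0.1)
  b <- continue_branch(m, c(mrna_GENE = 3), lps_start = 0,
                       lps_range = c(0, 0.5), ds = 0.05)
  bd <- structure(list(branches = list(only = b),
                       folds = b$folds, lps_range = c(0, 0.5)),
                  class = "grn_bifurcation")
  f <- tempfile(fileext = ".csv"); fj <- tempfile(fileext = ".json")
  write_bifurcation(bd, f, fj)
  tab <- utils::read.csv(f)
  expect_true(all(c("branch_id", "lps", "stability", "mrna_GENE") %in%
                    names(tab)))
  expect_true(file.exists(fj))
})
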