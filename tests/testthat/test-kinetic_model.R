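test_that("default parameters carry the documented scales", {
  p <- default_parameters()
  expect_equal(unname(p["protein_mrna_ratio"]), 3000)
  expect_equal(half_life(p, "IRF8"), 4.1, tolerance = 1e-8)
  expect_equal(half_life(p, "CSF1"), 5.2, tolerance = 1e-8)
  # Irf8 and Csf1 are the shortest-lived transcripts in the network
  hl <- vapply(grn_network()$components$name,
               function(c) half_life(p, c), numeric(1))
  expect_setequal(names(sort(hl)[1:2]), c("IRF8", "CSF1"))
  # closed form
  q <- c(kdm_X = log(2))
  expect_equal(half_life(q, "X"), 1)
  expect_error(half_life(p, "NOPE"), "unknown component")
})

test_that("parameter audit catches missing and orphan symbols", {
  net <- grn_network()
  p <- default_parameters(net)
  expect_silent(audit_parameters(p, net))
  p_missing <- p[-match("v_r5", names(p))]
  expect_error(audit_parameters(p_missing, net), "v_r5")
  p_orphan <- c(unclass(p), bogus_rate = 1)
  expect_error(audit_parameters(p_orphan, net), "bogus_rate")
  p_neg <- p; p_neg[["v0_CSF1"]] <- -1
  expect_error(audit_parameters(p_neg, net), "negative")
})

test_that("parameter sets round-trip through JSON", {
  p <- default_parameters()
  f <- tempfile(fileext = ".json")
  write_parameters(p, f, note = "round-trip test")
  back <- read_parameters(f)
  expect_equal(unclass(back)[names(p)], unclass(p), tolerance = 0)
})

test_that("basal state is an equilibrium of the assembled RHS", {
  m <- default_model()
  rhs <- build_rhs(m$network, m$params)
  f <- rhs(0, basal_state(m), 0)
  expect_lt(max(abs(f) / (1 + abs(basal_state(m)))), 1e-8)
})

test_that("with zero synthesis the system purely decays", {
  m <- default_model()
  p <- m$params
  p[grep("^(v0_|v_|ksp_)", names(p))] <- 0
  rhs <- build_rhs(m$network, p)
  set.seed(4)
  st <- basal_state(m) * runif(21, 0.5, 2)
  f <- rhs(0, st, 0)
  expect_true(all(f[1:11] <= 1e-12))          # every mRNA decays
  af <- sub("protein_inactive_", "", grep("^protein_inactive_", names(st),
                                          value = TRUE))
  for (c in af) {                              # total protein pools decay
    tot <- f[[paste0("protein_inactive_", c)]] +
      f[[paste0("protein_active_", c)]]
    expect_lte(tot, 1e-12)
  }
})

test_that("LPS raises the activation flux into active STAT1", {
  m <- default_model()
  rhs <- build_rhs(m$network, m$params)
  st <- basal_state(m)
  d0 <- rhs(0, st, 0)[["protein_active_STAT1"]]
  d1 <- rhs(0, st, 1)[["protein_active_STAT1"]]
  expect_gt(d1, d0)
})

test_that("a regulation without rate entries is a construction error", {
  net <- chain_net()
  p <- chain_params()
  expect_error(build_rhs(net, p[-match("v_r1", names(p))]), "v_r1")
})

test_that("effective protein follows the active-form rule", {
  m <- default_model()
  st <- basal_state(m)
  st[["mrna_PU1"]] <- 2
  expect_equal(effective_protein(st, "PU1", m$params), 6000)
  st[["mrna_PU1"]] <- 0
  expect_equal(effective_protein(st, "PU1", m$params), 0)
  st[["protein_active_STAT1"]] <- 5
  st[["mrna_STAT1"]] <- 99
  expect_equal(effective_protein(st, "STAT1", m$params), 5)
  expect_error(effective_protein(st, "NOPE", m$params), "unknown")
})

test_that("fold-change composition behaves multiplicatively", {
  inp <- model_inputs(lps = 0)
  same <- apply_fold_change(inp, "STAT1", 1)
  expect_equal(same$synthesis_scale, inp$synthesis_scale)
  back <- apply_fold_change(apply_fold_change(inp, "STAT1", 10),
                            "STAT1", 0.1)
  expect_equal(back$synthesis_scale, inp$synthesis_scale)
  expect_error(apply_fold_change(inp, "STAT1", -1), "positive")
  expect_error(apply_fold_change(inp, "NOPE", 2), "unknown")
})

test_that("halving synthesis halves the steady state of an unregulated gene", {
  m <- toy_model(v0 = 0.2, kdm = 0.1)
  e <- settle(m, 400, lps = 0, state = c(mrna_GENE = 2),
              synthesis_scale = c(GENE = 0.5))
  expect_equal(unname(e[["mrna_GENE"]]), 1, tolerance = 1e-6)
})

test_that("trajectories stay non-negative from random non-negative states", {
  m <- default_model()
  set.seed(21)
  for (i in 1:5) {
    st <- stats::setNames(runif(21, 0, 20), state_names(m$network))
    out <- csfgrn:::integrate_segment(m, st, seq(0, 60, by = 5),
                                      lps = runif(1, 0, 1))
    expect_true(all(out[, -1] > -1e-8))
  }
})

test_that("the state vector has the documented dimension and layout", {
  m <- default_model()
  snm <- names(basal_state(m))
  expect_length(snm, 21)
  expect_equal(sum(startsWith(snm, "mrna_")), 11)
  expect_equal(sum(startsWith(snm, "protein_inactive_")), 5)
  expect_equal(sum(startsWith(snm, "protein_active_")), 5)
})
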