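test_that("packaged network has the documented composition", {
  net <- grn_network()
  expect_equal(nrow(net$components), 11)
  expect_equal(sum(net$components$role == "ligand"), 1)
  expect_equal(sum(net$components$role == "transcription_factor"), 6)
  expect_equal(sum(net$components$role == "receptor"), 4)
  expect_setequal(net$components$name[net$components$has_active_form],
                  c("STAT1", "STAT3", "CSF1R", "NFKB", "CEBPA"))
  reg <- net$regulations
  expect_equal(nrow(reg), 42)
  expect_equal(sort(reg$id), 1:42)
  inh <- reg[reg$sign == "inhibition", ]
  expect_equal(nrow(inh), 2)
  expect_setequal(paste(inh$source, inh$target),
                  c("IRF8 STAT1", "LPS CEBPA"))
  expect_true(all(inh$level == "transcriptional"))
  # post-translational edges only target active-form components
  pt <- reg[reg$level == "post_translational", ]
  af <- net$components$name[net$components$has_active_form]
  expect_true(all(pt$target %in% af))
  # spot-check individual rows against the published regulation list
  expect_equal(unlist(reg[reg$id == 6, c("source", "target", "sign", "level")],
                      use.names = FALSE),
               c("IRF8", "STAT1", "inhibition", "transcriptional"))
  expect_equal(unlist(reg[reg$id == 42, c("source", "target", "level")],
                      use.names = FALSE),
               c("CSF1R", "STAT3", "post_translational"))
  expect_equal(reg$source[reg$id == 19], "CSF1")
  expect_equal(reg$target[reg$id == 19], "CSF1R")
})

test_that("packaged network file loads and matches the in-code definition", {
  path <- system.file("extdata", "network.json", package = "csfgrn")
  expect_true(nzchar(path))
  net <- read_grn_network(path)
  ref <- grn_network()
  expect_equal(net$components, ref$components)
  expect_equal(net$regulations[, c("id", "source", "target", "sign", "level")],
               ref$regulations[, c("id", "source", "target", "sign", "level")])
})

test_that("validation rejects malformed networks", {
  net <- grn_network()
  bad <- net
  bad$regulations$target[1] <- "FOO"
  expect_error(validate_grn_network(bad), "FOO")
  dup <- net
  dup$regulations$id[2] <- dup$regulations$id[1]
  expect_error(validate_grn_network(dup), "duplicate regulation id")
  # duplicate (source, target, level) triple
  tri <- net
  tri$regulations[1, c("source", "target", "sign", "level")] <-
    tri$regulations[2, c("source", "target", "sign", "level")]
  expect_error(validate_grn_network(tri), "duplicate")
  # post-translational edge to a component without an active form
  pt <- net
  i <- which(pt$regulations$level == "post_translational")[1]
  pt$regulations$target[i] <- "PU1"
  expect_error(validate_grn_network(pt), "active form")
})

test_that("network round-trips through JSON and exports SIF", {
  net <- grn_network()
  f <- tempfile(fileext = ".json")
  write_grn_network(net, f)
  back <- read_grn_network(f)
  expect_equal(back$components, net$components)
  expect_equal(back$regulations$source, net$regulations$source)
  expect_equal(back$regulations$level, net$regulations$level)
  # minimal network round-trip
  mini <- toy_net()
  f2 <- tempfile(fileext = ".json")
  write_grn_network(mini, f2)
  expect_equal(read_grn_network(f2)$components$name, "GENE")
  # SIF export: one line per regulation, tab separated
  f3 <- tempfile(fileext = ".sif")
  write_sif(net, f3)
  lines <- readLines(f3)
  expect_length(lines, 42)
  expect_true(all(lengths(strsplit(lines, "\t")) == 3))
  expect_true("LPS\tinhibition\tCEBPA" %in% lines)
})

test_that("feedback loops include the documented positive cycles", {
  net <- grn_network()
  l3 <- feedback_loops(net, max_length = 3)
  il6r <- l3[l3$cycle == "STAT1->IL6R->STAT1" |
             l3$cycle == "IL6R->STAT1->IL6R", ]
  expect_equal(nrow(il6r), 1)
  expect_equal(il6r$sign, "positive")
  l4 <- feedback_loops(net, max_length = 4)
  # the STAT1 -> STAT3 -> CEBPA -> NFKB -> STAT1 loop (any rotation)
  rot <- c("NFKB->STAT1->STAT3->CEBPA->NFKB",
           "STAT1->STAT3->CEBPA->NFKB->STAT1",
           "STAT3->CEBPA->NFKB->STAT1->STAT3",
           "CEBPA->NFKB->STAT1->STAT3->CEBPA")
  hit <- l4[l4$cycle %in% rot, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$sign, "positive")
  # negative loop through the IRF8 repression of STAT1
  neg <- l3[l3$cycle %in% c("STAT1->IRF8->STAT1", "IRF8->STAT1->IRF8"), ]
  expect_equal(neg$sign, "negative")
  # empty network
  empty <- toy_net()
  expect_equal(nrow(feedback_loops(empty, 4)), 0)
})

test_that("cycle finder agrees with brute-force enumeration", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(3:6, 1)
    comp <- data.frame(name = LETTERS[1:n], role = "transcription_factor",
                       has_active_form = FALSE, stringsAsFactors = FALSE)
    pairs <- expand.grid(source = LETTERS[1:n], target = LETTERS[1:n],
                         stringsAsFactors = FALSE)
    pairs <- pairs[stats::runif(nrow(pairs)) < 0.35, ]
    if (!nrow(pairs)) next
    reg <- data.frame(id = seq_len(nrow(pairs)), source = pairs$source,
                      target = pairs$target,
                      sign = sample(c("activation", "inhibition"),
                                    nrow(pairs), replace = TRUE,
                                    prob = c(0.8, 0.2)),
                      level = "transcriptional", description = "",
                      stringsAsFactors = FALSE)
    net <- grn_network(comp, reg, version = "rand")
    for (L in 2:4) {
      got <- feedback_loops(net, L)
      want <- brute_force_cycles(net, L)
      expect_setequal(paste(got$cycle, got$sign),
                      paste(want$cycle, want$sign))
    }
  }
})
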