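# Shared fixtures, built in code.

# default model, constructed once per test run
default_model <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- grn_model()
    m
  }
})

# single-gene toy network: constitutive production, first-order decay,
# no regulation -> monostable with steady state v0 / kdm
toy_net <- function() {
  grn_network(
    components = data.frame(name = "GENE", role = "transcription_factor",
                            has_active_form = FALSE,
                            stringsAsFactors = FALSE),
    regulations = data.frame(id = integer(), source = character(),
                             target = character(), sign = character(),
                             level = character(), description = character(),
                             stringsAsFactors = FALSE),
    version = "toy-1")
}

toy_params <- function(v0 = 0.2, kdm = 0.1) {
  structure(c(protein_mrna_ratio = 3000, v0_GENE = v0, kdm_GENE = kdm),
            class = c("grn_parameters", "numeric"))
}

toy_model <- function(v0 = 0.2, kdm = 0.1) {
  grn_model(toy_net(), toy_params(v0, kdm),
            state0 = c(mrna_GENE = v0 / kdm))
}

# two-gene chain A -> B (transcriptional activation); B has no outgoing edge
chain_net <- function() {
  grn_network(
    components = data.frame(name = c("A", "B"),
                            role = "transcription_factor",
                            has_active_form = FALSE,
                            stringsAsFactors = FALSE),
    regulations = data.frame(id = 1L, source = "A", target = "B",
                             sign = "activation", level = "transcriptional",
                             description = "A activates B",
                             stringsAsFactors = FALSE),
    version = "chain-1")
}

chain_params <- function() {
  structure(c(protein_mrna_ratio = 3000,
              v0_A = 0.1, v0_B = 0.05, kdm_A = 0.1, kdm_B = 0.1,
              v_r1 = 0.1, K_r1 = 3000, n_r1 = 2),
            class = c("grn_parameters", "numeric"))
}

chain_model <- function() {
  net <- chain_net(); p <- chain_params()
  # analytic steady state: A* = 1; B* = (v0_B + v_r1 * H(3000; 3000, 2))/kdm
  a <- 1
  b <- (0.05 + 0.1 * 0.5) / 0.1
  grn_model(net, p, state0 = c(mrna_A = a, mrna_B = b))
}

# brute-force simple-cycle enumeration oracle (rooted at the earliest
# component in component order, matching the package convention)
brute_force_cycles <- function(net, max_length) {
  comp <- net$components$name
  reg <- unique(net$regulations[net$regulations$source %in% comp,
                                c("source", "target", "sign")])
  has_edge <- function(a, b) which(reg$source == a & reg$target == b)
  out <- data.frame(cycle = character(), length = integer(),
                    sign = character(), stringsAsFactors = FALSE)
  idx <- stats::setNames(seq_along(comp), comp)
  for (root in comp) {
    others <- comp[idx > idx[[root]]]
    for (k in 1:max_length) {
      if (k == 1) {
        e <- has_edge(root, root)
        for (j in e) out[nrow(out) + 1L, ] <-
            list(paste(c(root, root), collapse = "->"), 1L,
                 if (reg$sign[j] == "inhibition") "negative" else "positive")
        next
      }
      if (length(others) < k - 1) next
      combos <- utils::combn(others, k - 1, simplify = FALSE)
      for (cmb in combos) {
        perms <- if (length(cmb) == 1) list(cmb) else all_perms(cmb)
        for (p in perms) {
          path <- c(root, p, root)
          ok <- TRUE; ninh <- 0L
          for (i in seq_len(length(path) - 1)) {
            e <- has_edge(path[i], path[i + 1])
            if (!length(e)) { ok <- FALSE; break }
            ninh <- ninh + sum(reg$sign[e[1]] == "inhibition")
          }
          if (ok) out[nrow(out) + 1L, ] <-
              list(paste(path, collapse = "->"), k,
                   if (ninh %% 2 == 0) "positive" else "negative")
        }
      }
    }
  }
  out
}

all_perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (p in all_perms(x[-i])) out[[length(out) + 1L]] <- c(x[i], p)
  out
}
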