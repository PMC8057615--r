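# Heterogeneous cell-population simulation: extrinsic variability is
# modelled by drawing each kinetic parameter once per cell from a uniform
# distribution around its reference value; each cell is then a deterministic
# model integrated independently.

#' Specify a heterogeneous population
#'
#' @param n_cells number of cells (default 500, the reference ensemble
#'   size).
#' @param variation half-width \code{a} of the uniform variation: each
#'   parameter is drawn from \code{Uniform(p(1-a), p(1+a))}.  Reference
#'   levels are 0.10, 0.20 and 0.40.
#' @param seed RNG seed; draws are reproducible given the seed.
#' @return object of class \code{grn_population_spec}.
#' @export
population_spec <- function(n_cells = 500, variation = 0.2, seed = 1) {
  stopifnot(n_cells >= 1, variation >= 0, variation < 1)
  structure(list(n_cells = as.integer(n_cells), variation = variation,
                 seed = as.integer(seed)), class = "grn_population_spec")
}

#' Draw per-cell parameter sets
#'
#' Every parameter of the model is perturbed independently per cell:
#' \code{p_cell = p * Uniform(1 - a, 1 + a)}.  Degradation rates are floored
#' at a small positive value so half-lives stay finite.  One random stream,
#' seeded from the spec, is used for the whole population; draws are fixed
#' per cell for the entire trajectory (extrinsic heterogeneity only).
#'
#' @param params reference parameter set.
#' @param spec a \code{grn_population_spec}.
#' @return list of \code{spec$n_cells} named parameter vectors.
#' @export
draw_population <- function(params, spec) {
  set.seed(spec$seed)
  a <- spec$variation
  n <- length(params)
  lapply(seq_len(spec$n_cells), function(i) {
    fac <- stats::runif(n, 1 - a, 1 + a)
    p <- unclass(params) * fac
    deg <- grep("^(kdm_|kdp_)", names(p))
    p[deg] <- pmax(p[deg], 1e-6)
    structure(p, class = class(params))
  })
}

cell_model <- function(model, p) {
  m <- model
  m$params <- p
  m
}

#' Population time courses
#'
#' Integrates every cell of a heterogeneous population independently under
#' the same protocol and reports the chosen readout, together with the
#' unperturbed reference trajectory and summary statistics.
#'
#' @param model reference \code{grn_model}.
#' @param population list of per-cell parameter sets from
#'   [draw_population()].
#' @param protocol a \code{grn_protocol}.
#' @param readout state variable to report (default \code{"mrna_STAT1"}).
#' @param times output grid (default hourly).
#' @return object of class \code{grn_population_result}: \code{times},
#'   \code{trajectories} (time x cell), \code{reference}, \code{endpoint}
#'   (per-cell final value) and \code{summary} (mean, sd, sem of the
#'   endpoint); cells whose integration fails are recorded in
#'   \code{failed_cells} and excluded with a warning.
#' @export
population_timecourse <- function(model, population, protocol,
                                  readout = "mrna_STAT1", times = NULL) {
  span <- protocol_span(protocol)
  if (is.null(times)) times <- seq(0, span, by = 1)
  traj <- matrix(NA_real_, nrow = length(times), ncol = length(population))
  failed <- integer()
  for (i in seq_along(population)) {
    tc <- tryCatch(
      run_protocol(cell_model(model, population[[i]]), protocol, times,
                   rtol = 1e-6, atol = 1e-8),
      error = function(e) NULL)
    if (is.null(tc)) { failed <- c(failed, i); next }
    traj[, i] <- tc$values[, readout]
  }
  if (length(failed))
    warning(length(failed), " cell(s) failed to integrate and were excluded")
  ref <- run_protocol(model, protocol, times)$values[, readout]
  endpoint <- traj[nrow(traj), ]
  ok <- !is.na(endpoint)
  structure(list(times = times, trajectories = traj, reference = ref,
                 endpoint = endpoint, failed_cells = failed,
                 readout = readout,
                 summary = c(mean = mean(endpoint[ok]),
                             sd = stats::sd(endpoint[ok]),
                             sem = stats::sd(endpoint[ok]) / sqrt(sum(ok)))),
            class = "grn_population_result")
}

#' @export
print.grn_population_result <- function(x, ...) {
  cat("Population result:", ncol(x$trajectories), "cells, readout",
      x$readout, "\n")
  cat(sprintf("  endpoint mean %.4g sd %.4g sem %.4g\n",
              x$summary["mean"], x$summary["sd"], x$summary["sem"]))
  invisible(x)
}

#' Population steady-state response across LPS levels
#'
#' For each LPS level, every cell starts from a shared initial condition —
#' \code{"low"} (the basal state) or \code{"high"} (the activated state of
#' the unperturbed model) — and is integrated for \code{dwell_h} hours; the
#' endpoint of the readout is recorded.  A bimodality summary counts cells
#' above and below a separatrix threshold: the unperturbed model's unstable
#' steady-state readout value at that LPS when one exists, otherwise the
#' midpoint of the two stable states (or of basal/activated when the system
#' is monostable there).
#'
#' @param model reference \code{grn_model}.
#' @param population list of per-cell parameter sets.
#' @param lps_grid LPS levels to scan.
#' @param initial \code{"low"} or \code{"high"}.
#' @param dwell_h dwell time per level (default 200 h).
#' @param readout state variable reported per cell (default
#'   \code{"mrna_STAT1"}).
#' @param thresholds optional named numeric vector of separatrix values per
#'   LPS level (skips the internal steady-state search).
#' @return data frame of class \code{grn_population_steady}: one row per
#'   (lps, cell) with \code{lps}, \code{cell}, \code{value}, \code{above}
#'   plus an attribute \code{summary} (per-lps mean/sd/sem and fraction
#'   above the threshold).
#' @export
population_steady_states <- function(model, population, lps_grid,
                                     initial = c("low", "high"),
                                     dwell_h = 200,
                                     readout = "mrna_STAT1",
                                     thresholds = NULL) {
  initial <- match.arg(initial)
  st0 <- if (initial == "low") basal_state(model) else activated_state(model)
  rows <- list()
  thr_used <- numeric(length(lps_grid)); names(thr_used) <- lps_grid
  for (k in seq_along(lps_grid)) {
    l <- lps_grid[k]
    if (!is.null(thresholds)) {
      thr <- unname(thresholds[as.character(l)])
    } else {
      ss <- find_steady_states(model, lps = l, n_starts = 8,
                               seed = 1000 + k)
      uns <- ss[ss$stability == "unstable", readout]
      stb <- ss[ss$stability == "stable", readout]
      thr <- if (length(uns)) mean(uns)
             else if (length(stb) >= 2) mean(range(stb))
             else mean(c(basal_state(model)[[readout]],
                         activated_state(model)[[readout]]))
    }
    thr_used[k] <- thr
    for (i in seq_along(population)) {
      e <- tryCatch(
        settle(cell_model(model, population[[i]]), dwell_h, lps = l,
               state = st0, rtol = 1e-6, atol = 1e-8),
        error = function(e) NULL)
      if (is.null(e)) next
      rows[[length(rows) + 1L]] <-
        data.frame(lps = l, cell = i, value = e[[readout]],
                   above = e[[readout]] > thr)
    }
  }
  out <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(out, out$lps), function(d)
    data.frame(lps = d$lps[1], n = nrow(d), mean = mean(d$value),
               sd = stats::sd(d$value),
               sem = stats::sd(d$value) / sqrt(nrow(d)),
               fraction_above = mean(d$above))))
  rownames(summ) <- NULL
  attr(out, "summary") <- summ
  attr(out, "thresholds") <- thr_used
  attr(out, "initial") <- initial
  class(out) <- c("grn_population_steady", "data.frame")
  out
}

#' @export
print.grn_population_steady <- function(x, ...) {
  cat("Population steady states (initial:", attr(x, "initial"), ")\n")
  print(attr(x, "summary"))
  invisible(x)
}
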