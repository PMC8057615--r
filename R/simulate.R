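# Protocol-driven simulation: LPS steps, washout, knockdown and
# overexpression screens.

#' Define an experiment protocol
#'
#' A protocol is an ordered list of contiguous segments, each with a constant
#' LPS level and per-component synthesis scaling; segment boundaries are
#' integration restarts, so input discontinuities are handled exactly.
#'
#' @param segments list of lists with fields \code{start_h}, \code{end_h},
#'   \code{lps} and optionally \code{synthesis_scale} (named vector).
#' @param initial \code{"basal"}, \code{"activated"}, or a named state
#'   vector.
#' @return object of class \code{grn_protocol}.
#' @examples
#' lps_step_protocol(48)                 # LPS = 1 from t = 0
#' washout_protocol(36, 48)              # LPS removed at 36 h
#' @export
grn_protocol <- function(segments, initial = "basal") {
  stopifnot(length(segments) >= 1)
  s0 <- vapply(segments, function(s) s$start_h, numeric(1))
  s1 <- vapply(segments, function(s) s$end_h, numeric(1))
  if (s0[1] != 0) stop("protocol must start at 0 h")
  if (any(s1 <= s0) && !(length(segments) == 1 && s1[1] == s0[1]))
    stop("segments must have positive duration")
  if (length(segments) > 1 && any(abs(s0[-1] - s1[-length(s1)]) > 1e-12))
    stop("segments must be contiguous and non-overlapping")
  structure(list(segments = segments, initial = initial),
            class = "grn_protocol")
}

#' @rdname grn_protocol
#' @param horizon_h protocol duration in hours.
#' @param lps LPS level during the stimulation.
#' @export
basal_protocol <- function(horizon_h = 48)
  grn_protocol(list(list(start_h = 0, end_h = horizon_h, lps = 0)))

#' @rdname grn_protocol
#' @export
lps_step_protocol <- function(horizon_h = 48, lps = 1)
  grn_protocol(list(list(start_h = 0, end_h = horizon_h, lps = lps)))

#' @rdname grn_protocol
#' @param t_on hours of LPS exposure before the medium change.
#' @param t_total total duration.
#' @param maintain keep LPS after the medium change (\code{TRUE}) or remove
#'   it (\code{FALSE}).
#' @export
washout_protocol <- function(t_on = 36, t_total = 48, maintain = FALSE, lps = 1) {
  if (t_on > t_total) stop("t_on must not exceed t_total")
  if (t_on == t_total) return(lps_step_protocol(t_total, lps))
  grn_protocol(list(
    list(start_h = 0, end_h = t_on, lps = lps),
    list(start_h = t_on, end_h = t_total, lps = if (maintain) lps else 0)))
}

protocol_span <- function(protocol)
  protocol$segments[[length(protocol$segments)]]$end_h

resolve_initial <- function(model, initial) {
  if (is.numeric(initial)) return(initial[state_names(model$network)])
  switch(initial,
         basal = basal_state(model),
         activated = activated_state(model),
         stop("unknown initial state preset: ", initial))
}

#' Integrate the model under a protocol
#'
#' Stiff integration (lsoda) of the kinetic model over the protocol, with
#' exact restarts at segment boundaries.
#'
#' @param model a \code{grn_model}.
#' @param protocol a \code{grn_protocol}.
#' @param times output time grid in hours (default: 0.25 h steps over the
#'   protocol span); must lie within the protocol span.
#' @param rtol,atol solver tolerances.
#' @return object of class \code{grn_timecourse}: a list with \code{times},
#'   \code{values} (time x variable matrix), \code{protocol} and solver
#'   diagnostics.
#' @examples
#' \donttest{
#' m <- grn_model()
#' tc <- run_protocol(m, lps_step_protocol(48))
#' }
#' @export
run_protocol <- function(model, protocol, times = NULL,
                         rtol = 1e-8, atol = 1e-10) {
  span <- protocol_span(protocol)
  if (is.null(times)) times <- seq(0, span, by = 0.25)
  if (any(times < 0 | times > span + 1e-9))
    stop("output times outside the protocol span")
  times <- sort(unique(times))
  state <- resolve_initial(model, protocol$initial)
  snm <- state_names(model$network)
  if (span == 0 || length(times) == 1) {
    values <- matrix(state, nrow = 1, dimnames = list(NULL, snm))
    return(structure(list(times = times[1], values = values,
                          protocol = protocol,
                          diagnostics = list(segments = 0L)),
                     class = "grn_timecourse"))
  }
  rows <- matrix(NA_real_, nrow = length(times), ncol = length(snm),
                 dimnames = list(NULL, snm))
  if (times[1] == 0) rows[1, ] <- state
  for (seg in protocol$segments) {
    sel <- which(times > seg$start_h + 1e-12 & times <= seg$end_h + 1e-12)
    grid <- unique(c(seg$start_h, times[sel], seg$end_h))
    out <- integrate_segment(model, state, grid, lps = seg$lps,
                             synthesis_scale = seg$synthesis_scale,
                             rtol = rtol, atol = atol)
    if (length(sel))
      rows[sel, ] <- out[match(times[sel], out[, 1]), -1, drop = FALSE]
    state <- out[nrow(out), -1]
  }
  structure(list(times = times, values = rows, protocol = protocol,
                 diagnostics = list(segments = length(protocol$segments),
                                    rtol = rtol, atol = atol)),
            class = "grn_timecourse")
}

#' @export
print.grn_timecourse <- function(x, ...) {
  cat("GRN time course:", length(x$times), "time points over",
      max(x$times), "h;", ncol(x$values), "state variables\n")
  invisible(x)
}

#' @export
as.data.frame.grn_timecourse <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  data.frame(time_h = rep(x$times, ncol(x$values)),
             variable = rep(colnames(x$values), each = length(x$times)),
             value = as.vector(x$values),
             stringsAsFactors = FALSE)
}

#' Extract mRNA trajectories from a time course
#'
#' @param tc a \code{grn_timecourse}.
#' @return matrix time x component (columns named by component).
#' @export
mrna_values <- function(tc) {
  cols <- grep("^mrna_", colnames(tc$values))
  out <- tc$values[, cols, drop = FALSE]
  colnames(out) <- sub("^mrna_", "", colnames(out))
  out
}

#' Write a time course as a tidy CSV
#'
#' Columns \code{time_h}, \code{variable}, \code{value}.
#'
#' @param tc a \code{grn_timecourse}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_timecourse <- function(tc, path) {
  utils::write.csv(as.data.frame(tc), path, row.names = FALSE)
  invisible(path)
}

#' @export
plot.grn_timecourse <- function(x, components = NULL, ...) {
  m <- mrna_values(x)
  if (!is.null(components)) m <- m[, components, drop = FALSE]
  graphics::matplot(x$times, m, type = "l", lty = 1,
                    xlab = "time (h)", ylab = "mRNA (rel. units)", ...)
  graphics::legend("topleft", legend = colnames(m), col = seq_len(ncol(m)),
                   lty = 1, cex = 0.7, bty = "n")
  invisible(x)
}

#' LPS washout experiment
#'
#' Simulates the paired washout design: cells stimulated with LPS for
#' \code{t_on} hours, then followed to \code{t_total} hours either with LPS
#' maintained or removed.  Both arms continue from the identical state at
#' \code{t_on}.
#'
#' @param model a \code{grn_model}.
#' @param t_on LPS exposure before the medium change (default 36 h).
#' @param t_total total duration (default 48 h).
#' @param lps stimulation level.
#' @return list with \code{maintained} and \code{removed} time courses and
#'   \code{relative_difference}, the per-component relative mRNA difference
#'   between arms at \code{t_total}.
#' @export
washout_experiment <- function(model, t_on = 36, t_total = 48, lps = 1) {
  if (t_on > t_total) stop("t_on must not exceed t_total")
  on_tc <- run_protocol(model, washout_protocol(t_on, t_total, TRUE, lps))
  off_tc <- run_protocol(model, washout_protocol(t_on, t_total, FALSE, lps))
  m_on <- mrna_values(on_tc); m_off <- mrna_values(off_tc)
  last <- nrow(m_on)
  rel <- abs(m_off[last, ] - m_on[last, ]) / pmax(m_on[last, ], .Machine$double.eps)
  list(maintained = on_tc, removed = off_tc, relative_difference = rel)
}

#' In-silico siRNA knockdown prediction
#'
#' Emulates siRNA inhibition by scaling the target's mRNA synthesis so that
#' its mRNA settles at \code{1 - knockdown_fraction} of the unperturbed
#' control at the stated horizon (the scaling factor is found by bisection).
#' The control condition is the unperturbed model in the absence of LPS at
#' the same horizon.
#'
#' @param model a \code{grn_model}.
#' @param target component to knock down.
#' @param knockdown_fraction fraction of expression removed, in (0, 1).
#' @param horizon_h observation horizon (48 h for Stat1/Stat3-style
#'   experiments, 24 h for Irf8).
#' @param lps LPS level of the condition (default 0, matching the
#'   experimental control).
#' @return list with \code{ratios} (per-component mRNA relative to control,
#'   target excluded), \code{target}, \code{scale} (the synthesis factor
#'   used), \code{control} and \code{perturbed} endpoint states.
#' @export
knockdown_prediction <- function(model, target, knockdown_fraction = 0.5,
                                 horizon_h = 48, lps = 0) {
  if (knockdown_fraction <= 0 || knockdown_fraction >= 1)
    stop("knockdown_fraction must be in (0, 1)")
  comps <- model$network$components$name
  if (!target %in% comps) stop("unknown component: ", target)
  st <- basal_state(model)
  endpoint <- function(scale) {
    sc <- stats::setNames(scale, target)
    settle(model, horizon_h, lps = lps, state = st, synthesis_scale = sc)
  }
  ctrl <- settle(model, horizon_h, lps = lps, state = st)
  key <- paste0("mrna_", target)
  goal <- (1 - knockdown_fraction) * ctrl[[key]]
  f <- function(s) endpoint(s)[[key]] - goal
  if (f(1e-3) > 0)
    stop("knockdown level unreachable: residual expression above target ",
         "even at near-total synthesis inhibition")
  scale <- stats::uniroot(f, c(1e-3, 1), tol = 1e-6)$root
  pert <- endpoint(scale)
  others <- setdiff(comps, target)
  ratios <- vapply(others, function(c)
    pert[[paste0("mrna_", c)]] / ctrl[[paste0("mrna_", c)]], numeric(1))
  list(target = target, knockdown_fraction = knockdown_fraction,
       scale = scale, ratios = ratios, control = ctrl, perturbed = pert)
}

#' Expression-level perturbation screen
#'
#' For each network component, simulates a fold decrease and increase of its
#' mRNA synthesis (5- to 10-fold in the reference design), integrates for
#' \code{horizon_h} hours without LPS from the basal state, and reports every
#' component's mRNA relative to the unperturbed control at the horizon.
#' The per-component influence summary is the maximum absolute log2 ratio
#' across readouts and both fold directions.
#'
#' @param model a \code{grn_model}.
#' @param fold_low,fold_high synthesis fold factors (defaults 1/10 and 10).
#' @param horizon_h horizon (default 48 h).
#' @return object of class \code{grn_screen}: list with \code{ratios} (array
#'   perturbed x readout x direction), \code{influence} (named, sorted
#'   decreasing), \code{control}.
#' @export
expression_screen <- function(model, fold_low = 0.1, fold_high = 10,
                              horizon_h = 48) {
  if (fold_low <= 0 || fold_high <= 0) stop("folds must be positive")
  comps <- model$network$components$name
  st <- basal_state(model)
  ctrl <- settle(model, horizon_h, lps = 0, state = st)
  ctrl_m <- ctrl[paste0("mrna_", comps)]
  ratios <- array(NA_real_, dim = c(length(comps), length(comps), 2),
                  dimnames = list(perturbed = comps, readout = comps,
                                  direction = c("low", "high")))
  for (c in comps) {
    for (d in 1:2) {
      f <- if (d == 1) fold_low else fold_high
      e <- settle(model, horizon_h, lps = 0, state = st,
                  synthesis_scale = stats::setNames(f, c))
      ratios[c, , d] <- e[paste0("mrna_", comps)] / ctrl_m
    }
  }
  infl <- vapply(comps, function(c) {
    r <- ratios[c, setdiff(comps, c), ]
    max(abs(log2(r)))
  }, numeric(1))
  structure(list(ratios = ratios,
                 influence = sort(infl, decreasing = TRUE),
                 control = ctrl_m, fold_low = fold_low,
                 fold_high = fold_high, horizon_h = horizon_h),
            class = "grn_screen")
}

#' @export
print.grn_screen <- function(x, ...) {
  cat("Expression screen (fold", x$fold_low, "and", x$fold_high, "at",
      x$horizon_h, "h)\n")
  cat("influence ranking (max |log2 ratio| across readouts):\n")
  print(round(x$influence, 3))
  invisible(x)
}
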