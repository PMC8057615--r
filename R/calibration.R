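# Calibration to qPCR-style mRNA time courses: weighted least squares over
# log-parameters with multi-start refinement, plus the qualitative
# shape-class report used to compare simulated LPS responses with the
# documented behaviour of the network.

condition_protocol <- function(condition, horizon_h) {
  if (condition == "basal") return(basal_protocol(horizon_h))
  if (condition == "lps") return(lps_step_protocol(horizon_h))
  if (condition == "lps_washout")
    return(washout_protocol(36, max(horizon_h, 48)))
  if (startsWith(condition, "knockdown:")) {
    parts <- strsplit(sub("^knockdown:", "", condition), ":")[[1]]
    # knockdown conditions carry a pre-calibrated synthesis scale
    sc <- stats::setNames(as.numeric(parts[2]), parts[1])
    return(grn_protocol(list(list(start_h = 0, end_h = horizon_h, lps = 0,
                                  synthesis_scale = sc))))
  }
  stop("condition not expressible as a protocol: ", condition)
}

#' Weighted least-squares objective against a qPCR dataset
#'
#' Simulates each condition present in the dataset and accumulates weighted
#' squared residuals between the simulated mRNA levels and the replicate
#' means, per component and time point.
#'
#' @param model a \code{grn_model} (its parameters are evaluated as-is).
#' @param data qPCR dataset: data frame with columns \code{condition}
#'   (\code{"basal"}, \code{"lps"}, or \code{"knockdown:<target>:<scale>"}),
#'   \code{component}, \code{time_h}, \code{replicate}, \code{value} and
#'   optionally \code{sd}.
#' @param weighting \code{"none"} (unit weights), \code{"inv_sd2"}
#'   (\code{1/sd^2} of the replicate spread) or \code{"inv_mean2"}
#'   (\code{1/mean^2}, i.e. relative error).
#' @param rtol,atol solver tolerances (looser than the simulation defaults;
#'   adequate for optimisation).
#' @return scalar objective value (>= 0).
#' @export
qpcr_objective <- function(model, data, weighting = c("none", "inv_sd2",
                                                      "inv_mean2"),
                           rtol = 1e-6, atol = 1e-8) {
  weighting <- match.arg(weighting)
  comps <- model$network$components$name
  bad <- setdiff(unique(data$component), comps)
  if (length(bad)) stop("dataset components not in the network: ",
                        paste(bad, collapse = ", "))
  total <- 0
  for (cond in unique(data$condition)) {
    d <- data[data$condition == cond, ]
    agg <- stats::aggregate(value ~ component + time_h, data = d, FUN = mean)
    if (weighting == "inv_sd2") {
      sds <- stats::aggregate(value ~ component + time_h, data = d,
                              FUN = stats::sd)
      agg$w <- 1 / pmax(sds$value, 1e-6)^2
    } else if (weighting == "inv_mean2") {
      agg$w <- 1 / pmax(agg$value, 1e-6)^2
    } else agg$w <- 1
    horizon <- max(agg$time_h)
    prot <- condition_protocol(cond, max(horizon, 1e-6))
    tc <- run_protocol(model, prot, times = sort(unique(c(0, agg$time_h))),
                       rtol = rtol, atol = atol)
    m <- mrna_values(tc)
    sim <- m[match(agg$time_h, tc$times), , drop = FALSE]
    pred <- sim[cbind(seq_len(nrow(agg)), match(agg$component, colnames(m)))]
    total <- total + sum(agg$w * (agg$value - pred)^2)
  }
  total
}

#' Fit model parameters to qPCR time courses
#'
#' Bounded multi-start least squares over log-parameters: the named free
#' parameters are optimised (all others fixed) by Levenberg-Marquardt on the
#' per-point weighted residuals, from the supplied start and
#' \code{restarts} random log-uniform starts inside the bounds.
#'
#' @param model a \code{grn_model} providing the fixed parameters and start.
#' @param data qPCR dataset (see [qpcr_objective()]).
#' @param free character vector of free parameter names.
#' @param lower,upper bounds as multiples of the starting value (defaults
#'   1/10 and 10), or named absolute vectors.
#' @param restarts number of random restarts (in addition to the given
#'   start).
#' @param seed RNG seed for the restarts.
#' @param weighting residual weighting, as in [qpcr_objective()].
#' @return object of class \code{grn_fit}: fitted model, parameter
#'   estimates, objective, restart table and configuration.
#' @export
grn_fit <- function(model, data, free, lower = NULL, upper = NULL,
                    restarts = 3, seed = 1,
                    weighting = c("none", "inv_sd2", "inv_mean2")) {
  weighting <- match.arg(weighting)
  p0 <- unclass(model$params)
  missing <- setdiff(free, names(p0))
  if (length(missing)) stop("unknown free parameters: ",
                            paste(missing, collapse = ", "))
  start <- p0[free]
  if (is.null(lower)) lower <- start / 10
  if (is.null(upper)) upper <- start * 10
  lower <- rep_len(lower, length(free)); upper <- rep_len(upper, length(free))
  if (any(lower <= 0)) stop("bounds must be positive")
  if (length(free) == 0)
    return(structure(list(model = model, estimate = numeric(0),
                          objective = qpcr_objective(model, data,
                                                     weighting = weighting),
                          restarts = data.frame(), free = free),
                     class = "grn_fit"))

  residual_fn <- make_residual_fn(model, data, free, weighting)

  run_one <- function(theta0) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = log(theta0), fn = residual_fn,
                         lower = log(lower), upper = log(upper),
                         control = minpack.lm::nls.lm.control(
                           maxiter = 60, ptol = 1e-8, ftol = 1e-8)),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    list(par = exp(fit$par), obj = sum(fit$fvec^2))
  }

  set.seed(seed)
  starts <- c(list(start),
              lapply(seq_len(restarts), function(i)
                exp(stats::runif(length(free), log(lower), log(upper)))))
  results <- lapply(starts, run_one)
  ok <- !vapply(results, is.null, logical(1))
  if (!any(ok)) stop("all fit restarts failed")
  objs <- vapply(results[ok], function(r) r$obj, numeric(1))
  best <- results[ok][[which.min(objs)]]
  fitted_params <- p0
  fitted_params[free] <- best$par
  fitted_model <- model
  fitted_model$params <- structure(fitted_params, class = class(model$params))
  restart_tab <- data.frame(
    restart = seq_along(results)[ok] - 1L,
    objective = objs,
    t(vapply(results[ok], function(r) r$par, numeric(length(free)))))
  names(restart_tab)[-(1:2)] <- free
  structure(list(model = fitted_model,
                 estimate = stats::setNames(best$par, free),
                 start = start, objective = best$obj,
                 restarts = restart_tab, free = free,
                 lower = lower, upper = upper, seed = seed,
                 weighting = weighting, data = data),
            class = "grn_fit")
}

make_residual_fn <- function(model, data, free, weighting) {
  # pre-aggregate once; residual function re-simulates per evaluation
  conds <- lapply(unique(data$condition), function(cond) {
    d <- data[data$condition == cond, ]
    agg <- stats::aggregate(value ~ component + time_h, data = d, FUN = mean)
    if (weighting == "inv_sd2") {
      sds <- stats::aggregate(value ~ component + time_h, data = d,
                              FUN = stats::sd)
      agg$w <- 1 / pmax(sds$value, 1e-6)^2
    } else if (weighting == "inv_mean2") {
      agg$w <- 1 / pmax(agg$value, 1e-6)^2
    } else agg$w <- 1
    list(cond = cond, agg = agg,
         prot = condition_protocol(cond, max(max(agg$time_h), 1e-6)),
         times = sort(unique(c(0, agg$time_h))))
  })
  p_full <- unclass(model$params)
  function(log_theta) {
    p <- p_full
    p[free] <- exp(log_theta)
    m <- model
    m$params <- structure(p, class = class(model$params))
    res <- numeric(0)
    for (cc in conds) {
      tc <- tryCatch(run_protocol(m, cc$prot, times = cc$times,
                                  rtol = 1e-6, atol = 1e-8),
                     error = function(e) NULL)
      if (is.null(tc)) return(rep(1e4, sum(vapply(conds, function(x)
        nrow(x$agg), integer(1)))))
      mm <- mrna_values(tc)
      sim <- mm[match(cc$agg$time_h, tc$times), , drop = FALSE]
      pred <- sim[cbind(seq_len(nrow(cc$agg)),
                        match(cc$agg$component, colnames(mm)))]
      res <- c(res, sqrt(cc$agg$w) * (cc$agg$value - pred))
    }
    res
  }
}

#' @export
print.grn_fit <- function(x, ...) {
  cat("GRN model fit:", length(x$free), "free parameter(s), objective",
      signif(x$objective, 6), "\n")
  if (length(x$free)) {
    tab <- data.frame(start = x$start, estimate = x$estimate,
                      ratio = x$estimate / x$start)
    print(signif(tab, 4))
  }
  invisible(x)
}

#' @export
coef.grn_fit <- function(object, ...) object$estimate

#' @export
summary.grn_fit <- function(object, ...) {
  cat("Multi-start bounded least-squares fit (log-parameter scale)\n")
  print(object)
  cat("restart objectives:",
      paste(signif(object$restarts$objective, 5), collapse = ", "), "\n")
  on_bound <- object$estimate <= object$lower * (1 + 1e-6) |
    object$estimate >= object$upper * (1 - 1e-6)
  if (any(on_bound))
    cat("estimates at a bound:", paste(object$free[on_bound], collapse=", "),
        "\n")
  invisible(object)
}

#' @export
fitted.grn_fit <- function(object, ...) {
  d <- object$data
  preds <- numeric(nrow(d))
  for (cond in unique(d$condition)) {
    idx <- d$condition == cond
    prot <- condition_protocol(cond, max(max(d$time_h[idx]), 1e-6))
    tc <- run_protocol(object$model, prot,
                       times = sort(unique(c(0, d$time_h[idx]))))
    m <- mrna_values(tc)
    preds[idx] <- m[cbind(match(d$time_h[idx], tc$times),
                          match(d$component[idx], colnames(m)))]
  }
  preds
}

#' @export
residuals.grn_fit <- function(object, ...) object$data$value - fitted(object)

#' Classify simulated LPS-response shapes
#'
#' Assigns each component's simulated mRNA trajectory under an LPS step to
#' one of \code{fast-rise}, \code{delayed-rise}, \code{transient-rise},
#' \code{transient-dip}, \code{sustained-dip} or \code{flat}.  Thresholds:
#' an excursion below 15% of baseline is flat; "fast" means half of the
#' baseline-to-peak change is reached before 25% of the horizon;
#' "transient" means the endpoint has returned by at least half of the
#' excursion; a dip is detected when the minimum precedes the maximum and
#' undercuts baseline by 15%.
#'
#' @param times time grid (hours).
#' @param values numeric trajectory on \code{times}.
#' @param horizon_h classification horizon (defaults to the grid span).
#' @return character class label.
#' @export
classify_trajectory <- function(times, values, horizon_h = max(times)) {
  base <- values[1]
  if (base <= 0) base <- .Machine$double.eps
  ymax <- max(values); ymin <- min(values); yend <- values[length(values)]
  if ((ymax - ymin) < 0.10 * base) return("flat")
  dmin <- base - ymin; dmax <- ymax - base
  tmin <- times[which.min(values)]; tmax <- times[which.max(values)]
  if (dmin >= 0.15 * base && (dmax < 0.15 * base || tmin < tmax)) {
    if (yend - ymin >= 0.5 * dmin) return("transient-dip")
    return("sustained-dip")
  }
  if (dmax < 0.15 * base) return("flat")
  if (yend <= base + 0.5 * dmax) return("transient-rise")
  thalf <- times[min(which(values >= base + 0.5 * dmax))]
  if (thalf <= 0.25 * horizon_h) "fast-rise" else "delayed-rise"
}

#' Qualitative LPS-response report
#'
#' Simulates the LPS step and classifies every component's mRNA trajectory,
#' comparing against the reference classes of the calibrated network:
#' fast rise for Stat1 and Stat3; delayed rise for Csf1, Irf8 and Tnfr1;
#' transient rise for Nfkb; transient dip for Il6r and Cebpa.
#'
#' @param model a \code{grn_model}.
#' @param horizon_h simulation horizon (default 48 h).
#' @param lps stimulation level (default 1).
#' @return data frame with \code{component}, \code{class} and, for
#'   components with a reference class, \code{expected} and \code{match}.
#' @export
qualitative_fit_report <- function(model, horizon_h = 48, lps = 1) {
  tc <- run_protocol(model, lps_step_protocol(horizon_h, lps))
  m <- mrna_values(tc)
  cls <- vapply(colnames(m), function(c)
    classify_trajectory(tc$times, m[, c], horizon_h), character(1))
  expected <- c(STAT1 = "fast-rise", STAT3 = "fast-rise",
                CSF1 = "delayed-rise", IRF8 = "delayed-rise",
                TNFR1 = "delayed-rise", NFKB = "transient-rise",
                IL6R = "transient-dip", CEBPA = "transient-dip")
  out <- data.frame(component = names(cls), class = unname(cls),
                    expected = unname(expected[names(cls)]),
                    stringsAsFactors = FALSE)
  out$match <- !is.na(out$expected) & out$class == out$expected
  out
}
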