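# Synthetic qPCR-like data generation: simulates a protocol with known
# ("true") parameters and overlays replicate measurement noise, so every
# downstream stage (objective, fitting, recovery benchmarks) is testable
# without measured data.

#' Configure the synthetic qPCR generator
#'
#' @param preset protocol preset: \code{"basal_48h"}, \code{"lps_step_48h"},
#'   \code{"washout_36_12"} or \code{"knockdown"}.
#' @param time_grid sampling times in hours; the default follows the dense
#'   early / sparse late sampling pattern of an LPS time-course experiment
#'   over 0-32 h plus a 48 h endpoint.
#' @param n_replicates replicates per time point (default 4).
#' @param noise \code{"lognormal"} (multiplicative, coefficient of variation
#'   \code{cv}; preserves positivity) or \code{"gaussian"} (additive,
#'   standard deviation \code{sd}).
#' @param cv coefficient of variation of the multiplicative noise
#'   (default 0.2).
#' @param sd standard deviation of the additive noise option.
#' @param seed RNG seed.
#' @param knockdown_target,knockdown_fraction,knockdown_horizon_h settings
#'   for the knockdown preset.
#' @return object of class \code{grn_synth_config}.
#' @export
synth_config <- function(preset = c("lps_step_48h", "basal_48h",
                                    "washout_36_12", "knockdown"),
                         time_grid = c(0, 2, 4, 6, 8, 12, 16, 24, 32, 48),
                         n_replicates = 4,
                         noise = c("lognormal", "gaussian"),
                         cv = 0.2, sd = 0.05, seed = 1,
                         knockdown_target = "STAT1",
                         knockdown_fraction = 0.5,
                         knockdown_horizon_h = 48) {
  preset <- match.arg(preset)
  noise <- match.arg(noise)
  stopifnot(cv >= 0, sd >= 0, n_replicates >= 1)
  structure(list(preset = preset, time_grid = sort(unique(time_grid)),
                 n_replicates = as.integer(n_replicates), noise = noise,
                 cv = cv, sd = sd, seed = as.integer(seed),
                 knockdown_target = knockdown_target,
                 knockdown_fraction = knockdown_fraction,
                 knockdown_horizon_h = knockdown_horizon_h),
            class = "grn_synth_config")
}

#' Generate a synthetic qPCR dataset
#'
#' Simulates the configured protocol with the model's (true) parameters and
#' samples replicate values under the noise model.  Identical configuration
#' and seed give an identical dataset.
#'
#' @param model a \code{grn_model} whose parameters play the role of the
#'   unknown truth.
#' @param config a \code{grn_synth_config}.
#' @return list with \code{data} (data frame: condition, component, time_h,
#'   replicate, value, sd) and \code{truth} (true parameters, the noiseless
#'   trajectories, and the configuration) for recovery benchmarks.
#' @export
generate_qpcr <- function(model, config) {
  grid <- config$time_grid
  if (config$preset == "knockdown") {
    kd <- knockdown_prediction(model, config$knockdown_target,
                               config$knockdown_fraction,
                               horizon_h = config$knockdown_horizon_h)
    sc <- stats::setNames(kd$scale, config$knockdown_target)
    prot <- grn_protocol(list(list(start_h = 0,
                                   end_h = max(grid),
                                   lps = 0, synthesis_scale = sc)))
    condition <- sprintf("knockdown:%s:%.8g", config$knockdown_target,
                         kd$scale)
  } else {
    prot <- switch(config$preset,
                   basal_48h = basal_protocol(max(grid)),
                   lps_step_48h = lps_step_protocol(max(grid)),
                   washout_36_12 = washout_protocol(36, max(max(grid), 48)))
    condition <- switch(config$preset, basal_48h = "basal",
                        lps_step_48h = "lps", washout_36_12 = "lps_washout")
  }
  tc <- run_protocol(model, prot, times = grid)
  m <- mrna_values(tc)
  comps <- colnames(m)
  set.seed(config$seed)
  rows <- list()
  sdlog <- sqrt(log(1 + config$cv^2))
  for (c in comps) for (k in seq_along(grid)) {
    mu <- m[k, c]
    vals <- if (config$noise == "lognormal") {
      if (config$cv == 0) rep(mu, config$n_replicates)
      else mu * stats::rlnorm(config$n_replicates,
                              meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else {
      mu + stats::rnorm(config$n_replicates, 0, config$sd)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      condition = condition, component = c, time_h = grid[k],
      replicate = seq_len(config$n_replicates), value = vals,
      sd = stats::sd(vals))
  }
  data <- do.call(rbind, rows)
  rownames(data) <- NULL
  list(data = data,
       truth = list(params = model$params, trajectories = m,
                    times = grid, config = config))
}

#' Re-express a dataset relative to a control condition
#'
#' The 2^-ddCt view: each value is divided by the control-condition mean of
#' the same component, so control rows average to 1 and treated rows read as
#' fold changes.
#'
#' @param data qPCR dataset data frame.
#' @param control name of the control condition present in \code{data}.
#' @return the dataset with \code{value} (and \code{sd}) on the ratio scale.
#' @export
generate_ddct_view <- function(data, control) {
  if (!control %in% data$condition)
    stop("control condition not present: ", control)
  ctrl <- data[data$condition == control, ]
  means <- tapply(ctrl$value, ctrl$component, mean)
  if (any(means == 0)) stop("zero control mean for: ",
                            paste(names(means)[means == 0], collapse = ", "))
  denom <- as.vector(means[data$component])
  data$value <- data$value / denom
  if ("sd" %in% names(data)) data$sd <- data$sd / denom
  data
}

#' Write a qPCR dataset as CSV
#'
#' @param data dataset data frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_qpcr <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' Read a qPCR dataset CSV
#'
#' @param path CSV with columns condition, component, time_h, replicate,
#'   value and optionally sd.
#' @return dataset data frame.
#' @export
read_qpcr <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition", "component", "time_h", "replicate", "value")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("dataset missing columns: ",
                         paste(miss, collapse = ", "))
  d
}
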