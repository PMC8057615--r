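# Additional S3 methods on the model object.

#' @export
summary.grn_model <- function(object, ...) {
  print(object)
  st <- basal_state(object)
  cat("basal mRNA levels (rel. units):\n")
  m <- st[grep("^mrna_", names(st))]
  names(m) <- sub("^mrna_", "", names(m))
  print(round(m, 3))
  hl <- vapply(object$network$components$name,
               function(c) half_life(object$params, c), numeric(1))
  cat("mRNA half-lives (h):\n")
  print(round(hl, 1))
  invisible(object)
}

#' Simulate qPCR-style datasets from the model
#'
#' \code{simulate()} draws \code{nsim} independent synthetic replicate
#' datasets under the configured protocol and noise model; it is a thin
#' wrapper around [generate_qpcr()].
#'
#' @param object a \code{grn_model}.
#' @param nsim number of datasets.
#' @param seed RNG seed for the first dataset; successive datasets increment
#'   it.
#' @param config a \code{grn_synth_config}; its seed field is overridden.
#' @param ... unused.
#' @return list of dataset data frames (length \code{nsim}).
#' @export
simulate.grn_model <- function(object, nsim = 1, seed = 1,
                               config = synth_config(), ...) {
  lapply(seq_len(nsim), function(i) {
    config$seed <- as.integer(seed + i - 1)
    generate_qpcr(object, config)$data
  })
}

#' Predict model trajectories under a protocol
#'
#' @param object a \code{grn_model}.
#' @param protocol a \code{grn_protocol} (default: 48 h LPS step).
#' @param times output grid.
#' @param ... unused.
#' @return a \code{grn_timecourse}.
#' @export
predict.grn_model <- function(object, protocol = lps_step_protocol(48),
                              times = NULL, ...) {
  run_protocol(object, protocol, times = times)
}

#' @export
plot.grn_model <- function(x, protocol = lps_step_protocol(48),
                           components = c("STAT1", "STAT3", "CSF1", "IRF8",
                                          "NFKB", "IL6R", "CEBPA"), ...) {
  tc <- run_protocol(x, protocol)
  plot(tc, components = intersect(components,
                                  x$network$components$name), ...)
}
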