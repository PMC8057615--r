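# Kinetic model assembly.
#
# State vector (length n_comp + 2 * n_prot):
#   mrna_<COMP>              mRNA, beta-actin-relative units, one per component
#   protein_inactive_<COMP>  inactive protein pool, active-form components only
#   protein_active_<COMP>    active protein pool, active-form components only
#
# mRNA kinetics: synthesis = scale_c * (v0 + sum of saturating Hill
# activation terms) * product of inhibition factors K^n/(K^n + A^n), minus
# first-order degradation.  Components with an explicit protein pair exchange
# inactive and active forms through activation fluxes contributed by the
# post-translational regulations; the active form is the transcriptionally
# competent species.  Components without a protein pair act through a protein
# proxy equal to protein_mrna_ratio times their mRNA.  LPS enters as a
# dimensionless external input.

MAX_PACK_LEN <- 2048L

state_names <- function(net) {
  af <- net$components$name[net$components$has_active_form]
  c(paste0("mrna_", net$components$name),
    paste0("protein_inactive_", af, recycle0 = TRUE),
    paste0("protein_active_", af, recycle0 = TRUE))
}

#' Model inputs: LPS level and per-component synthesis scaling
#'
#' @param lps dimensionless LPS level; 1 corresponds to the experimental
#'   dose.  Negative values are only meaningful inside numerical
#'   continuation.
#' @param synthesis_scale named numeric vector of multiplicative factors on
#'   mRNA synthesis (knockdown/overexpression); unnamed components default
#'   to 1.
#' @param net network supplying the component list.
#' @return named list of class \code{grn_inputs}.
#' @export
model_inputs <- function(lps = 0, synthesis_scale = NULL, net = grn_network()) {
  comps <- net$components$name
  scale <- stats::setNames(rep(1, length(comps)), comps)
  if (!is.null(synthesis_scale)) {
    bad <- setdiff(names(synthesis_scale), comps)
    if (length(bad)) stop("unknown component in synthesis_scale: ",
                          paste(bad, collapse = ", "))
    if (any(synthesis_scale <= 0)) stop("synthesis_scale must be positive")
    scale[names(synthesis_scale)] <- synthesis_scale
  }
  structure(list(lps = lps, synthesis_scale = scale), class = "grn_inputs")
}

#' Scale a component's mRNA synthesis by a fold factor
#'
#' Multiplies the synthesis scale of one component, implementing in-silico
#' knockdown (factor < 1) or overexpression (factor > 1).  Composing a factor
#' with its inverse restores the original inputs.
#'
#' @param inputs a \code{grn_inputs} object.
#' @param component component name.
#' @param factor positive scalar.
#' @return modified \code{grn_inputs}.
#' @export
apply_fold_change <- function(inputs, component, factor) {
  if (!is.numeric(factor) || factor <= 0) stop("factor must be positive")
  if (!component %in% names(inputs$synthesis_scale))
    stop("unknown component: ", component)
  inputs$synthesis_scale[[component]] <- inputs$synthesis_scale[[component]] * factor
  inputs
}

# Build the flat double vector consumed by the C evaluator.
build_pack <- function(net, params, lps = 0, synthesis_scale = NULL) {
  comp <- net$components
  reg <- net$regulations
  n_comp <- nrow(comp)
  af <- comp$name[comp$has_active_form]
  n_prot <- length(af)
  if (n_comp > 64 || n_prot > 16)
    stop("network too large for the compiled evaluator")
  cidx <- stats::setNames(seq_len(n_comp) - 1L, comp$name)  # 0-based
  pidx <- stats::setNames(seq_len(n_prot) - 1L, af)
  src_code <- function(s) if (s == "LPS") n_comp else cidx[[s]]

  scale <- stats::setNames(rep(1, n_comp), comp$name)
  if (!is.null(synthesis_scale)) scale[names(synthesis_scale)] <- synthesis_scale

  p <- function(key) {
    if (!key %in% names(params)) stop("missing parameter: ", key)
    params[[key]]
  }
  tE <- c(); pE <- c()
  if (nrow(reg)) for (i in seq_len(nrow(reg))) {
    id <- reg$id[i]
    if (reg$level[i] == "post_translational") {
      pE <- c(pE, pidx[[reg$target[i]]], src_code(reg$source[i]),
              p(paste0("ka_r", id)), p(paste0("Ka_r", id)), p(paste0("n_r", id)))
    } else if (reg$sign[i] == "activation") {
      tE <- c(tE, cidx[[reg$target[i]]], src_code(reg$source[i]), 1,
              p(paste0("v_r", id)), p(paste0("K_r", id)), p(paste0("n_r", id)))
    } else {
      tE <- c(tE, cidx[[reg$target[i]]], src_code(reg$source[i]), -1,
              0, p(paste0("Ki_r", id)), p(paste0("n_r", id)))
    }
  }
  pack <- c(n_comp, n_prot, p("protein_mrna_ratio"), lps,
            if (n_prot) unname(cidx[af]),
            vapply(paste0("v0_", comp$name), p, numeric(1)),
            vapply(paste0("kdm_", comp$name), p, numeric(1)),
            if (n_prot) vapply(paste0("ksp_", af), p, numeric(1)),
            if (n_prot) vapply(paste0("kdp_", af), p, numeric(1)),
            if (n_prot) vapply(paste0("kin_", af), p, numeric(1)),
            unname(scale),
            length(tE) / 6, tE,
            length(pE) / 5, pE)
  unname(pack)
}

# Slot of the LPS level inside a pack (0-based header position 3).
pack_set_lps <- function(pack, lps) { pack[4] <- lps; pack }

#' Construct a kinetic GRN model
#'
#' Binds a network definition, a kinetic parameter set and a reference basal
#' state into a single model object used by all simulation, steady-state and
#' calibration functions.
#'
#' @param network a \code{grn_network} (default: the packaged network).
#' @param params parameter set (default: the packaged calibration).
#' @param state0 basal initial state; if \code{NULL}, the packaged basal
#'   state is used for the default network/parameters, otherwise the model is
#'   settled for 500 h at LPS = 0 from a small uniform state.
#' @return object of class \code{grn_model}.
#' @examples
#' m <- grn_model()
#' m
#' @export
grn_model <- function(network = grn_network(),
                      params = default_parameters(network),
                      state0 = NULL) {
  audit_parameters(params, network)
  model <- structure(list(network = network, params = params, state0 = NULL),
                     class = "grn_model")
  if (is.null(state0)) {
    path <- system.file("extdata", "initial_state.json", package = "csfgrn")
    snm <- state_names(network)
    packaged <- NULL
    if (nzchar(path)) {
      cand <- unlist(jsonlite::fromJSON(path))
      if (identical(sort(names(cand)), sort(snm))) packaged <- cand[snm]
    }
    if (!is.null(packaged) &&
        identical(params, default_parameters_if_packaged(network, params))) {
      state0 <- packaged
    } else {
      state0 <- settle(model, horizon_h = 500,
                       state = stats::setNames(rep(0.1, length(snm)), snm))
    }
  }
  model$state0 <- state0[state_names(network)]
  model
}

# identity helper: returns `params` when they equal the packaged defaults for
# this network (so the packaged basal state may be reused), otherwise NULL.
default_parameters_if_packaged <- function(network, params) {
  path <- system.file("extdata", "params_default.json", package = "csfgrn")
  if (!nzchar(path)) return(NULL)
  ok <- tryCatch({
    def <- read_parameters(path)
    length(def) == length(params) &&
      all(names(def) %in% names(params)) &&
      isTRUE(all.equal(unclass(def)[names(params)], unclass(params),
                       check.attributes = FALSE))
  }, error = function(e) FALSE)
  if (ok) params else NULL
}

#' @export
print.grn_model <- function(x, ...) {
  cat("Kinetic GRN model\n")
  print(x$network)
  cat("  state dimension:", length(x$state0),
      sprintf("(%d mRNA + 2 x %d protein pools)\n",
              nrow(x$network$components),
              sum(x$network$components$has_active_form)))
  cat("  parameters:", length(x$params), "\n")
  invisible(x)
}

#' @export
coef.grn_model <- function(object, ...) object$params

#' Build the ODE right-hand side
#'
#' Returns the derivative function of the model: a deterministic,
#' time-autonomous function of the state, with time dependence entering only
#' through the inputs.
#'
#' @param net a \code{grn_network}.
#' @param params parameter set covering the network ([audit_parameters()] is
#'   applied; a regulation without its rate entries is a construction error).
#' @return \code{function(t, state, inputs)} returning dstate/dt, where
#'   \code{inputs} is a \code{grn_inputs} object (or a bare LPS level).
#' @export
build_rhs <- function(net, params) {
  audit_parameters(params, net)
  base_pack <- build_pack(net, params, lps = 0)
  n_comp <- nrow(net$components)
  scale_off <- 4 + sum(net$components$has_active_form) + 2 * n_comp +
    3 * sum(net$components$has_active_form)  # offset of scale block (0-based)
  snm <- state_names(net)
  function(t, state, inputs = 0) {
    if (is.numeric(inputs)) inputs <- list(lps = inputs, synthesis_scale = NULL)
    pack <- base_pack
    pack[4] <- inputs$lps
    if (!is.null(inputs$synthesis_scale)) {
      sc <- inputs$synthesis_scale
      full <- stats::setNames(rep(1, n_comp), net$components$name)
      full[names(sc)] <- sc
      pack[(scale_off + 1):(scale_off + n_comp)] <- unname(full)
    }
    dy <- .Call(C_grn_rhs, as.double(pack), as.double(state))
    stats::setNames(dy, snm)
  }
}

#' Effective protein activity of a component
#'
#' The regulatory activity a component exerts on its transcriptional targets:
#' the active protein pool for components with an explicit protein pair, and
#' \code{protein_mrna_ratio} times the mRNA for all others (the bulk
#' protein/mRNA proxy).
#'
#' @param state named state vector.
#' @param component component name.
#' @param params parameter set (supplies \code{protein_mrna_ratio}).
#' @param net network definition.
#' @return scalar activity on the protein concentration scale.
#' @examples
#' st <- grn_model()$state0
#' effective_protein(st, "PU1", default_parameters())
#' @export
effective_protein <- function(state, component, params, net = grn_network()) {
  comp <- net$components
  if (!component %in% comp$name) stop("unknown component: ", component)
  if (comp$has_active_form[comp$name == component]) {
    unname(state[[paste0("protein_active_", component)]])
  } else {
    unname(params[["protein_mrna_ratio"]] * state[[paste0("mrna_", component)]])
  }
}

# Integrate the model at constant inputs for `horizon_h` hours and return the
# final state; the workhorse for basal/activated presets and dwell stages.
settle <- function(model, horizon_h = 500, lps = 0, state = NULL,
                   synthesis_scale = NULL, rtol = 1e-8, atol = 1e-10) {
  if (is.null(state)) state <- model$state0
  out <- integrate_segment(model, state, c(0, horizon_h), lps, synthesis_scale,
                           rtol = rtol, atol = atol)
  out[nrow(out), -1]
}

# Low-level fixed-inputs integration over a time grid using the compiled
# derivative; returns a matrix with a time column followed by state columns.
integrate_segment <- function(model, state, times, lps = 0,
                              synthesis_scale = NULL,
                              rtol = 1e-8, atol = 1e-10) {
  pack <- build_pack(model$network, model$params, lps = lps,
                     synthesis_scale = synthesis_scale)
  parms <- c(pack, rep(0, MAX_PACK_LEN - length(pack)))
  y <- as.double(state[state_names(model$network)])
  names(y) <- state_names(model$network)
  out <- deSolve::ode(y = y, times = times, parms = parms,
                      func = "grn_derivs", initfunc = "grn_initmod",
                      dllname = "csfgrn", method = "lsoda",
                      rtol = rtol, atol = atol, maxsteps = 50000)
  if (attr(out, "istate")[1] < 0)
    stop("integration failed; last good time ",
         out[nrow(out), 1], " h")
  class(out) <- "matrix"
  out
}

#' Basal and activated reference states
#'
#' \code{basal_state()} returns the stored basal steady state (LPS = 0);
#' \code{activated_state()} settles the model for \code{dwell} hours at the
#' given LPS level starting from the basal state and returns the endpoint,
#' i.e. the GRN-activated state for LPS = 1 under the default calibration.
#'
#' @param model a \code{grn_model}.
#' @param lps LPS level for activation (default 1).
#' @param dwell settling horizon in hours.
#' @return named state vector.
#' @export
basal_state <- function(model) model$state0

#' @rdname basal_state
#' @export
activated_state <- function(model, lps = 1, dwell = 500) {
  st <- settle(model, horizon_h = dwell, lps = lps)
  # release the stimulus and let the persistent attractor be reached
  settle(model, horizon_h = dwell, lps = 0, state = st)
}
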