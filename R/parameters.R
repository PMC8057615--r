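# Parameter-set handling.  A parameter set is a named numeric vector whose
# name scheme is derived mechanically from the network definition, so that a
# set and a network can be audited against each other:
#   protein_mrna_ratio                     dimensionless protein/mRNA scale
#   v0_<COMP>    basal transcription rate            [conc / h]
#   kdm_<COMP>   mRNA degradation rate               [1 / h]
#   ksp_<COMP>   protein synthesis rate per mRNA     [1 / h]   (active-form)
#   kdp_<COMP>   protein degradation rate            [1 / h]   (active-form)
#   kin_<COMP>   active -> inactive return rate      [1 / h]   (active-form)
#   v_r<id>, K_r<id>, n_r<id>    activating transcriptional regulation <id>
#   Ki_r<id>, n_r<id>            inhibitory transcriptional regulation <id>
#   ka_r<id>, Ka_r<id>, n_r<id>  post-translational regulation <id>
# Ka_r<id> = 0 encodes a rate linear in the source activity (used for the
# LPS input, which is already dimensionless).

#' Expected parameter names for a network
#'
#' Derives, from the network alone, the exact set of parameter names the
#' kinetic model requires.  Used by [audit_parameters()] to fail loudly on
#' missing or orphan entries.
#'
#' @param net a \code{grn_network}.
#' @return character vector of parameter names.
#' @export
parameter_names <- function(net) {
  comp <- net$components
  reg <- net$regulations
  af <- comp$name[comp$has_active_form]
  nm <- c("protein_mrna_ratio",
          paste0("v0_", comp$name), paste0("kdm_", comp$name),
          paste0("ksp_", af, recycle0 = TRUE),
          paste0("kdp_", af, recycle0 = TRUE),
          paste0("kin_", af, recycle0 = TRUE))
  if (nrow(reg)) {
    for (i in seq_len(nrow(reg))) {
      id <- reg$id[i]
      if (reg$level[i] == "post_translational") {
        nm <- c(nm, paste0(c("ka_r", "Ka_r", "n_r"), id))
      } else if (reg$sign[i] == "activation") {
        nm <- c(nm, paste0(c("v_r", "K_r", "n_r"), id))
      } else {
        nm <- c(nm, paste0(c("Ki_r", "n_r"), id))
      }
    }
  }
  nm
}

#' Audit a parameter set against a network
#'
#' Checks that the parameter set carries exactly the entries the network
#' requires: every regulation has its rate/threshold/cooperativity entries,
#' every component its basal synthesis and degradation rates, and no orphan
#' symbols remain.  All rates must be non-negative.
#'
#' @param params named numeric vector.
#' @param net a \code{grn_network}.
#' @return \code{params}, invisibly.
#' @export
audit_parameters <- function(params, net) {
  want <- parameter_names(net)
  have <- names(params)
  missing <- setdiff(want, have)
  if (length(missing))
    stop("parameter set is missing entries for the network: ",
         paste(missing, collapse = ", "))
  orphan <- setdiff(have, want)
  if (length(orphan))
    stop("parameter set has orphan entries not used by the network: ",
         paste(orphan, collapse = ", "))
  if (any(!is.finite(params)))
    stop("non-finite parameter value: ",
         paste(names(params)[!is.finite(params)], collapse = ", "))
  if (any(params < 0))
    stop("negative parameter value: ",
         paste(names(params)[params < 0], collapse = ", "))
  invisible(params)
}

#' Default calibrated parameter set
#'
#' Reads the packaged parameter file.  The values are the package's own
#' calibration: they were chosen so that the model reproduces the documented
#' behaviour of the network (basal steady state on the beta-actin-relative
#' mRNA scale, the qualitative LPS response classes, the influence ranking,
#' irreversible bistability at low LPS, and the knockdown phenotypes), with
#' the protein/mRNA scale fixed at 3000 and the Irf8 and Csf1 mRNA half-lives
#' at 4.1 h and 5.2 h.
#'
#' @param net network used to audit the set (default packaged network).
#' @return named numeric vector of class \code{grn_parameters}.
#' @export
default_parameters <- function(net = grn_network()) {
  path <- system.file("extdata", "params_default.json", package = "csfgrn")
  params <- read_parameters(path)
  audit_parameters(params, net)
  params
}

#' Read a parameter set from JSON
#'
#' @param path JSON file mapping parameter name to value; entries whose name
#'   starts with \code{"_"} are treated as metadata and ignored.
#' @return named numeric vector.
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  raw <- jsonlite::fromJSON(path)
  raw <- raw[!startsWith(names(raw), "_")]
  out <- vapply(raw, function(x) as.numeric(x)[1], numeric(1))
  structure(out, class = c("grn_parameters", "numeric"))
}

#' Write a parameter set to JSON
#'
#' @param params named numeric vector.
#' @param path output path.
#' @param note optional provenance/metadata string stored under \code{"_note"}.
#' @return \code{path}, invisibly.
#' @export
write_parameters <- function(params, path, note = NULL) {
  lst <- as.list(unclass(params))
  if (!is.null(note)) lst <- c(list(`_note` = note), lst)
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' mRNA half-life of a component
#'
#' Converts the first-order mRNA degradation constant to a half-life,
#' \eqn{t_{1/2} = \ln 2 / k_{deg}}.  With the default parameters the shortest
#' half-lives in the network are Irf8 (4.1 h) and Csf1 (5.2 h).
#'
#' @param params parameter set.
#' @param component component name.
#' @return half-life in hours.
#' @examples
#' half_life(default_parameters(), "IRF8")  # 4.1
#' @export
half_life <- function(params, component) {
  key <- paste0("kdm_", component)
  if (!key %in% names(params)) stop("unknown component: ", component)
  unname(log(2) / params[[key]])
}

#' @export
print.grn_parameters <- function(x, ...) {
  cat("GRN kinetic parameter set:", length(x), "entries\n")
  cat("  protein/mRNA scale:", x[["protein_mrna_ratio"]], "\n")
  kd <- x[startsWith(names(x), "kdm_")]
  hl <- sort(round(log(2) / kd, 1))
  names(hl) <- sub("kdm_", "", names(hl))
  cat("  mRNA half-lives (h):",
      paste(names(hl), hl, sep = "=", collapse = " "), "\n")
  invisible(x)
}
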