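#' @useDynLib csfgrn, .registration = TRUE
"_PACKAGE"

# Canonical component order used throughout the package (mRNA index order).
GRN_COMPONENTS <- c("CSF1", "STAT1", "STAT3", "IRF8", "PU1", "NFKB",
                    "CEBPA", "IL6R", "TNFR1", "CSF1R", "CSF3R")

# Components carrying an explicit inactive/active protein pair.
GRN_ACTIVE_FORM <- c("STAT1", "STAT3", "NFKB", "CEBPA", "CSF1R")

GRN_ROLES <- c(CSF1 = "ligand",
               STAT1 = "transcription_factor", STAT3 = "transcription_factor",
               IRF8 = "transcription_factor", PU1 = "transcription_factor",
               NFKB = "transcription_factor", CEBPA = "transcription_factor",
               IL6R = "receptor", TNFR1 = "receptor",
               CSF1R = "receptor", CSF3R = "receptor")

# id, source, target, sign, level, description.  LPS is the external input,
# not a component.  The two indirect links (4: via IRF7; 31: via the LIF/OSM
# receptors) are encoded as single direct edges with the net sign, because the
# intermediates are not model variables.
grn_regulation_table <- function() {
  reg <- function(id, source, target, sign, level, description)
    list(id = id, source = source, target = target, sign = sign,
         level = level, description = description)
  regs <- list(
    reg(1L,  "LPS",   "STAT1", "activation", "post_translational", "Activation of STAT1 protein by LPS"),
    reg(2L,  "LPS",   "NFKB",  "activation", "transcriptional",    "Activation of NFKB transcription by LPS"),
    reg(3L,  "NFKB",  "NFKB",  "activation", "transcriptional",    "Auto-activation of NFKB transcription"),
    reg(4L,  "NFKB",  "STAT1", "activation", "transcriptional",    "Indirect activation of STAT1 transcription by NFKB (via IRF7)"),
    reg(5L,  "STAT1", "STAT1", "activation", "transcriptional",    "Auto-activation of STAT1 transcription"),
    reg(6L,  "IRF8",  "STAT1", "inhibition", "transcriptional",    "Inhibition of STAT1 transcription by IRF8"),
    reg(7L,  "STAT1", "IRF8",  "activation", "transcriptional",    "Activation of IRF8 transcription by STAT1"),
    reg(8L,  "STAT1", "IL6R",  "activation", "transcriptional",    "Activation of IL6R transcription by STAT1"),
    reg(9L,  "IL6R",  "STAT1", "activation", "post_translational", "Activation of STAT1 protein by IL6R"),
    reg(10L, "NFKB",  "PU1",   "activation", "transcriptional",    "Activation of PU1 transcription by NFKB"),
    reg(11L, "PU1",   "NFKB",  "activation", "transcriptional",    "Activation of NFKB transcription by PU1"),
    reg(12L, "CEBPA", "NFKB",  "activation", "transcriptional",    "Activation of NFKB transcription by CEBPA"),
    reg(13L, "TNFR1", "NFKB",  "activation", "post_translational", "Activation of NFKB protein by TNFR1"),
    reg(14L, "CEBPA", "IL6R",  "activation", "transcriptional",    "Activation of IL6R transcription by CEBPA"),
    reg(15L, "LPS",   "CEBPA", "inhibition", "transcriptional",    "Inhibition of CEBPA transcription by LPS"),
    reg(16L, "CEBPA", "TNFR1", "activation", "transcriptional",    "Activation of TNFR1 transcription by CEBPA"),
    reg(17L, "CEBPA", "CSF1R", "activation", "transcriptional",    "Activation of CSF1R transcription by CEBPA"),
    reg(18L, "STAT3", "TNFR1", "activation", "transcriptional",    "Activation of TNFR1 transcription by STAT3"),
    reg(19L, "CSF1",  "CSF1R", "activation", "post_translational", "Activation of CSF1R by its ligand CSF1"),
    reg(20L, "STAT1", "CSF1",  "activation", "transcriptional",    "Activation of CSF1 transcription by STAT1"),
    reg(21L, "CSF1R", "STAT1", "activation", "post_translational", "Activation of STAT1 protein by CSF1R"),
    reg(22L, "NFKB",  "CSF1",  "activation", "transcriptional",    "Activation of CSF1 transcription by NFKB"),
    reg(23L, "STAT3", "IL6R",  "activation", "transcriptional",    "Activation of IL6R transcription by STAT3"),
    reg(24L, "CEBPA", "PU1",   "activation", "transcriptional",    "Activation of PU1 transcription by CEBPA"),
    reg(25L, "PU1",   "CEBPA", "activation", "transcriptional",    "Activation of CEBPA transcription by PU1"),
    reg(26L, "PU1",   "IRF8",  "activation", "transcriptional",    "Activation of IRF8 transcription by PU1"),
    reg(27L, "PU1",   "PU1",   "activation", "transcriptional",    "Auto-activation of PU1 transcription"),
    reg(28L, "PU1",   "CSF3R", "activation", "transcriptional",    "Activation of CSF3R transcription by PU1"),
    reg(29L, "STAT1", "CSF3R", "activation", "transcriptional",    "Activation of CSF3R transcription by STAT1"),
    reg(30L, "STAT1", "STAT3", "activation", "transcriptional",    "Activation of STAT3 transcription by STAT1"),
    reg(31L, "STAT1", "STAT3", "activation", "post_translational", "Activation of STAT3 protein by STAT1 (via LIF/OSM receptors)"),
    reg(32L, "STAT3", "STAT1", "activation", "post_translational", "Activation of STAT1 protein by STAT3"),
    reg(33L, "CEBPA", "CSF3R", "activation", "transcriptional",    "Activation of CSF3R transcription by CEBPA"),
    reg(34L, "CSF3R", "CEBPA", "activation", "post_translational", "Activation of CEBPA protein by CSF3R"),
    reg(35L, "PU1",   "CSF1R", "activation", "transcriptional",    "Activation of CSF1R transcription by PU1"),
    reg(36L, "PU1",   "CSF1",  "activation", "transcriptional",    "Activation of CSF1 transcription by PU1"),
    reg(37L, "STAT3", "CSF1",  "activation", "transcriptional",    "Activation of CSF1 transcription by STAT3"),
    reg(38L, "STAT3", "STAT3", "activation", "transcriptional",    "Auto-activation of STAT3 transcription"),
    reg(39L, "CSF3R", "STAT3", "activation", "post_translational", "Activation of STAT3 protein by CSF3R"),
    reg(40L, "STAT3", "CEBPA", "activation", "transcriptional",    "Activation of CEBPA transcription by STAT3"),
    reg(41L, "TNFR1", "STAT3", "activation", "post_translational", "Activation of STAT3 protein by TNFR1"),
    reg(42L, "CSF1R", "STAT3", "activation", "post_translational", "Activation of STAT3 protein by CSF1R"))
  do.call(rbind, lapply(regs, function(r)
    data.frame(id = r$id, source = r$source, target = r$target,
               sign = r$sign, level = r$level, description = r$description,
               stringsAsFactors = FALSE)))
}

#' Construct the CSF1R-centered gene regulatory network
#'
#' Builds the default 11-component network: 1 ligand (CSF1), 6 transcription
#' factors (STAT1, STAT3, IRF8, PU1, NFKB, CEBPA) and 4 receptors (IL6R,
#' TNFR1, CSF1R, CSF3R), wired by 42 signed regulations, each tagged as
#' transcriptional or post-translational.  The pro-inflammatory stimulus LPS
#' is an external input (a literal edge source), not a component.
#'
#' @param components data frame with columns \code{name}, \code{role},
#'   \code{has_active_form}; defaults to the packaged 11 components.
#' @param regulations data frame with columns \code{id}, \code{source},
#'   \code{target}, \code{sign}, \code{level} (and optionally
#'   \code{description}); defaults to the packaged 42 regulations.
#' @param version free-text version tag stored with the network.
#' @return an object of class \code{grn_network} with elements
#'   \code{components}, \code{regulations} and \code{version}.
#' @examples
#' net <- grn_network()
#' nrow(net$regulations)  # 42
#' @export
grn_network <- function(components = NULL, regulations = NULL,
                        version = "csfgrn-default-1") {
  if (is.null(components)) {
    components <- data.frame(
      name = GRN_COMPONENTS,
      role = unname(GRN_ROLES[GRN_COMPONENTS]),
      has_active_form = GRN_COMPONENTS %in% GRN_ACTIVE_FORM,
      stringsAsFactors = FALSE)
  }
  if (is.null(regulations)) regulations <- grn_regulation_table()
  if (is.null(regulations$description))
    regulations$description <- character(nrow(regulations))
  net <- structure(list(components = components,
                        regulations = regulations,
                        version = version),
                   class = "grn_network")
  validate_grn_network(net)
  net
}

#' Validate a network definition
#'
#' Checks referential integrity (every regulation source/target resolves to a
#' component or the literal input \code{"LPS"}), uniqueness of regulation ids
#' and of (source, target, level) triples, legal enum values, and that
#' post-translational regulations only target components carrying an active
#' protein form.
#'
#' @param net a \code{grn_network}.
#' @return \code{net}, invisibly, if valid; otherwise an error naming the
#'   offending entry.
#' @export
validate_grn_network <- function(net) {
  comp <- net$components
  reg <- net$regulations
  if (anyDuplicated(comp$name))
    stop("duplicate component name: ",
         paste(comp$name[duplicated(comp$name)], collapse = ", "))
  bad_role <- setdiff(unique(comp$role),
                      c("ligand", "transcription_factor", "receptor"))
  if (length(bad_role))
    stop("unknown component role: ", paste(bad_role, collapse = ", "))
  if (nrow(reg)) {
    if (anyDuplicated(reg$id))
      stop("duplicate regulation id: ",
           paste(reg$id[duplicated(reg$id)], collapse = ", "))
    known <- c(comp$name, "LPS")
    bad_src <- setdiff(unique(reg$source), known)
    if (length(bad_src))
      stop("regulation source is not a component or LPS: ",
           paste(bad_src, collapse = ", "))
    bad_tgt <- setdiff(unique(reg$target), comp$name)
    if (length(bad_tgt))
      stop("regulation target is not a component: ",
           paste(bad_tgt, collapse = ", "))
    bad_sign <- setdiff(unique(reg$sign), c("activation", "inhibition"))
    if (length(bad_sign))
      stop("unknown regulation sign: ", paste(bad_sign, collapse = ", "))
    bad_lvl <- setdiff(unique(reg$level),
                       c("transcriptional", "post_translational"))
    if (length(bad_lvl))
      stop("unknown regulation level: ", paste(bad_lvl, collapse = ", "))
    key <- paste(reg$source, reg$target, reg$level)
    if (anyDuplicated(key))
      stop("duplicate (source, target, level) regulation: ",
           paste(unique(key[duplicated(key)]), collapse = "; "))
    pt <- reg$level == "post_translational"
    if (any(pt)) {
      af <- comp$name[comp$has_active_form]
      bad <- reg$target[pt][!(reg$target[pt] %in% af)]
      if (length(bad))
        stop("post-translational regulation targets component without an ",
             "active form: ", paste(unique(bad), collapse = ", "))
    }
  }
  invisible(net)
}

#' @export
print.grn_network <- function(x, ...) {
  cat("Gene regulatory network (", x$version, ")\n", sep = "")
  cat("  components: ", nrow(x$components),
      " (", sum(x$components$role == "ligand"), " ligand, ",
      sum(x$components$role == "transcription_factor"), " TF, ",
      sum(x$components$role == "receptor"), " receptor)\n", sep = "")
  cat("  regulations:", nrow(x$regulations),
      sprintf("(%d transcriptional, %d post-translational; %d inhibitory)\n",
              sum(x$regulations$level == "transcriptional"),
              sum(x$regulations$level == "post_translational"),
              sum(x$regulations$sign == "inhibition")))
  invisible(x)
}

#' Read a network definition from JSON
#'
#' @param path path to a JSON file with keys \code{components} (name, role,
#'   has_active_form) and \code{regulations} (id, source, target, sign, level,
#'   description), as written by [write_grn_network()].  The packaged default
#'   lives at \code{system.file("extdata", "network.json", package="csfgrn")}.
#' @return a validated \code{grn_network}.
#' @export
read_grn_network <- function(path) {
  if (!file.exists(path)) stop("network file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(raw$components) || is.null(raw$regulations))
    stop("network file must contain 'components' and 'regulations': ", path)
  comp <- as.data.frame(raw$components, stringsAsFactors = FALSE)
  need <- c("name", "role", "has_active_form")
  if (!all(need %in% names(comp)))
    stop("components table missing fields: ",
         paste(setdiff(need, names(comp)), collapse = ", "))
  reg <- as.data.frame(raw$regulations, stringsAsFactors = FALSE)
  if (nrow(reg)) {
    needr <- c("id", "source", "target", "sign", "level")
    if (!all(needr %in% names(reg)))
      stop("regulations table missing fields: ",
           paste(setdiff(needr, names(reg)), collapse = ", "))
    reg$id <- as.integer(reg$id)
  }
  grn_network(components = comp, regulations = reg,
              version = if (is.null(raw$version)) "unversioned" else raw$version)
}

#' Write a network definition to JSON
#'
#' Round-trips through [read_grn_network()]: reloading the written file
#' reproduces the network.
#'
#' @param net a \code{grn_network}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_grn_network <- function(net, path) {
  validate_grn_network(net)
  jsonlite::write_json(
    list(version = net$version,
         components = net$components,
         regulations = net$regulations),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Export a network as a SIF-style edge list
#'
#' Tab-separated rows \code{source  sign  target}; the interaction term is
#' \code{activation} or \code{inhibition}.
#'
#' @param net a \code{grn_network}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_sif <- function(net, path) {
  validate_grn_network(net)
  reg <- net$regulations
  lines <- sprintf("%s\t%s\t%s", reg$source, reg$sign, reg$target)
  writeLines(lines, path)
  invisible(path)
}

#' Enumerate signed feedback loops
#'
#' Finds all simple directed cycles of length at most \code{max_length} in the
#' regulatory graph (self-loops count as length 1 cycles and are included when
#' present).  Each cycle is annotated positive or negative by the parity of
#' its inhibitory edges; positive loops are the classic substrate of
#' bistability.  LPS input edges never participate (LPS has no incoming
#' edges).  Parallel edges between the same ordered pair (for instance a
#' transcriptional and a post-translational activation) are collapsed: only
#' distinct vertex sequences are reported, with the sign computed from the
#' most repressive annotation being treated per-edge pair; if an ordered pair
#' carries both an activating and an inhibiting regulation the cycle is
#' reported once per distinct sign combination.
#'
#' @param net a \code{grn_network}.
#' @param max_length maximum cycle length (number of edges), >= 1.
#' @return a data frame with columns \code{cycle} (component names joined by
#'   \code{"->"}), \code{length}, and \code{sign} (\code{"positive"} or
#'   \code{"negative"}).
#' @examples
#' loops <- feedback_loops(grn_network(), max_length = 3)
#' @export
feedback_loops <- function(net, max_length) {
  stopifnot(max_length >= 1)
  comp <- net$components$name
  reg <- net$regulations
  reg <- reg[reg$source %in% comp, , drop = FALSE]
  if (!nrow(reg) || !length(comp))
    return(data.frame(cycle = character(), length = integer(),
                      sign = character(), stringsAsFactors = FALSE))
  # distinct signed ordered pairs
  pairs <- unique(reg[, c("source", "target", "sign")])
  adj <- split(seq_len(nrow(pairs)), pairs$source)
  out_cycle <- character(); out_len <- integer(); out_sign <- character()
  n <- length(comp)
  # DFS from each root; only visit nodes with index >= root to avoid duplicates
  idx <- stats::setNames(seq_along(comp), comp)
  dfs <- function(root, node, path, ninhib) {
    edges <- adj[[node]]
    if (is.null(edges)) return()
    for (e in edges) {
      tgt <- pairs$target[e]
      ninh <- ninhib + (pairs$sign[e] == "inhibition")
      if (tgt == root) {
        out_cycle[[length(out_cycle) + 1L]] <<-
          paste(c(path, root), collapse = "->")
        out_len[[length(out_len) + 1L]] <<- length(path)
        out_sign[[length(out_sign) + 1L]] <<-
          if (ninh %% 2 == 0) "positive" else "negative"
      } else if (length(path) < max_length &&
                 idx[[tgt]] > idx[[root]] && !(tgt %in% path)) {
        dfs(root, tgt, c(path, tgt), ninh)
      }
    }
  }
  for (root in comp) dfs(root, root, root, 0L)
  data.frame(cycle = out_cycle, length = out_len, sign = out_sign,
             stringsAsFactors = FALSE)
}
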