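# Steady-state analysis: multi-start root finding, stability, and
# pseudo-arclength continuation of the one-parameter (LPS) bifurcation
# diagram.  Negative LPS values are permitted here (and only here): they are
# non-physical but required to trace the saddle-node that joins the middle
# and upper branches below LPS = 0.

# finite-difference Jacobian of the RHS at fixed inputs (central differences,
# step scaled to the state magnitude)
grn_jacobian <- function(model, state, lps = 0, synthesis_scale = NULL) {
  rhs <- build_rhs(model$network, model$params)
  inputs <- list(lps = lps, synthesis_scale = synthesis_scale)
  n <- length(state)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- 1e-6 * max(abs(state[j]), 1e-3)
    sp <- state; sp[j] <- sp[j] + h
    sm <- state; sm[j] <- sm[j] - h
    J[, j] <- (rhs(0, sp, inputs) - rhs(0, sm, inputs)) / (2 * h)
  }
  dimnames(J) <- list(names(state), names(state))
  J
}

scaled_residual <- function(f, x) max(abs(f) / (1 + abs(x)))

# damped Newton iteration for a steady state at fixed inputs
newton_steady_state <- function(model, state, lps = 0, synthesis_scale = NULL,
                                tol = 1e-9, max_iter = 60) {
  rhs <- build_rhs(model$network, model$params)
  inputs <- list(lps = lps, synthesis_scale = synthesis_scale)
  x <- as.numeric(state); names(x) <- names(state)
  f <- rhs(0, x, inputs)
  for (it in seq_len(max_iter)) {
    if (scaled_residual(f, x) < tol)
      return(list(state = x, converged = TRUE, iterations = it - 1L))
    J <- grn_jacobian(model, x, lps, synthesis_scale)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step)))
      return(list(state = x, converged = FALSE, iterations = it))
    lambda <- 1
    r0 <- scaled_residual(f, x)
    repeat {
      xn <- x + lambda * step
      fn <- rhs(0, xn, inputs)
      if (all(is.finite(fn)) && scaled_residual(fn, xn) < r0) break
      lambda <- lambda / 2
      if (lambda < 1e-6) break
    }
    x <- x + lambda * step
    f <- rhs(0, x, inputs)
  }
  list(state = x, converged = scaled_residual(f, x) < tol,
       iterations = max_iter)
}

classify_stability <- function(model, state, lps = 0, synthesis_scale = NULL) {
  ev <- eigen(grn_jacobian(model, state, lps, synthesis_scale),
              only.values = TRUE)$values
  lead <- max(Re(ev))
  list(stability = if (lead < 0) "stable" else "unstable",
       leading_eigenvalue = lead)
}

states_distinct <- function(a, b, tol = 1e-4)
  max(abs(a - b) / (1 + pmax(abs(a), abs(b)))) > tol

#' Locate steady states by multi-start root finding
#'
#' Runs damped Newton iterations from dispersed initial conditions — the
#' basal and activated presets plus \code{n_starts} random states with every
#' variable drawn uniformly in [0, 20] — de-duplicates the converged roots,
#' and classifies each by the eigenvalues of a finite-difference Jacobian.
#'
#' @param model a \code{grn_model}.
#' @param lps LPS level (may be negative; negative values are non-physical
#'   and meaningful only for continuation studies).
#' @param n_starts number of random starts (>= 1).
#' @param seed RNG seed for the random starts.
#' @param synthesis_scale optional named synthesis scaling (knockdowns).
#' @param include_presets also start from the basal and activated states.
#' @param tol scaled residual tolerance.
#' @return data frame of class \code{grn_steady_states}: one row per state
#'   with \code{lps}, \code{stability}, \code{leading_eigenvalue} and one
#'   column per state variable.  Zero rows (with a warning) if no start
#'   converged.
#' @export
find_steady_states <- function(model, lps = 0, n_starts = 30, seed = NULL,
                               synthesis_scale = NULL,
                               include_presets = TRUE, tol = 1e-9) {
  stopifnot(n_starts >= 1)
  if (!is.null(seed)) set.seed(seed)
  snm <- state_names(model$network)
  starts <- list()
  if (include_presets) {
    starts <- list(basal_state(model), activated_state(model))
    # settle the presets at the requested conditions first: cheap and robust
    starts <- lapply(starts, function(s)
      tryCatch(settle(model, 300, lps = lps, state = s,
                      synthesis_scale = synthesis_scale),
               error = function(e) s))
  }
  for (i in seq_len(n_starts))
    starts[[length(starts) + 1L]] <-
      stats::setNames(stats::runif(length(snm), 0, 20), snm)
  found <- list()
  for (s in starts) {
    res <- newton_steady_state(model, s, lps, synthesis_scale, tol = tol)
    if (!res$converged) next
    if (any(res$state < -1e-6) && lps >= 0) next  # non-physical root
    dup <- any(vapply(found, function(g)
      !states_distinct(g, res$state), logical(1)))
    if (!dup) found[[length(found) + 1L]] <- res$state
  }
  if (!length(found)) {
    warning("no steady state found from any start at lps = ", lps)
    out <- data.frame(lps = numeric(), stability = character(),
                      leading_eigenvalue = numeric())
    return(structure(out, class = c("grn_steady_states", "data.frame")))
  }
  rows <- lapply(found, function(x) {
    cls <- classify_stability(model, x, lps, synthesis_scale)
    c(list(lps = lps, stability = cls$stability,
           leading_eigenvalue = cls$leading_eigenvalue), as.list(x))
  })
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  out <- out[order(out[[paste0("mrna_", "STAT1")]] %||% out[[4]]), ]
  rownames(out) <- NULL
  structure(out, class = c("grn_steady_states", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# d f / d lps by central differences
rhs_dlps <- function(model, state, lps, h = 1e-6) {
  rhs <- build_rhs(model$network, model$params)
  (rhs(0, state, lps + h) - rhs(0, state, lps - h)) / (2 * h)
}

#' Pseudo-arclength continuation of a steady-state branch
#'
#' Traces a branch of steady states as LPS varies, passing around folds.
#' Fold (saddle-node) points are detected as sign changes of the LPS
#' component of the unit tangent and refined by interpolation.
#'
#' @param model a \code{grn_model}.
#' @param start named steady-state vector (must satisfy the steady-state
#'   tolerance at \code{lps_start}).
#' @param lps_start LPS value of the starting state.
#' @param lps_range length-2 numeric: continuation stops when LPS leaves
#'   this interval (the lower bound may be negative).
#' @param direction initial direction of travel along LPS (+1 or -1).
#' @param ds initial arclength step; adapted between \code{ds_min} and
#'   \code{ds_max}.
#' @param ds_min,ds_max step-size bounds.
#' @param max_steps maximum number of continuation steps.
#' @param tol scaled residual tolerance for the corrector.
#' @return list of class \code{grn_branch}: \code{points} (data frame with
#'   \code{lps}, \code{stability}, \code{leading_eigenvalue}, state
#'   columns), \code{folds} (data frame of fold locations), and
#'   \code{truncated} (TRUE if the step size collapsed).
#' @export
continue_branch <- function(model, start, lps_start, lps_range,
                            direction = 1, ds = 0.02, ds_min = 1e-6,
                            ds_max = 0.05, max_steps = 400, tol = 1e-9) {
  res <- newton_steady_state(model, start, lps_start, tol = tol)
  if (!res$converged) stop("starting point is not a converged steady state")
  x <- res$state
  n <- length(x)
  w <- 1 / (1 + abs(x))               # variable weights for arclength
  lam <- lps_start
  # tangent: solve [J fl; t_prev] t = [0; 1]
  tangent <- function(x, lam, t_prev) {
    J <- grn_jacobian(model, x, lam)
    fl <- rhs_dlps(model, x, lam)
    A <- rbind(cbind(J, fl), t_prev * c(w^2, 1))
    t <- tryCatch(solve(A, c(rep(0, n), 1)), error = function(e) NULL)
    if (is.null(t)) return(NULL)
    t / sqrt(sum((t * c(w, 1))^2))
  }
  t_prev <- c(rep(0, n), direction)
  t_cur <- tangent(x, lam, t_prev)
  if (is.null(t_cur)) stop("singular Jacobian at starting point")
  if (sign(t_cur[n + 1]) != sign(direction)) t_cur <- -t_cur
  rhs_f <- build_rhs(model$network, model$params)
  pts <- list(); folds <- list(); truncated <- FALSE
  add_point <- function(x, lam) {
    cls <- classify_stability(model, x, lam)
    pts[[length(pts) + 1L]] <<-
      as.data.frame(c(list(lps = lam, stability = cls$stability,
                           leading_eigenvalue = cls$leading_eigenvalue),
                      as.list(x)), stringsAsFactors = FALSE)
  }
  add_point(x, lam)
  for (step in seq_len(max_steps)) {
    repeat {
      # predictor
      xp <- x + ds * t_cur[1:n]
      lp <- lam + ds * t_cur[n + 1]
      # corrector: Newton on [f; pseudo-arclength constraint]
      ok <- FALSE
      xc <- xp; lc <- lp
      for (it in 1:12) {
        f <- rhs_f(0, xc, lc)
        g <- sum((c(xc - x, lc - lam) * t_cur) * c(w^2, 1)) - ds
        if (scaled_residual(f, xc) < tol && abs(g) < 1e-10) { ok <- TRUE; break }
        J <- grn_jacobian(model, xc, lc)
        fl <- rhs_dlps(model, xc, lc)
        A <- rbind(cbind(J, fl), t_cur * c(w^2, 1))
        d <- tryCatch(solve(A, -c(f, g)), error = function(e) NULL)
        if (is.null(d) || any(!is.finite(d))) break
        xc <- xc + d[1:n]; lc <- lc + d[n + 1]
      }
      if (ok) break
      ds <- ds / 2
      if (ds < ds_min) { truncated <- TRUE; break }
    }
    if (truncated) break
    t_new <- tangent(xc, lc, t_cur)
    if (is.null(t_new)) { truncated <- TRUE; break }
    if (sum(t_new * t_cur * c(w^2, 1)) < 0) t_new <- -t_new
    # fold: sign change of the lps tangent component
    if (sign(t_new[n + 1]) != sign(t_cur[n + 1]) &&
        abs(t_cur[n + 1]) > 1e-12) {
      a <- abs(t_cur[n + 1]); b <- abs(t_new[n + 1])
      wts <- b / (a + b)
      fold_lam <- wts * lam + (1 - wts) * lc
      fold_x <- wts * x + (1 - wts) * xc
      folds[[length(folds) + 1L]] <-
        as.data.frame(c(list(lps = fold_lam), as.list(fold_x)),
                      stringsAsFactors = FALSE)
    }
    x <- xc; lam <- lc; t_cur <- t_new
    add_point(x, lam)
    if (lam < min(lps_range) - 1e-9 || lam > max(lps_range) + 1e-9) break
    ds <- min(ds * 1.3, ds_max)
  }
  points <- do.call(rbind, pts); rownames(points) <- NULL
  folds <- if (length(folds)) do.call(rbind, folds) else
    data.frame(lps = numeric())
  structure(list(points = points, folds = folds, truncated = truncated),
            class = "grn_branch")
}

#' One-parameter bifurcation diagram in LPS
#'
#' Continues the branches through the basal and activated states across
#' \code{lps_range} and collects fold (saddle-node) points.  The lower bound
#' may be negative: the connection of the middle and upper branches lies at
#' (non-physical) negative LPS.
#'
#' @param model a \code{grn_model}.
#' @param lps_range continuation interval (default c(-0.4, 1)).
#' @param ds initial arclength step.
#' @return object of class \code{grn_bifurcation}: list of
#'   \code{grn_branch} objects plus a combined \code{folds} data frame.
#' @export
bifurcation_diagram <- function(model, lps_range = c(-0.4, 1), ds = 0.02) {
  lo <- max(0, min(lps_range))
  b_low <- continue_branch(model, basal_state(model), lps_start = lo,
                           lps_range = lps_range, direction = 1, ds = ds)
  b_high <- continue_branch(model, activated_state(model), lps_start = 0,
                            lps_range = lps_range, direction = 1, ds = ds)
  b_high_dn <- continue_branch(model, activated_state(model), lps_start = 0,
                               lps_range = lps_range, direction = -1, ds = ds)
  branches <- list(lower = b_low, upper = b_high, upper_down = b_high_dn)
  folds <- do.call(rbind, lapply(branches, function(b) b$folds))
  folds <- folds[is.finite(folds$lps), , drop = FALSE]
  structure(list(branches = branches, folds = folds,
                 lps_range = lps_range), class = "grn_bifurcation")
}

#' @export
print.grn_bifurcation <- function(x, ...) {
  cat("Bifurcation diagram over LPS in [",
      paste(x$lps_range, collapse = ", "), "]\n")
  for (nm in names(x$branches)) {
    b <- x$branches[[nm]]
    cat(sprintf("  branch %-10s: %d points, %d fold(s)%s\n", nm,
                nrow(b$points), nrow(b$folds),
                if (b$truncated) " [truncated]" else ""))
  }
  if (nrow(x$folds))
    cat("  fold LPS values:",
        paste(signif(x$folds$lps, 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.grn_bifurcation <- function(x, var = "mrna_STAT1", ...) {
  pts <- do.call(rbind, lapply(x$branches, function(b) b$points))
  plot(NA, xlim = range(pts$lps), ylim = range(pts[[var]]),
       xlab = "LPS", ylab = var, ...)
  for (b in x$branches) {
    p <- b$points
    st <- p$stability == "stable"
    graphics::points(p$lps[st], p[[var]][st], pch = 16, cex = 0.4)
    graphics::points(p$lps[!st], p[[var]][!st], pch = 1, cex = 0.4,
                     col = "grey50")
  }
  if (nrow(x$folds) && var %in% names(x$folds))
    graphics::points(x$folds$lps, x$folds[[var]], pch = 4, col = 2, cex = 1.2)
  invisible(x)
}

#' Write a bifurcation diagram as CSV
#'
#' Columns \code{branch_id}, \code{lps}, \code{stability}, then one column
#' per state variable.
#'
#' @param diagram a \code{grn_bifurcation}.
#' @param path output CSV path.
#' @param folds_path optional JSON path for the fold points.
#' @return \code{path}, invisibly.
#' @export
write_bifurcation <- function(diagram, path, folds_path = NULL) {
  tab <- do.call(rbind, lapply(names(diagram$branches), function(nm) {
    p <- diagram$branches[[nm]]$points
    cbind(branch_id = nm, p)
  }))
  tab$leading_eigenvalue <- NULL
  utils::write.csv(tab, path, row.names = FALSE)
  if (!is.null(folds_path))
    jsonlite::write_json(diagram$folds, folds_path, digits = NA,
                         dataframe = "rows")
  invisible(path)
}

#' Quasi-static hysteresis sweep
#'
#' Walks LPS up and then back down, letting the system settle for
#' \code{dwell_h} hours at each level, starting from the basal state.  On an
#' irreversible bistable system the up-sweep jumps to the activated state
#' past the fold and the down-sweep stays on it all the way to LPS = 0.
#'
#' @param model a \code{grn_model}.
#' @param lps_up increasing LPS levels (the reverse is used coming down).
#' @param dwell_h dwell per level (default 200 h).
#' @return data frame with \code{direction}, \code{lps} and state columns.
#' @export
hysteresis_sweep <- function(model, lps_up = seq(0, 1, by = 0.1),
                             dwell_h = 200) {
  st <- basal_state(model)
  rows <- list()
  for (l in lps_up) {
    st <- settle(model, dwell_h, lps = l, state = st)
    rows[[length(rows) + 1L]] <-
      as.data.frame(c(list(direction = "up", lps = l), as.list(st)),
                    stringsAsFactors = FALSE)
  }
  for (l in rev(lps_up)) {
    st <- settle(model, dwell_h, lps = l, state = st)
    rows[[length(rows) + 1L]] <-
      as.data.frame(c(list(direction = "down", lps = l), as.list(st)),
                    stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows); rownames(out) <- NULL
  out
}
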