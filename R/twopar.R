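# Two-parameter bifurcation curves in the (gCANTot, h) plane and
# trajectory-crossing diagnostics.

#' Fold bifurcation curve in the (gCANTot, h) plane
#'
#' For each h on the grid, the fold `gCANTot` values from the exact
#' condition `d gCANTot / dV = 0` of the closed-form equilibrium curve.
#' Curve branches are labelled by the fold rank at each h (F1 = larger
#' `gCANTot`); the curve ends (cusp) where the folds coalesce.
#'
#' @param p `prebotc_params`.
#' @param h_range frozen-gate interval within \[0, 1\].
#' @param n_h grid points in h.
#' @param V_range voltage window searched for knees.
#' @return An object of class `prebotc_twopar`: data frame
#'   `kind, h, gCANTot, V, label`.
#' @export
fold_curve <- function(p, h_range = c(0, 0.35), n_h = 141,
                       V_range = c(-72, 15)) {
  hh <- seq(h_range[1], h_range[2], length.out = n_h)
  rows <- lapply(hh, function(h) {
    vf <- .fold_voltages(p, h, V_range)
    if (!length(vf)) return(NULL)
    g <- .gcan_of_V(vf, p, h)
    data.frame(kind = "fc", h = h, gCANTot = g, V = vf,
               label = paste0("F", rank(-g)))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(kind = character(0), h = numeric(0),
                      gCANTot = numeric(0), V = numeric(0),
                      label = character(0))
  structure(out, params = p, class = c("prebotc_twopar", "data.frame"))
}

#' Hopf bifurcation curve in the (gCANTot, h) plane
#'
#' Per-h Hopf location on the closed-form equilibrium branch (upper-branch
#' crossing of the complex pair's real part), assembled over the h grid.
#'
#' @inheritParams fold_curve
#' @return `prebotc_twopar` data frame `kind, h, gCANTot, V`.
#' @export
hopf_curve <- function(p, h_range = c(0, 0.35), n_h = 141,
                       V_range = c(-72, 15)) {
  hh <- seq(h_range[1], h_range[2], length.out = n_h)
  rows <- lapply(hh, function(h) {
    eq <- equilibrium_curve(p, h, seq(V_range[1], V_range[2], by = 0.1))
    hp <- find_hopf(eq, probe = FALSE)
    if (!nrow(hp)) return(NULL)
    hp <- hp[which.max(hp$V), , drop = FALSE]
    data.frame(kind = "hc", h = h, gCANTot = hp$gCANTot, V = hp$V)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(kind = character(0), h = numeric(0),
                      gCANTot = numeric(0), V = numeric(0))
  structure(out, params = p, class = c("prebotc_twopar", "data.frame"))
}

#' Fold-of-limit-cycles curve in the (gCANTot, h) plane
#'
#' Per-h LPC location: the upper endpoint of the stable cycle branch,
#' refined by bisection (see [find_cycle_boundary()]).  Computed on a
#' coarse h grid; points where no cycle branch exists leave gaps.
#'
#' @inheritParams fold_curve
#' @param n_h grid points (the per-point cost is a cycle continuation).
#' @param boundary_tol bisection tolerance in `gCANTot`.
#' @return `prebotc_twopar` data frame `kind, h, gCANTot, period`.
#' @export
lpc_curve <- function(p, h_range = c(0.02, 0.32), n_h = 13,
                      boundary_tol = 5e-4) {
  hh <- seq(h_range[1], h_range[2], length.out = n_h)
  rows <- lapply(hh, function(h) {
    d <- tryCatch(
      fastslow_diagram(p, h, n_branch = 25, boundary_tol = boundary_tol),
      error = function(e) NULL)
    if (is.null(d) || is.null(d$lpc)) return(NULL)
    data.frame(kind = "lc", h = h, gCANTot = d$lpc$gCANTot,
               period = d$lpc$period)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(kind = character(0), h = numeric(0),
                      gCANTot = numeric(0), period = numeric(0))
  structure(out, params = p, class = c("prebotc_twopar", "data.frame"))
}

#' Approximate homoclinic / termination contour in the (gCANTot, h) plane
#'
#' Per-h parameter at which the stable cycle branch terminates with period
#' blow-up (period above `period_max`).  Below the fold-curve cusp these
#' points lie on the fold curve itself (SNIC); elsewhere they approximate
#' the homoclinic curve.  Explicitly an approximation by period contour,
#' not a boundary-value continuation.
#'
#' @inheritParams lpc_curve
#' @param period_max blow-up period (ms).
#' @return `prebotc_twopar` data frame `kind, h, gCANTot, type`.
#' @export
homoclinic_contour <- function(p, h_range = c(0.02, 0.32), n_h = 13,
                               period_max = 2e4, boundary_tol = 5e-4) {
  hh <- seq(h_range[1], h_range[2], length.out = n_h)
  rows <- lapply(hh, function(h) {
    d <- tryCatch(
      fastslow_diagram(p, h, n_branch = 25, period_max = period_max,
                       boundary_tol = boundary_tol),
      error = function(e) NULL)
    if (is.null(d)) return(NULL)
    data.frame(kind = "homo", h = h, gCANTot = d$termination$gCANTot,
               type = d$termination$type)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(kind = character(0), h = numeric(0),
                      gCANTot = numeric(0), type = character(0))
  structure(out, params = p, class = c("prebotc_twopar", "data.frame"))
}

#' Project a full-system trajectory into the (gCANTot, h) plane
#'
#' The slow coordinates of the burst: `gCANTot(t) = gCAN * f([Ca](t))` and
#' `h(t)`.
#'
#' @param traj full-system `prebotc_traj`.
#' @param p `prebotc_params` (defaults to the trajectory's own).
#' @return Data frame `t, gCANTot, h`.
#' @export
project_trajectory <- function(traj, p = attr(traj, "params")) {
  data.frame(t = traj$t, gCANTot = ca_to_gcan(traj$Ca, p), h = traj$h)
}

#' Crossings of a two-parameter curve by the slow trajectory
#'
#' Interpolates the curve as `gCANTot(h)` (per branch label where present)
#' and reports each time the projected trajectory crosses it, with
#' direction (+1 crossing toward larger `gCANTot`).
#'
#' @param curve `prebotc_twopar` (one kind).
#' @param proj projected trajectory from [project_trajectory()].
#' @return Data frame `t, kind, label, direction`; zero rows if no
#'   crossing.
#' @export
curve_crossings <- function(curve, proj) {
  empty <- data.frame(t = numeric(0), kind = character(0),
                      label = character(0), direction = numeric(0))
  if (!nrow(curve)) return(empty)
  labs <- if ("label" %in% names(curve)) unique(curve$label) else ""
  out <- list()
  for (lb in labs) {
    cc <- if (nzchar(lb)) curve[curve$label == lb, ] else curve
    cc <- cc[order(cc$h), ]
    cc <- cc[!duplicated(cc$h), ]
    if (nrow(cc) < 2) next
    hok <- proj$h >= min(cc$h) & proj$h <= max(cc$h)
    if (!any(hok)) next
    gi <- rep(NA_real_, nrow(proj))
    gi[hok] <- stats::approx(cc$h, cc$gCANTot, xout = proj$h[hok])$y
    s <- proj$gCANTot - gi
    i <- which(!is.na(s[-1]) & !is.na(s[-length(s)]) &
                 s[-1] * s[-length(s)] < 0)
    if (!length(i)) next
    out[[length(out) + 1]] <-
      data.frame(t = proj$t[i], kind = curve$kind[1], label = lb,
                 direction = ifelse(s[i + 1] > s[i], 1, -1))
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$t), ]
}

#' Shift of the S-shaped curve with the induction gain k1
#'
#' For each `k1`, the fold locations and branch extents of the closed-form
#' equilibrium curve at fixed `h`, quantifying how the magnetic-flux
#' feedback moves the knees without changing the fold count.
#'
#' @param k1_values non-negative induction gains.
#' @param p base `prebotc_params`.
#' @param h_frozen frozen slow gate.
#' @return Data frame `k1, n_folds, g_F1, g_F2, V_F1, V_F2`.
#' @export
scurve_shift <- function(k1_values, p = botc_params(), h_frozen = 0.2834) {
  stopifnot(all(k1_values >= 0))
  rows <- lapply(k1_values, function(k1) {
    pp <- p
    pp$k1 <- k1
    eq <- equilibrium_curve(pp, h_frozen)
    f <- find_folds(eq)
    data.frame(k1 = k1, n_folds = nrow(f),
               g_F1 = if (nrow(f)) f$gCANTot[f$label == "F1"] else NA_real_,
               g_F2 = if (nrow(f) > 1) f$gCANTot[f$label == "F2"] else NA_real_,
               V_F1 = if (nrow(f)) f$V[f$label == "F1"] else NA_real_,
               V_F2 = if (nrow(f) > 1) f$V[f$label == "F2"] else NA_real_)
  })
  do.call(rbind, rows)
}
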