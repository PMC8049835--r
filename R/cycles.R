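# Limit-cycle machinery for the fast subsystem: attractor-based cycle
# tracking, Newton shooting refinement with Floquet multipliers, LPC
# detection, and HC / SNIC termination of the cycle branch.

# raw integration of the fast subsystem (no trajectory wrapper)
.fast_ode <- function(fp, y0, times, rtol = 1e-9, atol = 1e-11) {
  out <- deSolve::ode(y = unname(y0[c(1, 2, 3)]), times = times,
                      func = "prebotc_deriv_fast", parms = .par_vec_fast(fp),
                      dllname = "prebotc", initfunc = "prebotc_init_fast",
                      method = "lsoda", rtol = rtol, atol = atol,
                      maxsteps = 1e5)
  if (attr(out, "istate")[1] < 0) stop("fast-subsystem integration failed")
  out
}

.upcrossings <- function(t, v, level) {
  s <- v - level
  i <- which(s[-length(s)] < 0 & s[-1] >= 0)
  if (!length(i)) return(numeric(0))
  t[i] + (t[i + 1] - t[i]) * (-s[i]) / (s[i + 1] - s[i])
}

#' Measure the attracting limit cycle of the fast subsystem
#'
#' Integrates from `y0`, discards a transient fraction, and measures the
#' oscillation period from upward crossings of the mid-range voltage level.
#' Declares "no cycle" when the post-transient trajectory has collapsed
#' onto an equilibrium (voltage amplitude below `amp_min`) or shows fewer
#' than two section crossings within the window.
#'
#' @param fp `prebotc_fastpars`.
#' @param y0 initial state (V, n, phi).
#' @param t_max integration window (ms); long windows are needed near
#'   period blow-up.
#' @param transient_frac leading fraction of the window discarded.
#' @param amp_min minimal voltage amplitude (mV) accepted as oscillation.
#' @param dt_out sampling interval (ms).
#' @return List: `has_cycle`, `period` (last inter-crossing interval),
#'   `Vmax`, `Vmin`, `y_end` (state at the last sample), `n_crossings`.
#' @export
measure_cycle <- function(fp, y0 = c(V = -30, n = 0.1, phi = -10),
                          t_max = 3000, transient_frac = 0.3,
                          amp_min = 0.1, dt_out = 0.05) {
  out <- .fast_ode(fp, y0, seq(0, t_max, by = dt_out))
  t <- out[, 1]; v <- out[, 2]
  sel <- t >= transient_frac * t_max
  t <- t[sel]; v <- v[sel]
  y_end <- out[nrow(out), -1]
  names(y_end) <- c("V", "n", "phi")
  Vmax <- max(v); Vmin <- min(v)
  if (Vmax - Vmin < amp_min)
    return(list(has_cycle = FALSE, period = NA_real_, Vmax = Vmax,
                Vmin = Vmin, y_end = y_end, n_crossings = 0L))
  cr <- .upcrossings(t, v, (Vmax + Vmin) / 2)
  if (length(cr) < 2)
    return(list(has_cycle = FALSE, period = NA_real_, Vmax = Vmax,
                Vmin = Vmin, y_end = y_end, n_crossings = length(cr)))
  list(has_cycle = TRUE, period = diff(utils::tail(cr, 2)),
       Vmax = Vmax, Vmin = Vmin, y_end = y_end,
       n_crossings = length(cr))
}

#' Track the stable cycle branch of the fast subsystem
#'
#' Marches `gCANTot` from `g_start` toward `g_end` (either direction),
#' warm-starting each point from the previous cycle state, and records
#' period and voltage extrema.  Stops when the cycle disappears (collapse
#' onto an equilibrium) or its period exceeds `period_max`; the exact
#' endpoint can then be refined with [find_cycle_boundary()].
#'
#' @param p `prebotc_params`.
#' @param h_frozen frozen slow gate.
#' @param g_start,g_end parameter range to traverse.
#' @param n_pts number of grid points.
#' @param period_max period (ms) declared as blow-up; default 2e4.
#' @param y0 initial state for the first point.
#' @param t_base integration window (ms) per point; extended automatically
#'   when the period grows.
#' @return An object of class `prebotc_cycbranch`: data frame with columns
#'   `gCANTot, period, Vmax, Vmin, has_cycle` and attributes with the
#'   settings and the last valid cycle state.
#' @export
cycle_branch <- function(p, h_frozen, g_start, g_end, n_pts = 60,
                         period_max = 2e4,
                         y0 = c(V = -30, n = 0.1, phi = -10),
                         t_base = 3000) {
  gg <- seq(g_start, g_end, length.out = n_pts)
  res <- data.frame(gCANTot = gg, period = NA_real_, Vmax = NA_real_,
                    Vmin = NA_real_, has_cycle = FALSE)
  y <- y0
  y_last <- NULL
  last_period <- 50
  for (i in seq_along(gg)) {
    fp <- fast_params(p, h_frozen, gg[i])
    t_max <- max(t_base, 30 * last_period)
    m <- measure_cycle(fp, y, t_max = min(t_max, 2.5 * period_max))
    if (m$has_cycle && m$period <= period_max) {
      res$period[i] <- m$period
      res$Vmax[i] <- m$Vmax
      res$Vmin[i] <- m$Vmin
      res$has_cycle[i] <- TRUE
      y <- m$y_end
      y_last <- m$y_end
      last_period <- m$period
    } else {
      res$period[i] <- m$period
      break
    }
  }
  structure(res, params = p, h_frozen = h_frozen, period_max = period_max,
            y_last = y_last, class = c("prebotc_cycbranch", "data.frame"))
}

#' Refine a cycle-branch endpoint by bisection
#'
#' Bisects `gCANTot` between a value with a (finite-period) cycle and a
#' value without one, warm-starting every probe, until the bracket is
#' narrower than `tol`.  Used for both cycle termination (HC / SNIC, cycle
#' lost toward low `gCANTot`) and the fold of limit cycles (LPC, cycle lost
#' toward high `gCANTot`).
#'
#' @param p `prebotc_params`.
#' @param h_frozen frozen slow gate.
#' @param g_ok value with a cycle (period below `period_max`).
#' @param g_bad value without.
#' @param y0 state on the cycle at `g_ok`.
#' @param tol bracket width target.
#' @param period_max blow-up period (ms).
#' @return List: `g_boundary` (midpoint of the final bracket), `g_ok`,
#'   `g_bad`, `period_last` (period at the last surviving probe).
#' @export
find_cycle_boundary <- function(p, h_frozen, g_ok, g_bad, y0,
                                tol = 1e-4, period_max = 2e4) {
  period_last <- NA_real_
  y <- y0
  while (abs(g_bad - g_ok) > tol) {
    gm <- (g_ok + g_bad) / 2
    fp <- fast_params(p, h_frozen, gm)
    t_max <- if (is.na(period_last)) 3000 else
      min(max(3000, 30 * period_last), 2.5 * period_max)
    m <- measure_cycle(fp, y, t_max = t_max)
    if (m$has_cycle && m$period <= period_max) {
      g_ok <- gm
      y <- m$y_end
      period_last <- m$period
    } else {
      g_bad <- gm
    }
  }
  list(g_boundary = (g_ok + g_bad) / 2, g_ok = g_ok, g_bad = g_bad,
       period_last = period_last)
}

# flow map and its state derivative (monodromy) by finite differences
.flow <- function(fp, y, T, rtol = 1e-11, atol = 1e-13) {
  out <- .fast_ode(fp, y, c(0, T), rtol = rtol, atol = atol)
  out[nrow(out), -1]
}

#' Monodromy matrix and Floquet multipliers of a cycle
#'
#' Finite-difference derivative of the time-T flow map around the cycle
#' point `y0`; the multipliers are its eigenvalues, one of which must equal
#' +1 (the trivial multiplier along the flow).
#'
#' @param fp `prebotc_fastpars`.
#' @param y0 point on the cycle.
#' @param T period (ms).
#' @param eps finite-difference step scale.
#' @return List with `M` (3x3 monodromy) and `multipliers` (complex,
#'   ordered by decreasing modulus).
#' @export
floquet_multipliers <- function(fp, y0, T, eps = 1e-6) {
  M <- matrix(NA_real_, 3, 3)
  base <- .flow(fp, y0, T)
  for (i in 1:3) {
    step <- eps * (1 + abs(y0[i]))
    yp <- y0; ym <- y0
    yp[i] <- y0[i] + step
    ym[i] <- y0[i] - step
    M[, i] <- (.flow(fp, yp, T) - .flow(fp, ym, T)) / (2 * step)
  }
  mult <- eigen(M, only.values = TRUE)$values
  list(M = M, multipliers = mult[order(-Mod(mult))], residual = base - y0)
}

#' Newton shooting refinement of a periodic orbit
#'
#' Solves `flow_T(y) - y = 0` together with the phase condition
#' `dV/dt(y) = 0` (anchoring y at a voltage extremum) for `(y, T)` by
#' damped Newton with finite-difference derivatives.  Works for unstable
#' cycles, where forward integration cannot converge.
#'
#' @param fp `prebotc_fastpars`.
#' @param y0 initial guess for a point on the cycle.
#' @param T0 initial guess for the period (ms).
#' @param max_iter Newton iterations.
#' @param tol residual tolerance.
#' @return List: `y`, `T`, `converged`, `residual`, `multipliers`.
#' @export
refine_cycle <- function(fp, y0, T0, max_iter = 25, tol = 1e-9) {
  u <- c(unname(y0), T0)
  Ffun <- function(u) {
    y <- u[1:3]; T <- u[4]
    c(.flow(fp, y, T) - y,
      fast_rhs(c(V = y[1], n = y[2], phi = y[3]), fp)[["V"]])
  }
  conv <- FALSE
  Fv <- Ffun(u)
  for (it in seq_len(max_iter)) {
    if (max(abs(Fv)) < tol) { conv <- TRUE; break }
    J <- matrix(NA_real_, 4, 4)
    for (i in 1:4) {
      step <- 1e-7 * (1 + abs(u[i]))
      up <- u; um <- u
      up[i] <- u[i] + step; um[i] <- u[i] - step
      J[, i] <- (Ffun(up) - Ffun(um)) / (2 * step)
    }
    du <- tryCatch(solve(J, -Fv), error = function(e) NULL)
    if (is.null(du)) break
    lam <- 1
    repeat {
      unew <- u + lam * du
      if (unew[4] <= 0) { lam <- lam / 2; next }
      Fnew <- tryCatch(Ffun(unew), error = function(e) NULL)
      if (!is.null(Fnew) && (max(abs(Fnew)) < max(abs(Fv)) || lam < 1e-3))
        break
      lam <- lam / 2
      if (lam < 1e-4) break
    }
    if (is.null(Fnew)) break
    u <- unew; Fv <- Fnew
  }
  y <- u[1:3]; names(y) <- c("V", "n", "phi")
  fl <- if (conv) floquet_multipliers(fp, y, u[4]) else
    list(multipliers = rep(NA_complex_, 3))
  list(y = y, T = u[4], converged = conv, residual = max(abs(Fv)),
       multipliers = fl$multipliers)
}

#' Continue the unstable cycle born at a subcritical Hopf point
#'
#' Seeds a small cycle from the Hopf linearization (equilibrium plus a
#' small multiple of the critical eigenplane, period `2*pi/omega`) and
#' continues it in `gCANTot` by Newton shooting with secant prediction,
#' heading away from the Hopf point (toward the fold of limit cycles).
#'
#' @param p `prebotc_params`.
#' @param h_frozen frozen slow gate.
#' @param hopf one row of [find_hopf()] output.
#' @param dg0 initial parameter step away from the Hopf point.
#' @param n_steps maximum continuation steps.
#' @param direction +1 to increase `gCANTot`, -1 to decrease; the
#'   subcritical branch lives on the stable-focus side.
#' @return Data frame `gCANTot, period, Vmax_proxy, mult1, converged`
#'   (`mult1` = modulus of the largest nontrivial multiplier).
#' @export
continue_cycles_from_hopf <- function(p, h_frozen, hopf, dg0 = 2e-4,
                                      n_steps = 40, direction = +1) {
  Vh <- hopf$V
  eqst <- c(V = Vh, n = gating_inf(Vh, p$theta_n, p$sigma_n), phi = Vh / p$k2)
  fp_h <- fast_params(p, h_frozen, max(hopf$gCANTot, 0))
  fp_h$gCANTot <- hopf$gCANTot
  J <- fast_jacobian(eqst, fp_h)
  ed <- eigen(J)
  ic <- which(abs(Im(ed$values)) > 1e-9)[1]
  vwork <- ed$vectors[, ic]
  vre <- Re(vwork) / max(abs(Re(vwork)))
  omega <- abs(Im(ed$values[ic]))
  eps <- 0.35
  g <- hopf$gCANTot + direction * dg0
  y_guess <- eqst + eps * vre
  T_guess <- 2 * pi / omega
  rows <- list()
  prev <- NULL
  dg <- direction * dg0
  for (k in seq_len(n_steps)) {
    fp <- fast_params(p, h_frozen, max(g, 0)); fp$gCANTot <- g
    rc <- refine_cycle(fp, y_guess, T_guess)
    if (!rc$converged) {
      dg <- dg / 2
      if (abs(dg) < dg0 / 16) break
      g <- g - dg
      next
    }
    mult <- rc$multipliers
    nontriv <- mult[order(abs(mult - 1))][-1]
    rows[[length(rows) + 1]] <-
      data.frame(gCANTot = g, period = rc$T,
                 V_anchor = rc$y[["V"]],
                 mult1 = max(Mod(nontriv)), converged = TRUE)
    if (!is.null(prev)) {
      y_guess <- rc$y + (rc$y - prev$y)
      T_guess <- rc$T + (rc$T - prev$T)
    } else {
      y_guess <- rc$y; T_guess <- rc$T
    }
    prev <- rc
    g <- g + dg
  }
  if (!length(rows))
    return(data.frame(gCANTot = numeric(0), period = numeric(0),
                      V_anchor = numeric(0), mult1 = numeric(0),
                      converged = logical(0)))
  do.call(rbind, rows)
}

#' Classify how the cycle branch terminates
#'
#' SNIC when the blow-up parameter coincides with a fold of equilibria
#' (within `tol`); homoclinic (HC) when the period diverges away from any
#' fold, i.e. onto a middle-branch saddle.
#'
#' @param g_term termination parameter from [find_cycle_boundary()].
#' @param folds fold table from [find_folds()].
#' @param tol coincidence tolerance in `gCANTot` (default 1e-3).
#' @return List: `type` ("snic" or "hc"), `gCANTot`, `dg_fold` (distance to
#'   the nearest fold), `fold_label`.
#' @export
classify_cycle_termination <- function(g_term, folds, tol = 1e-3) {
  if (!nrow(folds))
    return(list(type = "hc", gCANTot = g_term, dg_fold = Inf,
                fold_label = NA_character_))
  d <- abs(folds$gCANTot - g_term)
  i <- which.min(d)
  list(type = if (d[i] < tol) "snic" else "hc", gCANTot = g_term,
       dg_fold = d[i], fold_label = folds$label[i])
}

#' One-parameter fast-slow bifurcation diagram
#'
#' Assembles the full one-parameter picture at frozen `h`: the closed-form
#' equilibrium curve with stability, folds F1/F2, the subcritical Hopf
#' point, the stable cycle branch with its LPC endpoint (toward high
#' `gCANTot`) and its HC or SNIC termination (toward low `gCANTot`).
#'
#' @param p `prebotc_params`.
#' @param h_frozen frozen slow gate value (typically [average_h()] of the
#'   matched full simulation).
#' @param V_grid voltage grid for the equilibrium curve.
#' @param n_branch points on the cycle-branch grid.
#' @param period_max blow-up period (ms).
#' @param g_margin fraction of the subH-to-fold span probed beyond subH for
#'   the LPC search.
#' @param boundary_tol bisection tolerance for the LPC and termination
#'   parameters.
#' @return An object of class `prebotc_fsdiag`: list with `equilibria`,
#'   `folds`, `hopf`, `cycles`, `lpc`, `termination`.
#' @export
fastslow_diagram <- function(p, h_frozen, V_grid = seq(-72, 15, by = 0.05),
                             n_branch = 40, period_max = 2e4,
                             g_margin = 0.5, boundary_tol = 1e-4) {
  eq <- equilibrium_curve(p, h_frozen, V_grid)
  folds <- find_folds(eq)
  hopf <- find_hopf(eq, probe = FALSE)
  if (!nrow(hopf)) stop("no Hopf point found on the equilibrium curve")
  hopf <- hopf[which.max(hopf$V), , drop = FALSE]  # upper-branch point
  g_h <- hopf$gCANTot
  fold_pos <- folds$gCANTot[folds$gCANTot > 0 & folds$gCANTot < 1.5 * g_h]
  # start inside the bistable window between the upper knee and subH
  g0 <- if (length(fold_pos)) (max(fold_pos) + g_h) / 2 else 0.8 * g_h
  br_dn <- cycle_branch(p, h_frozen, g0, 1e-4,
                        n_pts = n_branch, period_max = period_max)
  ok_dn <- which(br_dn$has_cycle)
  if (!length(ok_dn)) stop("no stable cycle found below the Hopf point")
  i_last <- ok_dn[length(ok_dn)]
  if (i_last == nrow(br_dn)) {
    # branch survives to (numerically) zero conductance: no termination
    term <- list(type = "none", gCANTot = NA_real_, dg_fold = NA_real_,
                 fold_label = NA_character_, period_last = NA_real_)
  } else {
    g_ok <- br_dn$gCANTot[i_last]
    g_bad <- br_dn$gCANTot[i_last + 1]
    term_b <- find_cycle_boundary(p, h_frozen, g_ok, g_bad,
                                  attr(br_dn, "y_last"), tol = boundary_tol,
                                  period_max = period_max)
    term <- classify_cycle_termination(term_b$g_boundary, folds)
    if (term_b$g_boundary < 10 * boundary_tol) term$type <- "none"
    term$period_last <- term_b$period_last
  }
  # upward: find where the stable cycle is lost (LPC)
  fp0 <- fast_params(p, h_frozen, g0)
  m0 <- measure_cycle(fp0, c(V = -30, n = 0.1, phi = -10))
  g_hi <- g_h * (1 + g_margin)
  br_up <- cycle_branch(p, h_frozen, g0, g_hi, n_pts = n_branch,
                        period_max = period_max, y0 = m0$y_end)
  ok_up <- which(br_up$has_cycle)
  i_up <- ok_up[length(ok_up)]
  lpc <- NULL
  if (i_up < nrow(br_up)) {
    lpc_b <- find_cycle_boundary(p, h_frozen, br_up$gCANTot[i_up],
                                 br_up$gCANTot[i_up + 1],
                                 attr(br_up, "y_last"), tol = boundary_tol,
                                 period_max = period_max)
    lpc <- list(gCANTot = lpc_b$g_boundary, period = lpc_b$period_last)
  }
  cycles <- rbind(br_up[rev(seq_len(nrow(br_up))), ], br_dn[-1, ])
  cycles <- cycles[cycles$has_cycle, , drop = FALSE]
  structure(list(equilibria = eq, folds = folds, hopf = hopf,
                 cycles = cycles, lpc = lpc, termination = term,
                 h_frozen = h_frozen, params = p),
            class = "prebotc_fsdiag")
}

#' @export
print.prebotc_fsdiag <- function(x, ...) {
  cat("<prebotc_fsdiag> h =", x$h_frozen, "\n")
  if (nrow(x$folds))
    cat("  folds:", paste(sprintf("%s at g=%.5f", x$folds$label,
                                  x$folds$gCANTot), collapse = ", "), "\n")
  cat("  subH at g =", signif(x$hopf$gCANTot, 5), " V =",
      signif(x$hopf$V, 5), "\n")
  if (!is.null(x$lpc))
    cat("  LPC at g =", signif(x$lpc$gCANTot, 5), "\n")
  cat("  cycle termination:", x$termination$type, "at g =",
      signif(x$termination$gCANTot, 5), "(nearest fold",
      x$termination$fold_label, "dg =", signif(x$termination$dg_fold, 3),
      ")\n")
  invisible(x)
}

#' Burst-type label from diagram and trajectory
#'
#' Combines the fast-subsystem diagram with the full-system attractor:
#' when the resting phase sits on the lower branch (low-potential
#' quiescence), the hysteresis loop engages the fold, and the spiking
#' phase ends at the branch termination (homoclinic or SNIC); when the
#' low-potential rest is gone, rest is lost at the subcritical Hopf and
#' spiking at the fold of limit cycles.
#'
#' @param diag `prebotc_fsdiag`.
#' @param traj matched full-system `prebotc_traj`.
#' @param ... classification settings passed to [classify_pattern()].
#' @return Burst-type string, e.g.
#'   `"subHopf/homoclinic via fold/homoclinic"`, or `"not bursting"`.
#' @export
label_bursting <- function(diag, traj, ...) {
  pat <- classify_pattern(traj, ...)
  if (pat == "quiescent") return("not bursting")
  if (pat == "continuous_spiking") {
    # the slow loop may still shuttle across subH and LPC even when the
    # spiking never pauses (slow-passage bursting without quiescence)
    proj <- project_trajectory(traj, diag$params)
    engaged <- min(proj$gCANTot) < diag$hopf$gCANTot &&
      !is.null(diag$lpc) && max(proj$gCANTot) > diag$lpc$gCANTot
    if (!engaged) return("not bursting")
    return("subHopf/fold cycle")
  }
  rest_fold <- pat == "bursting_low_quiescence" &&
    any(diag$folds$gCANTot > 0)
  if (rest_fold) {
    if (diag$termination$type == "hc")
      "subHopf/homoclinic via fold/homoclinic"
    else
      "subHopf/fold cycle via fold/circle"
  } else {
    "subHopf/fold cycle"
  }
}
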