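# One-parameter bifurcation analysis of the fast subsystem in gCANTot at
# frozen h: closed-form equilibrium curve, folds, subcritical Hopf, cycle
# branch with LPC and HC/SNIC termination, and burst-type labeling.

# closed-form equilibrium parametrization: at a fast-subsystem equilibrium
# n = n_inf(V), phi = V/k2, and gCANTot balances the voltage equation
.gcan_of_V <- function(V, p, h_frozen) {
  n <- gating_inf(V, p$theta_n, p$sigma_n)
  INa <- p$gNa * gating_inf(V, p$theta_m, p$sigma_m)^3 * (1 - n) * (V - p$VNa)
  IK <- p$gK * n^4 * (V - p$VK)
  IL <- p$gL * (V - p$VL)
  INaP <- p$gNaP * gating_inf(V, p$theta_mp, p$sigma_mp) * h_frozen * (V - p$VNa)
  Iton <- p$gtonic_e * (V - p$Vsyn_e)
  rho <- memductance(V / p$k2, p$alpha, p$beta)
  (-INa - IK - IL - INaP - Iton + p$Iextz - p$k1 * V * rho) / (V - p$VNa)
}

.dgcan_dV <- function(V, p, h_frozen, dV = 1e-6) {
  (.gcan_of_V(V + dV, p, h_frozen) - .gcan_of_V(V - dV, p, h_frozen)) / (2 * dV)
}

.stability_class <- function(ev) {
  re <- Re(ev)
  cplx <- any(abs(Im(ev)) > 1e-9)
  if (cplx) {
    if (max(re) < 0) "stable_focus" else "unstable_focus"
  } else {
    if (max(re) < 0) "stable_node"
    else if (min(re) > 0) "unstable_node"
    else "saddle"
  }
}

#' Closed-form equilibrium curve of the fast subsystem
#'
#' At an equilibrium of the `(V, n, phi)` subsystem, `n = n_inf(V)` and
#' `phi = V / k2` exactly, and the effective CAN conductance balancing the
#' voltage equation is an explicit function of V.  The curve is therefore
#' parameterized by V; eigenvalues of the 3x3 Jacobian and the stability
#' class are attached per point, and branches (lower / middle / upper) are
#' split at the fold voltages.
#'
#' @param p `prebotc_params` (carries Iextz, k1, k2, alpha, beta).
#' @param h_frozen frozen slow gate value.
#' @param V_grid voltages (mV) sampled along the curve; must exclude `VNa`.
#' @return An object of class `prebotc_eqcurve`: data frame with columns
#'   `V, gCANTot, n, phi, re1, re2, re3, im1, im2, im3, class, branch` plus
#'   attributes `params`, `h_frozen`, `folds`.
#' @export
equilibrium_curve <- function(p, h_frozen,
                              V_grid = seq(-72, 15, by = 0.05)) {
  validate_params(p)
  stopifnot(all(abs(V_grid - p$VNa) > 1e-6))
  g <- .gcan_of_V(V_grid, p, h_frozen)
  n <- gating_inf(V_grid, p$theta_n, p$sigma_n)
  phi <- V_grid / p$k2
  ev <- matrix(NA_complex_, length(V_grid), 3)
  cls <- character(length(V_grid))
  for (i in seq_along(V_grid)) {
    fp <- fast_params(p, h_frozen, max(g[i], 0))
    fp$gCANTot <- g[i]  # allow negative part of the formal curve
    J <- fast_jacobian(c(V = V_grid[i], n = n[i], phi = phi[i]), fp)
    e <- eigen(J, only.values = TRUE)$values
    ev[i, ] <- e[order(-Re(e))]
    cls[i] <- .stability_class(e)
  }
  folds <- .fold_voltages(p, h_frozen, range(V_grid))
  branch <- rep("lower", length(V_grid))
  if (length(folds) >= 2) {
    vf <- sort(folds)
    branch[V_grid > vf[1] & V_grid <= vf[length(vf)]] <- "middle"
    branch[V_grid > vf[length(vf)]] <- "upper"
  } else if (length(folds) == 1) {
    branch[V_grid > folds] <- "upper"
  } else {
    branch <- rep("upper", length(V_grid))
  }
  df <- data.frame(V = V_grid, gCANTot = g, n = n, phi = phi,
                   re1 = Re(ev[, 1]), re2 = Re(ev[, 2]), re3 = Re(ev[, 3]),
                   im1 = Im(ev[, 1]), im2 = Im(ev[, 2]), im3 = Im(ev[, 3]),
                   class = cls, branch = branch)
  structure(df, params = p, h_frozen = h_frozen, folds = folds,
            class = c("prebotc_eqcurve", "data.frame"))
}

# fold voltages: roots of d gCANTot / dV
.fold_voltages <- function(p, h_frozen, V_range, grid_n = 4001) {
  vv <- seq(V_range[1], V_range[2], length.out = grid_n)
  d <- .dgcan_dV(vv, p, h_frozen)
  sc <- which(d[-1] * d[-length(d)] < 0)
  vapply(sc, function(i) {
    stats::uniroot(function(V) .dgcan_dV(V, p, h_frozen),
                   c(vv[i], vv[i + 1]), tol = 1e-12)$root
  }, numeric(1))
}

#' Fold bifurcations of the equilibrium curve
#'
#' Folds are roots of `d gCANTot / dV` of the closed-form curve; at each,
#' one real eigenvalue of the Jacobian is (numerically) zero.  `F1` labels
#' the knee at the top of the lower branch (largest `gCANTot`), `F2` the
#' knee at the bottom of the middle branch.
#'
#' @param curve `prebotc_eqcurve`.
#' @return Data frame with columns `type, label, gCANTot, V, lambda_min`
#'   (`lambda_min` = smallest-magnitude eigenvalue at the fold); empty when
#'   the curve has no fold.
#' @export
find_folds <- function(curve) {
  p <- attr(curve, "params"); h <- attr(curve, "h_frozen")
  vf <- attr(curve, "folds")
  if (!length(vf))
    return(data.frame(type = character(0), label = character(0),
                      gCANTot = numeric(0), V = numeric(0),
                      lambda_min = numeric(0)))
  g <- .gcan_of_V(vf, p, h)
  lam <- vapply(seq_along(vf), function(i) {
    fp <- fast_params(p, h, max(g[i], 0)); fp$gCANTot <- g[i]
    st <- c(V = vf[i], n = gating_inf(vf[i], p$theta_n, p$sigma_n),
            phi = vf[i] / p$k2)
    ev <- eigen(fast_jacobian(st, fp), only.values = TRUE)$values
    min(abs(ev))
  }, numeric(1))
  out <- data.frame(type = "fold", label = paste0("F", rank(-g)),
                    gCANTot = g, V = vf, lambda_min = lam)
  out[order(out$label), , drop = FALSE]
}

#' Hopf bifurcations along the equilibrium curve
#'
#' Scans the V-parameterized curve for sign changes of the real part of the
#' complex eigenvalue pair and refines each crossing by root-finding; the
#' criticality is probed by integrating a small perturbation of the
#' equilibrium just on the unstable-focus side (growth beyond the linear
#' regime without settling onto a nearby small cycle indicates a
#' subcritical Hopf).
#'
#' @param curve `prebotc_eqcurve`.
#' @param probe logical; run the criticality probe (default TRUE).
#' @return Data frame with columns
#'   `type, gCANTot, V, re, im, criticality`; empty if no crossing.
#' @export
find_hopf <- function(curve, probe = TRUE) {
  p <- attr(curve, "params"); h <- attr(curve, "h_frozen")
  pair_re <- function(V) {
    g <- .gcan_of_V(V, p, h)
    fp <- fast_params(p, h, max(g, 0)); fp$gCANTot <- g
    st <- c(V = V, n = gating_inf(V, p$theta_n, p$sigma_n), phi = V / p$k2)
    ev <- eigen(fast_jacobian(st, fp), only.values = TRUE)$values
    cp <- ev[abs(Im(ev)) > 1e-9]
    if (!length(cp)) return(NA_real_)
    max(Re(cp))
  }
  vv <- curve$V
  re <- ifelse(abs(curve$im1) + abs(curve$im2) + abs(curve$im3) > 1e-9,
               pmax(ifelse(abs(curve$im1) > 1e-9, curve$re1, -Inf),
                    ifelse(abs(curve$im2) > 1e-9, curve$re2, -Inf),
                    ifelse(abs(curve$im3) > 1e-9, curve$re3, -Inf)),
               NA_real_)
  idx <- which(!is.na(re[-1]) & !is.na(re[-length(re)]) &
                 re[-1] * re[-length(re)] < 0)
  if (!length(idx))
    return(data.frame(type = character(0), gCANTot = numeric(0),
                      V = numeric(0), re = numeric(0), im = numeric(0),
                      criticality = character(0)))
  out <- lapply(idx, function(i) {
    r <- stats::uniroot(pair_re, c(vv[i], vv[i + 1]), tol = 1e-12)
    V <- r$root
    g <- .gcan_of_V(V, p, h)
    fp <- fast_params(p, h, max(g, 0)); fp$gCANTot <- g
    st <- c(V = V, n = gating_inf(V, p$theta_n, p$sigma_n), phi = V / p$k2)
    ev <- eigen(fast_jacobian(st, fp), only.values = TRUE)$values
    cp <- ev[abs(Im(ev)) > 1e-9]
    crit <- NA_character_
    if (probe) crit <- .hopf_criticality(p, h, V, g, st, Im(cp[1]))
    data.frame(type = "hopf", gCANTot = g, V = V, re = max(Re(cp)),
               im = abs(Im(cp[1])), criticality = crit)
  })
  do.call(rbind, out)
}

# probe: slightly on the unstable-focus side, kick the equilibrium by a tiny
# amount; subcritical -> the oscillation escapes the linear neighbourhood
.hopf_criticality <- function(p, h, V_hopf, g_hopf, st, omega) {
  # move a little along the branch toward the unstable side
  for (sgn in c(-1, 1)) {
    V <- V_hopf + sgn * 0.1
    g <- .gcan_of_V(V, p, h)
    fp <- fast_params(p, h, max(g, 0)); fp$gCANTot <- g
    eqst <- c(V = V, n = gating_inf(V, p$theta_n, p$sigma_n), phi = V / p$k2)
    ev <- eigen(fast_jacobian(eqst, fp), only.values = TRUE)$values
    cp <- ev[abs(Im(ev)) > 1e-9]
    if (length(cp) && max(Re(cp)) > 0) {
      # growth time from the linear rate, then watch whether the
      # oscillation saturates at small amplitude (supercritical) or
      # escapes the neighbourhood (subcritical)
      T <- 2 * pi / abs(omega)
      t_lin <- min(log(1e4) / max(Re(cp)), 5e4)
      y0 <- eqst + c(0.01, 0, 0)
      tr <- simulate_fast(fp, initial = y0, t_end = max(3 * t_lin, 50 * T),
                          dt_out = T / 40, rtol = 1e-10, atol = 1e-12)
      # subcritical: the orbit leaves the focus neighbourhood entirely
      # (no small saturated cycle near the equilibrium)
      dev <- max(abs(tr$V - eqst[["V"]]))
      return(if (dev > 10) "subcritical" else "supercritical")
    }
  }
  NA_character_
}

#' Pseudo-arclength continuation of fast-subsystem equilibria
#'
#' General predictor-corrector path following of
#' `fast_rhs(V, n, phi; gCANTot) = 0` in `(V, n, phi, gCANTot)`, used to
#' cross-validate the closed-form parametrization of
#' [equilibrium_curve()].
#'
#' @param p `prebotc_params`.
#' @param h_frozen frozen slow gate.
#' @param V_start starting voltage (converted to an exact equilibrium via
#'   the closed form).
#' @param ds initial arclength step.
#' @param n_steps maximum number of steps.
#' @param V_bounds stop when V exits this interval.
#' @return Data frame with columns `V, n, phi, gCANTot`.
#' @export
continue_equilibria <- function(p, h_frozen, V_start = -65, ds = 0.25,
                                n_steps = 2000, V_bounds = c(-72, 15)) {
  validate_params(p)
  mkF <- function(u) {
    fp <- fast_params(p, h_frozen, max(u[4], 0)); fp$gCANTot <- u[4]
    fast_rhs(c(V = u[1], n = u[2], phi = u[3]), fp)
  }
  jac4 <- function(u) {
    J <- matrix(0, 3, 4)
    for (i in 1:4) {
      hstep <- 1e-7 * (1 + abs(u[i]))
      up <- u; um <- u
      up[i] <- u[i] + hstep; um[i] <- u[i] - hstep
      J[, i] <- (mkF(up) - mkF(um)) / (2 * hstep)
    }
    J
  }
  u <- c(V_start, gating_inf(V_start, p$theta_n, p$sigma_n),
         V_start / p$k2, .gcan_of_V(V_start, p, h_frozen))
  tang <- c(0, 0, 0, 1)
  path <- matrix(NA_real_, n_steps + 1, 4)
  path[1, ] <- u
  nkept <- 1
  step <- ds
  k <- 1
  while (k <= n_steps) {
    J <- jac4(u)
    # tangent: null vector of J, oriented along previous tangent
    tt <- svd(J, nu = 0, nv = 4)$v[, 4]
    if (sum(tt * tang) < 0) tt <- -tt
    tang <- tt
    upred <- u + step * tang
    unew <- upred
    ok <- FALSE
    for (it in 1:12) {
      Fv <- mkF(unew)
      res <- c(Fv, sum(tang * (unew - upred)))
      if (max(abs(res)) < 1e-11) { ok <- TRUE; break }
      A <- rbind(jac4(unew), tang)
      dnew <- tryCatch(solve(A, -res), error = function(e) NULL)
      if (is.null(dnew)) break
      unew <- unew + dnew
    }
    if (!ok) {
      step <- step / 2
      if (step < ds / 64) break
      next
    }
    u <- unew
    nkept <- nkept + 1
    path[nkept, ] <- u
    if (u[1] < V_bounds[1] || u[1] > V_bounds[2]) break
    step <- min(step * 1.3, ds)
    k <- k + 1
  }
  out <- as.data.frame(path[seq_len(nkept), , drop = FALSE])
  names(out) <- c("V", "n", "phi", "gCANTot")
  out
}
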