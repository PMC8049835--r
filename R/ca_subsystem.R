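# Analysis of the independent (Ca, l) slow / super-slow subsystem:
# nullclines, relaxation orbit, the gCANTot <-> [Ca] map, and the
# IP3 activity window.

#' Map effective CAN conductance to calcium and back
#'
#' Exact mutual inverses through the Hill activation:
#' `gCANTot = gCAN / (1 + (K_CAN/[Ca])^n_CAN)` and
#' `[Ca] = K_CAN / (gCAN/gCANTot - 1)^(1/n_CAN)`.
#'
#' @param gCANTot effective conductance (nS), in `(0, gCAN)`.
#' @param Ca calcium (uM), positive.
#' @param p `prebotc_params`.
#' @return The mapped value.
#' @export
gcan_to_ca <- function(gCANTot, p) {
  if (any(gCANTot <= 0) || any(gCANTot >= p$gCAN))
    stop("gCANTot must lie strictly between 0 and gCAN")
  p$K_CAN / (p$gCAN / gCANTot - 1)^(1 / p$n_CAN)
}

#' @rdname gcan_to_ca
#' @export
ca_to_gcan <- function(Ca, p) {
  p$gCAN * f_can(Ca, p$K_CAN, p$n_CAN)
}

#' Nullclines of the calcium subsystem
#'
#' The l-nullcline is analytic: `l = K_d / (K_d + [Ca])`.  The
#' [Ca]-nullcline solves `d[Ca]/dt = 0` for `l` at each sampled calcium:
#' `(G l)^3 = (J_out/([Ca]_ER - [Ca]) - L_IP3) / P_IP3`, defined where the
#' right side is non-negative and the ER gradient positive; gaps are
#' recorded as NA.  Knees of the [Ca]-nullcline (extrema of `l([Ca])`) are
#' reported.
#'
#' @param p `prebotc_params`.
#' @param Ca_range calcium interval (uM).
#' @param grid_n sample count.
#' @return List with data frames `ca_nullcline` (Ca, l), `l_nullcline`
#'   (Ca, l), and `knees` (Ca, l at the sign changes of dl/dCa).
#' @export
ca_nullclines <- function(p, Ca_range = c(0.005, 1.2), grid_n = 2000) {
  Ca <- seq(Ca_range[1], Ca_range[2], length.out = grid_n)
  G <- p$IP3 * Ca / ((p$IP3 + p$K_I) * (Ca + p$K_a))
  CaER <- (p$Ca_Tot - Ca) / p$sigma
  Jout <- p$V_SERCA * Ca^2 / (p$K_SERCA^2 + Ca^2)
  rhs <- (Jout / (CaER - Ca) - p$L_IP3) / p$P_IP3
  l <- ifelse(CaER > Ca & rhs >= 0, rhs^(1 / 3) / G, NA_real_)
  dl <- diff(l) / diff(Ca)
  kn <- which(!is.na(dl[-1]) & !is.na(dl[-length(dl)]) &
                dl[-1] * dl[-length(dl)] < 0) + 1
  list(ca_nullcline = data.frame(Ca = Ca, l = l),
       l_nullcline = data.frame(Ca = Ca, l = p$K_d / (p$K_d + Ca)),
       knees = data.frame(Ca = Ca[kn], l = l[kn]))
}

#' Converged relaxation orbit of the calcium subsystem
#'
#' Integrates the standalone `([Ca], l)` subsystem to its attracting
#' relaxation oscillation, measures the period from calcium peaks, and
#' extracts one cycle.  Marker `P1` is the jump-up point (maximum of
#' `d[Ca]/dt`); marker `P2` is the downward crossing of `Ca = Ca_SNIC`
#' when a SNIC calcium level is supplied.
#'
#' @param p `prebotc_params` (must be in the oscillatory IP3 window).
#' @param initial initial (Ca, l).
#' @param t_end integration span (ms).
#' @param Ca_SNIC optional calcium level of the fast-subsystem SNIC.
#' @param period_rtol relative agreement required between the last two
#'   periods.
#' @return An object of class `prebotc_caorbit`: list with `orbit` (t, Ca,
#'   l over one period, time zeroed at a calcium peak), `period` (ms),
#'   `P1`, `P2` (rows of the orbit or NULL).
#' @export
ca_orbit <- function(p, initial = c(Ca = 0.03, l = 0.93), t_end = 200000,
                     Ca_SNIC = NULL, period_rtol = 1e-3) {
  tr <- simulate_ca(p, initial = initial, t_end = t_end, dt_out = 0.5)
  v <- tr$Ca
  pk <- which(diff(sign(diff(v))) == -2) + 1
  pk <- pk[v[pk] > mean(range(v))]
  if (length(pk) < 3)
    stop("calcium subsystem is not oscillating at these parameters; ",
         "final state Ca = ", signif(v[length(v)], 4))
  tpk <- tr$t[pk]
  pers <- diff(tpk)
  last2 <- utils::tail(pers, 2)
  if (abs(diff(last2)) / mean(last2) > period_rtol)
    warning("orbit period not converged to ", period_rtol,
            " relative tolerance")
  period <- last2[2]
  sel <- tr$t >= tpk[length(tpk) - 1] & tr$t <= tpk[length(tpk)]
  orbit <- data.frame(t = tr$t[sel] - tpk[length(tpk) - 1],
                      Ca = tr$Ca[sel], l = tr$l[sel])
  dca <- diff(orbit$Ca) / diff(orbit$t)
  # jump-up: steepest calcium rise (just after leaving the left knee)
  P1 <- orbit[which.max(c(dca, -Inf)), ]
  P2 <- NULL
  if (!is.null(Ca_SNIC)) {
    s <- orbit$Ca - Ca_SNIC
    dn <- which(s[-length(s)] > 0 & s[-1] <= 0)
    if (length(dn)) P2 <- orbit[dn[1] + 1, ]
  }
  structure(list(orbit = orbit, period = period, P1 = P1, P2 = P2),
            class = "prebotc_caorbit")
}

#' @export
print.prebotc_caorbit <- function(x, ...) {
  cat("<prebotc_caorbit> period =", signif(x$period, 6), "ms, Ca in [",
      signif(min(x$orbit$Ca), 4), ",", signif(max(x$orbit$Ca), 4), "] uM\n")
  invisible(x)
}

#' Scan the IP3 window of calcium oscillation
#'
#' Flags each IP3 concentration as oscillatory or steady.  The detector
#' requires a sustained peak-to-peak calcium amplitude above `amp_min`
#' over the trailing half of the run.
#'
#' @param p base `prebotc_params`.
#' @param ip3_values IP3 grid (uM), at least 3 values.
#' @param t_end run length (ms) per point.
#' @param amp_min amplitude criterion (uM).
#' @return Data frame `IP3, oscillating, amplitude`.
#' @export
ip3_activity_scan <- function(p, ip3_values, t_end = 200000,
                              amp_min = 0.005) {
  stopifnot(length(ip3_values) >= 3)
  res <- lapply(ip3_values, function(ip3) {
    pp <- p
    pp$IP3 <- ip3
    tr <- simulate_ca(pp, t_end = t_end, dt_out = 2)
    tail_half <- tr[tr$t >= t_end / 2, ]
    amp <- diff(range(tail_half$Ca))
    data.frame(IP3 = ip3, oscillating = amp > amp_min, amplitude = amp)
  })
  do.call(rbind, res)
}
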