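# Nondimensionalization: scale constants, rate coefficients, and the
# fast / slow / super-slow classification of the six variables.

#' Maximal gate rate over a voltage range
#'
#' `T_x = max over V of 1 / tau_x(V)` for gate `x` on `V_range`, computed on
#' a uniform grid and refined by local optimization.
#'
#' @param p `prebotc_params`.
#' @param gate `"n"` or `"h"`.
#' @param V_range voltage interval (mV); the physiological default is
#'   \[-60, 0\].
#' @param grid_n number of grid points (>= 2).
#' @return Maximal rate in 1/ms.
#' @export
gate_rate_max <- function(p, gate = c("n", "h"), V_range = c(-60, 0),
                          grid_n = 2001) {
  gate <- match.arg(gate)
  stopifnot(grid_n >= 2, length(V_range) == 2, V_range[1] < V_range[2])
  tb <- if (gate == "n") p$tau_n else p$tau_h
  th <- if (gate == "n") p$theta_n else p$theta_h
  sl <- if (gate == "n") p$sigma_n else p$sigma_h
  f <- function(V) 1 / tau_gate(V, tb, th, sl)
  vv <- seq(V_range[1], V_range[2], length.out = grid_n)
  i <- which.max(f(vv))
  lo <- vv[max(i - 1, 1)]; hi <- vv[min(i + 1, grid_n)]
  if (lo == hi) return(f(lo))
  opt <- stats::optimize(f, c(lo, hi), maximum = TRUE)
  max(opt$objective, f(vv[i]))
}

#' Maximal cubed IP3-receptor gain G_c
#'
#' `G([Ca]) = [IP3][Ca] / (([IP3]+K_I)([Ca]+K_a))` is increasing in calcium,
#' so the maximum of `G^3` on a range is attained at the right endpoint; a
#' dense grid confirms this.
#'
#' @param p `prebotc_params`.
#' @param Ca_range calcium interval (uM); default \[0, 1\].
#' @param grid_n grid points used for the brute-force check.
#' @return Maximum of `G^3` (dimensionless).
#' @export
compute_Gc <- function(p, Ca_range = c(0, 1), grid_n = 10001) {
  G <- function(Ca) p$IP3 * Ca / ((p$IP3 + p$K_I) * (Ca + p$K_a))
  cc <- seq(Ca_range[1], Ca_range[2], length.out = grid_n)
  max(G(cc)^3)
}

#' Maximal SERCA rate coefficient G_S
#'
#' Writing the SERCA efflux as `g_SERCA([Ca]) * [Ca]` with
#' `g_SERCA = V_SERCA [Ca] / (K_SERCA^2 + [Ca]^2)`, the scale `G_S` is the
#' maximum of `g_SERCA` on the range, attained at `[Ca] = K_SERCA` where it
#' equals `V_SERCA / (2 K_SERCA)`.
#'
#' @param p `prebotc_params`.
#' @param Ca_range calcium interval (uM); default \[0, 1\].
#' @param grid_n grid points.
#' @return Maximal rate (pL/ms under the model's printed convention).
#' @export
compute_Gs <- function(p, Ca_range = c(0, 1), grid_n = 10001) {
  g <- function(Ca) p$V_SERCA * Ca / (p$K_SERCA^2 + Ca^2)
  cc <- seq(Ca_range[1], Ca_range[2], length.out = grid_n)
  i <- which.max(g(cc))
  lo <- cc[max(i - 1, 1)]; hi <- cc[min(i + 1, grid_n)]
  opt <- stats::optimize(g, c(lo, hi), maximum = TRUE)
  max(opt$objective, g(cc[i]))
}

#' ER flux scale P_max
#'
#' `P_max = max(L_IP3, P_IP3 * G_c, G_S)`.
#'
#' @param p `prebotc_params`.
#' @param Gc maximum of `G^3` (see [compute_Gc()]).
#' @param Gs maximal SERCA rate (see [compute_Gs()]).
#' @return Flux scale (pL/ms).
#' @export
compute_Pmax <- function(p, Gc, Gs) {
  stopifnot(Gc >= 0, Gs >= 0)
  max(p$L_IP3, p$P_IP3 * Gc, Gs)
}

#' Order-of-magnitude class of a rate coefficient
#'
#' Maps `R` (ms) to its nearest-integer decade `n = round(log10(R))`
#' (half-away-from-zero) and then to the three-way verdict: `n <= 0` fast,
#' `n == 1` slow, `n >= 2` super-slow.
#'
#' @param R positive rate coefficient (ms); vectorized.
#' @return Character vector of classes.
#' @export
timescale_class <- function(R) {
  stopifnot(all(R > 0))
  lg <- log10(R)
  n <- sign(lg) * floor(abs(lg) + 0.5)  # round half away from zero
  ifelse(n <= 0, "fast", ifelse(n == 1, "slow", "superslow"))
}

#' Nondimensionalization report
#'
#' Computes the scale constants and the six rate coefficients of the
#' rescaled system:
#' `R_v = C / (Q_t g_max)`, `R_n = 1 / (Q_t T_n)`, `R_h = 1 / (Q_t T_h)`,
#' `R_phi = 1 / Q_t`, `R_c = sigma / (Q_t P_max K_Ca)`,
#' `R_l = 1 / (Q_t Q_c A)`, and classifies each variable by nearest-integer
#' decade.  Two conventions are carried side by side: `computed` uses the
#' gate-rate maxima and flux scales evaluated from the model functions;
#' `printed` uses the published reference constants
#' (`T_n = 1.3`, `T_h = 0.0025` per ms, `G_S = 1000`, `G_c` rounded to two
#' decimals) so that the published arithmetic is reproduced exactly.  The
#' default report (`$R`, `$classification`) follows the printed convention;
#' both sets are stored.
#'
#' @param p `prebotc_params`.
#' @param Qv,Qphi,Qc,Qt voltage, flux, calcium, and time scales; defaults
#'   100 mV, 100 mV, 1 uM, 1 ms.
#' @param convention `"printed"` (default) or `"computed"`; selects which
#'   constants feed `$R` and `$classification`.
#' @param gmax normalizer `max(g_Na, ..., I_extz, k1)` taken over the whole
#'   stimulation range studied; defaults to 50, the top of the explored
#'   current range, which dominates every conductance.
#' @return An object of class `prebotc_timescales`.
#' @export
timescale_report <- function(p = botc_params(), Qv = 100, Qphi = 100,
                             Qc = 1, Qt = 1,
                             convention = c("printed", "computed"),
                             gmax = 50) {
  convention <- match.arg(convention)
  validate_params(p)
  gmax <- max(p$gNa, p$gK, p$gL, p$gNaP, p$gtonic_e, p$gCAN, p$Iextz, p$k1,
              gmax)
  Tn_c <- gate_rate_max(p, "n")
  Th_c <- gate_rate_max(p, "h")
  Gc_c <- compute_Gc(p)
  Gs_c <- compute_Gs(p)
  printed <- list(Tn = 1.3, Th = 0.0025, Gc = round(Gc_c, 2), Gs = 1000)
  computed <- list(Tn = Tn_c, Th = Th_c, Gc = Gc_c, Gs = Gs_c)
  use <- if (convention == "printed") printed else computed
  Pmax <- compute_Pmax(p, use$Gc, use$Gs)
  R <- c(v = p$C / (Qt * gmax),
         n = 1 / (Qt * use$Tn),
         h = 1 / (Qt * use$Th),
         phi = 1 / Qt,
         Ca = p$sigma / (Qt * Pmax * p$K_Ca),
         l = 1 / (Qt * Qc * p$A))
  if (any(!is.finite(R)))
    stop("zero denominator in a rate coefficient")
  structure(list(Qv = Qv, Qphi = Qphi, Qc = Qc, Qt = Qt, gmax = gmax,
                 convention = convention,
                 printed = printed, computed = computed, Pmax = Pmax,
                 R = R, classification = timescale_class(R)),
            class = "prebotc_timescales")
}

#' Variable classification from a timescale report
#'
#' @param report `prebotc_timescales`.
#' @return Named character vector mapping each variable to
#'   fast / slow / superslow.
#' @export
classify_variables <- function(report) {
  stopifnot(inherits(report, "prebotc_timescales"))
  report$classification
}

#' @export
print.prebotc_timescales <- function(x, ...) {
  cat("<prebotc_timescales> (", x$convention, " convention)\n", sep = "")
  cat("  scales: Qv =", x$Qv, "mV  Qphi =", x$Qphi, "mV  Qc =", x$Qc,
      "uM  Qt =", x$Qt, "ms  gmax =", x$gmax, "\n")
  cat("  Gc =", signif(x$printed$Gc, 4), "(computed",
      signif(x$computed$Gc, 4), ")  Gs =", x$printed$Gs,
      "(computed", signif(x$computed$Gs, 6), ")  Pmax =",
      signif(x$Pmax, 6), "\n")
  cat("  rate coefficients (ms):\n")
  for (v in names(x$R))
    cat(sprintf("    R_%-3s = %10.4g   %s\n", v, x$R[[v]],
                x$classification[[v]]))
  invisible(x)
}
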