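# Model parameters: single source of truth for every constant of the model.

# order of the flat parameter vector handed to the compiled derivatives;
# must match the enum in src/model.c
.par_order_full <- c(
  "C", "sigma", "gNa", "gK", "gL", "gNaP", "gtonic_e", "gCAN",
  "VNa", "VK", "VL", "Vsyn_e",
  "theta_m", "theta_mp", "theta_n", "theta_h",
  "sigma_m", "sigma_mp", "sigma_n", "sigma_h",
  "tau_n", "tau_h",
  "K_CAN", "n_CAN", "IP3", "L_IP3", "P_IP3", "K_I", "K_a", "K_d",
  "Ca_Tot", "K_Ca", "V_SERCA", "K_SERCA", "A",
  "Iextz", "k1", "k2", "alpha", "beta"
)

#' Model parameters for the memristive pre-BotC neuron
#'
#' Builds the full parameter set of the model: the Butera-type somatic
#' currents (fast Na, delayed-rectifier K, leak, persistent Na, tonic
#' excitatory drive), the calcium-activated nonspecific cation (CAN) current
#' with Hill-type calcium activation, the Park-Rubin IP3/ER calcium fluxes,
#' and the electromagnetic stimulation terms: a direct current `Iextz` and a
#' flux-controlled memristor feedback current `k1 * V * rho(phi)` with
#' memductance `rho(phi) = alpha + 3 * beta * phi^2`.
#'
#' Defaults are the published reference values of the model.  Conductances
#' are in nS, potentials in mV, times in ms, calcium concentrations in uM,
#' ER fluxes in pL/ms, and the printed numbers are used as given in the
#' model's own mutually consistent convention (the capacitance `C = 21`
#' divides the summed currents directly).
#'
#' @param ... named overrides of any default, e.g. `Iextz = 30, k1 = 0.1`.
#' @return An object of class `prebotc_params`: a named list of constants.
#' @examples
#' p <- botc_params(Iextz = 5, k1 = 0.1)
#' p$gNaP
#' @export
botc_params <- function(...) {
  p <- list(
    C = 21, sigma = 0.185,
    gNa = 10, gK = 4, gL = 2.8, gNaP = 2.8, gtonic_e = 0.3, gCAN = 0.7,
    VNa = 50, VK = -85, VL = -65, Vsyn_e = 0,
    theta_m = -34, theta_mp = -40, theta_n = -29, theta_h = -48,
    sigma_m = -5, sigma_mp = -6, sigma_n = -4, sigma_h = 6,
    tau_n = 10, tau_h = 10000,
    K_CAN = 0.74, n_CAN = 0.97, IP3 = 1.2,
    L_IP3 = 0.37, P_IP3 = 31000, K_I = 1.0, K_a = 0.4, K_d = 0.4,
    Ca_Tot = 1.25, K_Ca = 0.000025, V_SERCA = 400, K_SERCA = 0.2, A = 0.005,
    Iextz = 0, k1 = 0, k2 = 3, alpha = 1, beta = 0.00006
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  p <- structure(p, class = "prebotc_params")
  validate_params(p)
  p
}

#' Validate a parameter set
#'
#' Checks positivity/sign constraints: conductances and kinetic constants
#' non-negative, time constants positive, the cytosol/ER volume ratio in
#' (0, 1), and all entries finite scalars.
#'
#' @param p a `prebotc_params` object (or plain named list with the same
#'   fields).
#' @return `p`, invisibly classed as `prebotc_params`; errors on violation.
#' @export
validate_params <- function(p) {
  need <- .par_order_full
  miss <- setdiff(need, names(p))
  if (length(miss))
    stop("missing parameter(s): ", paste(miss, collapse = ", "))
  num <- vapply(p[need], function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num))
    stop("non-finite or non-scalar parameter(s): ",
         paste(need[!num], collapse = ", "))
  if (any(unlist(p[c("gNa", "gK", "gL", "gNaP", "gtonic_e", "gCAN")]) < 0))
    stop("conductances must be >= 0")
  if (p$tau_n <= 0 || p$tau_h <= 0) stop("tau_n and tau_h must be > 0")
  if (p$sigma <= 0 || p$sigma >= 1) stop("sigma must lie in (0, 1)")
  pos <- c("K_SERCA", "K_CAN", "K_I", "K_a", "K_d", "n_CAN")
  if (any(unlist(p[pos]) <= 0))
    stop(paste(pos, collapse = "/"), " must be > 0")
  if (p$sigma_m == 0 || p$sigma_mp == 0 || p$sigma_n == 0 || p$sigma_h == 0)
    stop("gating slopes must be nonzero")
  if (!inherits(p, "prebotc_params")) class(p) <- "prebotc_params"
  invisible(p)
}

# flat numeric vector in compiled-code order
.par_vec_full <- function(p) unlist(p[.par_order_full], use.names = FALSE)

#' Fast-subsystem parameters
#'
#' Freezes the super-slow gate `h` and replaces the CAN current by an
#' effective conductance `gCANTot = gCAN * f([Ca])`, turning the
#' three-dimensional `(V, n, phi)` electrical subsystem into a family
#' parameterized by `(h_frozen, gCANTot)`.
#'
#' @param p base `prebotc_params`.
#' @param h_frozen frozen value of the NaP inactivation gate, in \[0, 1\].
#' @param gCANTot effective CAN conductance (nS), `>= 0`.
#' @return An object of class `prebotc_fastpars`.
#' @export
fast_params <- function(p, h_frozen, gCANTot) {
  stopifnot(is.numeric(h_frozen), length(h_frozen) == 1,
            h_frozen >= 0, h_frozen <= 1,
            is.numeric(gCANTot), length(gCANTot) == 1, gCANTot >= 0)
  structure(list(base = validate_params(p), h_frozen = h_frozen,
                 gCANTot = gCANTot),
            class = "prebotc_fastpars")
}

.par_vec_fast <- function(fp) {
  c(.par_vec_full(fp$base), fp$h_frozen, fp$gCANTot)
}

#' @export
print.prebotc_params <- function(x, ...) {
  cat("<prebotc_params>\n")
  cat("  stimulation: Iextz =", x$Iextz, " k1 =", x$k1, " k2 =", x$k2,
      " alpha =", x$alpha, " beta =", x$beta, "\n")
  cat("  conductances (nS): gNa =", x$gNa, " gK =", x$gK, " gL =", x$gL,
      " gNaP =", x$gNaP, " gCAN =", x$gCAN, " gtonic_e =", x$gtonic_e, "\n")
  cat("  calcium: [IP3] =", x$IP3, "uM  Ca_Tot =", x$Ca_Tot,
      "uM  V_SERCA =", x$V_SERCA, "\n")
  invisible(x)
}

#' @export
print.prebotc_fastpars <- function(x, ...) {
  cat("<prebotc_fastpars> h_frozen =", x$h_frozen,
      " gCANTot =", x$gCANTot, "\n")
  invisible(x)
}
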