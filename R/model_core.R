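# Gating functions, currents, and vector fields (reference R implementation;
# the compiled versions in src/model.c are used for integration).

#' Steady-state gating sigmoid
#'
#' `x_inf(V) = 1 / (1 + exp((V - theta) / sigma_slope))`.  With a negative
#' slope this is an activation curve (increasing in V), with a positive
#' slope an inactivation curve.
#'
#' @param V membrane potential (mV); vectorized.
#' @param theta half-activation voltage (mV).
#' @param sigma_slope slope factor (mV), nonzero.
#' @return Gating fraction in (0, 1).
#' @export
gating_inf <- function(V, theta, sigma_slope) {
  if (any(sigma_slope == 0)) stop("sigma_slope must be nonzero")
  1 / (1 + exp((V - theta) / sigma_slope))
}

#' Voltage-dependent gate time constant
#'
#' `tau(V) = tau_max / cosh((V - theta) / (2 * sigma_slope))`; maximal at
#' `V = theta` and symmetric about it.
#'
#' @param V membrane potential (mV); vectorized.
#' @param tau_max maximal time constant (ms), positive.
#' @param theta half-activation voltage (mV).
#' @param sigma_slope slope factor (mV), nonzero.
#' @return Time constant in ms, in (0, tau_max].
#' @export
tau_gate <- function(V, tau_max, theta, sigma_slope) {
  if (any(sigma_slope == 0)) stop("sigma_slope must be nonzero")
  if (any(tau_max <= 0)) stop("tau_max must be > 0")
  tau_max / cosh((V - theta) / (2 * sigma_slope))
}

#' Calcium activation of the CAN current
#'
#' Hill function `f([Ca]) = 1 / (1 + (K_CAN / [Ca])^n_CAN)`, a monotonically
#' increasing concave function of calcium with midpoint at `[Ca] = K_CAN`.
#'
#' @param Ca cytosolic calcium (uM), positive; vectorized.
#' @param K_CAN half-activation concentration (uM).
#' @param n_CAN Hill exponent.
#' @return Activation fraction in (0, 1).
#' @export
f_can <- function(Ca, K_CAN, n_CAN) {
  if (any(Ca <= 0)) stop("Ca must be > 0")
  1 / (1 + (K_CAN / Ca)^n_CAN)
}

#' Memductance of the flux-controlled memristor
#'
#' `rho(phi) = alpha + 3 * beta * phi^2`; even in the flux, so the induced
#' current `k1 * V * rho(phi)` is invariant under `phi -> -phi`.
#'
#' @param phi magnetic flux (same numeric scale as V); vectorized.
#' @param alpha,beta memristor coefficients.
#' @return Memductance value.
#' @export
memductance <- function(phi, alpha, beta) {
  alpha + 3 * beta * phi^2
}

#' Full model state constructor
#'
#' @param V membrane potential (mV)
#' @param n delayed-rectifier K activation gate in \[0,1\]
#' @param h persistent-Na inactivation gate in \[0,1\]
#' @param phi magnetic flux
#' @param Ca cytosolic calcium (uM), positive
#' @param l fraction of non-inactivated IP3 channels in \[0,1\]
#' @return Named numeric vector of length 6.
#' @export
full_state <- function(V, n, h, phi, Ca, l) {
  s <- c(V = V, n = n, h = h, phi = phi, Ca = Ca, l = l)
  if (!all(is.finite(s))) stop("state must be finite")
  if (n < 0 || n > 1 || h < 0 || h > 1 || l < 0 || l > 1)
    stop("gates n, h, l must lie in [0, 1]")
  if (Ca <= 0) stop("Ca must be > 0")
  s
}

#' Membrane currents at a state
#'
#' Evaluates every current of the voltage equation: fast sodium
#' `INa = gNa * m_inf^3 * (1 - n) * (V - VNa)`, delayed-rectifier potassium
#' `IK = gK * n^4 * (V - VK)`, leak, persistent sodium
#' `INaP = gNaP * mp_inf * h * (V - VNa)`, CAN current
#' `ICAN = gCAN * f([Ca]) * (V - VNa)`, tonic drive, and the induced
#' (memristor) current `Iind = k1 * V * rho(phi)`.
#'
#' @param state named vector with components V, n, h, phi, Ca, l
#'   (see [full_state()]).
#' @param p `prebotc_params`.
#' @return Named numeric vector `INa, IK, IL, INaP, ICAN, Itonic_e, Iind`.
#' @export
membrane_currents <- function(state, p) {
  V <- state[["V"]]; n <- state[["n"]]; h <- state[["h"]]
  phi <- state[["phi"]]; Ca <- state[["Ca"]]
  c(INa = p$gNa * gating_inf(V, p$theta_m, p$sigma_m)^3 * (1 - n) * (V - p$VNa),
    IK = p$gK * n^4 * (V - p$VK),
    IL = p$gL * (V - p$VL),
    INaP = p$gNaP * gating_inf(V, p$theta_mp, p$sigma_mp) * h * (V - p$VNa),
    ICAN = p$gCAN * f_can(Ca, p$K_CAN, p$n_CAN) * (V - p$VNa),
    Itonic_e = p$gtonic_e * (V - p$Vsyn_e),
    Iind = p$k1 * V * memductance(phi, p$alpha, p$beta))
}

#' Time derivatives of the full six-dimensional system
#'
#' The electrical equations
#' `C dV/dt = -INa - IK - IL - INaP - Itonic_e - ICAN + Iextz - k1*V*rho(phi)`,
#' `dn/dt = (n_inf - n)/tau_n(V)`, `dh/dt = (h_inf - h)/tau_h(V)`,
#' `dphi/dt = V - k2*phi`, coupled one-way to the calcium subsystem
#' (see [ca_rhs()]).
#'
#' @param state named vector (V, n, h, phi, Ca, l).
#' @param p `prebotc_params`.
#' @return Named numeric vector of the six time derivatives (per ms).
#' @export
full_rhs <- function(state, p) {
  if (!all(is.finite(state))) stop("state must be finite")
  V <- state[["V"]]; n <- state[["n"]]; h <- state[["h"]]
  phi <- state[["phi"]]; Ca <- state[["Ca"]]; l <- state[["l"]]
  cur <- membrane_currents(state, p)
  dV <- (-cur[["INa"]] - cur[["IK"]] - cur[["IL"]] - cur[["INaP"]] -
           cur[["Itonic_e"]] - cur[["ICAN"]] + p$Iextz - cur[["Iind"]]) / p$C
  dn <- (gating_inf(V, p$theta_n, p$sigma_n) - n) /
    tau_gate(V, p$tau_n, p$theta_n, p$sigma_n)
  dh <- (gating_inf(V, p$theta_h, p$sigma_h) - h) /
    tau_gate(V, p$tau_h, p$theta_h, p$sigma_h)
  dphi <- V - p$k2 * phi
  dca <- ca_rhs(Ca, l, p)
  c(V = dV, n = dn, h = dh, phi = dphi, Ca = dca[["Ca"]], l = dca[["l"]])
}

#' Time derivatives of the three-dimensional fast subsystem
#'
#' The `(V, n, phi)` equations with the super-slow gate frozen at
#' `h_frozen` and the CAN current replaced by the effective conductance
#' `gCANTot`, i.e. `ICAN = gCANTot * (V - VNa)`.  Identical to the matching
#' components of [full_rhs()] when `gCANTot = gCAN * f([Ca])` and
#' `h = h_frozen`.
#'
#' @param state named vector (V, n, phi).
#' @param fp `prebotc_fastpars` from [fast_params()].
#' @return Named numeric vector (V, n, phi) of derivatives.
#' @export
fast_rhs <- function(state, fp) {
  p <- fp$base
  V <- state[["V"]]; n <- state[["n"]]; phi <- state[["phi"]]
  INa <- p$gNa * gating_inf(V, p$theta_m, p$sigma_m)^3 * (1 - n) * (V - p$VNa)
  IK <- p$gK * n^4 * (V - p$VK)
  IL <- p$gL * (V - p$VL)
  INaP <- p$gNaP * gating_inf(V, p$theta_mp, p$sigma_mp) * fp$h_frozen * (V - p$VNa)
  ICAN <- fp$gCANTot * (V - p$VNa)
  Iton <- p$gtonic_e * (V - p$Vsyn_e)
  dV <- (-INa - IK - IL - INaP - Iton - ICAN + p$Iextz -
           p$k1 * V * memductance(phi, p$alpha, p$beta)) / p$C
  dn <- (gating_inf(V, p$theta_n, p$sigma_n) - n) /
    tau_gate(V, p$tau_n, p$theta_n, p$sigma_n)
  dphi <- V - p$k2 * phi
  c(V = dV, n = dn, phi = dphi)
}

#' Time derivatives of the calcium subsystem
#'
#' The `([Ca], l)` equations: `d[Ca]/dt = K_Ca * (J_ER_IN - J_ER_OUT)` with
#' IP3-receptor influx
#' `J_ER_IN = (L_IP3 + P_IP3 * (G([Ca]) * l)^3) * ([Ca]_ER - [Ca])`,
#' `G = [IP3][Ca] / (([IP3]+K_I)([Ca]+K_a))`,
#' `[Ca]_ER = (Ca_Tot - [Ca]) / sigma`, SERCA efflux
#' `J_ER_OUT = V_SERCA [Ca]^2 / (K_SERCA^2 + [Ca]^2)`, and IP3-channel
#' de-inactivation `dl/dt = A*K_d*(1 - l) - A*[Ca]*l`.  Independent of the
#' electrical variables: the calcium subsystem drives the membrane (through
#' the CAN current) but receives no feedback.
#'
#' @param Ca cytosolic calcium (uM), positive.
#' @param l IP3-channel availability in \[0,1\].
#' @param p `prebotc_params`.
#' @return Named numeric vector (Ca, l) of derivatives.
#' @export
ca_rhs <- function(Ca, l, p) {
  G <- p$IP3 * Ca / ((p$IP3 + p$K_I) * (Ca + p$K_a))
  CaER <- (p$Ca_Tot - Ca) / p$sigma
  JIN <- (p$L_IP3 + p$P_IP3 * (G * l)^3) * (CaER - Ca)
  JOUT <- p$V_SERCA * Ca^2 / (p$K_SERCA^2 + Ca^2)
  c(Ca = p$K_Ca * (JIN - JOUT), l = p$A * p$K_d * (1 - l) - p$A * Ca * l)
}

#' Numerical Jacobian of a model vector field
#'
#' Central finite differences with step `1e-6 * (1 + |x_i|)` per coordinate.
#'
#' @param fun function of a single numeric state vector returning the
#'   derivative vector (same length).
#' @param x evaluation point (named or plain numeric).
#' @param step_scale relative step size (default `1e-6`).
#' @return Square Jacobian matrix.
#' @export
numeric_jacobian <- function(fun, x, step_scale = 1e-6) {
  m <- length(fun(x))
  J <- matrix(NA_real_, m, length(x))
  for (i in seq_along(x)) {
    hstep <- step_scale * (1 + abs(x[i]))
    xp <- x; xm <- x
    xp[i] <- x[i] + hstep
    xm[i] <- x[i] - hstep
    J[, i] <- (fun(xp) - fun(xm)) / (2 * hstep)
  }
  if (!all(is.finite(J))) stop("non-finite entries in numerical Jacobian")
  J
}

#' Jacobian of the fast subsystem
#'
#' Analytic 3x3 Jacobian of [fast_rhs()] at a point; cross-validated in the
#' test suite against [numeric_jacobian()].
#'
#' @param state named vector (V, n, phi).
#' @param fp `prebotc_fastpars`.
#' @return 3x3 matrix, rows/cols ordered (V, n, phi).
#' @export
fast_jacobian <- function(state, fp) {
  p <- fp$base
  V <- state[["V"]]; n <- state[["n"]]; phi <- state[["phi"]]

  minf <- gating_inf(V, p$theta_m, p$sigma_m)
  dminf <- -minf * (1 - minf) / p$sigma_m
  mpinf <- gating_inf(V, p$theta_mp, p$sigma_mp)
  dmpinf <- -mpinf * (1 - mpinf) / p$sigma_mp
  rho <- memductance(phi, p$alpha, p$beta)

  dINa_dV <- p$gNa * (1 - n) * (3 * minf^2 * dminf * (V - p$VNa) + minf^3)
  dINaP_dV <- p$gNaP * fp$h_frozen * (dmpinf * (V - p$VNa) + mpinf)
  dIK_dV <- p$gK * n^4
  dsum_dV <- dINa_dV + dIK_dV + p$gL + dINaP_dV + fp$gCANTot + p$gtonic_e +
    p$k1 * rho
  dV_dV <- -dsum_dV / p$C
  dV_dn <- (p$gNa * minf^3 * (V - p$VNa) - 4 * p$gK * n^3 * (V - p$VK)) / p$C
  dV_dphi <- -p$k1 * V * 6 * p$beta * phi / p$C

  ninf <- gating_inf(V, p$theta_n, p$sigma_n)
  dninf <- -ninf * (1 - ninf) / p$sigma_n
  taun <- tau_gate(V, p$tau_n, p$theta_n, p$sigma_n)
  # d/dV [ (ninf - n)/taun ] = dninf/taun + (ninf - n) * d(1/taun)/dV
  dinvtau <- sinh((V - p$theta_n) / (2 * p$sigma_n)) / (2 * p$sigma_n * p$tau_n)
  dn_dV <- dninf / taun + (ninf - n) * dinvtau
  dn_dn <- -1 / taun

  matrix(c(dV_dV, dV_dn, dV_dphi,
           dn_dV, dn_dn, 0,
           1, 0, -p$k2),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("V", "n", "phi"), c("V", "n", "phi")))
}
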