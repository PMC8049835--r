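# Stiff integration of the full system and its subsystems (deSolve, lsoda,
# compiled right-hand sides).

#' Simulation configuration
#'
#' @param params `prebotc_params`.
#' @param initial named initial state (V, n, h, phi, Ca, l).  The default
#'   lies in the basin of the bursting attractor; the transient discards the
#'   approach.
#' @param t_end total integrated model time (ms).
#' @param transient leading span (ms) discarded before analysis.
#' @param rtol,atol solver tolerances.
#' @param dt_out output sampling interval (ms) after the transient; 0.05 ms
#'   resolves spike peaks (about 20 samples per ms).
#' @param max_step optional cap on the internal solver step (ms).
#' @return An object of class `prebotc_simcfg`.
#' @export
sim_config <- function(params = botc_params(),
                       initial = c(V = -60, n = 0.01, h = 0.45, phi = -20,
                                   Ca = 0.03, l = 0.93),
                       t_end = 60000, transient = 20000,
                       rtol = 1e-8, atol = 1e-10,
                       dt_out = 0.05, max_step = NULL) {
  stopifnot(transient >= 0, t_end > transient, dt_out > 0)
  validate_params(params)
  stopifnot(setequal(names(initial), c("V", "n", "h", "phi", "Ca", "l")))
  structure(list(params = params,
                 initial = initial[c("V", "n", "h", "phi", "Ca", "l")],
                 t_end = t_end, transient = transient,
                 rtol = rtol, atol = atol, dt_out = dt_out,
                 max_step = max_step),
            class = "prebotc_simcfg")
}

.ode_ctrl <- function(cfg) {
  if (is.null(cfg$max_step)) list() else list(hmax = cfg$max_step)
}

.as_traj <- function(out, params, cfg) {
  df <- as.data.frame(out)
  names(df)[1] <- "t"
  structure(df, params = params, config = cfg, class = c("prebotc_traj",
                                                         class(df)))
}

#' Integrate the full six-dimensional system
#'
#' Adaptive stiff integration (lsoda with a compiled right-hand side).  The
#' transient span is integrated first and discarded; the returned trajectory
#' covers `[transient, t_end]` sampled every `dt_out` ms.
#'
#' @param cfg `prebotc_simcfg` from [sim_config()].
#' @return A `prebotc_traj`: data frame with columns
#'   `t, V, n, h, phi, Ca, l` and the configuration attached as attributes.
#' @examples
#' \donttest{
#' cfg <- sim_config(botc_params(), t_end = 26000, transient = 20000)
#' tr <- simulate_full(cfg)
#' range(tr$V)
#' }
#' @export
simulate_full <- function(cfg) {
  stopifnot(inherits(cfg, "prebotc_simcfg"))
  pv <- .par_vec_full(cfg$params)
  y0 <- cfg$initial
  if (cfg$transient > 0) {
    pre <- deSolve::ode(y = y0, times = seq(0, cfg$transient, length.out = 201),
                        func = "prebotc_deriv_full", parms = pv,
                        dllname = "prebotc", initfunc = "prebotc_init_full",
                        method = "lsoda", rtol = cfg$rtol, atol = cfg$atol,
                        maxsteps = 1e5)
    if (pre[nrow(pre), 1] < cfg$transient)
      stop("transient integration stopped early at t = ", pre[nrow(pre), 1])
    y0 <- pre[nrow(pre), -1]
  }
  times <- seq(0, cfg$t_end - cfg$transient, by = cfg$dt_out)
  args <- c(list(y = y0, times = times, func = "prebotc_deriv_full",
                 parms = pv, dllname = "prebotc",
                 initfunc = "prebotc_init_full", method = "lsoda",
                 rtol = cfg$rtol, atol = cfg$atol, maxsteps = 1e5),
            .ode_ctrl(cfg))
  out <- do.call(deSolve::ode, args)
  if (attr(out, "istate")[1] < 0 || out[nrow(out), 1] < times[length(times)])
    stop("full-system integration failed; last state: ",
         paste(signif(out[nrow(out), ], 6), collapse = ", "))
  out[, 1] <- out[, 1] + cfg$transient
  .as_traj(out, cfg$params, cfg)
}

#' Integrate the three-dimensional fast subsystem
#'
#' @param fp `prebotc_fastpars` from [fast_params()].
#' @param initial named initial state (V, n, phi).
#' @param t_end integration span (ms).
#' @param dt_out output sampling interval (ms).
#' @param rtol,atol solver tolerances.
#' @param transient leading span (ms) discarded.
#' @return A `prebotc_traj` with columns `t, V, n, phi`.
#' @export
simulate_fast <- function(fp, initial = c(V = -60, n = 0.1, phi = -20),
                          t_end = 2000, dt_out = 0.05,
                          rtol = 1e-8, atol = 1e-10, transient = 0) {
  stopifnot(inherits(fp, "prebotc_fastpars"))
  pv <- .par_vec_fast(fp)
  y0 <- initial[c("V", "n", "phi")]
  if (transient > 0) {
    pre <- deSolve::ode(y = y0, times = c(0, transient),
                        func = "prebotc_deriv_fast", parms = pv,
                        dllname = "prebotc", initfunc = "prebotc_init_fast",
                        method = "lsoda", rtol = rtol, atol = atol,
                      maxsteps = 1e5)
    y0 <- pre[nrow(pre), -1]
  }
  out <- deSolve::ode(y = y0, times = seq(0, t_end - transient, by = dt_out),
                      func = "prebotc_deriv_fast", parms = pv,
                      dllname = "prebotc", initfunc = "prebotc_init_fast",
                      method = "lsoda", rtol = rtol, atol = atol,
                      maxsteps = 1e5)
  if (attr(out, "istate")[1] < 0)
    stop("fast-subsystem integration failed; last state: ",
         paste(signif(out[nrow(out), ], 6), collapse = ", "))
  out[, 1] <- out[, 1] + transient
  .as_traj(out, fp, NULL)
}

#' Integrate the standalone calcium subsystem
#'
#' @param p `prebotc_params`.
#' @param initial named initial state (Ca, l).
#' @param t_end integration span (ms).
#' @param dt_out output sampling interval (ms); the subsystem is slow, so a
#'   coarse grid suffices.
#' @param rtol,atol solver tolerances.
#' @return A `prebotc_traj` with columns `t, Ca, l`.
#' @export
simulate_ca <- function(p, initial = c(Ca = 0.03, l = 0.93),
                        t_end = 200000, dt_out = 1,
                        rtol = 1e-10, atol = 1e-12) {
  validate_params(p)
  out <- deSolve::ode(y = initial[c("Ca", "l")],
                      times = seq(0, t_end, by = dt_out),
                      func = "prebotc_deriv_ca", parms = .par_vec_full(p),
                      dllname = "prebotc", initfunc = "prebotc_init_full",
                      method = "lsoda", rtol = rtol, atol = atol,
                      maxsteps = 1e5)
  .as_traj(out, p, NULL)
}

#' Burst-cycle-averaged value of the slow gate h
#'
#' Time-weighted (trapezoidal) mean of `h` over an integer number of burst
#' cycles.  Burst starts are detected from V spikes separated by inter-burst
#' gaps, and the averaging window is snapped to run from the first to the
#' last detected burst onset.  This average is the value at which `h` is
#' frozen in the fast-slow decomposition.
#'
#' @param traj full-system `prebotc_traj`.
#' @param gap_min minimal spike-free gap (ms) taken as a burst boundary.
#' @param quiescence_ceiling mV level separating the low-potential rest
#'   from the depolarized intra-burst passage; boundaries are preferentially
#'   placed after low-potential gaps so that one cycle spans one full burst.
#' @param threshold,min_prominence spike detection settings
#'   (see [detect_spikes()]).
#' @return Scalar mean of h.
#' @export
average_h <- function(traj, gap_min = 300, quiescence_ceiling = -35,
                      threshold = -35, min_prominence = 1) {
  stopifnot("h" %in% names(traj))
  train <- detect_spikes(traj, threshold = threshold,
                         min_prominence = min_prominence)
  st <- train$peak_times
  if (length(st) < 2)
    stop("no spiking found; cannot identify burst cycles")
  gapdur <- diff(st)
  big <- which(gapdur > gap_min)
  if (length(big)) {
    gap_mean <- vapply(big, function(i) {
      mean(traj$V[traj$t > st[i] & traj$t < st[i + 1]])
    }, numeric(1))
    low <- big[gap_mean < quiescence_ceiling]
    if (length(low) >= 2) big <- low   # snap to full burst cycles
    starts <- st[big + 1]
  } else starts <- numeric(0)
  if (length(starts) < 2)
    stop("fewer than one full burst cycle in the trajectory window")
  sel <- traj$t >= starts[1] & traj$t <= starts[length(starts)]
  tt <- traj$t[sel]; hh <- traj$h[sel]
  sum(diff(tt) * (hh[-1] + hh[-length(hh)]) / 2) / (tt[length(tt)] - tt[1])
}

#' @export
print.prebotc_traj <- function(x, ...) {
  cat("<prebotc_traj> ", nrow(x), " samples, t in [",
      signif(x$t[1], 6), ", ", signif(x$t[nrow(x)], 6), "] ms, variables: ",
      paste(setdiff(names(x), "t"), collapse = ", "), "\n", sep = "")
  invisible(x)
}
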