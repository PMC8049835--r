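# Named experiment configurations: every stimulation condition studied,
# plus reduced toy systems for fast tests of the continuation machinery.

#' Named experiment scenarios of the reference study conditions
#'
#' The full set of stimulation conditions studied with the model: the
#' no-stimulation baseline, the direct-current series
#' (`Iextz` in -2, 5, 25, 30, 40, 50 at `k1 = 0.1`), the induction-gain
#' series (`k1` in 0.1, 0.8, 1.0, 1.5 at `Iextz = 0`), and the sweep
#' configurations for the ISI bifurcation diagrams.  Each scenario carries
#' its parameters, a simulation configuration, the preset frozen-gate value
#' for the fast-slow decomposition where applicable, and the expected
#' qualitative outcome.
#'
#' @return Named list of scenarios; each is a list with elements `name`,
#'   `params`, `config`, `h_preset` (or NA), `expect` (qualitative label).
#' @export
reference_scenarios <- function() {
  base <- function(...) botc_params(...)
  mk <- function(name, params, h_preset = NA_real_, expect = NA_character_,
                 sweep = NULL) {
    list(name = name, params = params,
         config = sim_config(params, t_end = 60000, transient = 20000,
                             dt_out = 0.1),
         h_preset = h_preset, expect = expect, sweep = sweep)
  }
  iexts <- c(-2, 5, 25, 30, 40, 50)
  hpre <- c(0.2788, 0.2375, 0.1288, 0.0986, 0.0490, 0.0307)
  expect_i <- c("bursting_low_quiescence", "bursting_low_quiescence",
                "bursting_low_quiescence", "bursting_low_quiescence",
                "continuous_spiking", "bursting_high_quiescence")
  sc <- list(mk("baseline", base(), h_preset = 0.2834,
                expect = "bursting_low_quiescence"))
  for (i in seq_along(iexts))
    sc[[length(sc) + 1]] <-
      mk(paste0("current_", iexts[i]), base(Iextz = iexts[i], k1 = 0.1),
         h_preset = hpre[i], expect = expect_i[i])
  k1s <- c(0.1, 0.8, 1.0, 1.5)
  expect_k <- c("bursting_low_quiescence", "bursting_low_quiescence",
                "continuous_spiking", "bursting_high_quiescence")
  for (i in seq_along(k1s))
    sc[[length(sc) + 1]] <-
      mk(paste0("induction_", k1s[i]), base(Iextz = 0, k1 = k1s[i]),
         expect = expect_k[i])
  sc[[length(sc) + 1]] <- mk("sweep_Iextz", base(k1 = 0.1),
                             sweep = list(param = "Iextz",
                                          values = seq(-5, 55, by = 0.5)))
  sc[[length(sc) + 1]] <- mk("sweep_k1", base(Iextz = 0),
                             sweep = list(param = "k1",
                                          values = seq(0, 2, by = 0.01)))
  sc[[length(sc) + 1]] <- mk("sweep_alpha", base(Iextz = 0, k1 = 0.1),
                             sweep = list(param = "alpha",
                                          values = seq(0.5, 3, by = 0.025)))
  sc[[length(sc) + 1]] <- mk("sweep_beta", base(Iextz = 0, k1 = 0.1),
                             sweep = list(param = "beta",
                                          values = 6e-5 * 10^seq(-0.5, 0.5,
                                                                 by = 0.02)))
  names(sc) <- vapply(sc, `[[`, character(1), "name")
  sc
}

#' Frozen-gate presets for the fast-slow decomposition
#'
#' Burst-averaged h values matched to the stimulation conditions; these are
#' the constants at which the fast subsystem is analyzed.
#'
#' @return Named numeric vector keyed by scenario name.
#' @export
h_presets <- function() {
  c(baseline = 0.2834, `current_-2` = 0.2788, current_5 = 0.2375,
    current_25 = 0.1288, current_30 = 0.0986, current_40 = 0.0490,
    current_50 = 0.0307)
}

#' Toy test systems with known bifurcations
#'
#' Analytic fixtures for validating the continuation machinery: a cubic
#' scalar fold problem (`g(V) = V^3 - 3V`, folds at `V = +-1`) and a planar
#' Hopf normal form embedded in 3-D (Hopf at `mu = 0`, first Lyapunov sign
#' set by construction).
#'
#' @return List with `cubic` (function g and its analytic fold voltages)
#'   and `hopf_normal_form` (rhs factory `function(mu, lyap_sign)` and the
#'   analytic Hopf location).
#' @export
toy_scenarios <- function() {
  list(
    cubic = list(g = function(V) V^3 - 3 * V, folds_V = c(-1, 1)),
    hopf_normal_form = list(
      rhs = function(mu, lyap_sign = -1) {
        force(mu); force(lyap_sign)
        function(x) {
          r2 <- x[1]^2 + x[2]^2
          c(mu * x[1] - x[2] + lyap_sign * x[1] * r2,
            x[1] + mu * x[2] + lyap_sign * x[2] * r2,
            -x[3])
        }
      },
      hopf_mu = 0
    )
  )
}
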