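#' Q10 temperature factor for gating rates
#'
#' Returns `q10^((t_sim - t_exp)/10)`.  The factor multiplies rate
#' constants (equivalently divides time constants).  Steady-state values
#' are unaffected by temperature scaling.
#'
#' @param q10 dimensionless Q10 coefficient (> 0).
#' @param t_sim simulation temperature, degrees C.
#' @param t_exp reference (experimental) temperature, degrees C.
#' @return rate multiplier.
#' @export
q10_factor <- function(q10, t_sim, t_exp) {
  stopifnot(q10 > 0)
  q10^((t_sim - t_exp) / 10)
}

# ---------------------------------------------------------------------------
# Rate functions.  All rates in 1/ms, voltages in mV, calcium in mM.  These
# R versions are the reference transcription of the channel kinetics; the
# compiled engine implements the same expressions and is cross-checked
# against them in the test-suite.

#' Gating-variable kinetics for one mechanism
#'
#' Returns the steady state and time constant of each gate of a named
#' mechanism at voltage `v` (and shell calcium `ca` for the BK-type KCa
#' channel).  Gates are named after their role: `m`/`a`/`s`/`n`/`l` are
#' activation gates, `h`/`b`/`u` inactivation gates.
#'
#' @param mechanism one of `"kv"`, `"ka"`, `"kca"`, `"kslow"`, `"cahva"`,
#'   `"calva"`, `"h"`.
#' @param v membrane potential, mV.
#' @param ca shell calcium concentration, mM (KCa only).
#' @param h_pars optional H-gate parameter list (`vhalf`, `slope`,
#'   `tau_mode`, `tau_a`, `tau_ka`, `tau_b`, `tau_kb`, `tau_scale`);
#'   defaults to the packaged configuration.
#' @param kv_pars optional KV tau-scale list (`taum_scale`, `tauh_scale`).
#' @return data.frame with columns `gate`, `exponent`, `inf`, `tau` (ms).
#' @export
gate_kinetics <- function(mechanism, v, ca = 1e-4,
                          h_pars = NULL, kv_pars = NULL) {
  switch(mechanism,
    kv = {
      if (is.null(kv_pars)) kv_pars <- ubc_config()$mechanisms$kv
      minf <- 1 / (1 + exp(-(v + 24) / 15.4))
      taum <- kv_pars$taum_scale * 1000 * (3.4225e-5 + 0.00498 * exp(-v / 28.29))
      hinf <- 0.31 + 0.69 / (1 + exp((v + 5.802) / 11.2))
      tauh <- kv_pars$tauh_scale * 1000 * (0.0012 + 0.0023 * exp(-0.141 * v))
      data.frame(gate = c("m", "h"), exponent = c(3L, 1L),
                 inf = c(minf, hinf), tau = c(taum, tauh))
    },
    ka = {
      aa <- 4.88826 / (1 + exp(-(v + 9.197) / 23.327))
      ba <- 0.99285 * exp(-(v + 18.2791) / 19.4717)
      ab <- 0.11 / (1 + exp((v + 111.33) / 12.84))
      bb <- 0.1 / (1 + exp(-(v + 49.95) / 8.9))
      data.frame(gate = c("a", "b"), exponent = c(3L, 1L),
                 inf = c(1 / (1 + exp(-(v + 38) / 17)),
                         1 / (1 + exp((v + 78.8) / 8.4))),
                 tau = c(1 / (aa + ba), 1 / (ab + bb)))
    },
    kca = {
      r <- kca_rates(v, ca)
      data.frame(gate = "c", exponent = 1L,
                 inf = r$alpha / (r$alpha + r$beta),
                 tau = 1 / (r$alpha + r$beta))
    },
    kslow = {
      a <- 0.0033 * exp((v + 30) / 40)
      b <- 0.0033 * exp(-(v + 30) / 20)
      data.frame(gate = "n", exponent = 1L,
                 inf = 1 / (1 + exp(-(v + 45) / 6)), tau = 1 / (a + b))
    },
    cahva = {
      as_ <- 0.04944 * exp((v + 29.06) / 15.87)
      bs <- 0.08298 * exp(-(v + 18.66) / 25.641)
      au <- 0.0013 * exp(-(v + 48) / 18.183)
      bu <- 0.0013 * exp((v + 48) / 83.33)
      data.frame(gate = c("s", "u"), exponent = c(2L, 1L),
                 inf = c(as_ / (as_ + bs), au / (au + bu)),
                 tau = c(1 / (as_ + bs), 1 / (au + bu)))
    },
    calva = {
      data.frame(gate = c("m", "h"), exponent = c(2L, 1L),
                 inf = c(1 / (1 + exp(-(v + 52) / 5)),
                         1 / (1 + exp((v + 72) / 7))),
                 tau = c(1 + 1 / (exp((v + 40) / 9) + exp(-(v + 102) / 18)),
                         15 + exp(-(v + 32) / 7)))
    },
    h = {
      if (is.null(h_pars)) h_pars <- ubc_config()$mechanisms$h
      linf <- 1 / (1 + exp((v - h_pars$vhalf) / h_pars$slope))
      x <- v + 91.5
      taul <- if (identical(h_pars$tau_mode, "printed")) {
        h_pars$tau_scale * exp(0.13 * x) / (0.00225 * (1 + exp(0.2 * x)))
      } else {
        h_pars$tau_scale / (h_pars$tau_a * exp(-x / h_pars$tau_ka) +
                            h_pars$tau_b * exp(x / h_pars$tau_kb))
      }
      data.frame(gate = "l", exponent = 1L, inf = linf, tau = taul)
    },
    stop("unknown mechanism: ", mechanism)
  )
}

#' Steady-state open fraction of a gate
#'
#' @inheritParams gate_kinetics
#' @param gate gate name within the mechanism (default: first gate).
#' @return steady-state fraction in \[0, 1\].
#' @export
gate_steady_state <- function(mechanism, v, ca = 1e-4, gate = NULL, ...) {
  k <- gate_kinetics(mechanism, v, ca, ...)
  if (is.null(gate)) k$inf[1] else k$inf[match(gate, k$gate)]
}

#' BK-channel forward/backward rates
#'
#' Calcium- and voltage-dependent opening (`alpha`) and closing (`beta`)
#' rates of the KCa (BK-type) gate.
#'
#' @param v membrane potential, mV.
#' @param ca_in shell calcium, mM (> 0).
#' @return list with `alpha` and `beta` in 1/ms.
#' @export
kca_rates <- function(v, ca_in) {
  if (any(ca_in <= 0)) stop("ca_in must be positive")
  list(alpha = 2.5 / (1 + (1.5e-3 * exp(-v / 11.765)) / ca_in),
       beta = 1.5 / (1 + ca_in / (1.5e-4 * exp(-v / 11.765))))
}

#' Ohmic channel current
#'
#' `I = gmax * area * prod(gate^exponent) * (v - e_rev)`, outward positive.
#'
#' @param gmax_density maximum conductance density, S/cm2.
#' @param area_um2 membrane area, um2.
#' @param gates vector of gate open fractions.
#' @param exponents integer exponents matching `gates`.
#' @param v membrane potential, mV.
#' @param e_rev reversal potential, mV.
#' @return current in nA (outward positive).
#' @export
channel_current <- function(gmax_density, area_um2, gates, exponents, v, e_rev) {
  stopifnot(all(gates >= 0 & gates <= 1), gmax_density >= 0)
  g_uS <- gmax_density * area_um2 * 1e-8 * 1e6
  g_uS * prod(gates^exponents) * (v - e_rev)
}

#' GHK current density for a divalent ion
#'
#' Goldman-Hodgkin-Katz flux equation for calcium.  Continuous through
#' v = 0 (series expansion at the removable singularity).
#'
#' @param permeability cm/s.
#' @param v membrane potential, mV.
#' @param ca_in,ca_out intra/extracellular calcium, mM (> 0).
#' @param temperature degrees C.
#' @return current density in mA/cm2 (outward positive).
#' @export
ghk_ca_current <- function(permeability, v, ca_in, ca_out, temperature = 30) {
  if (any(ca_in <= 0) || any(ca_out <= 0)) stop("concentrations must be positive")
  FC <- 96485.332; R <- 8.314462618; z <- 2
  tk <- temperature + 273.15
  x <- z * FC * (v * 1e-3) / (R * tk)
  ratio <- ifelse(abs(x) < 1e-4,
                  (ca_in - ca_out) + x * (ca_out + (ca_in - ca_out) / 2),
                  x * (ca_in - ca_out * exp(-x)) / (1 - exp(-x)))
  permeability * z * FC * ratio * 1e-6 * 1e3 # mM -> mol/cm3, A -> mA
}

#' Default rate constants of the 13-state resurgent Na scheme
#'
#' Five closed states, one open state, an open-blocked state responsible
#' for the resurgent component, and six inactivated states.  Rates follow
#' the canonical resurgent-sodium formulation for Nav1.6: activation
#' `alpha = alpha_a exp(v/valpha)`, deactivation `beta = beta_a exp(-v/vbeta)`,
#' opening `gamma`, closing `delta`, block `epsilon`, unblock
#' `zeta = zeta_a exp(-v/vzeta)`, and inactivation coupling factors
#' `Con/Coff/Oon/Ooff` with the usual `a = (Oon/Con)^(1/4)`,
#' `b = (Ooff/Coff)^(1/4)` scaling along the closed chain.
#'
#' @return named list of rate parameters (1/ms).
#' @export
na_markov_params <- function() {
  list(alpha_a = 150, valpha = 20, beta_a = 3, vbeta = 20,
       gamma = 150, delta = 40, epsilon = 1.75,
       zeta_a = 0.03, vzeta = 25,
       Con = 0.005, Coff = 0.5, Oon = 0.75, Ooff = 0.005,
       v_shift = 0)
}

#' Transition-rate matrix of the Markov Na scheme
#'
#' Returns the 13 x 13 generator matrix `A` with `ds/dt = A s`
#' (`A[to, from]` holds the rate from state `from` to state `to`;
#' diagonal entries are minus the total leaving rate, so columns sum to
#' zero and total occupancy is conserved).
#'
#' State order: C1..C5, O, B (open-blocked), I1..I6.
#'
#' @param v membrane potential, mV.
#' @param pars rate parameters, see [na_markov_params()].
#' @param q temperature rate multiplier (see [q10_factor()]).
#' @return 13 x 13 numeric matrix, units 1/ms.
#' @export
markov_na_rates <- function(v, pars = na_markov_params(), q = 1) {
  A <- .na_rate_matrix_cpp(v, pars, q)
  states <- c(paste0("C", 1:5), "O", "B", paste0("I", 1:6))
  dimnames(A) <- list(states, states)
  A
}

#' Stationary occupancy of the Markov Na scheme
#'
#' @inheritParams markov_na_rates
#' @return named occupancy vector summing to 1.
#' @export
markov_na_stationary <- function(v, pars = na_markov_params(), q = 1) {
  A <- markov_na_rates(v, pars, q)
  n <- nrow(A)
  A[n, ] <- 1
  b <- c(rep(0, n - 1), 1)
  s <- solve(A, b)
  s[s < 0] <- 0
  s / sum(s)
}
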