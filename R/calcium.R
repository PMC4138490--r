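#' Sub-membrane calcium shell
#'
#' Each calcium-bearing compartment (soma, shaft, brush) carries a thin
#' shell of depth `d` under the membrane.  The shell concentration obeys
#' `d[Ca]/dt = -I_Ca / (2 F A d) - beta_ca ([Ca] - [Ca]_0)`: influx from
#' the high-voltage-activated calcium current, first-order removal
#' lumping pumps, buffers and diffusion.  The low-voltage-activated
#' (T-type) current is excluded from the pool by construction.
#'
#' @param area_um2 shell (compartment) membrane area, um2.
#' @param depth_nm shell depth, nm (default 200).
#' @param beta_ca removal rate, 1/ms (default 1.5).
#' @param ca_rest resting calcium, mM (default 1e-4, i.e. 100 nM).
#' @param ca_out extracellular calcium, mM.
#' @return a `ubc_ca_shell` list with the state field `ca_in`.
#' @export
calcium_shell <- function(area_um2, depth_nm = 200, beta_ca = 1.5,
                          ca_rest = 1e-4, ca_out = 2) {
  stopifnot(area_um2 > 0, depth_nm > 0, beta_ca >= 0, ca_rest > 0, ca_out > 0)
  vol_cm3 <- area_um2 * 1e-8 * depth_nm * 1e-7
  structure(list(area_um2 = area_um2, depth_nm = depth_nm, beta_ca = beta_ca,
                 ca_rest = ca_rest, ca_out = ca_out, vol_cm3 = vol_cm3,
                 kflux = 1e-6 / (2 * 96485.332 * vol_cm3),
                 ca_in = ca_rest),
            class = "ubc_ca_shell")
}

#' Advance a calcium shell by one time step
#'
#' Implicit (backward-Euler) update of the shell equation.  `i_ca` is the
#' calcium current in nA with the outward-positive convention, so inward
#' (negative) current raises `ca_in`.
#'
#' @param shell a [calcium_shell()].
#' @param i_ca calcium current, nA (outward positive).
#' @param dt time step, ms (> 0).
#' @return the shell with updated `ca_in`.
#' @export
step_calcium <- function(shell, i_ca, dt) {
  if (dt <= 0) stop("dt must be positive")
  J <- -i_ca * shell$kflux # mM/ms, influx positive
  shell$ca_in <- (shell$ca_in + dt * (J + shell$beta_ca * shell$ca_rest)) /
    (1 + dt * shell$beta_ca)
  shell$ca_in <- max(shell$ca_in, 1e-9)
  shell
}

#' Calcium equilibrium (reversal) potential
#'
#' Divalent Nernst potential `(RT/2F) ln(ca_out/ca_in)`, updated at run
#' time from the shell concentration (the GHK equilibrium condition for a
#' single permeant ion reduces to the Nernst form).
#'
#' @param ca_in,ca_out intra/extracellular calcium, mM (> 0).
#' @param temperature degrees C.
#' @return reversal potential, mV.
#' @export
calcium_reversal <- function(ca_in, ca_out, temperature = 30) {
  if (any(ca_in <= 0) || any(ca_out <= 0)) stop("concentrations must be positive")
  R <- 8.314462618; FC <- 96485.332
  (R * (temperature + 273.15) / (2 * FC)) * log(ca_out / ca_in) * 1e3
}

#' Back-solve the extracellular calcium for a target initial reversal
#'
#' The model is initialised with a stated calcium equilibrium potential;
#' the fixed extracellular concentration consistent with it at resting
#' shell calcium is recovered here.
#'
#' @param e_rev_mV target reversal potential, mV.
#' @param ca_in resting shell calcium, mM.
#' @param temperature degrees C.
#' @return extracellular calcium, mM.
#' @export
ca_out_for_reversal <- function(e_rev_mV, ca_in = 1e-4, temperature = 30) {
  R <- 8.314462618; FC <- 96485.332
  ca_in * exp(e_rev_mV * 1e-3 * 2 * FC / (R * (temperature + 273.15)))
}
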