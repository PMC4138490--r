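#' Second-messenger cascade parameters
#'
#' The late-onset response is driven by a generic two-stage cascade.  A
#' receptor pool X is converted to X* at a rate alpha(t) that steps up by
#' `omega` for a window `tau` after each synaptic pulse and relaxes back at
#' rate `beta`.  X* gates the conversion of a messenger pool Y (initial
#' value `y_total`, of the order of neuronal ATP content) to Y* through a
#' sigmoidal forward rate `delta(X*)` with midpoint `x_half` and slope `k`;
#' Y* decays back at rate `gamma`.  The normalised Y* fraction scales the
#' TRP maximum conductance (`trp_baseline + Y*`) and shifts the H-current
#' half-activation by up to `h_shift_max` mV through a logistic with
#' midpoint `h_shift_mid` and slope `h_shift_slope` in normalised Y*.
#'
#' @param params optional list of overrides for the packaged values.
#' @return a `ubc_cascade_params` list.
#' @export
cascade_params <- function(params = NULL) {
  p <- ubc_config()$cascade
  if (!is.null(params)) p[names(params)] <- params
  stopifnot(p$omega >= 0, p$tau > 0, p$beta >= 0, p$gamma >= 0,
            p$x_total > 0, p$y_total > 0, p$delta_max >= 0)
  structure(p, class = "ubc_cascade_params")
}

#' Resting cascade state
#' @param params a [cascade_params()] list.
#' @return list with `x`, `x_star`, `y`, `y_star`, `y_star_norm` (mM except
#'   the normalised fraction).
#' @export
cascade_state <- function(params = cascade_params()) {
  list(x = params$x_total, x_star = 0, y = params$y_total, y_star = 0,
       y_star_norm = 0)
}

#' Synaptic drive rate alpha(t)
#'
#' Sum over pulses of `omega * \[t in \[t_s, t_s + tau))\]`; overlapping
#' windows add.
#'
#' @param t query time, ms (vectorised).
#' @param pulse_times sorted pulse times, ms.
#' @param params a [cascade_params()] list.
#' @return rate in 1/ms.
#' @export
synaptic_drive <- function(t, pulse_times, params = cascade_params()) {
  vapply(t, function(tt) {
    params$omega * sum(tt >= pulse_times & tt < pulse_times + params$tau)
  }, numeric(1))
}

#' Advance the X pool by one step
#'
#' `dX*/dt = alpha X - beta X*` with `X + X* = x_total` conserved exactly
#' (exponential update of the two-state scheme with alpha held constant
#' over the step).
#'
#' @param state a [cascade_state()] list.
#' @param alpha forward rate, 1/ms.
#' @param params a [cascade_params()] list.
#' @param dt time step, ms (> 0).
#' @return updated state.
#' @export
step_x <- function(state, alpha, params, dt) {
  if (dt <= 0) stop("dt must be positive")
  if (state$x_star < 0 || state$x < 0) stop("negative cascade state")
  r <- alpha + params$beta
  xs <- if (r > 0) {
    xinf <- params$x_total * alpha / r
    xinf + (state$x_star - xinf) * exp(-r * dt)
  } else state$x_star
  state$x_star <- xs
  state$x <- params$x_total - xs
  state
}

#' Sigmoidal forward rate delta(X*)
#'
#' Logistic in X* with midpoint `x_half` and slope `k` (1/mM), saturating
#' at `delta_max`, anchored so that `delta(0) = 0` exactly: the raw
#' logistic retains a small floor at zero drive which would convert Y at
#' rest; subtracting it (and renormalising to preserve the saturation
#' level) makes the resting cascade a true fixed point.
#'
#' @param x_star activated receptor concentration, mM.
#' @param params a [cascade_params()] list.
#' @return rate in 1/ms.
#' @export
delta_rate <- function(x_star, params = cascade_params()) {
  L <- 1 / (1 + exp(-(x_star - params$x_half) * params$k))
  L0 <- 1 / (1 + exp(params$x_half * params$k))
  pmax(params$delta_max * (L - L0) / (1 - L0), 0)
}

#' Advance the Y pool by one step
#'
#' `dY*/dt = delta Y - gamma Y*` with `Y + Y* = y_total` conserved.
#'
#' @param state a [cascade_state()] list.
#' @param delta forward rate, 1/ms.
#' @param params a [cascade_params()] list.
#' @param dt time step, ms (> 0).
#' @return updated state.
#' @export
step_y <- function(state, delta, params, dt) {
  if (dt <= 0) stop("dt must be positive")
  r <- delta + params$gamma
  ys <- if (r > 0) {
    yinf <- params$y_total * delta / r
    yinf + (state$y_star - yinf) * exp(-r * dt)
  } else state$y_star
  state$y_star <- ys
  state$y <- params$y_total - ys
  state$y_star_norm <- ys / params$y_total
  state
}

#' TRP maximum conductance under cascade modulation
#'
#' `gmax * (baseline + Y*_norm)`: at rest the TRP conductance sits at
#' `baseline` (16 percent) of its maximum.
#'
#' @param y_star_norm normalised Y* in \[0, 1\].
#' @param gmax_trp maximum conductance (any unit).
#' @param baseline resting fraction.
#' @return modulated conductance, same unit as `gmax_trp`.
#' @export
modulated_trp_gmax <- function(y_star_norm, gmax_trp, baseline = 0.16) {
  stopifnot(y_star_norm >= 0, y_star_norm <= 1)
  gmax_trp * (baseline + y_star_norm)
}

#' H-current half-activation under cascade modulation
#'
#' Baseline half-activation plus a logistic shift in normalised Y*
#' (midpoint `h_shift_mid`, slope `h_shift_slope`), saturating at
#' `h_shift_max` mV so the half-activation moves from -91.5 toward
#' -66.5 mV at full cascade activation.
#'
#' @param y_star_norm normalised Y* in \[0, 1\].
#' @param params a [cascade_params()] list.
#' @param vhalf_base baseline half-activation, mV.
#' @return half-activation potential, mV.
#' @export
modulated_h_half <- function(y_star_norm, params = cascade_params(),
                             vhalf_base = -91.5) {
  stopifnot(y_star_norm >= 0, y_star_norm <= 1)
  vhalf_base + params$h_shift_max /
    (1 + exp((params$h_shift_mid - y_star_norm) / params$h_shift_slope))
}

#' Run the cascade alone against a pulse train
#'
#' Stand-alone integration of the two-stage cascade (no membrane), useful
#' for inspecting X*/Y* trajectories and for testing.
#'
#' @param pulse_times pulse times, ms.
#' @param t_total total simulated time, ms.
#' @param dt step, ms.
#' @param params a [cascade_params()] list.
#' @return data.frame with time, alpha, x_star, delta, y_star, y_star_norm.
#' @export
run_cascade <- function(pulse_times, t_total, dt = 0.1,
                        params = cascade_params()) {
  nt <- floor(t_total / dt) + 1L
  tt <- (seq_len(nt) - 1) * dt
  st <- cascade_state(params)
  out <- matrix(0, nt, 5)
  for (i in seq_len(nt)) {
    a <- synaptic_drive(tt[i], pulse_times, params)
    d <- delta_rate(st$x_star, params)
    out[i, ] <- c(a, st$x_star, d, st$y_star, st$y_star_norm)
    st <- step_x(st, a, params, dt)
    st <- step_y(st, delta_rate(st$x_star, params), params, dt)
  }
  data.frame(time = tt, alpha = out[, 1], x_star = out[, 2],
             delta = out[, 3], y_star = out[, 4], y_star_norm = out[, 5])
}
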