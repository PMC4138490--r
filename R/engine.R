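#' Stimulation protocol
#'
#' Describes a current-clamp or voltage-clamp run.  In current clamp the
#' `holding` potential is realised through a constant bias current found by
#' [init_steady_state()]; steps are injected at the soma.  In voltage clamp
#' the soma is clamped through the pipette access resistance and the clamp
#' current is recorded.  A `pulse_train` drives the second-messenger
#' cascade only (the corresponding synaptic experiments are performed under
#' ionotropic receptor block, so pulses have no direct electrical effect).
#'
#' @param mode `"current_clamp"` or `"voltage_clamp"`.
#' @param holding holding potential, mV.
#' @param pre_time settling time before the first step/pulse, ms.
#' @param steps data.frame with `amplitude` (pA in current clamp, mV
#'   absolute command in voltage clamp) and `duration` (ms), applied
#'   sequentially after `pre_time`.
#' @param post_time simulated time after the last step/train, ms.
#' @param pulse_train optional list: `n_pulses`, `frequency_hz`,
#'   `intensity` (multiplies the cascade per-pulse weight omega).
#' @param dt integration step, ms.
#' @param record_dt recording interval, ms (defaults to `dt`).
#' @return a `ubc_protocol` list.
#' @export
ubc_protocol <- function(mode = c("current_clamp", "voltage_clamp"),
                         holding = -80, pre_time = 1000,
                         steps = NULL, post_time = 200,
                         pulse_train = NULL,
                         dt = 0.025, record_dt = NULL) {
  mode <- match.arg(mode)
  if (dt <= 0) stop("dt must be positive")
  if (!is.null(steps)) {
    stopifnot(is.data.frame(steps), all(c("amplitude", "duration") %in%
                                          names(steps)))
    if (any(steps$duration <= 0)) stop("step durations must be positive")
  }
  if (!is.null(pulse_train)) {
    stopifnot(pulse_train$n_pulses >= 1, pulse_train$frequency_hz > 0)
    pulse_train$intensity <- pulse_train$intensity %||% 1
  }
  structure(list(mode = mode, holding = holding, pre_time = pre_time,
                 steps = steps, post_time = post_time,
                 pulse_train = pulse_train, dt = dt,
                 record_dt = record_dt %||% dt),
            class = "ubc_protocol")
}

#' Current-step protocol shorthand
#' @param amplitude_pA step amplitude, pA.
#' @param duration step duration, ms.
#' @param holding holding potential, mV.
#' @param ... passed to [ubc_protocol()].
#' @export
protocol_step <- function(amplitude_pA, duration = 800, holding = -80, ...) {
  ubc_protocol("current_clamp", holding = holding,
               steps = data.frame(amplitude = amplitude_pA,
                                  duration = duration), ...)
}

#' Synaptic-train (LOR) protocol shorthand
#' @param n_pulses number of pulses.
#' @param frequency_hz train frequency, Hz.
#' @param intensity stimulation intensity (omega scale, arbitrary units).
#' @param post_time simulated time after the train, ms.
#' @param ... passed to [ubc_protocol()].
#' @export
protocol_train <- function(n_pulses = 10, frequency_hz = 100, intensity = 1,
                           post_time = 5000, ...) {
  ubc_protocol("current_clamp",
               pulse_train = list(n_pulses = n_pulses,
                                  frequency_hz = frequency_hz,
                                  intensity = intensity),
               post_time = post_time, ...)
}

#' Voltage-step protocol shorthand
#' @param step_mV step amplitude relative to holding, mV.
#' @param duration step duration, ms.
#' @param holding holding potential, mV.
#' @param ... passed to [ubc_protocol()].
#' @export
protocol_vstep <- function(step_mV = -10, duration = 250, holding = -70, ...) {
  ubc_protocol("voltage_clamp", holding = holding,
               steps = data.frame(amplitude = holding + step_mV,
                                  duration = duration), ...)
}

#' Steady state at a holding potential
#'
#' Finds the constant somatic bias current that holds the soma at `v_hold`
#' and the corresponding full-model steady state (gates, Markov
#' occupancies, calcium, cascade).  A secant iteration on the settled
#' somatic potential is used; each evaluation relaxes the model for
#' `settle_ms`.
#'
#' @param model a [ubc_model()].
#' @param v_hold target somatic potential, mV (between -120 and -40).
#' @param settle_ms relaxation time per iteration, ms.
#' @param tol_mV convergence tolerance on the settled potential, mV.
#' @param dt integration step for the relaxation, ms.
#' @return list with `holding_current` (nA), `state` (engine state
#'   snapshot) and `v` (settled compartment potentials).
#' @export
init_steady_state <- function(model, v_hold, settle_ms = 1500, tol_mV = 0.05,
                              dt = 0.05) {
  if (v_hold < -120 || v_hold > -40)
    stop("v_hold outside the supported range [-120, -40] mV")
  cur_state <- NULL
  # relax at fixed bias until the endpoint is stationary (slow gates such
  # as the H current equilibrate over seconds)
  settle <- function(i_bias) {
    v_prev <- NA_real_
    for (rep in seq_len(8)) {
      r <- .run_ubc_engine(model$engine, engine_proto(
        dt = dt, t_total = settle_ms, record_dt = settle_ms,
        v_init = v_hold, i_bias = i_bias, init_state = cur_state))
      cur_state <<- r$final_state
      v_now <- r$final_state$v[1]
      if (!is.na(v_prev) && abs(v_now - v_prev) < tol_mV / 4) break
      v_prev <- v_now
    }
    r
  }
  # successive relaxations are chained through cur_state, so the secant
  # iteration converges to the true fixed point even in the presence of
  # slowly equilibrating gates
  i0 <- 0
  r0 <- settle(i0)
  f0 <- tail_v_soma(r0) - v_hold
  # probe a second point using a rough 1 GOhm input-resistance guess
  i1 <- i0 - f0 * 1e-3 # nA = mV / (1e3 MOhm)
  f1 <- tail_v_soma(settle(i1)) - v_hold
  # maintain a bracket when one appears; fall back to bisection whenever
  # the secant proposal misbehaves (the settled response can be locally
  # non-monotonic while slow gates equilibrate)
  lo <- NA_real_; flo <- NA_real_; hi <- NA_real_; fhi <- NA_real_
  note <- function(i, f) {
    # f increases with bias current; keep the tightest bracket around 0
    if (f < 0 && (is.na(lo) || i > lo)) { lo <<- i; flo <<- f }
    if (f > 0 && (is.na(hi) || i < hi)) { hi <<- i; fhi <<- f }
    # slow-gate drift can make near-root signs unreliable; drop an
    # inconsistent bracket and rebuild it from later evaluations
    if (!is.na(lo) && !is.na(hi) && lo >= hi) { lo <<- NA; hi <<- NA }
  }
  note(i0, f0); note(i1, f1)
  converged <- FALSE
  for (k in seq_len(40)) {
    if (abs(f1) < tol_mV) {
      # require stationarity as well: relax once more at the same bias
      f1 <- tail_v_soma(settle(i1)) - v_hold
      note(i1, f1)
      if (abs(f1) < tol_mV) { converged <- TRUE; break }
      next
    }
    i2 <- if (f1 != f0) i1 - f1 * (i1 - i0) / (f1 - f0) else NA_real_
    if (!is.na(lo) && !is.na(hi) &&
        (is.na(i2) || i2 <= min(lo, hi) || i2 >= max(lo, hi)))
      i2 <- (lo + hi) / 2
    if (is.na(i2)) i2 <- i1 - sign(f1) * max(abs(i1), 0.005)
    i2 <- max(min(i2, i1 + 0.05), i1 - 0.05) # damp large proposals
    i0 <- i1; f0 <- f1; i1 <- i2
    f1 <- tail_v_soma(settle(i1)) - v_hold
    note(i1, f1)
  }
  if (!converged)
    stop(sprintf("no convergence to %g mV: settled at %g mV (bias %g nA)",
                 v_hold, f1 + v_hold, i1))
  list(holding_current = i1, state = cur_state, v = cur_state$v)
}

tail_v_soma <- function(res) {
  res$final_state$v[1]
}

# low-level protocol structure for the compiled engine
engine_proto <- function(dt, t_total, record_dt, v_init, i_bias = 0,
                         steps = matrix(numeric(0), 0, 3), vc_on = FALSE,
                         vc_rs = 20, vc_segments = matrix(numeric(0), 0, 3),
                         pulses = numeric(0), omega_scale = 1,
                         init_state = NULL) {
  list(dt = dt, t_total = t_total, record_dt = record_dt, v_init = v_init,
       i_bias = i_bias, steps = steps, vc_on = vc_on, vc_rs = vc_rs,
       vc_segments = vc_segments, pulses = pulses,
       omega_scale = omega_scale, init_state = init_state)
}

#' Run a protocol on a model
#'
#' Integrates the full coupled system (cable, gating, calcium, cascade)
#' under the given protocol and returns a tidy trace.  Current clamp first
#' solves for the holding bias current ([init_steady_state()]) and starts
#' from the corresponding steady state, matching the experimental practice
#' of setting the resting potential with a bias current.
#'
#' @param model a [ubc_model()].
#' @param protocol a [ubc_protocol()].
#' @param hold optional precomputed result of [init_steady_state()] (to
#'   reuse across runs of the same model and holding potential).
#' @return a `ubc_trace` data.frame (time in ms, per-compartment voltages,
#'   shell calcium, cascade observables, per-mechanism total currents,
#'   injected/clamp current) with attributes `stim_onset`,
#'   `stim_end`, `holding_current`, `dt`, `max_occupancy_error`,
#'   `config_hash`, `final_state`.
#' @export
run_protocol <- function(model, protocol, hold = NULL) {
  stopifnot(inherits(model, "ubc_model"), inherits(protocol, "ubc_protocol"))
  p <- protocol
  step_total <- if (is.null(p$steps)) 0 else sum(p$steps$duration)
  train_dur <- if (is.null(p$pulse_train)) 0 else
    (p$pulse_train$n_pulses - 1) * 1000 / p$pulse_train$frequency_hz
  t_total <- p$pre_time + max(step_total, train_dur) + p$post_time
  onset <- p$pre_time

  if (p$mode == "current_clamp") {
    if (is.null(hold)) hold <- init_steady_state(model, p$holding)
    steps <- matrix(numeric(0), 0, 3)
    if (!is.null(p$steps)) {
      t0 <- onset
      rows <- list()
      for (i in seq_len(nrow(p$steps))) {
        rows[[i]] <- c(t0, t0 + p$steps$duration[i],
                       p$steps$amplitude[i] * 1e-3) # pA -> nA
        t0 <- t0 + p$steps$duration[i]
      }
      steps <- do.call(rbind, rows)
    }
    pulses <- numeric(0)
    omega_scale <- 1
    if (!is.null(p$pulse_train)) {
      pulses <- onset + (seq_len(p$pulse_train$n_pulses) - 1) *
        1000 / p$pulse_train$frequency_hz
      omega_scale <- p$pulse_train$intensity
    }
    res <- .run_ubc_engine(model$engine, engine_proto(
      dt = p$dt, t_total = t_total, record_dt = p$record_dt,
      v_init = p$holding, i_bias = hold$holding_current, steps = steps,
      pulses = pulses, omega_scale = omega_scale,
      init_state = hold$state))
    holding_current <- hold$holding_current
  } else {
    segs <- list(c(0, onset, p$holding))
    t0 <- onset
    if (!is.null(p$steps)) {
      for (i in seq_len(nrow(p$steps))) {
        segs[[length(segs) + 1]] <- c(t0, t0 + p$steps$duration[i],
                                      p$steps$amplitude[i])
        t0 <- t0 + p$steps$duration[i]
      }
    }
    segs[[length(segs) + 1]] <- c(t0, t_total + p$dt, p$holding)
    res <- .run_ubc_engine(model$engine, engine_proto(
      dt = p$dt, t_total = t_total, record_dt = p$record_dt,
      v_init = p$holding, vc_on = TRUE,
      vc_rs = model$morphology$pipette$access_resistance_mohm,
      vc_segments = do.call(rbind, segs)))
    holding_current <- NA_real_
  }

  build_trace(res, model, protocol, onset = onset,
              stim_end = onset + max(step_total, train_dur),
              holding_current = holding_current)
}

build_trace <- function(res, model, protocol, onset, stim_end,
                        holding_current) {
  nms <- vapply(model$morphology$compartments, `[[`, character(1), "name")
  df <- data.frame(time = res$time)
  vv <- res$v; colnames(vv) <- paste0("v_", nms)
  df <- cbind(df, vv)
  shells <- which(model$engine$ca$has_shell)
  for (i in shells) df[[paste0("ca_", nms[i])]] <- res$ca[, i]
  sc <- res$scalars
  df$alpha <- sc[, 1]; df$x_star <- sc[, 2]; df$y_star_norm <- sc[, 3]
  df$delta <- sc[, 4]; df$trp_factor <- sc[, 5]; df$h_vhalf <- sc[, 6]
  df$i_inj <- sc[, 7]; df$i_clamp <- sc[, 8]
  im <- res$i_mech; colnames(im) <- paste0("i_", MECH_ORDER)
  df <- cbind(df, im)
  df$na_open_soma <- res$na_open_soma
  structure(df, class = c("ubc_trace", "data.frame"),
            stim_onset = onset, stim_end = stim_end,
            holding_current = holding_current, dt = protocol$dt,
            mode = protocol$mode,
            max_occupancy_error = res$max_occupancy_error,
            config_hash = config_hash(model$config),
            final_state = res$final_state)
}

#' Integration-step convergence report
#'
#' Reruns a protocol at each step size in `dt_list` and reports the
#' maximum somatic voltage difference between successive refinements
#' (voltages compared on the coarser recording grid) and the spike counts.
#'
#' @param model a [ubc_model()].
#' @param protocol a [ubc_protocol()].
#' @param dt_list decreasing vector of at least two step sizes, ms.
#' @return data.frame with one row per refinement pair.
#' @export
convergence_check <- function(model, protocol, dt_list) {
  if (length(dt_list) < 2) stop("need at least two dt values")
  dt_list <- sort(dt_list, decreasing = TRUE)
  record_dt <- max(dt_list)
  hold <- if (protocol$mode == "current_clamp")
    init_steady_state(model, protocol$holding) else NULL
  traces <- lapply(dt_list, function(d) {
    p <- protocol; p$dt <- d; p$record_dt <- record_dt
    run_protocol(model, p, hold = hold)
  })
  out <- data.frame(dt_coarse = dt_list[-length(dt_list)],
                    dt_fine = dt_list[-1])
  out$max_dv_mV <- NA_real_; out$spikes_coarse <- NA_integer_
  out$spikes_fine <- NA_integer_
  for (i in seq_len(nrow(out))) {
    a <- traces[[i]]; b <- traces[[i + 1]]
    nt <- min(nrow(a), nrow(b))
    out$max_dv_mV[i] <- max(abs(a$v_soma[seq_len(nt)] - b$v_soma[seq_len(nt)]))
    out$spikes_coarse[i] <- nrow(detect_spikes(a))
    out$spikes_fine[i] <- nrow(detect_spikes(b))
  }
  out
}

#' Per-compartment membrane currents from an engine state
#'
#' Independent R-side evaluation of every mechanism's current given a
#' state snapshot, used to verify Kirchhoff consistency of engine steady
#' states (sum of membrane + axial + injected current approximately zero
#' in every compartment).
#'
#' @param model a [ubc_model()].
#' @param state engine state snapshot (`final_state` of a run or
#'   `state` of [init_steady_state()]).
#' @param i_inj_soma injected somatic current, nA.
#' @return list with `per_mech` (matrix mech x compartment, nA) and
#'   `residual` (net current per compartment, nA).
#' @export
membrane_currents <- function(model, state, i_inj_soma = 0) {
  en <- model$engine
  n <- en$n_comp
  v <- state$v
  ynorm <- state$cascade[2] / en$cascade$y_total
  out <- matrix(0, length(en$mechs), n,
                dimnames = list(MECH_ORDER, NULL))
  for (k in seq_along(en$mechs)) {
    me <- en$mechs[[k]]
    gm <- state$gates[[k]]
    for (i in seq_len(n)) {
      if (me$g_abs[i] <= 0) next
      cur <- switch(me$name,
        leak = me$g_abs[i] * (v[i] - me$erev),
        trp = me$g_abs[i] * (me$baseline + ynorm) * (v[i] - me$erev),
        h = me$g_abs[i] * gm[1, i] * (v[i] - me$erev),
        na = me$g_abs[i] * state$markov[6, i] * (v[i] - me$erev),
        kv = me$g_abs[i] * gm[1, i]^3 * gm[2, i] * (v[i] - me$erev),
        ka = me$g_abs[i] * gm[1, i]^3 * gm[2, i] * (v[i] - me$erev),
        kca = me$g_abs[i] * gm[1, i] * (v[i] - me$erev),
        kslow = me$g_abs[i] * gm[1, i] * (v[i] - me$erev),
        cahva = me$g_abs[i] * gm[1, i]^2 * gm[2, i] *
          (v[i] - calcium_reversal(state$ca[i], en$ca$cao, en$temperature)),
        # calva g_abs holds P*A (cm^3/s); ghk_ca_current at unit
        # permeability is mA/cm2, so P*A * (that/1 cm/s) * 1e6 gives nA
        calva = me$g_abs[i] * gm[1, i]^2 * gm[2, i] *
          ghk_ca_current(1, v[i], en$ca$ca0, en$ca$cao, en$temperature) * 1e6
      )
      out[k, i] <- cur
    }
  }
  axial <- numeric(n)
  for (i in seq_len(n)) {
    p <- en$parent[i] + 1L
    if (p >= 1) {
      f <- en$g_axial[i] * (v[i] - v[p]) # current leaving i toward parent
      axial[i] <- axial[i] + f
      axial[p] <- axial[p] - f
    }
  }
  inj <- numeric(n); inj[1] <- i_inj_soma
  residual <- -colSums(out) - axial + inj
  list(per_mech = out, residual = residual)
}
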