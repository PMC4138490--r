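#' Spike detection by depolarisation-rate threshold
#'
#' A spike is registered where the depolarisation rate first reaches
#' `rate_threshold` (default 5 mV/ms); the following local maximum gives
#' the overshoot.  Detections are grouped so that one spike yields one
#' event (a new threshold crossing is only accepted after the previous
#' spike's peak).
#'
#' @param trace a `ubc_trace` (or any data.frame with `time` and the
#'   voltage column).
#' @param rate_threshold mV/ms.
#' @param v_col voltage column to analyse.
#' @param peak_min minimum peak potential for a crossing to count as a
#'   spike, mV.
#' @param t_min,t_max optional analysis window, ms.
#' @return data.frame with `threshold_time`, `threshold_v`, `peak_time`,
#'   `peak_v` (one row per spike; zero rows if none).
#' @export
detect_spikes <- function(trace, rate_threshold = 5, v_col = "v_soma",
                          peak_min = -10, t_min = NULL, t_max = NULL) {
  tt <- trace$time
  vv <- trace[[v_col]]
  keep <- rep(TRUE, length(tt))
  if (!is.null(t_min)) keep <- keep & tt >= t_min
  if (!is.null(t_max)) keep <- keep & tt <= t_max
  tt <- tt[keep]; vv <- vv[keep]
  empty <- data.frame(threshold_time = numeric(0), threshold_v = numeric(0),
                      peak_time = numeric(0), peak_v = numeric(0))
  if (length(tt) < 3) return(empty)
  dvdt <- c(diff(vv) / diff(tt), 0)
  # small tolerance so a ramp at exactly the threshold rate does not
  # retrigger on floating-point jitter
  above <- dvdt >= rate_threshold - 1e-9
  crossings <- which(above & !c(FALSE, above[-length(above)]))
  if (!length(crossings)) return(empty)
  res <- list()
  last_peak_idx <- 0L
  for (ci in crossings) {
    if (ci <= last_peak_idx) next
    # forward local maximum (first downturn), capped at 10 ms lookahead
    j <- ci
    jmax <- length(vv)
    while (j < jmax && tt[j + 1] - tt[ci] <= 10 && vv[j + 1] >= vv[j]) j <- j + 1
    if (vv[j] < peak_min) next
    res[[length(res) + 1]] <- c(tt[ci], vv[ci], tt[j], vv[j])
    last_peak_idx <- j
  }
  if (!length(res)) return(empty)
  out <- as.data.frame(do.call(rbind, res))
  names(out) <- c("threshold_time", "threshold_v", "peak_time", "peak_v")
  out
}

#' Spike-train metrics for a current step
#'
#' First-spike delay from stimulus onset, per-spike overshoots,
#' inter-spike intervals, instantaneous frequency (1000/ISI1),
#' steady-state frequency (1000/ISI4) and the frequency ratio ISI1/ISI4
#' (equivalently steady-state/instantaneous frequency).  Frequencies need
#' at least 2 (instantaneous) or 5 (steady-state, ratio) spikes and are
#' `NA` otherwise.
#'
#' @param spikes data.frame from [detect_spikes()].
#' @param stim_onset stimulus onset time, ms.
#' @return list of class `ubc_spike_metrics`.
#' @export
spike_metrics <- function(spikes, stim_onset) {
  n <- nrow(spikes)
  isi <- if (n >= 2) diff(spikes$threshold_time) else numeric(0)
  inst <- if (n >= 2) 1000 / isi[1] else NA_real_
  ss <- if (n >= 5) 1000 / isi[4] else NA_real_
  structure(list(
    spike_count = n,
    first_spike_delay = if (n >= 1) spikes$threshold_time[1] - stim_onset
                        else NA_real_,
    overshoots = spikes$peak_v,
    isi = isi,
    instantaneous_frequency = inst,
    steady_state_frequency = ss,
    frequency_ratio = if (n >= 5) isi[1] / isi[4] else NA_real_
  ), class = "ubc_spike_metrics")
}

#' Sag amplitude of a hyperpolarising response
#'
#' Minimum membrane potential during the step minus the mean potential
#' over the final fraction (default 10 percent) of the step; negative
#' values mean the trough undershoots the steady state (sag).
#'
#' @param trace a `ubc_trace`.
#' @param step_window numeric `c(t0, t1)`, ms; defaults to the trace's
#'   stimulus window.
#' @param v_col voltage column.
#' @param ss_fraction fraction of the window used for the steady state.
#' @return sag amplitude, mV.
#' @export
sag_amplitude <- function(trace, step_window = NULL, v_col = "v_soma",
                          ss_fraction = 0.1) {
  if (is.null(step_window))
    step_window <- c(attr(trace, "stim_onset"), attr(trace, "stim_end"))
  sel <- trace$time >= step_window[1] & trace$time <= step_window[2]
  vv <- trace[[v_col]][sel]
  tt <- trace$time[sel]
  t_ss <- step_window[2] - ss_fraction * diff(step_window)
  vss <- mean(vv[tt >= t_ss])
  min(vv) - vss
}

#' Tri-exponential fit of a voltage-clamp current transient
#'
#' Least-squares fit of `I(t) = A1 exp(-t/tau1) + A2 exp(-t/tau2) +
#' A3 exp(-t/tau3) + C` to the clamp current after a voltage step,
#' with `tau1 < tau2 < tau3`.  Input capacitance is derived from the
#' displaced charge (`integral of (I - C) dt / dV`, robust to fit
#' degeneracy) and also from `sum(Ai tau_i)/dV`; input resistance from
#' the steady-state current (corrected for the access resistance); series
#' resistance as `tau1 / C_in`.
#'
#' @param trace a voltage-clamp `ubc_trace` (or data.frame with `time`
#'   and `i_clamp`).
#' @param step_onset,step_end step window, ms; default from attributes.
#' @param delta_mV step amplitude, mV; required if the trace carries no
#'   protocol attributes.
#' @param i_col clamp-current column.
#' @return list of class `ubc_passive_fit` with `A` (nA), `tau` (ms),
#'   `C` (nA), `r_in_gohm`, `c_in_pF` (charge-based), `c_in_fit_pF`,
#'   `r_s_mohm` (tau1/C_in convention), `r_s_peak_mohm` (from the
#'   instantaneous current jump), `fitted` model object.
#' @export
fit_triexponential <- function(trace, step_onset = NULL, step_end = NULL,
                               delta_mV = NULL, i_col = "i_clamp") {
  if (is.null(step_onset)) step_onset <- attr(trace, "stim_onset")
  if (is.null(step_end)) step_end <- attr(trace, "stim_end")
  if (is.null(delta_mV)) stop("delta_mV (step amplitude) is required")
  if (delta_mV == 0) stop("zero-amplitude step: no transient to fit")
  sel <- trace$time >= step_onset & trace$time <= step_end
  tt <- trace$time[sel] - step_onset
  ii <- trace[[i_col]][sel]
  window <- max(tt)
  # baseline current before the step
  pre <- trace$time < step_onset & trace$time >= step_onset - 50
  i_base <- mean(trace[[i_col]][pre])
  # late steady state as a linear trend: slow gating (H, M-type) drifts
  # the clamp current on the hundreds-of-ms scale and would otherwise
  # masquerade as displaced charge
  late <- tt >= 0.7 * window
  drift <- stats::lm(ii[late] ~ tt[late])
  i_ss_at <- function(t) stats::coef(drift)[1] + stats::coef(drift)[2] * t
  i_ss <- unname(i_ss_at(window))
  # skip the first sample (command discontinuity)
  use <- tt > 0
  tt <- tt[use]; ii <- ii[use]
  # charge displaced by the capacitive transient, integrated over an
  # early window that contains every cable mode; the baseline is a local
  # linear fit just after the window so that slow gating drift (H,
  # M-type, time constants of hundreds of ms) cancels to first order
  t_q <- min(window / 2, 40)
  qwin <- tt <= t_q
  post <- tt > t_q & tt <= min(t_q + 30, window)
  local_drift <- stats::lm(ii[post] ~ tt[post])
  base_at <- function(t) stats::coef(local_drift)[1] +
    stats::coef(local_drift)[2] * t
  di_q <- ii[qwin] - base_at(tt[qwin])
  q_pC <- sum(diff(tt[qwin]) * (utils::head(di_q, -1) + utils::tail(di_q, -1)) / 2)
  c_in_charge <- abs(q_pC / delta_mV) * 1e3          # pF
  amp0 <- ii[1] - i_ss
  start <- list(A1 = amp0 * 0.7, t1 = 0.3, A2 = amp0 * 0.2, t2 = 5,
                A3 = amp0 * 0.1, t3 = 60, C = i_ss)
  fit <- minpack.lm::nlsLM(
    ii ~ A1 * exp(-tt / t1) + A2 * exp(-tt / t2) + A3 * exp(-tt / t3) + C,
    start = start,
    lower = c(-Inf, 1e-3, -Inf, 5e-2, -Inf, 1, -Inf),
    upper = c(Inf, 2, Inf, 25, Inf, 150, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  ord <- order(cf[c("t1", "t2", "t3")])
  taus <- unname(cf[c("t1", "t2", "t3")][ord])
  amps <- unname(cf[c("A1", "A2", "A3")][ord])
  C <- unname(cf["C"])
  c_in_fit <- abs(sum(amps * taus) / delta_mV) * 1e3 # pF
  r_s <- taus[1] / c_in_charge * 1e3                 # MOhm (tau1/C_in)
  # instantaneous-jump estimate: at step onset the whole command step
  # drops across the access resistance, so Rs = dV / dI_peak; the peak is
  # extrapolated back to the onset from the first two samples because the
  # fastest (somatic) component already decays within one sample
  i1 <- ii[1] - i_base; i2 <- ii[2] - i_base
  i_jump <- if (i1 * i2 > 0 && abs(i1) > abs(i2)) i1 * i1 / i2 else i1
  r_s_peak <- abs(delta_mV / i_jump)                 # MOhm
  di <- i_ss - i_base
  r_in <- (abs(delta_mV / di) - r_s_peak) * 1e-3     # GOhm
  structure(list(A = amps, tau = taus, C = C,
                 c_in_pF = c_in_charge, c_in_fit_pF = c_in_fit,
                 r_in_gohm = r_in, r_s_mohm = r_s,
                 r_s_peak_mohm = r_s_peak,
                 i_ss = i_ss, i_base = i_base, fitted = fit),
            class = "ubc_passive_fit")
}

#' Late-onset response metrics
#'
#' Delay from train onset to the first spike, slope of the depolarising
#' ramp (linear fit between the end of the train and the first spike
#' threshold, or the whole post-train trace when no spike occurs),
#' duration (first to last spike), instantaneous frequency and spike
#' count.
#'
#' @param trace a `ubc_trace` of a train protocol.
#' @param train_onset,train_end ms; default from attributes.
#' @param v_col voltage column.
#' @return list of class `ubc_lor_metrics` (`has_lor` flags whether any
#'   late spike occurred).
#' @export
lor_metrics <- function(trace, train_onset = NULL, train_end = NULL,
                        v_col = "v_soma") {
  if (is.null(train_onset)) train_onset <- attr(trace, "stim_onset")
  if (is.null(train_end)) train_end <- attr(trace, "stim_end")
  spikes <- detect_spikes(trace, v_col = v_col, t_min = train_onset)
  n <- nrow(spikes)
  ramp_t1 <- if (n >= 1) {
    spikes$threshold_time[1]
  } else {
    # no spike: fit the depolarising phase only (up to the peak of the
    # subthreshold response), not the later decay
    post <- trace$time >= train_end
    trace$time[post][which.max(trace[[v_col]][post])]
  }
  sel <- trace$time >= train_end & trace$time <= ramp_t1
  ramp_slope <- if (sum(sel) >= 2) {
    unname(stats::coef(stats::lm(trace[[v_col]][sel] ~ trace$time[sel]))[2]) *
      1e3 # mV/ms -> mV/s
  } else NA_real_
  isi <- if (n >= 2) diff(spikes$threshold_time) else numeric(0)
  structure(list(
    has_lor = n >= 1,
    spike_count = n,
    delay = if (n >= 1) spikes$threshold_time[1] - train_onset else NA_real_,
    duration = if (n >= 2) spikes$threshold_time[n] - spikes$threshold_time[1]
               else if (n == 1) 0 else NA_real_,
    ramp_slope = ramp_slope,
    instantaneous_frequency = if (n >= 2) 1000 / isi[1] else NA_real_,
    steady_state_frequency = if (n >= 5) 1000 / isi[4] else NA_real_,
    frequency_ratio = if (n >= 5) isi[1] / isi[4] else NA_real_,
    overshoots = spikes$peak_v
  ), class = "ubc_lor_metrics")
}

#' Experimental acceptance windows
#'
#' Reference ranges of the electroresponsive and LOR parameters measured
#' in the recorded UBC populations, used by the robustness sweep.
#'
#' @return nested list with `step` and `lor` window sets, each a list of
#'   `c(min, max)` pairs.
#' @export
ubc_experimental_windows <- function() {
  list(
    step = list(first_spike_delay = c(31.1, 93.4),
                overshoot = c(15.0, 45.1),
                instantaneous_frequency = c(95.9, 202.7),
                steady_state_frequency = c(41.2, 141.8),
                frequency_ratio = c(0.61, 1.3)),
    lor = list(delay = c(98, 1000),
               duration = c(100, 2500),
               instantaneous_frequency = c(92, 209))
  )
}

#' @export
print.ubc_spike_metrics <- function(x, ...) {
  cat(sprintf(
    "spikes: %d  delay %.1f ms  overshoot %.1f mV  inst %.1f Hz  ss %.1f Hz  ratio %.3f\n",
    x$spike_count, x$first_spike_delay,
    if (length(x$overshoots)) x$overshoots[1] else NA,
    x$instantaneous_frequency, x$steady_state_frequency, x$frequency_ratio))
  invisible(x)
}

#' @export
print.ubc_lor_metrics <- function(x, ...) {
  cat(sprintf(
    "LOR: %s  spikes %d  delay %.0f ms  duration %.0f ms  ramp %.2f mV/s  inst %.1f Hz\n",
    if (x$has_lor) "yes" else "no", x$spike_count, x$delay, x$duration,
    x$ramp_slope, x$instantaneous_frequency))
  invisible(x)
}

#' @export
print.ubc_passive_fit <- function(x, ...) {
  cat(sprintf("tri-exponential fit: taus %.3g / %.3g / %.3g ms\n",
              x$tau[1], x$tau[2], x$tau[3]))
  cat(sprintf("C_in %.2f pF (charge) / %.2f pF (fit)  R_in %.3f GOhm  Rs %.1f MOhm\n",
              x$c_in_pF, x$c_in_fit_pF, x$r_in_gohm, x$r_s_mohm))
  invisible(x)
}
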