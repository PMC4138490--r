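# Synthetic trace generator: ground-truth fixtures for the analysis
# pipeline, independent of the simulator.

#' Generate synthetic analysis fixtures
#'
#' Produces deterministic (seeded) synthetic traces with known ground
#' truth, for testing the analysis functions independently of the
#' simulator.  Kinds:
#'
#' * `"spiketrain"`: baseline plus stereotyped spike waveforms at known
#'   times (truth: spike times, overshoot).
#' * `"exponential_transient"`: tri-exponential clamp current with known
#'   amplitudes/time constants plus offset (truth: A, tau, C).
#' * `"sag_trace"`: hyperpolarising response with a known trough and
#'   steady state (truth: sag amplitude).
#' * `"lor_like"`: slow depolarising ramp followed by a spike burst
#'   (truth: ramp slope, burst spike times).
#'
#' @param kind fixture kind (see above).
#' @param seed integer seed; identical seeds give identical fixtures.
#' @param dir optional directory: when given, the trace is written as CSV
#'   with a JSON ground-truth sidecar and the two paths are returned.
#' @param noise_sd observation noise s.d. (mV or nA).
#' @return list with `trace` (data.frame) and `truth` (list); when `dir`
#'   is given, also `paths`.
#' @export
generate_fixtures <- function(kind = c("spiketrain", "exponential_transient",
                                       "sag_trace", "lor_like"),
                              seed = 1, dir = NULL, noise_sd = 0) {
  kind <- match.arg(kind)
  set.seed(seed)
  fx <- switch(kind,
    spiketrain = fixture_spiketrain(noise_sd),
    exponential_transient = fixture_transient(noise_sd),
    sag_trace = fixture_sag(noise_sd),
    lor_like = fixture_lor(noise_sd))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    csv <- file.path(dir, paste0(kind, "_seed", seed, ".csv"))
    js <- file.path(dir, paste0(kind, "_seed", seed, ".json"))
    utils::write.csv(format(fx$trace, digits = 17, trim = TRUE,
                            scientific = TRUE),
                     csv, row.names = FALSE, quote = FALSE)
    jsonlite::write_json(fx$truth, js, auto_unbox = TRUE, digits = NA)
    fx$paths <- c(trace = csv, truth = js)
  }
  fx
}

spike_waveform <- function(t_rel) {
  # stylised action potential: fast rise, exponential decay, small AHP
  ifelse(t_rel < 0, 0,
    ifelse(t_rel < 0.4, 110 * (t_rel / 0.4)^2,
      110 * exp(-(t_rel - 0.4) / 0.7) - 12 * (1 - exp(-(t_rel - 0.4) / 2)) *
        exp(-(t_rel - 0.4) / 8)))
}

fixture_spiketrain <- function(noise_sd) {
  dt <- 0.025
  tt <- seq(0, 120, by = dt)
  base <- -80
  spike_times <- c(20, 26, 33.5, 42, 51.5)
  vv <- rep(base, length(tt))
  for (ts in spike_times) vv <- vv + spike_waveform(tt - ts)
  vv <- vv + stats::rnorm(length(tt), 0, noise_sd)
  list(trace = data.frame(time = tt, v_soma = vv),
       truth = list(kind = "spiketrain", spike_times = spike_times,
                    baseline = base, peak_v = base + 110))
}

fixture_transient <- function(noise_sd) {
  dt <- 0.01
  tt <- seq(0, 250, by = dt)
  A <- c(-0.45, -0.08, -0.02); tau <- c(0.35, 6, 55); C <- -0.012
  onset <- 50
  ii <- ifelse(tt < onset, 0,
               A[1] * exp(-(tt - onset) / tau[1]) +
               A[2] * exp(-(tt - onset) / tau[2]) +
               A[3] * exp(-(tt - onset) / tau[3]) + C)
  ii <- ii + stats::rnorm(length(tt), 0, noise_sd)
  tr <- data.frame(time = tt, i_clamp = ii)
  attr(tr, "stim_onset") <- onset
  attr(tr, "stim_end") <- 250
  list(trace = tr,
       truth = list(kind = "exponential_transient", A = A, tau = tau, C = C,
                    onset = onset, delta_mV = -10,
                    c_in_fit_pF = abs(sum(A * tau) / -10) * 1e3))
}

fixture_sag <- function(noise_sd) {
  dt <- 0.05
  tt <- seq(0, 1200, by = dt)
  onset <- 100; dur <- 800
  v0 <- -80; trough <- -105; steady <- -95
  rel <- tt - onset
  vv <- ifelse(rel < 0, v0,
        ifelse(rel < dur,
               v0 + (trough - v0) * (1 - exp(-rel / 20)) +
                 (steady - trough) * (1 - exp(-rel / 150)),
               steady + (v0 - steady) * (1 - exp(-(rel - dur) / 25))))
  vv <- vv + stats::rnorm(length(tt), 0, noise_sd)
  tr <- data.frame(time = tt, v_soma = vv)
  attr(tr, "stim_onset") <- onset
  attr(tr, "stim_end") <- onset + dur
  # analytic sag: minimum of the double-exponential minus its value at
  # the end of the step
  f <- function(x) v0 + (trough - v0) * (1 - exp(-x / 20)) +
    (steady - trough) * (1 - exp(-x / 150))
  xm <- stats::optimize(f, c(0, dur))$minimum
  list(trace = tr,
       truth = list(kind = "sag_trace", sag = f(xm) - f(dur),
                    onset = onset, duration = dur))
}

fixture_lor <- function(noise_sd) {
  dt <- 0.05
  tt <- seq(0, 3000, by = dt)
  train_onset <- 200; train_end <- 290
  ramp_slope <- 0.012 # mV/ms
  first_spike <- 900
  spike_times <- first_spike + c(0, 6, 13, 21, 30, 40, 52)
  vv <- rep(-80, length(tt))
  ramp <- tt >= train_end & tt < first_spike
  vv[ramp] <- -80 + ramp_slope * (tt[ramp] - train_end)
  after <- tt >= first_spike
  vv[after] <- -80 + ramp_slope * (first_spike - train_end)
  for (ts in spike_times) vv <- vv + spike_waveform(tt - ts)
  vv <- vv + stats::rnorm(length(tt), 0, noise_sd)
  tr <- data.frame(time = tt, v_soma = vv)
  attr(tr, "stim_onset") <- train_onset
  attr(tr, "stim_end") <- train_end
  list(trace = tr,
       truth = list(kind = "lor_like", train_onset = train_onset,
                    train_end = train_end, ramp_slope_mV_s = ramp_slope * 1e3,
                    spike_times = spike_times,
                    delay = first_spike - train_onset,
                    duration = max(spike_times) - min(spike_times)))
}
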