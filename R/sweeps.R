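#' Conductance robustness sweep
#'
#' Scales the maximum conductance of each listed mechanism over a grid,
#' reruns the reference depolarising-step and train protocols, and
#' records which scalings keep every measured parameter inside the
#' experimental acceptance windows.
#'
#' @param model a [ubc_model()].
#' @param mechanisms mechanisms to vary (default: all ten).
#' @param scales multiplicative grid (default `c(0.8, 1, 1.2)`).
#' @param windows acceptance windows, see [ubc_experimental_windows()].
#' @param step_pA reference step amplitude, pA.
#' @param protocols optional list with `step` and `lor` protocol
#'   overrides.
#' @param include_lor also run the train protocol at every grid point
#'   (slower); if `FALSE` only the step windows are checked.
#' @return tidy data.frame, one row per (mechanism, scale): metrics plus
#'   `inside_step`, `inside_lor`, `inside_all`.
#' @export
robustness_sweep <- function(model, mechanisms = MECH_ORDER,
                             scales = c(0.8, 1, 1.2),
                             windows = ubc_experimental_windows(),
                             step_pA = 16, protocols = NULL,
                             include_lor = TRUE) {
  p_step <- protocols$step %||% protocol_step(step_pA, 800, post_time = 200)
  p_lor <- protocols$lor %||% protocol_train(10, 100, post_time = 4000)
  rows <- list()
  for (m in mechanisms) {
    for (s in scales) {
      mod <- scale_gmax(model, m, s)
      hold <- init_steady_state(mod, p_step$holding)
      tr <- run_protocol(mod, p_step, hold = hold)
      sm <- spike_metrics(detect_spikes(tr, t_min = attr(tr, "stim_onset")),
                         attr(tr, "stim_onset"))
      row <- data.frame(mechanism = m, scale = s,
                        first_spike_delay = sm$first_spike_delay,
                        overshoot = if (length(sm$overshoots))
                          sm$overshoots[1] else NA_real_,
                        instantaneous_frequency = sm$instantaneous_frequency,
                        steady_state_frequency = sm$steady_state_frequency,
                        frequency_ratio = sm$frequency_ratio)
      row$inside_step <- metrics_inside(row, windows$step)
      if (include_lor) {
        lt <- run_protocol(mod, p_lor, hold = hold)
        lm_ <- lor_metrics(lt)
        row$lor_delay <- lm_$delay
        row$lor_duration <- lm_$duration
        row$lor_instantaneous_frequency <- lm_$instantaneous_frequency
        row$inside_lor <- lm_$has_lor &&
          inside(lm_$delay, windows$lor$delay) &&
          inside(lm_$duration, windows$lor$duration) &&
          inside(lm_$instantaneous_frequency,
                 windows$lor$instantaneous_frequency)
        row$inside_all <- row$inside_step && row$inside_lor
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  do.call(rbind, rows)
}

inside <- function(x, w) {
  if (is.na(x)) return(FALSE)
  if (diff(w) == 0) return(x == w[1])
  x >= w[1] & x <= w[2]
}

metrics_inside <- function(row, wins) {
  all(vapply(names(wins), function(nm) {
    col <- if (nm == "overshoot") "overshoot" else nm
    inside(row[[col]], wins[[nm]])
  }, logical(1)))
}

#' LOR response space
#'
#' Runs the train protocol over a grid of pulse counts and intensities
#' and maps delay, duration and instantaneous frequency of the late-onset
#' response, along with the peak normalised Y* of each run.
#'
#' @param model a [ubc_model()].
#' @param n_pulses_grid vector of pulse counts.
#' @param intensity_grid vector of intensities (omega scale, arbitrary
#'   units).
#' @param frequency_hz train frequency.
#' @param post_time simulated time after each train, ms.
#' @param hold optional precomputed [init_steady_state()] result.
#' @param dt integration step, ms.
#' @return tidy data.frame, one row per grid point.
#' @export
response_space <- function(model, n_pulses_grid, intensity_grid,
                           frequency_hz = 100, post_time = 4000,
                           hold = NULL, dt = 0.025) {
  if (!length(n_pulses_grid) || !length(intensity_grid))
    stop("empty grid")
  if (is.null(hold)) hold <- init_steady_state(model, -80)
  rows <- list()
  for (np in n_pulses_grid) {
    for (w in intensity_grid) {
      p <- protocol_train(np, frequency_hz, intensity = w,
                          post_time = post_time, dt = dt, record_dt = 0.1)
      tr <- run_protocol(model, p, hold = hold)
      lm_ <- lor_metrics(tr)
      rows[[length(rows) + 1]] <- data.frame(
        n_pulses = np, intensity = w,
        delay = lm_$delay, duration = lm_$duration,
        instantaneous_frequency = lm_$instantaneous_frequency,
        spike_count = lm_$spike_count,
        peak_y_star_norm = max(tr$y_star_norm),
        has_lor = lm_$has_lor)
    }
  }
  do.call(rbind, rows)
}
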