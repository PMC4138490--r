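# Shared, lazily computed canonical-model objects so that the expensive
# holding-current searches and reference runs happen once per test run.

.test_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.test_cache[[key]])) .test_cache[[key]] <- force(expr)
  .test_cache[[key]]
}

canonical_model <- function() memo("model", ubc_model())

canonical_hold <- function() {
  memo("hold80", init_steady_state(canonical_model(), -80))
}

# reference +16 pA / 800 ms step trace from -80 mV
canonical_step_trace <- function() {
  memo("step16", run_protocol(
    canonical_model(),
    protocol_step(16, 800, pre_time = 200, post_time = 100),
    hold = canonical_hold()))
}

canonical_step_metrics <- function() {
  tr <- canonical_step_trace()
  spike_metrics(detect_spikes(tr, t_min = attr(tr, "stim_onset")),
                attr(tr, "stim_onset"))
}

# canonical 10-pulse 100 Hz train, 5 s follow-up
canonical_lor_trace <- function() {
  memo("lor", run_protocol(
    canonical_model(),
    protocol_train(10, 100, post_time = 5000, record_dt = 0.2),
    hold = canonical_hold()))
}

blocked_lor_trace <- function(mechs) {
  key <- paste0("lor_", paste(sort(mechs), collapse = "_"))
  memo(key, {
    mb <- apply_channel_block(canonical_model(), mechs)
    run_protocol(mb,
                 protocol_train(10, 100, post_time = 5000, record_dt = 0.2),
                 hold = init_steady_state(mb, -80))
  })
}
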