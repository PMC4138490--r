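# Canonical unipolar brush cell model configuration.
#
# Units: lengths um, conductance densities S/cm2 (CaLVA permeability cm/s),
# potentials mV, rates 1/ms unless noted.  Per-compartment channel placement
# is expressed as density multipliers applied to the tabulated maximum
# density; multipliers were calibrated against the reference
# electroresponsive measurements (first-spike delay, overshoot,
# instantaneous and steady-state frequency, sag, resting potential).
name: ubc_canonical
temperature_c: 30
morphology:
  soma: {diam_um: 8.0}
  shaft: {length_um: 50.0, diam_um: 2.0, area_scale: 1.0}
  # brush membrane is folded dendrioles: effective area exceeds the
  # equivalent cylinder; scale set so brush + shaft capacitance = 12.7 pF
  brush: {length_um: 25.25, diam_um: 10.0, area_scale: 1.20497}
  ais: {n_sections: 5, length_um: 0.5, diam_first_um: 3.2, diam_last_um: 0.8}
  # axon area scaled so that AIS + axon capacitance totals 2 pF
  axon: {n_sections: 5, length_um: 80.0, diam_um: 0.5, area_scale: 0.29333}
  pipette: {access_resistance_mohm: 20.0}
mechanisms:
  leak:
    gmax: 2.75e-5
    erev: -70.0
    q10: 3.0
    t_exp: 30.0
    density: {soma: 1.0, shaft: 1.0, brush: 1.0, ais: 1.0, axon: 1.0}
  trp:
    gmax: 1.2e-5
    erev: 0.0
    baseline: 0.16
    q10: 3.0
    t_exp: 30.0
    density: {soma: 1.0, shaft: 1.0, brush: 1.0}
  h:
    gmax: 5.72e-4
    erev: -30.0
    q10: 3.0
    t_exp: 30.0
    vhalf: -91.5
    slope: 7.7
    # activation time constant: calibrated bell (tau ~180 ms at -130 mV,
    # ~630 ms at -90 mV); the printed closed form is selectable via
    # tau_mode: printed
    tau_mode: calibrated
    tau_a: 8.1e-4
    tau_ka: 20.0
    tau_b: 7.8e-4
    tau_kb: 20.0
    tau_scale: 1.0
    density: {soma: 1.0}
  na:
    gmax: 0.192
    erev: 63.0
    q10: 3.0
    t_exp: 22.0
    density: {soma: 1.2, ais: 3.0, axon: 0.02}
    markov:
      # canonical resurgent-scheme rate constants; v_shift offsets the
      # voltage-dependent rates (adapted to fit: restores a silent rest
      # by trimming the subthreshold persistent component)
      v_shift: 5.0
      alpha_a: 150.0
      valpha: 20.0
      beta_a: 3.0
      vbeta: 20.0
      gamma: 150.0
      delta: 40.0
      epsilon: 1.75
      zeta_a: 0.03
      vzeta: 25.0
      Con: 0.005
      Coff: 0.5
      Oon: 0.75
      Ooff: 0.005
  kv:
    gmax: 6.75e-4
    erev: -84.69
    q10: 3.0
    t_exp: 30.0
    # activation time-constant scale and placement multipliers tuned to
    # balance spike repolarisation against the resurgent Na current
    taum_scale: 0.1
    tauh_scale: 1.0
    density: {soma: 310.0, ais: 310.0, axon: 310.0}
  ka:
    gmax: 0.007
    erev: -84.69
    q10: 3.0
    t_exp: 24.0
    density: {brush: 1.3, shaft: 1.3, soma: 1.3}
  kca:
    gmax: 0.0052
    erev: -84.69
    q10: 3.0
    t_exp: 30.0
    density: {brush: 0.9, shaft: 0.9, soma: 0.9}
  kslow:
    gmax: 8.0e-4
    erev: -84.69
    q10: 3.0
    t_exp: 30.0
    density: {brush: 0.5, shaft: 0.5, soma: 0.5}
  cahva:
    gmax: 2.15e-4
    q10: 3.0
    t_exp: 30.0
    density: {brush: 4.0, shaft: 4.0, soma: 4.0}
  calva:
    perm: 6.3e-5
    q10: 5.0
    q10_inact: 3.0
    t_exp: 30.0
    # inactivation tau scale < 1: the burst rides the decaying phase of
    # the low-threshold spike
    tauh_scale: 0.62
    density: {brush: 3.8, shaft: 1.2, soma: 1.2}
calcium:
  depth_nm: 200.0
  beta_ca: 1.5
  ca_rest_mM: 1.0e-4
  e_ca_init_mV: 129.33
  shells: [soma, shaft, brush]
cascade:
  # per-pulse drive increment (1/ms) and window (ms)
  omega: 2.0e-3
  tau: 100.0
  # X* -> X backward rate
  beta: 1.5e-3
  x_total: 4.0
  x_half: 2.7
  k: 0.75
  # Y* <-> Y rates; y_total in the range of neuronal ATP content
  gamma: 1.5e-3
  y_total: 5.0
  delta_max: 3.0e-2
  trp_baseline: 0.16
  h_shift_max: 25.0
  h_shift_mid: 0.6
  h_shift_slope: 0.1
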