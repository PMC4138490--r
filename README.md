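# ubcsim

Biophysical simulation of the cerebellar **unipolar brush cell** (UBC),
the excitatory interneuron of the vestibulo-cerebellar granular layer
that receives a giant mossy-fiber synapse on its dendritic brush.

UBCs are silent at rest near −67.5 mV but generate a rich burst
repertoire: a low-threshold calcium spike (LTS) crowned by a
high-frequency sodium burst when depolarised from hyperpolarised
potentials, a sag and rebound around hyperpolarising steps, and — after
synaptic train stimulation with ionotropic receptors blocked — a
**late-onset response** (LOR): a slow depolarising ramp followed by a
delayed spike burst, produced by an intracellular cascade that modulates
H- and TRP-channel gating.  `ubcsim` is a tool for simulating and
analysing these behaviours in a single, fully specified model cell.

## The model

A 13-compartment cable model (soma, dendritic shaft, brush, five
axon-initial-segment and five axonal sections; 16.7 pF total) with ten
ionic mechanisms per the Hodgkin–Huxley / Markov formalism:

$$C_m \frac{dV}{dt} = -\sum_i g_i (V - V_i) - I_{axial} + i_{inj}$$

* leak and TRP background conductances (TRP reversal 0 mV);
* H current (HCN; half-activation −91.5 mV, slope 7.7 mV);
* a 13-state Markov Na scheme with transient, persistent and resurgent
  components;
* delayed-rectifier, A-type, BK-type (calcium-dependent) and M-type
  potassium currents;
* L-type (ohmic, runtime calcium reversal) and T-type (GHK permeation)
  calcium currents;
* sub-membrane calcium shells,
  $d[\mathrm{Ca}]/dt = -I_{Ca}/(2FAd) - \beta_{Ca}([\mathrm{Ca}]-[\mathrm{Ca}]_0)$,
  with the T-type flux deliberately excluded from the pool;
* a two-stage second-messenger cascade
  $X \rightleftharpoons X^{*}$, $Y \rightleftharpoons Y^{*}$ driven by
  synaptic pulse trains, whose normalised $Y^{*}$ scales the TRP maximum
  conductance ($0.16 + Y^{*}$) and shifts the H activation curve from
  −91.5 toward −66.5 mV — the LOR generator.

The integrator (backward Euler with staggered exponential gate updates
and an implicit Markov solve, dt = 0.025 ms) is compiled C++; model
structure, protocols and analysis live in R.  The canonical parameter
set ships as a YAML configuration (`inst/extdata/ubc-canonical.yaml`).
See the methods vignette (`vignettes/ubc-model.Rmd`) for the science and
every design decision.

## Worked example

```r
library(ubcsim)

m <- ubc_model()
#> UBC model: 13 compartments, 16.71 pF total capacitance

hold <- init_steady_state(m, -80)   # bias current holding the soma at -80 mV
round(hold$holding_current * 1e3, 1)
#> [1] -17.2                          # pA

## +16 pA, 800 ms current step: LTS-triggered burst
tr <- run_protocol(m, protocol_step(16, 800), hold = hold)
spike_metrics(detect_spikes(tr, t_min = attr(tr, "stim_onset")),
              attr(tr, "stim_onset"))
#> spikes: 7  delay 40.6 ms  overshoot 39.4 mV  inst 171.7 Hz  ss 132.0 Hz  ratio 0.769

## canonical synaptic train (10 pulses at 100 Hz): the late-onset response
lor <- run_protocol(m, protocol_train(10, 100), hold = hold)
lor_metrics(lor)
#> LOR: yes  spikes 11  delay 225 ms  duration 886 ms  ramp 112.12 mV/s  inst 113.0 Hz
```

The step metrics are the standard burst descriptors: delay from step
onset to the first 5 mV/ms threshold crossing, peak overshoot,
instantaneous (1/ISI1) and steady-state (1/ISI4) frequency and their
ratio.  The LOR fires about a quarter of a second *after* the train —
the signature of the cascade pathway rather than of direct synaptic
current (pulses here carry no electrical charge at all).

In-silico pharmacology is one call away:

```r
no_trp <- apply_channel_block(m, "trp")
lor_metrics(run_protocol(no_trp, protocol_train(10, 100)))
# -> no full LOR; only a subthreshold depolarisation carried by H remains
```

A thin command-line front end (`inst/exec/ubcsim`) exposes the same
protocols (`ubcsim run --protocol lor --pulses 10 --freq 100`), the
robustness/response-space sweeps and the synthetic fixture generator.

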