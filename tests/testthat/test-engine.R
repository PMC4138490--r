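# Integration-scheme oracles: analytic RC circuits, an independent ODE
# solver, conservation laws and determinism.

# single passive compartment as a raw engine structure (2 pF, leak only)
passive_engine <- function(g_leak_uS = 2e-4, e_leak = -70, cap_nF = 2e-3) {
  canon <- ubc_model()$engine
  mechs <- lapply(canon$mechs, function(m) { m$g_abs[] <- 0; m })
  mechs[[1]]$g_abs <- c(g_leak_uS, rep(0, 12))
  en <- canon
  en$cap <- c(cap_nF, canon$cap[-1])
  en$g_axial[] <- 0 # decouple: soma alone carries the leak
  en$mechs <- mechs
  en
}

run_engine <- function(en, ...) {
  ubcsim:::.run_ubc_engine(en, ubcsim:::engine_proto(...))
}

test_that("single-compartment passive response matches the analytic RC solution", {
  g <- 2e-4; C <- 2e-3 # uS, nF: tau = C/g = 10 ms
  en <- passive_engine(g_leak_uS = g, cap_nF = C)
  I <- 0.01 # nA
  out <- run_engine(en, dt = 0.002, t_total = 60, record_dt = 0.01,
                    v_init = -70, i_bias = 0,
                    steps = matrix(c(10, 60, I), 1))
  tt <- out$time
  v <- out$v[, 1]
  tau <- C / g
  expected <- ifelse(tt < 10, -70, -70 + I / g * (1 - exp(-(tt - 10) / tau)))
  # < 0.1% of the 50 mV excursion
  expect_lt(max(abs(v - expected)), 0.001 * (I / g))
})

test_that("dt refinement of the passive model converges below 0.01 mV", {
  en <- passive_engine()
  run_at <- function(dt) run_engine(en, dt = dt, t_total = 50,
                                    record_dt = 0.1, v_init = -70,
                                    i_bias = 0,
                                    steps = matrix(c(5, 50, 0.02), 1))$v[, 1]
  v1 <- run_at(0.01)
  v2 <- run_at(0.005)
  expect_lt(max(abs(v1 - v2)), 0.01)
  # first-order scheme: the refinement gap shrinks linearly with dt
  v0 <- run_at(0.02)
  expect_lt(max(abs(v1 - v2)), 0.75 * max(abs(v0 - v1)))
})

test_that("engine gating agrees with an independent ODE solver (H current)", {
  skip_if_not_installed("deSolve")
  # one compartment with leak + H, step hyperpolarisation; reference
  # solution via lsoda on the same equations written independently in R
  g_leak <- 2e-4; g_h <- 4e-4; C <- 2e-3
  en <- passive_engine(g_leak_uS = g_leak, cap_nF = C)
  en$mechs[[3]]$g_abs <- c(g_h, rep(0, 12)) # H at soma
  I <- -0.015
  out <- run_engine(en, dt = 0.01, t_total = 1500, record_dt = 1,
                    v_init = -70, i_bias = 0,
                    steps = matrix(c(0, 1500, I), 1))
  hp <- ubc_config()$mechanisms$h
  rhs <- function(t, y, parms) {
    v <- y[1]; l <- y[2]
    k <- gate_kinetics("h", v, h_pars = hp)
    i_leak <- g_leak * (v + 70)
    i_h <- g_h * l * (v + 30)
    list(c(-(i_leak + i_h - I) / C, (k$inf - l) / k$tau))
  }
  l0 <- gate_kinetics("h", -70, h_pars = hp)$inf
  ref <- deSolve::lsoda(c(v = -70, l = l0), seq(0, 1500, by = 1), rhs,
                        NULL, rtol = 1e-8, atol = 1e-10)
  # staggered gate updates introduce a first-order coupling error of a
  # few hundredths of a millivolt at this step size
  expect_lt(max(abs(out$v[, 1] - ref[, "v"])), 0.1)
  # the sag should be present in both (H activates during the step)
  expect_gt(out$v[nrow(ref), 1], min(out$v[, 1]) + 0.5)
})

test_that("Markov occupancies stay normalised through a spiking protocol", {
  m <- ubc_model()
  hold <- init_steady_state(m, -80)
  tr <- run_protocol(m, protocol_step(16, 300, pre_time = 100,
                                      post_time = 50), hold = hold)
  expect_lt(attr(tr, "max_occupancy_error"), 1e-8)
  expect_gt(nrow(detect_spikes(tr, t_min = 100)), 0) # protocol did spike
})

test_that("identical configuration and protocol give bit-identical traces", {
  m <- ubc_model()
  hold <- init_steady_state(m, -80)
  p <- protocol_step(16, 150, pre_time = 50, post_time = 20)
  t1 <- run_protocol(m, p, hold = hold)
  t2 <- run_protocol(m, p, hold = hold)
  expect_identical(t1$v_soma, t2$v_soma)
  expect_identical(t1$ca_soma, t2$ca_soma)
  expect_identical(attr(t1, "config_hash"), attr(t2, "config_hash"))
})

test_that("steady state satisfies Kirchhoff consistency in every compartment", {
  m <- ubc_model()
  hold <- init_steady_state(m, -80)
  # long extra relaxation so even slow gates are stationary
  res <- ubcsim:::.run_ubc_engine(m$engine, ubcsim:::engine_proto(
    dt = 0.1, t_total = 20000, record_dt = 20000, v_init = -80,
    i_bias = hold$holding_current, init_state = hold$state))
  mc <- membrane_currents(m, res$final_state,
                          i_inj_soma = hold$holding_current)
  expect_lt(max(abs(mc$residual)), 1e-4)
})

test_that("blocking nothing reproduces the control trace exactly", {
  m <- ubc_model()
  hold <- init_steady_state(m, -80)
  p <- protocol_step(16, 100, pre_time = 20, post_time = 10)
  t1 <- run_protocol(m, p, hold = hold)
  t2 <- run_protocol(apply_channel_block(m, character(0)), p, hold = hold)
  expect_identical(t1$v_soma, t2$v_soma)
})

test_that("convergence check runs and reports stable spike counts", {
  m <- ubc_model()
  p <- protocol_step(16, 120, pre_time = 60, post_time = 20)
  rep_ <- convergence_check(m, p, c(0.05, 0.025))
  expect_equal(nrow(rep_), 1)
  expect_true(rep_$spikes_coarse == rep_$spikes_fine)
  expect_error(convergence_check(m, p, 0.025), "two")
})

test_that("voltage-clamp transient recovers the configured access resistance", {
  # passive cell (active conductances zeroed): the instantaneous clamp
  # current jump equals dV/Rs
  m <- ubc_model()
  for (k in seq_along(m$engine$mechs))
    if (!m$engine$mechs[[k]]$name %in% c("leak"))
      m$engine$mechs[[k]]$g_abs[] <- 0
  tr <- run_protocol(m, protocol_vstep(-10, 250, holding = -70,
                                       pre_time = 200, dt = 0.005))
  ft <- fit_triexponential(tr, delta_mV = -10)
  rs_cfg <- m$morphology$pipette$access_resistance_mohm
  expect_lt(abs(ft$r_s_peak_mohm - rs_cfg) / rs_cfg, 0.10)
  # displaced charge accounts for the full membrane capacitance
  expect_equal(ft$c_in_pF, sum(m$engine$cap) * 1e3, tolerance = 0.08)
})
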