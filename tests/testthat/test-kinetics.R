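test_that("Q10 factor follows the defining relation", {
  expect_equal(q10_factor(3, 30, 30), 1)
  expect_equal(q10_factor(3, 40, 30), 3)
  expect_equal(q10_factor(5, 20, 30), 0.2)
  expect_error(q10_factor(-1, 30, 30))
})

test_that("H-gate steady state hits its half-activation and slope", {
  expect_equal(gate_steady_state("h", -91.5), 0.5, tolerance = 1e-12)
  # one slope factor above the midpoint: 1/(1+e)
  expect_equal(gate_steady_state("h", -91.5 + 7.7), 1 / (1 + exp(1)),
               tolerance = 1e-12)
  # stated 10% point lies at midpoint + slope*ln(9)
  expect_equal(gate_steady_state("h", -91.5 + 7.7 * log(9)), 0.1,
               tolerance = 1e-10)
})

test_that("calibrated H time constant matches its two anchor points", {
  k <- gate_kinetics("h", -130)
  expect_equal(k$tau, 180, tolerance = 0.05 * 180)
  k <- gate_kinetics("h", -90)
  expect_equal(k$tau, 630, tolerance = 0.05 * 630)
  # printed mode remains available and differs
  hp <- ubc_config()$mechanisms$h
  hp$tau_mode <- "printed"
  k_printed <- gate_kinetics("h", -130, h_pars = hp)
  expect_lt(k_printed$tau, 20)
})

test_that("KV activation midpoint is -24 mV", {
  k <- gate_kinetics("kv", -24)
  expect_equal(k$inf[k$gate == "m"], 0.5, tolerance = 1e-12)
})

test_that("gate steady states are monotone in voltage", {
  v <- seq(-120, 60, by = 1)
  direction <- list(
    kv = c(m = 1, h = -1), ka = c(a = 1, b = -1),
    kslow = c(n = 1), cahva = c(s = 1, u = -1),
    calva = c(m = 1, h = -1), h = c(l = -1))
  for (mech in names(direction)) {
    for (g in names(direction[[mech]])) {
      inf <- vapply(v, function(vv) {
        k <- gate_kinetics(mech, vv)
        k$inf[k$gate == g]
      }, numeric(1))
      d <- diff(inf) * direction[[mech]][g]
      expect_true(all(d >= -1e-12),
                  info = sprintf("%s gate %s not monotone", mech, g))
      expect_true(all(inf >= 0 & inf <= 1))
    }
  }
})

test_that("gate time constants are positive over the physiological range", {
  v <- seq(-120, 60, by = 2.5)
  for (mech in c("kv", "ka", "kslow", "cahva", "calva", "h")) {
    taus <- vapply(v, function(vv) min(gate_kinetics(mech, vv)$tau),
                   numeric(1))
    expect_true(all(taus > 0), info = mech)
  }
})

test_that("KCa rates respond to calcium as expected", {
  # saturating calcium: alpha -> 2.5
  expect_equal(kca_rates(0, 1e6)$alpha, 2.5, tolerance = 1e-4)
  # vanishing calcium: alpha -> 0
  expect_lt(kca_rates(0, 1e-9)$alpha, 1e-5)
  # at v = 0 and ca = 1.5e-3 the exponential term is 1: alpha = 2.5/2
  expect_equal(kca_rates(0, 1.5e-3)$alpha, 1.25, tolerance = 1e-12)
  # alpha increases and beta decreases with calcium
  a <- kca_rates(-40, c(1e-4, 1e-3, 1e-2))
  expect_true(all(diff(a$alpha) > 0))
  expect_true(all(diff(a$beta) < 0))
  expect_error(kca_rates(0, 0))
})

test_that("ohmic current law: zero at reversal, closed at zero gates, outward positive", {
  expect_equal(channel_current(0.01, 100, 0.5, 1, v = -84.69, e_rev = -84.69), 0)
  expect_equal(channel_current(0.01, 100, 0, 3, v = 0, e_rev = -84.69), 0)
  # leak-like: depolarised above reversal gives outward (positive) current
  expect_gt(channel_current(2.1e-5, 201, 1, 1, v = -60, e_rev = -70), 0)
})

test_that("GHK calcium current is continuous at v = 0 and has the right asymptotes", {
  # equal concentrations at v = 0: equilibrium, no flux
  expect_equal(ghk_ca_current(6.3e-5, 0, 2, 2), 0, tolerance = 1e-15)
  # continuity across the removable singularity
  eps <- 1e-9
  i_minus <- ghk_ca_current(6.3e-5, -eps, 1e-4, 2)
  i_plus <- ghk_ca_current(6.3e-5, eps, 1e-4, 2)
  i_zero <- ghk_ca_current(6.3e-5, 0, 1e-4, 2)
  expect_lt(abs(i_plus - i_minus), 1e-9 * abs(i_zero) + 1e-12)
  # large negative v with ca_out >> ca_in: inward, proportional to ca_out
  i1 <- ghk_ca_current(6.3e-5, -120, 1e-4, 2)
  i2 <- ghk_ca_current(6.3e-5, -120, 1e-4, 4)
  expect_lt(i1, 0)
  expect_equal(i2 / i1, 2, tolerance = 1e-3)
  expect_error(ghk_ca_current(6.3e-5, 0, -1, 2))
})

test_that("independent GHK evaluation agrees with the packaged one", {
  # direct transcription of the flux equation, written separately
  ghk_direct <- function(P, v, ci, co, temp = 30) {
    z <- 2; FF <- 96485.332; R <- 8.314462618; TK <- temp + 273.15
    E <- v / 1000
    num <- z^2 * FF^2 * E / (R * TK) *
      (ci * 1e-6 - co * 1e-6 * exp(-z * FF * E / (R * TK))) /
      (1 - exp(-z * FF * E / (R * TK)))
    P * num * 1e3
  }
  for (v in c(-90, -50, -10, 0.5, 25)) {
    expect_equal(ghk_ca_current(6.3e-5, v, 1e-4, 2),
                 ghk_direct(6.3e-5, v, 1e-4, 2), tolerance = 1e-8)
  }
})

test_that("Markov Na rate matrix conserves probability and has valid rates", {
  for (v in c(-100, -60, -30, 0, 40)) {
    A <- markov_na_rates(v)
    off <- A; diag(off) <- 0
    expect_true(all(off >= 0), info = paste("v =", v))
    expect_true(all(abs(colSums(A)) < 1e-10), info = paste("v =", v))
  }
  s <- markov_na_stationary(-80)
  expect_equal(sum(s), 1, tolerance = 1e-12)
  expect_true(all(s >= 0))
  # at -80 the channel should be mostly closed/inactivated, rarely open
  expect_lt(s["O"], 1e-3)
})

test_that("Q10 scaling leaves the stationary distribution unchanged", {
  s1 <- markov_na_stationary(-60, q = 1)
  s2 <- markov_na_stationary(-60, q = 3)
  expect_equal(s1, s2, tolerance = 1e-10)
})

test_that("Markov scheme produces a resurgent open-state transient", {
  # depolarise to +30 for 20 ms, then repolarise to -40: open occupancy
  # should rise transiently above its -40 steady state as blocked
  # channels reopen
  pars <- na_markov_params()
  q <- q10_factor(3, 30, 22)
  evolve <- function(s, v, t_ms, dt = 0.005) {
    A <- markov_na_rates(v, pars, q)
    M <- diag(13) - dt * A
    for (i in seq_len(round(t_ms / dt))) s <- solve(M, s)
    s
  }
  s <- markov_na_stationary(-80, pars, q)
  s <- evolve(s, 30, 20)
  expect_gt(s["B"], 0.2) # most open channels blocked at +30
  # track O during repolarisation
  A <- markov_na_rates(-40, pars, q)
  dt <- 0.005
  M <- diag(13) - dt * A
  o_traj <- numeric(800)
  for (i in seq_len(800)) { s <- solve(M, s); o_traj[i] <- s["O"] }
  o_ss <- markov_na_stationary(-40, pars, q)["O"]
  expect_gt(max(o_traj), 2 * o_ss) # transient resurgent peak
  expect_gt(which.max(o_traj), 5)  # not instantaneous
})
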