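# Master-equation kinetics: generator structure, detailed balance,
# stationarity, relaxation and regime switching.

test_that("generators conserve probability and satisfy detailed balance", {
  r <- rate_rules()
  for (p in random_params(25, seed = 31)) {
    V <- runif(1, -150, 200)
    T_K <- celsius_to_kelvin(runif(1, 5, 60))
    Q <- build_generator(p, r, V, T_K)
    expect_lt(max(abs(rowSums(Q))), 1e-8 * max(abs(Q)))
    w <- state_weights(V, T_K, p)
    flux <- outer(w, rep(1, 8)) * Q
    expect_lt(max(abs(flux - t(flux))), 1e-10 * max(abs(flux)))
    # stationarity of the analytic weights
    expect_lt(max(abs(as.numeric(w %*% Q))), 1e-8 * max(abs(Q)))
  }
})

test_that("symmetric neutral parameters give equal gate rates", {
  p <- gating_parameters(L = 1, K0 = 1, z = 0, dH = 0, dS = 0, dHc = 0,
                         dSc = 0, D = 1, E = 1)
  Q <- build_generator(p, rate_rules(k_gate = 100, phi = 0.5), 0, 298.15)
  gate_pairs <- cbind(1:4, 5:8)
  expect_equal(unname(Q[gate_pairs]), rep(100, 4))
  expect_equal(unname(Q[gate_pairs[, 2:1]]), rep(100, 4))
})

test_that("per-class phi shapes the rate split without breaking equilibrium", {
  p <- regime_parameters("blue")
  r <- rate_rules(phi = c(gate = 0.5, vsensor = 1, tsensor = 0.3))
  Q <- build_generator(p, r, -70, 298.15)
  w <- state_weights(-70, 298.15, p)
  flux <- outer(w, rep(1, 8)) * Q
  expect_lt(max(abs(flux - t(flux))), 1e-10 * max(abs(flux)))
  # phi = 1: deactivating voltage-sensor rate pinned at the reference rate
  expect_equal(Q["C10", "C00"], r$k_vsensor)
})

test_that("simulation is stationary at equilibrium and converges from off-equilibrium", {
  p <- regime_parameters("blue")
  r <- rate_rules()
  pr <- stimulus_protocol(data.frame(duration_s = 0.5, voltage_mV = 60,
                                     temp_start_C = 30, temp_end_C = 30),
                          dt = 1e-3)
  eq <- simulate_gating(p, r, pr, initial = "equilibrium")
  expect_lt(max(abs(sweep(eq$occupancy, 2, eq$occupancy[1, ]))), 1e-9)

  tr <- simulate_gating(p, r, pr, initial = c(1, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(tail(tr$po, 1),
               open_probability(60, celsius_to_kelvin(30), p),
               tolerance = 1e-8)
  expect_lt(max(abs(rowSums(tr$occupancy) - 1)), 1e-9)
})

test_that("the two-state limit relaxes at the analytic rate", {
  L <- 0.7
  p <- gating_parameters(L = L, K0 = 0.003, z = 0.74, dH = 91, dS = 0.317,
                         dHc = 0, dSc = 0, D = 1, E = 1)
  k_gate <- 40
  r <- rate_rules(k_gate = k_gate, k_vsensor = 1e5, k_tsensor = 1e5,
                  phi = 0.5)
  pr <- stimulus_protocol(data.frame(duration_s = 0.4, voltage_mV = 0,
                                     temp_start_C = 25, temp_end_C = 25),
                          dt = 5e-4)
  tr <- simulate_gating(p, r, pr, initial = c(1, 0, 0, 0, 0, 0, 0, 0))
  po_inf <- L / (1 + L)
  fit <- fit_relaxation(tr$time_s * 1000, (po_inf - tr$po) * 1000,
                        n_components = 1, dead_time = 1)
  analytic <- k_gate * (L^0.5 + L^(-0.5))
  expect_equal(1000 / fit$tau_fast, analytic, tolerance = 1e-4)
})

test_that("probability is conserved over long simulations", {
  p <- regime_parameters("blue")
  pr <- protocol_temperature("staircase", dt = 0.005)
  tr <- simulate_gating(p, rate_rules(), pr)
  expect_gt(length(tr$time_s), 5000)
  expect_lt(max(abs(rowSums(tr$occupancy) - 1)), 1e-9)
})

test_that("halving dt barely changes ramp-protocol endpoints", {
  p <- regime_parameters("blue")
  r <- rate_rules()
  mk <- function(dt) stimulus_protocol(
    data.frame(duration_s = c(0.2, 1.0, 0.2),
               voltage_mV = 80,
               temp_start_C = c(25, 25, 60),
               temp_end_C = c(25, 60, 60)), dt = dt)
  a <- simulate_gating(p, r, mk(0.002))
  b <- simulate_gating(p, r, mk(0.001))
  expect_lt(max(abs(tail(a$occupancy, 1) - tail(b$occupancy, 1))), 1e-5)
})

test_that("occupancy is continuous across a regime switch", {
  regs <- list(blue = regime_parameters("blue"),
               green = regime_parameters("green"))
  pr <- stimulus_protocol(data.frame(duration_s = c(1, 0.5, 1),
                                     voltage_mV = -70,
                                     temp_start_C = c(10, 62, 10),
                                     temp_end_C = c(10, 62, 10)),
                          dt = 0.01)
  tr <- simulate_regimes(regs, regime_schedule(list(
    list(regime = "green", T_min = 60, dwell_s = 0))),
    rate_rules(), pr)
  expect_setequal(unique(tr$regime), c("blue", "green"))
  k <- which(tr$regime == "green")[1]
  # one propagation step across the switch: occupancy changes by O(dt * rate)
  expect_lt(max(abs(tr$occupancy[k, ] - tr$occupancy[k - 1, ])), 0.2)
  expect_lt(max(abs(rowSums(tr$occupancy) - 1)), 1e-9)
})

test_that("schedules validate their regime references and conditions", {
  expect_error(regime_schedule(list(list(regime = "x"))), "no condition")
  expect_error(regime_schedule(list(list(regime = "a", T_min = 60),
                                    list(regime = "a", V_min = 0))),
               "one latch")
  regs <- list(blue = regime_parameters("blue"))
  pr <- stimulus_protocol(data.frame(duration_s = 0.1, voltage_mV = 0,
                                     temp_start_C = 25, temp_end_C = 25),
                          dt = 0.01)
  expect_error(simulate_regimes(regs, regime_schedule(), rate_rules(), pr),
               "undefined regime")
  # no triggers fired: identical to a plain simulation
  tr1 <- simulate_regimes(regs, NULL, rate_rules(), pr)
  tr2 <- simulate_gating(regime_parameters("blue"), rate_rules(), pr)
  expect_equal(tr1$occupancy, tr2$occupancy)
})

test_that("current conversion is ohmic", {
  p <- regime_parameters("blue")
  pr <- stimulus_protocol(data.frame(duration_s = 0.05, voltage_mV = -70,
                                     temp_start_C = 25, temp_end_C = 25),
                          dt = 0.01)
  tr <- simulate_gating(p, rate_rules(), pr)
  tr$po <- rep(0.5, length(tr$po))
  expect_equal(occupancy_to_current(tr, N = 100, g = 0.1, Vrev = 0),
               rep(-350, length(tr$po)))
  expect_equal(occupancy_to_current(tr, N = 100, g = 0.1, Vrev = -70),
               rep(0, length(tr$po)))
  tr$po <- rep(0, length(tr$po))
  expect_equal(occupancy_to_current(tr), rep(0, length(tr$po)))
})

test_that("protocol validation catches bad inputs", {
  expect_error(stimulus_protocol(data.frame(duration_s = 0.1,
                                            voltage_mV = 0,
                                            temp_start_C = 5,
                                            temp_end_C = 60), dt = 0.01),
               "slew")
  expect_error(stimulus_protocol(data.frame(duration_s = 0.01,
                                            voltage_mV = 0,
                                            temp_start_C = 25,
                                            temp_end_C = 25), dt = 0.1),
               "shortest segment")
  expect_error(stimulus_protocol(data.frame(duration_s = -1,
                                            voltage_mV = 0,
                                            temp_start_C = 25,
                                            temp_end_C = 25), dt = 0.1),
               "durations")
})
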