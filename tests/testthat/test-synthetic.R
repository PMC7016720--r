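# Synthetic whole-cell recording generator and presets.

test_that("noise-free synthetic current equals the analytic ohmic value", {
  p <- transform_params(regime_parameters("blue"), D = 1, E = 1,
                        dHc = 0, dSc = 0, L = 1)   # Po = 0.5 everywhere
  pr <- stimulus_protocol(data.frame(duration_s = 0.2, voltage_mV = -70,
                                     temp_start_C = 25, temp_end_C = 25),
                          dt = 1e-3)
  spec <- recording_spec(N = 100, g = 0.1, noise_sd = 0, sample_rate_kHz = 1,
                         filter_cutoff_kHz = 0.25)
  rec <- synthesize_recording(p, pr, rate_rules(), spec)
  expect_equal(unique(round(rec$current_pA, 9)), -350)
})

test_that("the generator is seeded and bit-reproducible", {
  pr <- protocol_voltage_steps("A", dt = 1e-3)
  spec <- recording_spec(noise_sd = 5, sample_rate_kHz = 1,
                         filter_cutoff_kHz = 0.25, seed = 42)
  h <- orthologue_presets("hTRPA1")
  r1 <- synthesize_recording(h$params, pr, h$rates, spec)
  r2 <- synthesize_recording(h$params, pr, h$rates, spec)
  expect_identical(r1$current_pA, r2$current_pA)
  spec2 <- recording_spec(noise_sd = 5, sample_rate_kHz = 1,
                          filter_cutoff_kHz = 0.25, seed = 43)
  r3 <- synthesize_recording(h$params, pr, h$rates, spec2)
  expect_false(identical(r1$current_pA, r3$current_pA))
})

test_that("G-V analysis of a synthetic variant-A recording recovers the landscape", {
  h <- orthologue_presets("hTRPA1")
  pr <- protocol_voltage_steps("A", temp_C = 25, dt = 5e-4)
  spec <- recording_spec(noise_sd = 0, sample_rate_kHz = 2,
                         filter_cutoff_kHz = 0.5)
  rec <- synthesize_recording(h$params, pr, h$rates, spec)
  gv <- measure_gv(rec)
  po <- open_probability(gv$voltage_mV, celsius_to_kelvin(25), h$params)
  gnorm <- gv$conductance / (spec$N * spec$g)
  expect_lt(max(abs(gnorm - po)), 0.03)
  # and with 1% noise the Boltzmann midpoint is still recovered closely
  spec_n <- recording_spec(noise_sd = 0.01 * max(abs(rec$current_pA)),
                           sample_rate_kHz = 2, filter_cutoff_kHz = 0.5,
                           seed = 7)
  rec_n <- synthesize_recording(h$params, pr, h$rates, spec_n)
  gv_n <- measure_gv(rec_n)
  fit0 <- fit_boltzmann(gv$voltage_mV, gv$conductance, 298.15)
  fit_n <- fit_boltzmann(gv_n$voltage_mV, gv_n$conductance, 298.15)
  expect_lt(abs(fit_n$V50 - fit0$V50), 5)
})

test_that("orthologue presets reproduce the documented contrasts", {
  h <- orthologue_presets("hTRPA1")
  m <- orthologue_presets("mTRPA1")
  # open-shifted equilibrium: larger basal fraction of Gmax at -150 mV, 25 C
  V <- seq(-150, 100, 25)
  bh <- fit_boltzmann(V, open_probability(V, 298.15, h$params), 298.15)
  bm <- fit_boltzmann(V, open_probability(V, 298.15, m$params), 298.15)
  frac_h <- open_probability(-150, 298.15, h$params) / bh$Gmax
  frac_m <- open_probability(-150, 298.15, m$params) / bm$Gmax
  expect_gt(frac_m, 2 * frac_h)

  # tails at -150 mV: mTRPA1 relaxes mono-exponentially and faster
  pr <- protocol_voltage_steps("A", dt = 5e-4)
  spec <- recording_spec(noise_sd = 0, sample_rate_kHz = 2,
                         filter_cutoff_kHz = 0.5)
  tail_of <- function(pre) {
    rec <- synthesize_recording(pre$params, pr, pre$rates, spec)
    tl <- extract_tail(rec, 11)
    fit_relaxation(tl$t_ms, tl$I_pA, n_components = 2)
  }
  fh <- tail_of(h)
  fm <- tail_of(m)
  expect_equal(fm$n_components, 1L)
  expect_lt(fm$tau_w, 0.6 * fh$tau_w)

  # S804N: strongly left-shifted half-activation voltage
  s <- orthologue_presets("hTRPA1-S804N")
  bs <- fit_boltzmann(V, open_probability(V, 298.15, s$params), 298.15)
  expect_lt(bs$V50, 35)
  expect_gt(bs$V50, 5)
  expect_lt(s$rates$k_gate, h$rates$k_gate / 5)  # slow kinetics

  expect_error(orthologue_presets("rTRPA1"), "arg")
})

test_that("recording specs validate the sampling theorem and units", {
  expect_error(recording_spec(sample_rate_kHz = 2, filter_cutoff_kHz = 2),
               "sample_rate")
  expect_error(recording_spec(noise_sd = -1), "noise_sd")
  expect_error(recording_spec(N = 0), "N >= 1")
})

test_that("staircase currents at +80 mV are U-shaped in temperature", {
  h <- orthologue_presets("hTRPA1")
  pr <- protocol_temperature("staircase", dt = 0.02)
  rec <- synthesize_recording(h$params, pr, h$rates,
                              recording_spec(noise_sd = 0,
                                             sample_rate_kHz = 0.05,
                                             filter_cutoff_kHz = 0.01))
  # current at the end of each temperature plateau
  plateaus <- split(seq_along(rec$time_s),
                    cumsum(c(1, diff(rec$role == "plateau") != 0)))
  lev <- vapply(plateaus, function(ix) {
    ix <- ix[rec$role[ix] == "plateau"]
    if (!length(ix)) return(c(NA_real_, NA_real_))
    c(mean(rec$temperature_C[tail(ix, 3)]), mean(rec$current_pA[tail(ix, 3)]))
  }, numeric(2))
  lev <- lev[, is.finite(lev[1, ])]
  i_min <- which.min(lev[2, ])
  expect_gt(i_min, 1)                    # interior minimum:
  expect_lt(i_min, ncol(lev))            # rises on both sides
  expect_gt(lev[1, i_min], 12)
  expect_lt(lev[1, i_min], 35)           # near room temperature
})
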