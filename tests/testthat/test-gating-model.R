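# Equilibrium thermodynamics of the eight-state allosteric model.

test_that("sensor and coupling equilibrium constants match closed forms", {
  p <- gating_parameters(L = 1, K0 = 0.003, z = 0.74, dH = 91, dS = 0.317,
                         dHc = 6.1, dSc = 0.020, D = 1, E = 1)
  # half-activation temperature of the heat sensor: exponent exactly zero
  expect_equal(sensor_J(91 / 0.317, p), 1, tolerance = 1e-12)
  # independent arithmetic: exp(-(91 - 298.15*0.317)/(1.9872e-3*298.15))
  expect_equal(sensor_J(298.15, p),
               exp(-(91 - 298.15 * 0.317) / (1.98720e-3 * 298.15)),
               tolerance = 1e-12)
  expect_equal(sensor_J(298.15, p), 376.23, tolerance = 1e-4)
  p0 <- gating_parameters(L = 1, K0 = 0.003, z = 0.74, dH = 0, dS = 0,
                          dHc = 0, dSc = 0, D = 1, E = 1)
  expect_equal(sensor_J(312.9, p0), 1)
  expect_equal(coupling_C(250, p0), 1)

  expect_equal(sensor_K(0, 298.15, p), 0.003)
  expect_equal(sensor_K(80, 298.15, p),
               0.003 * exp(0.74 * 80 / (1000 * 8.314 * 298.15 / 96485.332)),
               tolerance = 1e-12)
  expect_equal(sensor_K(80, 298.15, p), 0.0300, tolerance = 2e-3)
  pz <- gating_parameters(L = 1, K0 = 0.003, z = 0, dH = 0, dS = 0,
                          dHc = 0, dSc = 0, D = 1, E = 1)
  expect_equal(sensor_K(c(-150, 0, 200), 298.15, pz), rep(0.003, 3))

  expect_equal(coupling_C(6.1 / 0.020, p), 1, tolerance = 1e-12)
  expect_equal(coupling_C(298.15, p), 0.794, tolerance = 1e-3)

  expect_error(sensor_J(-1, p), "temperature")
  expect_error(coupling_C(0, p), "temperature")
})

test_that("open probability reduces to the two-state limit when couplings are off", {
  for (L in c(0.01, 0.5, 3, 1e6)) {
    p <- gating_parameters(L = L, K0 = 0.003, z = 0.74, dH = 91, dS = 0.317,
                           dHc = 0, dSc = 0, D = 1, E = 1)
    po <- open_probability(c(-150, 0, 100), celsius_to_kelvin(c(5, 25, 60)), p)
    expect_equal(po, rep(L / (1 + L), 3), tolerance = 1e-12)
  }
})

test_that("open probability matches the hand-enumerated weight sum", {
  # craft parameters so that J = 5, K = 2, C = 3 at every (V, T):
  # dH = 0 makes ln J = dS/R, z = 0 makes K = K0, dHc = 0 makes ln C = dSc/R
  R <- 1.98720e-3
  p <- gating_parameters(L = 0.01, K0 = 2, z = 0, dH = 0, dS = R * log(5),
                         dHc = 0, dSc = R * log(3), D = 4, E = 2)
  # open weights: L(1 + KD + JC + JKCDE) = 0.01(1 + 8 + 15 + 240) = 2.64
  # closed weights: 1 + K + J + JKE = 1 + 2 + 5 + 20 = 28
  expect_equal(open_probability(0, 298.15, p), 2.64 / 30.64,
               tolerance = 1e-12)
  expect_equal(open_probability(37, 310, p), 2.64 / 30.64, tolerance = 1e-12)
})

test_that("state weights are normalized and consistent with the closed form", {
  p <- gating_parameters(L = 1, K0 = 1, z = 0, dH = 0, dS = 0,
                         dHc = 0, dSc = 0, D = 1, E = 1)
  w <- state_weights(0, 298.15, p)
  expect_equal(unname(w), rep(1 / 8, 8), tolerance = 1e-12)

  for (p in random_params(50, seed = 11)) {
    V <- runif(1, -150, 200)
    T_K <- celsius_to_kelvin(runif(1, 5, 60))
    w <- state_weights(V, T_K, p)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w >= 0))
    expect_equal(sum(w[5:8]), open_probability(V, T_K, p), tolerance = 1e-12)
  }
})

test_that("Po is monotone in L always, and in V under favorable coupling", {
  # Monotonicity in voltage requires favorable couplings (D, E, C >= 1);
  # with D < 1 the model rectifies inward by design (the cold-sensitized
  # regime), so voltage monotonicity is a property of this regime only.
  for (p0 in random_params(20, seed = 21)) {
    T_K <- celsius_to_kelvin(25)
    p <- transform_params(p0, D = 1 + p0$D, E = 1 + p0$E,
                          dHc = -abs(p0$dHc), dSc = abs(p0$dSc))
    po_v <- open_probability(seq(-150, 200, 10), T_K, p)
    expect_true(all(diff(po_v) > -1e-14))
    po_L <- vapply(c(0.5, 1, 2, 4),
                   function(f) open_probability(0, T_K, transform_params(p0, L = f * p0$L)),
                   numeric(1))
    expect_true(all(diff(po_L) > 0))
  }
  # and the red regime is a genuine counterexample: depolarization closes it
  red <- regime_parameters("red")
  po_red <- open_probability(c(-70, 80), celsius_to_kelvin(5), red)
  expect_lt(po_red[2], po_red[1])
})

test_that("extreme exponents saturate cleanly instead of overflowing", {
  # underlying weight exponents up to about +/-700
  p_hot <- gating_parameters(L = 1e8, K0 = 1e-6, z = 3.5, dH = 180, dS = 0.8,
                             dHc = 40, dSc = 0.15, D = 1e6, E = 1e6)
  p_cold <- gating_parameters(L = 1e-8, K0 = 1e-6, z = 3.5, dH = 180,
                              dS = 0.001, dHc = -40, dSc = -0.15,
                              D = 1e-6, E = 1e-6)
  for (p in list(p_hot, p_cold)) {
    po <- open_probability(c(-400, 0, 400), c(200, 300, 500), p)
    expect_true(all(is.finite(po)))
    expect_true(all(po >= 0 & po <= 1))
  }
  expect_equal(open_probability(0, 298.15,
                                transform_params(p_hot, D = 1, E = 1,
                                                 dHc = 0, dSc = 0)), 1)
})

test_that("landscapes evaluate element-wise on the grids", {
  p <- regime_parameters("blue")
  ls1 <- po_landscape(p, voltages = 80, temperatures = 25)
  expect_equal(as.numeric(ls1$po),
               open_probability(80, celsius_to_kelvin(25), p))

  pc <- transform_params(p, D = 1, E = 1, dHc = 0, dSc = 0)
  lsc <- po_landscape(pc, seq(-100, 100, 50), seq(5, 60, 5))
  expect_equal(max(lsc$po) - min(lsc$po), 0, tolerance = 1e-12)

  expect_error(po_landscape(p, voltages = c(0, -10, 5)), "monotone")

  # fitted blue landscape: interior Po minimum at +80 mV across 5-60 C
  tg <- seq(5, 60, 1)
  po80 <- open_probability(80, celsius_to_kelvin(tg), p)
  i <- which.min(po80)
  expect_gt(i, 1)
  expect_lt(i, length(tg))
  expect_lt(tg[i], 30)  # near room temperature
})

test_that("parameter sets serialize losslessly and normalize the z convention", {
  p <- regime_parameters("green")
  for (ext in c("json", "yaml")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_gating_parameters(p, f)
    q <- read_gating_parameters(f)
    expect_equal(unclass(q), unclass(p), tolerance = 1e-12)
  }
  # a file with the opposite exponent convention (negative z) loads with a flag
  f <- tempfile(fileext = ".json")
  write_gating_parameters(transform_params(p, z = -0.74), f)
  q <- read_gating_parameters(f, z_convention = "inverted")
  expect_equal(q$z, 0.74)
  expect_error(read_gating_parameters(tempfile(fileext = ".json")), "not found")
})

test_that("landscape CSV round-trips", {
  p <- regime_parameters("blue")
  ls <- po_landscape(p, seq(-100, 100, 50), seq(10, 50, 10))
  f <- tempfile(fileext = ".csv")
  write_landscape_csv(ls, f)
  back <- read_landscape_csv(f)
  expect_equal(back$voltages, ls$voltages)
  expect_equal(back$temperatures, ls$temperatures)
  expect_equal(unname(back$po), unname(ls$po), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("invalid parameters are rejected", {
  expect_error(gating_parameters(L = -1, K0 = 0.003, z = 0.74, dH = 91,
                                 dS = 0.317, dHc = 6.1, dSc = 0.02, D = 1,
                                 E = 1), "L must be")
  expect_error(gating_parameters(L = 1, K0 = 0.003, z = 5, dH = 91,
                                 dS = 0.317, dHc = 6.1, dSc = 0.02, D = 1,
                                 E = 1), "z")
  expect_error(gating_parameters(L = 1, K0 = 0.003, z = 0.74, dH = 91,
                                 dS = 0.317, dHc = 6.1, dSc = 0.02, D = 0,
                                 E = 1), "D must be")
})
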