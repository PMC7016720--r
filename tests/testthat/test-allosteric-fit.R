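# Constrained global fit of the allosteric model.

test_that("an all-frozen fit returns the input parameters with residuals", {
  pins <- regime_pins("green")
  start <- regime_parameters("green")
  fit <- fit_allosteric(start, pins = pins, frozen = trpgating:::.FIT_PAR_NAMES,
                        seed = 1)
  expect_equal(coef(fit),
               unlist(unclass(start)[trpgating:::.FIT_PAR_NAMES]))
  expect_false(is.null(fit$pin_table))
  expect_true(all(is.finite(fit$pin_table$rel_residual)))
})

test_that("fits are bit-reproducible for a fixed seed", {
  pins <- regime_pins("green")
  start <- transform_params(regime_parameters("blue"), dHc = 1.4)
  f1 <- fit_allosteric(start, pins = pins, frozen = c("K0", "z", "dH", "dS", "dHc"),
                       seed = 7, generations = 40)
  f2 <- fit_allosteric(start, pins = pins, frozen = c("K0", "z", "dH", "dS", "dHc"),
                       seed = 7, generations = 40)
  expect_identical(coef(f1), coef(f2))
  f3 <- fit_allosteric(start, pins = pins, frozen = c("K0", "z", "dH", "dS", "dHc"),
                       seed = 8, generations = 40)
  expect_false(identical(coef(f1), coef(f3)))
})

test_that("the best objective is monotone non-increasing over generations", {
  fit <- fit_allosteric(transform_params(regime_parameters("blue"), dHc = 1.4),
                        pins = regime_pins("green"),
                        frozen = c("K0", "z", "dH", "dS", "dHc"),
                        seed = 3, generations = 60)
  expect_true(all(diff(fit$objective_trace) <= 1e-15))
})

test_that("noiseless conductance curves are recovered at the landscape level", {
  truth <- regime_parameters("blue")
  V <- seq(-150, 200, 25)
  temps <- c(25, 12)
  gmax_syn <- 500
  curves <- do.call(rbind, lapply(temps, function(tc)
    data.frame(voltage_mV = V,
               conductance = gmax_syn *
                 open_probability(V, celsius_to_kelvin(tc), truth),
               temperature_C = tc)))
  fit <- fit_allosteric(truth, gv_curves = curves, frozen = character(),
                        seed = 11, generations = 250,
                        reference_temp_C = 25, anchor_weight = 0)
  # conductances are normalized by the fitted Boltzmann Gmax of the reference
  # curve, so the landscape is identified up to that scale; compare the
  # normalized landscapes (parameters themselves may be degenerate)
  grid <- expand.grid(voltage_mV = V, temperature_C = temps)
  fitted_po <- predict(fit, grid)
  true_po <- open_probability(grid$voltage_mV,
                              celsius_to_kelvin(grid$temperature_C), truth)
  err <- abs(fitted_po / max(fitted_po) - true_po / max(true_po))
  expect_lt(max(err), 0.02)
})

test_that("under-constrained fits warn and report identifiability", {
  pins <- regime_pins("green")[1:2, ]
  expect_warning(
    fit <- fit_allosteric(transform_params(regime_parameters("blue"), dHc = 1.4),
                          pins = pins, frozen = c("K0", "z", "dH"),
                          seed = 1, generations = 10),
    "under-constrained")
  expect_false(fit$identifiable)
})

test_that("pin inputs are validated", {
  start <- regime_parameters("blue")
  expect_error(fit_allosteric(start, pins = data.frame(voltage_mV = 0,
                                                       temperature_C = 25,
                                                       po = 1.2)),
               "inside")
  expect_error(fit_allosteric(start), "supply")
  expect_error(fit_allosteric(start, pins = regime_pins("green"),
                              frozen = "bogus"), "unknown frozen")
})
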