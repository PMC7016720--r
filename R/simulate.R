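#' Master-equation simulation of the eight-state model
#'
#' Propagates the state-occupancy vector under a piecewise
#' voltage/temperature protocol. Within each sample interval the voltage and
#' temperature are held constant (temperature taken at the interval midpoint
#' on ramp segments) and the occupancy is advanced by the matrix exponential
#' of the generator, which is exact on constant segments; a single matrix
#' exponential per constant-temperature segment is reused across its steps.
#'
#' @param p a [gating_parameters()] object.
#' @param r a [rate_rules()] object.
#' @param protocol a [stimulus_protocol()].
#' @param initial `"equilibrium"` (stationary distribution at the protocol's
#'   first voltage/temperature) or a probability 8-vector summing to 1.
#' @return An object of class `occupancy_trace`: a list with `time_s`,
#'   `occupancy` (matrix, one row per sample, columns [state_names()]), `po`,
#'   `voltage_mV`, `temperature_C`, `sweep`, `role`, `regime` and `protocol`.
#' @seealso [simulate_regimes()] for simulations that switch parameter
#'   regimes mid-protocol, [occupancy_to_current()] to obtain current.
#' @export
#' @examples
#' pr <- stimulus_protocol(data.frame(duration_s = 0.2, voltage_mV = 80,
#'                                    temp_start_C = 25, temp_end_C = 25),
#'                         dt = 1e-3)
#' tr <- simulate_gating(regime_parameters("blue"), rate_rules(), pr)
#' tail(tr$po, 1)  # converged to the closed-form open probability
simulate_gating <- function(p, r, protocol, initial = "equilibrium") {
  validate_gating_parameters(p)
  regimes <- list(only = p)
  .simulate_core(regimes, schedule = NULL, r = r, protocol = protocol,
                 initial = initial, start_regime = "only")
}

#' Regime-switching schedule
#'
#' Latching rules that swap the active gating-parameter regime when the
#' stimulus satisfies a condition for a dwell time. Each rule latches at most
#' once; the occupancy vector is carried over unchanged at a switch (only the
#' generator changes).
#'
#' Default rules mirror the irreversible behavior of heat-exposed TRPA1:
#' `"green"` latches once the applied temperature exceeds 60 degrees C, and
#' `"red"` latches once V >= +80 mV and T >= 60 C hold simultaneously for at
#' least 0.5 s.
#'
#' @param rules list of rules; each rule is a list with elements `regime`
#'   (label), optional `V_min`, `T_min` (thresholds; a missing threshold is
#'   ignored) and `dwell_s` (required continuous duration, default 0).
#' @return An object of class `regime_schedule`.
#' @export
regime_schedule <- function(rules = list(
  list(regime = "green", T_min = 60, dwell_s = 0),
  list(regime = "red", V_min = 80, T_min = 60, dwell_s = 0.5))) {
  for (rl in rules) {
    if (is.null(rl$regime)) stop("every rule needs a regime label")
    if (is.null(rl$V_min) && is.null(rl$T_min))
      stop("rule for regime '", rl$regime, "' has no condition")
  }
  labs <- vapply(rules, `[[`, character(1), "regime")
  if (anyDuplicated(labs))
    stop("at most one latch per regime: duplicated ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  structure(list(rules = rules), class = "regime_schedule")
}

#' Simulation with latched regime switches
#'
#' Like [simulate_gating()] but with a set of named parameter regimes and a
#' [regime_schedule()]: the occupancy is continuous across a switch while the
#' generator is rebuilt from the newly latched regime, reproducing e.g. the
#' blue-to-green-to-red sequence of heat-exposed TRPA1.
#'
#' @param params_by_regime named list of [gating_parameters()], one per
#'   regime label.
#' @param schedule a [regime_schedule()] (or `NULL` for no switching).
#' @param r a [rate_rules()] object.
#' @param protocol a [stimulus_protocol()].
#' @param initial as in [simulate_gating()].
#' @param start_regime label of the initial regime (default: first of
#'   `params_by_regime`).
#' @return An `occupancy_trace`; its `regime` column records the active
#'   regime at every sample.
#' @export
simulate_regimes <- function(params_by_regime, schedule = regime_schedule(),
                             r = rate_rules(), protocol,
                             initial = "equilibrium",
                             start_regime = names(params_by_regime)[1]) {
  if (is.null(names(params_by_regime)) || any(!nzchar(names(params_by_regime))))
    stop("params_by_regime must be a named list")
  for (p in params_by_regime) validate_gating_parameters(p)
  if (!is.null(schedule)) {
    stopifnot(inherits(schedule, "regime_schedule"))
    labs <- vapply(schedule$rules, `[[`, character(1), "regime")
    undef <- setdiff(labs, names(params_by_regime))
    if (length(undef))
      stop("schedule references undefined regime(s): ",
           paste(undef, collapse = ", "))
  }
  if (!start_regime %in% names(params_by_regime))
    stop("undefined start regime: ", start_regime)
  .simulate_core(params_by_regime, schedule, r, protocol, initial, start_regime)
}

.expm_dt <- function(Q, dt) {
  as.matrix(Matrix::expm(Matrix::Matrix(Q * dt)))
}

.simulate_core <- function(regimes, schedule, r, protocol, initial,
                           start_regime) {
  stopifnot(inherits(protocol, "stimulus_protocol"), inherits(r, "rate_rules"))
  tr <- protocol_trace(protocol)
  n <- nrow(tr)
  dt <- protocol$dt
  occ <- matrix(NA_real_, n, 8, dimnames = list(NULL, .STATE_NAMES))
  regime_at <- character(n)

  active <- start_regime
  if (identical(initial, "equilibrium")) {
    occ[1, ] <- state_weights(tr$voltage_mV[1],
                              celsius_to_kelvin(tr$temperature_C[1]),
                              regimes[[active]])
  } else {
    initial <- as.numeric(initial)
    if (length(initial) != 8 || abs(sum(initial) - 1) > 1e-8 ||
        any(initial < 0))
      stop("initial must be 'equilibrium' or a probability 8-vector")
    occ[1, ] <- initial / sum(initial)
  }
  regime_at[1] <- active

  fired <- logical(length(if (is.null(schedule)) list() else schedule$rules))
  dwell <- numeric(length(fired))

  # transition-matrix cache, keyed by regime/V/T
  cache_key <- ""
  P <- NULL
  pvec <- occ[1, ]

  for (k in 2:n) {
    V <- tr$voltage_mV[k]
    Tc_mid <- (tr$temperature_C[k - 1] + tr$temperature_C[k]) / 2

    # evaluate latching rules on the stimulus driving this interval
    if (!is.null(schedule)) {
      for (j in seq_along(schedule$rules)) {
        if (fired[j]) next
        rl <- schedule$rules[[j]]
        ok <- TRUE
        if (!is.null(rl$V_min)) ok <- ok && V >= rl$V_min
        if (!is.null(rl$T_min)) ok <- ok && Tc_mid >= rl$T_min
        dwell[j] <- if (ok) dwell[j] + dt else 0
        need <- if (is.null(rl$dwell_s)) 0 else rl$dwell_s
        if (ok && dwell[j] >= need) {
          fired[j] <- TRUE
          active <- rl$regime
        }
      }
    }

    key <- paste(active, V, signif(Tc_mid, 12), sep = "|")
    if (!identical(key, cache_key)) {
      Q <- build_generator(regimes[[active]], r, V,
                           celsius_to_kelvin(Tc_mid))
      P <- .expm_dt(Q, dt)
      cache_key <- key
    }
    pvec <- as.numeric(pvec %*% P)
    pvec[pvec < 0] <- 0
    pvec <- pvec / sum(pvec)
    occ[k, ] <- pvec
    regime_at[k] <- active
  }

  structure(list(time_s = tr$time_s,
                 occupancy = occ,
                 po = rowSums(occ[, 5:8, drop = FALSE]),
                 voltage_mV = tr$voltage_mV,
                 temperature_C = tr$temperature_C,
                 sweep = tr$sweep,
                 role = tr$role,
                 regime = regime_at,
                 protocol = protocol),
            class = "occupancy_trace")
}

#' @export
print.occupancy_trace <- function(x, ...) {
  cat(sprintf("Occupancy trace: %d samples over %.3f s (dt = %g s)\n",
              length(x$time_s), max(x$time_s), x$protocol$dt))
  cat(sprintf("  Po range %.4g .. %.4g; regime(s): %s\n",
              min(x$po), max(x$po), paste(unique(x$regime), collapse = " -> ")))
  invisible(x)
}

#' @export
as.data.frame.occupancy_trace <- function(x, ...) {
  data.frame(time_s = x$time_s, x$occupancy, po = x$po,
             voltage_mV = x$voltage_mV, temperature_C = x$temperature_C,
             sweep = x$sweep, role = x$role, regime = x$regime)
}

#' @export
plot.occupancy_trace <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$time_s, x$po, type = "l", xlab = "Time (s)",
                 ylab = expression(P[o]), ylim = c(0, 1), ...)
  graphics::plot(x$time_s, x$temperature_C, type = "l", col = "red",
                 xlab = "Time (s)", ylab = "Temperature (°C)")
  invisible(x)
}

#' Macroscopic current from an occupancy trace
#'
#' Ohmic conversion I(t) = N g Po(t) (V(t) - Vrev): with `g` in nS and
#' voltages in mV the current comes out in pA.
#'
#' @param trace an `occupancy_trace`.
#' @param N channel count (>= 1).
#' @param g single-channel conductance (nS).
#' @param Vrev reversal potential (mV).
#' @return Numeric vector of currents (pA), one per trace sample.
#' @export
occupancy_to_current <- function(trace, N = 5000, g = 0.1, Vrev = 0) {
  stopifnot(inherits(trace, "occupancy_trace"), N >= 1, g > 0)
  N * g * trace$po * (trace$voltage_mV - Vrev)
}
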