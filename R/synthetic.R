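#' Recording specification for the synthetic whole-cell generator
#'
#' Channel count, single-channel conductance, reversal potential and the
#' noise/filter model of the synthetic rig. Defaults give a maximal
#' whole-cell conductance N g = 500 nS Po-weighted down to the ~23 nS Gmax
#' scale of the fitted recordings at typical open probabilities, with 5 pA
#' Gaussian noise shaped by a 2 kHz single-pole low-pass at 10 kHz sampling.
#'
#' @param N channel count (>= 1).
#' @param g single-channel conductance (nS).
#' @param Vrev reversal potential (mV).
#' @param noise_sd Gaussian noise standard deviation before filtering (pA).
#' @param filter_cutoff_kHz low-pass corner frequency (kHz).
#' @param sample_rate_kHz sampling rate (kHz); must be >= 2 x the cutoff.
#' @param seed integer seed for the noise generator.
#' @return An object of class `recording_spec`.
#' @export
recording_spec <- function(N = 5000, g = 0.1, Vrev = 0, noise_sd = 5,
                           filter_cutoff_kHz = 2, sample_rate_kHz = 10,
                           seed = 1L) {
  stopifnot(N >= 1, g > 0, noise_sd >= 0,
            sample_rate_kHz >= 2 * filter_cutoff_kHz)
  structure(list(N = N, g = g, Vrev = Vrev, noise_sd = noise_sd,
                 filter_cutoff_kHz = filter_cutoff_kHz,
                 sample_rate_kHz = sample_rate_kHz, seed = as.integer(seed)),
            class = "recording_spec")
}

#' @export
print.recording_spec <- function(x, ...) {
  cat(sprintf("Recording spec: N = %d channels x %g nS, Vrev = %g mV; noise %g pA, %g kHz low-pass, %g kHz sampling, seed %d\n",
              x$N, x$g, x$Vrev, x$noise_sd, x$filter_cutoff_kHz,
              x$sample_rate_kHz, x$seed))
  invisible(x)
}

# Single-pole low-pass (exponential smoother) at cutoff fc for sample rate fs.
.lowpass <- function(x, fc_kHz, fs_kHz) {
  if (fc_kHz <= 0) return(x)
  alpha <- 1 - exp(-2 * pi * fc_kHz / fs_kHz)
  as.numeric(stats::filter(alpha * x, 1 - alpha, method = "recursive",
                           init = x[1]))
}

#' Synthesize a noisy whole-cell recording
#'
#' Forward model of a voltage-clamp experiment: the occupancy of the
#' eight-state model is simulated under the protocol (with optional latched
#' regime switches), converted to current by ohmic conduction, and Gaussian
#' recording noise with a single-pole low-pass character is added. The
#' protocol's own `dt` is overridden by the spec's sampling rate. Seeded and
#' bit-reproducible.
#'
#' @param params a [gating_parameters()] object, or a named list of them
#'   (regimes) when `schedule` is given.
#' @param protocol a [stimulus_protocol()].
#' @param rates a [rate_rules()] object.
#' @param spec a [recording_spec()].
#' @param schedule optional [regime_schedule()] (requires named `params`).
#' @return An object of class `synthetic_recording`: a list with `time_s`,
#'   `voltage_mV`, `temperature_C`, `current_pA`, `sweep`, `role`, `po`
#'   (noise-free open probability), `regime` and `ground_truth` (params,
#'   rates, spec, schedule).
#' @export
#' @examples
#' pr <- protocol_voltage_steps("A", dt = 1e-3)
#' rec <- synthesize_recording(regime_parameters("blue"), pr,
#'                             spec = recording_spec(noise_sd = 2,
#'                                                   sample_rate_kHz = 1))
#' range(rec$current_pA)
synthesize_recording <- function(params, protocol, rates = rate_rules(),
                                 spec = recording_spec(), schedule = NULL) {
  stopifnot(inherits(spec, "recording_spec"),
            inherits(protocol, "stimulus_protocol"))
  dt <- 1e-3 / spec$sample_rate_kHz
  protocol <- stimulus_protocol(protocol$segments, dt = dt)
  trace <- if (is.null(schedule)) {
    simulate_gating(params, rates, protocol)
  } else {
    simulate_regimes(params, schedule, rates, protocol)
  }
  I_clean <- occupancy_to_current(trace, N = spec$N, g = spec$g,
                                  Vrev = spec$Vrev)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)
  noise <- if (spec$noise_sd > 0) {
    raw <- stats::rnorm(length(I_clean), 0, spec$noise_sd)
    .lowpass(raw, spec$filter_cutoff_kHz, spec$sample_rate_kHz)
  } else 0
  structure(list(time_s = trace$time_s,
                 voltage_mV = trace$voltage_mV,
                 temperature_C = trace$temperature_C,
                 current_pA = I_clean + noise,
                 sweep = trace$sweep,
                 role = trace$role,
                 po = trace$po,
                 regime = trace$regime,
                 ground_truth = list(params = params, rates = rates,
                                     spec = spec, schedule = schedule)),
            class = "synthetic_recording")
}

#' @export
print.synthetic_recording <- function(x, ...) {
  cat(sprintf("Synthetic recording: %d samples over %.3f s; %d sweep(s)\n",
              length(x$time_s), max(x$time_s), length(unique(x$sweep))))
  cat(sprintf("  current %.4g .. %.4g pA\n", min(x$current_pA),
              max(x$current_pA)))
  print(x$ground_truth$spec)
  invisible(x)
}

#' @export
as.data.frame.synthetic_recording <- function(x, ...) {
  data.frame(time_s = x$time_s, voltage_mV = x$voltage_mV,
             temperature_C = x$temperature_C, current_pA = x$current_pA,
             sweep = x$sweep, role = x$role)
}

#' Steady-state conductance-voltage points from a stepped recording
#'
#' For each sweep of a voltage-step recording, averages the current over the
#' last fraction of the `"test"` segment and converts it to conductance.
#' Points at the reversal potential are dropped.
#'
#' @param rec a [synthesize_recording()] result (or any list with `time_s`,
#'   `voltage_mV`, `current_pA`, `sweep`, `role`).
#' @param Vrev reversal potential (mV).
#' @param tail_frac final fraction of the test segment to average over.
#' @return data.frame with `voltage_mV`, `conductance` (nS), `temperature_C`.
#' @export
measure_gv <- function(rec, Vrev = 0, tail_frac = 0.1) {
  sw <- unique(rec$sweep)
  out <- lapply(sw, function(s) {
    sel <- rec$sweep == s & rec$role == "test"
    if (!any(sel)) return(NULL)
    tt <- rec$time_s[sel]
    last <- tt >= max(tt) - tail_frac * diff(range(tt))
    V <- rec$voltage_mV[sel][1]
    if (V == Vrev) return(NULL)
    I <- mean(rec$current_pA[sel][last])
    data.frame(voltage_mV = V, conductance = I / (V - Vrev),
               temperature_C = mean(rec$temperature_C[sel]))
  })
  do.call(rbind, out)
}

#' Extract a tail-current relaxation from a stepped recording
#'
#' Returns the `"tail"` segment of one sweep with time in ms from the start
#' of the tail, ready for [fit_relaxation()].
#'
#' @param rec a [synthesize_recording()] result.
#' @param sweep sweep number.
#' @return data.frame with `t_ms`, `I_pA`.
#' @export
extract_tail <- function(rec, sweep) {
  sel <- rec$sweep == sweep & rec$role == "tail"
  if (!any(sel)) stop("sweep ", sweep, " has no tail segment")
  tt <- rec$time_s[sel]
  data.frame(t_ms = (tt - min(tt)) * 1000, I_pA = rec$current_pA[sel])
}
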