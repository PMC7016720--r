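#' Piecewise voltage/temperature stimulation protocol
#'
#' A protocol is an ordered table of segments, each holding the command
#' voltage constant while temperature moves linearly from `temp_start_C` to
#' `temp_end_C` over `duration_s`. Optional `sweep` and `role` columns tag
#' segments for downstream analysis (e.g. which segment is the test step and
#' which the tail of a voltage-clamp sweep).
#'
#' @param segments data.frame with columns `duration_s`, `voltage_mV`,
#'   `temp_start_C`, `temp_end_C` and optionally `sweep`, `role`.
#' @param dt sample interval (s) used for simulation and export.
#' @return An object of class `stimulus_protocol`.
#' @export
#' @examples
#' pr <- stimulus_protocol(data.frame(duration_s = c(0.1, 0.4),
#'                                    voltage_mV = c(0, 100),
#'                                    temp_start_C = 25, temp_end_C = 25),
#'                         dt = 1e-3)
#' pr
stimulus_protocol <- function(segments, dt = 1e-3) {
  segments <- as.data.frame(segments)
  need <- c("duration_s", "voltage_mV", "temp_start_C", "temp_end_C")
  missing <- setdiff(need, names(segments))
  if (length(missing))
    stop("protocol segments lack column(s): ", paste(missing, collapse = ", "))
  if (!"sweep" %in% names(segments)) segments$sweep <- 1L
  if (!"role" %in% names(segments)) segments$role <- "step"
  if (any(segments$duration_s <= 0)) stop("segment durations must be > 0")
  if (dt <= 0) stop("dt must be > 0")
  if (dt > min(segments$duration_s))
    stop("dt (", dt, " s) exceeds the shortest segment (",
         min(segments$duration_s), " s)")
  slew <- abs(segments$temp_end_C - segments$temp_start_C) / segments$duration_s
  if (any(slew > 120))
    stop("temperature slew exceeds 120 C/s in segment(s) ",
         paste(which(slew > 120), collapse = ", "))
  structure(list(segments = segments, dt = dt), class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  s <- x$segments
  cat(sprintf("Stimulus protocol: %d segment(s), %d sweep(s), %.3f s total, dt = %g s\n",
              nrow(s), length(unique(s$sweep)), sum(s$duration_s), x$dt))
  cat(sprintf("  voltage %g..%g mV, temperature %g..%g C\n",
              min(s$voltage_mV), max(s$voltage_mV),
              min(c(s$temp_start_C, s$temp_end_C)),
              max(c(s$temp_start_C, s$temp_end_C))))
  invisible(x)
}

# Expand a protocol to its sample grid. Returns a data.frame with time_s,
# voltage_mV, temperature_C, sweep, role, one row per sample point, starting
# at t = 0 (state before the first step) and ending at the total duration.
protocol_trace <- function(protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  s <- protocol$segments
  dt <- protocol$dt
  n_steps <- pmax(1L, as.integer(round(s$duration_s / dt)))
  total <- sum(n_steps)
  time <- seq(0, by = dt, length.out = total + 1)
  volt <- numeric(total + 1)
  temp <- numeric(total + 1)
  sweep <- integer(total + 1)
  role <- character(total + 1)
  idx <- 1L
  volt[1] <- s$voltage_mV[1]; temp[1] <- s$temp_start_C[1]
  sweep[1] <- s$sweep[1]; role[1] <- s$role[1]
  for (i in seq_len(nrow(s))) {
    n <- n_steps[i]
    frac <- seq_len(n) / n
    rows <- idx + seq_len(n)
    volt[rows] <- s$voltage_mV[i]
    temp[rows] <- s$temp_start_C[i] + frac * (s$temp_end_C[i] - s$temp_start_C[i])
    sweep[rows] <- s$sweep[i]
    role[rows] <- s$role[i]
    idx <- idx + n
  }
  data.frame(time_s = time, voltage_mV = volt, temperature_C = temp,
             sweep = sweep, role = role)
}

#' Read and write protocol CSV files
#'
#' Segment rows with columns `duration_s, voltage_mV, temp_start_C,
#' temp_end_C` (plus optional `sweep`, `role`).
#'
#' @param protocol a [stimulus_protocol()] object.
#' @param path CSV path.
#' @param dt sample interval (s) for the protocol read back.
#' @return `read_protocol_csv` returns a `stimulus_protocol`;
#'   `write_protocol_csv` returns `path` invisibly.
#' @export
write_protocol_csv <- function(protocol, path) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  utils::write.csv(protocol$segments, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_protocol_csv
#' @export
read_protocol_csv <- function(path, dt = 1e-3) {
  stimulus_protocol(utils::read.csv(path), dt = dt)
}

#' Voltage-step protocol families
#'
#' Variant `"A"`: sweeps of 400-ms steps from -150 to +100 mV in +25 mV
#' increments, each followed by a 400-ms tail step to -150 mV, from a holding
#' potential of 0 mV (11 sweeps). Variant `"B"`: 100-ms steps from -80 to
#' +200 mV in +20 mV increments from a holding potential of -70 mV
#' (15 sweeps). Temperature is held constant.
#'
#' @param variant `"A"` or `"B"`.
#' @param temp_C bath temperature (degrees C).
#' @param holding_s holding-segment duration before each test step (s).
#' @param dt sample interval (s).
#' @return A [stimulus_protocol()] with `role` tags `"hold"`, `"test"`,
#'   `"tail"`.
#' @export
protocol_voltage_steps <- function(variant = c("A", "B"), temp_C = 25,
                                   holding_s = 0.1, dt = 2e-4) {
  variant <- match.arg(variant)
  if (variant == "A") {
    steps <- seq(-150, 100, by = 25)
    hold_mV <- 0; test_s <- 0.4; tail_s <- 0.4; tail_mV <- -150
  } else {
    steps <- seq(-80, 200, by = 20)
    hold_mV <- -70; test_s <- 0.1; tail_s <- NA_real_; tail_mV <- NA_real_
  }
  seg <- do.call(rbind, lapply(seq_along(steps), function(i) {
    rows <- data.frame(duration_s = c(holding_s, test_s),
                       voltage_mV = c(hold_mV, steps[i]),
                       sweep = i, role = c("hold", "test"))
    if (!is.na(tail_s))
      rows <- rbind(rows, data.frame(duration_s = tail_s, voltage_mV = tail_mV,
                                     sweep = i, role = "tail"))
    rows
  }))
  seg$temp_start_C <- temp_C
  seg$temp_end_C <- temp_C
  stimulus_protocol(seg, dt = dt)
}

#' Temperature stimulation protocol families
#'
#' Variant `"staircase"`: increasing temperature steps from ~11 to ~52
#' degrees C in 3-s intervals at a constant +80 mV. Variant `"ramp"`: a
#' 25-to-60 degree ramp at 35 C/s (1.0 s rise) and back, at a fixed voltage.
#' Variant `"conditioning"`: at a cold base temperature, a 10-s depolarization from
#' -70 to +80 mV, a heat step at -70 mV, then a second 10-s depolarization
#' during which a concurrent heat step is applied, followed by cooling and
#' repolarization to -70 mV; the order of the conditioning voltage and heat
#' stimuli is switchable.
#'
#' @param variant `"staircase"`, `"ramp"` or `"conditioning"`.
#' @param voltage_mV fixed voltage for `"staircase"`/`"ramp"` (mV).
#' @param base_C cold base temperature for `"conditioning"` (degrees C).
#' @param heat_peak_C peak of the heat steps for `"conditioning"` (degrees C).
#' @param order `"voltage_first"` applies the lone depolarization before the
#'   lone heat step; `"heat_first"` swaps them.
#' @param dt sample interval (s).
#' @return A [stimulus_protocol()].
#' @export
protocol_temperature <- function(variant = c("staircase", "ramp", "conditioning"),
                                 voltage_mV = 80, base_C = 5,
                                 heat_peak_C = 61,
                                 order = c("voltage_first", "heat_first"),
                                 dt = 0.01) {
  variant <- match.arg(variant)
  order <- match.arg(order)
  if (variant == "staircase") {
    targets <- seq(11, 52, length.out = 12)
    seg <- NULL
    prev <- targets[1]
    for (tt in targets) {
      ramp_s <- max(abs(tt - prev) / 100, dt)    # <= 100 C/s transitions
      seg <- rbind(seg,
                   data.frame(duration_s = ramp_s, voltage_mV = voltage_mV,
                              temp_start_C = prev, temp_end_C = tt,
                              role = "transition"),
                   data.frame(duration_s = 3 - ramp_s, voltage_mV = voltage_mV,
                              temp_start_C = tt, temp_end_C = tt,
                              role = "plateau"))
      prev <- tt
    }
    seg$sweep <- 1L
    return(stimulus_protocol(seg, dt = dt))
  }
  if (variant == "ramp") {
    seg <- data.frame(
      duration_s = c(0.5, 1.0, 1.0, 0.5),
      voltage_mV = voltage_mV,
      temp_start_C = c(25, 25, 60, 25),
      temp_end_C = c(25, 60, 25, 25),
      role = c("baseline", "ramp_up", "ramp_down", "baseline"))
    seg$sweep <- 1L
    return(stimulus_protocol(seg, dt = dt))
  }
  # conditioning: interleaved long depolarizations and heat steps at a cold base
  ramp_s <- max((heat_peak_C - base_C) / 35, dt)  # ~35 C/s heat delivery
  depol <- data.frame(duration_s = 10, voltage_mV = 80,
                      temp_start_C = base_C, temp_end_C = base_C,
                      role = "depol")
  rest <- function(dur = 3) data.frame(duration_s = dur, voltage_mV = -70,
                                       temp_start_C = base_C,
                                       temp_end_C = base_C, role = "rest")
  heat_at_rest <- data.frame(
    duration_s = c(ramp_s, 5, ramp_s),
    voltage_mV = -70,
    temp_start_C = c(base_C, heat_peak_C, heat_peak_C),
    temp_end_C = c(heat_peak_C, heat_peak_C, base_C),
    role = "heat")
  concurrent <- data.frame(
    duration_s = c(2, ramp_s, 5, ramp_s, 2),
    voltage_mV = 80,
    temp_start_C = c(base_C, base_C, heat_peak_C, heat_peak_C, base_C),
    temp_end_C = c(base_C, heat_peak_C, heat_peak_C, base_C, base_C),
    role = "concurrent")
  cold_test <- data.frame(duration_s = 10, voltage_mV = -70,
                          temp_start_C = base_C, temp_end_C = base_C,
                          role = "cold_test")
  pre <- if (order == "voltage_first") {
    rbind(rest(2), depol, rest(), heat_at_rest, rest())
  } else {
    rbind(rest(2), heat_at_rest, rest(), depol, rest())
  }
  pre$role[pre$role == "depol"] <- "pre_depol"
  seg <- rbind(pre,
               transform(depol, role = "post_depol"),
               rest(),
               concurrent,
               cold_test)
  seg$sweep <- 1L
  stimulus_protocol(seg, dt = dt)
}
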