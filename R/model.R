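#' Sensor and coupling equilibrium constants
#'
#' The temperature sensor obeys J(T) = exp[-(dH - T dS)/RT], the voltage
#' sensor K(V) = K0 exp(zFV/RT), and the temperature-sensor-to-gate coupling
#' C(T) = exp[-(dHc - T dSc)/RT]. All are dimensionless equilibrium constants;
#' R is taken in kcal units to match the enthalpy/entropy parameters.
#'
#' @param T_K absolute temperature (K), strictly positive.
#' @param V membrane voltage (mV).
#' @param p a [gating_parameters()] object (or any list carrying the needed
#'   fields).
#' @return Numeric vector of equilibrium constants.
#' @export
#' @examples
#' p <- regime_parameters("blue")
#' sensor_J(298.15, p)        # ~376: temperature sensor mostly active at 25 C
#' sensor_K(80, 298.15, p)    # K at +80 mV
#' coupling_C(298.15, p)      # < 1: unfavorable (inverted) coupling
sensor_J <- function(T_K, p) {
  .check_T(T_K)
  exp(.log_J(T_K, p$dH, p$dS))
}

#' @rdname sensor_J
#' @export
sensor_K <- function(V, T_K, p) {
  .check_T(T_K)
  exp(.log_K(V, T_K, p$K0, p$z))
}

#' @rdname sensor_J
#' @export
coupling_C <- function(T_K, p) {
  .check_T(T_K)
  exp(.log_C(T_K, p$dHc, p$dSc))
}

.check_T <- function(T_K) {
  if (any(!is.finite(T_K)) || any(T_K <= 0))
    stop("absolute temperature must be finite and > 0 K")
  invisible(T_K)
}

.log_J <- function(T_K, dH, dS) -(dH - T_K * dS) / (.R_KCAL * T_K)
.log_C <- function(T_K, dHc, dSc) -(dHc - T_K * dSc) / (.R_KCAL * T_K)
.log_K <- function(V, T_K, K0, z) log(K0) + z * V / .rt_over_f_mV(T_K)

# State order used everywhere: bit v (voltage sensor active) fastest, then bit
# t (temperature sensor active), then bit g (gate open):
#   1 C00  2 C10  3 C01  4 C11  5 O00  6 O10  7 O01  8 O11
# where the first digit flags the voltage sensor and the second the
# temperature sensor.
.STATE_NAMES <- c("C00", "C10", "C01", "C11", "O00", "O10", "O01", "O11")
.STATE_BITS <- cbind(
  v = c(0, 1, 0, 1, 0, 1, 0, 1),
  t = c(0, 0, 1, 1, 0, 0, 1, 1),
  g = c(0, 0, 0, 0, 1, 1, 1, 1)
)

#' Names of the eight model states
#'
#' States are labelled `C`/`O` for gate closed/open followed by two digits
#' flagging the voltage and temperature sensor (1 = active): e.g. `O10` is
#' open with an activated voltage sensor and a resting temperature sensor.
#'
#' @return Character vector of length 8.
#' @export
state_names <- function() .STATE_NAMES

# Unnormalized log statistical weights of the 8 states at a single (V, T).
# Weight of C00 is 1; every other state accumulates log-factors for its
# activated modules and the allosteric couplings between them.
.state_log_weights <- function(V, T_K, p) {
  lJ <- .log_J(T_K, p$dH, p$dS)
  lK <- .log_K(V, T_K, p$K0, p$z)
  lC <- .log_C(T_K, p$dHc, p$dSc)
  lL <- log(p$L)
  lD <- log(p$D)
  lE <- log(p$E)
  v <- .STATE_BITS[, "v"]; t <- .STATE_BITS[, "t"]; g <- .STATE_BITS[, "g"]
  lw <- v * lK + t * lJ + g * lL + (v * t) * lE + (g * v) * lD + (g * t) * lC
  names(lw) <- .STATE_NAMES
  lw
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Equilibrium statistical weights of the eight states
#'
#' Normalized Boltzmann weights of the eight gate/voltage-sensor/
#' temperature-sensor states at a single voltage and temperature. The sum of
#' the four open-state weights equals [open_probability()].
#'
#' @inheritParams sensor_J
#' @return Named numeric vector of length 8 summing to 1, in [state_names()]
#'   order.
#' @export
state_weights <- function(V, T_K, p) {
  .check_T(T_K)
  stopifnot(length(V) == 1, length(T_K) == 1)
  lw <- .state_log_weights(V, T_K, p)
  w <- exp(lw - .logsumexp(lw))
  w / sum(w)
}

#' Closed-form open probability of the eight-state allosteric model
#'
#' Po = L(1 + KD + JC + JKCDE) / [(1 + K + J + JKE) + L(1 + KD + JC + JKCDE)]
#' with J = J(T), K = K(V,T), C = C(T). Computed via log-sum-exp over the
#' eight state weights, so extreme exponents (e.g. dH = 91 kcal/mol at high
#' temperature) saturate cleanly to 0/1 instead of overflowing.
#'
#' @param V membrane voltage (mV); vectorized.
#' @param T_K absolute temperature (K); vectorized, recycled against `V`.
#' @param p a [gating_parameters()] object.
#' @return Numeric vector of probabilities in [0, 1].
#' @export
open_probability <- function(V, T_K, p) {
  .check_T(T_K)
  .po_vectorized(V, T_K, p)
}

# Vectorized log-sum-exp evaluation of Po over paired (V, T) points.
.po_vectorized <- function(V, T_K, p) {
  n <- max(length(V), length(T_K))
  V <- rep_len(V, n); T_K <- rep_len(T_K, n)
  lJ <- .log_J(T_K, p$dH, p$dS)
  lK <- .log_K(V, T_K, p$K0, p$z)
  lC <- .log_C(T_K, p$dHc, p$dSc)
  lL <- log(p$L); lD <- log(p$D); lE <- log(p$E)
  lw <- cbind(0, lK, lJ, lJ + lK + lE,
              lL, lL + lK + lD, lL + lJ + lC, lL + lJ + lK + lC + lD + lE)
  m <- lw[cbind(seq_len(n), max.col(lw))]
  e <- exp(lw - m)
  rowSums(e[, 5:8, drop = FALSE]) / rowSums(e)
}

#' Open-probability landscape over a voltage x temperature grid
#'
#' Evaluates [open_probability()] element-wise on ordered voltage (mV) and
#' temperature (degrees Celsius) grids. Grids are stored as given; Kelvin is
#' used internally.
#'
#' @param p a [gating_parameters()] object.
#' @param voltages ordered voltage grid (mV).
#' @param temperatures ordered temperature grid (degrees C).
#' @return An object of class `po_landscape`: a list with `voltages`,
#'   `temperatures`, `po` (matrix, rows = temperatures, cols = voltages) and
#'   `params`.
#' @export
#' @examples
#' ls <- po_landscape(regime_parameters("blue"),
#'                    voltages = seq(-150, 200, 25),
#'                    temperatures = seq(5, 60, 5))
#' range(ls$po)
po_landscape <- function(p, voltages = seq(-150, 200, by = 10),
                         temperatures = seq(5, 60, by = 1)) {
  validate_gating_parameters(p)
  .check_grid(voltages, "voltages")
  .check_grid(temperatures, "temperatures")
  T_K <- celsius_to_kelvin(temperatures)
  po <- outer(T_K, voltages, function(tt, vv) open_probability(vv, tt, p))
  dimnames(po) <- list(format(temperatures, trim = TRUE),
                       format(voltages, trim = TRUE))
  structure(list(voltages = voltages, temperatures = temperatures,
                 po = po, params = p),
            class = "po_landscape")
}

.check_grid <- function(g, what) {
  if (length(g) < 1 || any(!is.finite(g)))
    stop(what, " must be a non-empty finite grid")
  if (length(g) > 1 && !(all(diff(g) > 0) || all(diff(g) < 0)))
    stop(what, " grid must be strictly monotone")
  invisible(g)
}

#' @export
print.po_landscape <- function(x, ...) {
  cat(sprintf("Open-probability landscape [%s]: %d temperatures (%g..%g C) x %d voltages (%g..%g mV)\n",
              x$params$label, length(x$temperatures), min(x$temperatures),
              max(x$temperatures), length(x$voltages), min(x$voltages),
              max(x$voltages)))
  cat(sprintf("  Po range: %.4g .. %.4g\n", min(x$po), max(x$po)))
  invisible(x)
}

#' @export
as.matrix.po_landscape <- function(x, ...) x$po

#' @describeIn po_landscape filled-contour display of the landscape
#'   (temperature on the x axis, voltage on the y axis).
#' @param x a `po_landscape` object.
#' @param ... passed to [graphics::filled.contour()].
#' @export
plot.po_landscape <- function(x, ...) {
  graphics::filled.contour(x$temperatures, x$voltages, x$po,
                           xlab = "Temperature (°C)",
                           ylab = "Voltage (mV)",
                           zlim = c(0, 1),
                           main = paste("Open probability", x$params$label),
                           ...)
  invisible(x)
}

#' Write / read a landscape as a CSV matrix
#'
#' Layout: header row of voltages (mV), first column of temperatures
#' (degrees C), body of open probabilities.
#'
#' @param x a `po_landscape` object.
#' @param path output path.
#' @return `write_landscape_csv` returns `path` invisibly;
#'   `read_landscape_csv` returns a list with `voltages`, `temperatures`, `po`.
#' @export
write_landscape_csv <- function(x, path) {
  stopifnot(inherits(x, "po_landscape"))
  df <- data.frame(temperature_C = x$temperatures, x$po, check.names = FALSE)
  names(df) <- c("temperature_C", paste0("V_", x$voltages, "_mV"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landscape_csv
#' @export
read_landscape_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "temperature_C")
    stop("landscape CSV must start with a temperature_C column")
  voltages <- as.numeric(sub("^V_(.*)_mV$", "\\1", names(df)[-1]))
  list(voltages = voltages, temperatures = df$temperature_C,
       po = as.matrix(df[, -1, drop = FALSE]))
}
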