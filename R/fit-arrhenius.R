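#' Arrhenius fit of rate versus temperature
#'
#' Ordinary least squares of ln(rate) on 1/T; the activation energy is
#' Ea = -slope * R, reported in kJ mol^-1, together with the equivalent Q10
#' over the default 10-degree window (see [q10_from_ea()]).
#'
#' @param T_K absolute temperatures (K); at least 3 unless exactly 2 points
#'   are supplied (then the line passes through both).
#' @param rate rates (s^-1), strictly positive.
#' @return An object of class `arrhenius_fit` with `Ea_kJ`, `intercept`
#'   (ln A), `Q10`, `T_range_C`, `fit` and `data`.
#' @export
#' @examples
#' T_K <- celsius_to_kelvin(c(12, 20, 25, 30, 35))
#' r <- 1e12 * exp(-87.6e3 / (8.314 * T_K))
#' fit_arrhenius(T_K, r)   # recovers Ea = 87.6 kJ/mol, Q10 ~ 3.3
fit_arrhenius <- function(T_K, rate) {
  stopifnot(length(T_K) == length(rate))
  keep <- is.finite(T_K) & is.finite(rate)
  T_K <- T_K[keep]; rate <- rate[keep]
  .check_T(T_K)
  if (any(rate <= 0)) stop("rates must be strictly positive")
  if (length(T_K) < 2) stop("need at least 2 temperatures")
  x <- 1 / T_K
  fit <- stats::lm(log(rate) ~ x)
  slope <- stats::coef(fit)[["x"]]
  Ea_kJ <- -slope * .R_J / 1000
  structure(list(Ea_kJ = Ea_kJ,
                 intercept = stats::coef(fit)[["(Intercept)"]],
                 Q10 = q10_from_ea(Ea_kJ),
                 T_range_C = range(kelvin_to_celsius(T_K)),
                 fit = fit,
                 data = data.frame(T_K = T_K, rate = rate)),
            class = "arrhenius_fit")
}

#' Convert an Arrhenius activation energy to a Q10
#'
#' Q10 = exp[(Ea/R)(1/T1 - 1/T2)] with T2 - T1 = 10 K. The default window,
#' 290.65 to 300.65 K, is a 10-degree interval centred on the midpoint of
#' the 10-35 degree working range used for the kinetic comparisons.
#'
#' @param Ea_kJ activation energy (kJ mol^-1).
#' @param T1_K,T2_K window bounds (K), `T2_K > T1_K`.
#' @return Dimensionless Q10.
#' @export
#' @examples
#' q10_from_ea(87.6)   # 3.3 after 1-decimal rounding
#' q10_from_ea(67.2)   # 2.5
q10_from_ea <- function(Ea_kJ, T1_K = 290.65, T2_K = 300.65) {
  stopifnot(T2_K > T1_K)
  exp((Ea_kJ * 1000 / .R_J) * (1 / T1_K - 1 / T2_K))
}

#' @export
coef.arrhenius_fit <- function(object, ...) {
  c(Ea_kJ = object$Ea_kJ, intercept = object$intercept, Q10 = object$Q10)
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("Arrhenius fit over %.1f..%.1f C: Ea = %.2f kJ/mol (Q10 = %.2f)\n",
              x$T_range_C[1], x$T_range_C[2], x$Ea_kJ, x$Q10))
  invisible(x)
}

#' @export
predict.arrhenius_fit <- function(object, newdata = NULL, ...) {
  T_K <- if (is.null(newdata)) object$data$T_K else newdata$T_K
  exp(object$intercept - object$Ea_kJ * 1000 / (.R_J * T_K))
}

#' @export
plot.arrhenius_fit <- function(x, ...) {
  graphics::plot(1000 / x$data$T_K, log(x$data$rate),
                 xlab = "1000/T (1/K)", ylab = "ln(rate)", ...)
  graphics::abline(x$intercept, -x$Ea_kJ / .R_J, col = 2)
  invisible(x)
}
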