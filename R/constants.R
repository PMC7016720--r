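#' Physical constants used throughout the package
#'
#' Gas constant in the two unit systems the package works in (model
#' thermodynamics in kcal, Arrhenius kinetics in kJ), the Faraday constant,
#' and the kcal-to-kJ conversion factor.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{R_kcal}{gas constant, kcal mol^-1 K^-1 (1.98720e-3)}
#'   \item{R_kJ}{gas constant, kJ mol^-1 K^-1 (8.314e-3)}
#'   \item{R_J}{gas constant, J mol^-1 K^-1 (8.314)}
#'   \item{F_C}{Faraday constant, C mol^-1 (96485.332)}
#'   \item{kcal_to_kJ}{4.184 kJ per kcal}
#' }
#' @export
#' @examples
#' gating_constants()$R_kcal
gating_constants <- function() {
  list(
    R_kcal = 1.98720e-3,
    R_kJ = 8.314e-3,
    R_J = 8.314,
    F_C = 96485.332,
    kcal_to_kJ = 4.184
  )
}

.R_KCAL <- 1.98720e-3
.R_J <- 8.314
.F_C <- 96485.332
.KCAL_TO_KJ <- 4.184
.T0_K <- 273.15

#' Temperature unit conversions
#'
#' @param celsius,kelvin temperature values to convert.
#' @return Numeric vector in the other unit.
#' @export
celsius_to_kelvin <- function(celsius) celsius + .T0_K

#' @rdname celsius_to_kelvin
#' @export
kelvin_to_celsius <- function(kelvin) kelvin - .T0_K

# RT/F in mV at absolute temperature T (K); ~25.693 mV at 298.15 K
.rt_over_f_mV <- function(T_K) 1000 * .R_J * T_K / .F_C
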