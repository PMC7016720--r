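#' Parameter set of the eight-state allosteric gating model
#'
#' Bundles the nine thermodynamic parameters that define one open-probability
#' landscape: the intrinsic gate equilibrium constant `L`, the voltage-sensor
#' pair (`K0`, `z`), the temperature-sensor enthalpy/entropy pair (`dH`, `dS`),
#' the temperature-dependent sensor-to-gate coupling pair (`dHc`, `dSc`), and
#' the temperature-independent couplings `D` (voltage sensor to gate) and `E`
#' (voltage sensor to temperature sensor).
#'
#' Sign convention: `z > 0` means the voltage sensor is activated by
#' depolarization (the equilibrium constant K(V) = K0 exp(zFV/RT) grows with
#' V). Parameter files written with the opposite exponent convention (negative
#' z for a depolarization-activated sensor) can be normalized on input; see
#' [read_gating_parameters()].
#'
#' @param L intrinsic closed-open equilibrium constant (dimensionless, > 0).
#' @param K0 voltage-sensor equilibrium constant at 0 mV (dimensionless, > 0).
#' @param z apparent gating charge (elementary charges, |z| <= 4).
#' @param dH temperature-sensor enthalpy difference (kcal mol^-1).
#' @param dS temperature-sensor entropy difference (kcal mol^-1 K^-1).
#' @param dHc coupling enthalpy of the temperature-sensor-to-gate factor
#'   C(T) (kcal mol^-1).
#' @param dSc coupling entropy of C(T) (kcal mol^-1 K^-1).
#' @param D voltage-sensor-to-gate allosteric coupling (dimensionless, > 0).
#' @param E voltage-sensor-to-temperature-sensor coupling (dimensionless, > 0).
#' @param label free-text tag for the parameter regime (e.g. "blue").
#' @return An object of class `gating_parameters` (a named list).
#' @seealso [open_probability()], [po_landscape()], [read_gating_parameters()]
#' @export
#' @examples
#' p <- gating_parameters(L = 0.165, K0 = 0.003, z = 0.74,
#'                        dH = 91, dS = 0.317, dHc = 6.1, dSc = 0.0149,
#'                        D = 45, E = 35, label = "blue")
#' open_probability(80, celsius_to_kelvin(25), p)
gating_parameters <- function(L, K0, z, dH, dS, dHc, dSc, D, E, label = "") {
  p <- list(L = as.numeric(L), K0 = as.numeric(K0), z = as.numeric(z),
            dH = as.numeric(dH), dS = as.numeric(dS),
            dHc = as.numeric(dHc), dSc = as.numeric(dSc),
            D = as.numeric(D), E = as.numeric(E), label = as.character(label))
  class(p) <- "gating_parameters"
  validate_gating_parameters(p)
  p
}

#' Validate a gating parameter set
#'
#' Checks positivity of the equilibrium constants and coupling factors and the
#' sanity bound on the gating charge.
#'
#' @param p a `gating_parameters` object.
#' @return `p`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_gating_parameters <- function(p) {
  stopifnot(inherits(p, "gating_parameters"))
  num <- p[c("L", "K0", "z", "dH", "dS", "dHc", "dSc", "D", "E")]
  bad <- names(num)[!vapply(num, function(x) is.numeric(x) && length(x) == 1 &&
                              is.finite(x), logical(1))]
  if (length(bad))
    stop("non-finite or non-scalar gating parameter(s): ",
         paste(bad, collapse = ", "))
  if (p$L <= 0) stop("L must be > 0")
  if (p$K0 <= 0) stop("K0 must be > 0")
  if (abs(p$z) > 4) stop("|z| must be <= 4 elementary charges")
  if (p$D <= 0) stop("D must be > 0")
  if (p$E <= 0) stop("E must be > 0")
  invisible(p)
}

#' @export
print.gating_parameters <- function(x, ...) {
  cat("Eight-state allosteric gating parameters",
      if (nzchar(x$label)) paste0("[", x$label, "]"), "\n")
  cat(sprintf("  gate:     L = %g\n", x$L))
  cat(sprintf("  V-sensor: K0 = %g, z = %g e0\n", x$K0, x$z))
  cat(sprintf("  T-sensor: dH = %g kcal/mol, dS = %g kcal/mol/K (T1/2 = %.1f K)\n",
              x$dH, x$dS, if (x$dS > 0) x$dH / x$dS else NA_real_))
  cat(sprintf("  coupling: D = %g, E = %g, dHc = %g kcal/mol, dSc = %g kcal/mol/K\n",
              x$D, x$E, x$dHc, x$dSc))
  invisible(x)
}

#' @export
as.list.gating_parameters <- function(x, ...) unclass(x)

.PARAM_KEYS <- c("L", "K0", "z", "dH", "dS", "dHc", "dSc", "D", "E")

#' Read and write gating parameter files
#'
#' Parameters are serialized as a flat key/value document (JSON or YAML,
#' decided by file extension) with keys `L, K0, z, dH, dS, dHc, dSc, D, E,
#' label`. Reading is lossless with respect to writing.
#'
#' `z_convention` controls how the sign of `z` on file is interpreted:
#' `"standard"` takes the value as-is (z > 0 depolarization-activated, the
#' package convention); `"inverted"` flips the sign, for files written under
#' the opposite exponent convention where a depolarization-activated sensor
#' carries a negative z.
#'
#' @param path file path; extension `.json`, `.yaml` or `.yml`.
#' @param z_convention `"standard"` or `"inverted"` (sign flip on input).
#' @param p a `gating_parameters` object.
#' @return `read_gating_parameters` returns a `gating_parameters` object;
#'   `write_gating_parameters` returns `path` invisibly.
#' @export
read_gating_parameters <- function(path, z_convention = c("standard", "inverted")) {
  z_convention <- match.arg(z_convention)
  doc <- .read_kv_document(path)
  missing <- setdiff(.PARAM_KEYS, names(doc))
  if (length(missing))
    stop("parameter file ", path, " is missing key(s): ",
         paste(missing, collapse = ", "))
  z <- as.numeric(doc$z)
  if (z_convention == "inverted") z <- -z
  gating_parameters(L = doc$L, K0 = doc$K0, z = z, dH = doc$dH, dS = doc$dS,
                    dHc = doc$dHc, dSc = doc$dSc, D = doc$D, E = doc$E,
                    label = if (is.null(doc$label)) "" else doc$label)
}

#' @rdname read_gating_parameters
#' @export
write_gating_parameters <- function(p, path) {
  validate_gating_parameters(p)
  .write_kv_document(unclass(p), path)
  invisible(path)
}

.read_kv_document <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    stop("unsupported parameter document extension: .", ext,
         " (expected .json, .yaml or .yml)")
  }
}

.write_kv_document <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(x, path, precision = 15)
  } else {
    stop("unsupported parameter document extension: .", ext)
  }
  invisible(path)
}
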