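#' Read and write whole-cell trace CSV files
#'
#' The on-disk trace format is a UTF-8 CSV with header columns `time_s,
#' voltage_mV, temperature_C, current_pA` (comma separator, "." decimal).
#' Extra columns are preserved. Round-trips are lossless at 12 significant
#' digits; reading validates the header and time monotonicity and reports
#' the offending column or line.
#'
#' @param trace a data.frame (or [synthesize_recording()] result) with the
#'   four trace columns.
#' @param path CSV file path.
#' @return `read_trace` returns a data.frame; `write_trace` returns `path`
#'   invisibly.
#' @export
write_trace <- function(trace, path) {
  df <- as.data.frame(trace)
  need <- c("time_s", "voltage_mV", "temperature_C", "current_pA")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("trace lacks column(s): ", paste(missing, collapse = ", "))
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 12))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("time_s", "voltage_mV", "temperature_C", "current_pA")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("trace file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  bad <- which(diff(df$time_s) <= 0)
  if (length(bad))
    stop("non-monotone time_s at line ", bad[1] + 2,  # +1 header, +1 diff
         " of ", path)
  df
}

#' Write an analysis report
#'
#' Serializes one or more fit results as a JSON document with provenance
#' (package version, seed, input hashes) and units metadata for every
#' numeric block.
#'
#' @param results named list of fit objects (`boltzmann_fit`,
#'   `relaxation_fit`, `arrhenius_fit`, `allosteric_fit`) or plain lists.
#' @param path output JSON path.
#' @param seed the seed the analysis ran under (recorded in the report).
#' @param inputs character vector of input file paths to fingerprint.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, seed = NA_integer_,
                         inputs = character()) {
  ser <- lapply(results, .serialize_result)
  doc <- list(
    package = "trpgating",
    version = as.character(utils::packageVersion("trpgating")),
    seed = seed,
    inputs = lapply(inputs, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))),
    results = ser)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(doc, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  file.rename(tmp, path)  # atomic publish
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

.serialize_result <- function(x) {
  if (inherits(x, "boltzmann_fit")) {
    list(type = "boltzmann_fit",
         V50 = list(value = x$V50, units = "mV"),
         z = list(value = x$z, units = "e0"),
         Gmin = list(value = x$Gmin, units = "nS"),
         Gmax = list(value = x$Gmax, units = "nS"),
         Vrev = list(value = x$Vrev, units = "mV"),
         T = list(value = x$T_K, units = "K"),
         residual_norm = list(value = x$residual_norm, units = "nS"),
         flagged = x$flagged, flag_reason = x$flag_reason)
  } else if (inherits(x, "relaxation_fit")) {
    list(type = "relaxation_fit",
         n_components = x$n_components,
         tau_fast = list(value = x$tau_fast, units = "ms"),
         tau_slow = list(value = x$tau_slow, units = "ms"),
         A_fast = list(value = x$A_fast, units = "pA"),
         A_slow = list(value = x$A_slow, units = "pA"),
         tau_w = list(value = x$tau_w, units = "ms"),
         dead_time = list(value = x$dead_time, units = "ms"),
         fallback = x$fallback)
  } else if (inherits(x, "arrhenius_fit")) {
    list(type = "arrhenius_fit",
         Ea = list(value = x$Ea_kJ, units = "kJ/mol"),
         Q10 = list(value = x$Q10, units = "dimensionless"),
         temperature_range = list(value = x$T_range_C, units = "C"))
  } else if (inherits(x, "allosteric_fit")) {
    list(type = "allosteric_fit",
         params = unclass(x$params),
         params_units = list(L = "dimensionless", K0 = "dimensionless",
                             z = "e0", dH = "kcal/mol", dS = "kcal/mol/K",
                             dHc = "kcal/mol", dSc = "kcal/mol/K",
                             D = "dimensionless", E = "dimensionless"),
         frozen = x$frozen,
         objective = x$objective,
         seed = x$seed,
         dispersion = x$dispersion,
         pins = x$pin_table)
  } else {
    x
  }
}
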