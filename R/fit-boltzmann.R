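#' Conductance from current and voltage
#'
#' G = I / (V - Vrev); points at the reversal potential are undefined and
#' returned as `NA`.
#'
#' @param I current (pA).
#' @param V voltage (mV).
#' @param Vrev reversal potential (mV).
#' @return Conductance (nS).
#' @export
conductance_from_iv <- function(I, V, Vrev = 0) {
  out <- I / (V - Vrev)
  out[V == Vrev] <- NA_real_
  out
}

#' Boltzmann fit of a conductance-voltage relation
#'
#' Fits G(V) = (Gmax - Gmin) / (1 + exp(-zF(V - V50)/RT)) + Gmin by
#' Levenberg-Marquardt least squares, with Gmin bounded at zero. The fit is
#' flagged unidentifiable for flat inputs (voltage-insensitive conductance).
#'
#' @param V voltages (mV).
#' @param G conductances (nS), same length as `V`.
#' @param T_K absolute temperature of the recording (K).
#' @param Vrev reversal potential used to form `G` (mV, carried as metadata).
#' @param start optional named list overriding starting values
#'   (`V50`, `z`, `Gmin`, `Gmax`).
#' @return An object of class `boltzmann_fit` with components `V50`, `z`,
#'   `Gmin`, `Gmax`, `Vrev`, `T_K`, `residual_norm`, `flagged`, `flag_reason`,
#'   `data` and the underlying `nls` fit (`fit`, `NULL` when flagged early).
#' @export
#' @examples
#' V <- seq(-150, 100, 25)
#' G <- boltzmann_conductance(V, V50 = 66.5, z = 0.76, Gmin = 0.8,
#'                            Gmax = 23.5, T_K = 298.15)
#' fit_boltzmann(V, G, T_K = 298.15)
fit_boltzmann <- function(V, G, T_K = 298.15, Vrev = 0, start = NULL) {
  stopifnot(length(V) == length(G))
  keep <- is.finite(V) & is.finite(G)
  V <- V[keep]; G <- G[keep]
  if (length(V) < 5)
    stop("need at least 5 (V, G) points spanning V50")
  .check_T(T_K)
  kT <- .rt_over_f_mV(T_K)

  out <- list(V50 = NA_real_, z = NA_real_, Gmin = NA_real_, Gmax = NA_real_,
              Vrev = Vrev, T_K = T_K, residual_norm = NA_real_,
              flagged = FALSE, flag_reason = "",
              data = data.frame(V = V, G = G), fit = NULL)
  class(out) <- "boltzmann_fit"

  spread <- diff(range(G))
  if (spread <= 0 || spread < 0.02 * max(abs(G))) {
    out$flagged <- TRUE
    out$flag_reason <- "flat G-V relation: z unidentifiable"
    out$Gmin <- out$Gmax <- mean(G)
    out$z <- 0
    return(out)
  }

  s <- list(V50 = V[which.min(abs(G - (max(G) + min(G)) / 2))],
            z = 1, Gmin = max(min(G), 0), Gmax = max(G))
  if (!is.null(start)) s[names(start)] <- start

  fit <- tryCatch(
    minpack.lm::nlsLM(
      G ~ (Gmax - Gmin) / (1 + exp(-z * (V - V50) / kT)) + Gmin,
      start = s,
      lower = c(V50 = -500, z = 1e-3, Gmin = 0, Gmax = 1e-12),
      upper = c(V50 = 500, z = 4, Gmin = max(G), Gmax = 10 * max(G)),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    out$flagged <- TRUE
    out$flag_reason <- paste("non-convergence:", conditionMessage(fit))
    return(out)
  }
  cf <- stats::coef(fit)
  out[c("V50", "z", "Gmin", "Gmax")] <-
    as.list(cf[c("V50", "z", "Gmin", "Gmax")])
  out$residual_norm <- sqrt(sum(stats::resid(fit)^2))
  out$fit <- fit
  if (out$Gmax <= out$Gmin) {
    out$flagged <- TRUE
    out$flag_reason <- "Gmax <= Gmin after fit"
  }
  out
}

#' Boltzmann conductance curve
#'
#' Evaluates the two-state Boltzmann conductance model; used both as the
#' prediction function of [fit_boltzmann()] and as a noiseless generator in
#' round-trip validation.
#'
#' @param V voltages (mV).
#' @param V50 half-activation voltage (mV).
#' @param z apparent gating charge (elementary charges).
#' @param Gmin,Gmax minimum and maximum conductance (nS).
#' @param T_K absolute temperature (K).
#' @return Conductances (nS).
#' @export
boltzmann_conductance <- function(V, V50, z, Gmin, Gmax, T_K = 298.15) {
  (Gmax - Gmin) / (1 + exp(-z * (V - V50) / .rt_over_f_mV(T_K))) + Gmin
}

#' @export
coef.boltzmann_fit <- function(object, ...) {
  c(V50 = object$V50, z = object$z, Gmin = object$Gmin, Gmax = object$Gmax)
}

#' @export
predict.boltzmann_fit <- function(object, newdata = NULL, ...) {
  V <- if (is.null(newdata)) object$data$V else newdata$V
  boltzmann_conductance(V, object$V50, object$z, object$Gmin, object$Gmax,
                        object$T_K)
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat("Boltzmann G-V fit\n")
  if (x$flagged) cat("  FLAGGED:", x$flag_reason, "\n")
  cat(sprintf("  V50 = %.2f mV, z = %.3f e0, Gmin = %.3f nS, Gmax = %.3f nS (T = %.2f K)\n",
              x$V50, x$z, x$Gmin, x$Gmax, x$T_K))
  if (is.finite(x$residual_norm))
    cat(sprintf("  residual norm = %.4g nS\n", x$residual_norm))
  invisible(x)
}

#' @export
residuals.boltzmann_fit <- function(object, ...) {
  object$data$G - predict(object)
}

#' @export
plot.boltzmann_fit <- function(x, ...) {
  graphics::plot(x$data$V, x$data$G, xlab = "Voltage (mV)",
                 ylab = "Conductance (nS)", ...)
  vv <- seq(min(x$data$V), max(x$data$V), length.out = 200)
  graphics::lines(vv, boltzmann_conductance(vv, x$V50, x$z, x$Gmin, x$Gmax,
                                            x$T_K), col = 2)
  invisible(x)
}
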