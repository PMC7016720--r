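# Constrained global fit of the eight-state allosteric model.
#
# The optimizer is a compact, seeded differential-evolution (DE/rand/1/bin)
# search over the non-frozen parameters, in a transformed space where the
# multiplicative parameters (L, K0, D, E) live on the log scale. The study.s
# fitting problem constrains equilibria only, and several parameter
# combinations are degenerate; a mild quadratic anchor toward the starting
# parameter set keeps refits on the branch of the solution manifold nearest
# the parent regime, mirroring the sequential constraint scheme in which each
# landscape is refit from the previous one with most parameters frozen.

.FIT_PAR_NAMES <- c("L", "K0", "z", "dH", "dS", "dHc", "dSc", "D", "E")
.LOG_SCALE <- c(L = TRUE, K0 = TRUE, z = FALSE, dH = FALSE, dS = FALSE,
                dHc = FALSE, dSc = FALSE, D = TRUE, E = TRUE)

.DEFAULT_BOUNDS <- list(
  L = c(1e-7, 1e7), K0 = c(1e-7, 10), z = c(0.01, 4),
  dH = c(0, 200), dS = c(0, 1), dHc = c(-60, 60), dSc = c(-0.2, 0.2),
  D = c(1e-7, 1e7), E = c(1e-7, 1e7))

.to_trans <- function(x, names) {
  if (length(names) == 0) return(numeric(0))
  i <- .LOG_SCALE[names]
  x[i] <- log(x[i])
  x
}
.from_trans <- function(x, names) {
  i <- .LOG_SCALE[names]
  x[i] <- exp(x[i])
  x
}

.params_from_vector <- function(theta_free, free, start) {
  p <- unclass(start)
  p[free] <- as.list(theta_free)
  class(p) <- "gating_parameters"
  p
}

#' Constrained global fit of the eight-state allosteric model
#'
#' Estimates the non-frozen gating parameters from normalized
#' conductance-voltage curves and/or open-probability pins by a seeded
#' population-based global search (differential evolution). Conductance
#' curves are normalized by the fitted Boltzmann Gmax at the reference
#' temperature, after which the model's open probability is fit to them
#' directly; pins are target open probabilities at stated (V, T) points and
#' enter as relative residuals.
#'
#' @param start a [gating_parameters()] object: starting values, the values
#'   of all frozen parameters, and the centre of the initial population.
#' @param gv_curves `NULL`, or a data.frame with columns `voltage_mV`,
#'   `conductance` and `temperature_C` (multiple temperatures allowed).
#' @param pins `NULL`, or a data.frame with columns `voltage_mV`,
#'   `temperature_C`, `po`.
#' @param frozen character vector of parameter names held at their `start`
#'   values.
#' @param seed integer seed; the fit is bit-reproducible given a seed.
#' @param reference_temp_C temperature whose curve supplies Gmax for
#'   normalization (defaults to the first curve temperature).
#' @param weights two-element numeric, relative total weight of curve and pin
#'   residuals.
#' @param anchor_weight quadratic pull toward `start`, computed in the
#'   bound-scaled transformed space. Either a single weight for all free
#'   parameters or a named vector (unnamed free parameters get the scalar
#'   default 0.01; a weight of 0 leaves a parameter unregularized). The
#'   anchor resolves exactly degenerate directions (e.g. L versus the
#'   coupling entropy dSc, which enter the open-state weights only through
#'   ln L + dSc/R) toward the parent regime.
#' @param bounds named list of `c(lower, upper)` overrides in natural units.
#' @param pop_size DE population size (default `max(20, 10 * n_free)`).
#' @param generations DE generations.
#' @param n_repeats number of independent restarts (seeds `seed`,
#'   `seed + 1000`, ...); the best restart is returned and the dispersion of
#'   the restart landscapes is reported.
#' @param label label for the fitted parameter set.
#' @return An object of class `allosteric_fit` with elements `params` (the
#'   fitted [gating_parameters()]), `start`, `frozen`, `objective`,
#'   `objective_trace` (best objective per generation, non-increasing),
#'   `pin_table` (pins with achieved Po and relative residuals),
#'   `curve_rmse`, `seed`, `repeats` (per-restart parameter sets and
#'   objectives), `dispersion` (max pairwise |delta Po| across restarts on a
#'   reference grid), `identifiable` and the data used.
#' @export
#' @examples
#' pins <- data.frame(voltage_mV = c(-70, -70, 80, 80),
#'                    temperature_C = c(60, 5, 5, 60),
#'                    po = c(0.15, 0.005, 0.21, 0.71))
#' fit <- fit_allosteric(regime_parameters("blue"), pins = pins,
#'                       frozen = c("K0", "z", "dH", "dS"),
#'                       seed = 1, generations = 60)
#' fit$pin_table
fit_allosteric <- function(start, gv_curves = NULL, pins = NULL,
                           frozen = character(),
                           seed = 1L,
                           reference_temp_C = NULL,
                           weights = c(curves = 1, pins = 1),
                           anchor_weight = 0.01,
                           bounds = NULL,
                           pop_size = NULL,
                           generations = 150L,
                           n_repeats = 1L,
                           label = start$label) {
  validate_gating_parameters(start)
  if (length(frozen)) {
    bad <- setdiff(frozen, .FIT_PAR_NAMES)
    if (length(bad)) stop("unknown frozen parameter(s): ",
                          paste(bad, collapse = ", "))
  }
  free <- setdiff(.FIT_PAR_NAMES, frozen)
  if (is.null(gv_curves) && is.null(pins))
    stop("supply gv_curves, pins, or both")

  curve_data <- NULL
  if (!is.null(gv_curves)) {
    gv_curves <- as.data.frame(gv_curves)
    need <- c("voltage_mV", "conductance", "temperature_C")
    if (!all(need %in% names(gv_curves)))
      stop("gv_curves needs columns ", paste(need, collapse = ", "))
    temps <- unique(gv_curves$temperature_C)
    if (is.null(reference_temp_C)) reference_temp_C <- temps[1]
    ref <- gv_curves[gv_curves$temperature_C == reference_temp_C, ]
    if (nrow(ref) < 5)
      stop("reference-temperature curve has fewer than 5 points")
    bfit <- fit_boltzmann(ref$voltage_mV, ref$conductance,
                          T_K = celsius_to_kelvin(reference_temp_C))
    gmax <- if (bfit$flagged) max(gv_curves$conductance) else bfit$Gmax
    curve_data <- data.frame(
      V = gv_curves$voltage_mV,
      T_K = celsius_to_kelvin(gv_curves$temperature_C),
      gnorm = gv_curves$conductance / gmax)
  }
  pin_data <- NULL
  if (!is.null(pins)) {
    pins <- as.data.frame(pins)
    need <- c("voltage_mV", "temperature_C", "po")
    if (!all(need %in% names(pins)))
      stop("pins needs columns ", paste(need, collapse = ", "))
    if (any(pins$po <= 0 | pins$po >= 1))
      stop("pin targets must lie strictly inside (0, 1)")
    pin_data <- data.frame(V = pins$voltage_mV,
                           T_K = celsius_to_kelvin(pins$temperature_C),
                           po = pins$po)
  }

  n_constraints <- sum(nrow(curve_data), nrow(pin_data))
  identifiable <- length(free) <= n_constraints
  if (!identifiable)
    warning(sprintf("under-constrained fit: %d free parameters (%s) vs %d data constraints",
                    length(free), paste(free, collapse = ", "), n_constraints))

  b <- .DEFAULT_BOUNDS
  if (!is.null(bounds)) {
    for (nm in names(bounds)) {
      if (!nm %in% .FIT_PAR_NAMES) stop("unknown bound name: ", nm)
      b[[nm]] <- bounds[[nm]]
    }
  }
  lo <- .to_trans(vapply(b[free], `[`, numeric(1), 1), free)
  hi <- .to_trans(vapply(b[free], `[`, numeric(1), 2), free)
  theta0 <- .to_trans(unlist(unclass(start)[free]), free)
  theta0 <- pmin(pmax(theta0, lo), hi)
  width <- hi - lo

  aw <- rep(if (is.null(names(anchor_weight))) anchor_weight[1] else 0.01,
            length(free))
  names(aw) <- free
  if (!is.null(names(anchor_weight))) {
    bad <- setdiff(names(anchor_weight), .FIT_PAR_NAMES)
    if (length(bad)) stop("unknown anchor name(s): ", paste(bad, collapse = ", "))
    hit <- intersect(names(anchor_weight), free)
    aw[hit] <- anchor_weight[hit]
  }

  objective <- function(theta) {
    p <- .params_from_vector(.from_trans(theta, free), free, start)
    val <- 0
    if (!is.null(curve_data)) {
      po <- .po_vectorized(curve_data$V, curve_data$T_K, p)
      val <- val + weights[[1]] * mean((po - curve_data$gnorm)^2)
    }
    if (!is.null(pin_data)) {
      po <- .po_vectorized(pin_data$V, pin_data$T_K, p)
      val <- val + weights[[2]] * mean(((po - pin_data$po) / pin_data$po)^2)
    }
    if (length(theta) && any(aw > 0))
      val <- val + mean(aw * ((theta - theta0) / width)^2)
    val
  }

  seeds <- seed + 1000L * (seq_len(n_repeats) - 1L)
  if (length(free) == 0) {
    # everything frozen: no search, just evaluate the start set
    p0 <- start; p0$label <- label
    runs <- list(list(par = numeric(0), value = objective(numeric(0)),
                      trace = numeric(0), params = p0))
  } else {
    runs <- lapply(seeds, function(s) {
      de <- .de_optimize(objective, lo, hi, centre = theta0, seed = s,
                         pop_size = pop_size, generations = generations)
      de$params <- .params_from_vector(.from_trans(de$par, free), free, start)
      de$params$label <- label
      de
    })
  }
  best_i <- which.min(vapply(runs, `[[`, numeric(1), "value"))
  best <- runs[[best_i]]

  dispersion <- NA_real_
  if (n_repeats > 1) {
    vg <- seq(-150, 200, by = 25)
    tg <- celsius_to_kelvin(seq(5, 60, by = 5))
    grid <- expand.grid(V = vg, T_K = tg)
    pos <- vapply(runs, function(r)
      .po_vectorized(grid$V, grid$T_K, r$params), numeric(nrow(grid)))
    dispersion <- max(apply(pos, 1, function(row) diff(range(row))))
  }

  pin_table <- NULL
  if (!is.null(pin_data)) {
    achieved <- .po_vectorized(pin_data$V, pin_data$T_K, best$params)
    pin_table <- data.frame(voltage_mV = pin_data$V,
                            temperature_C = kelvin_to_celsius(pin_data$T_K),
                            target_po = pin_data$po,
                            achieved_po = achieved,
                            rel_residual = (achieved - pin_data$po) / pin_data$po)
  }
  curve_rmse <- NA_real_
  if (!is.null(curve_data)) {
    po <- .po_vectorized(curve_data$V, curve_data$T_K, best$params)
    curve_rmse <- sqrt(mean((po - curve_data$gnorm)^2))
  }

  structure(list(params = best$params,
                 start = start,
                 frozen = frozen,
                 free = free,
                 objective = best$value,
                 objective_trace = best$trace,
                 pin_table = pin_table,
                 curve_rmse = curve_rmse,
                 seed = seed,
                 repeats = lapply(runs, function(r)
                   list(params = r$params, objective = r$value)),
                 dispersion = dispersion,
                 identifiable = identifiable,
                 gv_curves = gv_curves,
                 pins = pins),
            class = "allosteric_fit")
}

# DE/rand/1/bin with bound clipping. Deterministic for a given seed; restores
# the caller's RNG state on exit.
.de_optimize <- function(fn, lo, hi, centre, seed, pop_size = NULL,
                         generations = 150L, F = 0.8, CR = 0.9) {
  d <- length(lo)
  if (is.null(pop_size)) pop_size <- max(20L, 10L * d)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed %% .Machine$integer.max))

  pop <- matrix(stats::runif(pop_size * d, lo, hi), pop_size, d, byrow = TRUE)
  # half the population starts near the centre (parent regime)
  n_near <- pop_size %/% 2
  jitter_sd <- 0.05 * (hi - lo)
  for (i in seq_len(n_near))
    pop[i, ] <- pmin(pmax(centre + stats::rnorm(d, 0, jitter_sd), lo), hi)
  pop[1, ] <- pmin(pmax(centre, lo), hi)

  vals <- apply(pop, 1, fn)
  trace <- numeric(generations)
  for (g in seq_len(generations)) {
    for (i in seq_len(pop_size)) {
      idx <- sample(setdiff(seq_len(pop_size), i), 3)
      mutant <- pop[idx[1], ] + F * (pop[idx[2], ] - pop[idx[3], ])
      cross <- stats::runif(d) < CR
      cross[sample.int(d, 1)] <- TRUE
      trial <- ifelse(cross, mutant, pop[i, ])
      trial <- pmin(pmax(trial, lo), hi)
      v <- fn(trial)
      if (v <= vals[i]) {
        pop[i, ] <- trial
        vals[i] <- v
      }
    }
    trace[g] <- min(vals)
  }
  best <- which.min(vals)
  par <- pop[best, ]
  val <- vals[best]
  # deterministic local polish of the DE optimum
  if (d > 1) {
    pol <- stats::optim(par, function(th) fn(pmin(pmax(th, lo), hi)),
                        method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-12))
    if (pol$value <= val) {
      par <- pmin(pmax(pol$par, lo), hi)
      val <- pol$value
    }
  }
  trace[generations] <- min(trace[generations], val)
  list(par = par, value = val, trace = trace)
}

#' @export
print.allosteric_fit <- function(x, ...) {
  cat("Constrained global fit of the eight-state allosteric model\n")
  cat(sprintf("  objective = %.4g (seed %d, %d restart%s)\n", x$objective,
              x$seed, length(x$repeats), if (length(x$repeats) > 1) "s" else ""))
  cat("  frozen:", if (length(x$frozen)) paste(x$frozen, collapse = ", ")
      else "(none)", "\n")
  if (!x$identifiable)
    cat("  WARNING: under-constrained parameter set\n")
  if (!is.null(x$pin_table)) {
    cat(sprintf("  pins: max |relative residual| = %.3g\n",
                max(abs(x$pin_table$rel_residual))))
  }
  if (is.finite(x$curve_rmse))
    cat(sprintf("  curve RMSE (normalized G): %.4g\n", x$curve_rmse))
  if (is.finite(x$dispersion))
    cat(sprintf("  restart dispersion (max |dPo|): %.3g\n", x$dispersion))
  print(x$params)
  invisible(x)
}

#' @export
coef.allosteric_fit <- function(object, ...) {
  unlist(unclass(object$params)[.FIT_PAR_NAMES])
}

#' @export
predict.allosteric_fit <- function(object, newdata, ...) {
  stopifnot(all(c("voltage_mV", "temperature_C") %in% names(newdata)))
  open_probability(newdata$voltage_mV,
                   celsius_to_kelvin(newdata$temperature_C),
                   object$params)
}

#' @export
summary.allosteric_fit <- function(object, ...) {
  cf <- rbind(start = unlist(unclass(object$start)[.FIT_PAR_NAMES]),
              fitted = coef(object))
  structure(list(coefficients = cf,
                 fold_change = cf["fitted", ] / cf["start", ],
                 frozen = object$frozen,
                 objective = object$objective,
                 pin_table = object$pin_table,
                 dispersion = object$dispersion),
            class = "summary.allosteric_fit")
}

#' @export
print.summary.allosteric_fit <- function(x, ...) {
  cat("Allosteric global fit summary\n\nParameters:\n")
  print(signif(x$coefficients, 4))
  cat("\nFold change (fitted / start):\n")
  print(signif(x$fold_change, 4))
  if (!is.null(x$pin_table)) {
    cat("\nPins:\n")
    print(x$pin_table, digits = 4)
  }
  invisible(x)
}

#' @export
plot.allosteric_fit <- function(x, ...) {
  plot(po_landscape(x$params), ...)
}
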