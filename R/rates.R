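#' Kinetic rate rules for the eight-state model
#'
#' The equilibrium landscape fixes only ratios of forward/backward rates; the
#' absolute time base is set by one reference rate per transition class (gate,
#' voltage sensor, temperature sensor) and an equilibrium-split exponent
#' `phi`: along each edge with full equilibrium constant Keq (including the
#' allosteric factors of the two states) the activating rate is
#' `k_ref * Keq^phi` and the deactivating rate `k_ref * Keq^(phi - 1)`, so
#' detailed balance holds on every edge by construction.
#'
#' Defaults place voltage-step current relaxations in the tens-of-milliseconds
#' range typical of whole-cell TRPA1 recordings.
#'
#' @param k_gate reference rate of gate (closed/open) transitions, s^-1.
#' @param k_vsensor reference rate of voltage-sensor transitions, s^-1.
#' @param k_tsensor reference rate of temperature-sensor transitions, s^-1.
#' @param phi equilibrium-split exponent(s) in [0, 1]: either one scalar for
#'   all three transition classes or a named vector with elements `gate`,
#'   `vsensor`, `tsensor`. With phi = 1 the deactivating rate of a class is
#'   pinned at its reference rate however strong the bias, which keeps sensor
#'   relaxations on an observable time scale.
#' @return An object of class `rate_rules`.
#' @export
rate_rules <- function(k_gate = 100, k_vsensor = 1000, k_tsensor = 1000,
                       phi = 0.5) {
  stopifnot(k_gate > 0, k_vsensor > 0, k_tsensor > 0,
            all(phi >= 0), all(phi <= 1))
  if (length(phi) == 1 && is.null(names(phi))) {
    phi <- c(gate = phi, vsensor = phi, tsensor = phi)
  } else {
    if (!all(c("gate", "vsensor", "tsensor") %in% names(phi)))
      stop("phi must be a scalar or named with gate, vsensor, tsensor")
    phi <- phi[c("gate", "vsensor", "tsensor")]
  }
  structure(list(k_gate = k_gate, k_vsensor = k_vsensor,
                 k_tsensor = k_tsensor, phi = phi),
            class = "rate_rules")
}

#' @export
print.rate_rules <- function(x, ...) {
  cat(sprintf("Rate rules: k_gate = %g /s, k_vsensor = %g /s, k_tsensor = %g /s\n",
              x$k_gate, x$k_vsensor, x$k_tsensor))
  cat(sprintf("  phi: gate = %g, vsensor = %g, tsensor = %g\n",
              x$phi[["gate"]], x$phi[["vsensor"]], x$phi[["tsensor"]]))
  invisible(x)
}

# Cube edges: ordered pairs (a, b) with a the state where the toggled module
# is resting and b where it is active, plus the transition class.
.cube_edges <- local({
  out <- NULL
  for (a in 1:8) for (b in 1:8) {
    d <- .STATE_BITS[b, ] - .STATE_BITS[a, ]
    if (sum(abs(d)) == 1 && sum(d) == 1) {
      cls <- c("v" = "k_vsensor", "t" = "k_tsensor", "g" = "k_gate")[
        names(which(d == 1))]
      out <- rbind(out, data.frame(a = a, b = b, class = cls,
                                   stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
})

# Rates capped here so that extreme equilibrium constants yield a finite,
# stiff-but-integrable generator rather than Inf entries.
.RATE_CAP <- 1e12

#' Transition-rate generator of the eight-state model
#'
#' Builds the 8x8 master-equation generator Q at a fixed voltage and
#' temperature: `Q[i, j]` (i != j) is the transition rate from state i to
#' state j (s^-1) and rows sum to zero. Rates derive from the state
#' statistical weights via the split rule of [rate_rules()], so the stationary
#' distribution of Q equals [state_weights()] and detailed balance holds on
#' all twelve cube edges.
#'
#' @param p a [gating_parameters()] object.
#' @param r a [rate_rules()] object.
#' @param V membrane voltage (mV), scalar.
#' @param T_K absolute temperature (K), scalar.
#' @return An 8x8 numeric matrix with rows summing to zero.
#' @export
build_generator <- function(p, r, V, T_K) {
  stopifnot(inherits(r, "rate_rules"), length(V) == 1, length(T_K) == 1)
  .check_T(T_K)
  lw <- .state_log_weights(V, T_K, p)
  Q <- matrix(0, 8, 8, dimnames = list(.STATE_NAMES, .STATE_NAMES))
  for (e in seq_len(nrow(.cube_edges))) {
    a <- .cube_edges$a[e]; b <- .cube_edges$b[e]
    cls <- .cube_edges$class[e]
    kref <- r[[cls]]
    phi <- r$phi[[sub("^k_", "", cls)]]
    lq <- lw[b] - lw[a]                      # log Keq of this edge
    kf <- kref * exp(phi * lq)
    kb <- kref * exp((phi - 1) * lq)
    m <- max(kf, kb)
    if (m > .RATE_CAP) {                     # scale both: preserves Keq and
      kf <- kf * (.RATE_CAP / m)             # hence exact detailed balance
      kb <- kb * (.RATE_CAP / m)
    }
    Q[a, b] <- kf
    Q[b, a] <- kb
  }
  diag(Q) <- -rowSums(Q)
  Q
}
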