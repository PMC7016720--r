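# Independent brute-force oracle for the eight-state open probability:
# enumerates the eight Boltzmann weights {1, K, J, JKE | L, LKD, LJC,
# LJKCDE} from directly computed log equilibrium constants and takes the
# open/total partition ratio. Kept deliberately separate from the package's
# bit-matrix implementation.
po_bruteforce <- function(V, T_K, p) {
  R <- 1.98720e-3
  kT_mV <- 1000 * 8.314 * T_K / 96485.332
  lJ <- -(p$dH - T_K * p$dS) / (R * T_K)
  lK <- log(p$K0) + p$z * V / kT_mV
  lC <- -(p$dHc - T_K * p$dSc) / (R * T_K)
  lw <- c(0,
          lK,
          lJ,
          lJ + lK + log(p$E),
          log(p$L),
          log(p$L) + lK + log(p$D),
          log(p$L) + lJ + lC,
          log(p$L) + lJ + lK + lC + log(p$D) + log(p$E))
  w <- exp(lw - max(lw))
  sum(w[5:8]) / sum(w)
}

# Random but physically plausible parameter draws; wide enough to include
# extreme exponents in the underlying state weights.
random_params <- function(n, seed = 1, extreme = FALSE) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    if (extreme) {
      gating_parameters(
        L = 10^runif(1, -8, 8), K0 = 10^runif(1, -6, 1),
        z = runif(1, 0.05, 3.5),
        dH = runif(1, 0, 180), dS = runif(1, 0, 0.8),
        dHc = runif(1, -40, 40), dSc = runif(1, -0.15, 0.15),
        D = 10^runif(1, -6, 6), E = 10^runif(1, -6, 6))
    } else {
      gating_parameters(
        L = 10^runif(1, -3, 1), K0 = 10^runif(1, -4, -1),
        z = runif(1, 0.2, 2),
        dH = runif(1, 20, 120), dS = runif(1, 0.05, 0.45),
        dHc = runif(1, -10, 10), dSc = runif(1, -0.03, 0.03),
        D = 10^runif(1, -2, 3), E = 10^runif(1, -2, 3))
    }
  })
}
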