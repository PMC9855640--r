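#' L-type calcium channel gating parameters
#'
#' Six-state Markov model of a single L-type channel with states
#' C1, O2, O3, C4, C5, C6. C6 is the deep resting closed state, C1 the
#' voltage-primed closed state, O2 and O3 conducting states (O3 favoured by
#' strong depolarisation), C4 the Ca:CaM-inactivated (CDI) state and C5 the
#' voltage-inactivated (VDI) state. Only the O2 -> C4 rate depends on the
#' dyadic Ca:CaM concentration:
#'
#' `rate(O2 -> C4) = cdi_factor * k24_base * [Ca:CaM]`
#'
#' with `k24_base = 8 s^-1 uM^-1`. All other transitions use exponential
#' voltage dependence `a * exp(+/- v / b)`; those coefficients are calibrated
#' (not published values) so that channels rest in C6 at -80 mV, open on
#' depolarisation, shift towards O3 for strong depolarisations, and recover
#' from inactivation on a 100-300 ms timescale at rest.
#'
#' @param k24_base CDI rate constant, s^-1 uM^-1 (published default 8).
#' @param k42 CDI recovery rate C4 -> O2, s^-1.
#' @param k12_a,k12_b C1 -> O2 opening `k12_a * exp(v / k12_b)`.
#' @param k21_a,k21_b O2 -> C1 deactivation `k21_a * exp(-v / k21_b)`: fast
#'   on repolarisation, very small at depolarised potentials where
#'   inactivation dominates closing.
#' @param k16_a,k16_b C1 -> C6 deactivation `k16_a * exp(-v / k16_b)`.
#' @param k61_a,k61_b C6 -> C1 activation `k61_a * exp(v / k61_b)`.
#' @param k23_a,k23_b O2 -> O3 `k23_a * exp(v / k23_b)`.
#' @param k32_a,k32_b O3 -> O2 `k32_a * exp(-v / k32_b)`.
#' @param k25_a,k25_b O2 -> C5 (VDI) `k25_a * exp(v / k25_b)`.
#' @param k52_a,k52_b C5 -> O2 recovery `k52_a * exp(-v / k52_b)`.
#' @param n_lcc Channels per release unit (published: 7).
#' @param nu_lcc Per-open-channel Ca2+ flux rate constant into the dyad, s^-1
#'   (driving-force form, calibrated).
#' @param ca_o Extracellular Ca2+, uM.
#' @param cdi_hill Ca2+ stoichiometry of the CDI effector (fixed at 2; lives
#'   in the Ca:CaM binding step).
#' @return An `lcc_params` list.
#' @export
lcc_params <- function(k24_base = 8, k42 = 6,
                       k12_a = 500, k12_b = 12,
                       k21_a = 15,  k21_b = 25,
                       k16_a = 300, k16_b = 12,
                       k61_a = 300, k61_b = 15,
                       k23_a = 80,  k23_b = 40,
                       k32_a = 600, k32_b = 40,
                       k25_a = 8,   k25_b = 20,
                       k52_a = 4,   k52_b = 40,
                       n_lcc = 7, nu_lcc = 30, ca_o = 1800,
                       cdi_hill = 2) {
  p <- as.list(environment())
  num <- unlist(p[setdiff(names(p), "cdi_hill")])
  if (any(!is.finite(num)) || any(num <= 0)) {
    stop("lcc_params: all parameters must be finite and > 0")
  }
  if (cdi_hill != 2) stop("lcc_params: the CDI effector stoichiometry is fixed at 2")
  structure(p, class = "lcc_params")
}

#' LCC state labels in generator order
#' @export
lcc_states <- function() c("C1", "O2", "O3", "C4", "C5", "C6")

#' Continuous-time generator of the six-state LCC model
#'
#' Builds the 6x6 transition-rate matrix among \{C1, O2, O3, C4, C5, C6\} at a
#' given voltage and dyadic Ca:CaM level. Off-diagonal entries are
#' nonnegative transition rates (s^-1); each row sums to zero.
#'
#' @param v Membrane potential, mV.
#' @param ca_cam_dyad Dyadic Ca:CaM, uM (>= 0).
#' @param params An [lcc_params()] object.
#' @param cdi_factor Variant multiplier on `k24_base`, in (0, 1].
#' @return A 6x6 matrix with dimnames [lcc_states()].
#' @examples
#' Q <- lcc_rate_matrix(0, 1)
#' Q["O2", "C4"]   # 8 s^-1 at the default k24 and 1 uM Ca:CaM
#' @export
lcc_rate_matrix <- function(v, ca_cam_dyad, params = lcc_params(),
                            cdi_factor = 1) {
  if (!is.finite(cdi_factor) || cdi_factor <= 0 || cdi_factor > 1) {
    stop("lcc_rate_matrix: cdi_factor must lie in (0, 1]")
  }
  if (!is.finite(ca_cam_dyad) || ca_cam_dyad < 0) {
    stop("lcc_rate_matrix: ca_cam_dyad must be >= 0")
  }
  p <- params
  s <- lcc_states()
  Q <- matrix(0, 6, 6, dimnames = list(s, s))
  Q["C1", "O2"] <- p$k12_a * exp(v / p$k12_b)
  Q["O2", "C1"] <- p$k21_a * exp(-v / p$k21_b)
  Q["C1", "C6"] <- p$k16_a * exp(-v / p$k16_b)
  Q["C6", "C1"] <- p$k61_a * exp(v / p$k61_b)
  Q["O2", "O3"] <- p$k23_a * exp(v / p$k23_b)
  Q["O3", "O2"] <- p$k32_a * exp(-v / p$k32_b)
  Q["O2", "C4"] <- cdi_factor * p$k24_base * ca_cam_dyad
  Q["C4", "O2"] <- p$k42
  Q["O2", "C5"] <- p$k25_a * exp(v / p$k25_b)
  Q["C5", "O2"] <- p$k52_a * exp(-v / p$k52_b)
  diag(Q) <- -rowSums(Q)
  Q
}

#' Stationary distribution of the LCC generator
#'
#' Solves the null space of the generator transpose (the linear system
#' `pi Q = 0`, `sum(pi) = 1`).
#'
#' @inheritParams lcc_rate_matrix
#' @return Named probability vector over [lcc_states()].
#' @export
lcc_stationary <- function(v, ca_cam_dyad, params = lcc_params(),
                           cdi_factor = 1) {
  Q <- lcc_rate_matrix(v, ca_cam_dyad, params, cdi_factor)
  A <- rbind(t(Q), rep(1, 6))
  b <- c(rep(0, 6), 1)
  pi <- qr.solve(A, b)
  pi[pi < 0 & pi > -1e-12] <- 0
  names(pi) <- lcc_states()
  pi / sum(pi)
}

#' Monte Carlo occupancy of a single LCC at clamped conditions
#'
#' Simulates one channel with the same per-step Bernoulli update used by the
#' whole-cell engine (transition probability `1 - exp(-rate * dt)` per step)
#' at fixed voltage and Ca:CaM, recording the state at widely spaced sample
#' times so the samples are approximately independent draws from the
#' stationary distribution.
#'
#' @inheritParams lcc_rate_matrix
#' @param n_samples Number of spaced state samples to record.
#' @param sample_every Spacing between samples, s.
#' @param dt Integration step, s.
#' @param seed Integer seed for the channel's random stream.
#' @param init Initial state index (1..6; default 6 = C6).
#' @return Named vector of occupancy fractions over [lcc_states()], with
#'   attribute `n` = `n_samples`.
#' @export
lcc_occupancy_mc <- function(v, ca_cam_dyad, params = lcc_params(),
                             cdi_factor = 1, n_samples = 2000,
                             sample_every = 0.05, dt = 1e-5, seed = 1,
                             init = 6L) {
  counts <- cpp_lcc_occupancy(
    lcc_rate_matrix(v, ca_cam_dyad, params, cdi_factor),
    as.integer(n_samples), sample_every, dt, as.integer(seed),
    as.integer(init))
  occ <- counts / sum(counts)
  names(occ) <- lcc_states()
  attr(occ, "n") <- as.integer(n_samples)
  occ
}
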