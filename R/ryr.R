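#' Ryanodine receptor (RyR2) gating parameters
#'
#' Two-state (closed/open) RyR2 model with an opening rate activated by
#' dyadic Ca2+ (Hill form), modulated by junctional-SR Ca2+ (saturating,
#' non-decreasing "luminal" factor) and by the open fraction of the cluster
#' (mean-field coupled gating). The closing rate is a Ca2+-independent
#' constant. All constants are calibration parameters (the functional form
#' follows the two-state cytosolic + luminal + coupled-gating scheme; the
#' numbers are tuned so that an isolated 49-channel cluster at diastolic
#' conditions produces sparks with durations in the low tens of ms).
#'
#' @param k_open_base Opening rate scale, s^-1.
#' @param ca_half Dyadic Ca2+ half-activation, uM.
#' @param hill Activation cooperativity (dimensionless).
#' @param lum_floor Luminal factor at empty jSR (dimensionless, >= 0).
#' @param luminal_gain Amplitude of the jSR modulation (dimensionless, >= 0).
#' @param lum_half jSR Ca2+ half-saturation of the luminal factor, uM.
#' @param lum_hill Luminal cooperativity.
#' @param coupling_strength Mean-field cluster coupling coefficient; the
#'   opening rate is multiplied by `1 + coupling_strength * open_fraction`.
#' @param k_close Closing rate, s^-1 (constant).
#' @param n_ryr Channels per cluster (published: 49).
#' @param nu_ryr Per-open-channel release flux rate constant jSR -> dyad,
#'   s^-1 (calibrated).
#' @return An `ryr_params` list.
#' @export
ryr_params <- function(k_open_base = 400, ca_half = 25, hill = 2,
                       lum_floor = 0.05, luminal_gain = 0.95, lum_half = 700,
                       lum_hill = 4, coupling_strength = 1, k_close = 120,
                       n_ryr = 49, nu_ryr = 300) {
  p <- as.list(environment())
  num <- unlist(p)
  if (any(!is.finite(num)) || any(num < 0)) {
    stop("ryr_params: all parameters must be finite and nonnegative")
  }
  if (k_close <= 0) stop("ryr_params: k_close must be > 0")
  structure(p, class = "ryr_params")
}

#' RyR2 opening rate
#'
#' `k_open = k_open_base * H(ca_dyad) * L(ca_jsr) * (1 + c * f_open)` with
#' `H(x) = x^h / (x^h + ca_half^h)` and
#' `L(y) = lum_floor + luminal_gain * y^hl / (y^hl + lum_half^hl)`.
#' Strictly increasing in `ca_dyad` (for `ca_dyad > 0`), non-decreasing in
#' `ca_jsr` and in the cluster open fraction; the closing rate is the
#' constant `k_close` and does not depend on Ca2+.
#'
#' @param ca_dyad Dyadic Ca2+, uM (>= 0).
#' @param ca_jsr Junctional SR Ca2+, uM (>= 0).
#' @param open_fraction Fraction of the cluster currently open, in \[0, 1\].
#' @param params An [ryr_params()] object.
#' @return Opening rate per closed channel, s^-1.
#' @export
ryr_open_rate <- function(ca_dyad, ca_jsr, open_fraction = 0,
                          params = ryr_params()) {
  if (any(ca_dyad < 0) || any(ca_jsr < 0)) {
    stop("ryr_open_rate: concentrations must be >= 0")
  }
  if (any(open_fraction < 0) || any(open_fraction > 1)) {
    stop("ryr_open_rate: open_fraction must lie in [0, 1]")
  }
  p <- params
  act <- ca_dyad^p$hill / (ca_dyad^p$hill + p$ca_half^p$hill)
  lum <- p$lum_floor +
    p$luminal_gain * ca_jsr^p$lum_hill / (ca_jsr^p$lum_hill + p$lum_half^p$lum_hill)
  p$k_open_base * act * lum * (1 + p$coupling_strength * open_fraction)
}

#' Open probability of a clamped RyR2 cluster (engine scheme)
#'
#' Runs the per-step Bernoulli/binomial channel update used by the whole-cell
#' engine for a single cluster at clamped dyadic and jSR Ca2+ (no depletion,
#' no flux feedback) and returns the time-averaged open fraction together
#' with spaced samples of the open count for uncertainty estimates. Intended
#' for validating the engine's gating scheme against an exact event-driven
#' (Gillespie) simulation of the same cluster.
#'
#' @inheritParams ryr_open_rate
#' @param duration Simulated time, s.
#' @param dt Step size, s.
#' @param seed Integer seed.
#' @param sample_every Spacing of recorded open-count samples, s.
#' @return List with `p_open` (time-averaged per-channel open probability),
#'   `samples` (integer open counts at spaced times), `n_ryr`.
#' @export
ryr_cluster_open_probability <- function(ca_dyad, ca_jsr, params = ryr_params(),
                                         duration = 100, dt = 2e-5, seed = 1,
                                         sample_every = 0.05) {
  out <- cpp_ryr_cluster_clamped(ca_dyad, ca_jsr, unclass(params),
                                 duration, dt, as.integer(seed), sample_every)
  list(p_open = out$p_open, samples = as.integer(out$samples),
       n_ryr = params$n_ryr)
}
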