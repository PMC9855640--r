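#' Construct a single-CRU state
#'
#' State of one calcium release unit: the Markov states of its 7 L-type
#' channels, the number of open RyR2s, dyadic subspace and junctional-SR free
#' Ca2+, dyadic Ca:CaM and the sarcolemmal / SR-membrane buffer occupancies.
#'
#' @param params A [default_params()] set (used for channel counts, buffer
#'   totals and equilibria).
#' @param ca_ds Dyadic free Ca2+, uM.
#' @param ca_jsr Junctional SR Ca2+, uM.
#' @param lcc_state Integer vector of channel states (1..6 indexing
#'   [lcc_states()]); default all C6.
#' @param n_ryr_open Open RyR2 count (0..n_ryr).
#' @return A `cru_state` list with buffers initialised at equilibrium with
#'   `ca_ds`.
#' @export
cru_state <- function(params = default_params(), ca_ds = 0.1, ca_jsr = 1000,
                      lcc_state = NULL, n_ryr_open = 0L) {
  nl <- params$lcc$n_lcc
  if (is.null(lcc_state)) lcc_state <- rep(6L, nl)
  stopifnot(length(lcc_state) == nl, all(lcc_state %in% 1:6),
            n_ryr_open >= 0, n_ryr_open <= params$ryr$n_ryr,
            ca_ds >= 0, ca_jsr >= 0)
  b <- params$buffers
  st <- list(
    lcc_state = as.integer(lcc_state),
    n_ryr_open = as.integer(n_ryr_open),
    ca_ds = ca_ds, ca_jsr = ca_jsr,
    ca_cam_ds = cam_equilibrium(ca_ds, cam_kinetics(params$cam$cam_total,
                                                    params$cam$k_on,
                                                    params$cam$k_off)),
    b_sl = b$sl$total * ca_ds / (ca_ds + b$sl$k_off / b$sl$k_on),
    b_srm = b$srm$total * ca_ds / (ca_ds + b$srm$k_off / b$srm$k_on))
  class(st) <- "cru_state"
  st
}

#' Advance one CRU by one step (reference implementation)
#'
#' Readable single-CRU version of the engine update: each channel transitions
#' with probability `1 - exp(-rate * dt)` (one uniform per L-type channel;
#' binomial counts for the RyR2 cluster), the subspace and jSR Ca2+ advance
#' by explicit Euler on the flux balance, the SL/SR buffers by explicit Euler
#' on single-site mass action, and dyadic Ca:CaM by the exact exponential
#' relaxation of the mass-action step. Uses R's RNG stream: set a seed for
#' reproducibility. The compiled ensemble engine implements the identical
#' update; a unit test checks the two agree on the deterministic part.
#'
#' @param state A [cru_state()].
#' @param v Membrane potential, mV.
#' @param ca_myo Bulk myoplasmic Ca2+, uM.
#' @param ca_nsr Network SR Ca2+, uM.
#' @param dt Step, s.
#' @param params A [default_params()] set.
#' @param lcc_scale Beta-adrenergic L-type flux scale.
#' @return List with `state` (advanced `cru_state`) and `fluxes`
#'   (`j_lcc`, `j_ryr`, `j_ds_to_myo` in uM/s referenced to subspace volume,
#'   `j_nsr_to_jsr` in uM/s referenced to jSR volume).
#' @export
step_cru <- function(state, v, ca_myo, ca_nsr, dt, params = default_params(),
                     lcc_scale = 1) {
  stopifnot(inherits(state, "cru_state"), dt > 0)
  p <- params
  Q <- lcc_rate_matrix(v, state$ca_cam_ds, do.call(lcc_params, p$lcc),
                       p$variant$cdi_factor)
  new_lcc <- state$lcc_state
  for (c in seq_along(new_lcc)) {
    s <- new_lcc[c]
    rates <- Q[s, ]; rates[s] <- 0
    rtot <- sum(rates)
    if (rtot <= 0) next
    u <- stats::runif(1)
    pp <- -expm1(-rtot * dt)
    if (u < pp) {
      w <- u / pp * rtot
      new_lcc[c] <- which(w < cumsum(rates))[1]
    }
  }
  ry <- do.call(ryr_params, p$ryr)
  f <- state$n_ryr_open / ry$n_ryr
  ko <- ryr_open_rate(state$ca_ds, state$ca_jsr, f, ry)
  p_open <- -expm1(-ko * dt)
  p_close <- -expm1(-ry$k_close * dt)
  n_up <- stats::rbinom(1, ry$n_ryr - state$n_ryr_open, p_open)
  n_dn <- stats::rbinom(1, state$n_ryr_open, p_close)
  n_ryr <- state$n_ryr_open + n_up - n_dn

  n_open_lcc <- sum(new_lcc %in% c(2L, 3L))  # O2, O3
  j_lcc <- n_open_lcc * p$lcc$nu_lcc * lcc_scale * (p$lcc$ca_o - state$ca_ds)
  j_ryr <- n_ryr * p$ryr$nu_ryr * (state$ca_jsr - state$ca_ds)
  j_eff <- (state$ca_ds - ca_myo) / p$geometry$tau_efflux
  b <- p$buffers
  r_sl <- b$sl$k_on * state$ca_ds * (b$sl$total - state$b_sl) -
    b$sl$k_off * state$b_sl
  r_sr <- b$srm$k_on * state$ca_ds * (b$srm$total - state$b_srm) -
    b$srm$k_off * state$b_srm
  ca2 <- state$ca_ds^2
  lam <- p$cam$k_on * ca2 + p$cam$k_off
  cceq <- p$cam$k_on * ca2 * p$cam$cam_total / lam
  dcc <- (cceq - state$ca_cam_ds) * (-expm1(-lam * dt))
  j_refill <- (ca_nsr - state$ca_jsr) / p$geometry$tau_refill

  out <- state
  out$lcc_state <- new_lcc
  out$n_ryr_open <- as.integer(n_ryr)
  out$ca_ds <- state$ca_ds + dt * (j_lcc + j_ryr - j_eff - r_sl - r_sr) -
    2 * dcc
  out$ca_cam_ds <- state$ca_cam_ds + dcc
  out$b_sl <- state$b_sl + dt * r_sl
  out$b_srm <- state$b_srm + dt * r_sr
  out$ca_jsr <- state$ca_jsr + dt * p$geometry$beta_jsr *
    (j_refill - j_ryr * p$geometry$v_ds_pl / p$geometry$v_jsr_pl)
  for (nm in c("ca_ds", "ca_jsr", "ca_cam_ds", "b_sl", "b_srm")) {
    if (!is.finite(out[[nm]]) || out[[nm]] < 0) {
      stop("step_cru: integration instability, ", nm, " = ", out[[nm]])
    }
  }
  list(state = out,
       fluxes = list(j_lcc = j_lcc, j_ryr = j_ryr, j_ds_to_myo = j_eff,
                     j_nsr_to_jsr = j_refill))
}

#' Deterministic non-junctional DHPR Ca2+ influx
#'
#' A small fraction of L-type channels (default 15%) sits outside the dyads
#' on the external sarcolemma and feeds the bulk myoplasm directly. Modelled
#' as a deterministic influx proportional to that fraction, with a sigmoidal
#' voltage activation and a linear driving-force factor.
#'
#' @param v Membrane potential, mV.
#' @param ca_myo Bulk Ca2+, uM.
#' @param fraction Non-junctional DHPR fraction, in \[0, 0.2\] (default 0.15).
#' @param params A [default_params()] set.
#' @return Influx to the bulk myoplasm, uM/s.
#' @export
nonjunctional_dhpr_flux <- function(v, ca_myo, fraction = 0.15,
                                    params = default_params()) {
  if (fraction < 0 || fraction > 0.2) {
    stop("nonjunctional_dhpr_flux: fraction must lie in [0, 0.2]")
  }
  nj <- params$dhpr_nj
  dinf <- 1 / (1 + exp(-(v - nj$v_half) / nj$v_slope))
  fraction * nj$nu * dinf * (params$lcc$ca_o - ca_myo) / params$lcc$ca_o
}

#' Resting spark calibration run
#'
#' Simulates an unpaced ensemble, detects sparks on every CRU's dyadic trace
#' over the whole run, and returns the spark summary. Used to calibrate the
#' RyR2 cluster constants against the target scale of spontaneous spark
#' durations (low tens of ms).
#'
#' @param params A [default_params()] set.
#' @param n_cru Ensemble size (>= 100 for usable statistics).
#' @param duration Simulated time, s.
#' @param seed Integer seed.
#' @param start_thresh,end_thresh Detection thresholds, uM.
#' @return List with `summary` (a [summarize_sparks()] row), `events` and the
#'   `crusim_ts` object.
#' @export
spark_calibration_run <- function(params = default_params(), n_cru = 200,
                                  duration = 2, seed = 1,
                                  start_thresh = 25, end_thresh = 5) {
  if (n_cru < 100) stop("spark_calibration_run: n_cru must be >= 100")
  prot <- protocol(pacing_hz = 0, duration = duration, n_cru = n_cru,
                   seed = seed, record_fraction = 1)
  ts <- simulate(prot, params)
  ev <- detect_sparks_ts(ts, from = 0, start_thresh = start_thresh,
                         end_thresh = end_thresh)
  list(summary = summarize_sparks(ev, window = duration, n_cru = n_cru,
                                  n_cru_full = params$geometry$n_cru_full),
       events = ev, ts = ts)
}
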