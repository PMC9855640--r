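#' Pacing / experiment protocol
#'
#' Describes one simulation run: ensemble size, duration, pacing, the
#' current-clamp stimulus, beta-adrenergic state and output options. Under
#' the beta-adrenergic flag the L-type Ca2+ flux is scaled by 1.2 and the
#' SERCA flux by 1.3 (published scalings); both are overridable.
#'
#' @param pacing_hz Stimulation frequency, Hz (0 = unpaced/resting).
#' @param duration Simulated time, s.
#' @param n_cru Number of release units in the ensemble.
#' @param beta_adrenergic Logical; applies `lcc_scale`/`serca_scale`.
#' @param lcc_scale Multiplier on L-type (and non-junctional DHPR) Ca2+ flux;
#'   default 1.2 under the beta flag, else 1.
#' @param serca_scale Multiplier on SERCA uptake; default 1.3 under the beta
#'   flag, else 1.
#' @param stim_amplitude Current-clamp pulse amplitude, pA/pF (negative =
#'   depolarising).
#' @param stim_width Pulse width, s.
#' @param stim_start Time of the first stimulus, s.
#' @param seed Integer seed; every per-site random stream derives from it.
#' @param record_fraction Fraction of CRUs whose dyadic traces are retained
#'   (published analysis convention: 0.10).
#' @param out_dt Output sampling cadence, s (must be <= 1 ms for
#'   action-potential metrics).
#' @param clamp Optional voltage-clamp template: a list with vectors `t`
#'   (segment start times, s, first must be 0) and `v` (mV); overrides
#'   pacing.
#' @return A `crusim_protocol` list.
#' @export
protocol <- function(pacing_hz = 1, duration = 5, n_cru = 200,
                     beta_adrenergic = FALSE,
                     lcc_scale = if (beta_adrenergic) 1.2 else 1,
                     serca_scale = if (beta_adrenergic) 1.3 else 1,
                     stim_amplitude = -40, stim_width = 0.002,
                     stim_start = 0.05, seed = 1, record_fraction = 0.10,
                     out_dt = 5e-4, clamp = NULL) {
  stopifnot(pacing_hz >= 0, duration > 0, n_cru >= 1,
            record_fraction >= 0, record_fraction <= 1, out_dt > 0,
            out_dt <= 1e-3)
  if (!beta_adrenergic && (lcc_scale > 1 || serca_scale > 1)) {
    stop("protocol: flux scalings above 1 require beta_adrenergic = TRUE")
  }
  if (!is.null(clamp)) {
    stopifnot(is.list(clamp), length(clamp$t) == length(clamp$v),
              clamp$t[1] == 0, !is.unsorted(clamp$t))
  }
  structure(list(pacing_hz = pacing_hz, duration = duration,
                 n_cru = as.integer(n_cru),
                 beta_adrenergic = beta_adrenergic,
                 lcc_scale = lcc_scale, serca_scale = serca_scale,
                 stim_amplitude = stim_amplitude, stim_width = stim_width,
                 stim_start = stim_start, seed = as.integer(seed),
                 record_fraction = record_fraction, out_dt = out_dt,
                 clamp = clamp),
            class = "crusim_protocol")
}

#' Stimulus onset times implied by a protocol
#' @param prot A [protocol()].
#' @return Numeric vector of stimulus times, s.
#' @export
stim_times <- function(prot) {
  if (prot$pacing_hz <= 0) return(numeric(0))
  seq(prot$stim_start, prot$duration, by = 1 / prot$pacing_hz)
}

#' Run a whole-cell simulation
#'
#' Advances the coupled system (CRU ensemble + bulk compartments + membrane)
#' with the stochastic adaptive-timestep engine. Identical
#' (protocol, params, seed) give bit-identical output; per-site random
#' streams are independent and derived from the protocol seed.
#'
#' @param prot A [protocol()].
#' @param params A [default_params()] parameter set.
#' @param seed Optional override of `prot$seed`.
#' @return A `crusim_ts` object: list with `data` (data frame of sampled
#'   whole-cell variables: `t`, `v`, `ca_myo`, `ca_nsr`, currents, fluxes and
#'   conservation audit columns), `cru` (retained per-CRU traces: `t`, `ids`,
#'   matrices `ca_ds`, `ca_jsr`, `n_ryr_open`, `n_lcc_open`), `stats`
#'   (timestep audit), plus the protocol, parameters and seed.
#' @examples
#' \donttest{
#' ts <- simulate(protocol(pacing_hz = 0, duration = 0.2, n_cru = 20))
#' head(ts$data)
#' }
#' @export
simulate <- function(prot, params = default_params(), seed = NULL) {
  stopifnot(inherits(prot, "crusim_protocol"))
  if (!inherits(params, "crusim_params")) stop("params must come from default_params()")
  pl <- unclass(prot)
  if (!is.null(seed)) pl$seed <- as.integer(seed)
  raw <- cpp_simulate(unclass(params), pl)
  ts <- as.data.frame(raw$ts)
  cru <- raw$cru
  if (!is.null(cru)) cru$t <- ts$t
  structure(list(data = ts, cru = cru, stats = raw$stats,
                 final = list(v = raw$final_v, ca_myo = raw$final_ca_myo,
                              ca_nsr = raw$final_ca_nsr, na_i = raw$final_na_i,
                              k_i = raw$final_k_i),
                 protocol = prot, params = params, seed = pl$seed),
            class = "crusim_ts")
}

#' @export
print.crusim_ts <- function(x, ...) {
  d <- x$data
  cat(sprintf(paste0(
    "<crusim_ts> %d CRUs, %.3g s, %.3g Hz pacing%s, seed %d\n",
    "  %d samples; v range [%.1f, %.1f] mV; ca_myo range [%.3g, %.3g] uM\n",
    "  steps %g (mean dt %.3g s), %g rejected (10%% rule), %g dt shrinks\n"),
    x$protocol$n_cru, x$protocol$duration, x$protocol$pacing_hz,
    if (x$protocol$beta_adrenergic) " (beta)" else "", x$seed,
    nrow(d), min(d$v), max(d$v), min(d$ca_myo), max(d$ca_myo),
    x$stats$n_steps, x$stats$dt_mean,
    x$stats$n_reject_frac, x$stats$n_shrink_inc))
  invisible(x)
}

#' Adaptive timestep controller
#'
#' Pure decision rule used by the engine: the proposed step is rejected
#' (halved) when more than `max_frac_cru` of the CRUs changed channel state,
#' when any tracked concentration's relative Euler increment exceeded
#' `max_rel_inc`, or when the voltage step exceeded `max_dv`; otherwise the
#' step is accepted and dt grows geometrically up to `dt_max`.
#'
#' @param proposed_dt Current step, s.
#' @param n_changed CRUs that changed channel state in the trial step.
#' @param n_cru Ensemble size.
#' @param max_rel_increment Largest relative concentration increment of the
#'   trial step.
#' @param dv_abs Absolute voltage increment of the trial step, mV.
#' @param control List of controller constants (defaults from
#'   [default_params()]`$dt_control`).
#' @return List with `dt` (the dt to use next) and `accept` (logical: was the
#'   trial step acceptable?).
#' @export
adaptive_dt <- function(proposed_dt, n_changed, n_cru,
                        max_rel_increment = 0, dv_abs = 0,
                        control = default_params()$dt_control) {
  frac_viol <- (n_changed > floor(control$max_frac_cru * n_cru)) && n_changed > 1
  inc_viol <- (max_rel_increment > control$max_rel_inc) ||
    (dv_abs > control$max_dv)
  if ((frac_viol || inc_viol) && proposed_dt > control$dt_min) {
    return(list(dt = max(proposed_dt * control$shrink, control$dt_min),
                accept = FALSE))
  }
  list(dt = min(proposed_dt * control$grow, control$dt_max), accept = TRUE)
}

#' Sarcolemmal and SR membrane currents at a given cell state
#'
#' R-side mirror of the engine's current set (Na+ current with
#' Hodgkin-Huxley gates, transient-outward and steady-state K+ currents,
#' inward rectifier, Na/K pump, 3Na:1Ca electrogenic exchanger, background
#' leaks, sarcolemmal Ca2+ pump) plus SERCA uptake and NSR leak fluxes.
#' Currents in pA/pF, outward positive; positive exchanger current is
#' Ca2+-entry (reverse) mode. SERCA scales linearly with `serca_scale`.
#'
#' @param state Named list: `v` (mV), `ca_myo` (uM), `na_i`, `k_i` (mM) and
#'   gate variables `m`, `h`, `j`, `r`, `s` (defaults: steady state at `v`).
#' @param params A [default_params()] set.
#' @param lcc_scale,serca_scale Beta-adrenergic flux scalings.
#' @param ca_nsr NSR Ca2+ for the leak flux, uM.
#' @return Named list of currents (pA/pF) and fluxes (`j_serca`, `j_leak`,
#'   `j_dhpr_nj` in uM/s).
#' @export
membrane_currents <- function(state, params = default_params(),
                              lcc_scale = 1, serca_scale = 1, ca_nsr = 1000) {
  m <- params$membrane
  v <- state$v; ca <- state$ca_myo; na_i <- state$na_i; k_i <- state$k_i
  stopifnot(ca > 0, na_i > 0, k_i > 0)
  gates <- hh_gates_inf(v)
  g <- utils::modifyList(gates, state[intersect(names(state),
                                                c("m", "h", "j", "r", "s"))])
  e_na <- m$rtf * log(m$na_o / na_i)
  e_k <- m$rtf * log(m$k_o / k_i)
  ca_mM <- ca * 1e-3
  e_ca <- 0.5 * m$rtf * log(m$ca_o_mM / ca_mM)
  i_na <- m$g_na * g$m^3 * g$h * g$j * (v - e_na)
  i_to <- m$g_to * g$r * g$s * (v - e_k)
  rss <- 1 / (1 + exp(-(v + 11.5) / 11.82))
  i_ss <- m$g_ss * rss * (v - e_k)
  vk <- v - e_k
  a1 <- 1.02 / (1 + exp(0.2385 * (vk - 59.215)))
  b1 <- (0.49124 * exp(0.08032 * (vk + 5.476)) + exp(0.06175 * (vk - 594.31))) /
    (1 + exp(-0.5143 * (vk + 4.753)))
  i_k1 <- m$g_k1 * a1 / (a1 + b1) * vk
  vfrt <- v / m$rtf
  sig <- (exp(m$na_o / 67.3) - 1) / 7
  fnak <- 1 / (1 + 0.1245 * exp(-0.1 * vfrt) + 0.0365 * sig * exp(-vfrt))
  i_nak <- m$i_nak_max * fnak * (m$k_o / (m$k_o + m$km_ko)) /
    (1 + (m$km_nai / na_i)^1.5)
  na3 <- na_i^3; nao3 <- m$na_o^3
  i_ncx <- m$k_ncx *
    (exp(m$eta_ncx * vfrt) * na3 * m$ca_o_mM -
     exp((m$eta_ncx - 1) * vfrt) * nao3 * ca_mM) /
    ((m$km_na_ncx^3 + nao3) * (m$km_ca_ncx + m$ca_o_mM) *
     (1 + m$ksat_ncx * exp((m$eta_ncx - 1) * vfrt)))
  i_bca <- m$g_bca * (v - e_ca)
  i_bna <- m$g_bna * (v - e_na)
  i_pca <- m$g_pca * ca / (ca + m$km_pca)
  s2 <- params$serca
  loadf <- max(0, 1 - (ca_nsr / s2$nsr_max)^s2$load_hill)
  j_serca <- serca_scale * s2$vmax * loadf * ca^s2$hill /
    (ca^s2$hill + s2$km^s2$hill)
  j_leak <- s2$k_leak * (ca_nsr - ca)
  j_nj <- nonjunctional_dhpr_flux(v, ca, params$dhpr_nj$fraction, params) *
    lcc_scale
  list(i_na = i_na, i_to = i_to, i_ss = i_ss, i_k1 = i_k1, i_nak = i_nak,
       i_ncx = i_ncx, i_bca = i_bca, i_bna = i_bna, i_pca = i_pca,
       j_serca = j_serca, j_leak = j_leak, j_dhpr_nj = j_nj)
}

#' Steady-state Hodgkin-Huxley gate values at a voltage
#' @param v Membrane potential, mV.
#' @return List with `m`, `h`, `j`, `r`, `s`.
#' @keywords internal
#' @export
hh_gates_inf <- function(v) {
  am <- if (abs(v + 47.13) < 1e-6) 3.2 else
    0.32 * (v + 47.13) / (1 - exp(-0.1 * (v + 47.13)))
  bm <- 0.08 * exp(-v / 11)
  if (v < -40) {
    ah <- 0.135 * exp((80 + v) / -6.8)
    bh <- 3.56 * exp(0.079 * v) + 3.1e5 * exp(0.35 * v)
    aj <- (-1.2714e5 * exp(0.2444 * v) - 3.474e-5 * exp(-0.04391 * v)) *
      (v + 37.78) / (1 + exp(0.311 * (v + 79.23)))
    bj <- 0.1212 * exp(-0.01052 * v) / (1 + exp(-0.1378 * (v + 40.14)))
  } else {
    ah <- 0; bh <- 1 / (0.13 * (1 + exp((v + 10.66) / -11.1)))
    aj <- 0; bj <- 0.3 * exp(-2.535e-7 * v) / (1 + exp(-0.1 * (v + 32)))
  }
  list(m = am / (am + bm), h = ah / (ah + bh), j = aj / (aj + bj),
       r = 1 / (1 + exp(-(v + 10.6) / 11.4)),
       s = 1 / (1 + exp((v + 45.3) / 6.88)))
}
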