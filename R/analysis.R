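#' Detect Ca2+ sparks in a dyadic Ca2+ trace
#'
#' A spark starts when the dyadic Ca2+ rises above `start_thresh` (published
#' convention: 25 uM) and terminates when it subsequently falls below
#' `end_thresh` (5 uM). Crossing times are linearly interpolated between
#' samples. Events still in progress at either end of the trace are
#' discarded (this biases durations slightly short; see the methods
#' vignette).
#'
#' @param t Time axis, s (strictly increasing, uniformly sampled).
#' @param ca Dyadic Ca2+ samples, uM (same length as `t`).
#' @param start_thresh Start threshold, uM (default 25).
#' @param end_thresh End threshold, uM (default 5; must be < `start_thresh`).
#' @param cru_id Optional identifier copied into the result.
#' @return A data frame of spark events with columns `cru_id`, `t_start`,
#'   `t_end`, `t_peak` (s), `duration`, `time_to_peak` (ms), `amplitude`
#'   (peak Ca2+, uM). Zero rows when no sparks.
#' @examples
#' t <- seq(0, 0.1, by = 1e-4)
#' ca <- pmax(0, 100 * (1 - abs(t - 0.03) / 0.02))
#' detect_sparks(t, ca)
#' @export
detect_sparks <- function(t, ca, start_thresh = 25, end_thresh = 5,
                          cru_id = NA_integer_) {
  if (length(t) != length(ca)) stop("detect_sparks: t and ca lengths differ")
  if (any(diff(t) <= 0)) stop("detect_sparks: time axis must be strictly increasing")
  if (start_thresh <= end_thresh) stop("detect_sparks: start_thresh must exceed end_thresh")
  empty <- data.frame(cru_id = integer(0), t_start = numeric(0),
                      t_end = numeric(0), t_peak = numeric(0),
                      duration = numeric(0), time_to_peak = numeric(0),
                      amplitude = numeric(0))
  n <- length(t)
  if (n < 2L) return(empty)

  cross_time <- function(i, level) {
    # linear interpolation of the crossing between samples i and i+1
    t[i] + (level - ca[i]) * (t[i + 1] - t[i]) / (ca[i + 1] - ca[i])
  }

  events <- list()
  i <- 1L
  # skip any event already in progress at the trace start
  if (ca[1] >= start_thresh) {
    while (i <= n && ca[i] >= end_thresh) i <- i + 1L
  }
  while (i < n) {
    # find upward crossing of the start threshold
    up <- which(ca[(i + 1L):n] >= start_thresh & ca[i:(n - 1L)] < start_thresh)
    if (!length(up)) break
    iu <- i + up[1] - 1L            # ca[iu] < start <= ca[iu+1]
    t_start <- cross_time(iu, start_thresh)
    # find the subsequent downward crossing of the end threshold
    dn <- which(ca[(iu + 1L):(n - 1L)] >= end_thresh &
                ca[(iu + 2L):n] < end_thresh)
    if (!length(dn)) break          # spark in progress at trace end: discard
    id <- iu + dn[1]                # ca[id] >= end > ca[id+1]
    t_end <- cross_time(id, end_thresh)
    seg <- (iu + 1L):id
    ipk <- seg[which.max(ca[seg])]
    events[[length(events) + 1L]] <- data.frame(
      cru_id = cru_id,
      t_start = t_start, t_end = t_end, t_peak = t[ipk],
      duration = (t_end - t_start) * 1000,
      time_to_peak = (t[ipk] - t_start) * 1000,
      amplitude = ca[ipk])
    i <- id + 1L
  }
  if (!length(events)) return(empty)
  do.call(rbind, events)
}

#' Detect sparks across the retained CRU traces of a simulation
#'
#' @param ts A `crusim_ts` object from [simulate()].
#' @param from Analyse from this time, s. Defaults to the final second of the
#'   run (published analysis window).
#' @param start_thresh,end_thresh Detection thresholds, uM.
#' @return A data frame of spark events (see [detect_sparks()]).
#' @export
detect_sparks_ts <- function(ts, from = NULL, start_thresh = 25, end_thresh = 5) {
  stopifnot(inherits(ts, "crusim_ts"))
  tt <- ts$cru$t
  if (is.null(from)) from <- max(tt[length(tt)] - 1, tt[1])
  keep <- tt >= from
  out <- lapply(seq_along(ts$cru$ids), function(j) {
    detect_sparks(tt[keep], ts$cru$ca_ds[keep, j],
                  start_thresh = start_thresh, end_thresh = end_thresh,
                  cru_id = ts$cru$ids[j])
  })
  do.call(rbind, out)
}

#' Summarise spark events
#'
#' Pools events across CRUs and reports the count, three frequency
#' conventions, and distributional statistics for duration, time-to-peak and
#' amplitude. Frequencies: `freq_per_cru_s` (sparks s^-1 CRU^-1),
#' `freq_cell_s` (scaled to `n_cru_full` release units), and `freq_pooled_ms`
#' (pooled sparks per ms over the analysed subset — the convention of the
#' published spark table).
#'
#' @param events Data frame from [detect_sparks()] / [detect_sparks_ts()].
#' @param window Observation window, s (> 0).
#' @param n_cru Number of CRUs analysed.
#' @param n_cru_full Full-scale release-unit count used for the whole-cell
#'   frequency (default 20000).
#' @return A one-row data frame (`spark_summary`). With zero events the
#'   frequencies are 0 and the distributional columns are `NA` (flagged by
#'   `empty = TRUE`).
#' @export
summarize_sparks <- function(events, window, n_cru, n_cru_full = 20000) {
  if (window <= 0) stop("summarize_sparks: window must be > 0")
  n <- nrow(events)
  base <- data.frame(n_sparks = n, window_s = window, n_cru = n_cru,
                     freq_per_cru_s = n / window / n_cru,
                     freq_cell_s = n / window / n_cru * n_cru_full,
                     freq_pooled_ms = n / (window * 1000),
                     empty = n == 0L)
  qstat <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    c(mean = mean(x), sd = stats::sd(x), q25 = q[1], q50 = q[2], q75 = q[3])
  }
  cols <- c("duration", "time_to_peak", "amplitude")
  for (cl in cols) {
    st <- if (n > 0) qstat(events[[cl]]) else
      c(mean = NA_real_, sd = NA_real_, q25 = NA_real_, q50 = NA_real_,
        q75 = NA_real_)
    names(st) <- paste(cl, names(st), sep = "_")
    base <- cbind(base, as.data.frame(as.list(st)))
  }
  class(base) <- c("spark_summary", class(base))
  base
}

#' Action-potential-duration metrics
#'
#' For each stimulus, the diastolic potential is measured just before the
#' stimulus and the amplitude as peak voltage minus diastolic. APD at
#' repolarisation fraction `f` is the time between the upward and the
#' subsequent downward crossing of the level
#' `diastolic + (1 - f) * amplitude` (so APD90 is measured at 90%
#' repolarisation), with linear interpolation between samples. Beats that
#' have not repolarised to the level when the next stimulus arrives (or the
#' trace ends) are censored at the cycle length and flagged.
#'
#' @param t Time axis, s.
#' @param v Membrane potential, mV.
#' @param stim_times Stimulus onset times, s (>= 1).
#' @param fractions Repolarisation fractions (default 0.5, 0.8, 0.9).
#' @return An `apd_result` list: `beats` (data frame with one row per beat:
#'   `t_stim`, `v_dia`, `v_peak`, `amplitude`, one `apd<f>` column per
#'   fraction in ms, matching `censored_<f>` flags) and `alternans_index`
#'   (named per fraction: mean |successive APD difference| / mean APD).
#' @export
apd_metrics <- function(t, v, stim_times, fractions = c(0.5, 0.8, 0.9)) {
  if (!length(stim_times)) stop("apd_metrics: need at least one stimulus")
  if (any(diff(t) <= 0)) stop("apd_metrics: time axis must be strictly increasing")
  stim_times <- sort(stim_times)
  nb <- length(stim_times)
  ends <- c(stim_times[-1], t[length(t)])
  rows <- vector("list", nb)
  for (b in seq_len(nb)) {
    t0 <- stim_times[b]; t1 <- ends[b]
    pre <- which(t < t0)
    v_dia <- if (length(pre)) v[max(pre)] else v[1]
    seg <- which(t >= t0 & t <= t1)
    if (length(seg) < 3) next
    # include the sample just before the stimulus so the upstroke crossing
    # (often between that sample and the first in-beat sample) is found
    if (min(seg) > 1) seg <- c(min(seg) - 1L, seg)
    v_peak <- max(v[seg])
    amp <- v_peak - v_dia
    row <- list(t_stim = t0, v_dia = v_dia, v_peak = v_peak, amplitude = amp)
    for (f in fractions) {
      lev <- v_dia + (1 - f) * amp
      ts_ <- t[seg]; vs <- v[seg]
      upi <- which(vs[-1] >= lev & vs[-length(vs)] < lev)
      cen <- FALSE
      if (!length(upi)) { apd <- NA_real_; cen <- TRUE } else {
        iu <- upi[1]
        t_up <- ts_[iu] + (lev - vs[iu]) * (ts_[iu + 1] - ts_[iu]) / (vs[iu + 1] - vs[iu])
        after <- iu + which(vs[(iu + 1):(length(vs) - 1)] >= lev &
                            vs[(iu + 2):length(vs)] < lev)
        if (!length(after)) {            # censored: never repolarised
          apd <- (t1 - t_up) * 1000
          cen <- TRUE
        } else {
          id <- after[1]
          t_dn <- ts_[id] + (lev - vs[id]) * (ts_[id + 1] - ts_[id]) / (vs[id + 1] - vs[id])
          apd <- (t_dn - t_up) * 1000
        }
      }
      row[[sprintf("apd%d", round(100 * f))]] <- apd
      row[[sprintf("censored_%d", round(100 * f))]] <- cen
    }
    rows[[b]] <- as.data.frame(row)
  }
  beats <- do.call(rbind, rows)
  ai <- vapply(fractions, function(f) {
    x <- beats[[sprintf("apd%d", round(100 * f))]]
    x <- x[is.finite(x)]
    if (length(x) < 2) return(NA_real_)
    mean(abs(diff(x))) / mean(x)
  }, numeric(1))
  names(ai) <- sprintf("apd%d", round(100 * fractions))
  structure(list(beats = beats, alternans_index = ai, fractions = fractions),
            class = "apd_result")
}

#' @export
print.apd_result <- function(x, ...) {
  cat(sprintf("<apd_result> %d beats; alternans index: %s\n",
              nrow(x$beats),
              paste(sprintf("%s=%.3f", names(x$alternans_index),
                            x$alternans_index), collapse = ", ")))
  invisible(x)
}

#' Welch's two-sample t-test
#'
#' Two-sided t-test for a difference in means under unequal variances and
#' sample sizes (Welch-Satterthwaite degrees of freedom). The statistic and
#' dof are computed directly from the defining formulas; the p-value uses the
#' t distribution. When both samples have zero variance and equal means the
#' result is t = 0, p = 1 by convention. Because simulated spark counts can
#' be enormous (so that tiny mean differences reach significance), the result
#' also carries Cohen's d as an effect size.
#'
#' @param a,b Numeric samples (each of length >= 2).
#' @return List with `t`, `df`, `p_value`, `mean_a`, `mean_b`, `cohens_d`.
#' @examples
#' welch_ttest(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))
#' @export
welch_ttest <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("welch_ttest: each sample needs n >= 2")
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    tstat <- if (mean(a) == mean(b)) 0 else sign(mean(a) - mean(b)) * Inf
    df <- na + nb - 2
    p <- if (tstat == 0) 1 else 0
  } else {
    tstat <- (mean(a) - mean(b)) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- 2 * stats::pt(-abs(tstat), df)
  }
  sp <- sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2))
  d <- if (sp > 0) (mean(a) - mean(b)) / sp else 0
  list(t = tstat, df = df, p_value = p,
       mean_a = mean(a), mean_b = mean(b), cohens_d = d)
}

#' Sodium-calcium exchanger recovery time per beat
#'
#' Time after each stimulus for the exchanger current to return within
#' `tol_frac` of its pre-stimulus (diastolic) level and stay there until the
#' next beat; beats that never recover are censored at the cycle length.
#'
#' @param t Time axis, s.
#' @param i_ncx Exchanger current trace.
#' @param stim_times Stimulus onsets, s.
#' @param tol_frac Recovery band as a fraction of the beat's current
#'   excursion (default 0.1).
#' @return Numeric vector of recovery times, ms (one per beat).
#' @export
ncx_recovery_time <- function(t, i_ncx, stim_times, tol_frac = 0.1) {
  stim_times <- sort(stim_times)
  ends <- c(stim_times[-1], t[length(t)])
  out <- numeric(length(stim_times))
  for (b in seq_along(stim_times)) {
    t0 <- stim_times[b]; t1 <- ends[b]
    pre <- which(t < t0)
    base <- if (length(pre)) i_ncx[max(pre)] else i_ncx[1]
    seg <- which(t >= t0 & t <= t1)
    x <- i_ncx[seg]; ts_ <- t[seg]
    exc <- max(abs(x - base))
    band <- tol_frac * exc
    ok <- abs(x - base) <= band
    # last excursion outside the band defines the recovery point
    out_idx <- which(!ok)
    rec <- if (!length(out_idx)) ts_[1] else if (max(out_idx) == length(x))
      NA_real_ else ts_[max(out_idx) + 1]
    out[b] <- if (is.na(rec)) (t1 - t0) * 1000 else (rec - t0) * 1000
  }
  out
}

#' Beat-to-beat regularity of the Ca2+ transient
#'
#' Quantifies loss of a regular transient train as the alternation index of
#' successive beat peaks: mean |successive peak difference| / mean peak.
#' Near 0 for a regular train; large under alternans or irregular dynamics.
#'
#' @param t Time axis, s.
#' @param ca Myoplasmic Ca2+ trace, uM.
#' @param stim_times Stimulus onsets, s.
#' @return List with `peaks` (per-beat peak Ca2+) and `irregularity`.
#' @export
transient_regularity <- function(t, ca, stim_times) {
  stim_times <- sort(stim_times)
  ends <- c(stim_times[-1], t[length(t)])
  peaks <- vapply(seq_along(stim_times), function(b) {
    seg <- which(t >= stim_times[b] & t <= ends[b])
    if (length(seg) < 2) return(NA_real_)
    max(ca[seg])
  }, numeric(1))
  pk <- peaks[is.finite(peaks)]
  irr <- if (length(pk) < 2) NA_real_ else mean(abs(diff(pk))) / mean(pk)
  list(peaks = peaks, irregularity = irr)
}

#' Box-and-whisker summary plot of spark properties
#'
#' Quartile boxes, whiskers, outlier points and a mean marker for one spark
#' property across conditions (ggplot2 required).
#'
#' @param events Data frame of spark events with an added `condition` column.
#' @param property One of `"duration"`, `"time_to_peak"`, `"amplitude"`.
#' @return A ggplot object.
#' @export
spark_boxplot <- function(events, property = "duration") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("spark_boxplot requires ggplot2")
  }
  stopifnot(property %in% c("duration", "time_to_peak", "amplitude"),
            "condition" %in% names(events))
  ggplot2::ggplot(events,
                  ggplot2::aes(x = .data$condition, y = .data[[property]])) +
    ggplot2::geom_boxplot(outlier.shape = 1) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 4, size = 3) +
    ggplot2::labs(x = NULL,
                  y = switch(property,
                             duration = "spark duration (ms)",
                             time_to_peak = "time to peak (ms)",
                             amplitude = "peak amplitude (uM)"))
}
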