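#' Summarise one simulation run
#'
#' Computes the standard readouts from a `crusim_ts`: per-beat APD50/80/90
#' and alternans index, diastolic and systolic myoplasmic Ca2+, diastolic NSR
#' Ca2+, Ca2+-transient regularity, time-integrated L-type current per beat,
#' mean exchanger recovery time, and the spark summary over the final second
#' of the retained CRU traces.
#'
#' @param ts A `crusim_ts` from [simulate()].
#' @param settle Discard beats (and spark data) before this time, s. Defaults
#'   to the first third of the run.
#' @return A one-row data frame.
#' @export
summarize_run <- function(ts, settle = NULL) {
  stopifnot(inherits(ts, "crusim_ts"))
  d <- ts$data
  prot <- ts$protocol
  if (is.null(settle)) settle <- prot$duration / 3
  st <- stim_times(prot)
  st <- st[st >= settle & st < prot$duration - 0.5 / max(prot$pacing_hz, 1)]
  out <- data.frame(variant = ts$params$variant$name,
                    pacing_hz = prot$pacing_hz,
                    beta = prot$beta_adrenergic, seed = ts$seed,
                    n_cru = prot$n_cru, duration = prot$duration)
  keep <- d$t >= settle
  apdcols <- c(apd50 = NA_real_, apd80 = NA_real_, apd90 = NA_real_,
               alternans_index = NA_real_, ca_dia = NA_real_,
               ca_sys = NA_real_, ca_nsr_dia = NA_real_,
               transient_irregularity = NA_real_,
               lcc_integral = NA_real_, ncx_recovery_ms = NA_real_)
  if (length(st) >= 2) {
    apd <- apd_metrics(d$t, d$v, st)
    b <- apd$beats
    apdcols["apd50"] <- mean(b$apd50, na.rm = TRUE)
    apdcols["apd80"] <- mean(b$apd80, na.rm = TRUE)
    apdcols["apd90"] <- mean(b$apd90, na.rm = TRUE)
    apdcols["alternans_index"] <- apd$alternans_index[["apd80"]]
    # diastolic = just before each stimulus; systolic = per-beat peak
    pre_idx <- vapply(st, function(s0) max(which(d$t < s0)), integer(1))
    apdcols["ca_dia"] <- mean(d$ca_myo[pre_idx])
    tr <- transient_regularity(d$t, d$ca_myo, st)
    apdcols["ca_sys"] <- mean(tr$peaks, na.rm = TRUE)
    apdcols["transient_irregularity"] <- tr$irregularity
    apdcols["ca_nsr_dia"] <- mean(d$ca_nsr[pre_idx])
    # time integral of the (inward) L-type current per beat, pA/pF*ms
    cl <- 1 / prot$pacing_hz
    integ <- vapply(st, function(s0) {
      seg <- d$t >= s0 & d$t < s0 + cl
      sum(-d$i_lcc[seg]) * prot$out_dt * 1e3
    }, numeric(1))
    apdcols["lcc_integral"] <- mean(integ)
    apdcols["ncx_recovery_ms"] <- mean(ncx_recovery_time(d$t, d$i_ncx, st))
  } else {
    apdcols["ca_dia"] <- mean(d$ca_myo[keep])
    apdcols["ca_nsr_dia"] <- mean(d$ca_nsr[keep])
  }
  out <- cbind(out, as.data.frame(as.list(apdcols)))
  if (!is.null(ts$cru)) {
    ev <- detect_sparks_ts(ts)
    sp <- summarize_sparks(ev, window = min(1, prot$duration),
                           n_cru = length(ts$cru$ids),
                           n_cru_full = ts$params$geometry$n_cru_full)
    names(sp) <- paste0("spark_", names(sp))
    out <- cbind(out, sp)
  }
  out
}

#' Run a variant x frequency x beta x seed experiment grid
#'
#' One simulation per grid cell; failures are caught and recorded in the
#' summary table (`error` column) without stopping the grid.
#'
#' @param variants Vector of variant specifications (see [as_cam_variant()]).
#' @param frequencies Pacing frequencies, Hz.
#' @param beta_flags Logical vector of beta-adrenergic states.
#' @param seeds Integer seeds (published protocol: 6 repeats).
#' @param n_cru,duration Ensemble size and run length per cell.
#' @param settle Analysis start time passed to [summarize_run()].
#' @param keep_timeseries Keep the full `crusim_ts` objects in the returned
#'   archive (memory-heavy for large grids).
#' @param params_fn Function(variant) returning the parameter set; default
#'   [default_params()].
#' @param ... Extra arguments to [protocol()].
#' @return List with `summary` (tidy data frame, one row per cell) and
#'   `archive` (list of `crusim_ts` or `NULL`s).
#' @export
run_experiment_grid <- function(variants = c("WT", "mut90", "mut75"),
                                frequencies = c(1, 2, 4, 6),
                                beta_flags = FALSE, seeds = 1,
                                n_cru = 200, duration = 5, settle = NULL,
                                keep_timeseries = FALSE,
                                params_fn = default_params, ...) {
  cells <- expand.grid(variant = variants, hz = frequencies,
                       beta = beta_flags, seed = seeds,
                       stringsAsFactors = FALSE)
  archive <- vector("list", nrow(cells))
  rows <- vector("list", nrow(cells))
  for (k in seq_len(nrow(cells))) {
    ce <- cells[k, ]
    res <- tryCatch({
      pars <- params_fn(as_cam_variant(ce$variant))
      prot <- protocol(pacing_hz = ce$hz, duration = duration, n_cru = n_cru,
                       beta_adrenergic = ce$beta, seed = ce$seed, ...)
      ts <- simulate(prot, pars)
      sm <- summarize_run(ts, settle = settle)
      sm$error <- NA_character_
      if (keep_timeseries) archive[[k]] <- ts
      sm
    }, error = function(e) {
      data.frame(variant = as.character(ce$variant), pacing_hz = ce$hz,
                 beta = ce$beta, seed = ce$seed, n_cru = n_cru,
                 duration = duration, error = conditionMessage(e))
    })
    rows[[k]] <- res
  }
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    r[setdiff(all_cols, names(r))] <- NA
    r[all_cols]
  })
  list(summary = do.call(rbind, rows), archive = archive)
}

#' Rerun the variant-by-frequency experiment grid and audit the trends
#'
#' Drives [run_experiment_grid()] over wild type and the two CDI-reduction
#' mutants (0.90 and 0.75 x k24) at 1/2/4/6 Hz, with and without
#' beta-adrenergic scaling, writes the summary table, per-run manifests and a
#' pass/fail report of the qualitative trend checks (Ca2+ loading, APD and
#' spark ordering with CDI severity and pacing; mutant-specific alternans).
#'
#' @param out_dir Output directory (created if needed).
#' @param preset `"smoke"` (tiny: 1 seed, short runs), `"desk-small"`
#'   (200 CRUs) or `"desk-standard"` (800 CRUs).
#' @param seeds Integer seeds; default 1:6 for the desk presets, 1 for smoke.
#' @return Invisibly, a list with `summary`, `checks` and the output paths.
#' @export
reproduce_paper_grid <- function(out_dir, preset = "desk-small",
                                 seeds = NULL) {
  cfg <- switch(preset,
    smoke = list(n_cru = 40, duration = 1.5, seeds = 1,
                 frequencies = c(1, 4)),
    `desk-small` = list(n_cru = 200, duration = 6, seeds = 1:6,
                        frequencies = c(1, 2, 4, 6)),
    `desk-standard` = list(n_cru = 800, duration = 10, seeds = 1:6,
                           frequencies = c(1, 2, 4, 6)),
    stop("unknown preset: ", preset))
  if (!is.null(seeds)) cfg$seeds <- seeds
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- run_experiment_grid(variants = c("WT", "mut90", "mut75"),
                             frequencies = cfg$frequencies,
                             beta_flags = c(FALSE, TRUE),
                             seeds = cfg$seeds, n_cru = cfg$n_cru,
                             duration = cfg$duration)
  sm <- res$summary
  utils::write.csv(sm, file.path(out_dir, "grid_summary.csv"),
                   row.names = FALSE)
  write_manifest(file.path(out_dir, "manifest.json"),
                 config = list(preset = preset, n_cru = cfg$n_cru,
                               duration = cfg$duration,
                               frequencies = cfg$frequencies),
                 seed = cfg$seeds,
                 outputs = file.path(out_dir, "grid_summary.csv"))
  checks <- grid_trend_checks(sm)
  utils::write.csv(checks, file.path(out_dir, "trend_report.csv"),
                   row.names = FALSE)
  invisible(list(summary = sm, checks = checks,
                 paths = file.path(out_dir,
                                   c("grid_summary.csv", "trend_report.csv",
                                     "manifest.json"))))
}

#' Evaluate the qualitative trend checks on a grid summary table
#'
#' @param sm Summary table from [run_experiment_grid()].
#' @return Data frame with columns `check` and `pass` (NA when the grid does
#'   not contain the cells a check needs).
#' @export
grid_trend_checks <- function(sm) {
  val <- function(variant, hz, beta, col) {
    x <- sm[[col]][sm$variant == variant & sm$pacing_hz == hz &
                   sm$beta == beta & is.na(sm$error)]
    if (!length(x)) NA_real_ else mean(x, na.rm = TRUE)
  }
  cmp <- function(a, b) if (is.na(a) || is.na(b)) NA else a >= b
  hz_hi <- max(sm$pacing_hz)
  checks <- list(
    c("diastolic Ca rises with CDI severity (4 Hz)",
      cmp(val("mut75", 4, FALSE, "ca_dia"), val("WT", 4, FALSE, "ca_dia"))),
    c("NSR loading rises with CDI severity (4 Hz)",
      cmp(val("mut75", 4, FALSE, "ca_nsr_dia"),
          val("WT", 4, FALSE, "ca_nsr_dia"))),
    c("APD50 rises with CDI severity (4 Hz)",
      cmp(val("mut75", 4, FALSE, "apd50"), val("WT", 4, FALSE, "apd50"))),
    c("APD90 rises with CDI severity (4 Hz)",
      cmp(val("mut75", 4, FALSE, "apd90"), val("WT", 4, FALSE, "apd90"))),
    c("spark frequency rises with pacing (WT)",
      cmp(val("WT", 4, FALSE, "spark_freq_per_cru_s"),
          val("WT", 1, FALSE, "spark_freq_per_cru_s"))),
    c("spark frequency rises with CDI severity (4 Hz)",
      cmp(val("mut75", 4, FALSE, "spark_freq_per_cru_s"),
          val("WT", 4, FALSE, "spark_freq_per_cru_s"))),
    c(sprintf("mutant alternans exceeds WT (%g Hz)", hz_hi),
      cmp(val("mut75", hz_hi, FALSE, "alternans_index"),
          val("WT", hz_hi, FALSE, "alternans_index"))),
    c(sprintf("mutant transient irregularity exceeds WT (%g Hz, beta)", hz_hi),
      cmp(val("mut75", hz_hi, TRUE, "transient_irregularity"),
          val("WT", hz_hi, TRUE, "transient_irregularity")))
  )
  data.frame(check = vapply(checks, `[[`, "", 1),
             pass = as.logical(vapply(checks, function(x) x[2], "")),
             stringsAsFactors = FALSE)
}
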