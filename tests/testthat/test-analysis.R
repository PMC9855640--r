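test_that("the detector resolves analytic piecewise-linear sparks exactly", {
  # 0 -> 100 uM over 2 ms, 100 -> 0 over 20 ms, sampled at 0.1 ms
  t <- seq(0, 0.03, by = 1e-4)
  ca <- ifelse(t <= 0.002, t / 0.002 * 100,
               pmax(0, 100 * (1 - (t - 0.002) / 0.020)))
  ev <- detect_sparks(t, ca)
  expect_equal(nrow(ev), 1L)
  t_up <- 25 / 100 * 0.002                       # crossing 25 on the rise
  t_dn <- 0.002 + (1 - 5 / 100) * 0.020          # crossing 5 on the decay
  expect_equal(ev$t_start, t_up, tolerance = 1e-9)
  expect_equal(ev$t_end, t_dn, tolerance = 1e-9)
  expect_equal(ev$duration, (t_dn - t_up) * 1000, tolerance = 1e-6)
  expect_equal(ev$amplitude, 100)
  expect_lte(ev$time_to_peak, ev$duration)
})

test_that("sub-threshold and flat traces yield no sparks", {
  t <- seq(0, 0.1, by = 1e-4)
  expect_equal(nrow(detect_sparks(t, rep(0.1, length(t)))), 0L)
  peaky <- 20 * exp(-(t - 0.05)^2 / 1e-5)        # peaks at 20 uM < 25
  expect_equal(nrow(detect_sparks(t, peaky)), 0L)
  expect_error(detect_sparks(rev(t), rep(1, length(t))), "increasing")
  expect_error(detect_sparks(t, rep(1, length(t)), 5, 25), "exceed")
})

test_that("the detector agrees with a brute-force scanner on random traces", {
  for (sd in 1:20) {
    tr <- random_spark_trace(seed = sd)
    ev <- detect_sparks(tr$t, tr$ca)
    bf <- scan_sparks_bruteforce(tr$t, tr$ca)
    expect_equal(nrow(ev), nrow(bf), info = paste("seed", sd))
    if (nrow(ev)) {
      expect_equal(ev$t_start, bf$t_start, tolerance = 1e-9)
      expect_equal(ev$t_end, bf$t_end, tolerance = 1e-9)
      expect_equal(ev$amplitude, bf$amplitude)
    }
  }
})

test_that("raising the start threshold never increases the spark count", {
  for (sd in 1:10) {
    tr <- random_spark_trace(seed = 30 + sd)
    counts <- vapply(c(10, 25, 50, 90), function(th) {
      nrow(detect_sparks(tr$t, tr$ca, start_thresh = th, end_thresh = 5))
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("spark summaries pool events and report every frequency convention", {
  ev1 <- detect_sparks(seq(0, 0.05, 1e-4),
                       100 * exp(-abs(seq(0, 0.05, 1e-4) - 0.02) / 0.004),
                       cru_id = 1L)
  ev2 <- ev1; ev2$cru_id <- 2L
  s <- summarize_sparks(rbind(ev1, ev2), window = 1, n_cru = 2)
  expect_equal(s$n_sparks, 2L)
  expect_equal(s$freq_per_cru_s, 1)
  expect_equal(s$freq_cell_s, 20000)
  expect_equal(s$freq_pooled_ms, 2 / 1000)
  expect_true(s$duration_q25 <= s$duration_q50 &&
              s$duration_q50 <= s$duration_q75)
  e <- summarize_sparks(ev1[0, ], window = 1, n_cru = 2)
  expect_true(e$empty)
  expect_equal(e$freq_per_cru_s, 0)
  expect_true(is.na(e$duration_mean))
})

test_that("APD metrics match closed-form crossings on analytic waveforms", {
  # square pulse: -80 -> +20 for 100 ms
  t <- seq(0, 0.5, by = 2e-4)
  v <- ifelse(t >= 0.1 & t < 0.2, 20, -80)
  a <- apd_metrics(t, v, stim_times = 0.1)
  expect_equal(a$beats$apd50, 100, tolerance = 0.5)
  expect_equal(a$beats$apd80, 100, tolerance = 0.5)
  expect_equal(a$beats$apd90, 100, tolerance = 0.5)

  # instant rise then triangular repolarisation +20 -> -80 over 100 ms:
  # APD_f crossing level = -80 + (1-f)*100, reached at f*100 ms on the ramp
  v2 <- rep(-80, length(t))
  ramp <- t >= 0.1 & t <= 0.2
  v2[ramp] <- 20 - (t[ramp] - 0.1) / 0.1 * 100
  a2 <- apd_metrics(t, v2, stim_times = 0.1)
  expect_equal(a2$beats$apd50, 50, tolerance = 0.5)
  expect_equal(a2$beats$apd80, 80, tolerance = 0.5)
  expect_equal(a2$beats$apd90, 90, tolerance = 0.5)
  expect_true(a2$beats$apd50 <= a2$beats$apd80 &&
              a2$beats$apd80 <= a2$beats$apd90)
})

test_that("alternating APs give a positive alternans index, constant APs zero", {
  t <- seq(0, 4, by = 5e-4)
  v <- rep(-80, length(t))
  stims <- seq(0.1, 3.6, by = 0.5)
  for (k in seq_along(stims)) {
    w <- if (k %% 2 == 0) 0.2 else 0.1         # alternate 200/100 ms
    v[t >= stims[k] & t < stims[k] + w] <- 20
  }
  a <- apd_metrics(t, v, stims)
  expect_gt(a$alternans_index[["apd80"]], 0.2)
  v_const <- rep(-80, length(t))
  for (k in seq_along(stims)) v_const[t >= stims[k] & t < stims[k] + 0.1] <- 20
  # tiny residual comes from sample-grid alignment of the pulse edges
  expect_lt(apd_metrics(t, v_const, stims)$alternans_index[["apd80"]], 5e-3)
})

test_that("beats that never repolarise are censored at the cycle length", {
  t <- seq(0, 1, by = 5e-4)
  v <- ifelse(t >= 0.1, 20, -80)               # depolarises and stays up
  a <- apd_metrics(t, v, stim_times = c(0.1, 0.6))
  expect_true(a$beats$censored_90[1])
  expect_equal(a$beats$apd90[1], 500, tolerance = 1)
})

test_that("Welch's t-test matches long-hand formula evaluation", {
  w <- welch_ttest(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))
  expect_equal(w$t, -1)
  expect_equal(w$df, 8)
  expect_equal(w$p_value, 2 * pt(-1, 8))
  for (sd in 1:10) {
    set.seed(sd)
    a <- rnorm(sample(5:40, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1), sd = runif(1, 0.5, 3))
    w <- welch_ttest(a, b)
    d <- welch_direct(a, b)
    expect_equal(w$t, d$t, tolerance = 1e-12)
    expect_equal(w$df, d$df, tolerance = 1e-12)
    expect_equal(w$p_value, d$p, tolerance = 1e-12)
    # and against the standard library implementation
    r <- stats::t.test(a, b)
    expect_equal(w$t, unname(r$statistic), tolerance = 1e-10)
    expect_equal(w$p_value, r$p.value, tolerance = 1e-10)
  }
  ident <- welch_ttest(c(1, 1, 1), c(1, 1, 1))
  expect_equal(ident$t, 0)
  expect_equal(ident$p_value, 1)
})

test_that("Welch type-I error is near nominal under the null", {
  set.seed(99)
  n <- 20; reps <- 10000; alpha <- 0.001
  a <- matrix(rnorm(n * reps), n)
  b <- matrix(rnorm(n * reps), n)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- colSums((a - rep(ma, each = n))^2) / (n - 1)
  vb <- colSums((b - rep(mb, each = n))^2) / (n - 1)
  se2 <- va / n + vb / n
  tt <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / n)^2 / (n - 1) + (vb / n)^2 / (n - 1))
  p <- 2 * pt(-abs(tt), df)
  rate <- mean(p < alpha)
  expect_lt(abs(rate - alpha), 3 * sqrt(alpha * (1 - alpha) / reps) + 2 / reps)
})

test_that("exchanger recovery time and transient regularity behave sanely", {
  t <- seq(0, 2, by = 1e-3)
  i <- rep(-0.2, length(t))
  # one beat: excursion then exponential return with tau = 50 ms
  seg <- t >= 0.5
  i[seg] <- -0.2 + 1.0 * exp(-(t[seg] - 0.5) / 0.05)
  rec <- ncx_recovery_time(t, i, stim_times = 0.5, tol_frac = 0.1)
  expect_equal(rec, -log(0.1) * 50, tolerance = 3)  # ~115 ms
  ca <- 0.1 + 0.5 * (sin(2 * pi * t)^2)
  tr <- transient_regularity(t, ca, stim_times = c(0.4, 0.9, 1.4))
  expect_lt(tr$irregularity, 0.05)
})
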