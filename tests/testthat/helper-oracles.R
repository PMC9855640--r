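# Independent oracles kept out of the package: an exact event-driven
# (Gillespie) simulation of one RyR2 cluster at clamped Ca2+, and a
# brute-force sample-by-sample spark scanner.

# time-averaged open fraction of a clamped 49-channel cluster, exact CTMC
gillespie_cluster_popen <- function(ca_ds, ca_jsr, params = ryr_params(),
                                    duration = 10, seed = 1) {
  set.seed(seed)
  n <- 0L
  t <- 0
  open_time <- 0
  nr <- params$n_ryr
  repeat {
    up <- (nr - n) * ryr_open_rate(ca_ds, ca_jsr, n / nr, params)
    dn <- n * params$k_close
    rate <- up + dn
    if (rate <= 0) {
      open_time <- open_time + n / nr * (duration - t)
      break
    }
    dt <- stats::rexp(1, rate)
    if (t + dt >= duration) {
      open_time <- open_time + n / nr * (duration - t)
      break
    }
    open_time <- open_time + n / nr * dt
    t <- t + dt
    n <- n + if (stats::runif(1) < up / rate) 1L else -1L
  }
  open_time / duration
}

# brute-force spark scan: walk samples, track in-spark state, no interpolation
# beyond the same linear rule as the detector
scan_sparks_bruteforce <- function(t, ca, start_thresh = 25, end_thresh = 5) {
  n <- length(t)
  events <- data.frame(t_start = numeric(0), t_end = numeric(0),
                       amplitude = numeric(0))
  in_spark <- ca[1] >= start_thresh
  skip_initial <- in_spark  # truncated at window start: discard
  t_start <- NA_real_
  pk <- -Inf
  for (i in 2:n) {
    if (!in_spark) {
      if (ca[i] >= start_thresh && ca[i - 1] < start_thresh) {
        in_spark <- TRUE
        skip_initial <- FALSE
        t_start <- t[i - 1] + (start_thresh - ca[i - 1]) *
          (t[i] - t[i - 1]) / (ca[i] - ca[i - 1])
        pk <- ca[i]
      }
    } else {
      if (ca[i] > pk) pk <- ca[i]
      if (ca[i] < end_thresh && ca[i - 1] >= end_thresh) {
        if (!skip_initial) {
          t_end <- t[i - 1] + (end_thresh - ca[i - 1]) *
            (t[i] - t[i - 1]) / (ca[i] - ca[i - 1])
          events <- rbind(events, data.frame(t_start = t_start, t_end = t_end,
                                             amplitude = pk))
        }
        in_spark <- FALSE
        skip_initial <- FALSE
      }
    }
  }
  events
}

# random piecewise-linear dyadic traces for detector equivalence tests
random_spark_trace <- function(n = 400, seed = 1) {
  set.seed(seed)
  t <- seq(0, 0.2, length.out = n)
  base <- 0.1 + stats::runif(1, 0, 2)
  ca <- rep(base, n)
  for (k in seq_len(sample(1:5, 1))) {
    c0 <- sample(10:(n - 30), 1)
    amp <- stats::runif(1, 3, 160)
    w <- sample(5:25, 1)
    shape <- amp * exp(-abs(seq(-3, 3, length.out = 2 * w + 1)))
    idx <- c0:(c0 + 2 * w)
    idx <- idx[idx <= n]
    ca[idx] <- ca[idx] + shape[seq_along(idx)]
  }
  list(t = t, ca = ca)
}

# direct Welch formula (long-hand, independent of the package code path)
welch_direct <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  t <- (mean(a) - mean(b)) / sqrt(va / na + vb / nb)
  df <- (va / na + vb / nb)^2 /
    ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}
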