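test_that("the opening rate is monotone in each argument", {
  set.seed(7)
  for (k in 1:25) {
    p <- ryr_params(k_open_base = runif(1, 50, 2000),
                    ca_half = runif(1, 5, 60),
                    hill = sample(1:4, 1),
                    luminal_gain = runif(1, 0, 2),
                    lum_half = runif(1, 200, 2000),
                    coupling_strength = runif(1, 0, 3),
                    k_close = runif(1, 20, 300))
    ca <- sort(runif(2, 0.01, 300))
    js <- sort(runif(2, 10, 3000))
    f <- sort(runif(2, 0, 1))
    expect_lt(ryr_open_rate(ca[1], js[2], f[2], p),
              ryr_open_rate(ca[2], js[2], f[2], p))       # strict in ca_ds
    expect_lte(ryr_open_rate(ca[2], js[1], f[2], p),
               ryr_open_rate(ca[2], js[2], f[2], p))      # jSR
    expect_lte(ryr_open_rate(ca[2], js[2], f[1], p),
               ryr_open_rate(ca[2], js[2], f[2], p))      # coupled gating
  }
})

test_that("the basal rate at zero trigger Ca2+ is essentially nil", {
  expect_equal(ryr_open_rate(0, 1000), 0)
  expect_lt(ryr_open_rate(0.1, 1000) * 49, 1.5)  # < 1.5 openings/s/cluster
  expect_error(ryr_open_rate(-1, 1000), "concentrations")
  expect_error(ryr_open_rate(1, 1000, open_fraction = 2), "open_fraction")
})

test_that("the engine's clamped-cluster open probability matches Gillespie", {
  ca <- 5; jsr <- 1000
  pe <- vapply(1:8, function(s) {
    ryr_cluster_open_probability(ca, jsr, duration = 10, dt = 2e-5,
                                 seed = s)$p_open
  }, numeric(1))
  pg <- vapply(1:8, function(s) {
    gillespie_cluster_popen(ca, jsr, duration = 10, seed = 100 + s)
  }, numeric(1))
  se <- sqrt(stats::var(pe) / 8 + stats::var(pg) / 8)
  expect_lt(abs(mean(pe) - mean(pg)), 3 * se)
})

test_that("first-opening latency of a quiescent cluster is exponential", {
  # with all channels closed and clamped Ca2+, the waiting time to the first
  # opening is exactly Exp(n_ryr * k_open); the per-step Bernoulli scheme
  # must reproduce it up to O(rate*dt) discretisation
  p <- ryr_params()
  ca <- 2; jsr <- 1000
  rate <- p$n_ryr * ryr_open_rate(ca, jsr, 0, p)
  lat <- vapply(1:400, function(s) {
    cpp_ryr_cluster_clamped(ca, jsr, unclass(p), 2, 1e-5, s, 1)$first_open_t
  }, numeric(1))
  lat <- lat[lat > 0]
  expect_gt(length(lat), 380)  # nearly all fire within the window
  ks <- suppressWarnings(stats::ks.test(lat, stats::pexp, rate = rate))
  expect_gt(ks$p.value, 0.01)
})
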