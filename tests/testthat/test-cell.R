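test_that("an unpaced cell stays at rest", {
  ts <- simulate(protocol(pacing_hz = 0, duration = 1, n_cru = 30, seed = 4))
  d <- ts$data
  expect_lt(abs(d$v[nrow(d)] - d$v[1]), 1.5)            # mV
  expect_lt(abs(d$ca_myo[nrow(d)] - d$ca_myo[1]) / d$ca_myo[1], 0.2)
  expect_true(all(is.finite(d$v)))
  expect_true(all(d$ca_myo > 0))
})

test_that("fixed-seed reruns are bit-identical; different seeds differ", {
  prot <- protocol(pacing_hz = 2, duration = 0.8, n_cru = 25, seed = 11)
  a <- simulate(prot)
  b <- simulate(prot)
  expect_identical(a$data, b$data)
  expect_identical(a$cru$ca_ds, b$cru$ca_ds)
  c2 <- simulate(prot, seed = 12)
  expect_false(identical(a$data$ca_myo, c2$data$ca_myo))
})

test_that("voltage bookkeeping: dv equals the integrated total current", {
  ts <- simulate(protocol(pacing_hz = 2, duration = 0.8, n_cru = 25, seed = 5))
  d <- ts$data
  lhs <- diff(d$v)
  rhs <- -diff(d$cum_itotal_mv)
  expect_lt(max(abs(lhs - rhs)), 1e-6)
})

test_that("the timestep controller follows the 10%-of-CRUs rule", {
  ctl <- default_params()$dt_control
  # quiescent: no transitions, dt grows toward the ceiling
  r <- adaptive_dt(1e-5, n_changed = 0, n_cru = 200, control = ctl)
  expect_true(r$accept)
  expect_gt(r$dt, 1e-5)
  dt <- 1e-6
  for (i in 1:100) dt <- adaptive_dt(dt, 0, 200, control = ctl)$dt
  expect_equal(dt, ctl$dt_max)
  # forced 20% transition fraction: rejected, dt shrinks
  r <- adaptive_dt(1e-5, n_changed = 40, n_cru = 200, control = ctl)
  expect_false(r$accept)
  expect_lt(r$dt, 1e-5)
  # accuracy violation shrinks dt
  r <- adaptive_dt(1e-5, 0, 200, max_rel_increment = 0.5, control = ctl)
  expect_lt(r$dt, 1e-5)
})

test_that("accepted steps obey the 10% rule on a paced run", {
  ts <- simulate(protocol(pacing_hz = 4, duration = 0.6, n_cru = 50, seed = 2))
  expect_equal(ts$stats$n_accepted_over_rule, 0)
  expect_lte(ts$stats$dt_max_seen, default_params()$dt_control$dt_max)
  expect_gte(ts$stats$dt_min_seen, default_params()$dt_control$dt_min)
})

test_that("SERCA and L-type scalings act linearly on the fluxes", {
  p <- default_params()
  st <- list(v = -20, ca_myo = 0.5, na_i = 10, k_i = 140)
  c1 <- membrane_currents(st, p, serca_scale = 1, ca_nsr = 1000)
  c13 <- membrane_currents(st, p, serca_scale = 1.3, ca_nsr = 1000)
  expect_equal(c13$j_serca / c1$j_serca, 1.3)
  l1 <- membrane_currents(st, p, lcc_scale = 1, ca_nsr = 1000)
  l12 <- membrane_currents(st, p, lcc_scale = 1.2, ca_nsr = 1000)
  expect_equal(l12$j_dhpr_nj / l1$j_dhpr_nj, 1.2)
})

test_that("gradient-driven currents vanish at zero transmembrane gradients", {
  p <- default_params(membrane = list(na_o = 10, k_o = 140, ca_o_mM = 5e-4))
  st <- list(v = 0, ca_myo = 0.5, na_i = 10, k_i = 140)
  cc <- membrane_currents(st, p, ca_nsr = 0.5)
  expect_equal(cc$i_ncx, 0, tolerance = 1e-12)
  expect_equal(cc$i_na, 0, tolerance = 1e-12)
  expect_equal(cc$i_to, 0, tolerance = 1e-12)
  expect_equal(cc$i_k1, 0, tolerance = 1e-12)
  expect_equal(cc$i_bna, 0, tolerance = 1e-12)
  expect_equal(cc$i_bca, 0, tolerance = 1e-12)
  expect_equal(cc$j_leak, 0, tolerance = 1e-12)
})

test_that("reduced CDI never decreases integrated L-type opening under clamp", {
  clamp <- list(t = c(0, 0.02, 0.22), v = c(-84, 0, -84))
  for (s in 1:2) {
    prot <- protocol(pacing_hz = 0, duration = 0.25, n_cru = 200, seed = s,
                     clamp = clamp, record_fraction = 0)
    wt <- simulate(prot, default_params("WT"))
    mu <- simulate(prot, default_params("mut75"))
    expect_gte(sum(mu$data$n_lcc_open), sum(wt$data$n_lcc_open))
  }
})

test_that("the experiment grid returns one row per cell and survives failures", {
  g <- run_experiment_grid(variants = c("WT", "mut75"), frequencies = 2,
                           beta_flags = FALSE, seeds = 1, n_cru = 20,
                           duration = 1.2)
  expect_equal(nrow(g$summary), 2)
  expect_true(all(is.na(g$summary$error)))
  expect_true(all(c("apd50", "apd90", "ca_dia", "spark_n_sparks",
                    "alternans_index") %in% names(g$summary)))
  # an invalid cell is recorded, not fatal
  g2 <- run_experiment_grid(variants = c("WT", "nosuchvariant"),
                            frequencies = 2, beta_flags = FALSE, seeds = 1,
                            n_cru = 5, duration = 0.3)
  expect_equal(nrow(g2$summary), 2)
  expect_true(any(!is.na(g2$summary$error)))
})
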