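test_that("the LCC generator is a valid CTMC generator across a grid", {
  for (v in c(-90, -60, -30, 0, 30, 60)) {
    for (cc in c(0, 0.5, 5, 24)) {
      Q <- lcc_rate_matrix(v, cc)
      expect_lt(max(abs(rowSums(Q))) / max(abs(Q)), 1e-12)
      off <- Q; diag(off) <- 0
      expect_true(all(off >= 0))
    }
  }
})

test_that("the CDI transition rate is cdi_factor * k24 * [Ca:CaM]", {
  Q <- lcc_rate_matrix(0, 1)
  expect_equal(Q["O2", "C4"], 8)  # default k24 at 1 uM effector
  Q <- lcc_rate_matrix(0, 2.5, cdi_factor = 0.74)
  expect_equal(Q["O2", "C4"], 0.74 * 8 * 2.5)
  # deactivation is small relative to inactivation at depolarised potentials
  Qd <- lcc_rate_matrix(10, 20)
  expect_lt(Qd["O2", "C1"], 0.1 * Qd["O2", "C4"])
  expect_error(lcc_rate_matrix(0, 1, cdi_factor = 0), "cdi_factor")
  expect_error(lcc_rate_matrix(0, -1), "ca_cam")
})

test_that("channels rest in C6 at the resting potential", {
  pi <- lcc_stationary(-80, 0.1)
  expect_gt(pi["C6"], 0.99)
  # depolarisation moves mass into open/inactivated states
  pi0 <- lcc_stationary(0, 20)
  expect_lt(pi0["C6"], 0.1)
  expect_gt(pi0["C4"], 0.3)  # CDI dominates with high Ca:CaM
})

test_that("Monte Carlo occupancy matches the eigen-solved stationary law", {
  v <- 0; cc <- 1
  # slowest rates (recovery from inactivation) mix in ~0.25 s; samples are
  # spaced 3 mixing times apart so the binomial error model applies
  n <- 1500
  occ <- lcc_occupancy_mc(v, cc, n_samples = n, sample_every = 0.75,
                          dt = 1e-5, seed = 42)
  pi <- lcc_stationary(v, cc)
  for (s in lcc_states()) {
    tol <- 3 * sqrt(pi[s] * (1 - pi[s]) / n) + 2 / n
    expect_lt(abs(occ[s] - pi[s]), tol)
  }
})
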