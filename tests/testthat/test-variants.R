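test_that("affinity-derived CDI factors reproduce the published multipliers", {
  # WT reference 2.5 uM, dyadic Ca 10 uM
  expect_equal(round(cdi_factor_from_affinity(3.1), 2), 0.99)   # N54I
  expect_equal(round(cdi_factor_from_affinity(38.0), 2), 0.74)  # D96V
  expect_equal(round(cdi_factor_from_affinity(11.0), 2), 0.92)  # N98S
  expect_equal(round(cdi_factor_from_affinity(150.0), 2), 0.41) # D130G
  expect_equal(round(cdi_factor_from_affinity(15.0), 2), 0.89)  # F142L
  expect_identical(cdi_factor_from_affinity(2.5), 1)            # identity
  expect_error(cdi_factor_from_affinity(-1), "finite and > 0")
  expect_error(cdi_factor_from_affinity(38, ca_dyad = 0), "ca_dyad")
})

test_that("the bundled variant table carries the published affinities", {
  vs <- read_variant_table()
  expect_named(vs, c("WT", "N54I", "D96V", "N98S", "D130G", "F142L"))
  expect_identical(vs$WT$cdi_factor, 1)
  got <- round(vapply(vs, `[[`, numeric(1), "cdi_factor"), 2)
  expect_equal(unname(got),
               c(1.00, 0.99, 0.74, 0.92, 0.41, 0.89))
})

test_that("cam_variant validates its inputs", {
  expect_error(cam_variant("X"), "kd_ca")
  expect_error(cam_variant("X", cdi_factor = 1.2), "0, 1")
  expect_error(cam_variant("WT", cdi_factor = 0.9), "exactly 1")
  v <- as_cam_variant("mut75")
  expect_equal(v$cdi_factor, 0.75)
  expect_equal(as_cam_variant(0.9)$cdi_factor, 0.9)
})

test_that("Ca:CaM mass-action rate matches its defining cases", {
  k <- cam_kinetics()
  expect_equal(k$keq, 71.4 / 30)
  # zero Ca: pure dissociation
  expect_equal(cam_binding_rhs(0, 5, k), -71.4 * 5)
  # empty CaM at 10 uM Ca: pure association
  expect_equal(cam_binding_rhs(10, 0, k), 30 * 100 * 24)
  # vanishes at the closed-form equilibrium
  cc <- cam_equilibrium(10, k)
  expect_lt(abs(cam_binding_rhs(10, cc, k)), 1e-8)  # ~1e-15 of the term scale
  expect_error(cam_binding_rhs(1, 30, k), "cam_total")
})

test_that("the rhs root found by bisection equals the closed form", {
  k <- cam_kinetics()
  for (ca in c(0.5, 3, 10, 40)) {
    f <- function(cc) cam_binding_rhs(ca, cc, k)
    root <- stats::uniroot(f, c(0, k$cam_total), tol = 1e-12)$root
    expect_equal(root, cam_equilibrium(ca, k), tolerance = 1e-8)
  }
})
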