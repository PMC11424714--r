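test_that("Bessel ratios satisfy the recurrence identities", {
  set.seed(3)
  for (c0 in c(runif(10, 0.01, 50), 1e-7, 300)) {
    xi <- bessel_ratios(c0)
    expect_equal(xi$xi2 - xi$xi0, 2 / c0, tolerance = 1e-12)
    expect_equal(xi$xi3, 1 + 4 / c0 * xi$xi2, tolerance = 1e-12)
    expect_true(xi$xi0 > 0 && xi$xi0 < 1)
  }
  expect_equal(bessel_ratios(1)$xi0, besselK(1, 0) / besselK(1, 1),
               tolerance = 1e-14)
  expect_equal(bessel_ratios(700)$xi0, 1, tolerance = 1e-2)
  expect_error(bessel_ratios(0), "c > 0")
})

test_that("classical baselines and their equivalence", {
  expect_equal(saffman_delbruck_rotational(), 4 * pi)
  expect_equal(evans_sackmann_rotational(0), 1)
  expect_equal(evans_sackmann_rotational(1),
               1 + 0.5 * besselK(1, 0) / besselK(1, 1), tolerance = 1e-14)
  cs <- seq(0.1, 20, length.out = 40)
  es <- vapply(cs, evans_sackmann_rotational, 0)
  expect_true(all(diff(es) > 0))   # monotone in friction
  expect_equal(resistance_ies(0), 4 * pi)
  # scaled-resistance identity between the two printed forms
  for (c0 in cs) {
    expect_equal(resistance_ies(c0), 4 * pi * evans_sackmann_rotational(c0),
                 tolerance = 1e-12)
  }
})

test_that("correction coefficients reach their analytic frictionless limits", {
  lim <- resistance_corrections(0)
  expect_equal(lim$R10, pi / 2)
  expect_equal(lim$R20, -pi / 32)
  expect_equal(lim$R01, 0); expect_equal(lim$R11, 0); expect_equal(lim$R02, 0)
  # the printed formulas approach the same limits smoothly from c > 0
  for (c0 in c(1e-3, 1e-2)) {
    rc <- resistance_corrections(c0)
    expect_equal(rc$R10, pi / 2, tolerance = 1e-4)
    expect_equal(rc$R20, -pi / 32, tolerance = 5e-2)
    expect_lt(abs(rc$R01), 1e-2)
    expect_lt(abs(rc$R11), 1e-3)
    expect_lt(abs(rc$R02), 5e-2)
  }
  # spot re-evaluation of every printed coefficient at c = 1
  xi0 <- besselK(1, 0) / besselK(1, 1)
  xi2 <- 2 + xi0; xi3 <- 1 + 4 * xi2
  rc <- resistance_corrections(1)
  expect_equal(rc$R10, pi / 8 * (4 + (1 - xi0^2)), tolerance = 1e-13)
  expect_equal(rc$R01, pi * ((1 - xi0^2) - 2 * xi0), tolerance = 1e-13)
  Pi_ <- 14 * xi2^3 + 4 * xi0^2 * xi2 - 24 * xi0 * xi2^2 - xi0 + 7 * xi2
  Lam <- 8 * xi2^2 * (xi0^2 - 4 * xi0 * xi2 + xi2^2)
  expect_equal(rc$R20, -pi / 512 / xi3 * (Pi_ + Lam), tolerance = 1e-13)
  expect_equal(rc$R11, pi / 8 * (xi0 * (xi0^2 - 1) + 2 * xi0^2 - 1),
               tolerance = 1e-13)
  expect_equal(rc$R02, pi / 4 * (3 * xi0 * (xi0^2 - 1) + (8 * xi0^2 - 5) + 4 * xi0),
               tolerance = 1e-13)
})

test_that("mobility report is internally consistent", {
  rep <- mobility(0.3, 0.2, 1.5)
  expect_equal(rep$R_total,
               rep$R_ies + rep$R10 * 0.3 + rep$R01 * 0.2 +
                 rep$R20 * 0.09 + rep$R11 * 0.06 + rep$R02 * 0.04,
               tolerance = 1e-13)
  expect_equal(rep$mu10, -rep$R10 / rep$R_ies, tolerance = 1e-13)
  expect_equal(rep$mu20, rep$mu10^2 - rep$R20 / rep$R_ies, tolerance = 1e-13)
  expect_equal(rep$mu11, 2 * rep$mu10 * rep$mu01 - rep$R11 / rep$R_ies,
               tolerance = 1e-13)
  expect_equal(rep$mu02, rep$mu01^2 - rep$R02 / rep$R_ies, tolerance = 1e-13)
  # inverse-series property: mu * R = 1 + O(eps^3)
  eps <- 1e-3
  r2 <- mobility(eps, eps, 1)
  expect_lt(abs(r2$mu_total * r2$R_total - 1), 1e-8)
  # isotropic input: mobility is exactly the reciprocal base resistance
  r0 <- mobility(0, 0, 2)
  expect_equal(r0$mu_total, 1 / r0$R_ies, tolerance = 1e-14)
  # frictionless input flags beta as undefined
  expect_false(mobility(0.5, 0.4, 0)$beta_defined)
  expect_equal(mobility(0.5, 0.4, 0)$R01, 0)
})

test_that("frictionless mobility expansion has the printed Taylor coefficients", {
  for (A in c(0.05, 0.2)) {
    expect_equal(mobility(A, 0, 0)$mu_total,
                 1 / (4 * pi) * (1 - A / 8 + 3 * A^2 / 128), tolerance = 1e-13)
  }
})

test_that("mobility corrections show the documented c-dependence", {
  cs <- exp(seq(log(0.01), log(100), length.out = 30))
  # friction-anisotropy-only correction is positive over the whole range
  dmu_beta <- vapply(cs, function(c0) {
    r <- mobility(0, 0.5, c0); r$mu_total - r$mu_ies
  }, 0)
  expect_true(all(dmu_beta > 0))
  # viscosity-anisotropy-only correction is largest at weak friction and
  # decays to zero at strong friction
  dmu_A <- vapply(cs, function(c0) {
    r <- mobility(0.5, 0, c0); r$mu_total - r$mu_ies
  }, 0)
  expect_true(all(diff(abs(dmu_A)) < 1e-12))
  expect_lt(abs(dmu_A[length(cs)]), abs(dmu_A[1]) / 50)
})

test_that("base velocity and pressure of the isotropic substrate-coupled film", {
  expect_equal(ies_velocity(1, 1)$v_theta, 1)
  expect_equal(ies_velocity(2, 1)$v_theta, besselK(2, 1) / besselK(1, 1),
               tolerance = 1e-14)
  expect_lt(ies_velocity(30, 1)$v_theta, 1e-11)   # exponential screening
  expect_error(ies_velocity(0.5, 1), "inside")
  # frictionless limit of the base state approaches the vortex field
  for (c0 in c(1e-2, 1e-4)) {
    expect_equal(ies_velocity(2 * c0, c0)$v_theta, 0.5, tolerance = 5 * c0)
  }
  expect_equal(base_pressure_correction(2, 0.7, 1, 0), 0)
  expect_equal(base_pressure_correction(2, 0, 1, 1), 0)
  expect_equal(base_pressure_correction(1.7, 0.4, 1, 0.5),
               0.5 / 2 * besselK(1.7, 2) / besselK(1, 1) * sin(0.8),
               tolerance = 1e-14)
  # rim value joins the frictionless rim pressure as c -> 0
  for (c0 in c(1e-2, 1e-3, 1e-4)) {
    expect_equal(base_pressure_correction(c0, 0.6, c0, 1),
                 rim_pressure(0.6, 0, 1), tolerance = 5 * c0)
  }
})

test_that("torque routes agree: rim identity vs direct stress integration", {
  # isotropic frictionless field h0 = a/rho
  expect_equal(torque_from_mode_derivatives(-1, 0, 0), 4 * pi)
  visotropic <- function(r, t) list(v_rho = 0 * r, v_theta = 1 / r)
  expect_equal(torque_stress_integral(visotropic, A = 0, b = 0), 4 * pi,
               tolerance = 1e-8)
  # anisotropic exact field: full traction integral against the closed form
  pr <- suppressWarnings(disk_problem(fluid_from_anisotropies(4)))
  vexact <- function(r, t) exact_velocity(r, t, pr)
  expect_equal(torque_stress_integral(vexact, A = 4, b = 0),
               2 * pi * sqrt(8), tolerance = 1e-6)
  # b enters delta_pm but integrates out of the net torque
  prb <- suppressWarnings(disk_problem(fluid_from_anisotropies(4, 1)))
  vb <- function(r, t) exact_velocity(r, t, prb)
  expect_equal(torque_stress_integral(vb, A = 4, b = 1),
               2 * pi * sqrt(8), tolerance = 1e-6)
})
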