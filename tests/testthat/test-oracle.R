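iso_frictionless <- function() disk_problem(fluid_from_anisotropies(0))

test_that("isotropic frictionless system decouples onto the first mode", {
  sol <- oracle_solve(iso_frictionless(), N_modes = 4)
  expect_equal(sol$c_odd[1], 1, tolerance = 1e-12)
  expect_equal(sol$d_odd[1], -1, tolerance = 1e-12)
  expect_equal(sol$c_odd[-1], rep(0, 3), tolerance = 1e-12)
  expect_equal(as.numeric(sol$R_numeric), 4 * pi, tolerance = 1e-8)
  expect_lt(sol$bc_residual, 1e-12)
})

test_that("angular kernel carries only even harmonics, decoupling opposite parities", {
  # the phi-integrals of the inverse transform vanish whenever the full
  # Fourier indices differ by an odd amount; the mechanism is that the
  # angular kernel Gamma(phi) is even and pi-periodic, hence purely
  # even-harmonic.  Under rigid-rotation forcing this kills every even
  # force mode, which is why the solver carries odd modes only.
  pr <- suppressWarnings(disk_problem(fluid_from_anisotropies(1, 0.3),
                                      friction_from_alphas(1, 0.6)))
  phi <- 2 * pi * (0:127) / 128
  B <- anisotropy_factor(phi, 1)
  sg <- sqrt((1^2 * sin(phi)^2 + 0.6^2 * cos(phi)^2) / B)
  for (mn in list(c(0, 0), c(2, 1), c(1, 3))) {
    G <- gamma_integral(mn[1], mn[2], 1, sg, B)
    odd <- vapply(seq(1, 9, by = 2), function(k) harmonic_amplitude(G, k), 0)
    sine <- vapply(seq(2, 8, by = 2), function(k)
      abs(mean(G * sin(k * phi))), 0)
    expect_lt(max(odd), 1e-13)
    expect_lt(max(sine), 1e-13)
  }
  expect_error(assemble_system(pr, 4, N_quad = 30), "multiple of 4")
})

test_that("frictionless anisotropy reproduces the exact rim coefficient and resistance", {
  pr <- suppressWarnings(disk_problem(fluid_from_anisotropies(4)))
  sol <- oracle_solve(pr, N_modes = 16)
  expect_equal(sol$c_odd[1], sqrt(2), tolerance = 1e-10)
  expect_equal(sol$d_odd[1], -sqrt(2), tolerance = 1e-10)
  expect_equal(as.numeric(sol$R_numeric), 2 * pi * sqrt(8), tolerance = 1e-7)
  # force-mode amplitudes beyond the first vanish at zero friction
  expect_lt(max(abs(sol$c_odd[-1])), 1e-10)
})

test_that("isotropic substrate-coupled limit matches the closed base solution", {
  pr <- disk_problem(fluid_from_anisotropies(0), friction_from_alphas(1, 1))
  sol <- oracle_solve(pr, N_modes = 4)
  xi <- bessel_ratios(1)
  expect_equal(as.numeric(sol$R_numeric), 2 * pi * xi$xi2, tolerance = 1e-8)
  v <- oracle_velocity(c(1, 2, 4), 0.9, sol)
  expect_equal(v$v_theta, besselK(c(1, 2, 4), 1) / besselK(1, 1),
               tolerance = 1e-10)
  expect_equal(v$v_rho, rep(0, 3), tolerance = 1e-12)
})

test_that("spectral velocity agrees with the exact series off the symmetry axes", {
  pr <- suppressWarnings(disk_problem(fluid_from_anisotropies(4)))
  sol <- oracle_solve(pr, N_modes = 16, resistance = FALSE)
  pts_r <- c(1.05, 1.5, 2, 3.5)
  pts_t <- c(0.7, 2.1, 4.0, 5.9)
  vo <- oracle_velocity(pts_r, pts_t, sol)
  ve <- exact_velocity(pts_r, pts_t, pr)
  expect_equal(vo$v_rho, ve$v_rho, tolerance = 1e-6)
  expect_equal(vo$v_theta, ve$v_theta, tolerance = 1e-6)
  expect_error(oracle_velocity(0.9, 0, sol), "outside")
})

test_that("spectral pressure matches the closed forms in all validated regimes", {
  # isotropic friction with b: the printed base correction
  pr <- disk_problem(fluid_from_anisotropies(0, 0.5), friction_from_alphas(1, 1))
  sol <- oracle_solve(pr, N_modes = 4, resistance = FALSE)
  for (r in c(1, 1.5, 3)) for (th in c(pi / 8, 1.1)) {
    expect_equal(oracle_pressure(r, th, sol)$p,
                 base_pressure_correction(r, th, 1, 0.5), tolerance = 1e-7)
  }
  # frictionless anisotropic: interior series and rim resummation
  pr4 <- suppressWarnings(disk_problem(fluid_from_anisotropies(4, 1)))
  sol4 <- oracle_solve(pr4, N_modes = 16, resistance = FALSE)
  expect_equal(oracle_pressure(1.3, 0.6, sol4)$p,
               exact_pressure(1.3, 0.6, pr4)$p, tolerance = 1e-8)
  for (th in c(0.4, pi / 8, 2.0)) {
    expect_equal(oracle_pressure(1, th, sol4)$p, rim_pressure(th, 4, 1),
                 tolerance = 1e-5)
  }
  # isotropic: no pressure at all
  soli <- oracle_solve(iso_frictionless(), N_modes = 2, resistance = FALSE)
  expect_equal(oracle_pressure(c(1, 2), c(0.5, 1.3), soli)$p, c(0, 0),
               tolerance = 1e-12)
})

test_that("pressure gradient closes the momentum balance", {
  # anisotropic + friction + friction anisotropy: no closed form exists;
  # check grad p = nu3 (lambda+ vx,xx + vx,yy - apar^2 vx) pointwise by
  # finite differences (x-component of the momentum equation, f = 0 off
  # the rim)
  A <- 0.5; b <- 0.3; beta <- 0.4
  pr <- disk_problem(fluid_from_anisotropies(A, b),
                     friction_from_alphas(1, 1 - beta))
  sol <- oracle_solve(pr, N_modes = 8, resistance = FALSE)
  x0 <- 1.4; y0 <- 0.8
  h <- 2e-3
  topolar <- function(x, y) list(r = sqrt(x^2 + y^2), t = atan2(y, x))
  vx_at <- function(x, y) {
    pp <- topolar(x, y)
    oracle_velocity(pp$r, pp$t, sol)$v_x
  }
  p_at <- function(x, y) {
    pp <- topolar(x, y)
    oracle_pressure(pp$r, pp$t, sol)$p
  }
  lam_p <- 1 + A / 2 + b
  vxx <- (vx_at(x0 + h, y0) - 2 * vx_at(x0, y0) + vx_at(x0 - h, y0)) / h^2
  vyy <- (vx_at(x0, y0 + h) - 2 * vx_at(x0, y0) + vx_at(x0, y0 - h)) / h^2
  px <- (p_at(x0 + h, y0) - p_at(x0 - h, y0)) / (2 * h)
  rhs <- lam_p * vxx + vyy - pr$c^2 * vx_at(x0, y0)
  expect_equal(px, rhs, tolerance = 5e-3)
})

test_that("spectral solution is divergence-free and symmetric as expected", {
  A <- 0.5
  pr <- disk_problem(fluid_from_anisotropies(A), friction_from_alphas(1, 1))
  sol <- oracle_solve(pr, N_modes = 8, resistance = FALSE)
  vfun <- function(r, t) oracle_velocity(r, t, sol)
  for (pt in list(c(1.4, 0.5), c(2.5, 2.2))) {
    expect_lt(abs(discrete_divergence(vfun, pt[1], pt[2])), 1e-6)
  }
  # quarter-turn symmetry holds for beta = 0 ...
  th <- seq(0, 2 * pi, length.out = 9)[1:8]
  v1 <- oracle_velocity(rep(1.5, 8), th, sol)
  v2 <- oracle_velocity(rep(1.5, 8), th + pi / 2, sol)
  expect_equal(v1$v_theta, v2$v_theta, tolerance = 1e-9)
  expect_equal(v1$v_rho, v2$v_rho, tolerance = 1e-9)
  # ... and is broken by friction anisotropy
  prb <- disk_problem(fluid_from_anisotropies(A),
                      friction_from_alphas(1, 0.5))
  solb <- oracle_solve(prb, N_modes = 8, resistance = FALSE)
  v1b <- oracle_velocity(rep(1.5, 8), th, solb)
  v2b <- oracle_velocity(rep(1.5, 8), th + pi / 2, solb)
  expect_gt(max(abs(v1b$v_theta - v2b$v_theta)), 1e-4)
})

test_that("force-mode amplitudes decay and refinement is converged", {
  pr <- disk_problem(fluid_from_anisotropies(0.8, 0.2),
                     friction_from_alphas(1, 0.7))
  sol <- oracle_solve(pr, N_modes = 8)
  amp <- abs(sol$c_odd) + abs(sol$d_odd)
  expect_true(all(diff(amp[2:8]) < 0))
  sol2 <- oracle_solve(pr, N_modes = 16)
  expect_lt(abs(as.numeric(sol$R_numeric) - as.numeric(sol2$R_numeric)),
            1e-7 + attr(sol$R_numeric, "error_estimate") * 10)
})
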