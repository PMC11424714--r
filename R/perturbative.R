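## Perturbative (second-order in the anisotropies A and beta) resistance and
## mobility of the rotating disk, together with the classical isotropic
## baselines.  c = alpha_par * a is the scaled friction parameter.

#' Modified-Bessel ratios of the scaled friction parameter
#'
#' \eqn{\xi_i = K_i(c)/K_1(c)}.  Only \eqn{\xi_0} requires a Bessel
#' evaluation; \eqn{\xi_2 = 2/c + \xi_0} and \eqn{\xi_3 = 1 + (4/c)\xi_2}
#' follow from the standard recurrence, which keeps the ratios accurate for
#' very small and very large `c` (exponentially scaled Bessel functions are
#' used, so `c` up to ~1e300 is fine).
#'
#' @param c Scaled friction parameter `alpha_par * a`, strictly positive.
#' @return An object of class `"bessel_ratios"`: list with `c`, `xi0`,
#'   `xi2`, `xi3`.
#' @export
bessel_ratios <- function(c) {
  if (!(c > 0)) stop("bessel_ratios requires c > 0; use the frictionless branch at c = 0")
  xi0 <- if (c < 1e-8) {
    # K0/K1 ~ c (log(2/c) - gamma) for c -> 0
    c * (log(2 / c) - 0.5772156649015329)
  } else {
    besselK(c, 0, expon.scaled = TRUE) / besselK(c, 1, expon.scaled = TRUE)
  }
  xi2 <- 2 / c + xi0
  xi3 <- 1 + 4 / c * xi2
  structure(list(c = c, xi0 = xi0, xi2 = xi2, xi3 = xi3),
            class = "bessel_ratios")
}

#' Classical rotational drag of a disk in a thin viscous film
#'
#' The rotational resistance of a disk of radius `a` in an unbounded thin
#' viscous membrane, \eqn{R_R = 4\pi\eta_S a^2}, returned in units
#' \eqn{\eta_S a^2}.
#'
#' @return `4*pi`.
#' @export
saffman_delbruck_rotational <- function() 4 * pi

#' Substrate-coupled rotational drag (scaled)
#'
#' The membrane-on-substrate result
#' \eqn{R_R/(4\pi a^2\eta_S) = 1 + (c/2) K_0(c)/K_1(c)}, which reduces to
#' the unbounded-film value as \eqn{c \to 0}.
#'
#' @param c Scaled friction parameter, `c >= 0`.
#' @return The scaled resistance (1 at `c = 0`).
#' @export
evans_sackmann_rotational <- function(c) {
  if (c < 0) stop("c must be non-negative")
  if (c == 0) return(1)
  1 + c / 2 * bessel_ratios(c)$xi0
}

#' Isotropic base resistance R_IES
#'
#' \eqn{R^{IES} = 2\pi c\,\xi_2 = 2\pi(2 + c\xi_0)} in units
#' \eqn{\nu_3 a^2}; continuous at `c = 0` with value \eqn{4\pi}.
#'
#' @param c Scaled friction parameter, `c >= 0`.
#' @return The base resistance in units `nu3*a^2`.
#' @export
resistance_ies <- function(c) {
  if (c < 0) stop("c must be non-negative")
  if (c == 0) return(4 * pi)
  2 * pi * (2 + c * bessel_ratios(c)$xi0)
}

#' Anisotropy corrections to the rotational resistance
#'
#' The five correction coefficients of the expansion
#' \deqn{R = \nu_3 a^2\big(R^{IES} + R^{(1,0)}A + R^{(0,1)}\beta
#'   + R^{(2,0)}A^2 + R^{(1,1)}A\beta + R^{(0,2)}\beta^2\big).}
#' At `c = 0` the analytic limits are returned
#' (\eqn{R^{(1,0)} \to \pi/2}, \eqn{R^{(2,0)} \to -\pi/32}; the
#' \eqn{\beta} coefficients vanish, friction anisotropy being meaningless
#' without friction).
#'
#' @param c Scaled friction parameter, `c >= 0`.
#' @return Named list `R10`, `R01`, `R20`, `R11`, `R02`.
#' @export
resistance_corrections <- function(c) {
  if (c < 0) stop("c must be non-negative")
  if (c < 1e-8) {
    return(list(R10 = pi / 2, R01 = 0, R20 = -pi / 32, R11 = 0, R02 = 0))
  }
  xi <- bessel_ratios(c)
  xi0 <- xi$xi0; xi2 <- xi$xi2; xi3 <- xi$xi3
  Pi_ <- 14 * xi2^3 + 4 * xi0^2 * xi2 - 24 * xi0 * xi2^2 - xi0 + 7 * xi2
  Lam <- 8 * xi2^2 * (xi0^2 - 4 * xi0 * xi2 + xi2^2)
  list(
    R10 = pi / 8 * (4 + (1 - xi0^2) * c^2),
    R01 = pi * c * ((1 - xi0^2) * c - 2 * xi0),
    R20 = -pi / 512 * c^2 / xi3 * (Pi_ * c + Lam),
    R11 = pi / 8 * c^2 * (xi0 * (xi0^2 - 1) * c + 2 * xi0^2 - 1),
    R02 = pi / 4 * c * (3 * xi0 * (xi0^2 - 1) * c^2 + (8 * xi0^2 - 5) * c + 4 * xi0)
  )
}

#' Perturbative resistance and mobility report
#'
#' Assembles the full second-order expansion of the rotational resistance
#' and mobility in the anisotropy parameters `A` (viscosity) and `beta`
#' (friction).  The mobility corrections follow from the inverse series,
#' \eqn{\mu^{(1,0)} = -R^{(1,0)}/R^{IES}},
#' \eqn{\mu^{(2,0)} = (\mu^{(1,0)})^2 - R^{(2,0)}/R^{IES}}, etc.  The
#' mobility is reported both as the truncated series (`mu_total`) and as
#' the reciprocal of the truncated resistance (`mu_inverse`); their
#' difference is an \eqn{O(\epsilon^3)} error estimate.
#'
#' @param A Viscosity anisotropy.
#' @param beta Friction anisotropy; ignored (treated as 0, flagged) when
#'   `c = 0` where it is undefined.
#' @param c Scaled friction parameter, `c >= 0`.
#' @return An object of class `"resistance_report"`.
#' @export
#' @examples
#' mobility(0.5, 0.5, 1)
mobility <- function(A, beta, c) {
  if (A < -4) stop("A below the stability bound -4")
  if (c < 0) stop("c must be non-negative")
  beta_defined <- c > 0
  if (!beta_defined) beta <- 0
  R_ies <- resistance_ies(c)
  rc <- resistance_corrections(c)
  R_total <- R_ies + rc$R10 * A + rc$R01 * beta +
    rc$R20 * A^2 + rc$R11 * A * beta + rc$R02 * beta^2
  mu_ies <- 1 / R_ies
  mu10 <- -rc$R10 / R_ies
  mu01 <- -rc$R01 / R_ies
  mu20 <- mu10^2 - rc$R20 / R_ies
  mu11 <- 2 * mu10 * mu01 - rc$R11 / R_ies
  mu02 <- mu01^2 - rc$R02 / R_ies
  mu_total <- mu_ies * (1 + mu10 * A + mu01 * beta +
                          mu20 * A^2 + mu11 * A * beta + mu02 * beta^2)
  structure(list(
    A = A, beta = beta, c = c, beta_defined = beta_defined,
    R_ies = R_ies, R10 = rc$R10, R01 = rc$R01,
    R20 = rc$R20, R11 = rc$R11, R02 = rc$R02,
    R_total = R_total,
    mu_ies = mu_ies, mu10 = mu10, mu01 = mu01,
    mu20 = mu20, mu11 = mu11, mu02 = mu02,
    mu_total = mu_total, mu_inverse = 1 / R_total,
    series_error_estimate = abs(mu_total - 1 / R_total)
  ), class = "resistance_report")
}

#' @export
print.resistance_report <- function(x, ...) {
  cat("Rotational resistance / mobility (reduced units: nu3 = a = 1)\n")
  cat(sprintf("  inputs: A = %g, beta = %g%s, c = %g\n", x$A, x$beta,
              if (x$beta_defined) "" else " (undefined: frictionless)", x$c))
  cat(sprintf("  R_IES = %.10g   corrections: R10 = %.6g  R01 = %.6g  R20 = %.6g  R11 = %.6g  R02 = %.6g\n",
              x$R_ies, x$R10, x$R01, x$R20, x$R11, x$R02))
  cat(sprintf("  R_total  = %.10g\n", x$R_total))
  cat(sprintf("  mu_total = %.10g   (1/R_total = %.10g, diff %.3g)\n",
              x$mu_total, x$mu_inverse, x$series_error_estimate))
  invisible(x)
}

#' Isotropic base velocity field
#'
#' The azimuthal velocity of the isotropic substrate-coupled film:
#' \eqn{v_\rho = 0}, \eqn{v_\theta = K_1(r)/K_1(c)} with
#' \eqn{r = \alpha_\parallel\rho}; the pressure vanishes.
#'
#' @param r Scaled radial position(s) `alpha_par * rho`, `r >= c`.
#' @param c Scaled friction parameter, `c > 0`.
#' @return A data frame with `r`, `v_rho`, `v_theta` (units `a*Omega`).
#' @export
ies_velocity <- function(r, c) {
  if (!(c > 0)) stop("ies_velocity requires c > 0; the frictionless limit is v_theta = a/rho")
  if (any(r < c)) stop("r < c lies inside the disk")
  vth <- besselK(r, 1, expon.scaled = TRUE) /
    besselK(c, 1, expon.scaled = TRUE) * exp(c - r)
  data.frame(r = r, v_rho = 0, v_theta = vth)
}

#' Leading pressure correction of the isotropic base state
#'
#' For `A = beta = 0` but \eqn{b \neq 0} the pressure acquires
#' \deqn{p^* = \frac{bc}{2}\frac{K_2(r)}{K_1(c)}\sin(2\theta)}
#' (units \eqn{\Omega\nu_3/a}).
#'
#' @param r Scaled radial position(s), `r >= c`.
#' @param theta Polar angle(s).
#' @param c Scaled friction parameter, `c > 0`.
#' @param b Viscosity anisotropy entering the pressure.
#' @return Pressure correction value(s).
#' @export
base_pressure_correction <- function(r, theta, c, b) {
  if (!(c > 0)) stop("requires c > 0")
  if (any(r < c)) stop("r < c lies inside the disk")
  b * c / 2 * besselK(r, 2, expon.scaled = TRUE) /
    besselK(c, 1, expon.scaled = TRUE) * exp(c - r) * sin(2 * theta)
}

#' Resistance from rim derivatives of the azimuthal modes
#'
#' The rim identity for the torque: with \eqn{h_0(a) = 1},
#' \eqn{h_{n\ge1}(a) = 0} and \eqn{dg_n/d\rho(a) = 0} (no-slip plus
#' incompressibility), the resistance reduces to
#' \deqn{\frac{R}{\pi a^2\nu_3} = 2 + \frac A4 - a\frac{d}{d\rho}
#'   \Big[\big(2+\tfrac A4\big)h_0 - \tfrac A8 h_2\Big]\Big|_{\rho=a}.}
#' Sign convention: torque \eqn{T = -R\Omega}.
#'
#' @param h0_prime,h2_prime Rim derivatives `a * dh_n/drho` at `rho = a`
#'   (dimensionless).
#' @param A Viscosity anisotropy.
#' @return `R` in units `nu3*a^2`.
#' @export
#' @examples
#' torque_from_mode_derivatives(-1, 0, 0)   # 4*pi: isotropic frictionless
torque_from_mode_derivatives <- function(h0_prime, h2_prime, A) {
  pi * (2 + A / 4 - ((2 + A / 4) * h0_prime - A / 8 * h2_prime))
}

#' Torque by direct integration of the anisotropic rim stress
#'
#' Independent route to the resistance: integrates the full anisotropic
#' traction moment over the rim,
#' \eqn{-\sigma_{\rho\theta} = \nu_3(\Pi_{\rho\theta} + \Phi)} with
#' \eqn{\Pi_{\rho\theta} = v_{\theta,\rho} + (v_{\rho,\theta} -
#' v_\theta)/\rho} and the anisotropic extra stress
#' \eqn{\Phi = \tfrac A8(1-\cos4\theta)\Pi_{\rho\theta} +
#' \frac{v_\rho + v_{\theta,\theta}}{\rho}\delta_- -
#' v_{\rho,\rho}\,\delta_+}, where
#' \eqn{\delta_\pm = \tfrac12(\tfrac A4\sin4\theta \pm b\sin2\theta)}.
#' Derivatives are taken by one-sided finite differences in `rho` (the
#' field exists only outside the disk) and spectral differencing in
#' `theta`.  Used as a cross-check of the rim-derivative shortcut.
#'
#' @param vfun Function `(rho, theta) -> list/data.frame with v_rho,
#'   v_theta` in reduced units (`a = Omega = 1`).
#' @param A,b Viscosity anisotropies of the film.
#' @param n_theta Number of rim quadrature angles (default 64).
#' @param h Radial finite-difference step (default 1e-3).
#' @return `R` in units `nu3*a^2` (so that `T = -R`).
#' @export
torque_stress_integral <- function(vfun, A, b, n_theta = 64, h = 1e-3) {
  th <- 2 * pi * (0:(n_theta - 1)) / n_theta
  # one-sided 5-point first-derivative stencil at rho = 1
  st <- c(-25 / 12, 4, -3, 4 / 3, -1 / 4) / h
  rr <- 1 + h * (0:4)
  vr <- matrix(0, 5, n_theta); vt <- matrix(0, 5, n_theta)
  for (i in 1:5) {
    f <- vfun(rep(rr[i], n_theta), th)
    vr[i, ] <- f$v_rho; vt[i, ] <- f$v_theta
  }
  vt_r <- as.numeric(st %*% vt)     # d v_theta / d rho at rim
  vr_r <- as.numeric(st %*% vr)
  # spectral theta-derivatives of the rim values
  dtheta <- function(y) {
    nf <- length(y)
    ks <- c(0:(nf / 2 - 1), 0, (-nf / 2 + 1):(-1))
    Re(stats::fft(1i * ks * stats::fft(y), inverse = TRUE)) / nf
  }
  vr_t <- dtheta(vr[1, ]); vt_t <- dtheta(vt[1, ])
  Pi_rt <- vt_r + (vr_t - vt[1, ])      # rho = 1
  dm <- 0.5 * (A / 4 * sin(4 * th) - b * sin(2 * th))
  dp <- 0.5 * (A / 4 * sin(4 * th) + b * sin(2 * th))
  Phi <- A / 8 * (1 - cos(4 * th)) * Pi_rt + (vr[1, ] + vt_t) * dm - vr_r * dp
  Tq <- sum(Pi_rt + Phi) * (2 * pi / n_theta)   # T / (a^2 nu3 Omega)
  -Tq
}
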