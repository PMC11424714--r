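## Exact solution for the rotating disk at zero substrate friction.
##
## All quantities are expressed in reduced units: lengths in units of the
## disk radius a, velocities in a*Omega, pressure in Omega*nu3/a and
## resistance in nu3*a^2.  The radial variable enters through w = a/rho,
## with w in (0, 1] outside or on the rim.

## chi_n = (sqrt(A)/(2 + sqrt(A+4)))^n, written so that only integer powers
## of A appear wherever the physics guarantees them (even n, and the
## combination chi_n E_n for odd n).  This keeps every mode analytic in A
## and evaluable for complex A, which the series-extraction tests exploit.
.sqrtA4 <- function(A) {
  if (is.complex(A)) sqrt(A + 4) else sqrt(A + 4 + 0i)
}

.chi_even <- function(n, A) {
  stopifnot(n %% 2 == 0)
  s <- .sqrtA4(A)
  (A + 0i)^(n / 2) / (2 + s)^n
}

.maybe_real <- function(z) {
  if (all(abs(Im(z)) < 1e-12 * pmax(abs(Re(z)), 1))) Re(z) else z
}

#' Geometric decay factor of the exact mode series
#'
#' \eqn{\chi_n = \left(\sqrt A / (2 + \sqrt{A+4})\right)^n}.  Its modulus is
#' below one for all finite \eqn{A > 0}, which makes the exact Fourier
#' series geometrically convergent.
#'
#' @param n Mode index `>= 0`.
#' @param A Viscosity anisotropy, `A >= 0` for a real result.
#' @return `chi_n` (real for `A >= 0`).
#' @export
chi_factor <- function(n, A) {
  if (is.numeric(A) && A < 0)
    stop("chi_n is not real for A < 0; use the spectral solver for negative A")
  s <- sqrt(A + 4)
  (sqrt(A) / (2 + s))^n
}

#' Rim force-density coefficient of the exact solution
#'
#' At zero friction only the first Fourier mode of the rim force density
#' survives, with \eqn{c_1 = (1 + A/4)^{1/2}} and \eqn{d_1 = -c_1}.
#'
#' @param A Viscosity anisotropy, `A >= -4`.
#' @return `c_1`.
#' @export
force_coefficient_c1 <- function(A) {
  .check_A(A)
  sqrt(1 + A / 4)
}

#' Exact radial velocity mode g_n(w)
#'
#' \eqn{g_n = -2\chi_n w\,{}_2F_1(-n, n; 2; w^2)} for even \eqn{n \ge 2};
#' zero for odd `n` (a parity property of the zero-friction solution) and
#' for `n = 0`.
#'
#' @param n Mode index.
#' @param w Radius ratio `a/rho` in `(0, 1]` (vectorised).
#' @param A Viscosity anisotropy; `A >= 0`, or complex for series work.
#' @return `g_n(w)` in units `a*Omega`.
#' @export
exact_mode_g <- function(n, w, A) {
  .check_exact_A(A)
  if (n %% 2 == 1 || n == 0) return(rep(0, length(w)))
  val <- -2 * .chi_even(n, A) * w * hyp2f1_terminating(-n, n, 2, w^2)
  .maybe_real(val)
}

#' Exact azimuthal velocity mode h_n(w)
#'
#' \eqn{h_0 = w}; for even \eqn{n \ge 2},
#' \eqn{h_n = -n\chi_n w^3\,{}_2F_1(n+1, -n+1; 3; w^2)}; zero for odd `n`.
#'
#' @inheritParams exact_mode_g
#' @return `h_n(w)` in units `a*Omega`.
#' @export
exact_mode_h <- function(n, w, A) {
  .check_exact_A(A)
  if (n == 0) return(w)
  if (n %% 2 == 1) return(rep(0, length(w)))
  val <- -n * .chi_even(n, A) * w^3 * hyp2f1_terminating(n + 1, -n + 1, 3, w^2)
  .maybe_real(val)
}

#' Exact pressure mode u_n(w)
#'
#' \eqn{u_n = 2n\chi_n E_n w^2\,{}_2F_1(n+1, -n+1; 2; w^2)} with the
#' parity-dependent prefactor \eqn{E_n = 2bA^{-1/2}} for odd `n` and
#' \eqn{E_n = -(A+4)^{1/2}} for even `n`.  The apparent \eqn{A^{-1/2}} of
#' the odd branch cancels against \eqn{\chi_n \propto A^{n/2}}; the product
#' is evaluated in its simplified analytic form, so the \eqn{A \to 0} limit
#' is exact (e.g. \eqn{u_1 \to b w^2}).
#'
#' @inheritParams exact_mode_g
#' @param b Viscosity anisotropy entering the pressure.
#' @return `u_n(w)` in units `Omega*nu3/a`.
#' @export
exact_mode_u <- function(n, w, A, b) {
  .check_exact_A(A)
  if (n < 1) stop("pressure modes start at n = 1")
  s <- .sqrtA4(A)
  pre <- if (n %% 2 == 0) {
    # 2n chi_n E_n with E_n = -(A+4)^(1/2)
    -2 * n * (A + 0i)^(n / 2) * s / (2 + s)^n
  } else {
    # 2n chi_n E_n with E_n = 2 b A^(-1/2): the half-powers combine
    4 * n * b * (A + 0i)^((n - 1) / 2) / (2 + s)^n
  }
  val <- pre * w^2 * hyp2f1_terminating(n + 1, -n + 1, 2, w^2)
  .maybe_real(val)
}

## Magnitude of the terminating hypergeometric sum with all signs made
## positive: eps times this bounds the roundoff of the alternating
## evaluation, giving a per-mode noise floor for the adaptive truncation.
.hyp2f1_absmag <- function(a, b, cc, x) {
  N <- -min(a, b)
  s <- rep(1, length(x)); term <- s
  if (N >= 1) for (k in 0:(N - 1)) {
    term <- term * abs((a + k) * (b + k) / ((cc + k) * (k + 1))) * x
    s <- s + term
  }
  s
}

## value + roundoff-noise estimate for one exact mode
.mode_with_noise <- function(kind, n, w, A, b = 0) {
  chi <- abs(chi_factor(n, A))
  eps <- 4 * .Machine$double.eps
  if (kind == "g") {
    list(value = exact_mode_g(n, w, A),
         noise = eps * 2 * chi * w * .hyp2f1_absmag(-n, n, 2, w^2))
  } else if (kind == "h") {
    list(value = exact_mode_h(n, w, A),
         noise = eps * n * chi * w^3 * .hyp2f1_absmag(n + 1, -n + 1, 3, w^2))
  } else {
    s <- sqrt(A + 4)
    pre <- if (n %% 2 == 0) 2 * n * chi * s else 4 * n * abs(b) *
      A^((n - 1) / 2) / (2 + s)^n
    list(value = exact_mode_u(n, w, A, b),
         noise = eps * pre * w^2 * .hyp2f1_absmag(n + 1, -n + 1, 2, w^2))
  }
}

.check_exact_A <- function(A) {
  if (is.complex(A)) return(invisible(A))
  if (A < 0)
    stop("the exact zero-friction series is evaluated for A >= 0 only ",
         "(chi_n is imaginary for A < 0); use oracle_solve() instead")
  invisible(A)
}

#' Truncation order for the exact mode series
#'
#' The exact series decays like \eqn{|\chi|^n} with
#' \eqn{|\chi| = \sqrt A/(2+\sqrt{A+4})}.  This returns the smallest even
#' `N` whose geometric tail bound \eqn{C |\chi|^N N^2 / (1-|\chi|)} falls
#' below `tol`, with the prefactor `C` calibrated from the first retained
#' modes.  For `A = 0` the series is exactly `h_0` and `N = 2`.
#'
#' @param A Viscosity anisotropy, `A >= 0`.
#' @param w Largest radius ratio of interest (default 1, the rim).
#' @param tol Absolute tolerance on the field, default `1e-10`.
#' @return An even integer truncation order.
#' @export
truncation_order <- function(A, w = 1, tol = 1e-10) {
  stopifnot(tol > 0, w > 0, w <= 1)
  .check_exact_A(A)
  if (A == 0) return(2L)
  chi <- sqrt(A) / (2 + sqrt(A + 4))
  C <- max(2 * abs(chi_factor(2, A)), abs(chi_factor(4, A)) * 4, 1e-30) / chi^2
  N <- 2L
  while (C * (chi * w)^N * N^2 / (1 - chi * w) >= tol && N < 512L) N <- N + 2L
  N
}

#' Exact hydrodynamic velocity at zero friction
#'
#' Sums the exact Fourier mode series
#' \eqn{v_\rho = \sum_n g_n(\rho)\sin(2n\theta)},
#' \eqn{v_\theta = \sum_n h_n(\rho)\cos(2n\theta)} for a frictionless,
#' uniaxially anisotropic film.  On the rim this reproduces rigid-body
#' rotation (no slip), and for `A = 0` it collapses to the classical
#' \eqn{v_\theta = a^2\Omega/\rho} point-vortex-like field.
#'
#' @param rho Radial position(s) in units of `a`, `rho >= 1`.
#' @param theta Polar angle(s), recycled against `rho`.
#' @param problem A `"disk_problem"` with frictionless `friction`, or a
#'   single number interpreted as the anisotropy `A`.
#' @param N_trunc Even truncation order; default from [truncation_order()].
#' @return A data frame with columns `rho`, `theta`, `v_rho`, `v_theta`
#'   (velocities in units `a*Omega`).
#' @export
exact_velocity <- function(rho, theta, problem, N_trunc = NULL) {
  A <- .exact_A_of(problem)
  if (any(rho < 1)) stop("rho must be >= a (outside the disk)")
  nn <- max(length(rho), length(theta))
  rho <- rep_len(rho, nn); theta <- rep_len(theta, nn)
  w <- 1 / rho
  adaptive <- is.null(N_trunc)
  if (adaptive) N_trunc <- max(truncation_order(A), 2L)
  v_rho <- numeric(nn); v_theta <- exact_mode_h(0, w, A)
  if (A != 0) for (n in seq(2, N_trunc, by = 2)) {
    gn <- .mode_with_noise("g", n, w, A)
    hn <- .mode_with_noise("h", n, w, A)
    sz <- max(abs(gn$value), abs(hn$value))
    # stop once a mode no longer contributes, or once the roundoff of its
    # terminating-polynomial evaluation exceeds its value (noise onset in
    # the high-order modes)
    if (adaptive && (sz < 1e-12 ||
                     sz < max(gn$noise, hn$noise))) break
    v_rho <- v_rho + gn$value * sin(2 * n * theta)
    v_theta <- v_theta + hn$value * cos(2 * n * theta)
  }
  data.frame(rho = rho, theta = theta, v_rho = v_rho, v_theta = v_theta)
}

#' Exact pressure at zero friction
#'
#' Sums \eqn{p = \sum_{n\ge1} u_n(\rho)\sin(2n\theta)}; both parities of
#' `n` contribute (the odd ones proportionally to `b`).
#'
#' @inheritParams exact_velocity
#' @return A data frame with columns `rho`, `theta`, `p` (units
#'   `Omega*nu3/a`).
#' @export
exact_pressure <- function(rho, theta, problem, N_trunc = NULL) {
  A <- .exact_A_of(problem)
  b <- if (inherits(problem, "disk_problem")) problem$fluid$b else 0
  if (any(rho < 1)) stop("rho must be >= a (outside the disk)")
  nn <- max(length(rho), length(theta))
  rho <- rep_len(rho, nn); theta <- rep_len(theta, nn)
  w <- 1 / rho
  adaptive <- is.null(N_trunc)
  if (adaptive) N_trunc <- max(truncation_order(A), 3L)
  p <- numeric(nn)
  small_run <- 0L
  for (n in seq_len(N_trunc)) {
    if (n %% 2 == 1 && b == 0) next
    un <- .mode_with_noise("u", n, w, A, b)
    sz <- max(abs(un$value))
    if (adaptive && n > 4 && sz < max(un$noise)) break
    p <- p + un$value * sin(2 * n * theta)
    if (adaptive) {
      small_run <- if (sz < 1e-12) small_run + 1L else 0L
      if (small_run >= 2L) break
    }
  }
  data.frame(rho = rho, theta = theta, p = p)
}

.exact_A_of <- function(problem) {
  if (inherits(problem, "disk_problem")) {
    if (!problem$friction$frictionless)
      stop("exact series requires zero friction; use oracle_solve() with friction")
    A <- problem$fluid$A
  } else if (is.numeric(problem) && length(problem) == 1) {
    A <- problem
  } else stop("problem must be a disk_problem or a single anisotropy value A")
  .check_exact_A(A)
  A
}

#' Closed-form rim pressure at zero friction
#'
#' \deqn{p(\rho=a,\theta) = (A+4)^{1/2}\,
#'   \frac{4b\sin(2\theta) + A\sin(4\theta)}{8 + A(1-\cos(4\theta))}}
#' in units \eqn{\Omega\nu_3/a}.  This is the analytic resummation of the
#' rim limit of the exact pressure series.
#'
#' @param theta Polar angle(s).
#' @param A Viscosity anisotropy, `A > -4`.
#' @param b Viscosity anisotropy entering the pressure.
#' @return Rim pressure value(s).
#' @export
rim_pressure <- function(theta, A, b) {
  if (A <= -4) stop("rim pressure requires A > -4")
  sqrt(A + 4) * (4 * b * sin(2 * theta) + A * sin(4 * theta)) /
    (8 + A * (1 - cos(4 * theta)))
}

#' Exact rotational resistance at zero friction
#'
#' \eqn{R = 2\pi\sqrt{A+4}} in units \eqn{\nu_3 a^2}.  At `A = 0` this is
#' the classical rotational drag \eqn{4\pi\eta_S a^2} of a disk in a thin
#' viscous film, and it vanishes at the stability boundary `A = -4`.
#'
#' Note on units: the resistance is reported in units \eqn{\nu_3 a^2}
#' throughout, the only dimensionally consistent convention for a torque
#' per angular velocity in two dimensions.
#'
#' @param A Viscosity anisotropy, `A >= -4`.
#' @return `R` in units `nu3*a^2`.
#' @export
#' @examples
#' exact_resistance(0)   # 4*pi
exact_resistance <- function(A) {
  if (A < -4)
    stop("A below the stability bound -4")
  2 * pi * sqrt(A + 4)
}

## Taylor coefficients in A about A = 0 of an analytic function, by trapezoid
## (trigonometric) quadrature of the Cauchy integral on the circle |A| = r.
## Near machine precision for functions analytic in |A| < 4 when r ~ 1.
.taylor_in_A <- function(fun, order, r = 1, K = 64) {
  k <- 0:(K - 1)
  Ak <- r * exp(2i * pi * k / K)
  fk <- vapply(Ak, function(z) as.complex(fun(z)), complex(1))
  vapply(0:order, function(j) {
    Re(sum(fk * exp(-2i * pi * j * k / K)) / K / r^j)
  }, numeric(1))
}
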