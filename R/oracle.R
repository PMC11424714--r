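## Boundary-Galerkin spectral solver for the rotating disk at arbitrary
## anisotropy (A, b), friction (c) and friction anisotropy (beta).
##
## The rim force density is expanded in odd Fourier modes with real
## coefficients (c_{2n+1}, d_{2n+1}); the no-slip condition at the rim is
## projected onto the odd harmonics (Galerkin), giving a dense 2N x 2N
## linear system.  Angular integrals use the periodic trapezoid rule, which
## is spectrally accurate for these smooth 2*pi-periodic integrands.
## Everything is in reduced units (a = Omega = nu3 = 1).

.sigma_of_phi <- function(rho, phi, A, c_par, c_perp) {
  B <- anisotropy_factor(phi, A)
  if (c_par == 0 && c_perp == 0) return(list(B = B, sigma = rep(0, length(phi))))
  list(B = B, sigma = rho * sqrt((c_par^2 * sin(phi)^2 + c_perp^2 * cos(phi)^2) / B))
}

## Gamma_mn on the full periodic phi grid, computed on a quarter grid
## [0, pi/2] and unfolded: Gamma depends on phi only through B (pi/2
## periodic, even) and sigma (pi periodic, even about 0 and pi/2).
.gamma_grid <- function(m, n, w, rho, A, c_par, c_perp, N_quad, cache) {
  nq4 <- N_quad %/% 4
  phi_q <- 2 * pi * (0:nq4) / N_quad
  sb <- .sigma_of_phi(rho, phi_q, A, c_par, c_perp)
  g <- gamma_integral(m, n, w, sb$sigma, sb$B, cache)
  k <- (0:(N_quad - 1)) %% (N_quad %/% 2)
  k <- ifelse(k > nq4, N_quad %/% 2 - k, k)
  g[k + 1]
}

#' Assemble the rim-projection linear system
#'
#' Builds the Galerkin matrix of the no-slip condition: each row is the
#' projection of the rim velocity (x or y component) onto one odd harmonic
#' \eqn{\sin/\cos((2m+1)\theta)}; the unknowns are the odd force-density
#' coefficients \eqn{(c_1, c_3, \dots, d_1, d_3, \dots)}.  The right-hand
#' side is non-zero only in the first (m = 0) rows: rigid-body rotation
#' feeds only the first harmonic.
#'
#' @param problem A `"disk_problem"`.
#' @param N_modes Number of odd modes retained (`>= 1`).
#' @param N_quad Number of angular quadrature nodes (multiple of 4).
#' @param cache Optional memoisation environment.
#' @return List with the matrix `M` (2N x 2N), right-hand side `rhs`, and
#'   the quadrature grid pieces used.
#' @export
assemble_system <- function(problem, N_modes, N_quad = 256, cache = NULL) {
  stopifnot(inherits(problem, "disk_problem"), N_modes >= 1)
  if (N_quad %% 4 != 0) stop("N_quad must be a multiple of 4 (integrand symmetry)")
  A <- problem$fluid$A
  phi <- 2 * pi * (0:(N_quad - 1)) / N_quad
  sphi <- sin(phi); cphi <- cos(phi)
  wgt <- 2 * pi / N_quad
  N <- N_modes
  M <- matrix(0, 2 * N, 2 * N)
  for (m in 0:(N - 1)) {
    sm <- sin((2 * m + 1) * phi); cm <- cos((2 * m + 1) * phi)
    for (n in 0:(N - 1)) {
      G <- .gamma_grid(m, n, 1, 1, A, problem$c, problem$c_perp, N_quad, cache)
      sn1 <- sin((2 * n + 1) * phi); cn1 <- cos((2 * n + 1) * phi)
      M[m + 1, n + 1]         <- -(2 / pi) * wgt * sum(sm * sn1 * sphi * sphi * G)
      M[m + 1, N + n + 1]     <-  (2 / pi) * wgt * sum(sm * cn1 * cphi * sphi * G)
      M[N + m + 1, n + 1]     <-  (2 / pi) * wgt * sum(cm * sn1 * sphi * cphi * G)
      M[N + m + 1, N + n + 1] <- -(2 / pi) * wgt * sum(cm * cn1 * cphi * cphi * G)
    }
  }
  rhs <- numeric(2 * N)
  rhs[1] <- -1          # sin(theta) projection of v_x = -sin(theta)
  rhs[N + 1] <- 1       # cos(theta) projection of v_y =  cos(theta)
  list(M = M, rhs = rhs, phi = phi, N_modes = N)
}

#' Solve the rotating-disk boundary problem spectrally
#'
#' Solves the truncated rim-projection system for the odd force-density
#' coefficients, then checks the no-slip residual a posteriori by sampling
#' the reconstructed rim velocity at `4*N_modes` angles.  If the residual
#' exceeds `tol`, the mode count is doubled (up to `max_modes`); a
#' non-converged result is flagged, never silent.
#'
#' @param problem A `"disk_problem"`.
#' @param N_modes Starting number of odd modes (default 8).
#' @param N_quad Angular quadrature nodes (default 256, multiple of 4).
#' @param tol Target L2 rim residual (default 1e-8, in units `a*Omega`).
#' @param max_modes Mode-escalation cap (default 64).
#' @param resistance Also compute the resistance (default TRUE).
#' @return An object of class `"oracle_solution"`: coefficients `c_odd`,
#'   `d_odd`, the parameters, `bc_residual`, `converged`, and (if
#'   requested) `R_numeric` in units `nu3*a^2`.
#' @export
#' @examples
#' pr <- disk_problem(fluid_from_anisotropies(0))  # isotropic frictionless
#' sol <- oracle_solve(pr, N_modes = 2)
#' sol$c_odd[1]    # 1: only the first rim force mode survives
oracle_solve <- function(problem, N_modes = 8, N_quad = 256, tol = 1e-8,
                         max_modes = 64, resistance = TRUE) {
  stopifnot(inherits(problem, "disk_problem"))
  cache <- new.env(parent = emptyenv())
  N <- N_modes
  repeat {
    sys <- assemble_system(problem, N, N_quad, cache)
    x <- tryCatch(solve(sys$M, sys$rhs), error = function(e) {
      stop("rim system singular or ill-conditioned (kappa = ",
           format(kappa(sys$M)), "): ", conditionMessage(e))
    })
    sol <- structure(list(
      problem = problem,
      A = problem$fluid$A, b = problem$fluid$b,
      c = problem$c, c_perp = problem$c_perp, beta = problem$beta,
      c_odd = x[1:N], d_odd = x[(N + 1):(2 * N)],
      N_modes = N, N_quad = N_quad, tol = tol,
      cache = cache
    ), class = "oracle_solution")
    res <- .rim_residual(sol)
    sol$bc_residual <- res
    sol$converged <- res < tol
    if (sol$converged || N >= max_modes) break
    N <- min(2 * N, max_modes)
  }
  if (!sol$converged)
    warning("oracle did not reach rim residual ", format(tol),
            " at N_modes = ", N, " (residual ", format(res), ")")
  if (resistance) sol$R_numeric <- oracle_resistance(sol)
  sol
}

.rim_residual <- function(sol) {
  th <- 2 * pi * (0:(4 * sol$N_modes - 1)) / (4 * sol$N_modes)
  v <- oracle_velocity(rep(1, length(th)), th, sol)
  sqrt(mean(v$v_rho^2 + (v$v_theta - 1)^2))
}

#' @export
print.oracle_solution <- function(x, ...) {
  cat(sprintf("Spectral rim solution: A = %g, b = %g, c = %g, beta = %s\n",
              x$A, x$b, x$c, format(x$beta)))
  cat(sprintf("  N_modes = %d, N_quad = %d, rim residual = %.3g (%s)\n",
              x$N_modes, x$N_quad, x$bc_residual,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  c_1 = %.8g, d_1 = %.8g\n", x$c_odd[1], x$d_odd[1]))
  if (!is.null(x$R_numeric))
    cat(sprintf("  R = %.10g (units nu3 a^2)\n", x$R_numeric))
  invisible(x)
}

## Velocity harmonic amplitudes at one radius: returns, for each m,
## the four projection sums (Am, Bm, Cm, Dm) so that
##   v_x(theta) = sum_m Am cos((2m+1)theta) + Bm sin((2m+1)theta)
##   v_y(theta) = sum_m Cm cos((2m+1)theta) + Dm sin((2m+1)theta).
.vel_harmonics_at_rho <- function(rho, sol) {
  N <- sol$N_modes; Nq <- sol$N_quad
  phi <- 2 * pi * (0:(Nq - 1)) / Nq
  sphi <- sin(phi); cphi <- cos(phi)
  wgt <- 2 * pi / Nq
  w <- 1 / rho
  Am <- Bm <- Cm <- Dm <- numeric(N)
  for (m in 0:(N - 1)) {
    sm <- sin((2 * m + 1) * phi); cm <- cos((2 * m + 1) * phi)
    Pm <- 0
    for (n in 0:(N - 1)) {
      G <- .gamma_grid(m, n, w, rho, sol$A, sol$c, sol$c_perp, Nq, sol$cache)
      Zn <- sol$c_odd[n + 1] * sin((2 * n + 1) * phi) * sphi -
            sol$d_odd[n + 1] * cos((2 * n + 1) * phi) * cphi
      Pm <- Pm + Zn * G
    }
    Am[m + 1] <- -(2 / pi) * wgt * sum(cm * Pm * sphi)
    Bm[m + 1] <- -(2 / pi) * wgt * sum(sm * Pm * sphi)
    Cm[m + 1] <-  (2 / pi) * wgt * sum(cm * Pm * cphi)
    Dm[m + 1] <-  (2 / pi) * wgt * sum(sm * Pm * cphi)
  }
  list(Am = Am, Bm = Bm, Cm = Cm, Dm = Dm)
}

#' Velocity field from a spectral solution
#'
#' Reconstructs the hydrodynamic velocity at the requested polar points by
#' summing the truncated odd-harmonic mode series with the wavenumber
#' integrals evaluated through [gamma_integral()].
#'
#' @param rho Radial position(s) in units of `a`, `rho >= 1`.
#' @param theta Polar angle(s), recycled against `rho`.
#' @param sol An `"oracle_solution"`.
#' @return Data frame with `rho`, `theta`, `v_x`, `v_y`, `v_rho`,
#'   `v_theta` (units `a*Omega`).
#' @export
oracle_velocity <- function(rho, theta, sol) {
  stopifnot(inherits(sol, "oracle_solution"))
  if (any(rho < 1 - 1e-12)) stop("rho must be >= a (outside the disk)")
  nn <- max(length(rho), length(theta))
  rho <- rep_len(rho, nn); theta <- rep_len(theta, nn)
  vx <- vy <- numeric(nn)
  for (r in unique(rho)) {
    idx <- which(rho == r)
    hh <- .vel_harmonics_at_rho(r, sol)
    th <- theta[idx]
    for (m in 0:(sol$N_modes - 1)) {
      cmt <- cos((2 * m + 1) * th); smt <- sin((2 * m + 1) * th)
      vx[idx] <- vx[idx] + hh$Am[m + 1] * cmt + hh$Bm[m + 1] * smt
      vy[idx] <- vy[idx] + hh$Cm[m + 1] * cmt + hh$Dm[m + 1] * smt
    }
  }
  data.frame(rho = rho, theta = theta, v_x = vx, v_y = vy,
             v_rho = vx * cos(theta) + vy * sin(theta),
             v_theta = -vx * sin(theta) + vy * cos(theta))
}

## Terminating Weber-Schafheitlin integral  int_0^inf J_mu(u) J_nu(w u) du
## for even mu and odd nu: zero when mu <= nu - 1, otherwise a terminating
## hypergeometric polynomial.
.ws_jj_integral <- function(mu, nu, w) {
  a2 <- (nu - mu + 1) / 2
  if (a2 > 0) return(0)   # 1/Gamma of a non-positive integer: vanishes
  w^nu * exp(lgamma((mu + nu + 1) / 2) - lgamma(nu + 1) - lgamma((mu - nu + 1) / 2)) *
    as.numeric(hyp2f1_terminating(a2, (nu + mu + 1) / 2, nu + 1, w^2))
}

#' Pressure field from a spectral solution
#'
#' Recovers the pressure by longitudinal projection of the momentum balance
#' in Fourier space: with \eqn{\tilde v} eliminated through the Green's
#' function, \eqn{\tilde p = -(i/k)\,\hat k\cdot(I - \hat D G/H)\tilde f},
#' which on inverse transformation splits into a friction-independent part
#' (terminating Weber-Schafheitlin integrals) and a screened part carrying
#' the same modified-Bessel-product kernels as the velocity.  The gauge is
#' fixed by decay at infinity.  Only even azimuthal harmonics contribute.
#'
#' @inheritParams oracle_velocity
#' @param m_max Highest even pressure harmonic retained (default
#'   `2*N_modes + 8`).
#' @return Data frame with `rho`, `theta`, `p` (units `Omega*nu3/a`).
#' @export
oracle_pressure <- function(rho, theta, sol, m_max = NULL) {
  stopifnot(inherits(sol, "oracle_solution"))
  if (any(rho < 1 - 1e-12)) stop("rho must be >= a (outside the disk)")
  nn <- max(length(rho), length(theta))
  rho <- rep_len(rho, nn); theta <- rep_len(theta, nn)
  if (is.null(m_max)) m_max <- 2 * sol$N_modes + 8
  A <- sol$A; b <- sol$b
  Nq <- sol$N_quad
  phi <- 2 * pi * (0:(Nq - 1)) / Nq
  wgt <- 2 * pi / Nq
  B <- anisotropy_factor(phi, A)
  Pphi <- A / 2 * cos(2 * phi) + b
  S <- sol$c^2 * sin(phi)^2 + sol$c_perp^2 * cos(phi)^2
  Q <- sol$c^2 - sol$c_perp^2
  sphi <- sin(phi); cphi <- cos(phi)
  Cx0 <- cphi * (1 - Pphi * sphi^2 / B)
  Cy0 <- sphi * (1 + Pphi * cphi^2 / B)
  Yfac <- Q - Pphi * S / B
  has_friction <- !(sol$c == 0 && sol$c_perp == 0)
  active <- which(abs(sol$c_odd) + abs(sol$d_odd) > 1e-14) - 1L
  p <- numeric(nn)
  nq4 <- Nq %/% 4
  kunf <- (0:(Nq - 1)) %% (Nq %/% 2)
  kunf <- ifelse(kunf > nq4, Nq %/% 2 - kunf, kunf) + 1L
  for (r in unique(rho)) {
    idx <- which(rho == r)
    w <- 1 / r
    sigma_q <- if (has_friction) {
      phi_q <- 2 * pi * (0:nq4) / Nq
      .sigma_of_phi(r, phi_q, A, sol$c, sol$c_perp)$sigma
    } else NULL
    pscale <- 0; nsmall <- 0L; ngrow <- 0L; prev_tsz <- Inf
    for (m in seq(2, m_max, by = 2)) {
      contrib <- numeric(Nq)
      for (n in active) {
        cn <- sol$c_odd[n + 1]; dn <- sol$d_odd[n + 1]
        sn1 <- sin((2 * n + 1) * phi); cn1 <- cos((2 * n + 1) * phi)
        Xn <- Cx0 * cn * sn1 + Cy0 * dn * cn1
        T1 <- w * .ws_jj_integral(m, 2 * n + 1, w)   # 1/rho = w prefactor
        part <- Xn * T1
        if (has_friction) {
          T2q <- (.jj_u_integral(2 * n + 1, m - 1, w, sigma_q, sol$cache) +
                  .jj_u_integral(2 * n + 1, m + 1, w, sigma_q, sol$cache)) / (2 * m)
          Yn <- Yfac * (-cphi * sphi^2 * cn * sn1 + sphi * cphi^2 * dn * cn1)
          part <- part + Yn * (r / B) * T2q[kunf]
        }
        contrib <- contrib + (-1)^n * part
      }
      am <- wgt * sum(contrib * cos(m * phi))
      bm <- wgt * sum(contrib * sin(m * phi))
      term <- (2 / pi) * (-1)^(m / 2) *
        (am * cos(m * theta[idx]) + bm * sin(m * theta[idx]))
      p[idx] <- p[idx] + term
      # terminate the harmonic sum once terms are negligible: pushing to
      # very high harmonics only amplifies roundoff in the terminating
      # hypergeometric polynomials without changing the field
      tsz <- (2 / pi) * sqrt(am^2 + bm^2)
      pscale <- max(pscale, tsz)
      nsmall <- if (tsz < 1e-13 * pscale) nsmall + 1L else 0L
      if (nsmall >= 2L) break
      # harmonic amplitudes decay geometrically; sustained growth marks the
      # onset of roundoff in the high-order terminating polynomials
      ngrow <- if (m > 8 && tsz > prev_tsz) ngrow + 1L else 0L
      if (ngrow >= 2L) break
      prev_tsz <- tsz
    }
  }
  data.frame(rho = rho, theta = theta, p = p)
}

#' Resistance from a spectral solution
#'
#' Extracts the azimuthal Fourier modes \eqn{h_0(\rho)} and
#' \eqn{h_2(\rho)} of the reconstructed velocity near the rim,
#' differentiates them radially by a one-sided high-order stencil, and
#' applies the rim torque identity (see
#' [torque_from_mode_derivatives()]).  A step-refinement error estimate is
#' attached as an attribute `"error_estimate"`.
#'
#' @param sol An `"oracle_solution"`.
#' @param h Radial stencil spacing (default 1e-3, in units of `a`).
#' @return `R` in units `nu3*a^2`.
#' @export
oracle_resistance <- function(sol, h = 1e-3) {
  stopifnot(inherits(sol, "oracle_solution"))
  hprof <- function(hh) {
    rr <- 1 + hh * (0:5)
    n_t <- max(32, 4 * sol$N_modes)
    th <- 2 * pi * (0:(n_t - 1)) / n_t
    h0 <- h2 <- numeric(6)
    for (i in 1:6) {
      v <- oracle_velocity(rep(rr[i], n_t), th, sol)
      h0[i] <- mean(v$v_theta)
      # h_n multiplies cos(2 n theta): h_2 is the fourth harmonic
      h2[i] <- 2 * mean(v$v_theta * cos(4 * th))
    }
    # one-sided 6-point first-derivative stencil, O(h^5)
    st <- c(-137 / 60, 5, -5, 10 / 3, -5 / 4, 1 / 5) / hh
    c(sum(st * h0), sum(st * h2))
  }
  d1 <- hprof(h)
  R1 <- torque_from_mode_derivatives(d1[1], d1[2], sol$A)
  d2 <- hprof(2 * h)
  R2 <- torque_from_mode_derivatives(d2[1], d2[2], sol$A)
  structure(R1, error_estimate = abs(R1 - R2))
}
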