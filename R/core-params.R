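#' Fluid parameters of a uniaxially anisotropic two-dimensional film
#'
#' Builds the parameter set describing a thin, incompressible, uniaxially
#' anisotropic (weakly nematic) fluid film from its five two-dimensional
#' viscosities.  The director is taken globally aligned along the x axis.
#' The derived dimensionless anisotropies are
#' \deqn{A = 2\left(\frac{\nu_1+\nu_2}{\nu_3} - 2\right), \qquad
#'       b = \frac{\nu_1-\nu_4+\nu_5}{\nu_3},}
#' together with \eqn{\bar\nu = 2(\nu_1+\nu_2-2\nu_3)} and
#' \eqn{\lambda_\pm = 1 + A/2 \pm b}.
#'
#' Thermodynamic stability requires \eqn{\nu_2 > 0}, \eqn{\nu_3 > 0} and
#' \eqn{A \ge -4}; the latter guarantees that the angular factor
#' \eqn{B(\phi) = 1 + A\sin^2\phi\cos^2\phi} stays non-negative, so that the
#' Fourier-space Green's function is well defined.  \eqn{A = -4} exactly is
#' accepted with a warning: the rotational resistance then vanishes, but
#' field evaluation is refused because \eqn{B} touches zero.
#'
#' @param nu1,nu2,nu3,nu4,nu5 The five 2D viscosities (3D viscosity times
#'   length).  `nu2` and `nu3` must be strictly positive.
#' @return An object of class `"fluid_params"`: a list with the viscosities
#'   `nu` (length 5), `nu_bar`, and the dimensionless `A`, `b`,
#'   `lambda_plus`, `lambda_minus`.
#' @seealso [fluid_from_anisotropies()] to construct directly from `(A, b)`.
#' @export
#' @examples
#' fp <- fluid_params(1, 1, 1, 1, 1)   # isotropic in A, but b = 1
#' fp$A; fp$b
fluid_params <- function(nu1, nu2, nu3, nu4, nu5) {
  stopifnot(is.numeric(nu1), is.numeric(nu2), is.numeric(nu3),
            is.numeric(nu4), is.numeric(nu5))
  if (!(nu2 > 0)) stop("nu2 must be strictly positive (thermodynamic stability)")
  if (!(nu3 > 0)) stop("nu3 must be strictly positive (thermodynamic stability)")
  A <- 2 * ((nu1 + nu2) / nu3 - 2)
  b <- (nu1 - nu4 + nu5) / nu3
  .check_A(A)
  structure(list(
    nu = c(nu1 = nu1, nu2 = nu2, nu3 = nu3, nu4 = nu4, nu5 = nu5),
    nu_bar = 2 * (nu1 + nu2 - 2 * nu3),
    A = A, b = b,
    lambda_plus = 1 + A / 2 + b,
    lambda_minus = 1 + A / 2 - b
  ), class = "fluid_params")
}

.check_A <- function(A) {
  if (A < -4)
    stop("viscosity anisotropy A = ", format(A),
         " lies below the stability bound A >= -4 (B(phi) would become negative)")
  if (A == -4)
    warning("A = -4 sits exactly on the stability boundary: the rotational ",
            "resistance vanishes and hydrodynamic fields are not defined there")
  invisible(A)
}

#' Fluid parameters from the dimensionless anisotropies
#'
#' Convenience constructor used when only the dimensionless anisotropies
#' matter (as they do for every reduced-unit result in this package).  A
#' canonical representative set of viscosities with \eqn{\nu_3 = 1} is
#' chosen: \eqn{\nu_2 = \nu_4 = 1}, \eqn{\nu_1 = 1 + A/2},
#' \eqn{\nu_5 = b - A/2}.
#'
#' @param A Dimensionless viscosity anisotropy, must satisfy `A >= -4`.
#' @param b Dimensionless viscosity anisotropy entering the pressure (and
#'   the off-diagonal part of the viscous stress); defaults to 0.
#' @return A `"fluid_params"` object whose derived `A` and `b` equal the
#'   inputs.
#' @export
#' @examples
#' fluid_from_anisotropies(0.5, 0)$lambda_plus  # 1.25
fluid_from_anisotropies <- function(A, b = 0) {
  .check_A(A)
  fp <- suppressWarnings(fluid_params(1 + A / 2, 1, 1, 1, b - A / 2))
  stopifnot(isTRUE(all.equal(fp$A, A)), isTRUE(all.equal(fp$b, b)))
  fp
}

#' Substrate friction parameters
#'
#' Linear friction of the film with its environment (supporting substrate or
#' confining plates) is modelled by a diagonal friction tensor with entries
#' \eqn{m_\parallel^2} (along the director) and \eqn{m_\perp^2}.  The
#' inverse screening lengths are \eqn{\alpha_{\parallel,\perp}^2 =
#' m_{\parallel,\perp}^2/\nu_3} and the dimensionless friction anisotropy is
#' \deqn{\beta = 1 - \alpha_\perp/\alpha_\parallel.}
#' \eqn{\beta} is undefined in the frictionless case
#' \eqn{\alpha_\parallel = \alpha_\perp = 0} and is then reported as `NA`
#' with `frictionless = TRUE`.
#'
#' @param alpha_par,alpha_perp Inverse screening lengths (1/length), both
#'   non-negative.  `alpha_par = 0` with `alpha_perp > 0` is rejected: the
#'   `beta` parameterisation breaks down in that regime.
#' @return An object of class `"friction_params"` with fields `alpha_par`,
#'   `alpha_perp`, `m_par_sq`, `m_perp_sq` (in units `nu3 = 1`), `beta`
#'   and `frictionless`.
#' @export
#' @examples
#' friction_from_alphas(1, 0.5)$beta   # 0.5
#' friction_from_alphas(0, 0)$frictionless
friction_from_alphas <- function(alpha_par, alpha_perp) {
  stopifnot(is.numeric(alpha_par), is.numeric(alpha_perp))
  if (alpha_par < 0 || alpha_perp < 0)
    stop("friction coefficients must be non-negative")
  frictionless <- (alpha_par == 0 && alpha_perp == 0)
  if (alpha_par == 0 && alpha_perp > 0)
    stop("alpha_par = 0 with alpha_perp > 0 is not supported: ",
         "beta = 1 - alpha_perp/alpha_par is not defined in this regime")
  beta <- if (frictionless) NA_real_ else 1 - alpha_perp / alpha_par
  structure(list(
    alpha_par = alpha_par, alpha_perp = alpha_perp,
    m_par_sq = alpha_par^2, m_perp_sq = alpha_perp^2,
    beta = beta, frictionless = frictionless
  ), class = "friction_params")
}

#' Friction parameters from the friction tensor entries
#'
#' @param m_par_sq,m_perp_sq Friction coefficients per unit area per unit
#'   velocity, both non-negative.
#' @param nu3 The viscosity used to scale them into inverse lengths,
#'   `alpha^2 = m^2/nu3`; default 1 (reduced units).
#' @return A `"friction_params"` object; see [friction_from_alphas()].
#' @export
friction_from_m <- function(m_par_sq, m_perp_sq, nu3 = 1) {
  if (m_par_sq < 0 || m_perp_sq < 0)
    stop("friction tensor entries must be non-negative")
  stopifnot(nu3 > 0)
  friction_from_alphas(sqrt(m_par_sq / nu3), sqrt(m_perp_sq / nu3))
}

#' Define a rotating-disk problem
#'
#' Bundles a disk of radius `a` rotating at angular velocity `Omega` with
#' the fluid and friction parameters of the surrounding film.  All internal
#' computations use reduced units: lengths in units of `a`, velocities in
#' `a*Omega`, pressure in `Omega*nu3/a` and resistance in `nu3*a^2`.  The
#' scaled friction parameter is \eqn{c = \alpha_\parallel a}.
#'
#' @param fluid A `"fluid_params"` object.
#' @param friction A `"friction_params"` object; default frictionless.
#' @param a Disk radius (length), positive.  Default 1.
#' @param Omega Angular velocity (1/time).  Default 1.
#' @return An object of class `"disk_problem"` with the two parameter sets,
#'   `a`, `Omega`, the scaled friction `c = alpha_par * a`,
#'   `c_perp = alpha_perp * a`, and `beta`.
#' @export
#' @examples
#' pr <- disk_problem(fluid_from_anisotropies(0.5), friction_from_alphas(1, 0.5))
#' pr$c; pr$beta
disk_problem <- function(fluid, friction = friction_from_alphas(0, 0),
                         a = 1, Omega = 1) {
  stopifnot(inherits(fluid, "fluid_params"), inherits(friction, "friction_params"))
  if (!(a > 0)) stop("disk radius a must be positive")
  perturb_ok <- abs(fluid$A) <= 1 &&
    (friction$frictionless || abs(friction$beta) <= 1)
  if (!perturb_ok)
    warning("|A| > 1 or |beta| > 1: outside the weakly anisotropic regime; ",
            "perturbative results are not expected to be accurate there")
  structure(list(
    fluid = fluid, friction = friction, a = a, Omega = Omega,
    c = friction$alpha_par * a,
    c_perp = friction$alpha_perp * a,
    beta = friction$beta
  ), class = "disk_problem")
}

#' @export
print.fluid_params <- function(x, ...) {
  cat("Uniaxially anisotropic 2D fluid\n")
  cat(sprintf("  nu1..nu5 : %s\n", paste(format(x$nu, digits = 4), collapse = " ")))
  cat(sprintf("  A = %.6g  b = %.6g  lambda+ = %.6g  lambda- = %.6g\n",
              x$A, x$b, x$lambda_plus, x$lambda_minus))
  invisible(x)
}

#' @export
print.friction_params <- function(x, ...) {
  if (x$frictionless) {
    cat("Substrate friction: none (frictionless film)\n")
  } else {
    cat(sprintf("Substrate friction: alpha_par = %.6g  alpha_perp = %.6g  beta = %.6g\n",
                x$alpha_par, x$alpha_perp, x$beta))
  }
  invisible(x)
}

#' @export
print.disk_problem <- function(x, ...) {
  cat(sprintf("Rotating disk problem: a = %.6g, Omega = %.6g, c = %.6g\n",
              x$a, x$Omega, x$c))
  print(x$fluid)
  print(x$friction)
  invisible(x)
}
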