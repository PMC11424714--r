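#' Angular anisotropy factor B(phi)
#'
#' The angular factor \eqn{B(\phi) = 1 + A\sin^2\phi\cos^2\phi} of the
#' Fourier-space kernel.  It is bounded between \eqn{1} and \eqn{1 + A/4}
#' for \eqn{A \ge 0} and stays non-negative down to the stability bound
#' \eqn{A = -4}, where it touches zero at \eqn{\phi = \pi/4}.
#'
#' @param phi Angle(s) in radians.
#' @param A Dimensionless viscosity anisotropy, `A >= -4`.
#' @return `B(phi)`, vectorised over `phi`.
#' @export
anisotropy_factor <- function(phi, A) {
  .check_A(A)
  1 + A * sin(phi)^2 * cos(phi)^2
}

#' Scalar Fourier-space kernel H(k, phi)
#'
#' \deqn{H(k,\phi) = \alpha_\parallel^2\sin^2\phi + \alpha_\perp^2\cos^2\phi
#'   + k^2 B(\phi).}
#' The anisotropic Green's function is \eqn{G(\phi)/(\nu_3 H)}; positivity
#' of `H` is what keeps it well defined.
#'
#' @param k Wavenumber (1/length), `k >= 0`.
#' @param phi Angle in radians.
#' @param A Dimensionless viscosity anisotropy.
#' @param alpha_par,alpha_perp Inverse screening lengths.
#' @return The (vectorised) kernel value; errors if it vanishes.
#' @export
kernel_H <- function(k, phi, A, alpha_par = 0, alpha_perp = 0) {
  H <- alpha_par^2 * sin(phi)^2 + alpha_perp^2 * cos(phi)^2 +
    k^2 * anisotropy_factor(phi, A)
  if (any(H <= 0))
    stop("degenerate kernel: H(k, phi) <= 0 (Green's function undefined)")
  H
}

#' Transverse projector of the anisotropic Green's function
#'
#' The tensor part \eqn{G(\phi)} of the Green's function: the projector
#' onto the direction transverse to the unit wavevector
#' \eqn{\hat k = (\cos\phi, \sin\phi)}.  It is symmetric, idempotent, has
#' unit trace and annihilates \eqn{\hat k} (incompressibility).
#'
#' @param phi Angle in radians (scalar).
#' @return A 2x2 numeric matrix.
#' @export
transverse_projector <- function(phi) {
  s <- sin(phi); cc <- cos(phi)
  matrix(c(s^2, -s * cc, -s * cc, cc^2), 2L, 2L)
}

#' Terminating Gauss hypergeometric series
#'
#' Evaluates \eqn{{}_2F_1(a, b; c; x)} when `a` or `b` is a non-positive
#' integer, in which case the series terminates and the function is a
#' polynomial in `x` with rational coefficients.  All hypergeometric
#' factors appearing in the exact zero-friction solution are of this type,
#' so no general (infinite-series) evaluation is ever required.
#'
#' @param a,b,cc Parameters; at least one of `a`, `b` must be a
#'   non-positive integer, and `cc` must not be a non-positive integer
#'   reached before termination.
#' @param x Argument; may be a numeric or complex vector.
#' @return Polynomial value(s), same length as `x`.
#' @export
hyp2f1_terminating <- function(a, b, cc, x) {
  is_npi <- function(z) is.numeric(z) && z <= 0 && z == round(z)
  if (!is_npi(a)) {
    if (!is_npi(b)) stop("neither parameter is a non-positive integer: ",
                         "series does not terminate, refusing to sum")
    tmp <- a; a <- b; b <- tmp
  }
  N <- -a
  if (is_npi(cc) && -cc < N)
    stop("lower parameter produces a zero denominator before termination")
  s <- rep(if (is.complex(x)) 0 + 0i else 0, length(x)) + 1
  term <- s
  if (N >= 1) for (k in 0:(N - 1)) {
    term <- term * ((a + k) * (b + k) / ((cc + k) * (k + 1))) * x
    s <- s + term
  }
  s
}

## ---- Laurent principal parts of modified-Bessel products -----------------

## Internal workhorse in terms of the Bessel orders p (of I, argument
## w*sigma) and q (of K, argument sigma); q > p of equal parity required for
## a non-empty principal part.  Each retained monomial is
## coef * w^w_pow * t^t_pow with t = 1/sigma^2.
.pp_orders <- function(p, q) {
  stopifnot(p >= 0, q > p, (q - p) %% 2 == 0)
  rows <- list()
  jmax <- (q - p) %/% 2 - 1
  for (j in 0:max(jmax, 0)) {
    for (jp in 0:(q - 1)) {
      e <- (q - p) %/% 2 - j - jp          # t exponent
      if (e < 1) next
      if (q - 1 <= 18 && 2 * e - 1 <= 30) {
        num <- factorial(q - 1 - jp) * 2^(2 * e - 1)
        den <- factorial(jp) * factorial(j) * factorial(p + j)
        coef <- num / den
      } else {
        coef <- exp(lfactorial(q - 1 - jp) + (2 * e - 1) * log(2) -
                      lfactorial(jp) - lfactorial(j) - lfactorial(p + j))
      }
      rows[[length(rows) + 1L]] <-
        c(w_pow = p + 2 * j, t_pow = e, coef = (-1)^jp * coef)
    }
  }
  df <- as.data.frame(do.call(rbind, rows))
  df <- stats::aggregate(coef ~ w_pow + t_pow, df, sum)
  df[order(df$t_pow, df$w_pow), , drop = FALSE]
}

#' Principal part of the Laurent expansion of a modified-Bessel product
#'
#' For mode indices `m > n >= 0`, the product
#' \eqn{\Delta_{mn} = I_{2n+1}(w\sigma) K_{2m+1}(\sigma)} has a pole-type
#' (negative-exponent) part in its Laurent expansion about \eqn{\sigma = 0}.
#' This function extracts that part programmatically, by multiplying the
#' ascending series of \eqn{I_{2n+1}} with the finite singular sum of
#' \eqn{K_{2m+1}} and keeping only the monomials of negative total
#' \eqn{\sigma}-exponent (the logarithmic terms of \eqn{K} never reach
#' negative powers).  The result is an exact-coefficient bivariate
#' polynomial in \eqn{w} and \eqn{t = 1/\sigma^2}; every monomial carries
#' \eqn{t}-power at least one and the lowest \eqn{w}-power is
#' \eqn{w^{2n+1}}.
#'
#' @param m,n Mode indices with `m > n >= 0`.
#' @return An object of class `"pp_poly"`: list with `m`, `n`, the Bessel
#'   orders `p = 2n+1`, `q = 2m+1`, and `terms`, a data frame with columns
#'   `w_pow`, `t_pow`, `coef`.
#' @seealso [pp_eval()] to evaluate it numerically.
#' @export
#' @examples
#' principal_part(1, 0)$terms   # the single monomial 4 w t
principal_part <- function(m, n) {
  if (!(m > n && n >= 0)) stop("principal part requires m > n >= 0 (it is empty otherwise)")
  structure(list(m = m, n = n, p = 2 * n + 1, q = 2 * m + 1,
                 terms = .pp_orders(2 * n + 1, 2 * m + 1)),
            class = "pp_poly")
}

#' Evaluate a principal-part polynomial
#'
#' @param pp A `"pp_poly"` from [principal_part()].
#' @param w Dimensionless radius ratio `a/rho`, in `(0, 1]` (vectorised).
#' @param t `1/sigma^2` (vectorised, recycled against `w`).
#' @return Numeric value(s) of the polynomial.
#' @export
pp_eval <- function(pp, w, t) {
  stopifnot(inherits(pp, "pp_poly"))
  .pp_eval_terms(pp$terms, w, t)
}

.pp_eval_terms <- function(terms, w, t) {
  out <- 0
  for (i in seq_len(nrow(terms)))
    out <- out + terms$coef[i] * w^terms$w_pow[i] * t^terms$t_pow[i]
  out
}

#' @export
print.pp_poly <- function(x, ...) {
  cat(sprintf("Principal part of I_%d(w s) K_%d(s) about s = 0 (t = 1/s^2):\n",
              x$p, x$q))
  mono <- sprintf("%+g w^%d t^%d", x$terms$coef, x$terms$w_pow, x$terms$t_pow)
  cat(" ", paste(mono, collapse = " "), "\n")
  invisible(x)
}

## ---- numerically robust Bessel-product machinery --------------------------

## log I_nu(x) for integer nu >= 0, x >= 0, safe against underflow of
## besselI for x << nu.
.log_besselI <- function(nu, x) {
  if (x == 0) return(if (nu == 0) 0 else -Inf)
  r <- besselI(x, nu, expon.scaled = TRUE)
  if (is.finite(r) && r > 0) return(log(r) + x)
  j <- 0:60
  lt <- (nu + 2 * j) * log(x / 2) - lfactorial(j) - lfactorial(nu + j)
  M <- max(lt)
  M + log(sum(exp(lt - M)))
}

## log K_nu(x) for integer nu >= 0, x > 0, safe against overflow of
## besselK for x << nu (singular finite sum dominates there).
.log_besselK <- function(nu, x) {
  r <- besselK(x, nu, expon.scaled = TRUE)
  if (is.finite(r) && r > 0) return(log(r) - x)
  if (nu == 0) stop("besselK order-0 overflow not expected")
  jp <- 0:(nu - 1)
  lt <- lfactorial(nu - 1 - jp) - lfactorial(jp) + (2 * jp - nu) * log(x / 2) - log(2)
  sgn <- (-1)^jp
  M <- max(lt)
  M + log(sum(sgn * exp(lt - M)))
}

## Delta for general orders: I_p(w sigma) K_q(sigma), vectorised over sigma,
## with scalar log-space fallback where the scaled Bessel routines under- or
## overflow.
.delta_orders <- function(p, q, w, sigma) {
  Is <- besselI(w * sigma, p, expon.scaled = TRUE)
  Ks <- besselK(sigma, q, expon.scaled = TRUE)
  val <- Is * Ks * exp(-sigma * (1 - w))
  bad <- !is.finite(val) | val <= 0
  for (i in which(bad))
    val[i] <- exp(.log_besselI(p, w * sigma[i]) + .log_besselK(q, sigma[i]))
  val
}

## Series table for the regular (non-negative exponent) Laurent part of
## I_p(w s) K_q(s) about s = 0, for q > p of equal parity:
##   regular(s) = sum cf * w^we * s^(2e)
##              + log(s/2) * sum lcf * w^we * s^(2e)  + psi-tail terms.
## All sigma powers are even, so the table stores half-exponents e and the
## evaluation is a polynomial in x = sigma^2.  The table is independent of
## w (the w powers are kept symbolic) and is cached per (p, q); it is
## accurate for s up to ~2*sqrt(q+1), the cancellation regime of the direct
## subtraction.
.delta_reg_table <- function(p, q, smax) {
  l2 <- log(2); lsm <- log(smax)
  we1 <- e1 <- cf1 <- list(); we2 <- e2 <- lcf <- tcf <- list()
  scale <- 0
  # ascending-I x singular-K cross terms with non-negative sigma power
  for (j in 0:400) {
    lgI <- -(p + 2 * j) * l2 - lfactorial(j) - lfactorial(p + j)
    block_max <- -Inf
    for (jp in 0:(q - 1)) {
      spow <- p + 2 * j + 2 * jp - q
      if (spow < 0) next
      lgK <- lfactorial(q - 1 - jp) - lfactorial(jp) - (2 * jp - q) * l2 - l2
      cf <- (-1)^jp * exp(lgI + lgK)
      we1[[length(we1) + 1L]] <- p + 2 * j
      e1[[length(e1) + 1L]] <- spow %/% 2
      cf1[[length(cf1) + 1L]] <- cf
      block_max <- max(block_max, lgI + lgK + spow * lsm)
    }
    scale <- max(scale, block_max)
    if (is.finite(block_max) && block_max < scale - 52 && j > 2) break
  }
  # log term and psi-series tail of K_q, times the ascending series of I_p
  for (i in 0:400) {
    lgI <- -(p + 2 * i) * l2 - lfactorial(i) - lfactorial(p + i)
    done_i <- TRUE
    for (j2 in 0:400) {
      base <- lgI - (q + 2 * j2) * l2 - lfactorial(j2) - lfactorial(q + j2)
      pw <- p + 2 * i + q + 2 * j2
      if (base + pw * lsm < scale - 52) { if (j2 > 2) break } else done_i <- FALSE
      we2[[length(we2) + 1L]] <- p + 2 * i
      e2[[length(e2) + 1L]] <- pw %/% 2
      lcf[[length(lcf) + 1L]] <- (-1)^(q + 1) * exp(base)
      tcf[[length(tcf) + 1L]] <- (-1)^q * 0.5 *
        (digamma(j2 + 1) + digamma(q + j2 + 1)) * exp(base)
    }
    if (done_i && i > 2) break
  }
  list(we1 = unlist(we1), e1 = unlist(e1), cf1 = unlist(cf1),
       we2 = unlist(we2), e2 = unlist(e2),
       lcf = unlist(lcf), tcf = unlist(tcf))
}

## Evaluate an even polynomial sum(coef[k] x^e[k]) at x (vector), where the
## exponents e may repeat (coefficients are accumulated first).
.eval_even_poly <- function(e, coef, x) {
  emax <- max(e)
  full <- numeric(emax + 1)
  for (i in seq_along(e)) full[e[i] + 1] <- full[e[i] + 1] + coef[i]
  out <- numeric(length(x)); pv <- rep(1, length(x))
  for (k in 0:emax) {
    if (full[k + 1] != 0) out <- out + full[k + 1] * pv
    pv <- pv * x
  }
  out
}

.delta_reg_eval_w <- function(tab, w, sigma) {
  x <- sigma^2
  v <- .eval_even_poly(tab$e1, tab$cf1 * w^tab$we1, x)
  wfac2 <- w^tab$we2
  v + log(sigma / 2) * .eval_even_poly(tab$e2, tab$lcf * wfac2, x) +
    .eval_even_poly(tab$e2, tab$tcf * wfac2, x)
}

## Regularised difference Delta_pq - P Delta_pq for q > p, vectorised over
## sigma, switching to the termwise regular-part series where the direct
## subtraction would cancel catastrophically.
.delta_minus_pp_orders <- function(p, q, w, sigma, cache = NULL) {
  switchpt <- 2 * sqrt(q + 1)
  out <- numeric(length(sigma))
  small <- sigma <= switchpt
  if (any(small)) {
    tab <- .cache_get(cache, sprintf("tab_%d_%d", p, q),
                      function() .delta_reg_table(p, q, switchpt))
    out[small] <- .delta_reg_eval_w(tab, w, sigma[small])
  }
  if (any(!small)) {
    terms <- .cache_get(cache, sprintf("pp_%d_%d", p, q),
                        function() .pp_orders(p, q))
    sl <- sigma[!small]
    out[!small] <- .delta_orders(p, q, w, sl) - .pp_eval_terms(terms, w, 1 / sl^2)
  }
  out
}

.cache_get <- function(cache, key, make) {
  if (is.null(cache)) return(make())
  if (!exists(key, envir = cache, inherits = FALSE))
    assign(key, make(), envir = cache)
  get(key, envir = cache, inherits = FALSE)
}

## The u-weighted Bessel-product integral for general orders p, q of equal
## parity (both odd in practice):
##   int_0^inf u J_q(u) J_p(w u) / (u^2 + sigma^2) du
##     = (-1)^((q-p)/2) * (Delta_pq - [q>p] P Delta_pq).
.jj_u_integral <- function(p, q, w, sigma, cache = NULL) {
  base <- if (q > p) .delta_minus_pp_orders(p, q, w, sigma, cache)
          else .delta_orders(p, q, w, sigma)
  (-1)^((q - p) / 2) * base
}

#' Modified-Bessel product for the wavenumber integral
#'
#' \eqn{\Delta_{mn} = I_{2n+1}(w\sigma)\,K_{2m+1}(\sigma)}, evaluated
#' stably in log space so that large mode orders at small \eqn{\sigma}
#' (where `besselI` underflows and `besselK` overflows) still yield the
#' finite product.
#'
#' @param m,n Mode indices `>= 0`.
#' @param w Dimensionless radius ratio in `(0, 1]`.
#' @param sigma Screening variable, `> 0` (vectorised).
#' @return The product value (finite, positive).
#' @export
delta_product <- function(m, n, w, sigma) {
  if (any(sigma <= 0)) stop("sigma must be positive; use the frictionless branch at sigma = 0")
  if (!(w > 0 && w <= 1)) stop("w must lie in (0, 1]")
  .delta_orders(2 * n + 1, 2 * m + 1, w, sigma)
}

#' Exact wavenumber integral Gamma_mn
#'
#' The radial kernel of the mode sums: the wavenumber integral
#' \deqn{\Gamma_{mn} = \frac{(-1)^{m+n}}{B}\int_0^\infty
#'   \frac{u\,J_{2m+1}(u)\,J_{2n+1}(wu)}{u^2+\sigma^2}\,du}
#' evaluated in closed form as
#' \eqn{(\Delta_{mn} - [m>n]\,\mathcal P\Delta_{mn})/B}, where
#' \eqn{\mathcal P\Delta} is the Laurent principal part about
#' \eqn{\sigma = 0}.  The alternating sign of the defining integral is
#' absorbed here, so the returned value feeds directly into the velocity
#' mode sums.  At \eqn{\sigma = 0} the call dispatches to
#' [gamma_frictionless()].  Below an order-dependent switch point in
#' \eqn{\sigma} the difference is formed termwise from the regular part of
#' the Laurent series rather than by subtracting two nearly equal large
#' numbers.
#'
#' @param m,n Mode indices `>= 0`.
#' @param w Dimensionless radius ratio `a/rho`; must lie in `(0, 1]`
#'   (outside or on the disk rim).
#' @param sigma Screening variable `>= 0` (may be a vector).
#' @param B Angular factor `B(phi)` (scalar or vector recycled with
#'   `sigma`).
#' @param cache Optional environment used to memoise principal parts and
#'   series coefficients across calls.
#' @return `Gamma_mn`, vectorised over `sigma`/`B`.
#' @export
gamma_integral <- function(m, n, w, sigma, B = 1, cache = NULL) {
  if (any(w > 1) || any(w <= 0))
    stop("w must lie in (0, 1]: field points inside the disk are not admissible")
  ln <- max(length(sigma), length(B))
  sigma <- rep_len(sigma, ln); B <- rep_len(B, ln)
  out <- numeric(ln)
  zero <- sigma == 0
  if (any(zero)) out[zero] <- gamma_frictionless(m, n, w, B[zero])
  if (any(!zero)) {
    p <- 2 * n + 1; q <- 2 * m + 1
    base <- if (m > n) .delta_minus_pp_orders(p, q, w, sigma[!zero], cache)
            else .delta_orders(p, q, w, sigma[!zero])
    out[!zero] <- base / B[!zero]
  }
  out
}

#' Frictionless wavenumber integral
#'
#' Closed form of [gamma_integral()] at \eqn{\sigma = 0}:
#' \deqn{\Gamma_{mn} = \frac{(-1)^{m+n}}{2B}
#'   \frac{\Gamma(m+n+1)}{\Gamma(m-n+1)\Gamma(2n+2)}\,
#'   w^{2n+1}\,{}_2F_1(n-m,\,n+m+1;\,2n+2;\,w^2),}
#' which vanishes for `n > m` and reduces on the rim (`w = 1`) to
#' \eqn{\delta_{mn}/(2B(2m+1))}.  The hypergeometric factor terminates for
#' `m >= n`, so this is a polynomial evaluation.
#'
#' @inheritParams gamma_integral
#' @param B Angular factor `B(phi)` (vectorised).
#' @return `Gamma_mn` at zero friction.
#' @export
gamma_frictionless <- function(m, n, w, B = 1) {
  if (n > m) return(rep(0, length(B)))
  pref <- (-1)^(m + n) / 2 *
    exp(lgamma(m + n + 1) - lgamma(m - n + 1) - lgamma(2 * n + 2))
  as.numeric(pref * w^(2 * n + 1) *
               hyp2f1_terminating(n - m, n + m + 1, 2 * n + 2, w^2)) / B
}
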