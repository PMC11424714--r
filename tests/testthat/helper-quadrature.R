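# Independent brute-force oracle for the wavenumber integral
#   int_0^inf u J_{2m+1}(u) J_{2n+1}(w u) / (u^2 + sigma^2) du,
# by piecewise adaptive quadrature plus two-scale endpoint averaging over
# the fast (1+w) and beat (1-w) oscillation half-periods; at w = 1 the
# slowly decaying non-oscillatory component gets an analytic tail.
# Absolute accuracy is a few 1e-9 at L = 30000 (tail-limited), which sets
# the comparison threshold used by the tests.
quad_wavenumber_integral <- function(m, n, w, sigma, L = 30000) {
  f <- function(u) u * besselJ(u, 2 * m + 1) * besselJ(w * u, 2 * n + 1) /
    (u^2 + sigma^2)
  base <- 0
  brk <- seq(0, L, by = 8 * pi)
  for (i in seq_len(length(brk) - 1))
    base <- base + integrate(f, brk[i], brk[i + 1], rel.tol = 1e-11,
                             subdivisions = 600L, abs.tol = 1e-16)$value
  ext <- function(L1, L2)
    integrate(f, L1, L2, rel.tol = 1e-11, subdivisions = 2000L,
              abs.tol = 1e-16)$value
  if (w < 1 - 1e-9) {
    hb <- pi / (1 - w); hf <- pi / (1 + w)
    ends <- c(L, L + hf, L + hb, L + hb + hf)
    vals <- numeric(4); cur <- base; last <- L
    for (e in sort(ends)) {
      cur <- cur + ext(last, e); last <- e
      vals[which(abs(ends - e) < 1e-9)] <- cur
    }
    mean(vals)
  } else {
    base + (-1)^(m - n) / pi * (pi / 2 - atan(L / sigma)) / sigma
  }
}

# Azimuthal Fourier amplitude |mode k| of a sampled periodic signal
harmonic_amplitude <- function(y, k) {
  nf <- length(y)
  Mod(fft(y))[k + 1] / nf * if (k == 0) 1 else 2
}

# Discrete polar divergence (1/rho) d(rho v_rho)/drho + (1/rho) dv_theta/dtheta
# at a single interior point, using 5-point central stencils.
discrete_divergence <- function(vfun, rho, theta, h = 1e-3) {
  st <- c(1, -8, 0, 8, -1) / (12 * h)
  rr <- rho + h * (-2:2)
  f_r <- vfun(rr, rep(theta, 5))
  d_r <- sum(st * (rr * f_r$v_rho))
  tt <- theta + h * (-2:2)
  f_t <- vfun(rep(rho, 5), tt)
  d_t <- sum(st * f_t$v_theta)
  (d_r + d_t) / rho
}
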