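---
title: "Rotational hydrodynamics of a disk in a weakly nematic thin film: models and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rotational hydrodynamics of a disk in a weakly nematic thin film: models and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nemadisk)
```

## The physical problem

Membrane proteins and other disk-like inclusions rotate within an
essentially two-dimensional fluid: a lipid bilayer, a surfactant monolayer,
or a thin cell of nematic liquid crystal.  Two physical ingredients
distinguish such films from the textbook isotropic, unbounded membrane:

* **Uniaxial anisotropy.**  If the film carries orientational order — a
  nematic director, here taken globally aligned with the x axis — its
  viscous response requires five viscosities $\nu_1,\dots,\nu_5$ instead of
  one.  At the level of the flow equations only two dimensionless
  combinations matter for a rotating disk:
  $$A = 2\left(\frac{\nu_1+\nu_2}{\nu_3}-2\right), \qquad
    b = \frac{\nu_1-\nu_4+\nu_5}{\nu_3},$$
  with $A$ entering both velocity and pressure and $b$ the pressure only.
  Thermodynamic stability restricts $A \ge -4$.

* **Substrate friction.**  Momentum exchange with a supporting substrate or
  confining plates acts as a body force $-\mathbf M\cdot\mathbf v$ with a
  diagonal friction tensor.  The screening lengths
  $\alpha_{\parallel,\perp}^{-1}$ combine with the disk radius $a$ into a
  scaled friction $c=\alpha_\parallel a$ and a friction anisotropy
  $\beta = 1-\alpha_\perp/\alpha_\parallel$.

The package computes, for a rigid disk of radius $a$ rotating steadily at
angular velocity $\Omega$ under no-slip conditions, the hydrodynamic
velocity and pressure fields and the rotational resistance
$R$ (torque $T=-R\,\Omega$) and mobility $\mu=1/R$.  Unlike translation,
rotation is well behaved even without friction: the flow decays as $1/\rho$
rather than diverging logarithmically, so the zero-friction limit admits
exact results.

All computations are internally nondimensional — lengths in $a$, velocities
in $a\Omega$, pressure in $\Omega\nu_3/a$, resistance in $\nu_3a^2$ — and
all printed output uses these reduced units.  The radial coordinate enters
as $w=a/\rho \in (0,1]$.

## Three solution tiers

### 1. Perturbative closed forms (`mobility()` and friends)

For weak anisotropy ($|A|,|\beta|\ll1$) the resistance has the second-order
expansion
$$R = \nu_3 a^2\left(R^{\mathrm{IES}} + R^{(1,0)}A + R^{(0,1)}\beta
  + R^{(2,0)}A^2 + R^{(1,1)}A\beta + R^{(0,2)}\beta^2\right),$$
around the isotropic substrate-coupled base state
$R^{\mathrm{IES}} = 2\pi c\,\xi_2$, where $\xi_i = K_i(c)/K_1(c)$ are
modified-Bessel ratios.  The base state itself interpolates between the
classical unbounded-film drag $4\pi\nu_3a^2$ at $c\to0$ and
friction-dominated behaviour at large $c$; the identity
$2\pi c\,\xi_2 = 4\pi\bigl(1+\tfrac c2 K_0(c)/K_1(c)\bigr)$ connects the
two standard ways of writing it.  The five correction coefficients are
closed functions of $c$ through $\xi_0,\xi_2,\xi_3$; their $c\to0$ limits
($R^{(1,0)}\to\pi/2$, $R^{(2,0)}\to-\pi/32$, the $\beta$ coefficients
$\to0$) are implemented as dedicated analytic branches below $c<10^{-8}$,
because friction anisotropy is meaningless without friction and naive
evaluation of the $K$-ratios degrades there.  In practice the printed
formulas are numerically stable down to remarkably small $c$ since only
$\xi_0$ requires a Bessel evaluation; $\xi_2$ and $\xi_3$ follow from
recurrences.

Mobility corrections follow from inverting the series,
$\mu^{(1,0)}=-R^{(1,0)}/R^{\mathrm{IES}}$,
$\mu^{(2,0)}=(\mu^{(1,0)})^2-R^{(2,0)}/R^{\mathrm{IES}}$, and so on.  The
report exposes both the truncated mobility series and $1/R_{\rm total}$;
their difference is an honest $O(\epsilon^3)$ error estimate for the
truncation.  In the frictionless limit the scaled mobility reduces to
$1-\tfrac A8+\tfrac{3A^2}{128}$.

```{r}
mobility(0.5, 0.5, 1)
```

### 2. Exact frictionless series (`exact_velocity()`, `exact_resistance()`, ...)

At $\alpha_\parallel=\alpha_\perp=0$ the rim force density collapses onto
its first Fourier mode, with coefficient $c_1=(1+A/4)^{1/2}$, and every
field mode is a *terminating* Gauss hypergeometric polynomial weighted by
the geometric factor
$$\chi_n = \left(\frac{\sqrt A}{2+\sqrt{A+4}}\right)^{\!n}, \qquad
|\chi_1|<1 \text{ for all finite } A>0 .$$
Velocity modes of odd index vanish identically — hence the quarter-turn
symmetry of the flow — and the series converges geometrically.  The
resistance resums in closed form to
$$R = 2\pi\nu_3 a^2\sqrt{A+4},$$
which recovers $4\pi\nu_3a^2$ at $A=0$ and vanishes at the stability
boundary $A=-4$.  (The package fixes the $\nu_3a^2$ scale throughout; it is
the only dimensionally consistent choice for a 2D torque per angular
velocity.)  The rim pressure also resums exactly:
$$p(\rho=a,\theta)=\frac{\Omega\nu_3}{a}\,(A+4)^{1/2}\,
  \frac{4b\sin2\theta + A\sin4\theta}{8+A(1-\cos4\theta)} .$$

The parity-dependent prefactor of the pressure modes contains an apparent
$A^{-1/2}$ for odd modes; it always cancels against $\chi_n\propto A^{n/2}$
and the implementation evaluates only the cancelled, analytic-in-$A$ form,
so the $A\to0$ limit (e.g. $u_1\to b\,w^2$) is exact.  For the same reason
every mode function accepts complex $A$, which the test suite uses to read
off Taylor coefficients in $A$ by trigonometric interpolation of the Cauchy
integral on the circle $|A|=1$ — accurate to near machine precision since
the nearest singularity sits at $|A|=4$.

For $-4<A<0$ the factor $\chi_n$ is imaginary as written; whether the
series continues analytically there is not settled, so the exact-field
evaluators refuse negative $A$ and defer to the spectral solver, which has
no such restriction.

### 3. Spectral reference solver (`oracle_solve()`)

For arbitrary $(A,b,\beta,c)$ no closed solution exists.  The package's
reference solver expands the rim force density in odd Fourier modes with
real coefficients $(c_{2n+1}, d_{2n+1})$ and enforces no slip by Galerkin
projection of the reconstructed rim velocity onto the odd harmonics.  The
field reconstruction rests on the anisotropic Fourier-space Green's
function $G(\phi)/(\nu_3 H(k,\phi))$ with
$H = \alpha_\parallel^2\sin^2\phi + \alpha_\perp^2\cos^2\phi + k^2B(\phi)$
and $B(\phi)=1+A\sin^2\phi\cos^2\phi$: the wavenumber integral for each
mode pair evaluates in closed form to a modified-Bessel product
$I_{2n+1}(w\sigma)K_{2m+1}(\sigma)$ minus, for $m>n$, the principal part of
its Laurent expansion about $\sigma=0$ (`gamma_integral()`).  Angular
integrals use the periodic trapezoid rule (spectrally accurate for these
smooth $2\pi$-periodic integrands; default 256 nodes, computed on a quarter
period and unfolded by symmetry).  The solver starts from 8 modes and
doubles (up to 64) until the a-posteriori rim residual drops below the
tolerance (default $10^{-8}$); non-convergence is flagged, never silent.

Principal parts are *extracted programmatically*: the ascending series of
$I$ is multiplied by the finite singular sum of $K$ and monomials of
negative total exponent are kept, with exact integer coefficients for the
table-sized orders.  The printed low-order table is a test fixture, not a
data source.  Near $\sigma=0$ the difference $\Delta-\mathcal P\Delta$ is
formed termwise from the regular Laurent part (an even polynomial in
$\sigma$ plus a $\log\sigma$ series) instead of subtracting two nearly
equal large numbers; the switch point $\sigma = 2\sqrt{q+1}$ (with $q$ the
$K$ order) keeps both branches in their well-conditioned regimes, and the
two branches agree to $\sim10^{-9}$ at the seam.

The resistance is extracted through the rim identity
$$\frac{R}{\pi a^2\nu_3} = 2+\frac A4 - a\frac{d}{d\rho}
  \Bigl[\bigl(2+\tfrac A4\bigr)h_0 - \tfrac A8 h_2\Bigr]_{\rho=a},$$
where $h_0,h_2$ are the azimuthal-velocity harmonics (coefficients of
$\cos0$ and $\cos4\theta$), differentiated by a one-sided six-point stencil
(step $10^{-3}a$); a step-doubling error estimate is attached.  A fully
independent route — direct integration of the anisotropic traction moment
over the rim, including the anisotropic extra stress $\Phi$ and the
$\delta_\pm$ terms (`torque_stress_integral()`) — agrees with the rim
identity to quadrature accuracy and is exercised in the tests.

The pressure (`oracle_pressure()`) is recovered by longitudinal projection
of the momentum balance in Fourier space: eliminating the velocity through
the Green's function leaves a friction-free part, whose radial integrals
are *terminating* Weber–Schafheitlin polynomials (they vanish for harmonic
order $\le 2n$), plus a screened part that reuses the same Bessel-product
kernels.  Only even azimuthal harmonics contribute; the gauge is fixed by
decay at infinity.  The implementation is validated against every closed
form the model admits: the isotropic-friction pressure
$p^*=\tfrac{bc}2 K_2(r)/K_1(c)\sin2\theta$, the exact frictionless interior
series, and the rim resummation above.

## Numerical choices and degenerate inputs

* **Conditioning of high-order terminating polynomials.**  The
  hypergeometric mode polynomials have alternating coefficients growing
  roughly like $4^n$, so double precision limits the usable mode order near
  the rim.  The field summers therefore truncate adaptively: each mode's
  roundoff floor is estimated as machine epsilon times the all-positive
  magnitude of its series, and summation stops when a mode's value falls
  below its own noise floor (or below $10^{-12}$).  Consequently exact
  fields at $A\gtrsim8$ very close to the rim are accuracy-limited to about
  $10^{-7}$; the spectral solver, whose kernels involve only low-order
  differences, does not suffer from this.  The spectral pressure's harmonic
  sum carries an analogous guard that stops on sustained term growth.
* **$A=-4$** is accepted with a warning for the resistance (which cleanly
  vanishes there) but fields are refused, since $B(\phi)$ touches zero and
  the Green's function degenerates.
* **$\beta$ without friction** is undefined; the frictionless constructors
  flag it as `NA`, and the mobility report returns the $\beta$ coefficients
  as zero with `beta_defined = FALSE` rather than guessing.
* **Truncation order** for the exact series is chosen from the geometric
  tail bound $C|\chi|^N N^2/(1-|\chi|)<\mathrm{tol}$ with $C$ calibrated
  from the first retained modes; the bound is this package's own
  construction and is cross-checked empirically in the tests.
* **Perturbative-regime guard**: $|A|>1$ or $|\beta|>1$ triggers a warning,
  not an error — the exact and spectral tiers remain valid there.

## What the validation battery does and does not show

The cross-checks (`validate_crosschecks()`, and the test suite in
`tests/testthat/`) verify: the classical isotropic limits; exact-vs-
spectral agreement of fields, pressure and resistance at strong anisotropy;
the $O(\epsilon^3)$ decay of the perturbative remainder (halving
$\epsilon$ divides the discrepancy by $\approx8$, which validates all five
correction coefficients simultaneously); agreement of the wavenumber
kernels with brute-force oscillatory quadrature; rim no-slip residuals;
discrete incompressibility; quarter-turn symmetry at $\beta=0$ and its
breaking at $\beta\ne0$; and the harmonic content of velocity and pressure
order by order.  Problem sizes are kept desk-scale: spectral solves use 8
to 16 starting modes and 256 angular nodes, field grids are $O(10^2)$
points, and the quadrature oracle integrates to $u=3\times10^4$.

These checks validate the *mathematical model and its implementation*, not
the model's fidelity to any particular experimental membrane: real films
have director–flow coupling (deliberately excluded here: the director is
held fixed by assumption, as by a strong external field), thermal
fluctuations, finite inclusion thickness, and boundary effects, none of
which are represented.  Translational motion and translation–rotation
coupling are out of scope (for this geometry the coupling vanishes).

## Reproducing the reference numbers

`scripts/acceptance.R` recomputes, from the installed package, the two
archival reference values — the vanishing resistance at the stability
boundary and the evaluated low-order principal part — and writes them as
JSON; see the README for invocation.
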