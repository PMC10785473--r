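---
title: "Estimating hydraulic resistance of nonuniform ducts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating hydraulic resistance of nonuniform ducts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ductresist)
```

## The problem

Cerebrospinal fluid moves through perivascular spaces (PVSs) — annular,
CSF-filled channels around brain blood vessels — and hydraulic-network models
of that flow need, above all, the hydraulic resistance of each channel. For a
nonuniform duct the natural quantity is the resistance per unit length,

$$\mathcal{R}(z) \equiv -\frac{\partial p/\partial z}{Q},$$

the negative axial pressure gradient divided by the volume flow rate, in
Pa·s/µm⁴ throughout this package (a reporting conversion to mmHg·min/mL/m is
provided by `convert_resistance()`). Pial PVSs are open spaces with very low
Reynolds and Womersley numbers, so steady Stokes flow is the governing model
and $\mathcal{R}$ is flow-rate independent. The package estimates
$\mathcal{R}(z)$ from cross-sectional geometry alone, at a hierarchy of costs:

* **SUN** — solve the unidirectional (Poisson) problem
  $\mu \nabla^2 w = \mathrm{d}p/\mathrm{d}z$, $w=0$ on the boundary, on each
  cross section (`sun_resistance()`, `series_profile()`);
* **SUA** — the exact circular solution $8\mu/(\pi r^4)$ (`sua_circle()`);
* **methods I–IV** — closed-form approximations: area scaling
  $\mathcal{R}_\mathrm{ref}(A_\mathrm{ref}/A)^2$, the shape factor
  $\gamma = \tfrac1N\sum_j (r_\mathrm{eq}/d_j)^4$ on the Hagen–Poiseuille
  resistance, the matched-ellipse formula
  $4\mu(\beta^2+1)/(\pi r_\mathrm{eq}^4 \beta)$, and the polar-moment formula
  $16\pi^2 \mu I_p/A^4$ (`method_I()` … `method_IV()`);
* **extended lubrication theory (ELT)** — for nonuniform elliptical ducts,
  the second-order correction $\mathcal{R}_2$ to the uniform-duct resistance
  $\mathcal{R}_0$, and the induced error model and correction factor
  $\lambda$ (`ellipse_R2()`, `fixed_beta_R2()`, `elt_error()`,
  `lambda_correct()`);
* **axisymmetric Stokes oracle** — a full (truncation-free) Stokes solve for
  circular ducts of varying radius, the package's ground truth
  (`axisym_resistance_profile()`).

All of these consume a `duct_geometry`: an ordered stack of planar polygon
cross sections with axial stations, plus the area profile $A(z)$ and its
finite-difference derivatives.

## Geometry processing

Cross sections are simple, counter-clockwise polygons; `polygon_metrics()`
evaluates exact (shoelace-type) formulas for area, perimeter, centroid,
central second moments and the polar moment. The matched-ellipse aspect
ratio is $\beta = \sqrt{\lambda_1/\lambda_2}$ from the eigenvalues of the
central second-moment tensor; it is always reported $\ge 1$, and the
minor-to-major axis ratio quoted in accuracy rules is $1/\beta$. Section
frames are a reporting convention only — every resistance estimator here is
invariant under rigid motion of the section, and the tests assert this.

`build_duct()` interpolates $A(z)$ onto a uniform grid (cubic spline,
default spacing 0.7 µm, matching the sampling of segmented PVS stacks) and
differentiates by central differences, second-order one-sided at the ends —
exact for quadratic area profiles. Segmentation noise amplifies strongly in
$A''$, so an optional boxcar smoother (off by default, width recorded in the
object) can be applied before differentiation; how a given imaging pipeline
smooths its area function is not standardized, which is why smoothing here
is explicit rather than silent.

`circularize()` replaces every section with a circle of equal area on a
straight axis, separating size effects from shape effects. Circle and
ellipse polygons are *area-exact* (the vertex radius absorbs the inscribed
polygon's area deficit), so the circularized duct's area profile equals the
original's to machine precision rather than to $O(n^{-2})$.

## The SUN solver

No constrained-triangulation FEM stack is part of this package's dependency
footprint; instead the per-section Poisson problem is discretized by
boundary-corrected finite differences (Shortley–Weller) on a Cartesian grid:
interior nodes carry the five-point stencil, and nodes adjacent to the
boundary use the exact distances to the wall along grid lines. The scheme is
second order, and — because the stencil is exact for quadratics — it
reproduces the analytic velocity fields of circles and ellipses at the nodes
exactly; the remaining error is quadrature of $\int w\,\mathrm{d}A$.

The default grid spacing, $h = \min(2r_\mathrm{eq}/64,\ D_h/10)$, was fixed
by the circle benchmark: the computed resistance of a circular section must
sit within 0.5% of Hagen–Poiseuille, the same calibration criterion used for
the reference flow solvers in this field. At the default, the circle error
is ~5·10⁻⁵ % and ellipse errors at $\beta \le 3$ are below 0.005%;
`mesh_size` exposes the spacing, and the CLI logs the achieved circle error
for every run.

The shape-factor centre of method II is found by Nelder–Mead started at the
centroid ($\gamma \to \infty$ as the centre approaches the boundary, so the
problem is well-posed but multimodal for bi-lobed shapes); if the optimum
escapes the polygon, the search restarts from the best point of a coarse
interior grid. The boundary is resampled to $N = 100$ points at equal
arc-length spacing before evaluating $\gamma$ — the average is otherwise
biased by vertex density, and results are insensitive to $N$ beyond ~64.

## Extended lubrication theory and the λ correction

For an elliptical duct $(x/b(z))^2 + (y/c(z))^2 = 1$ the classical
(zeroth-order) lubrication resistance is
$\mathcal{R}_0 = 4\mu(b^2+c^2)/(\pi b^3 c^3)$, a purely local quantity. The
second-order term $\mathcal{R}_2$ (see `ellipse_R2()` for the full
expression) depends on the wall slope and curvature; the total is
$\mathcal{R}_0 + \mathcal{R}_2$. All formulas are implemented dimensionally
(primes are d/dz), so the formal aspect-ratio expansion parameter is
absorbed into the derivatives; this bookkeeping is validated by the analytic
error slope below. For self-similar cross sections
($\mathrm{d}\beta/\mathrm{d}z = 0$) the equivalent area form is
`fixed_beta_R2()`, and the two agree to 10⁻¹⁰ relative on random profiles —
this identity, together with exactness of methods III/IV on analytic ellipse
moments and a hand-derived linear-taper value
$-16\mu s^2/(3\pi r^4)$, forms the module's oracle suite.

The fractional error of the series-unidirectional (uniform-duct)
approximation predicted by ELT is, to leading order,
$\mathcal{E} \approx P(\beta)\, A''$ with
$P(\beta) = (\beta^4 + 14\beta^2 + 1)/(48\pi\beta(\beta^2+1))$: the second
derivative of the area dominates. $P$ is a weak function of shape:
$P(1) = 1/(6\pi)$, $P(\beta) = P(1/\beta)$, and $P$ stays within 13.3% of
$P(1)$ for $\beta < 7$ (13.33% on a 0.5-step grid, extremum 13.4% at
$\beta \approx 3.15$ under a continuous scan — `beta_prefactor_deviation()`
reports both, since the extremum falls between grid points).

The correction factor inverts an error line
$\mathrm{err}\% = \mathrm{slope}\cdot A'' + \mathrm{intercept}$ into
$\lambda = 100/(100 + \mathrm{err}\%)$, the unique multiplicative form
consistent with $\mathrm{err} = (\mathcal{R}_\mathrm{SU} -
\mathcal{R}_\mathrm{3D})/\mathcal{R}_\mathrm{3D}$. Three calibrations ship:
`"realistic"` (−1.8, −3.2) and `"circular"` (−4.4, 0.22), fitted error lines
for segmented murine pial PVSs and their circularized companions, and
`"analytic"` (−100/(6π) ≈ −5.3, 0), the pure ELT prediction for circular
ducts.

## The axisymmetric oracle

For circular ducts of varying radius the package carries its own ground
truth: the steady axisymmetric Stokes equations solved exactly via the
Stokes stream function, $E^2(E^2\psi) = 0$, on the boundary-fitted mapped
grid $(\zeta, \eta) = (z, r/R(z))$ — no meshing, exact wall conformity. The
fourth-order problem is split into the coupled second-order system
$E^2\psi = \phi$, $E^2\phi = 0$; boundary conditions are Poiseuille inflow
at the upstream end of a 40 µm uniform entrance extension (comfortably
beyond the creeping-flow entrance length $z_L \approx 0.5\,D_h$ for PVS-like
ducts), $\psi = \phi = 0$ on the axis, $\psi = Q/2\pi$ and no slip at the
wall, and fully developed outflow. Because $\phi = -r\,\omega_\theta$, the
pressure follows from first derivatives only:
$\partial p/\partial z = \mu\, r^{-1}\partial\phi/\partial r$ integrated
along the axis from the zero-pressure outlet, and
$\partial p/\partial r = -\mu\,\partial(\phi/r)/\partial z$ outward along
each column. Post-processing mirrors standard 3D practice: volume-weighted
average pressures in 2-µm slices, differenced between adjacent slices and
divided by $Q$; the last five stations are excluded from averages (exit
effects; the exclusion count is a parameter). The default grid (33 radial
nodes, 0.5 µm axial spacing) recovers Poiseuille to 0.34% and conserves flux
to 0.3%; halving the spacing moves the average resistance by well under 1%.

Default flow rate is $Q = 2.19\times 10^4$ µm³/s, a typical pial-PVS value;
resistance is $Q$-independent in Stokes flow and a test asserts this.

## Synthetic ducts

Three generators stand in for segmented imaging data:

* `make_sinusoidal_duct()` — the benchmark duct
  $r = 50 + 1.5\sin(2\pi z/50)$ µm; the default length, 100 µm, spans two
  full wavelengths so that axial statistics cover whole periods.
* `make_elliptical_duct()` — arbitrary $b(z)$, $c(z)$ with analytic
  derivative callbacks, the ELT cross-check geometry.
* `make_bilobed_duct()` — a single-lobe incomplete annulus hugging a
  circular vessel, emulating the structure of murine pial PVS lobes:
  sections ~0.7 µm apart, mean area rescaled to exactly 100 µm², and
  matched-ellipse $\beta$ emerging in ≈1.35–1.7 for the default vessel
  radius (8 µm), lobe thickness (8 µm) and angular span (drawn once per seed
  from 0.8–1.1 rad). One integer seed controls all randomness; identical
  seeds give identical ducts.

What the generators do **not** emulate: segmentation noise and pixelated
boundaries, azimuthally localized bulges, centerline curvature (generated
centerlines are straight; `dean_number()` quantifies why curvature is
negligible at $De \sim 10^{-4}$), and axial *shape* change at fixed area.
Tests passing on these ducts therefore validate the estimators'
mathematics, not any claim about a particular animal's geometry.

## Validity limits worth knowing

The ELT error model — and the $\lambda$ correction built on its slope — is
an expansion for ducts that vary *slowly* along their length. An independent
check of the axisymmetric solver makes the limit quantitative: for a
sinusoidal tube of mean radius $r_0$ and wavenumber $k$, the linearized
Stokes problem has an exact Bessel-function solution, and the true
error-versus-$A''$ slope falls from $-100/(6\pi) \approx -5.3$ as
$kr_0 \to 0$ to about $-3.5$ at $kr_0 = 2\pi$. The 50 µm-radius, 50
µm-wavelength benchmark duct sits at exactly $kr_0 = 2\pi$, so there the
full Stokes solution genuinely departs from the ELT slope (the package's
solver converges to ≈ −3.7..−3.9 for that duct, bracketing the exact −3.53
small-amplitude value), and the analytic $\lambda$ overcorrects — reducing
the RMS deviation from the oracle by just under half rather than by more
than half. Murine pial PVSs ($r \approx 6$ µm, variation scales of tens of
µm, $kr \lesssim 1$) are well inside the regime where the −5.3 slope and the
fitted correction factors apply. For ducts whose $|A''| > 2$, expect
series-unidirectional errors beyond ~15% and apply a correction; for very
oblong sections ($1/\beta < 0.7$) prefer SUN over method II.

Other known limitations: the oracle covers circular ducts only (that is its
role — non-circular ducts go through SUN/ELT); transient or pulsatile flow
is out of scope (resistance at low Womersley number equals the steady
value); and porous (tissue-filled) PVSs are a different physical regime not
modelled here.

## Problem sizes used in the shipped checks

The test suite builds all fixtures in code: section polygons of 100–256
vertices, SUN grids of a few thousand nodes, oracle grids of roughly
280 × 33 nodes, Monte-Carlo moment checks at 2·10⁵–10⁶ samples, and ducts of
6–150 sections. These sizes were chosen so the whole suite settles in tens
of seconds while leaving each check's margin (0.5% solver calibration, 10⁻¹⁰
algebraic identities, 0.5% flux conservation) far from its tolerance.
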