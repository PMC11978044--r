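---
title: "Methods: stenosed-artery hemodynamics with a Williamson fluid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stenosed-artery hemodynamics with a Williamson fluid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(stenoflow)
```

This vignette documents the model, the numerical method, the parameter
choices and the limits of what the package's tests demonstrate. It states no
empirical result that the test suite and `scripts/acceptance.R` do not
themselves compute.

## Physical model and assumptions

The package simulates steady, laminar, incompressible flow of blood through
an idealized arterial segment of length $L$ and base radius $R_0$, optionally
narrowed by a smooth axisymmetric stenosis and optionally of elliptic
cross-section. Blood is treated as a generalized-Newtonian fluid with the
Williamson apparent viscosity

$$\mu(\dot\gamma) = \mu_\infty + \frac{\mu_0 - \mu_\infty}{1 + \lambda\dot\gamma},$$

which captures shear-thinning between a zero-shear plateau $\mu_0$ and an
infinite-shear plateau $\mu_\infty$ with time constant $\lambda$. The shear
rate is the standard second invariant
$\dot\gamma = \sqrt{\tfrac12\,\gamma:\gamma}$ with
$\gamma_{ij} = \partial_j u_i + \partial_i u_j$; an alternative linear
stress closure $\delta_{ij} = \eta_0(1+\Gamma\dot\gamma)\gamma_{ij}$ is
exposed as `extra_stress_tensor()` for completeness. The two closures carry
independent parameters ($\lambda$ vs. $\Gamma$): no relation between them is
assumed, and the momentum solver uses the rational viscosity law, which is
the form consistent with writing the diffusion term as
$\nabla\cdot(\mu(\dot\gamma)\nabla \mathbf u)$.

The momentum equations carry no time derivative: the solver is steady (with
optional pseudo-transient continuation, `dt_pseudo`). Flow in small arteries
at the Reynolds numbers of interest (throat Reynolds up to a few hundred)
admits steady laminar solutions; pulsatility is out of scope.

Temperature is one-way coupled: the converged velocity field advects a
dimensionless temperature $\theta = (T - T_i)/(T_b - T_i)$, conduction
diffuses it, and viscous dissipation acts as a source. In dimensionless form
the diffusivity is $1/(\mathrm{Re}\,\mathrm{Pr})$ and the dissipation
coefficient $\mathrm{Br}/(\mathrm{Re}\,\mathrm{Pr})$. One-way coupling is
the consistent choice because the viscosity law is not
temperature-dependent; it also means the velocity field cannot respond to
Pr or Br. Sweeps over these groups are therefore *temperature-field*
responses (boundary-layer steepening with Pr, dissipation heating scaling
with Br), which is what the governing equations imply.

### Dimensionless groups

`dimensionless_groups()` computes
$\mathrm{Re} = \rho u_0 L/\mu_0$,
$\mathrm{Pr} = c_p \mu_0 / k$,
$\mathrm{Br} = \mu_0 u_0^2 / (k\,(T_b - T_i))$ and
$\beta = k/(\rho c_p)$, with the identity
$\mathrm{Re}\,\mathrm{Pr} = u_0 L/\beta$ holding by construction (tested).
Br is the standard Brinkman number: it is the only form for which the
$\mathrm{Br}/(\mathrm{Re}\,\mathrm{Pr})$ dissipation coefficient of the
dimensionless energy equation is dimensionless, so it is the form the
package uses.

## Geometry and the synthetic cases

The stenosis is a cosine bump: for degree $s$ (fractional diameter
reduction), window length $L_s$ and throat position $z_c$,

$$r(z) = R_0 - \frac{s R_0}{2}\Big(1 + \cos\frac{2\pi (z - z_c)}{L_s}\Big),
\qquad |z - z_c| \le L_s/2,$$

smooth ($C^1$), symmetric, and equal to $R_0(1-s)$ at the throat. The cosine
bump is the standard idealization in stenosis CFD; the profile family is a
tagged field of `stenosis_spec()` so other families can be added.

Elliptic cross-sections preserve area: at axis ratio $\kappa$ the semi-axes
are $a = r(z)/\sqrt\kappa$, $b = r(z)\sqrt\kappa$, so $\pi a b = \pi r^2$
exactly for every $\kappa$ (tested to machine precision). Comparing circular
and elliptic lumens at equal area isolates the effect of shape on otherwise
identical flow rates; the alternative (equal axis) convention would conflate
shape with severity.

The four canonical cases (`make_case`) are the healthy vessel and 40/60/80%
diameter reductions. **All numeric defaults are fixtures chosen once as
physiologically typical, not values taken from any particular dataset**:
$R_0 = 2$ mm, $L = 20$ mm $= 10R_0$, $L_s = L/5$, $z_c = L/2$; blood-like
$\rho = 1060$ kg/m³, $\mu_0 = 0.056$ Pa·s, $\mu_\infty = 0.00345$ Pa·s,
$\lambda = 3.313$ s (widely used shear-thinning constants for whole blood),
$k = 0.52$ W/m/K, $c_p = 3617$ J/kg/K, inlet mean speed $u_0 = 0.02$ m/s
(inlet Reynolds on the diameter $\approx 23$ at the high-shear viscosity,
throat Reynolds $\approx 115$ at 80% stenosis — squarely laminar), heated
wall $\theta_w = 1$ with $T_i = 310$ K, $T_b = 313$ K. Every case run echoes
its resolved parameters to YAML.

## Discretization

Staggered (MAC) finite volumes: velocity components on faces, pressure and
temperature at cell centres. Convection is first-order upwind by default
(`scheme = "central"` is available); diffusion is central with
face-interpolated viscosity.

Two grid engines:

* **Axisymmetric cylindrical `(r, z)`** with metric weight $w = r$; the axis
  is a symmetry boundary (the radial face area vanishes there, so the
  discrete operator needs no special casing). The lumen wall is a
  *stair-step mask* on the tensor-product grid: a cell is fluid when its
  centre lies inside $r(z)$. Wall-adjacent diffusion uses half-cell
  distances with the metric weight at the wall face. A body-fitted radial
  mapping was considered and rejected: metric terms break the exact
  telescoping of mass through cross-sections, which the masked orthogonal
  staggered scheme gives for free — the per-section flow-rate deviation in
  the converged canonical cases is at machine precision (the
  pressure-correction equation is solved by a direct sparse factorization,
  so each outer iteration projects the velocity onto the exactly
  divergence-free subspace). The price is a stair-step wall, acceptable
  because the acceptance checks on stenosed geometry are integral and
  monotonicity properties, and the wall-resolution error can be measured on
  the straight tube where the mask is exact.
* **Masked-cell Cartesian 3D** for elliptic lumens: a bounding box with an
  ellipse-containment mask per axial station. Diffusion of the axial
  velocity toward a masked wall uses the *true distance to the elliptic
  boundary along the grid axis* (a sharp immersed-boundary treatment,
  clamped to $[0.2h, h]$), which is what brings the straight elliptic duct
  within about 1% $L_\infty$ of the analytic paraboloid at $48^2\times 96$
  despite the stair-step mask.

In the planar 2D mode (used for the Couette verification) the same engine
runs with $w = 1$ and walls on both transverse boundaries; a moving lid can
be prescribed for the wall-shear evaluation (`field$wall_uz`).

Boundary conditions: parabolic fully developed inlet profile, rescaled so
the *discrete* area-weighted mean equals the nominal $u_0$ exactly; no-slip
walls (exact zeros on wall faces); zero gauge pressure and zero-gradient
velocity at the outlet (the outlet face velocities are solved with a
downstream ghost pressure of zero, which anchors the pressure level and
closes the global mass balance); symmetry on the axis.

## Pressure–velocity coupling and solver controls

SIMPLE-type outer iterations with SIMPLEC (consistent) correction
coefficients, which tolerate a pressure under-relaxation of 1:

1. recompute $\dot\gamma$ and $\mu$ (under-relaxed by `alpha_mu`, default
   0.15 — direct substitution of an apparent viscosity that varies by an
   order of magnitude across the post-stenotic shear layer limit-cycles);
2. solve the under-relaxed momentum equations (`alpha_u`, default 0.9;
   direct sparse LU in 2D, red-black Gauss–Seidel sweeps in 3D);
3. solve the pressure correction (2D: cached-pattern Cholesky
   factorization, exact; 3D: Jacobi-preconditioned conjugate gradients to a
   relative tolerance `cg_tol`) and correct velocities and pressure.

The transpose/extra viscous-stress terms of the full variable-viscosity
stress divergence are applied as an explicit deferred correction
(`stress_form = "full"`, the default), under-relaxed by `alpha_s` (default
0.3) across outer iterations; plain lagging of these terms limit-cycles in
strongly sheared stenosed cases. They vanish identically for constant
viscosity and for fully developed pipe flow, which is why the verification
errors are unaffected by the switch. The 3D engine implements the implicit
$\nabla\cdot(\mu\nabla\mathbf u)$ form only (its verification case is
Newtonian, where the forms coincide).

Convergence is declared when the scaled momentum residual (L1, normalized
by $\sum |a_P u_P|$) falls below `tol_mom` (default $10^{-6}$) and the
scaled continuity residual below `tol_cont` (default $10^{-9}$; in 2D it
sits at round-off, about $10^{-14}$, after every outer iteration because the
pressure solve is direct). Non-convergence is reported, never thrown:
`solve_steady` returns `converged = FALSE` and `run_case` flags a nonzero
status.

Determinism: zero-velocity/uniform-pressure initial fields in 2D; in 3D the
axial velocity is initialized by replicating the inlet profile (still fully
deterministic), which cuts the outer-iteration count several-fold on large
grids. No randomness exists anywhere in the pipeline; reruns are bitwise
identical (tested).

## Temperature solver

Cell-centred upwind advection–diffusion, assembled sparse and solved
directly in 2D (the problem is linear given the flow); Gauss–Seidel sweeps
in 3D. With the dissipation off, upwinding gives the discrete maximum
principle (tested). The dissipation function is implemented in the grouping
of the governing energy equation as published (`form = "printed"`), which in
the axisymmetric reduction omits the hoop term $2(u_r/r)^2$; the standard
full dissipation function is available as `form = "standard"`. Both are
pointwise non-negative (tested). For plane Couette flow the two coincide,
so the closed-form verification discriminates the transport solver, not the
grouping choice.

## Verification battery and what it shows

* **Hagen–Poiseuille** (Newtonian straight tube, 64×256): centerline
  velocity within 1% of $2U$ and pressure drop within 1% of
  $8\mu L U/R_0^2$ (measured ≈ 0.15% and 0.02%).
* **Elliptic duct** (Newtonian, $\kappa = 0.5$, 48×48×96): $L_\infty$ error
  vs. $2U(1 - x^2/a^2 - y^2/b^2)$ below 5% (measured ≈ 0.8%).
* **Williamson pipe flow** vs. an *independent* one-dimensional oracle:
  pointwise $\tau$–$\dot\gamma$ root-finding plus radial quadrature at the
  same discrete flow rate; profile agreement within 2% (measured ≈ 0.4%),
  and the centerline-to-mean ratio below the Newtonian 2 (shear-thinning
  flattening).
* **Conservation**: per-section and global flow-rate errors at machine
  precision on all four canonical cases (the staggered masked scheme
  telescopes mass exactly).
* **Severity monotonicity**: pressure drop and peak velocity strictly
  increasing across degrees {0, 0.4, 0.6, 0.8}; throat mean velocity equals
  the inlet mean times the discrete area ratio.
* **Couette dissipation**: mid-gap $\theta$ within 1% of
  $\mathrm{Br}/8$ (measured ≈ 0.2%).
* **Grid independence**: on the straight-tube oracle case the QoI error
  falls monotonically under refinement halves with < 1% change between the
  two finest grids — the package's re-realization of a mesh-independence
  test.

What passing these does *not* show: accuracy of the stair-step wall in the
stenotic window beyond integral quantities; transition or unsteady effects
(the solver is steady; a real 80% stenosis can shed vortices); elastic or
moving walls; pulsatile inflow; nanoparticle transport (no such transport
equation is part of the model — the Brinkman group is a dissipation group,
not particle physics); and patient-specific geometry. Figure-level numeric
values from idealized-stenosis studies in the literature are generally not
reproducible without their (unreported) fluid properties and Reynolds
numbers; the package therefore verifies against analytic and quadrature
oracles and reproduces the *qualitative* severity trends as testable
monotonicity properties.

## Numerical choices, degenerate inputs, tie-breaks

* Problem sizes in the tests (24–64 radial cells in 2D, $48^2\times96$ in
  3D, canonical cases at 32×96) are the package's documented study sizes:
  small enough to iterate on, large enough that every oracle check passes
  with an order-of-magnitude margin.
* Resolution refusal: a grid that would put fewer than 3 cells across the
  throat radius is refused with a clear message rather than solved badly.
* The SIMPLEC denominator $a_P/\alpha_u - \sum a_{nb}$ is clamped below by
  $0.02\,a_P/\alpha_u$: the net-mass-imbalance term can push it negative
  while unconverged, which would break the SPD pressure operator.
* Outlet backflow is clamped out of the convective outlet coefficient
  (first-order outflow), the standard guard for zero-gradient outlets.
* Centerline values are extrapolated to $r = 0$ with the parabola through
  the first two cell rows, $(9u_1 - u_2)/8$, second-order for even
  profiles; inlet/outlet plane pressures are linear extrapolations of the
  two adjacent cell columns (exact for linear pressure).
* Cell Reynolds number uses the geometric mean of the local spacings as the
  length scale — an isotropic measure on anisotropic grids — and the local
  apparent viscosity; it is non-negative by definition.
* `Cp` uses the outlet mean pressure and the inlet mean speed as
  references: the only two scales the problem defines; `Cp` at the outlet
  section is zero by construction.

## Known limitations

Steady-state only; first-order upwind convection (numerical diffusion at
higher Re — the central option exists but is not the default); stair-step
walls in the axisymmetric stenotic window; the 3D engine's gradient-form
diffusion; one-way thermal coupling; Newtonian-wall (rigid, impermeable)
assumptions throughout. These match the scope of idealized-stenosis CFD
studies rather than patient-specific simulation.
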