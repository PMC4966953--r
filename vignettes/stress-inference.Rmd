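---
title: "Inferring cortical shear stress from cytoplasmic streaming"
author: "streamstress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring cortical shear stress from cytoplasmic streaming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streamstress)
```

## The problem

Cytoplasmic streaming is a cell-wide circulation of the cytoplasm driven
by force generators at the cell cortex: actomyosin flows in the
C. elegans zygote, the Arp2/3-nucleated actin cap in the mouse oocyte at
meiosis II. The force generators exert a tangential (shear) stress on the
adjacent fluid, and because the cytoplasm is hydrodynamically coupled, a
stress applied in one place moves material everywhere. The inverse
problem this package addresses: given a measured intracellular velocity
field, where along the cortex is stress applied, and how strongly?

The forward physics is creeping flow. Reynolds numbers for streaming are
of order 1e-12, so inertia is negligible and the cytoplasm is treated as
an incompressible Newtonian fluid (Stokes equations). Streaming in both
cell types is axisymmetric about the axis through the two poles of the
circulation, which we call the *source* pole (cortical stress points away
from it) and the *drain* pole (stress converges into it). All quantities
are non-dimensionalised: viscosity and the cell short radius are 1, and
stresses convert back to physical units via
$\tau_{phys} = \tau^{*}\,\mu V/L$.

## Forward model: stream function-vorticity solver

In cylindrical coordinates $(z, r)$ with axial symmetry, incompressibility
is built in by the Stokes stream function $\Psi$
($v_z = \Psi_r / r$, $v_r = -\Psi_z / r$), and the Stokes equations
reduce to a coupled pair for $\Psi$ and the azimuthal vorticity
$\Omega = \partial v_r/\partial z - \partial v_z/\partial r$:
a vorticity transport equation ($E^2$-type operator applied to $\Omega$
equal to zero) and a Poisson equation linking $\Psi$ to $\Omega$. The cell
interior maps onto a rectangle with the boundary-fitted coordinates
$(z, s)$, $s = r/F(z)$, where $F(z)$ is the cell outline — a unit sphere
for the mouse oocyte, a capsule (cylinder of radius 1 with hemispherical
caps, total length 55/13) for the C. elegans embryo. The metric terms
$S_r = 1/F$, $S_z = -(s/F)F'$, $S_{zz} = (s/F)(2F'^2/F - F'')$ carry the
coordinate change.

Boundary conditions: $\Psi = \Omega = 0$ on the symmetry axis and at the
poles; $\Psi = 0$ on the cell surface (no penetration); and at the surface
the applied cortical stress enters through the wall vorticity,
$$\Omega_{wall} = \tau/\mu + 2\,v_t/R,$$
where $v_t$ is the tangential slip speed (positive from source towards
drain, like $\tau$) and $R$ the meridional curvature radius ($\infty$ on
the capsule cylinder). The sign convention is fixed by the analytic
interior-squirmer solution: on the unit sphere the stress profile
$\tau_0(z) = 3(1-z^2)^{1/2}$ and slip $u_0(z) = (1-z^2)^{1/2}$ satisfy
$\Omega_{wall} = 5(1-z^2)^{1/2} = \tau_0/\mu + 2u_0/R$, which the solver
reproduces; with the opposite sign on the $\tau$ term no consistent set of
orientations for $\Omega$, $v_t$ and $\tau$ exists for this solution.

Numerics (see `solve_stokes()`): second-order central differences for all
interior derivatives, including the mixed $\partial^2/\partial s\,
\partial z$ term. The vorticity equation is marched to steady state with
explicit Euler pseudo-time steps, with the step set by a diffusive
stability bound (safety factor 0.2 times the inverse of the largest
stencil diagonal; the iteration is stable up to a factor near 1, and
validation runs on refined grids use 0.8 to converge faster). Each outer
iteration interleaves one Euler step, one successive over-relaxation sweep
of the Poisson equation (relaxation factor 1.7), and a Thom-type refresh
of the wall vorticity from a second-order one-sided normal derivative of
$\Psi$ (under-relaxed by 0.7 for stability of the slip coupling).
Convergence requires the largest update of *both* fields in an outer
iteration to fall below 1e-7 (non-dimensional). Exact poles are excluded
from the stencil: the pole columns collapse to single physical points and
carry Dirichlet zeros. Near the axis, $\Psi$ is even in $r$ with
$\Psi = O(r^2)$, and the first off-axis row of the velocity
reconstruction uses the exact two-term even fit
$\Psi \approx a s^2 + b s^4$ — a centred difference there has an $O(1)$
relative error that otherwise contaminates everything downstream that
differentiates the velocities.

On the 25 x 13 grid used for the sphere (grid counts are interval counts;
the capsule uses 56 x 14), the benchmark stress-to-slip amplitude ratio is
recovered as 3.12 (analytic value 3, i.e. about 4% discretisation error,
shrinking to 1% at 50 x 26), and the interior field matches the
closed-form squirmer solution to about 1% at 50 x 26.

## Stress parametrisation

The cortical stress profile $\tau(z)$ is a clamped cubic B-spline whose
free de Boor control points $\Theta = (\tau_1,\dots,\tau_7)$ are the
parameters. The ends are pinned at zero — stress must vanish at the
poles, where "tangential" loses meaning — by a single zero control point
at each end on a knot vector with multiplicity 4 at the poles. We chose
this over additionally zeroing the neighbouring control points because
the latter forces $\tau'(\pm R) = 0$, which makes pole-steep profiles
such as the benchmark $3(1-z^2)^{1/2}$ (vertical tangent at the poles)
unrepresentable: its least-squares fit then deviates by 44% of the peak
and oscillates. With the value-only clamp the same fit deviates by at
most 9% of peak (5% with the optional poleward-clustered `"sine"` knot
spacing) and is accurate to under 1% at the seven node positions
(Greville abscissae). Because the parameters are control points, all
$\tau_i \ge 0$ guarantees $\tau(z) \ge 0$ by the convex-hull property —
this is the positivity restriction that encodes "stress acts from source
towards drain everywhere", and it is what makes truncated-positive
sampling of $\Theta$ meaningful.

Interior knots are uniform by default; nothing in the estimation depends
on that choice beyond representability, and it is configurable per cell.

## Estimating the stress: sampling-based data assimilation

Given observations $Y = \{(v^i_{z,exp}, v^i_{r,exp})\}$ at $N$ interior
points, Bayes' rule gives $p(\Theta|Y) \propto p(Y|\Theta)\,p(\Theta)$.
The prior is a product of independent Gaussians truncated to positive
values, common sd 0.75. Prior means: for the sphere (mouse-style), 2.5 at
nodes within the source-proximal third of the axis (the actin-cap region)
and 0.5 elsewhere; for the capsule (C. elegans-style), a least-squares
match of the spline to the cortical velocity profile scaled by 3 (the
sphere stress-to-slip ratio) — a reproducible stand-in for fitting the
profile by eye.

The likelihood at each candidate $\Theta$ compares the simulated
velocities at the observation points (bilinear interpolation in $(z,s)$)
with the data under an i.i.d. bivariate Gaussian whose covariance is the
maximum-likelihood plug-in (the empirical residual second moments
$\hat\sigma_z^2$, $\hat\sigma_r^2$, $\hat\sigma_{zr}$), giving
$\log p(Y|\Theta) = -N(1+\log 2\pi) - (N/2)\log\det\hat\Sigma$. A perfect
fit makes the plug-in density improper, so $\det\hat\Sigma$ is floored at
1e-24 and flagged. The estimate is the posterior-weighted mean of the
$M = 100$ samples with the highest likelihood (weights
$\propto \exp(\ell_i - \max\ell)$, ties broken by sample index), and the
procedure runs twice, re-centring the prior on the round-1 estimate.

Two design choices deserve comment.

**Superposition forward model.** Stokes flow is linear in the boundary
stress, including the slip term of the wall condition, so the flow for
any $\Theta$ is $\sum_i \theta_i \times$ (flow of basis spline $i$). The
package solves the 7 basis problems once per grid and scores an arbitrary
number of prior samples by matrix products; a per-sample direct-solve
path (`forward = "direct"`, memoised) is retained and tested to agree.
This makes the full 120,000-sample budget run in seconds on one core,
where solving every sample separately would demand massive parallelism —
and means no scaled-down sample budget is needed for testing.

**Proposal width of the refinement round.** The plug-in likelihood is
extremely peaked: its log scales like $-2N\log\|\text{residual}\|$, so
with clean data the top-$M$ weights collapse onto one or two samples and
each round's precision is essentially the distance from the best draw to
the optimum, which scales with the proposal sd (and only as
$n^{-1/7}$ with the sample count). Re-running round 2 at the full prior
width therefore re-explores instead of refining. The refinement rounds
shrink the proposal sd by a factor of 0.5 per round
(`round_sd_factor`; 1 restores flat reuse). With the full 120,000-sample
budget, two rounds recover the benchmark profile to within 5% of its peak
at all seven nodes.

## Pressure reconstruction

For comparing how stress placement shapes the intracellular pressure
field, the total stress is normalised to 1.5 (surface integral
$\int \tau\,dA$; an axial line-integral variant is available since
"total" admits either reading) and the converged flow is integrated to a
pressure: $\nabla p = \mu \nabla^2 u$, taken from the drain pole (the
reference $p = 0$) first along the axis and then radially. The
$-u_r/r^2$ term of the axisymmetric vector Laplacian is included — the
radial momentum balance is sometimes quoted without it, but dropping it
leaves a gradient field with non-zero curl whose line integral is
path-dependent, and the loop-closure error then fails to vanish under
refinement.

By default the gradient is evaluated through the vorticity identity
$\mu\nabla^2 u = -\mu\nabla\times\Omega$ (so
$\partial p/\partial z = -\mu(\Omega_r + \Omega/r)$,
$\partial p/\partial r = \mu\,\Omega_z$): it differentiates the solver's
vorticity once instead of the reconstructed velocity twice. On the
analytic benchmark the axial gradient is a constant $-10\mu u_0$; the
vorticity form reproduces $-9.8$ at 25 x 13, while the velocity form —
retained as `method = "velocity"` with first-order (one-sided) or centred
differencing — misses by over 20% on the same grid and its path-closure
residual grows rather than shrinks with refinement. The closure metric
itself (axis-first vs radial-first integration routes) is evaluated over
interior nodes with $|z| \le 0.8\,R$: on curved caps $F' \to \infty$ at
the poles, the pole-adjacent truncation error is self-similar under
refinement, and inside the retained region the residual converges as
$O(h^2)$ (about 0.07% of the pressure range at 25 x 13).

The "gradient at the source end" is the least-squares slope of the axial
pressure over the last 10% of the axis (at least 3 grid points). With
total stress fixed, a source-concentrated profile produces a strictly
steeper source gradient than a broad one in both the sphere and the
capsule — the hydrodynamic reading of why a tightly focused cap is good
at holding a spindle against the cortex. Group comparisons use Welch's
t-test.

## PIV

The image-side pipeline measures the observations the inference consumes.
Pixel-level motion between stacks maximises the windowed cross-correlation
in three passes (windows 33 x 33 x 1, 29 x 29 x 1, 25 x 25 x 1; search
ranges (±5, ±5, 0), (±2, ±2, ±1), (±1, ±1, 0) — the axial range is kept
small because the axial voxel, 1.0 um, is about four times the lateral
0.26 um). Ties break towards the smallest shift, then lexicographically.
Sub-pixel refinement solves the gradient (optical-flow) normal equations
over the aligned window, with central spatial differences and the
two-frame temporal difference $f_t = I_1 - I_2$; systems with condition
number above 1e8 (the aperture problem) have their unresolved components
zeroed and flagged. Displacements convert to um/s through the per-axis
voxel size and the frame interval. Interrogation centres sit on a regular
grid spaced at half the final window; windows that would leave the volume
are skipped, and invalid vectors are flagged, never interpolated. Fields
from consecutive frame pairs can be averaged componentwise (invalid
vectors excluded per position), the standard way to use a 50-minute
quasi-stationary recording as one field per cell.

## Synthetic data: what it does and does not emulate

All tests run on synthetic data built by the package itself:

- `synth_observations()` forward-solves a known stress profile and samples
  velocities at stratified-random interior positions (uniform strata over
  the $(z,s)$ rectangle, so every axial station is covered; a random sign
  on $r$ emulates the two image half-planes), adding i.i.d. Gaussian noise
  of a chosen fraction of the peak speed — 5% is the default working
  noise level, chosen as typical of PIV on yolk-granule texture.
- `synth_particle_stacks()` renders Gaussian particles (psf sd 0.5 um)
  advected by a known flow on the anisotropic voxel grid, for end-to-end
  PIV tests.
- `synth_cells()` builds species-style cohorts: capsule cells with broad,
  slightly source-shifted stress profiles at C. elegans scales (10 Poise,
  short radius 15 um, 1 non-dimensional velocity unit = 0.1 um/s), or
  sphere cells with source-concentrated profiles at mouse scales
  (1 Poise, 35 um, 1 nm/s). Observation tables are stored in measured
  units (um/s) and non-dimensionalised inside the inference, so estimated
  amplitudes convert to physical stress via $\tau^*\mu V/L$ — of order
  0.01 pN/um^2 for the C. elegans conditions.

What passing on these fixtures shows: the solver, the estimator, the unit
chain and the pressure analysis are internally consistent and match the
closed-form cases. What it does not show: robustness to the ways real
microscopy violates the model — correlated PIV errors, imperfect
axisymmetry, boundary-segmentation error, cytoplasmic elasticity or
active stresses in the bulk, and viscosity uncertainty (which rescales
all physical stresses proportionally).

## Numerical choices and limitations

Problem sizes in the tests mirror the study grids (25 x 13 sphere,
56 x 14 capsule), with 2x-refined runs (50 x 26) for convergence checks;
the refinement studies stop there because the explicit pseudo-time step
shrinks like $h^3$ near curved poles. Degenerate inputs are handled
explicitly: zero-variance interrogation windows, rank-deficient residual
covariances, zero-total stress normalisation and unconverged flows are
errors or flags, never silent. Tie-breaking is deterministic everywhere
(correlation peaks by smallest shift then lexicographic order; top-M
selection by sample index), and every stochastic routine takes a seed and
restores the caller's RNG state, so identical configurations are
bit-reproducible.

Known limitations: idealised outlines only (sphere, capsule), with
measured points remapped onto them by `rescale_axial()`/`fit_radial()`;
meridional curvature is used in the wall condition (exact for these two
shapes, an approximation for general outlines); the estimator reports no
posterior spread beyond the top-M scatter; and absolute physical stresses
inherit the full uncertainty of the assumed cytoplasmic viscosity.
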