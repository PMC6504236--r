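---
title: "Curvature-guided filament translocation on membranes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curvature-guided filament translocation on membranes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrebdyn)
```

This vignette is the package's account of its science: the two models it
implements, the assumptions behind them, the numerical choices, what the
synthetic dynamics do and do not emulate about real cells, and the known
limitations. Short, disconnected MreB filaments bind bacterial membranes,
orient along directions of largest principal curvature, and translocate
processively along that orientation; the package asks what binding
energetics and translocation statistics this implies for filament
localization in differently shaped cells.

## The binding model

A filament is a curved, cylindrical, linear-elastic rod (cross-sectional
radius $r_f$, Young's modulus $Y$, intrinsic curvature $\kappa_s$, length
$L_f$) that binds flat along one face. Deforming its centerline curvature
from $\kappa_s$ to $\kappa$ costs
$E_\mathrm{bend} = (\pi Y r_f^4/8)\int (\kappa - \kappa_s)^2\,d\ell$.
The membrane is a fluid, isotropic bilayer with the Helfrich energy
(bending rigidity $k_b$, saddle-splay modulus $k_t$, spontaneous curvature
$H_s = 0$, surface tension $\gamma = 0$ on the assumption that lipids are
freely recruited, pressure difference $p$). Small deformations are treated
in the Monge gauge, $h(x,y)$, where mechanical equilibrium is the
biharmonic shape equation $\Delta^2 h = p/k_b$ with Dirichlet data. The
solver splits it into two Poisson problems — first $\Delta m = p/k_b$ for
the mean-curvature field $m = \Delta h$, then $\Delta h = m$ — each solved
with P1 finite elements on a triangulated patch; this split is validated
against the uniformly loaded disk ($h(0) = 3qa^4/64$) and the Navier
double-sine series on the unit square, both to better than 0.5%.

**Coupling and the pressure term.** For a filament at angle $\theta$ from
the axis of a cylinder of radius $R_\mathrm{cell}$, the substrate's normal
curvature along the filament is $\sin^2\!\theta/R_\mathrm{cell}$ (Euler's
formula). Any excess filament curvature
$\delta = \kappa - \sin^2\!\theta/R_\mathrm{cell} \ge 0$ must be
accommodated by an inward membrane deformation. We impose the filament's
parabolic height profile and longitudinal curvature as Dirichlet data along
a straight footprint of length $L_f$ on the patch (far field $h = m = 0$ at
2.5 $L_f$), solve the homogeneous biharmonic problem, and charge the
membrane the bending energy of that solution plus the pressure work
$p\int h\,dA$ on the displaced volume. A literal bulk load $p/k_b$ on a
free patch with zero far-field data was rejected: with $\gamma = 0$ nothing
balances turgor in the Monge patch, so that formulation produces an
unphysical, patch-size-divergent background bulge that destroys the
linearization at physiological pressures. With the displaced-volume
treatment both membrane terms are exactly quadratic/linear in $\delta$, so
the optimal filament curvature is closed-form and the whole
$\Delta G(\theta)$ scan costs one finite-element solve. The saddle-splay
term integrates to a boundary constant at this order and cancels from
free-energy differences.

**Parameters and units.** Energies are reported in $k_BT$ at 300 K;
pressures are accepted in atm. Defaults are literature-standard MreB-like
values, not fitted: $r_f = 3.5$ nm (half the ~7 nm width of an MreB double
protofilament), $Y = 2$ GPa, $\kappa_s = 5\ \mu m^{-1}$ (relaxed radius
200 nm, well above typical cell curvatures $1/R_\mathrm{cell} \le
2\ \mu m^{-1}$), $L_f = 250$ nm, $k_b = 20\,k_BT$, $p = 20$ atm. With
these, binding is predicted circumferential ($\theta^* = \pi/2$) with a
well depth far above $1\,k_BT$ (the robustness threshold we use for
"orientation robust to thermal fluctuations"), shallower in wider cells,
and insensitive to $p$ over 0.2–20 atm; the filament conforms to the
membrane at physiological pressure and grossly deforms it only when the
pressure difference nearly vanishes (the classifier compares the elastic
energy fractions against a 0.8 dominance threshold).

## The translocation model

The membrane is a parametric surface $r(u,v)$; by convention $u$ is
axial/longitudinal, $v$ circumferential (radians). A filament is a point
that hops a fixed on-surface distance $L$ per step along its orientation:
the largest principal direction $d$, rotated in the tangent plane by a
Gaussian angular deviation $\eta \sim N(0, \sigma^2)$. The heading is
converted to a parameter-space angle $\theta$ (the metric decomposition of
the rotated tangent), and the parameter-space step length $\ell$ solves the
arclength equation so the on-surface step is exactly $L$. The sign of $d$
is chosen for continuity with the previous heading, so a filament keeps its
handedness for its lifetime (no backtracking); an option redraws the sign
each step. At umbilic points ($\Delta c = \kappa_1 - \kappa_2$ below
$10^{-6}\ \mu m^{-1}$), where $d$ is undefined, steps take uniformly random
directions. Filaments activate with probability proportional to the area
element (optionally reweighted by a user function of the Gaussian
curvature) at rate $k$ per area per step, and deactivate with probability
$\lambda$ per step.

**Noise model.** By default $\sigma = \alpha/\Delta c$ with $\alpha =
0.6$ rad µm⁻¹, capped at $\sigma_\mathrm{max} = \pi$ (effectively isotropic
near umbilics, continuous with the uniform-angle rule); on a 0.5 µm-radius
cylinder this gives the characteristic $\sigma = 0.3$ rad. A constant-σ
model is available.

**Time base and processivity.** The dynamics is per step; one step is one
reorientation. The ~5 min persistence time of MreB filaments is mapped to a
mean lifetime in steps through a configurable translocation speed. The
default is 20 nm/s — the *E. coli* value, matching the organism context of
the persistence measurement — giving $1/\lambda = (300\,\mathrm{s} \times
20\,\mathrm{nm/s})/200\,\mathrm{nm} = 30$ steps. This choice matters: the
spherocylinder bulk/pole ratio grows from ~1.7 at 18-step lifetimes through
~2.0 at 30 steps to ~5.4 at infinite processivity, so users modeling
*B. subtilis* (~50 nm/s) should set $\lambda$ accordingly.

**Chart-degeneracy safeguards.** Straight parameter-space rays are the
faithful discrete flow, and they follow curvature lines exactly when the
heading is circumferential or meridional. But within about one step of a
coordinate pole of a surface of revolution the chart degenerates: an
oblique ray wraps around the pole and traps filaments circling it (on a
sphere this inflated the polar concentration eleven-fold). Two safeguards
restore the correct invariant measure, both exact on spheres: (i) umbilic
points with appreciable curvature step as great-circle arcs on their
osculating sphere — the uniform-angle rule means a straight arc *on the
surface*, and umbilic regions in this geometry family are exactly
(spherocylinder caps) or nearly (ellipsoid tips) spherical; (ii) oblique
rays launched where the angular-coordinate circle is shorter than 0.75 L
step on the nearest pole's osculating sphere. With these, the simulated
concentration on a sphere is uniform to Monte Carlo noise, and the
ellipsoid with $\sigma = 0$ keeps its exactly uniform steady state (the
flow then follows the circumferential curvature lines, which parameter
rays reproduce exactly).

## The continuum steady state

The ensemble steady state is also computed by a deterministic solve. The
discrete flow is a jump process in parameter coordinates; truncating its
Kramers–Moyal expansion at second order gives, for the filament number
density $n(u,v)$ per unit parameter area,
$$\partial_t n = -\partial_a(A^a n) + \tfrac12 \partial_a\partial_b(B^{ab} n)
  + k\sqrt{g} - \lambda n,$$
with $A$ and $B$ the first and second jump moments per step. Two points
were load-bearing in getting this right:

* **The Itô (moment) form is essential.** Position-dependent step
  statistics produce the retention flux $-\tfrac12\partial(Bn)$ that
  concentrates filaments where angular spreading is slow (oriented
  cylindrical bulks) and depletes fast-spreading umbilic caps. A Fickian
  $-D\nabla\rho$ discretization admits the uniform density as an exact
  steady state on the spherocylinder and misses the localization entirely.
* **Moments are computed exactly, per cell, by quadrature** over the noise
  angle (33 Gaussian nodes; 32 uniform angles at umbilics), using the same
  step kernel as the simulator — including the arclength equation and the
  pole safeguards. Closed-form small-step moments (drift
  $L e^{-\sigma^2/2}$, transverse second moment $L^2 E[\sin^2\eta]$) are
  exposed for reference but miss the metric-induced drift of the chart,
  which is a first-order effect near caps and tips.

The equation is discretized as a conservative finite-volume scheme on the
structured $(u,v)$ grid (upwinded advection from face-averaged drift;
central second differences of $B^{ab}n$, including the mixed term), with
the two chirality populations ($\pm d$) solved separately on half the
source each and summed. Discrete mass balance $kA = \lambda \int N_F$ holds
to solver precision by construction. For $\lambda = 0$ (infinite
processivity) the stationary transport density is obtained as the
vanishing-turnover limit: a uniform birth rate with mean lifetime $10^4$
steps, far beyond the mixing time of every shipped geometry, renormalized
to unit total — one sparse solve, unconditionally positive.

The Langevin simulator is the ground truth; the continuum solution is its
second-order approximation. On all eight reference geometries the
area-weighted $L^1$ discrepancy of the normalized concentrations stays
within three Monte Carlo standard errors at 3000 lifetimes; the worst case
is the spherocylinder (ratio ~1.8), where the 200 nm step is not small
against the 0.5 µm cap and the truncation bias is visible (the continuum
bulk/pole ratio runs ~10% above the simulated one).

## Geometries and their defaults

All surfaces carry analytic first and second partials; curvatures come
from the shape operator (first/second fundamental forms), signed with
respect to the inward normal so convex-outward regions are positive, and
central-difference cross-checks of the derivatives run in the test suite.
Quadrature grids align cell edges with curvature-discontinuity lines (the
spherocylinder seams, the bulge support) so Gauss–Bonnet integrals hit
$4\pi$/0 to 0.1%.

Dimension defaults emulate the study conditions: rod radius 0.5 µm with a
3 µm cylindrical body; torus tube 0.5 µm on a 5 µm centerline (the
donut-confined cell); prolate spheroid 0.5 × 0.5 × 1.5 µm; undulating
cylinder of mean radius 0.5 µm, amplitude 0.2 µm, wavelength 2 µm (short
against the 4 µm body, with mean and Gaussian curvature positively
correlated across the surface); elliptical cylinder 0.7 × 0.35 µm (zero
Gaussian curvature everywhere); helix tube 0.5 µm around a 1.5 µm-radius,
4 µm-pitch helix, parameterized in the Frenet frame of the centerline so
the metric is translation-invariant and axial periodic wrapping is exact.
Translation-invariant open geometries wrap periodically in $u$ to avoid
edge artifacts; the bent rod is a torus arc with reflecting ends (full
torus by default).

The bulged cylinder deserves its own note. The bump is a raised cosine
(amplitude 0.3 µm, half-width 0.5 µm on the 0.5 µm cylinder): compactly
supported with bounded edge curvature. An exponential compact bump
$e^{1-1/(1-t^2)}$ was rejected because its curvature spikes at the support
edge (tens of µm⁻²) live below the 200 nm step scale and dominated the
dynamics artifactually. The default width is chosen so the crest meridian
curvature ($A\pi^2/2w^2 = 2.3\ \mu m^{-1}$) exceeds the circumferential one
($1.25\ \mu m^{-1}$) — the defining feature of this geometry: trajectories
reorient parallel to the long axis inside the bulge. With it, the bulge
holds more filaments than its area share (37% vs 24% at infinite
processivity; 27% at the MreB-like 30-step lifetime). One qualitative
feature of the original study is *not* reproduced and appears unreachable
with an axisymmetric radial bump under $\sigma = \alpha/\Delta c$: a
concentration that correlates *positively* with Gaussian curvature. A
circumferential trap stronger than the host cylinder needs $\Delta c >
1/R$, and on a radial protrusion ($\rho \ge R$) a convex meridian caps
$\Delta c$ below $1/R$ — so strong traps force a concave meridian, i.e.
negative Gaussian curvature. Both the undulating and the bulged geometry
therefore enrich at negative $K$ here; the original bulge geometry is
specified only in material unavailable to this implementation, and the
dimensions are exposed as configuration parameters.

## Localization summaries

Region partitions follow the simplest reproducible definitions: the
spherocylinder splits at the geometric cap–cylinder seam (optional
exclusion band); torus bands are tube-angle windows of half-width 15°
about the inner equator ($\pm\pi$), the midlines ($\pm\pi/2$) and the
outer equator; the bulge region is the bump support. Enrichment ratios are
ratios of area-weighted mean concentrations, invariant to rescaling.
Curvature–enrichment curves bin cells by $H$ or $K$ (25 equal-width bins
by default, area-weighted means) and normalize the anchor bin
($H = 1\ \mu m^{-1}$ or $K = 0\ \mu m^{-2}$) to exactly 1 a.u.

Per-hoop axial displacements split each cylinder trajectory at every
accumulated $2\pi R$ of unsigned circumferential arclength (partial final
hoops discarded; crossing positions linearly interpolated within a step)
and record the signed net axial displacement per hoop; absolute values are
also returned. The independent renewal oracle for the spread is
$\mathrm{sd} = \sqrt{2\pi R\,L\,E[\sin^2\eta]/E[\cos\eta]}$, which reduces
to $\sqrt{2\pi R L \sigma^2}$ in the small-angle limit; at $\sigma = 0.3$
the small-angle form overstates the exact value by the $\sigma^2/4$
truncation (≈2%), which the tests account for explicitly. At $R = 0.5$ µm,
$L = 0.2$ µm, $\sigma = 0.3$ rad the simulated spread is ≈0.23 µm,
i.e. ≈0.2 µm at the one-decimal precision of the motivating measurements.

## What the synthetic dynamics do and do not emulate

The generator reproduces the study conditions — geometry menu and
dimensions, $L = 200$ nm steps, $\alpha = 0.6$ rad µm⁻¹ noise,
persistence-matched turnover, area-proportional activation — and the
package's tests validate the model against closed forms and its own
continuum limit. They do not make the dynamics a cell: the surface is
static (no growth feedback from wall insertion), filaments are points
(no length, no filament–filament interactions, no twist or bundling
elasticity beyond the curvature-weighted activation hook), motion is
discrete-time (no Gillespie-style continuous time), and thermal membrane
fluctuations are absent. Passing tests therefore demonstrate internal
consistency and agreement with the model's analytic limits, not agreement
with any particular microscopy data set.

## Numerical choices, degenerate inputs, reproducibility

Step lengths solve the arclength equation by two fixed-point iterations on
two-point Gauss–Legendre quadrature (relative error $O((L\kappa)^4)$);
activation sampling is exact rejection against a 5%-padded grid envelope;
concentration grids are midpoint structured grids with metric area
weights. Degenerate inputs are rejected at specification time (positive
lengths, embedded undulation, torus tube inside centerline); coordinate
poles are measure-zero and grids avoid them by construction. Every
simulation is reproducible bit-for-bit from its seed; the pipeline derives
per-stage seeds deterministically from a master seed and writes the
resolved configuration beside its outputs. Default problem sizes
(10⁴ lifetimes for the spherocylinder comparison, ~10⁴ hoops for the axial
statistic, 3000-lifetime replicates for the Langevin–continuum check,
48×32-class grids) were chosen as the smallest that leave Monte Carlo
error clearly below the effect sizes under study.
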