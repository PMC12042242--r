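---
title: "Methods: simulating magnetic drug targeting in a Weibel airway model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating magnetic drug targeting in a Weibel airway model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdtsim)
```

## The problem

Magnetic drug targeting (MDT) steers aerosolised magnetic drug particles
toward a lesion with an external magnetic field gradient. Bulk
high-temperature superconductors, magnetized to trap several tesla at their
surface, offer field strengths and gradients an order of magnitude beyond
permanent magnets, which makes targeting from *outside the body* plausible.
`mdtsim` simulates this scenario for a bronchial tumor: a G0-G3 symmetric
Weibel airway tree lying in the z = 0 plane, an epithelial wall tumor
partially obstructing a G1 branch, and a magnetized bulk superconducting
cylinder facing the tumor from distance $d$ above the lung plane. The
figure of merit is the particle deposition efficiency (PDE): the percentage
of released particles that land on the tumor surface.

## Magnet model

A fully magnetized bulk superconductor in the Bean critical state carries
its critical current density $J_c$ azimuthally everywhere in its volume.
For a cylinder of radius $a$ and thickness $t$ the peak trapped flux
density at the top-surface centre is

$$B_T = k\,\mu_0 J_c\, a,\qquad
  k = \frac{t}{2a}\,\ln\!\left(\frac{a}{t}+\sqrt{1+\frac{a^2}{t^2}}\right),$$

which is exactly the on-axis Biot-Savart integral of the uniform azimuthal
current density (the test suite verifies the equivalence to better than
0.5%). Off axis, the field is computed by superposing circular current
loops on a Gauss-Legendre quadrature of the cross-section, each loop's
field expressed in complete elliptic integrals; a panel subdivision
refines the corner singularity seen by surface-centre evaluations.

Measured $J_c(B)$ curves for the simulated materials are not tabulated
anywhere we can draw from, but the printed peak fields $B_T$ are. The
default reproduction mode is therefore a *calibrated constant* $J_c$:
`calibrate_jc()` inverts the closed form so that the magnetized cylinder
reproduces the tabulated $B_T$ (2.11-3.99 T across the five sizes at 77 K;
3.42, 6.95 and 10.80 T for the reference 32.5 mm x 19 mm bulk at 77, 60
and 50 K). This is the quantity the deposition physics actually depends
on, since the magnetophoretic force senses only the external field. A Kim
model $J_c(B) = J_{c0} B_0/(B_0+|B|)$ with a damped fixed-point
magnetization iteration (damping 0.5, tolerance $10^{-3}$, at most 100
iterations) is provided for sensitivity studies with user-supplied curve
data.

One sensitivity deserves emphasis. Two magnets with the same peak surface
field do *not* have the same far field: a field-dependent $J_c$ suppresses
current where $|B|$ is high (near the axis), so matching $B_T$ requires a
higher zero-field $J_{c0}$ and the low-field outer regions then carry more
current, raising the total magnetic moment. For the reference 32.5 x 19 mm
bulk at 3.42 T, a Kim magnet with $B_0$ between 0.8 and 3 T produces a
19-34% stronger field (hence a 40-80% stronger $\nabla H^2$) at 34-46 mm
than the constant-$J_c$ magnet calibrated to the identical $B_T$. Since
the true curve shapes are not tabulated, the package does not guess a
$B_0$ per magnet and temperature; users with measured curves should use
the Kim mode, and absolute deposition efficiencies from the constant-mode
presets should be read as conservative for real field-dependent
materials.

Because the field is axisymmetric and steady, it is tabulated once per
magnet on a magnet-frame $(\rho, \zeta)$ grid (1 mm default spacing) along
with $\nabla H^2$ by centred differences, and queried by bilinear
interpolation after rotating into the magnet frame. One map therefore
serves every magnet-lung distance in a sweep. The map's discretisation is
itself under test: halving the spacing moves interpolated $|\nabla H^2|$
by less than 2%, and the cylindrical-coordinate divergence residual stays
below 1% of $|B|$ per cell.

## Airway and tumor geometry

Branch lengths/radii follow the standard Weibel dimensions (G0 120/9,
G1 47.6/6.1, G2 19/4.15, G3 7.6/2.8 mm). The bifurcation half-angle is not
fixed by the geometry tables we reproduce; we default to 35 degrees per
daughter, a common choice for symmetric planar renderings, and expose it
in the configuration. Daughter cylinders are extended upstream into their
parent by one parent radius, which merges the branches into a watertight
union at the carina for point classification.

The tumor is a sphere of radius $r = (r/R_{G1}) R_{G1}$ whose centre lies
*on* the host-branch wall, so the protruding spherical cap reaches a depth
$r$ into the lumen ("growing from the epithelium"). Its axial station is a
label - P0, P1, P2 at the proximal, mid and distal thirds of the host
branch (these stations are only drawn, not tabulated, in the source
figures; the thirds convention is ours and is configurable). The study
default is P1. The azimuth $\alpha$ rotates the tumor about the branch
axis away from the magnet-facing (+z) wall line; the magnet stays anchored
over the $\alpha = 0$ line, which is what makes large $|\alpha|$ adversarial.

## Airflow surrogate

The reference pipeline solves steady laminar Navier-Stokes by FEM; a full
CFD solver is out of scope here. The surrogate keeps the two flow features
the deposition physics needs - the branch flow split and the near-tumor
streamline geometry - and accepts an externally computed field
(`import_flow()`) when higher fidelity is wanted.

**Flow split.** Branch flow rates come from a Hagen-Poiseuille resistance
network ($R \propto \eta L/R^4$) with equal outlet pressures. The tumor
raises its host branch's resistance through $\int \mathrm{d}\xi /
r_{\rm eq}^4(\xi)$ over the constriction, where $\pi r_{\rm eq}^2$ is the
open cross-section area (a circle-circle lens formula, verified against a
Monte Carlo area oracle). Flux is conserved exactly by construction.

**Profiles.** At the study's inlet Reynolds number ($\approx 1.2\times
10^3$) the laminar entrance length $0.05\,\mathrm{Re}\,D \approx 0.7$ m
exceeds every branch, so no branch reaches fully developed flow. Each
branch therefore carries a developing profile: a flat core of speed $U_c$
surrounded by a parabolic boundary layer of thickness
$\delta(\xi) = \min(R, 5\sqrt{\nu \xi / \bar u})$, renormalised to carry
the branch flow. The family contains Poiseuille exactly: when $\delta = R$
the profile is $2\bar u(1-(\rho/R)^2)$, and the fully-developed contract
(centreline = 2 x mean) is tested in that limit. Daughter-branch profiles
are additionally skewed toward the inner (carinal) wall by a factor
$(1 + s\,\hat\rho\cos\phi)$ with $s = 0.3\,e^{-3\xi/L}$, the azimuthal
bias that bifurcations imprint on the velocity field; the modulation
integrates to zero flux.

**Junctions.** Over the last own-radius of an internal branch the tube
tapers conically to the daughter radius: axial speed rises as $1/R_t^2$
and streamlines move inward with $u_r/u_x = \rho R_t'/R_t$. Without this
contraction, tracer particles near the parent wall would impact the
junction end-face annulus (the band of parent cross-section wider than
the daughters), a purely geometric artifact.

**Tumor blockage.** The cap occludes up to ~26% of the host cross-section
at $r/R_{G1} = 0.8$. Near the cap the axial speed is multiplied by the
inverse open-area fraction, and a streamline-compression model diverts the
flow under the dome: each particle's column (resolved in the lateral
coordinate, so side columns pass around the cap) sees a *diving ceiling*
equal to the sphere underside minus a small standoff (0.02 r), continued
upstream and downstream by its tangent lines of slope 0.5 - a $C^1$
ceiling a zero-inertia particle can follow exactly. The vertical velocity
conserves the cross-sectional area quantile below the ceiling. By
construction, tracers are never deposited by the mean flow; deposition on
the tumor requires the inertial lag a particle accumulates where the
ceiling curves (classical impaction, scaling with $\tau = \rho_p d_p^2 /
18\eta$) or magnetophoretic drift across the ceiling. These are exactly
the two mechanisms the study identifies ("inertial impingement" without
the magnet; field-gradient capture with it). The standoff is a numerical
guard sized to the discrete stepper's ceiling-tracking error (~0.1 mm with
the default steps) with a safety factor of two. The consequence is a known
bias: inertial slip below ~0.3 mm - pure impaction of micron particles
with no magnet, worth a couple of percentage points at most - is not
resolved, so no-magnet PDEs are biased toward zero. Magnetophoretic
capture operates at millimetre slips and is unaffected.

## Particle transport

Each particle obeys Newton's second law with Schiller-Naumann drag

$$\mathbf F_d = 3\pi\eta d_p\left(1 + 0.15\,\mathrm{Re}_p^{0.687}\right)
  (\mathbf u - \mathbf v),\qquad
  \mathrm{Re}_p = \frac{\rho\,|\mathbf u - \mathbf v|\,d_p}{\eta},$$

(the algebraic reduction of the $C_D \mathrm{Re}_p$ form, exact Stokes
drag as $\mathrm{Re}_p \to 0$) and the magnetophoretic force

$$\mathbf F_m = \frac{\pi}{4} d_p^3 \mu_0 \mu_r
  \frac{\mu_{r,p}-\mu_r}{\mu_{r,p}+2\mu_r}\,\nabla H^2 ,$$

with $\mu_r = 1$ in air and tissue. Lift, gravity, Brownian and unsteady
forces are neglected, and coupling is one-way (dilute limit). The default
particle is 4 um, 5230 kg/m^3, $\mu_{r,p} = 9$.

The integrator treats drag exponentially - over a step the velocity
relaxes exactly toward $\mathbf u + \mathbf F_m \tau_{\rm eff}/m_p$ with
$\tau_{\rm eff} = \tau/(1+0.15\,\mathrm{Re}_p^{0.687})$ - which is
unconditionally stable for the stiff response times of micron particles
($\tau \sim 10^{-5}$-$10^{-3}$ s), so the step size is set by geometry,
not stability: $\Delta t \le \min(2\times10^{-4}\,\mathrm{s},\;
0.3R_b/|v|)$, refined near the tumor surface in proportion to the
remaining clearance. Because fields are steady and coupling one-way,
particles carry independent clocks. Wall crossings are located by
bisection of the step chord to $10^{-6}$ m; boundary rules follow the
study's: wall and tumor stick (absorbing), outlets freeze, and particles
still airborne after three convective transit times are counted as
suspended (they are almost exclusively slow boundary-layer crawlers; they
stay in the PDE denominator and out of the numerator). Step-halving
changes the toy-case PDE by well under one percentage point.

Seeding places particles on the inlet disc with flux weighting (the
probability of entering at radius $\rho$ proportional to the local axial
flux $u(\rho)\rho$, built numerically from the actual inlet profile);
uniform area weighting is available. The spatial seeding law of the
reference pipeline is unstated, so both options are exposed. Initial
velocity equals the local air velocity.

## PDE analysis and sweeps

$\mathrm{PDE} = 100\,n_{\rm tumor}/n_{\rm denominator}$. The denominator
defaults to every particle released at the inlet; because the defining
phrase ("entering the branch") is ambiguous, a `host_branch` mode is also
computed and reported (particles whose visit log includes the tumor's
branch). `run_sweep()` varies one dotted configuration key, derives a
fresh deterministic sub-seed per point from the master seed by counter,
reuses the magnet-frame field map whenever the axis does not alter the
magnet, and emits a CSV plus base-graphics plot.

Default particle count is 10,000 (the study's release size). The test and
acceptance tier uses 2,000, for which the binomial sampling error at
PDE around 10-15% is about +/-0.7-0.8 pp per point; trend assertions in the
test suite allow for this.

## What the synthetic conditions do and do not show

The generator reproduces the study conditions: printed airway dimensions,
air and particle properties, boundary rules, release size, magnet
dimensions and peak fields; where a quantity exists only as a figure
(bifurcation angle, P-station positions, $J_c(B)$ curve shapes) the
defaults above stand in and are configurable. Passing tests demonstrate
that the implemented transport physics reproduces the study's mechanisms
and trends under a surrogate flow; they do not validate the surrogate
against patient airways (cartilage rings, asymmetry, wall motion,
oscillatory breathing are all absent), and absolute PDE values inherit
the surrogate's fidelity gap, most visibly where deposition is dominated
by details of the separated flow behind the carina and around the cap.

## Numerical choices

- Biot-Savart quadrature: 12-point Gauss-Legendre per panel, 4 x 3 panels
  (accuracy tier, used for calibration checks); 8-point, 2 x 2 panels for
  field-map tabulation, where the integrand is smooth. Relative error at
  the surface centre is ~4e-4, far inside the 0.5% contract.
- Field map: 1 mm spacing, bilinear interpolation; radial extent covers
  the whole tree from the magnet axis, axial extent all swept distances.
- Magnetization fixed point (Kim mode): damping 0.5, tolerance 1e-3,
  <= 100 iterations, self-loop term excluded from node fields.
- Flow: resistance integral over 400 stations; skew 0.3; boundary-layer
  virtual origin 2 mm (keeps the inlet profile finite).
- Transport: dt_max 2e-4 s, cell-crossing factor 0.3, bisection tolerance
  1e-6 m, time budget 3 transit times, degenerate inputs (fully occluded
  branch, zero denominator) raise typed errors or error records.
- Problem sizes: the shipped tests run 2,000 particles per case and the
  acceptance script 5,000 (6-point distance sweeps); these sizes exercise
  every mechanism at desk scale while keeping the binomial sampling error
  near half a percentage point per case.

## Known limitations

- The surrogate flow has no secondary (Dean) vortices, no separation
  bubble behind the cap, and prescribed rather than computed skew;
  deposition hot-spot *locations* on the tumor are therefore only
  qualitative.
- Junction unions slightly bulge the lumen where extended daughters meet
  the parent; classification remains watertight but the local wall shape
  is approximate.
- The Kim-mode magnetization samples the self-consistent field at loop
  nodes only; it is a sensitivity tool, not a critical-state solver.
- Suspended (time-budget) particles would eventually exit in reality;
  their share is reported so the denominator convention is transparent.
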