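---
title: "Modeling cement injection as two-phase Darcy flow in a vertebral phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling cement injection as two-phase Darcy flow in a vertebral phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The physical model

Percutaneous vertebroplasty injects polymethylmethacrylate (PMMA) cement
into a fractured vertebral body; where the cement goes — and whether it
escapes the cortical wall — is the clinically interesting question. PMMA is
a curing, strongly non-Newtonian fluid, so the experiment this package
simulates replaces it with a constant-viscosity surrogate: silicone oil of
100,000 cSt kinematic viscosity, injected at a controlled rate into an
air-filled porous medium standing for cancellous (trabecular) bone.

`vertebroflow` models this as unsteady, incompressible, laminar two-phase
flow in a rigid, isotropic porous medium governed by Darcy's law,

$$\nabla P = -\frac{\mu}{\alpha}\,\mathbf{v},$$

for each phase (oil, air). Summing the phase equations under
incompressibility gives an elliptic pressure equation with
saturation-dependent total mobility $\lambda_t(s)$ and a hyperbolic
transport equation for the oil saturation $s$ (the fraction of pore space
occupied by oil, the quantity color-mapped in distribution plots):

$$\nabla\cdot\big(\alpha\,\lambda_t(s)\,\nabla P\big) = -q, \qquad
\phi\,\frac{\partial s}{\partial t} + \nabla\cdot\big(f(s)\,\mathbf{v}\big) = q_{oil},$$

with total Darcy flux $\mathbf{v} = -\alpha\lambda_t\nabla P$ and fractional
flow $f(s)$. Modeling assumptions, all inherited from the experimental
protocol being reproduced:

* the bone framework is rigid and immovable (no poroelasticity);
* material properties are constant; no heat transfer, curing, or phase
  change;
* cancellous bone is isotropic, with a single scalar permeability;
* cortical bone is impermeable (permeability exactly 0), which also
  realizes the no-slip condition at the wall;
* gravity is negligible over the few-second injection (the oil viscosity
  is 97 Pa s); an optional mixture buoyancy term is available for
  sensitivity studies (`numerics_config(gravity = TRUE)`);
* initially the pore space holds only air ($s = 0$ everywhere).

### Two-phase closure

The protocol names the two phases but no relative-permeability model. We
use linear relative permeabilities ($k_r = $ phase saturation), giving

$$\lambda_t(s) = \frac{s}{\mu_{oil}} + \frac{1-s}{\mu_{air}}, \qquad
f(s) = \frac{s/\mu_{oil}}{\lambda_t(s)}.$$

At the physical viscosity ratio $\mu_{oil}/\mu_{air} \approx 5.4\times10^6$
this choice is essentially immaterial: $f$ stays below $10^{-6}$ until $s$
is within $2\times10^{-7}$ of 1, so the displacement front is piston-like
for any monotone closure. The closure is configurable through the fluid
pair.

### Parameters and derived constants

| quantity | symbol | default | origin |
|---|---|---|---|
| porosity | $\phi$ | 0.75 | measured range 70–80% |
| mean pore diameter | $d$ | 0.90 mm | measured |
| permeability | $\alpha$ | $3.04\times10^{-8}$ m$^2$ | Kozeny–Carman $\phi^3 d^2/(180(1-\phi)^2)$ |
| oil viscosity | $\mu_{oil}$ | 97 Pa s | 100,000 cSt $\times$ 970 kg/m$^3$ (PDMS density) |
| air viscosity | $\mu_{air}$ | $1.8\times10^{-5}$ Pa s | standard air |
| injection rate | $Q$ | 0.3 mL/s | chosen (see below) |
| duration | — | 7 s | snapshot protocol (1, 4, 7 s) |

Two of these close gaps in the source protocol and deserve comment. The
protocol gives only the kinematic viscosity; converting to the dynamic
viscosity Darcy's law needs requires a density, and 970 kg/m$^3$ is typical
for high-viscosity polydimethylsiloxane. The injection was
pressure-controlled with no value reported; we default to a constant
0.3 mL/s for 7 s (2.1 mL total), a clinically plausible cement dose whose
front stays inside the default phantom for the full run, so every reported
metric is in the pre-overflow regime. Both are configurable; absolute
spread radii scale with $Q$, while the qualitative plane orderings do not.

## The phantom generator

The synthetic geometry module is the package's data generator: it stands in
for the CT-derived vertebral model with the simplified geometry the
protocol itself adopts — an elliptical cylinder of cancellous bone wrapped
in an impermeable cortical shell.

Vertebral dimensions are never stated in the protocol, so the defaults are
chosen once from typical lumbar anatomy: transverse semiaxis
$a_x = 21$ mm, anteroposterior semiaxis $a_y = 15$ mm, interior half-height
10 mm, shell thickness 1 mm. The half-height makes the section catalog
internally consistent: the pedicle-injection protocol places plane 4 at
$z = 9.7$ mm, "0.3 mm below the upper endplate", which fixes the endplate
interior surface at $z = +10$ mm above the injection point and fixes the
unit of the bare plane coordinates (0.002, 0.005, 0.0097) as meters.

Choices the generator makes where the design was genuinely open:

* **Vents.** Strictly sealed impermeable walls contradict incompressible
  flow with a mass source — displaced air must go somewhere. Rather than
  modeling air compressibility we convert a small patch (default 5 cells)
  of the wall into pressure-reference *vent* cells: on the posterior wall
  at $z=0$ for the body phantom (the basivertebral foramen / needle
  tract), on the anterior wall for the pedicle phantom. Until oil reaches
  a vent the results are insensitive to its size and position because the
  air mobility is $\sim5\times10^6$ times the oil's: the entire air region
  is effectively at the vent pressure.
* **Pedicle channel.** A cancellous cylinder (radius 2.5 mm) through the
  posterolateral shell at lateral offset 12 mm, running in $-y$; the
  injection point sits on its axis at the body–channel junction and is the
  coordinate origin. The channel's outer end is capped: the injection
  cannula occupies and seals the tract. The needle tract itself is not
  otherwise modeled; injection is a point source.
* **Sealing pass.** After voxelization, any exterior voxel in face contact
  with a cancellous voxel is converted to cortical, so the shell
  topologically separates interior from exterior regardless of voxel-size
  corner effects (validated by `validate_phantom()`).
* **Wall rings.** The ring-shaped observation sections of the lateral and
  posterior walls are not dimensioned in the protocol; we take the
  interior wall faces within $\pm 6$ mm of the injection plane over a 90°
  arc centered on each wall.

## Numerical scheme

Cell-centered conservative finite volumes on a uniform voxel grid
(default $h = 0.5$ mm, about $162{,}000$ cancellous cells), with an
IMPES-style sequential step: implicit pressure, then explicit-in-time
saturation transport.

* **Pressure.** Harmonic-mean face transmissibilities
  $T_f = h\,2a_ia_j/(a_i+a_j)$ with $a = \alpha\lambda_t(s)$; zero-flux
  cortical/exterior faces; Dirichlet vents (reference $P=0$; arbitrary
  per-cell values are supported, which the verification suite uses to
  impose analytic boundary data). The SPD system is solved by conjugate
  gradients with a symmetric Gauss–Seidel preconditioner, warm-started
  from the previous step, to a relative residual of $10^{-10}$.
* **Transport.** First-order upwinding. The classical explicit update is
  provided and used where its CFL bound
  $\Delta t \le \phi h/(|v|\max_s f'(s))$ is practical — but at the
  physical viscosity ratio $\max_s f'(s) = \mu_{oil}/\mu_{air} \sim 5\times10^6$,
  which would force $\Delta t \sim 10^{-10}$ s. The default is therefore an
  *exact implicit* upwind update: because upwind fluxes follow the
  pressure gradient, the flux graph is acyclic, and one nonlinear
  Gauss–Seidel sweep in decreasing-pressure order solves the backward-Euler
  system exactly, each cell reducing to a monotone scalar equation solved
  by bisection to machine precision. The update is unconditionally stable,
  conservative to round-off, and keeps $s\in[0,1]$ by construction
  (bounds are asserted, never silently clipped). Cells whose pressures tie
  exchange no flux, so the sweep order among ties is immaterial and runs
  are bit-reproducible.
* **Time step.** $\Delta t$ is chosen so that no cell's saturation changes
  by more than the CFL factor (default 0.5) in one step:
  $\Delta t = c\,\min_i \phi_i h^3 / |r_i|$ over the upwind net oil inflow
  rates $r_i$. At a moving front this reduces to the usual front CFL
  (the front advances at most half a cell per step, about
  $2R_{final}/h$ steps per run); stagnant oil/air interfaces — such as
  the sealed pedicle channel, where the net flux is zero — impose no
  limit. Steps are shortened to land exactly on requested output times.
* **Degenerate inputs.** Injecting with no vent raises a configuration
  error naming the vent requirement (the system is singular); a quiescent
  no-vent solve returns the zero reference field. Isolated cancellous
  cells with no flow connections are pinned to the reference pressure. A
  zero-rate protocol reproduces the initial state bit-exactly.
* **Mass audit.** Every step checks
  $\sum_i \phi_i s_i h^3 + V_{vented} = Q\min(t, t_{inj})$ and aborts if
  the drift exceeds 1%; in practice it stays below $10^{-10}$ relative.

## Observation metrics

The metrics module mirrors the experimental read-out. Plane fields are the
voxel layer nearest the section coordinate (ties broken toward the
injection point). The distribution area percentage is
$100\times$ (pixels with $s\ge\theta$) / (interior pixels of the section) —
normalized by the section's own interior area; the alternative (a fixed
reference area) would change absolute percentages but no ordering. The
distribution radius is the equivalent-area radius $\sqrt{A_\theta/\pi}$,
chosen over maximum extent because the spread is circle-like but not
exactly circular. Sphere-likeness is the smallest-to-largest eigenvalue
ratio of the thresholded region's second-moment ellipsoid.

The threshold $\theta$ is not stated by the protocol (areas were read off
color maps); we default to $\theta = 0.5$, the midpoint of a piston-like
front, which is robust to grid resolution since the front is 1–2 cells
wide. Reports can additionally be run at $\theta = 0.1$ to capture the
diffuse halo visible in color maps; orderings are unchanged.

## What the generator emulates — and what it does not

The phantom reproduces the *modeled* experiment: homogeneous isotropic
cancellous bone, a perfectly impermeable shell, simplified elliptical
geometry, constant-viscosity oil. Real vertebrae have heterogeneous
anisotropic trabecular architecture, fracture clefts, marrow (not air) in
the pore space, venous drainage, and curing cement whose viscosity rises
during injection. Passing tests therefore validate the solver against this
idealized configuration — conservation, analytic front radii
$R(t) = (3Qt/4\pi\phi)^{1/3}$, the point-source pressure Green's function
$P = Q\mu/(4\pi\alpha r)$, characteristic front speeds, and the qualitative
distribution patterns (datum-plane dominance, endplate lag, wall
spreading) — not quantitative prediction for any real patient or specimen.

## Problem sizes and runtimes

The shipped configurations run the body and pedicle experiments at
$h = 0.5$ mm ($\approx 3\times10^5$ voxels, $\approx 1.6\times10^5$
unknowns), roughly 80–150 time steps and one to four minutes each on one
CPU. Verification oracles use a $64^3$ homogeneous cube (pressure Green's
function), a 200-cell column (characteristics), and $h = 1$ mm phantoms
(unit tests, refinement studies at $h = 1 \to 0.5$ mm and $t = 1$ s).

## Known limitations

* Single scalar permeability; no anisotropy or spatial heterogeneity
  (both would be one-line extensions of the phantom material fields).
* Linear relative permeabilities and zero capillary pressure; at mild
  viscosity ratios the closure choice would matter.
* The first-order front is 1–2 cells wide; area metrics inherit
  $O(h)$ resolution error (under 5% between $h = 1$ and 0.5 mm).
* Vent placement is an idealization of air escape; once oil reaches a
  vent the conservation report separates vented volume explicitly.
* No curing rheology, thermal effects, or poroelastic coupling, by
  design.
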