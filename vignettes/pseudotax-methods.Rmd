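---
title: "A pseudopod-centred model of amoeboid chemotaxis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A pseudopod-centred model of amoeboid chemotaxis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`pseudotax` simulates a crawling amoeboid cell (a Dictyostelium-like
cell of diameter 10 model length units) as a closed curve whose motion is
driven entirely by a reaction-diffusion system living *on* the curve. There
is no internal compass: the cell's direction is represented by its
pseudopods, which are local peaks of a membrane-bound activator.

Three species live on the perimeter $\Gamma$:

* an activator $a$ (the analogue of Arp2/3-driven actin nucleation),
* a local inhibitor $c$ (analogue: depletion of a required substrate),
* a global inhibitor $b$ (analogue: membrane tension), a single scalar.

They obey a Meinhardt-type system,

$$\partial_t a = D_a \Delta_\Gamma a
  + \frac{s\,(a^2/b + b_a)}{(s_c + c)(1 + s_a a^2)} - r_a a, \qquad
  \frac{db}{dt} = r_b\,(\langle a\rangle - b), \qquad
\partial_t c = D_c \Delta_\Gamma c + b_c a - r_c c,$$

with $\langle a\rangle$ the length-weighted perimeter mean. Autocatalysis
($a^2/b$) lets a peak sustain itself; the global inhibitor makes peaks
compete for a shared budget; the slow local inhibitor accumulates under a
peak and eventually destabilizes it, keeping pseudopods dynamic. The
saturation $1 + s_a a^2$ caps peak amplitude.

The chemoattractant enters only through the **signal** $s$, which
modulates the production term per node:

$$s = (s_0 + w_a a)\,(1 + \eta_a \xi_1)
    + w_y\, Y\,(1 + \eta_y \xi_2), \qquad s \ge 0,$$

where $Y = C/(C + K_d)$ is the local fractional receptor occupancy of the
attractant concentration $C$ at that membrane point, and $\xi_1, \xi_2$
are independent per-node, per-step noises (uniform on $[-1,1]$ by
default; a Gaussian variant is available). The first component represents
noisy autocatalytic drive, the second noisy receptor signalling. There is
no adaptation, no spatial comparison, and no amplification step: each
membrane point reads only its own occupancy.

### Movement

Each perimeter node moves along the outward normal with speed

$$v = \lambda_p\, a \;-\; \lambda_\sigma\, \kappa\,
  \Big(1 + k_A \frac{A - A_0}{A_0}\Big),$$

an activator-proportional protrusion opposed by a curvature-based
retraction that emulates cortical tension. The tension gain rises when the
area exceeds its target $A_0$ and falls (through zero, pushing outward)
when the cell is far below it; the gain is clamped to $[-2, 4]$ so that
extreme transients cannot produce runaway retraction or expansion. Area
control acting multiplicatively on the tension term was chosen over a
global Lagrange multiplier because it is local, cheap and sufficient: over
default runs the area stays within a few percent of $A_0$.

Movement feeds back on the chemistry: where the boundary expands, the
transferred concentrations are divided by the local stretch factor
(conservative remap), so a growing pseudopod dilutes its own activator.
This geometric dilution is implemented in the field transfer between
successive meshes, not as an extra advection term in the PDE.

## Numerics

* **Surface FEM.** Piecewise-linear elements on the polygonal perimeter;
  consistent mass matrix $M$ and stiffness $K$. Reaction terms are
  explicit, diffusion implicit (first-order IMEX):
  $(M + \Delta t\, D\, K)\,u^{n+1} = M (u^n + \Delta t\, R(u^n))$, which
  is unconditionally stable in the diffusion part. $b$ advances as a
  scalar ODE.
* **Level set.** The cell is the region $\{\phi < 0\}$ on a fixed
  Cartesian grid ($128^2$ at spacing $h = 10/32$ by default, translated to
  follow the cell). Node speeds are extended to the narrow band
  ($|\phi| < 6h$) by closest-point extension, $\phi$ is advanced with a
  first-order Godunov upwind scheme under an internal CFL restriction
  ($\max|F|\,\delta t \le h/2$, sub-stepped), and reinitialized every
  frame by rebuilding the exact signed distance to the extracted zero
  contour. Because reinitialization goes through contour extraction
  (marching squares, whose vertex positions carry $O(h^2)$ error), a
  reinitialized $\phi$ is reproduced only to within a small fraction of
  $h$ on repeated application - exact idempotence is not attainable by
  this construction, and the tests assert contour drift $< 0.1\,h$
  instead.
* **Remeshing.** The zero contour is lightly smoothed (two passes of a
  1-2-1 kernel on the raw marching-squares vertices, removing node-scale
  stair-steps far below the grid error), resampled to `n_nodes` equal
  arc-length nodes, and the fields are transferred conservatively with the
  dilution factor clamped to $[0.5, 2]$ per frame (larger apparent
  stretches are geometry artifacts, not physical dilution).
* **Frames.** One output frame corresponds to `steps_per_frame` (default
  5) reaction-diffusion sub-steps of `dt` (default 1) followed by one
  boundary update over the same time span. The curvature entering the
  velocity law is smoothed with three 1-2-1 passes to suppress
  discretization noise; a per-frame speed cap (one third of the narrow
  band per frame) guards the geometry against pathological transients and
  is logged when it engages.
* All times are reported in model units; the underlying experimental
  literature does not fix a frame-to-minutes conversion.

## Parameters

Kinetic defaults (per `model_params()`): $D_a = 0.08$, $D_c = 0.35$,
$r_a = 0.02$, $r_b = 0.03$, $b_c = 0.13$, $r_c = 0.013$, $b_a = 0.1$,
$s_a = 0.005$, $s_c = 0.2$, $dt = 1$; signal: $s_0 = 1$, $w_a = 0.002$,
$w_y = 2$, $\eta_a = \eta_y = 0.15$, $K_d = 30$ nM. Mechanics:
$\lambda_p = 0.01$, $\lambda_\sigma = 0.2$, $k_A = 15$, $A_0 = 25\pi$.

These sit in the classical Meinhardt regime, rescaled to the
10-unit cell. Two constraints fixed the values that the source literature
leaves open, and they were frozen once:

1. **Linear instability of the uniform state.** Writing
   $\sigma = s_a a^{*2}$ for the saturation level at the uniform steady
   state, local growth of perturbations requires roughly
   $(P_a - r_a - D_a k^2)(r_c + D_c k^2) > r_a r_c$ with
   $P_a \approx 2 r_a/(1+\sigma)$. This forces $\sigma \lesssim 0.3$
   (the uniform activator must sit well below saturation) and a local
   inhibitor ratio $b_c / r_c = 10$, giving $a^* \approx 4.6$ and an
   unstable band at one to two wavelengths around the perimeter - the
   cell polarizes into a single front rather than forming many spots.
2. **Motility with area stability.** $\lambda_p$, $\lambda_\sigma$ and
   $k_A$ were chosen so the default unstimulated cell is persistently
   motile while its area stays within ±10% of $A_0$; weaker protrusion
   produces a polarized but nearly stationary cell, stronger protrusion
   destabilizes the boundary geometry.

$K_d = 30$ nM places the 5.3-6.6 nM gradient protocols in the sensitive
low-occupancy regime (15-18% occupancy) and makes a 0-20% occupancy span
reachable by a linear 0-7.5 nM gradient. The noise amplitudes (15%
multiplicative per node per step) are far larger than the across-cell
occupancy difference of the shallow protocols (a few percent), matching
the intended signal-in-noise regime.

## The stimulus layer

`stimulus_spec()` declares the protocol: linear gradients (clipped at zero
concentration), a 1/r point source with a plateau at the source scale, a
uniform step with optional exponential receptor adaptation applied to the
occupancy, and a scheduled mode in which the gradient is re-pointed to a
fixed offset (default +90 degrees) from the cell's current heading every
`reorientation_interval` frames (heading = direction of the centroid
displacement over the last 20 frames). The hyperbolic occupancy law and
the placement of adaptation downstream of occupancy are package choices;
the underlying literature specifies concentrations and occupancy fractions
but not the mapping between them.

## The analysis layer

Pseudopods are local maxima of the periodic activator profile passing
height (20% of run maximum), prominence (10%) and separation (10% of
perimeter) thresholds - defaults chosen so a polarized cell reads as one
to two pseudopods, all configurable. Peaks are tracked between frames by
greedy nearest-neighbour matching (radius 10% of perimeter); an appearing
peak within the bifurcation radius (20%) of a continued track is recorded
as that track's second daughter and the parent ends with fate `split`.
Tracks shorter than 5 frames are pruned as detection noise; when a pruned
track was a bifurcation daughter, its sibling is merged back into the
parent and the event discarded, preserving the invariant that a `split`
parent has exactly two children. A pseudopod's direction is the
centroid-to-peak angle; its birth direction is taken at first detection.

For each bifurcation, $\alpha$ is the attractant direction relative to the
parent pseudopod and $\gamma$ the dominant daughter's direction relative
to the parent. The dominant daughter is the survivor (tie-breaks: fate,
then lifetime, then peak height - documented order). Because it is
ambiguous whether the split-angle/attractant relation should be summarized
with signed or absolute angles, both are emitted: a signed fit in the
reflected convention (events mirrored so the attractant always lies
counterclockwise of the parent) and an $|\gamma|$-on-$|\alpha|$ fit. The
zero-bias crossing is the $\alpha$ at which the fitted split angle equals
the unstimulated mean. "Moving towards the attractant" is operationalized
as $|\alpha| < 30^\circ$ (the event yield at $|\alpha| < 15^\circ$ is too
small at smoke scale).

Kymographs unwrap each perimeter into equal angular sectors around the
centroid anchored at a fixed laboratory angle, falling back to arc-length
unwrapping for non-star-shaped outlines. Circular summaries use the
standard resultant-vector mean and $\sqrt{-2\ln R}$ dispersion, flagged
unreliable when $R < 0.05$.

## What the simulations do and do not emulate

Default runs reproduce, at reduced problem sizes: spontaneous polarization
from noise, persistent random migration, generation of new pseudopods
predominantly by bifurcation of the leading edge, travelling-wave
kymograph stripes, gradient-steepness-dependent chemotaxis accuracy, the
cringe response to a saturating uniform step with adaptation (global
activator surge, rounding, damped oscillatory recovery), and
circling under the periodic +90 degree reorientation protocol.

The model bifurcates more nearly symmetrically than real cells (no
"rabbit ears" of unequal splitting), carries no receptor-level kinetics,
no cell-cell or cell-obstacle contact, and no topology change. Split
angles in this implementation are systematically narrower than in the
measured cells (mean absolute dominant-daughter angle ~20-25 degrees
against ~55 degrees reported for real and originally simulated cells):
daughter directions are measured at first detection, when the daughters
have just crossed the peak-separation threshold, and the default peak
geometry is narrow relative to a real pseudopod's angular footprint. The
direction-dependent *bias* of the split angle (smaller towards the
attractant, growing away from it) is reproduced qualitatively; its slope
is correspondingly shallower on the compressed angular scale.

## Problem sizes

The package's own test suite and the acceptance script run the "smoke"
profile: a 64 x 64 grid, 120 perimeter nodes, and runs of 350-1200 frames
(5 reaction-diffusion steps each), completing in roughly 0.07 s per frame
on one CPU. The full default profile (128 x 128 grid, 200 nodes, 5000
frames) produces the same qualitative behaviour with better statistics and
is the recommended setting for research use.
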