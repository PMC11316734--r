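---
title: "Biophysical simulation of retinal vascular networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biophysical simulation of retinal vascular networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(retinavasc)
```

## The model

`retinavasc` generates digital replicas of the anterior retinal
circulation: a single central retinal artery and vein entering at the
optic disc, branching into space-filling arterial and venous trees that
are joined by a capillary bed into one closed circuit with exactly one
inlet and one outlet. That closure is what makes the hemodynamics simple
and well-posed: one pressure boundary condition at each end determines
blood flow everywhere.

Construction proceeds in stages, each governed by Murray's law — the
optimality principle that at a bifurcation the parent radius satisfies
$r_p^\gamma = r_1^\gamma + r_2^\gamma$, with associated optimal branching
angles

$$\cos\theta_1 = \frac{(1+\alpha^3)^{4/3} + \alpha^4 - 1}
                      {2\alpha^2(1+\alpha^3)^{2/3}}, \qquad
  \cos\theta_2 = \frac{(1+\alpha^3)^{4/3} + 1 - \alpha^4}
                      {2(1+\alpha^3)^{2/3}},$$

where $\alpha = r_2/r_1 \le 1$ is the daughter radius ratio, $\theta_1$
the deflection of the smaller daughter and $\theta_2$ that of the larger.
We use a population-calibrated exponent $\gamma \sim \mathcal N(2.4,
0.11)$ rather than the classical $\gamma = 3$.

1. **Seeding (L-system).** Root segments (calibres
   $\mathcal N(135, 15)$ µm artery, $\mathcal N(151, 15)$ µm vein,
   interpreted as diameters) start at the optic disc parallel to the
   optic nerve, branch once above and once below the retinal midline,
   then branch stochastically for five generations. Inter-bifurcation
   length is $18 \pm 3$ times the local calibre, angles follow the optimal
   formulas with 5° Gaussian noise applied independently per angle, and
   the larger daughter is steered toward the macula to form the arcades.
2. **Space-filling growth (constrained constructive optimisation).**
   Uniform leaf nodes (3 mm spacing, full scale) are attached by minimum
   cost increment, then square lattices with strides from 3000 µm down to
   150 µm (five linearly spaced levels, both endpoints included,
   8-neighbour adjacency) are invaded site by site. Each step commits the
   candidate attachment — a terminal from the nearest vessel within two
   strides, splitting the host segment — that minimises the expected
   increase of the cost $C = \sum_b r_b^{\rho} l_b^{\lambda}$ with
   $\rho = \lambda = 1$, under Murray-consistent radius updates propagated
   to the root. The macula region is kept vessel-free throughout; the
   original leaf tips are removed after the initial stage; root radii are
   finally rescaled to the sampled calibres (Murray's relation is
   homogeneous, so exponent recovery is unaffected).
3. **Refinement.** Node positions are optimised by coordinate-wise
   golden-section search (cost never increases; frozen vessels untouched;
   leaf nodes move at most a pinning fraction of the leaf spacing);
   highly asymmetric bifurcations ($\alpha < 0.2$) are trimmed for
   regrowth; low-flow sides of asymmetric bifurcations may shift one
   generation downstream and branches short relative to the
   West–Brown–Enquist expectation ($l_{child} = l_{parent} 2^{-1/3}$,
   "short" = below half) collapse into higher-order splits, each accepted
   only if the cost decreases; in-plane crossings within a tree are
   rewired (never bypassed) so later growth cannot recreate them.
4. **Macula.** The annulus between the avascular fovea and the 5.5
   mm-diameter macula boundary is filled radially inward from ring-based
   leaf targets, jittered within a disc so vessels do not align with the
   rings, thinned i.i.d. with sparsity 0.3, at a post-thinning density of
   the flow-density factor (uniform 1.5–2.0) times the measured
   peripheral terminal density, with a 90° hard limit on the angle
   between a new segment and its parent.
5. **Tortuosity.** Two sinusoidal displacements are superimposed
   perpendicular to each vessel's axis, with total amplitude 1–3.5 radii
   (arteries) or 1–7.5 radii (veins), periods 15–25 and 30–50 radii, and
   phases pinned so displacement vanishes at both branch nodes (each
   period is snapped to an integer number of half-waves per branch; this
   is how modulations are "matched" across bifurcations). The printed
   period ranges label the shorter period low-frequency; we implement the
   printed ranges and treat the labels as swapped.
6. **Capillary closure.** Either Voronoi edges of a random seed-point
   process (default 25 points/mm² full scale) or 2D space colonization;
   terminals connect to the bed, stray patches are stitched, and the
   result is a single component. Fine artery–vein intersections (both
   radii < 5 µm) lose their low-flow side, and crossings between the
   trees are resolved by smooth cosine out-of-plane excursions with
   clearance at least the sum of radii.
7. **Projection.** The planar network maps onto a hemisphere (diameter
   uniform 23–25 mm) by the azimuthal-equidistant inverse — planar
   distance from the disc centre becomes great-circle distance — with
   macula pit and disc relief as mixed radial Gaussians riding the
   surface normal. Radial arcs are preserved exactly; azimuthal arcs
   contract by $\sin\theta/\theta$, about 17 % at the retinal rim. (A
   naive expectation that projection never shortens segments is wrong for
   this mapping; the tests assert the correct differential-geometry
   bound.)

## Hemodynamics and fluorescein

Each segment is a Poiseuille resistor, $g = \pi r^4 / 8\mu l$, with
per-point radii entering through the series (harmonic $r^4$)
composition along the path and constant viscosity $\mu = 3.5$ mPa·s by
default (the diameter-dependent in-vivo law is deliberately out of the
default path for determinism). Node pressures solve the sparse
conservation system with Dirichlet pressures at the inlet
($\mathcal N(56.2, 14.0)$ mmHg) and outlet ($\mathcal N(20.0, 10.0)$
mmHg; sets violating the arteriovenous ordering are resampled). Internal
units are SI; interfaces use mmHg and µL/min (1 mmHg = 133.322 Pa).

Fluorescein delivery uses a two-Gaussian-plus-washout input,

$$C(t) = s_1 G(t; t_1, \sigma_1) + s_2 G(t; t_2, \sigma_2)
       + \alpha H(t - t_3) e^{-\beta (t - t_3)},$$

with $s_1 = 0.833$, $s_2 = 0.336$, $\alpha = 1.064$,
$t_{1,2,3} = 0.171, 0.364, 0.482$ min, $\sigma_{1,2} = 10, 25$ s,
$\beta = 0.043$/min, rescaled to unit maximum. Two consequences of these
constants are worth stating plainly, because the source expression is
loose with its symbols and we fixed a convention: the washout term
switches on discontinuously at $t_3$ and its onset value exceeds the
first-pass peak, so the global maximum sits at $t_3$; and with
$\sigma_1 = 10$ s against $t_1 = 10.26$ s the curve is far from zero at
$t = 0$. Both are properties of the printed constants, not of our
implementation choices; the unit-peak-Gaussian, step-gated-washout,
global-rescale convention is ours and is tested against an independent
evaluation.

Transport is pure advection: each node's arrival time accumulates
$l/v$ along the dominant-flow path from the inlet (a single sweep in
topological order of the oriented flow graph), each segment carries the
input delayed by the arrival at its downstream end, and signal amplitude
partitions with flow ($|q|/q_{inlet}$ — concentration itself is
intensive and undiluted at splits, so flow-weighted recombination at
merges conserves tracer). No dispersion is modelled. The arterio-venous
delay is read off as the half-maximum onset of the outlet-adjacent
venous curve against the undelayed inlet input — the only reading
consistent with a uniform-velocity path giving delay = length/velocity.

## Pathology

Retinal vein occlusion: a random artery–vein crossover on a large vein
(top radius quartile among crossing veins) has its diameter reduced by
80 %, flow is re-solved, and the deficit is reported as the flow drop
through the occluded vein plus the summed drop along its downstream
venous path. Diabetic retinopathy: arterioles below 35 µm radius are
fully occluded (diameter ×0.01, keeping the linear system regular) in
batches of five, from the periphery inward along a decreasing
minimum-distance schedule (default 10, 7.5, 5, 2.5 mm from the macula
at full scale); after each batch non-perfused vessels (|q| below 10⁻⁴
µL/min) are pruned to the component containing both roots, producing
ischaemic territories with occasional surviving through-vessels.

## Parameters

`parameter_table()` lists the 26 sampled parameters with their
distributions; `sample_parameters(seed)` draws them reproducibly and
resamples on constraint violations (all calibres/lengths/pressures
positive, inlet above outlet pressure). Calibres are diameters by
default — the source is ambiguous between radii and diameters and we
follow its Methods wording, with `calibre_interpretation = "radius"`
available. Constants that the model fixes rather than samples (cost
exponents ρ = λ = 1, trim threshold α < 0.2, WBE short-branch fraction
0.5, terminal radius 12 µm, capillary radius 4 µm, fovea diameter 0.8
mm, Voronoi seed density 25/mm², bolus constants, viscosity, pathology
defaults) live in `model_constants()` and are overridable at the
relevant call sites.

## The reduced-scale (mini) configuration

Full-scale cohorts (12.5 mm retina, 150 µm final stride) take hours per
batch on one CPU. All statistical checks therefore run on a
geometry-preserving reduction — 6 mm retina disc, strides 1200→300 µm
over three levels, four seed generations, 1.5 mm leaf spacing, capillary
seed density 3/mm² (`mini_parameters()`, `make_toy_fixture("mini-retina")`)
— chosen so a complete network builds and solves in under ten seconds
while every mechanism (Murray-governed growth, macula densification,
closure, flow, bolus) is exercised unchanged. Sampling distributions for
calibres, the exponent, pressures and the macula factor are untouched.
What transfers to full scale: exact conservation, Murray-exponent
recovery, the macula/periphery perfusion contrast, positive
second-scale arterio-venous delays. What does not: absolute total flow
(a reduced network has fewer parallel paths) and the absolute delay
value, which depend on network extent.

The synthetic networks themselves emulate geometry and perfusion, not
image formation: passing tests say nothing about scanner noise, optical
distortion, projection artefacts or pathology appearance in real
OCT-A/fundus/angiography data.

## Numerical choices

- Growth tie-breaks are deterministic (lowest cost, then site order);
  candidate Δ-cost caches are invalidated within 2.5 strides of each
  committed segment, so cached entries referencing upstream radii can be
  slightly stale between commits — standard practice in accelerated
  constructive optimisation, and the committed cost increment itself is
  always exact.
- Geometric optimisation stops when a sweep improves the cost by less
  than 10⁻⁴ relative, golden-section per coordinate.
- The Poiseuille system is solved sparsely (Matrix) after symmetric
  elimination of the two Dirichlet rows; a dense independent solver
  cross-checks it to 10⁻⁸ relative in the tests.
- Degenerate inputs: empty networks are refused by the Amira writer;
  zero-flow segments are excluded (with a warning) from bolus transport;
  an empty-vs-empty Dice comparison is defined as 1 and logged.
- Full occlusion scales diameters by 0.01 rather than deleting the
  segment, keeping the conductance matrix regular while suppressing flow
  by 10⁻⁸.

## Known limitations

Single-layer (planar) plexus — no superficial/deep capillary split; no
choroid or cilioretinal variants; advective bolus transport without
Taylor dispersion or haematocrit phase separation; constant viscosity by
default; rasterisation by dense sphere sampling (accurate to voxel
scale, with end-caps slightly rounding tube ends); trimming thresholds
and the macula density mechanism are model choices where the underlying
description names only intent.
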