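---
title: "Quantifying neural wiring from fiber-stained confocal stacks"
author: "WireScale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neural wiring from fiber-stained confocal stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(WireScale)
```

## The problem

Comparative neuroanatomy of the deep cerebellar nuclei (DCN) — the hub
connecting the cerebellar cortex with the rest of the brain — asks how the
"wiring" of a network scales when brains grow. Regular allometric scaling
predicts that neuron density falls with tissue volume to the power $-1/3$
while per-neuron dendritic length and dendritic field (region-of-influence)
diameter grow with volume to the power $+1/3$. Departures from these
exponents are biologically informative: a nucleus whose dendritic trees stay
small while its volume explodes can pack correspondingly more independent
modules.

WireScale implements the complete measurement chain behind such an analysis:

1. **Imaging**: preprocessing and fixed-threshold segmentation of confocal
   stacks of fiber-like immunostaining (dendritic MAP2, Purkinje-axon PCP2).
2. **Skeletonization**: distance maps, topology-preserving 3D thinning, and
   conversion to centreline graphs with a radius at every node, yielding
   fiber length density ($m/mm^3$) and diameter samples.
3. **Stereology**: optical-fractionator neuron counts with a coefficient of
   error, and Cavalieri point-counting volumes.
4. **Morphometry**: length per neuron with ratio confidence intervals,
   log-binned diameter histograms, bin-wise difference CIs, thin/thick
   diameter ratios, ANOVA batteries, robust log–log fits.
5. **Scaling analysis**: $\pm 1/3$ power-law predictions, the
   rectified-difference optimal scale-factor scan, region-of-influence
   equivalent diameters, and module-multiplicity estimates.
6. **Synthetic data**: phantoms with exact ground truth that make every one
   of the stages testable without any acquired tissue.

Because no raw probe stacks are publicly deposited for this kind of study,
the synthetic phantoms are first-class citizens: they define the conditions
under which the pipeline's accuracy claims are verified.

## The phantom generator

`generateFiberStack()` renders a probe volume from a `PhantomSpec`:

* **Centrelines** are persistent random walks with 1-µm steps and a
  per-step bend angle drawn uniformly in $[0, \theta_{\max}]$ (default
  $20^\circ$), giving controllable tortuosity with exact, analytic arc
  length. Walks reflect at the walls of a domain inset by the fiber radius,
  so every tube lies wholly inside the volume; boundary points are inserted
  into the polyline so the arc length stays exact through reflections.
  Fibers are appended (the last one truncated) until the summed length
  *equals* the target `lengthDensity × volume`, so the ground truth is
  exact rather than approximate.
* **Diameters** are log-normal (median 0.8 µm, log-sd 0.35 by default — a
  generator choice: the true family of DCN fiber calibres is not
  established), constant along a fiber.
* **Rasterization** marks a voxel as foreground when its centre lies within
  the local radius of the centreline (implemented as a union of balls along
  a densely resampled centreline).
* **Somata and lipofuscin-like speckles** are rendered at fiber intensity
  but recorded in masks, exercising mask subtraction exactly the way manual
  soma/lipofuscin removal is used on real probes.
* **Depth attenuation** multiplies intensity by $e^{-z/z_0}$, emulating
  limited antibody penetration; **blur** is an axis-wise Gaussian; **noise**
  adds a Gaussian component plus a signal-proportional variance term.
  Order: attenuate, blur, add noise, clip to [0, 255], quantize — mimicking
  the detector chain. A fixed spec and seed reproduce the stack
  bit-identically.

What the phantoms do *not* emulate: realistic point-spread functions (no
optics model beyond Gaussian blur, and consequently no deconvolution step),
spatially varying background, fiber-diameter variation along a fiber, and
multi-channel imaging. Passing the recovery tests therefore demonstrates
correctness of the measurement chain under idealized optics, not performance
on arbitrary tissue.

## Imaging choices

* **Edge-preserving smoothing** is Perona–Malik-style 3D diffusion with
  exponential conductance ($K = 10$ intensity units) and the stable step
  $dt = 1/7$ for a 6-neighbour stencil. The published processing chain names
  a proprietary tool's parameters (time-stop 50 for MAP2, 100 for PCP2, step
  size 5); we map them to `timeStop / stepSize` diffusion iterations, the
  closest published analogue. Gaussian filtering with a fixed 5×5×5 voxel
  kernel and $\sigma = 1$ follows.
* **Thresholds are constants per stain** (25 MAP2 rat, 40 MAP2 monkey, 80
  PCP2) — deliberately not adaptive, since threshold choice trades merged
  neighbouring dendrites against lost thin fibers. The companion audit
  (`auditSubthreshold()`) quantifies the lost fraction against ground truth
  or annotation.
* **Penetration window**: analysis is restricted to the contiguous run of
  optical slices, anchored at the brightest slice, whose per-slice maximum
  is at least 95.4% of the whole-probe maximum. Whether the original
  criterion was contiguous is not documented; we chose contiguity because a
  non-contiguous window would make the analyzed volume ambiguous. The
  window never grows when the level rises.

## Skeletonization choices

* **Distance map**: exact anisotropic Euclidean distance transform
  (lower-envelope algorithm) instead of a chamfer approximation — exactness
  simplifies every downstream tolerance. The radius read off the map is the
  distance to the nearest background voxel centre: on digitized tubes the
  inclusion rule erodes the digital object by roughly the half-voxel the
  background-centre distance overshoots, so the raw value estimates the
  continuous radius well (verified to max(0.1 µm, 1 voxel) on tubes).
  One-voxel-thin structures get half the smallest voxel edge, the natural
  radius of an isolated voxel.
* **Thinning** removes *simple points* — deletions that preserve both
  object (26-connected) and background (6-connected) topology, tested via
  the two topological numbers in the 3×3×3 neighbourhood — in order of
  increasing distance-map value, so erosion proceeds from the surface
  inwards; points with at most one object neighbour (curve endpoints) are
  kept. Two engineering details matter:
  * deletion proceeds in six directional sub-iterations per pass, and
  * priority ties are broken by a deterministic sub-voxel hash jitter.
  Without either, sequential erosion "zips" through axis-aligned structures
  with an even-width core (a 2×2-voxel ridge can be consumed end-to-end —
  a failure mode that also makes a well-known reference implementation of
  3D thinning return an empty skeleton for a 2×2×26 bar).
* **Graph conversion** traces 26-connected chains between terminals
  (branch voxels become vertices of degree ≥ 3, cycles are allowed), lightly
  smooths each chain (moving average, window 3, one pass — enough to damp
  voxel-grid zigzag without cutting corners), resamples at 0.5-µm arc
  spacing keeping both ends, and interpolates the distance map trilinearly
  at each node. Two corrections keep length estimates unbiased:
  * **tip extension**: the medial axis of a capped tube ends one radius
    short of the cap, so each degree-1 end is extended outward by its local
    radius;
  * **short-chord collapse**: where two tubes touch or cross, thinning
    leaves ladder-like double connections; chords closing cycles shorter
    than 3 µm are removed (via a minimum spanning tree; longer cycles are
    genuine topology and kept).
* **Particle filter**: components whose maximal path length is below
  0.25 µm are discarded; exactly 0.25 µm is kept (the cutoff excludes
  strictly smaller spurious particles). The cutoff is interpreted as an
  extent (not a radius) criterion.
* **Shrinkage**: densities are corrected by the measured-thickness /
  block-advance fraction (e.g. 22/60 ≈ 0.37); the windowed probe volume is
  divided by this factor along z, so corrected density = uncorrected ×
  fraction.

Verified accuracy under the phantom conditions (30×30×15 µm probes at
0.25-µm isotropic voxels, 5 m/mm³, 1-µm median diameter): total length
within 5% of truth noise-free and within 10% at SNR ≥ 5 through the full
smoothing–thresholding–skeletonization chain; radii within one voxel.

## Stereology choices

The optical fractionator estimates $N = \Sigma Q / (ssf \cdot asf \cdot
hsf)$ from systematic-random counting frames (left and bottom frame edges
exclude — the standard unbiased counting rule), dissector height inside
symmetric guard zones, and every $1/ssf$-th section. Defaults follow the rat
design (50×50 µm frames on a 200×200 µm grid, every 4th section, 14-µm
dissector, 2-µm guards, 23.4-µm measured sections). The coefficient of
error uses the Gundersen–Jensen formulation with smoothness class $m = 1$
(the variant in wide stereological use; the original analysis states only
"CE below 0.05", so the class is our choice). Cavalieri volumes follow
$V = \Sigma P_i \cdot a_F \cdot T / ssf$. Unbiasedness is verified by
averaging 200 systematic-random placements against a known population
(within 5% of N = 10,000).

## Morphometry and scaling choices

* **Diameter histograms** use 32 natural-log-spaced bins spanning 0.2–4 µm
  (a configuration default covering the observed calibre range), normalized
  per species × nucleus group. A diameter exactly on a bin edge belongs to
  the lower bin. Across-probe per-bin means, sds and probe counts feed the
  bin-wise difference CI
  $\mu_1 - \mu_2 \pm t_{1-\alpha/2,\,n_1+n_2-2}\sqrt{2\,\mathrm{MSE}/n_{12}}$
  with $\mathrm{MSE} = (sd_1^2 + sd_2^2)/2$ and the harmonic joint size
  $n_{12} = 2/(1/n_1 + 1/n_2)$; its empirical coverage is verified at
  ~99% under Gaussian simulation. The per-bin $n$ defaults to probes per
  group (recorded in the object); fibers per bin would be the alternative
  reading.
* **Ratio CIs** for length per neuron use MOVER (method of variance
  estimates recovery), recovering the ratio CI from the t-based CIs of
  numerator and denominator.
* **Thin/thick diameter ratio** uses the log-bin containing the reference
  diameter (rat presets 0.35/1.35 µm; macaque 0.41/2 µm — the published
  correspondence, asserted rather than derived); it is invariant to overall
  renormalization.
* **Robust fits** use iteratively reweighted least squares with the
  bisquare psi (the same family as the robust-fit routine used in the
  original analysis) on log10–log10 data.
* **Scale-factor scan**: candidate factors 0.80–2.00 in steps of 0.01
  (bracketing the observed optimum with finer resolution); the reference
  sample is multiplied by each factor, re-binned onto the target's log
  bins, and the absolute (rectified) bin-wise difference of normalized
  proportions is summed over all bins; ties resolve to the smaller factor.
  Restricting the objective to a sub-range of bins would be an alternative
  reading of the published figure; summing over all bins is the default
  here. Planted factors in {0.9, 1.2, 1.35, 1.5} are recovered within one
  grid step at $n = 10^5$.
* **3D region-of-influence**: the tip cloud is projected onto its
  principal (best-fit) plane and the equivalent-circle diameter
  $2\sqrt{A/\pi}$ is taken from the 2D hull of the projection — this makes
  3D estimates directly comparable with the 2D tip-polygon convention (the
  two agree statistically in published data; the projection convention is
  ours). Volume ratios entering the $1/3$-power predictions are user
  inputs: the underlying per-nucleus volumes are not published.

## Degenerate inputs and numerical conventions

* Coordinates are voxel-centred: 0-based index $i$ maps to
  $(i + 0.5)\,\times$ voxel size; the third array axis is z.
* All-zero stacks are rejected by the penetration window (no signal); empty
  skeletons yield zero length and density 0.
* Chain tracing breaks ties lexicographically and is deterministic; the
  thinning jitter is a pure function of the voxel index.
* Self-intersecting or collinear tip polygons are rejected, not repaired.
* An empty thick-diameter bin flags the ratio as undefined (NA) rather than
  returning infinity.

## Problem sizes

The validation suite uses 30×30×15 µm phantoms at 0.25-µm voxels (864,000
voxels, a handful of fibers), $10^5$-point diameter samples, populations of
10,000–60,000 stereology points, and 4,000–5,000-replicate simulations for
CI coverage — sizes chosen so the complete suite documents every claim while
running in well under an hour on a single core. Larger probes only improve
the statistics; the estimators themselves are resolution- and
size-independent.

## A worked end-to-end example

```{r example, eval = FALSE}
spec <- PhantomSpec(extent = c(30, 30, 15), voxelSize = c(0.25, 0.25, 0.25),
                    lengthDensity = 5, diameterMedian = 1, diameterLogSd = 0.1,
                    blurSigma = c(0.2, 0.2, 0.3), noiseGaussianSd = 20,
                    seed = 1)
ph <- generateFiberStack(spec)
sm <- preprocessStack(ph$stack, PreprocessParams("MAP2_RAT"))
bin <- segmentStack(sm, 40)
sk <- reconstructSkeleton(bin)
lengthDensity(sk, ph$stack, shrinkage = shrinkageFactor(60, 22))
totalLength(ph$truth)   # ground truth to compare against
```

## Known limitations

* The pipeline measures the fiber population; it does not classify fibers
  (dendrite vs axon is carried by the stain label) and does not bridge
  gaps where staining fails.
* The diffusion mapping of the proprietary edge-preserving smoother is an
  approximation; only its parameter *ratio* (iteration count) is mapped.
* Length recovery degrades for fibers thinner than ~3 voxels; the generator
  flags sub-voxel median diameters, and recovery there is not guaranteed.
* The literature compilation behind cross-species density regressions is
  external data; the regression operation is validated on synthetic
  power-law data only.
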