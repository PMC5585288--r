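# WireScale

Quantitative analysis of neural "wiring" — fiber length density, fiber
diameters, neuron numbers and their allometric scaling — from 3D confocal
stacks of fiber-like immunostaining. The package targets quantitative
neuroanatomists comparing network architecture across species (the
motivating case: dendrites and Purkinje-cell axons of the deep cerebellar
nuclei in rodents vs primates), and anyone who needs a tested, fully
synthetic-data-validated implementation of the underlying measurement chain.

## What it computes

* **3D reconstruction**: edge-preserving smoothing + Gaussian filtering,
  fixed-threshold segmentation, exact Euclidean distance maps,
  topology-preserving 3D thinning, and conversion to a fiber skeleton graph
  with nodes every 0.5 µm carrying the local radius. From the skeleton:
  length density `Dl_dens = L / V` (m/mm³, with antibody-penetration
  windowing and tissue-shrinkage correction) and per-probe diameter
  samples.
* **Design-based stereology**: optical fractionator
  `N = ΣQ / (ssf · asf · hsf)` with the Gundersen–Jensen coefficient of
  error (m = 1), and Cavalieri volumes `V = ΣPᵢ · aF · T / ssf`.
* **Morphometry**: length per neuron `Dl_neu = Dl_dens / N_V` with MOVER
  ratio confidence intervals; natural-log-binned, group-normalized diameter
  histograms; bin-wise difference CIs
  `µ₁ − µ₂ ± t₍₁₋α/2, n₁+n₂−2₎ · √(2·MSE/n₁₂)` with
  `MSE = (sd₁² + sd₂²)/2`, `n₁₂ = 2/(1/n₁ + 1/n₂)`; thin/thick
  diameter-count ratios; two-way ANOVA batteries; robust (bisquare) log–log
  regression.
* **Scaling analysis**: power-law predictions `ŷ = y · (V₂/V₁)^(1/3)`
  (densities: exponent −1/3); the rectified-difference scan that finds the
  diameter scale factor minimizing `Σ_bins |p_target − p_scaled(f)|`;
  dendritic region-of-influence equivalent diameters
  `d_ROI = 2·√(area/π)` from 2D tip polygons or 3D tip clouds; and module
  multiplicity `(d_pred/d_meas)³` implied by a region-of-influence deficit.
* **Synthetic phantoms**: fiber stacks with exact ground-truth centrelines
  and radii, point populations, paired diameter samples and tip polygons —
  every stage above is validated against them.

## Worked example

Generate a noisy phantom probe (30 × 30 × 15 µm at 0.25-µm voxels, target
density 5 m/mm³), run the full reconstruction, and compare against ground
truth:

```r
library(WireScale)
spec <- PhantomSpec(extent = c(30, 30, 15), voxelSize = c(0.25, 0.25, 0.25),
                    lengthDensity = 5, diameterMedian = 1, diameterLogSd = 0.1,
                    blurSigma = c(0.2, 0.2, 0.3), noiseGaussianSd = 20,
                    seed = 1)
ph  <- generateFiberStack(spec)
sm  <- preprocessStack(ph$stack, PreprocessParams("MAP2_RAT"))
bin <- segmentStack(sm, 40)
sk  <- reconstructSkeleton(bin)
sk
#> FiberSkeleton: 141 nodes, 139 edges, 2 components, total length 68.31 um
lengthDensity(sk, ph$stack, shrinkage = shrinkageFactor(60, 22))
#>   totalLength volumeUm3 correctedVolumeUm3  density correctedDensity
#> 1    67.60316     13500           36818.18 5.007641         1.836135
totalLength(ph$truth)
#> [1] 67.5
```

The reconstruction recovers the true 67.5 µm of fiber to within 0.2%
(`density` 5.008 vs the 5 m/mm³ target); `correctedDensity` additionally
applies the 22/60 section-shrinkage fraction. Downstream, the scaling
operations work on such probe records:

```r
s <- generateDiameterSamples(0.8, 0.35, 1e5, scaleFactor = 1.35, seed = 42)
scaleFactorScan(s$A, s$B)
#> scale-factor scan: 121 factors in [0.80, 2.00], optimum 1.35
moduleMultiplicity(850, 190)
#>   linearFactor volumetricMultiplicity
#> 1     4.473684               89.53565
lengthPerNeuron(28.3, 1e4)$ratio
#> [1] 2.83
```

A planted 1.35 diameter scale factor is recovered exactly; an 850 µm
predicted vs 190 µm measured region-of-influence diameter implies ~4.5-fold
linear hypometry and room for ~90× more modules.

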