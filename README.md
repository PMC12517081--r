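# flimScaffold

Quantitative image analysis of macrophage metabolic state and morphology on
microstructured (two-photon polymerized) scaffolds, built around NAD(P)H
fluorescence lifetime imaging (FLIM).

Macrophages polarize between a pro-inflammatory, glycolytic M1 phenotype and
an anti-inflammatory, oxidative M2 phenotype. NAD(P)H FLIM reads this out
label-free: free NAD(P)H has a short lifetime (~0.42 ns), enzyme-bound
NAD(P)H a long one (~2.0–3.0 ns), and the balance between them tracks
glycolysis versus oxidative phosphorylation. This package implements, for
researchers analysing such experiments (and for validating analysis choices
on fully synthetic data):

* **TCSPC decay fitting** — bi-exponential iterative reconvolution against a
  Gaussian instrument response function (IRF), periodically folded over the
  80 MHz repetition window:
  `I(t) = IRF ⊛ [α₁ exp(−t/τ₁) + α₂ exp(−t/τ₂)] + C`,
  with Poisson weighting, optional fixing of the free-NAD(P)H lifetime at
  0.42 ns, the amplitude-weighted mean lifetime
  `τ_mean = (α₁τ₁ + α₂τ₂)/(α₁ + α₂)`, and a reduced χ² < 1.2 fit gate.
* **Phasor analysis** — the fit-free transform
  `g = Σ I(t)cos(ωt)/Σ I(t)`, `s = Σ I(t)sin(ωt)/Σ I(t)` (ω = 2πf),
  calibration against a mono-exponential reference dye (fluorescein, 4.0 ns),
  iterated 3×3 median filtering, per-substrate intensity thresholds
  (50/120/150 counts), phasor-distance exclusion of scaffold
  autofluorescence, and cloud centroids.
* **Morphometry** — cell area, circularity `4π·area/perimeter²`, and maximum
  Feret diameter (convex hull + rotating calipers), with median-ratio
  percent-variation summaries.
* **Marker quantification** — background-subtracted iNOS/Arg1 ROI
  intensities normalized to the unpolarized M0 condition, percentage
  induction efficiency, and normality-gated statistics (Shapiro-Wilk →
  one-way ANOVA + Tukey, or Kruskal-Wallis + Dunn).
* **A synthetic-scene generator** — scaffold pore lattices (e.g. 50×50×20 µm³
  pores filling 500×500×40 µm³ = 200 pores), star-polygon cell masks,
  Poisson TCSPC stacks at ~10³ photons/pixel, and marker channels — all with
  exact ground-truth sidecars, so every stage can be validated without
  microscope data.

## Worked example

Simulate one M1-like ROI decay (free/bound NAD(P)H mixture, bound intensity
fraction 0.3, 10⁵ photons) and fit it with the short lifetime fixed:

```r
library(flimScaffold)
acq  <- AcquisitionConfig(nBins = 256L)        # 80 MHz, T = 12.5 ns
cell <- defaultPhotophysics("M1")$cell
h    <- simulateRoiDecay(cell, acq, totalPhotons = 1e5, seed = 42)
fitBiexponential(h, fixTau1 = 0.42)
#> BiExpFit: tau1 = 0.42 ns, tau2 = 2.47 ns, a1 = 8202, a2 = 583.7, C = 0
#>   tau_mean = 0.5562 ns, reduced chi2 = 1.232, converged (fixed: tau1)
```

The fitted bound lifetime (2.47 ns vs the generating 2.5 ns) and the
recovered bound intensity fraction `boundFraction(fit)` = 0.295 (vs 0.3)
show the reconvolution fit recovering the generator's ground truth; the
short `τ_mean` = 0.56 ns is the glycolytic (M1-like) signature — unpolarized
M0 cells sit near 0.72 ns and oxidative M2 cells near 1.0 ns under the
default photophysics.

A full experiment (3 substrates × 3 phenotypes: scenes, stacks, fits,
calibrated phasor centroids, marker quantification, statistics) runs with:

```r
res <- runExperiment(demoRunConfig(seed = 1))
head(res$tauTable); res$centroidTable; res$efficiencyTable
```

## Documentation

The methods vignette (`vignettes/flim-scaffold-methods.Rmd`) describes the
decay model and its numerical choices, the phasor workflow, what the
synthetic scenes do and do not emulate, and the package's design decisions.
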