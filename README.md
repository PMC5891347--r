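# DomainDynamics

Essential-dynamics and two-state conformer analysis of multidomain protein
trajectories at C-alpha resolution.

Many two-domain proteins — the motivating case is the Hsp90 co-chaperone
cyclophilin 40, an N-terminal peptidyl-prolyl-isomerase domain tethered to a
C-terminal TPR helix bundle by a charged linker — interconvert between an
*extended* and a *compact* conformer distinguished by the distance between
the two domain centroids. DomainDynamics provides the complete analysis
pipeline a structural-bioinformatics practitioner needs to characterize such
ensembles from molecular-dynamics output, plus a seeded synthetic generator
that produces two-state trajectories with known ground truth for validating
every estimator.

## What it computes

* **Superposition and essential dynamics.** Kabsch least-squares rigid
  superposition of every frame onto a fixed reference; the 3N x 3N
  positional population covariance of the C-alpha configuration vectors,
  C = ⟨(R − ⟨R⟩)(R − ⟨R⟩)ᵀ⟩; its eigendecomposition
  C = Σᵢ σᵢ pᵢ pᵢᵀ into principal components ordered by descending
  variance; per-frame projections sᵢ(t) = pᵢ · (R(t) − ⟨R⟩); and
  free-energy surfaces by Boltzmann inversion, A(R) = −kT ln f(R) + const.
* **Geometric descriptors.** Interdomain C-alpha centroid distance;
  salt-bridge distances between side-chain O and N centers of mass; helix
  axes (per-frame PC1 of helix C-alpha coordinates, oriented N→C) and
  interhelix angles θ = atan2(‖a×b‖, a·b); per-residue RMSF with
  B = (8π²/3)·RMSF²; and the coordination-shell radius
  R_g = (Σⱼ R²ᵢⱼ / nᵢ)^½ over neighboring C-alphas within a cutoff, a
  compactness metric.
* **Comparative maps.** Trajectory-averaged residue-pair distance matrices
  and distance-change maps between systems (classified increase/decrease
  windows); normalized dynamic cross-correlation matrices from the 3x3
  covariance blocks and anticorrelation-difference maps; per-domain-aligned
  intradomain correlation and B-factor analysis.
* **State classification.** Histogram/KDE distribution estimates, peak
  finding with topographic prominence, extended/compact frame labeling at
  the between-peak density minimum, compact-population fractions and
  population free-energy differences ΔA = −kT ln(f_ext/f_comp).
* **Synthetic two-state generator.** A two-domain C-alpha toy protein
  (globular domain, extended linker, ideal-helix bundle, proxy side-chain
  atoms) whose frames switch basins by a per-frame Markov chain with known
  stationary occupancy, plus iid Gaussian positional noise — every
  downstream estimator can be checked against analytic ground truth.

## Worked example

```r
library(DomainDynamics)

## a two-state ensemble with known ground truth: 30% compact at stationarity
spec <- SyntheticSpec(nFrames = 14400, pEC = 0.003, pCE = 0.007,
                      noiseSigma = 1.5, seed = 1)
run  <- generateTwoStateTrajectory(spec)
rg   <- domainRanges(spec)

d  <- interdomainDistance(run$trajectory, rg$domain1, rg$domain2)
dd <- estimateDistribution(d, "histogram", width = 0.5)
st <- classifyStates(d, dd)
st
#> StateAssignment: 14400 frames, 34.9% compact, boundary 35.73, peaks [43.73, 34.23]

populationFreeEnergyDifference(st, kT = thermalEnergy(310))
#> [1] -0.3836057
```

The classifier finds the two peaks near the generator's basin distances
(43.8 and 34.0 Å), places the state boundary at the density minimum between
them, and recovers a compact fraction of 34.9% for this seed — within
sampling error of the chain's stationary fraction
p_EC/(p_EC+p_CE) = 30% (a single 14 400-frame chain with these slow
switching rates has a standard error of ~5 percentage points). ΔA is
reported for the compact→extended direction, so the negative value says the
minority compact basin sits 0.38 kcal/mol above the extended one at 310 K.

The full pipeline (PCA scores, free-energy surface, descriptor series,
distributions, state summary, fluctuation and shell profiles, matrices) is
driven by `runSynthesize()` / `runAnalyze()` / `runCompare()`, each writing
TSV outputs with parameter headers and a JSON run manifest; a thin
command-line wrapper lives in `inst/scripts/domaindynamics.R`.

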