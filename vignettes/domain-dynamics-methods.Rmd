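---
title: "Methods: essential dynamics and two-state conformer analysis"
author: "DomainDynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: essential dynamics and two-state conformer analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DomainDynamics)
```

DomainDynamics analyzes coordinate ensembles of two-domain proteins at
C-alpha resolution. This vignette is the package's account of the methods:
the models and their assumptions, the parameters that matter, what the
synthetic generator does and does not emulate, and the numerical choices
made where the design was genuinely open.

## Superposition and essential dynamics

Every frame is superposed onto a **fixed reference structure** (typically
the crystal structure) by the Kabsch algorithm: the proper rotation
(det = +1) and translation minimizing the least-squares deviation of the
selected C-alpha atoms. Alignment is single-pass — frames are never
iteratively re-aligned onto an evolving mean — so the reference frame of
all downstream quantities is unambiguous. Degenerate (collinear)
selections are rejected because the rotation is then not unique.

From the aligned frames the package builds the configuration vector
$\mathbf{R}(t) \in \mathbb{R}^{3N}$ of the selected C-alphas and the
**population covariance**

$$C \;=\; \langle (\mathbf{R}-\langle\mathbf{R}\rangle)
                 (\mathbf{R}-\langle\mathbf{R}\rangle)^\mathsf{T} \rangle ,$$

dividing by the number of frames $T$, not $T-1$: the object is an ensemble
average, and at MD sample sizes (thousands of frames) the distinction is
negligible; it is documented because it is visible in small-$n$ tests.
Eigendecomposition $C = \sum_i \sigma_i\, \mathbf{p}_i \mathbf{p}_i^\mathsf{T}$
yields principal components ordered by descending variance $\sigma_i$
(Å²). Numerically: eigenvalues below $-10^{-8}\,\mathrm{tr}(C)$ are an
error (the input was not a covariance), small negative values are clamped
to zero, and each component's sign is fixed so that its largest-magnitude
entry is positive — the decomposition leaves the sign free, and a fixed
convention makes projections reproducible across platforms.

Projections $s_i(t) = \mathbf{p}_i\cdot(\mathbf{R}(t)-\langle\mathbf{R}\rangle)$
are in Å. Because the components are orthonormal, projecting onto all 3N
components is an isometry, and the score variance along $\mathbf{p}_i$
equals $\sigma_i$ — both identities are verified in the test suite.

**Free-energy surfaces** are Boltzmann inversions of the score density:
$A = -kT\,\ln f$, shifted so the minimum finite energy is zero, with
$k = 0.0019872$ kcal/mol/K and the temperature from the configuration
(default 310 K, so $kT = 0.616$ kcal/mol). One- and two-dimensional
histograms use 50 bins per axis by default; empty bins are reported as
infinite energy rather than capped, because a cap silently fabricates a
sampling statement the data do not support.

## Geometric descriptors

* **Interdomain distance**: the Euclidean distance between the unweighted
  C-alpha centroids of the two domains, per frame. It is invariant under
  global rigid motion, so it is computed on unaligned frames.
* **Salt-bridge distance**: distance between the center of mass of the
  acidic side-chain oxygens (OD1/OD2/OE1/OE2) and of the basic side-chain
  nitrogens (NZ/NH1/NH2/NE/ND1/NE2). Since each set is a single element,
  mass weighting reduces to the arithmetic mean. A summary threshold of
  4.5 Å ("formed") is used only in optional summaries and always written
  into output headers.
* **Helix axis and interhelix angle**: the axis is the first principal
  component of the helix's C-alpha coordinates *within one frame*,
  oriented N→C; the angle between two axes of the same frame is
  $\theta = \operatorname{atan2}(\lVert \mathbf{a}\times\mathbf{b}\rVert,
  \mathbf{a}\cdot\mathbf{b})$, the numerically stable equivalent of
  arccos of the dot product, in $[0^\circ, 180^\circ)$. Both axes are
  always taken from the same frame because angles are only
  rotation-invariant within a frame. A finite ideal helix's PC1 tilts
  slightly off the true screw axis (the phase-height cross moment decays
  with length: ~2° at 15 residues, <1° beyond ~26) — relevant when
  interpreting absolute axis directions, irrelevant for angle
  *distributions*. Near-degenerate cases ($\sigma_1 \approx \sigma_2$)
  raise a warning.
* **RMSF and B-factors**: $\mathrm{RMSF}_i = \langle |\mathbf{R}_i -
  \langle\mathbf{R}_i\rangle|^2 \rangle^{1/2}$ on aligned frames, and
  $B_i = (8\pi^2/3)\,\mathrm{RMSF}_i^2$. Domain averages are taken over
  the *fluctuation* (Å), not over $B$ — the two orderings differ and the
  fluctuation average is the one used for domain comparisons.
* **Coordination-shell radius**: for residue $i$, with neighbors $j$ the
  other C-alphas within a cutoff, $R_{g,i} = (\sum_j R_{ij}^2/n_i)^{1/2}$;
  the protein average runs over residues with at least one neighbor.
  The cutoff is a genuinely open parameter: it is not derivable from the
  metric's definition, so the package defaults to 10 Å — a value that
  yields per-residue radii in the 6–7 Å range on globular folds — keeps it
  configurable, and reports it in every output. By default the radius is
  computed per frame and averaged over frames; computing it on the mean
  structure is available as a flag (`perFrame = FALSE`) and differs where
  basin hopping blurs the mean.

## Comparative analysis

Mean distance matrices average the instantaneous C-alpha pair distances
over frames (no alignment needed). Distance-change maps classify
$\Delta_{ij} = d_{ij}^{\mathrm{mut}} - d_{ij}^{\mathrm{wt}}$ as
*decrease* in $[-10, -4]$ Å and *increase* in $[4, 10]$ Å, both ends
inclusive. The windows are read strictly by default — changes beyond
±10 Å fall out of both classes — with a `saturating` mode that treats the
outer bound as a saturation limit; the strict reading matches the printed
window definition, and the flag exists because the treatment of larger
changes is ambiguous.

Cross-correlation matrices use the standard dynamic cross-correlation
normalization: $c_{ij} = \langle \Delta\mathbf{R}_i\cdot\Delta\mathbf{R}_j
\rangle / (\langle \Delta\mathbf{R}_i^2\rangle \langle
\Delta\mathbf{R}_j^2\rangle)^{1/2}$, computed from the 3×3 residue blocks
of the covariance. This is the universally assumed convention behind
"anticorrelated residues"; zero-variance residues are flagged undefined
rather than silently dropped. Anticorrelation-difference maps consider
only pairs anticorrelated ($c < -0.1$ by default) in at least one system
and require the change to exceed a margin (default 0.05) before labeling
a pair less/more anticorrelated; both parameters are config-exposed and
written into output headers because the underlying dot-plot definition
fixes neither.

Whole-molecule correlation maps use the global crystal-structure
alignment; **intradomain** analysis re-aligns every frame on the domain's
own C-alphas before computing the domain covariance, removing the
domain's rigid-body motion so that the diagonal gives internal
fluctuations and the off-diagonals internal correlations.

## State classification

Descriptor distributions are estimated on a regular grid spanning the
data ± 3 widths. The default estimator is a histogram with 0.5 Å bins for
distances and 2° bins for angles — the granularity at which bimodality of
interdomain-distance distributions is conventionally displayed — with a
Gaussian KDE (Silverman bandwidth) as the cross-checking alternative.
Peaks are local maxima (plateaus collapse to their center) filtered by
topographic prominence, defaulting to 5% of the maximum density; a
completely flat density has no peaks.

With two peaks, the state boundary is the density minimum between them,
frames below the boundary are *compact* (the compact form is, by
definition, the one with the smaller interdomain distance) and ties go to
*extended* (documented, arbitrary). With one peak, all frames belong to
the single observed state — `extended` by default, since the extended
form is the crystal-like state — and the absent state's fraction is 0.
More than two peaks is an error prompting a wider bandwidth rather than a
silent guess. No procedure for "% compact" is canonical; the
density-minimum boundary is the simplest defensible estimator, and the
boundary value is reported alongside every fraction so the choice is
auditable. The population free-energy difference is
$\Delta A(\mathrm{compact}\to\mathrm{extended}) =
-kT\ln(f_{\mathrm{ext}}/f_{\mathrm{comp}})$, infinite when a state is
unpopulated.

## The synthetic generator: what it emulates, and what not

`SyntheticSpec()` defines a C-alpha toy protein: a globular domain
(3.8 Å cubic lattice), an extended linker (3.5 Å rise), and an
antiparallel bundle of ideal α-helices (2.3 Å radius, 1.5 Å rise/residue,
100°/residue). Designated linker residues carry two proxy acidic oxygens
(±1.2 Å about a virtual centroid 2.5 Å off the C-alpha) and designated
bundle residues one basic nitrogen (3.5 Å off the C-alpha) — geometry
fixed so salt-bridge center-of-mass distances have closed forms.

Two basin references differ by a rigid translation of domain 2 along the
centroid axis (linker C-alphas re-laid by linear interpolation between
the anchor residues), with defaults of 43.8 Å (extended) and 34.0 Å
(compact) centroid separation. Frames follow a per-frame two-state Markov
chain with switch probabilities $p_{EC} = 0.003$ and $p_{CE} = 0.007$
(stationary compact fraction $p_{EC}/(p_{EC}+p_{CE}) = 0.30$), and
coordinates are the labeled basin reference plus iid isotropic Gaussian
noise, default σ = 1.5 Å, with linker atoms scaled ×3 to emulate the
elevated linker mobility of flexible interdomain tethers. The default
trajectory length is 14 400 frames at a nominal 50 ps/frame (720 ns).

These defaults are the study conditions of the package's acceptance
checks and are not tuned per run. The design is deliberately the simplest
model with analytic ground truth: occupancy is the chain's stationary
fraction, per-basin means converge to the references at rate
$\sigma/\sqrt{n}$, and the noise-induced spread of the interdomain
distance (~0.3 Å for 30-atom domains) is far below the basin separation,
so classification against ground truth is essentially exact.

What the generator does **not** emulate: temporally correlated
within-basin dynamics (noise is white), anharmonic basin shapes,
alignment-induced correlations from overall tumbling (frames are
generated in a common frame), solvent effects, and any physical force
field. Consequently, passing tests demonstrate estimator correctness and
parameter recovery under a known model — they do not demonstrate that a
real trajectory's basins are Gaussian or its kinetics Markovian.

## Numerical choices and degenerate inputs

* Residue numbering is 1-based author numbering; all ranges are inclusive.
* Trajectory time metadata comes from the configuration, never from DCD
  headers (unreliable across writers); frame-count/production-length
  mismatches warn rather than silently proceed.
* Multi-model PDB carries 3 decimals, so its coordinate round-trip
  precision is 5×10⁻⁴ Å; DCD (single-precision) round-trips to ~10⁻⁶ Å.
* Kabsch uses SVD with the determinant correction; the collinearity guard
  triggers when the second singular value falls below 10⁻¹⁰ of the first.
* Histogram grids are regular; the all-identical-values distribution is a
  single occupied bin. KDE densities are renormalized on their grid so
  the discrete integral is exactly 1.
* Ties at the state boundary are assigned extended.
* The analysis pipeline defaults to shared PC axes across systems
  (combined PCA) so projections of different systems are comparable;
  per-system PCA is a configuration flag.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data:
toy proteins of 60–130 residues and trajectories of a few hundred to
14 400 frames, sizes at which every estimator's sampling error is small
relative to its test tolerance while the whole suite executes in well
under a minute on a single core. Oracle-equivalence tests (brute-force
double loops, characteristic-polynomial eigenvalues, 10⁴ random rigid
transforms) use 4–40 atoms, where the oracles are exact and fast.

## Known limitations

* C-alpha only: no all-atom descriptors, hydrogen bonds, SASA or
  secondary-structure assignment (helix ranges come from configuration).
* Two-state classification only; no multi-state clustering or
  hidden-Markov segmentation of the label series.
* The crystal-structure reference check requires the deposited PDB file,
  which must be present locally; it is not bundled.
* Single-chain analysis; multi-chain input requires an explicit chain id.
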