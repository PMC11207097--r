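---
title: "Methods: characterizing fuzzy conformational ensembles"
author: "fuzzyens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing fuzzy conformational ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzyens)
```

# Scope and data model

`fuzzyens` analyzes coarse-grained conformational ensembles of proteins
that combine a folded domain with a long intrinsically disordered region —
the archetype being galectin-3, whose 112-residue N-terminal domain (NTD)
is a Pro-Gly-rich disordered tail attached to the 138-residue carbohydrate
recognition domain (CRD, residues 113–250). The packaged annotation
(`galectin3Domains()`) carries this domain split and the eleven CRD
β-strand ranges (β1 = 118–121 through β11 = 240–249).

An `Ensemble` is an ordered list of conformation frames over a
`BeadTopology`: each residue owns one or more beads with one designated
backbone bead, and a frame holds one 3-vector per bead (nm) plus an
optional cubic box edge. Coordinates are stored in nm internally; PDB files
are treated as Angstrom on disk and converted on read/write. Residue
numbering is 1-based with inclusive domain intervals. Multi-molecule frames
concatenate identical molecules in a fixed order, so molecule identity is
positional.

The package does not generate or read molecular-dynamics trajectories in
binary formats, reconstruct molecules broken across periodic boundaries
(frames are assumed whole per molecule), or model hydration shells and
atomic form factors in scattering. Those steps belong to simulation and
scattering engines; `fuzzyens` starts where they end.

# Synthetic ensembles: what they emulate and what they do not

The generators produce ensembles with the statistical structure the
analyses assume, in place of long coarse-grained MD runs. Every generator
is a pure function of its integer seed.

**Freely jointed chain** (`generateFJC()`): one bead per residue, each bond
an independent uniform direction of fixed length b. The default
b = 0.55 nm is the Kuhn length commonly adopted for disordered proteins.
The FJC is the exact θ-state reference: ⟨R²(s)⟩ = b²s,
⟨Rg²⟩ = b²(n²−1)/(6n), and the end-to-end distance approaches the
Gaussian-chain density. Frames are independent, unlike MD frames.

**Solvent-quality chain** (`generateSolventChain()`): Metropolis Monte
Carlo of a bead-spring chain with stiff harmonic bonds (spring constant
200/b² kT/nm², i.e. bond fluctuations of a few percent of b), a hard core
of radius `excludedRadius`, and for `epsilon < 0` a square well of depth
|ε| kT over `[excludedRadius, excludedRadius + wellWidth)` between beads
two or more bonds apart. The well depth is the solvent-quality knob: it
plays the role that a protein–water interaction rescaling factor plays in
force-field calibration, moving the fitted scaling exponent through
swollen (ν ≈ 0.57 for a purely repulsive chain), ideal (ν = 1/2) and
collapsed (ν < 0.45) regimes. The mapping from ε to any particular
force-field parameter is qualitative by design: only the induced ν matters
to the analyses downstream.

Moves are a mix of single-bead displacements (uniform in a cube of
half-width 0.35 b), crankshaft rotations of interior beads about the axis
through their sequence neighbours, and two pivot moves per sweep that
rotate the whole tail beyond a random bead by a random angle. The pivot
moves are what decorrelate the global chain shape; with the default
60 sweeps between saved frames the lag-one autocorrelation of the radius
of gyration is below 0.2 for a 40-residue chain (checked in the tests;
the decorrelation criterion is the package's own choice — trajectory-style
generators would instead exhibit the frame-to-frame correlation that block
error analysis is designed for). The default burn-in is 2000 sweeps from a
straight-rod start.

**Gaussian end-to-end sampler** (`sampleGaussianDee()`): exact draws from
p(d) = 4d² exp[−(d/ξ)²]/(√π ξ³) as the norm of a 3-vector of independent
zero-mean Gaussians with standard deviation ξ/√2. The component-variance
identity is exact, so no rejection sampling is needed; the mean is 2ξ/√π.

**Two-domain generator** (`generateTwoDomain()`): a rigid bead template
(e.g. `rigidDomainTemplate()`, a jittered compact lattice blob with a
minimum bead separation) copied per frame with a uniformly random rotation
about its tether bead, plus a flexible tail drawn from the solvent chain
and attached one bond length from the tether. The tail is a phantom with
respect to the domain — tail–domain excluded volume is not imposed — so
tail statistics match the plain solvent chain exactly, which is what makes
the generator a usable ground truth. Real mixed-folded proteins do have
tail–domain interactions; tests passing on this generator therefore
validate the *statistics machinery*, not any biological contact pattern.

**Periodic box** (`generateBox()`): molecules drawn from a conformer pool,
randomly rotated and placed uniformly in a cubic box, rejecting placements
with any minimum-image inter-molecular bead distance below the tolerance
(default 0.4 nm, a typical packing tolerance). Default box edge 20 nm.
Because placements are independent per frame, there is no translational
diffusion; cluster *time series* from this generator are i.i.d. sequences,
unlike MD, and only their marginal histograms are meaningful.

**Reference scattering curves** (`generateReferenceSAXS()`): an affine
transform a·I(q) + b of a model profile plus Gaussian noise with standard
deviation `noiseLevel·|a·I(q)|`, with σ(q) set to exactly that value — so
χ² of the generating model against its own output is 1 in expectation.

# Size metrics and block error analysis

`radiusOfGyration()` is the RMS distance of beads from their centroid,
unweighted by default: coarse-grained beads lack canonical masses, and an
optional weights argument covers mass- or electron-weighted conventions.
`maxDiameter()` is an exhaustive O(n²) pairwise maximum — frames are
desk-scale, and exactness beats a convex-hull shortcut. `endToEnd()` is
the distance between the backbone beads of the first and last residues.

`blockError()` estimates the standard error of the mean of a correlated
series from the standard error of contiguous block means, reported at the
plateau (largest block size by default). Default block sizes are powers of
two up to n/32, so the plateau estimate still averages ≥ 32 blocks; the
series must be at least four times the largest block. For i.i.d. data the
plateau reproduces σ/√n; for an AR(1) process with autocorrelation φ it
approaches (σ/√n)·√((1+φ)/(1−φ)) once blocks exceed the correlation time
(both are asserted in the tests, at 20% and 30% respectively — the AR(1)
plateau is biased low by O(τ/blocksize)). Histograms default to 50
equal-width bins over the observed range and are normalized to integrate
to 1.

# Polymer scaling and the theta point

`scalingCurve()` averages inter-residue distances over frames and over all
residue pairs at each sequence separation, within one domain. Two
conventions are configurable because the literature uses both and the
choice matters quantitatively:

* **averaging**: arithmetic mean of distances, or RMS. For an ideal chain
  the RMS obeys R(s) = b√s exactly, while the arithmetic mean is smaller
  by the Maxwell factor √(8/3π) ≈ 0.921 (asymptotically); tests and the
  acceptance analyses use RMS so that closed forms hold.
* **residue distance**: minimum bead–bead distance (the natural partner
  of the contact definition) or backbone–backbone distance (the natural
  partner of polymer theory). Defaults are arithmetic mean with
  minimum-bead distances, the literal trajectory-analysis convention.

`fitFlory()` fits R(s) = b·s^ν by nonlinear least squares on the (s, R)
scale (not log–log, which would reweight the residuals), with start values
from a log–log regression. b is fixed at 0.55 nm by default and fitted
when `bFixed = NA`. The fit uses s ≥ 2 by default: the bonded pair's
distance is fixed by geometry, not chain statistics. ν is constrained to
(0, 1).

`thetaScan()` smooths scan points (control, ν) with isotonic regression in
the dominant direction followed by a monotone (Hyman-filtered) cubic
interpolant — the scan is physically monotone, and an unconstrained spline
could manufacture spurious crossings from noise. The θ point is the root
of ν = 1/2 on the smoothed curve, found by bisection to 10⁻¹⁰; if 1/2 is
not bracketed the scan honestly reports no crossing rather than
extrapolating.

`fitGaussianDee()` fits the Gaussian-chain density to a 50-bin normalized
histogram over [0, max sample], keeping empty bins at zero density, and
reports the squared Pearson correlation between histogram and fitted
densities at the bin centres. The R² ≥ 0.98 regime marks
Gaussian-chain-like statistics; well-separated bimodal mixtures fall below
0.9. A histogram with fewer than two occupied bins is rejected as
degenerate.

# Contact statistics

A residue pair is in contact when any bead of one residue is within
0.7 nm of any bead of the other. Within a molecule, pairs (i, i+1),
(i, i+2), (i, i+3) are excluded; across molecules every pair is eligible
and distances use the minimum-image convention on the cubic box. Minimum
image is equivalent to re-whole-ing the system for contact detection as
long as each molecule is stored whole, which the data model requires.

`contactProbabilityMap()` counts contact frames over total frames. With
several molecules, intra-molecular probabilities average over molecules
(each molecule-frame is a sample), and inter-molecular probabilities are
union events over molecule pairs, indexed by per-molecule residue numbers.
Per-pair errors are block errors over contiguous frame blocks (10 by
default), and the per-block frequencies are retained.

`domainProfile()` reports union events: the probability that residue i
touches ≥ 1 residue of a domain, that any residue of a β-strand does, and
(inter scope) that any D1–D2 cross-molecule contact exists in a frame.
Union probabilities dominate the per-pair maximum, which the tests assert
exactly.

`compareMaps()` runs, per residue pair, a one-way ANOVA with the two
ensembles' block means as replicates, flagging pairs below each p-value
threshold that also differ by more than `minDelta` (default 0.001) in
probability. The replicate structure of a published ANOVA on contact maps
is rarely stated; block means are this package's documented choice, with
the block length tied to the block-error analysis. Degenerate pairs are
resolved deterministically: zero variance within and between groups gives
p = 1, zero within-group variance with separated means gives p = 0. Masks
at 0.05/0.01/0.005 are nested by construction, and on null data
(same-generator ensembles) the flagged fraction is consistent with the
nominal level — the F-test on 0/1-derived block means is if anything
conservative for rarely-contacting pairs.

# Scattering comparison

`debyeProfile()` evaluates the Debye formula
I(q) = Σ fᵤfᵥ sin(q rᵤᵥ)/(q rᵤᵥ) with unit form factors by default;
per-bead weights can emulate electron counts. sin(x)/x uses a series
branch below 10⁻⁴ so I(0) = (Σf)² holds to rounding. This deliberately
coarse scattering model has no atomic form factors or hydration-shell
contrast; it is adequate for ensemble-shape comparison at low q (the
ensemble average matches the Gaussian-chain Debye function within 2% for
q·Rg ≤ 2 on ideal chains, asserted in the tests) but not for fitting wide
angle data.

`chi2Fit()` minimizes χ²(a,b) = (1/n)Σ(I_ref − a·I_sim − b)²/σ² in closed
form (weighted linear regression; the 1/n normalization is kept so values
are comparable across curve lengths). The model is linearly interpolated
onto the reference q grid, and must cover its range — no extrapolation.
The fit is affine-equivariant and returns χ² = 0 on noise-free affine
data.

# Oligomer clustering

`frameClusters()` implements agglomerative merging: start from singleton
clusters and merge any two clusters containing molecules in contact (any
bead pair within 0.7 nm, minimum image) until a fixed point. The fixed
point equals the connected components of the molecule contact graph — the
implementation performs the merge loop and the tests assert equality with
an independent union-find oracle, documenting the equivalence rather than
assuming it. The partition is invariant to molecule order and merge order,
and the cluster count is non-increasing in the cutoff.
`clusterSeries()` adds per-frame counts and normalized histograms over
1..n molecules.

# Numerical choices and problem sizes

Round-trip coordinate fidelity is 10⁻³ nm for both file formats (PDB
stores 3 decimals in Angstrom). Strides keep the first frame and then
every k-th, giving ⌈N/k⌉ frames. All randomized analyses in the tests and
the acceptance script run at fixed seeds; the test suite uses 10⁴–2×10⁴
frames for ideal-chain parameter recovery (where exact closed forms make
tight tolerances meaningful), 400–800 Monte Carlo frames per
solvent-quality point for scaling-exponent behaviour, and 10²–10³ random
frames for the exact oracle-equivalence checks. These sizes put parameter
recovery well inside the stated tolerances (1% on ξ, ±0.01 nm on b,
±0.02 on ν) while keeping the suite fast.

# Known limitations

* The synthetic ensembles are statistically idealized: no sequence
  specificity, no tail–domain excluded volume, no inter-frame dynamics in
  the box generator. They validate estimators, not biology.
* The Debye calculator ignores hydration and atomic detail; its χ² values
  are not comparable to those from all-atom scattering predictors.
* The ANOVA replicate structure (block means) is a documented convention,
  not an inference about any published analysis.
* Minimum-image contact detection assumes whole molecules; ensembles with
  molecules split across the boundary must be made whole upstream.
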