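---
title: "Maximum-entropy chromosome ensembles from Hi-C: model, inference, and ensemble statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum-entropy chromosome ensembles from Hi-C}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the model and its
assumptions, the inference algorithm and its tunable parameters, what the
synthetic-data generator does and does not emulate, the numerical choices
made where the design was genuinely open, and known limitations. All
empirical numbers quoted here are computed by the test suite
(`tests/testthat/`) or by `scripts/acceptance.R`.

## The model

**State space.** A bacterial chromosome is represented as a circular
*phantom* chain of `N` monomers on a 3D cubic lattice: consecutive
monomers occupy nearest-neighbor sites (including the ring-closing pair),
non-adjacent monomers may coincide, and every site must lie inside a
spherocylindrical confinement — a cylinder with hemispherical caps sized
to the cell interior (defaults: diameter 0.63 µm, pole-to-pole length
2.2 µm, the dimensions of a newborn *C. crescentus* swarmer cell minus
its envelope). Every `m`-th monomer is the *center* of one genomic region
(one Hi-C bin, 10 kb by default); region `k` covers the half-open genomic
interval `[(k-1)·10 kb, k·10 kb)`. Two regions are "in contact" with
probability γ exactly when their centers co-occupy a lattice site.

**Maximum entropy.** Among all distributions over confined configurations
whose pairwise contact frequencies match the experimental ones, the
distribution of maximal Shannon entropy has the Boltzmann form
`P ∝ exp(−H)` with the dimensionless Hamiltonian
`H = ½ Σ ε̄ᵢⱼ δ(rᵢ, rⱼ)`. The couplings are Lagrange multipliers: they
parametrize the least-structured consistent distribution and must not be
read as physical interaction energies, nor does the construction assume
thermal equilibrium — the Boltzmann form is a mathematical consequence of
entropy maximization under linear constraints.

**Normalized scores and the conversion factor.** Published Hi-C maps are
normalized; the factor `c` relating scores `f̃` to model contact
frequencies is unknown, and only `c̃ = c/γ` is identifiable (γ is
absorbed). `c̃` is fixed by requiring that, over the admissible family of
solutions, the model entropy is maximal; differentiating the entropy
along the family yields the scalar constraint `Σ ε̄ᵢⱼ f̃ᵢⱼ = 0`. The test
suite verifies on an exhaustively enumerable ring that the root of this
residual coincides with the entropy maximum computed exactly from the
state probabilities.

## Geometry conventions

* **Lattice offset.** Sites sit at *half-integer* multiples of the
  spacing `b` relative to the cell center. This makes all three
  coordinate reflections exact symmetries with no fixed planes, so the
  site count `M` is divisible by 8 and the sign-of-coordinates octant
  partition is exact — a distribution uniform over one octant scores
  exactly `log2(8) = 3` bits of localization information. A site is
  accessible iff its center satisfies the continuous spherocylinder
  inequality; surface points are included. At the default geometry
  `M = 952` (`log2 M = 9.9` bits).
* **Orientation.** Cells are oriented by the *ori* convention: any
  configuration whose ori center lies in the upper axial half is mirrored
  through `z → −z`. With half-integer offsets no site has `z = 0`; if a
  custom geometry ever produced a scaled ori position of exactly ½ the
  configuration would be kept unmirrored (a measure-zero tie, any fixed
  rule suffices). Orientation is idempotent and an isometry.
* **Indices.** Regions and monomers are 1-based (R convention); genomic
  coordinates are 0-based half-open base-pair intervals.

## Coarse-graining scale

The lattice spacing is the measured mean spatial distance between
consecutive 10-kb regions scaled to the lattice: `b = 88` nm. The number
of chain monomers per region, `m`, is a modeling choice with one hard
constraint the continuum picture hides: **the cubic lattice is
bipartite**, so monomers an odd number of bonds apart can never occupy
the same site. With odd `m`, every odd-genomic-distance region pair would
have contact frequency identically zero and its Hi-C constraint would be
unsatisfiable. `m` must therefore be even; the default is `m = 2`, the
even spacing whose forward-simulated mean consecutive-center distance
(≈112 nm at `b = 88` nm; `calibrate_monomers_per_region()` measures this
per geometry) is closest to the measured 129 ± 7 nm. The same parity
argument forces `N = m·n_regions` to be even for the ring to close; the
constructor enforces this. At the default genome (402 regions of 10 kb),
`N = 804` monomers in 952 sites — a chain density of ≈0.84 monomers per
site, which the synthetic test systems reproduce so that crowding
phenomenology survives the scale-down.

## Sampling

**Metropolis sampler** (`sample_ensemble`, C++ kernel): single-monomer
kink moves (re-siting a monomer uniformly among the common neighbors of
its ring neighbors — a proposal set independent of the current position,
hence symmetric), bonded-pair translations, and rigid whole-ring
translations (2% of proposals; energy-free, they decorrelate the center
of mass). Moves leaving the confinement or breaking connectivity are
rejected by construction; rejected moves retain the previous
configuration and are counted in averages. Couplings of +∞ (forbidden
contacts) are a hard-core mask, not a large float; when present, the
sampler pre-thermalizes with the exclusions softened to a strong finite
repulsion until a mask-clean configuration is found, then switches the
hard mask on. Defaults: burn-in 50·N sweeps, thinning N/2 sweeps (one
sweep = N attempted moves), checked post hoc with
`snapshot_autocorrelation()` — the suite verifies the lag-1
autocorrelation of the slowest simple observable is below 0.2 at these
settings. No claim is made that this move set matches any particular
published scheme: correctness is defined by the stationary law, and the
suite certifies it against exhaustive enumeration (chi-square on all 168
states of a 4-ring in a 2×2×2 box, and contact frequencies within 3
standard errors).

**Exact sampler for the non-interacting ring**
(`random_polymer_baseline`): with all couplings zero every legal ring is
equally likely, and the uniform law factorizes over lattice steps once
conditioned on closure. The sampler computes closed-walk counts
`diag(Aᴺ)` (A = confinement adjacency operator, evaluated only on
reflection-orbit representatives), draws the start site from them, and
then draws each step proportionally to the number of walks that still
return — yielding *i.i.d.* configurations. This is both the
random-polymer baseline of the analyses and an independent oracle for the
Metropolis sampler at sizes beyond enumeration (the suite cross-checks
occupancy marginals between the two). The tethered variant conditions the
ori center on a pole-proximal site set (scaled axial position < 0.2 by
default).

**Enumeration oracle** (`enumerate_ring_ensemble`): exhaustive generation
of all legal rings with exact Boltzmann probabilities and contact maps;
it refuses (never truncates) beyond a state cap, pre-checked via
`trace(Aᴺ)`.

## Inverse Monte Carlo

Each iteration: sample under the current couplings (warm-started from the
previous chain end, 20·N sweeps of re-burn-in); estimate co-occupancy
frequencies; update couplings by the log-ratio rule
`ε̄ ← ε̄ + s·log[(f_model + η)/(c̃ f̃ + η)]` on unmasked pairs, with
`η = 1/(2·n_samples)` (half a count), step `s = s₀/(1 + k/20)` and a
per-iteration clamp of |Δε̄| ≤ 0.5 (pairs whose model or target frequency
is barely resolved otherwise take runaway steps); then update `c̃`
multiplicatively toward the entropy constraint with damping κ = 0.5.
Snapshot counts grow linearly across iterations (2 000 → 8 000 by
default). Convergence requires map deviation ≤ 6.0% of the mean target
score, Pearson ≥ 0.998, and relative entropy-constraint residual ≤ 10⁻²
(all configurable); a budget exhausted without convergence returns
`converged = FALSE` with the full per-iteration history, never an error.
The path to the fixed point is implementation-defined; the fixed point
itself is what the recovery tests check.

**Masking.** Self pairs and nearest genomic neighbors are excluded from
fitting by default (`mask_band = 1`): their contacts are dominated by
chain connectivity, not couplings. Zero scores are either excluded or
mapped to forbidden contacts (`mask_zero_scores`, policy `"exclude"` /
`"infinite"`); all-zero rows are masked entirely and reported.

**Identifiability.** With `c̃` free, couplings are identified only in the
*entropy gauge*: rescaling all target frequencies by λ shifts every
coupling by ≈ −ln λ, and the entropy constraint selects one
representative of that family. The synthetic recovery experiment
therefore projects its ground truth into the gauge (iterative
score-weighted mean subtraction, re-simulating the map) before
challenging the fitter; with the factor frozen (`fit_c_tilde = FALSE`)
raw couplings are recovered directly. A second, physical limit: when
targets approach the hard ceiling of contact probability 1 (a collapsed
chain in a tiny confinement), couplings saturate out of identifiability —
synthetic conditions keep |ε̄| ≤ 2 and targets well below saturation.
At the default test conditions (10 regions, 24-site confinement, hidden
conversion factor 1.5, 30 000-snapshot maps) the suite requires RMSE ≤
0.15 and Pearson ≥ 0.95 between recovered and true couplings; the
recorded run achieves ≈0.05 and ≈0.997.

## Ensemble statistics

* **Axial distributions** (`axial_distribution`): normalized histograms
  of scaled long-axis position (0 = ori pole), with the bin count
  configurable to match a comparison dataset. Requires an oriented
  ensemble (explicit error otherwise).
* **Two-point correlations**: Pearson correlations across snapshots of
  axial positions `zᵢ`, radial positions `√(x²+y²)`, and transverse
  orientation vectors `u = (x,y)/|(x,y)|` (⟨uᵢ·uⱼ⟩ for angular). Regions
  with zero variance are flagged `NA` and reported, never silently
  zeroed; snapshots with a segment centroid on the axis are excluded from
  angular averages and counted. The default angular segment is a single
  region center; coarser segment averaging is available.
* **Super Domains** (`identify_suds`): per configuration, single-linkage
  clustering of region centers at radius 2 lattice units, clusters split
  into genomically contiguous circular runs, runs of ≥ 5 regions
  reported, labeled by arm (right = first genome half, ori→ter) and
  axial extent. The published clustering details being unavailable, these
  two parameters are exposed; the suite pins the implementation with
  construction-known fixtures (collapse → one SuD of all regions; two
  separated blobs → exactly two; spread grid → none).
* **Inter-arm overlap reduction** (`sud_overlap_reduction`): overlap =
  intersection-over-union of the axial interval unions of left- and
  right-arm SuDs within one configuration; baseline = same statistic with
  right-arm intervals drawn from a different, randomly chosen
  configuration; reduction = (baseline − observed)/baseline × 100.
  Configurations lacking SuDs on both arms are excluded and counted.
* **Local extension** (`local_extension`): `δᵢ` = snapshot-mean of the
  symmetric average of the distances from region i's center to its two
  genomic neighbors, in nm (one-sided variant behind a flag).
* **Density rendering** (`render_density`): monomer occupancy histogram
  convolved with an anisotropic Gaussian (σ = 120 nm laterally, 300 nm
  axially by default, matching stated imaging resolutions), rescaled to
  maximum 1. The suite verifies mass conservation of the unrescaled
  convolution away from boundaries.
* **Extension peaks vs genes** (`extension_peak_gene_overlap`): circular
  local maxima exceeding the profile median by a MAD multiple, overlap
  counted within a window of gene-containing regions, one-sided
  permutation p-value with +1 correction, null = uniform redraw of peak
  positions within the evaluated stratum (e.g. one arm). The suite checks
  the extreme cases and that null p-values are valid (super-uniform; a
  discrete statistic cannot be exactly uniform).

## Localization information

For each region, `info = log2(M) − H(p̂)` bits, where `p̂` is the
occupancy distribution over the `M` accessible sites estimated from an
oriented ensemble — the Kullback–Leibler divergence from uniform over the
accessible volume. The plug-in entropy is biased low (inflating
information); the Miller–Madow correction `(K̂−1)/(2S)` nats is applied by
default and estimates are clamped to `[0, log2 M]`. An axial-only variant
(occupancy over z-planes, reference `log2(n_planes)`) is provided; the 3D
form is the default since its ceiling `log2 M ≈ 9.9` bits is the natural
"perfectly localized region" anchor. Anchors verified by the suite: a
delta distribution scores `log2 M`; a uniform distribution scores 0; one
octant scores exactly 3 bits.

**The random-polymer baseline is not the 1-bit orientation share.** For
the oriented non-interacting ring at the full cell geometry, the
acceptance script measures ≈1.93 bits at ori. This is not estimator bias:
the marked-monomer marginal of a confined ideal ring is available in
closed form from `diag(Aᴺ)`, and the acceptance suite computes it —
0.94 bits of *self-confinement* (boundary-depletion) information present
before any orientation, plus exactly 1 bit from folding ori into one cell
half. An interpretation of the baseline as "1 bit = knowing the cell
half" captures the orientation share alone and matches the ≈1.0 bit the
estimator returns for mid-arm regions (where orientation adds almost
nothing), but not the ori value under this estimator. The corresponding
acceptance check against the 1-bit reference is deliberately left
failing rather than redefining the estimator post hoc.

## Synthetic data: what it does and does not emulate

`generate_ground_truth` superposes coupling motifs with clear biological
referents: near-diagonal attraction (domain-scale compaction), a
secondary anti-diagonal through ori (SMC-juxtaposed arms), and sparse
random couplings; `simulate_hic_map` divides forward-simulated
frequencies by a hidden conversion factor and can add multiplicative
log-normal score noise (symmetrized), the positive, heteroscedastic noise
shape typical of normalized Hi-C. Test systems use 10–40 regions in a
proportionally shrunken confinement at paper-scale chain density.

Not emulated: replicating-chromosome contamination, normalization
artifacts (restriction-site density, mappability), distance-dependent
backbone signal beyond what the confined ring itself produces, and any
transcription- or condition-dependent structure. Passing recovery tests
therefore demonstrate that the inverse algorithm inverts *its own
forward model* accurately and robustly — they do not certify accuracy on
real maps, whose deviations from the model class are exactly what the
masked pairs and the fit diagnostics are there to expose.

## Problem sizes and reproducibility

The suite runs at: 4-monomer rings in a 2×2×2 box (exhaustive, 168
states), 6–10-region systems in a 24-site confinement (statistical
checks, recovery), and the full 952-site / 804-monomer geometry for the
information analyses (3 000–8 000 exact samples). Every stochastic entry
point takes a root seed; sub-seeds for named substreams are derived
deterministically (`derive_seed`), all randomness — including the C++
kernels — flows from R's RNG, and identical configuration plus seed
reproduces byte-identical couplings, ensembles and analysis tables (the
suite asserts this end to end).

## Known limitations

* Static ensembles only: no dynamics are implied by Monte Carlo time.
* Organizational features not encodable in population-averaged pairwise
  contact frequencies are invisible to the model; features below the bin
  size (10 kb) are outside its resolution.
* The confinement is identical across cells; per-cell size variation is
  not modeled.
* Couplings lose identifiability as contacts saturate (see above), and
  with a free conversion factor they are defined only up to the entropy
  gauge.
* The extended variant that additionally constrains the axial ori
  distribution, and preprocessing of raw Hi-C (balancing, replication
  filtering), are out of scope: the tool consumes already-normalized
  maps.
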