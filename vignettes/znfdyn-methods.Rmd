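---
title: "Models and methods behind znfdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind znfdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(znfdyn)
```

znfdyn packages the statistical machinery used to dissect differentiated
RNA binding across tandem CCCH zinc-finger domains: sequence coevolution
over a family alignment, essential dynamics of conformational ensembles,
nonequilibrium pulling work converted to free-energy profiles, and
grid-based pocket volumes. This vignette explains each model, the
parameters that matter, the synthetic-data generators the validation
rests on, and the numerical and design choices that were genuinely open.

## Coevolution statistics

All information quantities are in bits (log base 2). Column frequencies
use `(counts + pc) / (total + 21·pc)` over the 21-symbol alphabet
(20 residues + gap) with pseudocount `pc = 0.5` by default; optional
Henikoff position-based sequence weights down-weight redundant
sequences (off by default, as the statistics are validated on synthetic
alignments of independent sequences). KL conservation compares each
column's residue distribution (gap mass dropped, renormalised) to a
strictly positive background, uniform by default, so a fully conserved
column scores log₂20 ≈ 4.32 bits.

Mutual information between columns is computed from pairwise-complete
joint counts over the 20-residue alphabet: a sequence gapped in either
column simply drops out of that pair's counts. A column with more than
50% gaps carries too little pairwise signal and is masked from the MI
matrix (zeroed and reported) rather than contributing noise. The
average-product correction subtracts the rank-one background
`MI_i·MI_j / MI_·` that shared conservation and phylogeny induce; the
permutation null shuffles each column independently across sequences and
re-applies APC to every replicate (100 permutations by default, seeded),
yielding Z-scores whose default significance threshold is 6.5. cMI sums
raw MI over a residue's significant partners; pMI aggregates the cMI of
3-D neighbours within 5 Å (minimal heavy-atom distance from the first
model of a reference structure).

Two points were genuinely open and are decided here: (i) the network
threshold is applied to the *Z-score*, not raw MI — a raw-MI cutoff of
6.5 bits would be unreachable (log₂20 ≈ 4.3 bits is the single-column
maximum); (ii) pMI uses the **mean** of neighbour cMI rather than the
sum, making values comparable across coordination numbers; both the
threshold and the aggregation are arguments.

## Essential dynamics

Frames are superposed by iterative least-squares rigid-body fitting:
Kabsch rotations with the reflection branch explicitly excluded
(determinant +1), reference refined to the ensemble mean until it moves
less than 10⁻⁶ Å. The positional covariance over the selected
coordinates (the Cα/N/C backbone for global analyses) is
eigendecomposed; eigenvalues are clamped at zero and each eigenvector's
sign is fixed by its largest-magnitude component, making decompositions
reproducible. Mode fluctuation profiles distribute the eigenvalue over
residues via `λ·|v(atom)|²`, so a profile sums exactly to its
eigenvalue. Windowed local fluctuations are per-residue RMSF over the
window's heavy atoms after superposing on the window's own backbone;
per-atom mean-square fluctuations are *summed* within a residue (so the
squared profile sums to the window covariance trace) with population
(1/N) normalisation throughout.

Subspace similarity is reported with three estimators because published
"conformational coverage" percentages rarely state which was used: RMSIP
over the top k modes (default k = 10), the Hess covariance overlap, and
the fraction of one set's top-k variance captured by the other's
subspace. Random k-dimensional subspaces of a 3m-dimensional space have
an RMSIP floor of √(k/3m), which the tests verify by simulation — a
reported overlap should always be read against that floor.

## Pulling simulation and Jarzynski analysis

The synthetic pulling engine integrates overdamped Langevin dynamics

x ← x + dt·(−U′(x) + k_s(λ(t) − x))/γ + √(2 kB T dt/γ)·η

with a constant-velocity anchor λ(t) = λ₀ + v·t and analytic 1-D
potentials (flat, harmonic, quartic double-well). Replicas start from an
equilibrated distribution at the initial anchor — a seeded burn-in of
2000 steps at fixed λ₀ — because the Jarzynski identity requires
equilibrium initial sampling. Specs are rejected when
`(k_s + well stiffness)·dt/γ ≥ 1`, the overdamped Euler stability bound.
External work is accumulated as the trapezoid of F·dλ at every
integration step and recorded at the output stride (default 1 in 10), so
recorded work does not depend on the stride. Units are Å, ps,
kcal·mol⁻¹; published pulling protocols often quote nm and nN·nm⁻¹, and
`spring_nN_nm_to_kcal()` converts the latter (1 nN·nm⁻¹ = 1 N/m ≈ 1.44
kcal·mol⁻¹·Å⁻²).

Analysis bins every profile on the deterministic anchor schedule λ
rather than the fluctuating coordinate x: replicas then align exactly
without interpolation, at the cost of a small systematic offset between
λ and ⟨x⟩ of order F/k_s (negligible for stiff springs). The Jarzynski
PMF is `−kBT ln⟨e^(−βW)⟩` with a log-sum-exp guard, gauged to zero at
the first grid point, accompanied by the second-cumulant (Gaussian)
estimate `⟨W⟩ − β var(W)/2`, a Student-t 95% confidence band on the mean
work, and the normalised-weight effective sample size `1/Σw̃²` — with
tens of replicas the exponential average is dominated by the smallest
works, and ESS makes that visible. The key analytic check: pulling a
particle out of a harmonic well with a harmonic spring has the
closed-form ΔG of two springs in series, ½·(k_w k_s/(k_w+k_s))·Δλ², and
slow pulling must recover it while Jensen's inequality (PMF ≤ mean work)
holds pointwise on every ensemble.

Rupture points are local maxima of the moving-average-smoothed mean
force (window 5 grid points), ranked by topographic prominence with
boundary maxima excluded — a monotone force profile therefore yields no
rupture point rather than a spurious boundary peak. Segment-wise
fluctuations split a trajectory into equal contiguous blocks (default 4)
and reuse the windowed RMSF; a `reversed` flag relabels blocks so an
unbinding trajectory reads unbound → bound.

## Pocket volumetrics

The measurement is deliberately the simple, reproducible POVME
convention: an axis-aligned lattice at fixed spacing (default 1.0 Å),
anchored at the first inclusion centre so results are
translation-invariant, restricted to points inside at least one
spherical inclusion region; points strictly closer to an atom centre
than that atom's Bondi van der Waals radius (plus an optional padding,
default 0) are removed, and volume is kept points × spacing³. A
26-neighbour flood fill from the inclusion centres is available behind a
`contiguity` flag for scenes with disconnected cavities, off by default.
Convergence is verified against the analytic sphere volume over spacings
1.0/0.5/0.25 Å and against seeded 10⁶-point Monte-Carlo integration on
blocked scenes (within 5% at 0.5 Å). A helper derives an inclusion
sphere from a bound structure as the centre of mass of residues within
4.5 Å of the ligand.

## What the synthetic generators emulate — and what they do not

The generators reproduce exactly the statistical structure the analyses
consume, with known ground truth:

* **Alignments**: independent background draws with planted conserved
  columns (fidelity ∈ [0,1]) and covarying pairs coupled through an
  explicit residue bijection (coupling ∈ [0,1]); optional uniform gaps.
  Real family alignments add phylogenetic correlation between sequences,
  which inflates background MI — the APC/permutation-Z machinery exists
  for that reason, but passing tests here demonstrate recovery under
  independence, not under strong phylogeny.
* **Ensembles**: Gaussian low-rank-plus-noise coordinates,
  frames = mean + Σ √v_k z_k d_k + noise, with optional rigid-body
  jitter. Planted directions are drawn orthogonal to the six rigid-body
  degrees of freedom of the mean structure so superposition cannot
  absorb planted variance; the generative variance along a planted
  direction is v_k + σ²_noise, and recovery is judged against that sum.
  Real trajectories are neither Gaussian nor low-rank, and their
  anharmonicity is not modelled.
* **Pulling**: 1-D overdamped Langevin with the exact work bookkeeping
  of steered MD. Multidimensional orthogonal relaxation, which broadens
  real work distributions, is absent.
* **Pockets**: spherical inclusion regions with spherical blockers —
  fixtures for the measurement, not models of real cavity shapes.

Validation problem sizes — 50 pulling replicas, 500-sequence alignments
with 100 permutations over 20 seeds, 5000-frame ensembles, 10⁶
Monte-Carlo points — were chosen so each estimator operates in the
regime where its sampling error is a few times smaller than the
tolerance being checked, and the whole suite runs in minutes on one CPU.

## Conventions and degenerate inputs

* 1-based closed residue/column indexing throughout, matching R and PDB
  author numbering, so published residue windows (e.g. ZnF1 18–38,
  ZnF2 52–72, ZnF3 184–204, ZnF4 218–238) apply verbatim.
* Unknown alignment symbols map to gaps with a warning; ragged
  alignments, collinear fitting selections, non-monotone anchor
  schedules, zero-variance profiles in a Pearson correlation, and
  unknown elements without explicit radii are all hard errors naming the
  offender.
* `sd_null` in permutation Z-scores is floored at 10⁻¹²; `0·log 0 = 0`
  in every information quantity; APC is defined as 0 when the mean MI is
  0; a single-replica work ensemble reports a missing confidence band
  rather than a fake zero.
* Every generator and the permutation null consume an explicit integer
  seed, and the pipeline manifest records seeds, parameters and md5
  checksums; reruns are byte-identical.

## Known limitations

Phylogenetically structured nulls, direct-coupling analysis,
mass-weighted PCA, bidirectional (Crooks) free-energy estimators,
x-binned work profiles with interpolation, and cavity *detection* (as
opposed to measurement inside a declared inclusion region) are out of
scope. The Jarzynski estimator with ~20 replicas is biased when
dissipation exceeds a few kBT — the ESS diagnostic and the
second-cumulant cross-check are reported precisely so that users can see
when the exponential average is undersampled.
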