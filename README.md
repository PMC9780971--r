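# znfdyn

Desk-scale analysis of how tandem CCCH-type zinc-finger (ZnF) RNA-binding
domains — the MBNL family of alternative-splicing regulators being the
motivating system — differentiate their RNA-binding behaviour. The package
implements, as tested and reusable R functions, the four quantitative
pillars of such a study:

1. **Sequence coevolution** over a multiple sequence alignment:
   per-column Kullback–Leibler conservation
   `KL(i) = Σ_a p_i(a) log₂ p_i(a)/q(a)`, mutual information
   `MI(i,j) = Σ_ab p_ij(a,b) log₂ p_ij(a,b)/(p_i(a) p_j(b))` in bits with
   the average-product correction `APC(i,j) = MI(i,j) − MI_i·MI_j/MI_·`,
   permutation Z-scores, the per-residue cumulative MI (cMI: sum of raw MI
   over partners with Z > 6.5) and proximity MI (pMI: mean neighbour cMI
   within 5 Å minimal heavy-atom distance).
2. **Essential dynamics** of coordinate ensembles: iterative Kabsch
   superposition, eigendecomposition of the positional covariance
   `C = ⟨(x−⟨x⟩)(x−⟨x⟩)ᵀ⟩` on the Cα/N/C backbone, per-residue
   fluctuation profiles from single modes and windowed RMSF, RMSIP
   subspace overlaps `√(Σ_ij (v_i·w_j)²/k)`, Pearson correlations between
   fluctuation profiles, and RMSD.
3. **Steered-pulling work analysis**: cumulative external work
   `W = ∫ F dλ` along a constant-velocity harmonic-spring schedule, mean
   work profiles with Student-t 95% bands, potential-of-mean-force
   reconstruction via the Jarzynski equality `⟨exp(−βW)⟩ = exp(−βΔG)`
   (log-sum-exp guarded, with a second-cumulant estimate
   `⟨W⟩ − βσ²_W/2` and effective-sample-size diagnostics), rupture-point
   detection on the smoothed mean force, and segment-wise fluctuations.
4. **POVME-style pocket volumetrics**: lattice points at fixed spacing
   inside spherical inclusion regions, minus points occluded by atomic
   van der Waals spheres; volume = kept points × spacing³, per frame over
   an ensemble.

Because the cluster-scale molecular dynamics that normally feeds these
analyses is out of reach on a desktop, a first-class **synthetic-data
module** generates every input with known ground truth: alignments with
planted conserved and covarying columns, low-rank-plus-noise coordinate
ensembles with planted principal modes, overdamped-Langevin
constant-velocity pulling trajectories on analytic 1-D potentials, and
toy pocket scenes. Every stage of the pipeline is validated against that
ground truth or an independent brute-force oracle.

Internal units: Å, ps, kcal·mol⁻¹ (kB = 0.0019872041 kcal·mol⁻¹·K⁻¹);
converters for nm and nN·nm⁻¹ are provided (`nm_to_angstrom()`,
`spring_nN_nm_to_kcal()`).

## Worked example

Recover a planted covarying column pair from a synthetic alignment, then
reconstruct a free-energy profile from simulated pulling:

```r
library(znfdyn)

msa <- generate_msa(msa_spec(
  n_sequences = 500, length = 20,
  coupled_pairs = list(list(i = 4, j = 15, coupling = 1.0,
                            state_map = c(A = "R", C = "K", D = "E", E = "D"))),
  seed = 42))
mi <- mi_zscores(msa, n_permutations = 100, seed = 42)
head(coevolution_network(mi, z_threshold = 6.5), 1)
#> # A tibble: 1 × 5
#>       i     j raw_mi     z band
#>   <int> <int>  <dbl> <dbl> <chr>
#> 1     4    15   1.73  291. top5
```

The planted pair (columns 4 and 15) tops the network with raw MI
≈ 1.73 bits (shrunk from the log₂4 = 2 theoretical maximum of four
equiprobable coupled states by the 0.5 pseudocount) and a permutation
Z-score around 291, far beyond the 6.5 significance threshold.

```r
pe <- simulate_pull(pull_spec(
  pull_potential("harmonic", k_well = 2, x0 = 0),
  spring_k = 10, velocity = 0.02, temperature = 300, friction = 1,
  dt = 0.005, start_anchor = 0, end_anchor = 2, n_replicas = 50, seed = 11))
glance(jarzynski_pmf(pe))
#> # A tibble: 1 × 6
#>   delta_g_jarzynski delta_g_cumulant2 final_mean_work n_replicas temperature min_ess
#>               <dbl>             <dbl>           <dbl>      <int>       <dbl>   <dbl>
#> 1              3.34              3.34            3.37         50         300    44.9
```

Pulling a particle out of a harmonic well (k = 2 kcal·mol⁻¹·Å⁻²) with a
10 kcal·mol⁻¹·Å⁻² spring over 2 Å has the closed-form free-energy change
½·k_eff·Δλ² = 3.33 kcal·mol⁻¹ (springs in series, k_eff = 5/3): the
Jarzynski estimate lands within 0.01 kcal·mol⁻¹ of it, below the mean
work as Jensen's inequality requires, with an effective sample size of
~45 of the 50 replicas.

`run_pipeline()` drives the same machinery end-to-end from YAML configs
(subcommands `simulate`, `coevolve`, `modes`, `localflucts`, `pull`,
`pocket`), writing CSV/JSON outputs plus a manifest with md5 checksums;
reruns with the same seed are byte-identical.

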