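# chaindyn

Conformational-dynamics analysis of alpha-carbon protein trajectories
treated as polymer chains, for structural bioinformaticians who
post-process molecular-dynamics output across temperature ensembles.

A protein's Cα trace r₀ … r_N is read as a chain of N virtual bonds of
length τ = 3.8 Å. The package computes, per time window and replica:

* **Chain extension**: end-to-end vectors R = r_N − r₀, the RMS
  end-to-end distance √⟨R²⟩, and the Flory–De Gennes size exponent
  μ = ln(R/τ)/ln N from the scaling law R ∼ τN^μ (μ = 1/2 for an ideal
  chain, ≈ 0.4 for a compact globule such as albumin);
* **RMSD series** √(Σᵢ Rᵢ·Rᵢ/n) with selectable alignment (centroid,
  none, or full Kabsch superposition);
* **Conformational entropy** S = −R₀ Σ pᵢ ln pᵢ (R₀ = 8.314 J K⁻¹ mol⁻¹)
  of the backbone angle-pair distribution (planar φ and dihedral ψ along
  the Cα trace) on a fixed 50×50 grid, as a per-frame time series;
* **Fisher's exact g-test** for hidden periodicity in entropy series:
  periodogram I(ω) = |Σⱼ e^(−iωj) yⱼ|²/N at ω_k = 2πk/N,
  g = max I / Σ I, and the exact null tail
  P(g ≥ x) = Σⱼ (−1)^(j−1) C(q,j)(1−jx)^(q−1);
* **Cross-temperature comparison**: uncorrected Kruskal–Wallis H,
  the Conover–Iman pairwise criterion |rsᵢ/nᵢ − rsⱼ/nⱼ| with its
  t-quantile threshold, and Kullback–Leibler divergence/distance
  matrices between per-temperature histograms (additive smoothing only
  when zero bins require it).

A seeded synthetic-trajectory generator (freely jointed, confined, and
noisy-helix chain models, plus the cosine-plus-noise signal model) stands
in for MD data so the entire pipeline runs and is tested offline.
Multi-model PDB input/output (via bio3d) connects to structure tools.

## Worked example

Published albumin summaries (five temperatures, two windows) ship with
the package; feeding the published RMS end-to-end distances through the
size-exponent estimator reproduces the published exponents exactly:

```r
library(chaindyn)
ref <- albumin_reference()
head(ref$rms_end_to_end, 2)
#>   window temperature r_rms
#> 1 0-30ns        300K 47.88
#> 2 0-30ns        303K 46.69

flory_exponent(47.88, tau = 3.8, n_bonds = 576)
#> Flory-De Gennes size exponent: mu = 0.3986  (R = 47.88 A, tau = 3.8 A, N = 576)

mean_pvalue(ref$fisher_pvalues_0_30ns[["300K"]])
#> [1] 0.2877778     # 0.288 at the published precision
```

The same machinery on a synthetic ensemble (5 × 9 replicas, 579 beads,
confined chain model — the compact-globule regime):

```r
cfg <- ensemble_config(chain_model = "confined", seed = 1)
ens <- generate_ensemble(cfg)                  # 45 trajectories
man <- run_pipeline(analysis_config(n_bonds = 578, output_dir = "results/pipeline"),
                    ens)
man$results[["0-30ns"]]$summary
#>   temperature    r_rms        mu
#> 1        300K 47.14432 0.3959719
#> 2        303K 46.08614 0.3924023
#> 3        306K 45.58320 0.3906768
#> 4        309K 46.27536 0.3930465
#> 5        312K 48.07152 0.3990344
man$results[["0-30ns"]]$kw_r$H                 # Kruskal-Wallis H across temperatures
#> [1] 2.141063
```

μ ≈ 0.40 against the ideal-chain 0.5: the confined generator reproduces
the globular scaling regime, and H is small because the per-temperature
differences are sub-percent — the same qualitative picture the published
summaries show. The numbered scripts under `analysis/` run the full
narrative (simulation, chain geometry, entropy/periodicity, group
comparison) and write every table family under `results/`.

## Layout

```
R/                  package code (generator, chain geometry, entropy/KL,
                    periodicity, rank tests, pipeline, PDB I/O)
analysis/           numbered narrative scripts over the package
inst/extdata/       published albumin summary tables (CSV)
tests/testthat/     unit, property and acceptance suites
scripts/acceptance.R
vignettes/          methods vignette
```
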