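# polyqens

Chemical-shift-based secondary-structure propensity and conformational-
ensemble analysis for intrinsically disordered polyglutamine (polyQ)
proteins — built around the ataxin-7 N-terminal fragment, where an
alanine-rich region (ARR) just ahead of the tract forms a marginal
α-helix that propagates into the glutamines when the tract expands.

It is aimed at NMR/structural-bioinformatics users who have backbone
chemical-shift assignments (BMRB NMR-STAR or CSV), optionally a pool of
candidate conformers, and optionally hydrogen/deuterium-exchange (HDX)
peak intensities, and want per-residue statements about transient
helicity.

## What it computes

* **Secondary shifts**: Δδ = δ(observed) − δ(random coil) per backbone
  nucleus (H, N, Hα, Cα, Cβ), plus the ΔδCα − ΔδCβ helicity indicator.
  A Wishart-style random-coil table is bundled.
* **SSP scores**: a windowed, nucleus-weighted normalisation of the
  secondary shifts onto a propensity scale where +1 is a fully formed
  helix and −1 a fully formed extended strand, with outlier exclusion
  and segment calling.
* **Ensemble reweighting** — the core: given a conformer pool with
  predicted shifts (matrix `M`, K conformers × J observables) and
  experimental shifts `y`, find simplex weights

  ```
  min_w  Σ_j ( Σ_k w_k M_kj − y_j )²  +  λ‖w‖²
  s.t.   w_k ≥ 0,  Σ_k w_k = 1
  ```

  solved exactly as a quadratic program, then report per-residue
  helix/strand/coil probabilities p_S(i) = Σ_k w_k·1[ss_k(i) = S],
  fit diagnostics and the effective ensemble size 1/Σw².
* **HDX classification**: slow vs fast exchangers from peak-intensity
  ratios against an H₂O control at 15/60/120 min, with the annotation
  conventions used for assigned (+) and unassigned tract glutamines (*).
* **Synthetic data**: seeded scenarios (`normal_10Q`, `expanded_22Q`,
  `expanded_33Q`, `helix_broken`) generating the 62-residue
  ARR–polyQ–PRR construct, conformer pools whose per-residue helix
  frequency matches a ground-truth propensity profile, ensemble-averaged
  shift tables with known mixture weights, and HDX decay series.

## Worked example

Simulate the normal-length and expanded constructs, refit their
ensembles from the synthetic shifts, and compare:

```r
library(polyqens)

sc10 <- make_scenario("normal_10Q",   seed = 7, pool_size = 100)
sc22 <- make_scenario("expanded_22Q", seed = 7, pool_size = 100)
r10 <- run_scenario_pipeline(sc10)
r22 <- run_scenario_pipeline(sc22)

# SSP on the synthetic experimental shifts
rc <- random_coil_table()
ssp <- ssp_score(secondary_shifts(r10$exp, rc))
call_segments(ssp, threshold = 0.3)
#>   start end mean_score
#> 1    18  29  0.6079053

r10$w
#> <weight_vector> K = 100  effective size = 52.48  objective = 0.5005
#>   note: prediction matrix is rank-deficient; weights are not uniquely identified

r10$summary
#> <ensemble_summary> 62 residues, K = 100, effective size = 52.48
#>   fit diagnostics (fitted vs experimental):
#>  nucleus       rmsd correlation  n
#>        H 0.04439647   0.9269911 46
#>        N 0.04048879   0.9999215 46
#>       HA 0.04814147   0.9520119 62
#>       CA 0.03918701   0.9999607 62
#>       CB 0.03990973   0.9999902 60

compare_variants(r10$summary, r22$summary,
                 region_a = sc10$polyq_range,
                 region_b = sc22$polyq_range)$region_mean_delta
#> [1] 0.1688945
```

Reading: the called segment 18–29 is the ARR helix (it runs through
ARR2, residues 21–28, up to Arg29); the fit reproduces the synthetic
experiment to ~0.04 ppm (the injected noise is 0.05 ppm); about 52 of
100 conformers carry meaningful weight; and the expanded variant's
tract is on average ~0.17 more helical than the normal one — the
helix-propagation signature.

The same steps run from the shell via the thin wrapper:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/polyq-ens.R", package = "polyqens"))')
Rscript $CLI simulate --preset expanded_22Q --k 100 --seed 42 --outdir sim/
Rscript $CLI ssp      --shifts sim/shifts.csv --out sim/ssp.csv
Rscript $CLI reweight --pool sim/pool.pdb --exp sim/shifts.csv --out sim/ensemble.json
Rscript $CLI hdx      --series sim/hdx.csv --out sim/hdx_map.csv
```

## Documentation

The methods vignette (`vignettes/polyq-ensemble-methods.Rmd`) describes
the models, their assumptions, the tunable parameters and the design
decisions; every exported function carries full help pages.
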