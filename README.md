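# mangroveED

Phylogenetic diversity, community structure and extinction risk in mangrove
floras.

Mangroves (~70 species of tidal forest plants spread over six biogeographic
coastal regions) are declining worldwide, and conservation planning
increasingly asks not just *how many* species a region stands to lose but
*how much evolutionary history* goes with them. `mangroveED` packages the
standard analysis chain for that question so it runs, fully seeded and
reproducible, from a dated phylogeny, a species threat table and range
maps — or from a built-in synthetic-study generator when real data are not
at hand.

## What it computes

* **Per-species phylodiversity** — fair-proportion evolutionary
  distinctiveness `ED(i) = Σ_e len(e)/n(e)` over the root path, and species
  age as the terminal branch length (BL).
* **Community structure** — MPD/MNTD per region against a tip-pool
  ("phylogeny pool") null, reported as NRI = −SES(MPD) and NTI = −SES(MNTD)
  with one-tailed clustering and two-sided rank p-values.
* **Phylogenetic signal** — Blomberg's K (`K = (MSE0/MSE) / E[MSE0/MSE]_BM`)
  with a tip-shuffling permutation test.
* **Threat models** — PGLS `y = Xb + e`, `e ~ N(0, σ²V(λ))` with Pagel's λ
  estimated by bounded ML on [0, 1]; IUCN category → 50-year extinction
  probability (editable IUCN50 mapping); Yates-corrected χ² tests of
  per-use association with global decline.
* **Spatial layers** — equal-area (Behrmann) quarter-degree gridding of
  ranges into species richness, mean decline, mean ED and mean BL layers,
  plus Pearson correlations between layers.
* **Pipeline + CLI** — `run_pipeline()` / `cli()` run everything from one
  config, writing plain CSV / ESRI ASCII / JSON outputs that are
  byte-identical under a fixed seed.

## Worked example

```r
library(mangroveED)

# a complete synthetic study: dated tree, threat table, regions, ranges
bundle <- generate_study(study_config(seed = 7), "study7")

# evolutionary distinctiveness and species age
head(fair_proportion_ed(bundle$tree), 3)
#>     sp001     sp002     sp003
#> 16.969194  6.902261 12.765753

# is decline phylogenetically structured?
C <- phylo_vcv(bundle$tree)
k_signal_test(C, setNames(bundle$species_table$global_decline,
                          bundle$species_table$species), 999, seed = 1)
#> Blomberg's K = 0.2735 (observed ratio 7.96 / expected 29.11)
#> permutation p = 0.002 (999 permutations)

# does species age predict decline? (log10 scales, ML lambda)
fr <- build_model_frame(bundle$species_table, bundle$tree,
                        "global_decline", "bl")
pgls_fit(fr$vcv, fr$y, fr$X)
#> PGLS fit (n = 54), lambda = 0 [ML], logLik = -7.3579
#>          term estimate      se      t         p
#> 1 (Intercept)   0.9802 0.04234 23.150 4.730e-29
#> 2          bl   0.2366 0.05534  4.276 8.157e-05
#> Multiple R2 = 0.2601, adjusted R2 = 0.2459, model p = 8.157e-05
```

The positive, significant `bl` slope recovers the effect the generator
plants (older species decline more); `lambda = 0` says the model residuals
carry no tree structure, exactly as the generator's i.i.d. noise implies.

Full report from the command line:

```sh
Rscript -e 'quit(status = mangroveED::cli())' -- simulate --seed 7 --out study7
Rscript -e 'quit(status = mangroveED::cli())' -- report --config study7/run.cfg
```

which writes `metrics.csv`, four `layer_*.asc/csv` grids,
`layer_correlations.csv`, `nri_nti.csv` (6 NRI + 6 NTI rows), `signal.csv`,
`pgls.csv` (all univariate + multivariate models), `uses_chisq.csv`
(16 uses, raw and Holm-adjusted p) and `manifest.json`.

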