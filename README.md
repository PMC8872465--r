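# sirscan

Subregion thermodynamic scanning for siRNA off-target analysis.

## What it does, and for whom

siRNAs silence unintended transcripts through seed-only complementarity
(guide positions 2–8), an off-target effect whose strength tracks the
thermodynamic stability of guide–target pairing. `sirscan` is for RNAi
researchers and siRNA designers who want to ask *which* contiguous stretch
of the guide strand drives that effect in their reporter-assay data. It

1. computes the nearest-neighbor melting temperature (Tm) of every
   contiguous subregion `[x..y]` of the 19-bp duplex core — 171 regions
   per guide;
2. correlates each subregion's Tm with relative luciferase activities
   (complete-match reporters for on-target RNAi, seed-match reporters for
   the off-target effect) across an siRNA panel, producing start-by-end
   correlation maps;
3. localizes the *responsible* subregions by repeated random subsampling
   (draw half the panel, rank regions by correlation, record top start/end
   positions, 1000×), with train/validation split distributions compared
   by Student's t-test and integrated two-region scoring;
4. ships a seeded synthetic-data generator (rule-compliant panels, planted
   region effects) so the full pipeline is testable without any external
   data, and a functional-siRNA design-rule checker.

## The model

Subregion stability is the duplex melting temperature under the
nearest-neighbor model with the Freier et al. (1986) RNA/RNA stacking
parameters (shipped as a swappable text asset):

    Tm = 1000·ΔH / (A + ΔS + R·ln(Ct/4)) − 273.15 + 16.6·log10([Na+])

ΔH in kcal/mol; ΔS and the helix initiation constant A = −10.8 in
cal/(mol K); R = 1.987 cal/(K mol); Ct = 100 µM and [Na+] = 100 mM by
default. The scanned statistic is the Pearson correlation r between
per-siRNA subregion Tm and per-siRNA activity; because activities are
percent-of-control (low = strong silencing), r < 0 means the region's
stability *promotes* silencing.

## Worked example

```r
library(sirscan)

params     <- simulation_params(seed = 1)     # 26 rule-compliant siRNAs
panel      <- generate_panel(params)
activities <- simulate_activities(panel, params)

melting_temperature("ACGUACGU")
#> [1] 37.94

cmap <- correlation_map(panel, activities, assay = "SM", concentration = 50)
round(cmap["2", "5"], 3); round(cmap["9", "14"], 3)
#> [1] -0.566
#> [1] 0.32

head(rank_regions(cmap, "negative"), 3)
#>   x y          r
#> 1 1 5 -0.5735566
#> 2 2 5 -0.5658394
#> 3 4 5 -0.5523390

cfg  <- sampling_config(n_reps = 1000, subset_size = 13, top_k = 1,
                        sign = "negative", seed = 1)
summ <- sampling_frequencies(panel, activities, cfg)
summ$modal_region      # most frequent top-1 region over 1000 half-panel draws
#> x y
#> 4 5
summ$end_hist[3:8]     # end-position counts concentrate on the planted end 5
#>   3   4   5   6   7   8
#>   9   9 741   7   6  25

sc <- split_correlations(panel, activities, c(2, 5), cfg)
round(c(train = mean(sc$train_r), valid = mean(sc$valid_r),
        t = sc$t_stat, p = sc$p_value), 3)
#> train valid     t     p
#> 0.564 0.563 0.095 0.924

count_subsets(26, 13)  # distinct half-panel draws
#> [1] 10400600
```

Reading: in this seed-1 synthetic panel the planted negative region 2–5
anchors the correlation minimum (the top three regions all end at position
5; end-position mode 741/1000), and its correlation is statistically
indistinguishable between training and validation halves (p = 0.92) —
i.e. it generalizes across subsets. The same commands run on a real panel
by loading `read_panel()`/`read_activities()` files instead of simulating.

End-to-end, with every artifact (Tm matrices, correlation maps, sampling
histograms, split summaries, manifest) written to `out/`:

```sh
Rscript -e 'sirscan::sirscan_cli()' -- run --simulate --seed 1 --out out
# or with your own data:
Rscript -e 'sirscan::sirscan_cli()' -- run --panel panel.tsv --activities act.tsv --out out
```

Subcommands: `simulate`, `tm-scan`, `correlate`, `find-regions`,
`rules-check`, `run` (see `exec/sirscan` and `?sirscan_cli`).

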