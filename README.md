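# mobulidID

Molecular and morphological identification of traded mobulid gill rakers.

Dried gill rakers ("Peng Yu Sai") of devil rays (*Mobula*) and manta rays
(*Manta*) are sold in dried-seafood markets in southern China. Because
*Manta birostris* is CITES Appendix II-listed, enforcement officers and
researchers need to tell which species a dried plate came from — ideally
without a sequencer at the border. `mobulidID` implements both routes of a
market-forensics workflow over the five species found in these surveys
(*Mobula japanica*, *Mo. kuhlii*, *Mo. tarapacana*, *Mo. thurstoni*,
*Manta birostris*):

* **DNA barcoding** over the mitochondrial COI (761 bp) and NADH2
  (1033 bp) markers: pairwise Kimura 2-parameter distances
  (`d = -1/2 log(1-2P-Q) - 1/4 log(1-2Q)`, with transition proportion `P`
  and transversion proportion `Q` under pairwise deletion), neighbor-joining
  trees with column-bootstrap support, monophyletic single-species cluster
  extraction, best-hit identity assignment at the 99% threshold, and the
  barcoding-gap summary (max intra-specific vs min inter-specific distance).
* **Morphology of the dried plate**: the mean of five filament-length
  measurements, the `> 70 mm` manta size screen, a three-step enforcement
  decision rule (fused terminal lobes -> not variegated -> finger-like
  projections => *Manta*), a naive-Bayes classifier parameterized by the
  published per-species trait-frequency table, and a bagged-tree ensemble
  (a forest of 1000 trees, Rcpp) with out-of-bag error and per-feature
  usefulness estimates.
* A **seeded synthetic survey generator** reproducing the published market
  structure (species mix 103/25/27/12/21, per-species filament-length and
  price Normals, trait frequencies, intra-species divergence below ~1% and
  inter-species divergence in the 4–13% band) which provides ground truth
  for every other module.
* **Market reporting**: composition percentages, count-weighted mean price,
  price-on-length OLS, an end-to-end `run_pipeline()` and a CLI
  (`inst/cli/mobulid.R`) with `simulate / distance / tree / gap / identify /
  classify / market` subcommands.

## Worked example

```r
library(mobulidID)

cfg    <- generator_config(seed = 1)              # the published market mix
panel  <- generate_reference_sequences(cfg)       # 2-marker reference panel
survey <- generate_specimen_set(cfg, panel)       # 188 specimens + queries

report <- run_pipeline(survey$specimens, survey$queries, panel,
                       replicates = 200, seed = 1)
report$market
#> Market summary: 188 identified specimens
#>   Mobula_japanica    n=103   54.8%  208 +/- 47 US$/kg
#>   Mobula_kuhlii      n= 25   13.3%  134 +/- 32 US$/kg
#>   Mobula_tarapacana  n= 27   14.4%  287 +/- 83 US$/kg
#>   Mobula_thurstoni   n= 12    6.4%  176 +/- 71 US$/kg
#>   Manta_birostris    n= 21   11.2%  354 +/- 173 US$/kg
#>   overall: 224 +/- 98 US$/kg (count-weighted mean)

report$gaps$COI
#> Barcoding gap summary (% K2P distance)
#>   intra-species: 0.00 - 0.93  (4427 pairs)
#>   inter-species: 6.80 - 13.62  (10451 pairs)
#>   gap present: TRUE
```

The composition percentages are the survey's published Table values by
construction (the generator draws exactly the published per-species
counts), the overall price is the count-weighted mean across species, and
the gap summary shows why a 99%-identity assignment is safe here: the
largest within-species K2P distance (0.93%) sits far below the smallest
between-species distance (6.8%). All five species come back as
monophyletic clusters, and every sequenced specimen is called correctly at
seed 1.

The trait-based ensemble, on the same synthetic survey:

```r
rf <- ensemble_classify(survey$specimens, n_trees = 1000, seed = 1)
rf
#> Bagged-tree OOB classification report (1000 trees)
#>   total OOB error: 8.51%
#>   Manta_birostris      4.76%
#>   Mobula_japanica      1.94%
#>   Mobula_kuhlii       12.00%
#>   Mobula_tarapacana    0.00%
#>   Mobula_thurstoni    83.33%
#>   per-feature standalone OOB error (lower = more useful):
#>     middle_lobe    13.30%  (permutation importance 0.1792)
#>     terminal_lobe  19.68%  (permutation importance 0.3071)
#>     color          33.51%  (permutation importance 0.0817)
#>     arrangement    38.30%  (permutation importance 0.0263)
#>     length         46.81%  (permutation importance 0.0307)
```

*Mo. thurstoni* is nearly always misread as *Mo. kuhlii* (both have oval
lobes and similar sizes), while *Mo. tarapacana* (variegated, cilia) and
*Mo. japanica* (sharp apex) are easy — the same structure the original
survey reported. Middle-lobe structure is the most useful single trait,
followed by the terminal lobes. See the methods vignette
(`vignettes/gill-raker-identification.Rmd`) for what these synthetic
numbers do and do not establish.

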