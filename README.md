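# formulanet

Quality control of multi-herb formulae (Traditional Chinese Medicine
decoctions and similar preparations) has to verify the presence of every
constituent herb in a mixture where each herb contributes hundreds of
secondary metabolites. `formulanet` implements a metabolite-profiling
workflow that, starting from aligned LC-MS feature tables, MS/MS spectra and
ELSD peak lists of a formula, its single-herb extracts and blanks:

1. builds a **feature-based molecular network** (FBMN) — nodes are aligned
   LC-MS features with MS/MS spectra; edges are modified-cosine spectral
   similarities (cosine ≥ 0.7, ≥ 6 matched peaks, 0.02 Da fragment
   tolerance) pruned by the mutual top-50 rank rule; clusters are connected
   components grouping putative structural analogues;
2. computes **herb-specificity statistics**: for a feature with height
   *h<sub>i</sub>* in herb *i*, the specificity percentage is
   *s<sub>i</sub> = 100 · h<sub>i</sub> / Σ<sub>j</sub> h<sub>j</sub>*
   (sum over herbs only), and the cluster specificity percentage is the
   unweighted mean of member shares; features with max share ≥ 90 % and
   clusters with max mean share ≥ 75 % are called herb-specific;
3. filters abundant components with **ELSD** areas (≥ 0.004 μV/s), labels
   peaks per herb by abundance rank (`SC1`, `SC2`, ...), and assigns them to
   HRMS features by retention time (optionally corroborated by nominal
   m/z);
4. **annotates** features by bounded CHNO molecular-formula search,
   spectral-library matching (0.005 Da precursor window, cosine ≥ 0.2, top
   6), chemotaxonomic re-ranking, and anchor-point propagation within
   clusters;
5. selects **abundant specific markers** (specific in every ionization mode
   where detected) and extracts **multi-component signatures** — analogue
   series classified into three cluster categories — rendered as 2D feature
   maps, bar chromatograms and ring-annotated network attribute exports.

A synthetic-data generator with full ground truth (planted analogue
families, ubiquitous metabolites, w/w mixture model, ionization-decoupled
ELSD areas, blank contaminants) makes every stage testable without any
instrument data.

## Worked example

```r
library(formulanet)

bundle <- generate_dataset(synth_config(seed = 42))  # 10 herbs, ground truth
res    <- run_workflow(bundle)

res$pi$network
#> <molecular_network PI> 199 nodes, 352 edges, 40 clusters (188 clustered, 11 singletons)

res$pi$counts
#> # A tibble: 10 × 3
#>   herb_code n_specific pct_of_specific
#>   <chr>          <int>           <dbl>
#> 1 A                 18             9.6
#> 2 C                 19            10.1
#> 3 G                 20            10.6
#> # i 7 more rows

dplyr::count(res$markers, status)
#> # A tibble: 2 × 2
#>   status             n
#>   <chr>          <int>
#> 1 not_in_formula    60
#> 2 specific         197

evaluate_recovery(res$markers, bundle)$overall
#> # A tibble: 1 × 4
#>   precision recall n_predicted n_planted
#>       <dbl>  <dbl>       <int>     <int>
#> 1         1      1         197       197
```

The 199 positive-mode nodes fall into 40 clusters that reproduce the 40
planted analogue families exactly; every herb contributes ~20 specific
features (its 20 planted single-herb metabolites); the 60 `not_in_formula`
ELSD peaks are the ubiquitous metabolites, which have no herb-specific
feature to attach to; and all 197 ELSD-backed specific markers are exactly
the planted ones (precision = recall = 1).

Plots: `plot_feature_map(res$pi$spec, bundle$manifest)` draws the RT × m/z
feature map with specific features colored by herb;
`plot_bar_chromatogram()` renders a signature's centroid bar chromatogram.

A thin command-line wrapper ships in `inst/cli/formulanet.R`
(`simulate` and `run` subcommands).

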