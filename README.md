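# barcodegap

DNA-barcode species delimitation for community surveys: from a COI FASTA
plus specimen metadata to distance summaries, barcode-gap and
nearest-neighbor analysis, threshold OTU clustering with concordance
classes, neighbor-joining trees with bootstrap support, and rule-based
candidate/cryptic species flags.

## The problem

Biodiversity surveys of poorly documented faunas (the motivating case is
small stream fishes) routinely pair morphological identification with COI
barcodes. The molecular side of such a study is a fixed sequence of steps:

1. **QC** — keep sequences ≥ 500 bp, without indels, ambiguities or
   premature stop codons under the vertebrate mitochondrial code.
2. **Distances** — pairwise Kimura 2-parameter (K2P) distances with
   pairwise deletion of non-comparable sites:

   d = −½ · ln[(1 − 2P − Q) · √(1 − 2Q)]

   where P and Q are the proportions of transitions (A↔G, C↔T) and
   transversions among comparable sites.
3. **Summaries** — base composition; mean/min/max distance at the
   intraspecific, intrageneric (same genus, different species) and
   intrafamilial (same family, different genus) ranks; and, per species,
   the maximum intraspecific distance and the nearest-neighbor distance
   (NND — minimum distance to any specimen of another species). A species
   has a *barcode gap* when NND exceeds its maximum intraspecific
   distance.
4. **OTUs** — single-linkage clusters at 2.2% K2P (a documented,
   reproducible proxy for BOLD's BIN clusters), each classified as
   concordant (one species), discordant (several species) or singleton
   (one specimen) against the morphospecies labels. Externally assigned
   clusters (true BINs) can be passed through instead.
5. **Tree** — neighbor joining on the K2P matrix with nonparametric
   bootstrap support (column resampling), written as Newick.
6. **Delimitation** — a species is a *candidate* when none of its OTUs is
   discordant and its NND > 2%; it is a *cryptic complex* when its maximum
   intraspecific distance > 2% and no morphological distinctiveness was
   reported.

The package implements the whole chain as composable tibble-in/tibble-out
functions, plus a seedable sequence simulator under the Kimura
two-parameter substitution process so every stage can be validated against
known ground truth without any external download.

## Worked example

```r
library(barcodegap)

sim <- simulate_barcodes(sim_config(
  n_species = 8, specimens_per_species = 5, enforce_orf = TRUE, seed = 42,
  cryptic_species = list(list(species = 3, divergence = 0.08, proportion = 0.4))))
write_simulation(sim, "demo")

res <- run_pipeline("demo/sim.fasta", "demo/metadata.tsv", "demo_out",
                    bootstrap = bootstrap_config(replicates = 100, seed = 7))
print(res)
#> Barcode delimitation run
#>   sequences: 40 (of 40 input)
#>   OTUs: 9 (concordant=9)
#>   species: 8; candidates: 8; cryptic complexes: 1

dplyr::select(tidy(res), species, candidate, cryptic_complex, n_otus,
              max_intra_pct, nnd_pct)
#> # A tibble: 8 × 6
#>   species   candidate cryptic_complex n_otus max_intra_pct nnd_pct
#>   <chr>     <lgl>     <lgl>            <int>         <dbl>   <dbl>
#> 1 Species01 TRUE      FALSE                1         1.69     4.31
#> 2 Species02 TRUE      FALSE                1         0.838    2.55
#> 3 Species03 TRUE      TRUE                 2         8.87     7.55
#> 4 Species04 TRUE      FALSE                1         1.35     4.12
#> 5 Species05 TRUE      FALSE                1         1.18     2.55
#> 6 Species06 TRUE      FALSE                1         0.334    5.56
#> 7 Species07 TRUE      FALSE                1         1.69     4.31
#> 8 Species08 TRUE      FALSE                1         0.334    4.12
```

The injected 8% lineage split in `Species03` is recovered: the species
splits into two concordant OTUs, its maximum intraspecific distance (8.9%)
crosses the 2% cryptic threshold, and — because neither OTU is discordant
and its NND stays above 2% — it remains a delimitation candidate as well.
All eight species are flagged as candidates, matching the construction.

`run_pipeline()` writes the full bundle (`qc_report.tsv`, distance
matrices, `composition.tsv`, `ranks.tsv`, `summary.tsv`, `otus.tsv`,
`species_profile.tsv`, `tree.nwk`, `delimitation.tsv`, `report.json`)
under the output directory; `report.json` echoes every threshold and seed
and is byte-identical across reruns with the same inputs.

A thin CLI wrapper lives at `inst/cli/barcodegap.R`:

```sh
Rscript inst/cli/barcodegap.R --fasta f.fa --metadata m.tsv --out out/ \
    --cluster-threshold 2.2 --bootstrap 1000 --seed 42
```

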