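---
title: "Distance-based barcode species delimitation: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-based barcode species delimitation: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodegap)
```

This vignette is the package's account of the science behind each stage:
the models and decision rules, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and
does not emulate, and the numerical and design choices that were genuinely
open.

## The distance model

All distances are Kimura 2-parameter (K2P): with `P` the proportion of
transition differences (A↔G, C↔T) and `Q` the proportion of transversion
differences among comparable sites,

$$d = -\tfrac{1}{2}\,\ln\!\big[(1 - 2P - Q)\sqrt{1 - 2Q}\big].$$

K2P is the conventional choice for COI barcode summaries, which makes the
numbers comparable across the barcoding literature; no other model (JC69,
TN93, GTR, gamma rates) is offered, deliberately.

**Pairwise deletion.** A column is excluded only for the pairs in which
either member carries a gap, `N` or a partial IUPAC ambiguity there. This
maximises comparable sites and matches the default of the common desktop
tools for distance summaries; complete deletion would discard a whole
column for one bad specimen. Partial ambiguities (R, Y, …) are treated as
non-comparable rather than probabilistically resolved — the simplest rule
that cannot manufacture signal.

**Undefined distances.** Two situations yield no usable distance: fewer
than `min_overlap` comparable sites (default 100 — below that, a 600 bp
barcode pair shares too little to say anything), and saturation, where the
log argument leaves its domain. Both are marked `NA` with a warning rather
than raised as errors, so one degenerate pair cannot kill a dataset run;
clustering treats them as "above threshold" (never merge on missing
evidence) and tree building refuses them explicitly. The domain check uses
an epsilon of 1e-12: counts that put $1-2P-Q$ exactly at zero leave
floating-point residue of order 1e-17, which would otherwise masquerade as
a finite, absurdly large distance.

## Distance summaries and the barcode gap

Rank summaries are strictly nested and mutually exclusive: intraspecific
(same species), intrageneric (same genus, *different* species),
intrafamilial (same family, *different* genus). Means are unweighted over
pairs, not over species — that is what a printed "based on N comparisons"
implies. Per species, the nearest-neighbor distance (NND) is the minimum
defined distance from any member to any specimen of another species, with
ties on the nearest species broken lexicographically; a barcode gap is
`nnd > max_intra`. Singletons (n = 1) have no intraspecific distance; they
are reported with the gap flag `TRUE` by convention and an explicit
`insufficient_sampling` note, since one specimen cannot contradict a gap.

## OTU clustering

The package's OTUs are single-linkage connected components at a K2P
threshold, default 0.022 substitutions/site — the published seed threshold
of BOLD's RESL algorithm. This is a documented *proxy*: RESL's refinement
step is proprietary and unpublished, so exact agreement with BOLD BIN
counts is not promised and never asserted. When true BINs are available
(as `external_cluster_id` in the metadata), the pass-through mode runs the
same concordance classification and delimitation on them, bypassing the
proxy. OTU IDs are the lexicographically smallest member ID, so clustering
is deterministic; a one-specimen OTU is classed `singleton` even though it
trivially contains one species, matching the three-way concordance
labelling used with BINs.

## Neighbor joining and bootstrap

NJ follows the standard Q-criterion algorithm. Two details are contracts,
not conveniences: ties in Q are broken by the lowest index pair in the
current node ordering, so runs are bit-reproducible across platforms; and
negative branch-length estimates are clamped to zero for display (the
usual convention in desktop phylogenetics software) with the raw estimates
kept in the `clamped_raw` attribute and summarised in a message. On
additive matrices the implementation recovers the generating tree exactly
(topology and branch lengths), which the test suite verifies against
independently generated random trees.

Bootstrap support is the standard column-resampling scheme: resample
alignment columns with replacement, recompute distances and the NJ tree,
and map bipartition frequencies onto the original-data tree (not a
consensus). Each replicate draws its own RNG stream from the master seed,
so supports are bit-identical for a fixed seed. Replicates whose resampled
matrix contains undefined distances are dropped with a warning and the
denominator adjusted — the alternative (imputing) would invent data.

## Delimitation rules

Two independent flags per species:

* **candidate** — no occupied OTU is discordant, and NND > 2%;
* **cryptic complex** — maximum intraspecific distance > 2%, and no
  morphological distinctiveness reported for the species.

Two interpretations were genuinely open. First, what "concordant cluster"
means for a species split over several OTUs: the package reads it as *no
discordant OTU* (singleton OTUs allowed), so a species whose deep lineages
fall into two clean OTUs remains a candidate — this is the reading under
which the arithmetic "species minus discordant-BIN species" reproduces the
kind of candidate counts such surveys report, and it is configurable
upstream by supplying external clusters. Second, morphological
distinctiveness is an input (`morphology_distinct`), defaulting to
`FALSE`: the package cannot assess morphology, so every deeply divergent
species is a cryptic candidate unless the user says otherwise. The
rationale string on every row names the rules that passed or failed, so
decisions are auditable. Both flags can be true at once; they answer
different questions.

Thresholds are in percent at every user-facing surface (matching how the
field writes them); internal computation is in substitutions/site, with
the conversion localised in `run_pipeline()`.

## The synthetic-data generator

`simulate_barcodes()` generates datasets with the statistical structure
the analysis assumes, with known truth labels:

* a root sequence carrying the configured base composition **exactly**
  (rounded per-base counts, shuffled site order). A multinomial draw at
  600 bp would leave ~1.8% composition noise that every descendant
  inherits, defeating the generator's own composition contract;
* species ancestors on a random coalescent-shaped tree rescaled so the
  mean pairwise divergence equals `inter_depth` (default 0.10), with a
  floor (`min_separation`, default 0.04) on the closest ancestor pair,
  implemented by extending terminal branches equally. The floor mirrors
  the smallest nearest-neighbor distances such surveys actually report
  (~4%); without it, coalescent scaling routinely produces sister species
  far closer than any observed NND, which would misrepresent the data the
  analysis is meant for. Injected discordant pairs deliberately bypass the
  floor;
* within species, a star genealogy: specimen branches exponential with
  mean `intra_depth / 2` (default pairwise expectation 0.5%). A full
  coalescent within species would add realism the summaries never see;
* evolution site-by-site under the K80 process at rate ratio `kappa`
  (default 3). Generator and estimator share the model family on purpose:
  `expected_k2p()` gives the closed-form expectation, and recovery checks
  are exact in expectation rather than approximate;
* cryptic complexes as two lineage ancestors `divergence` apart;
  discordant pairs as two species ancestors at `discordant_separation`
  (default 0.005, safely under the 0.022 cluster threshold);
* genus and family labels by cutting the species tree at `inter_depth`
  and `2 * inter_depth` — nested by construction.

Default sample sizes draw from an empirical per-species count multiset
(29 values, 2–24, mean ≈ 8.6) typical of single-basin fish surveys; with
29 species the multiset is used verbatim (250 specimens).

**ORF-preserving mode.** Neutral simulation produces stop codons almost
surely (a random 600 bp frame is stop-free with probability ~1e-6), so by
default the generator makes no reading-frame guarantee and QC is tested
with constructed fixtures. With `enforce_orf = TRUE` the root is drawn
stop-free in frame 1 and every branch is redrawn until the child keeps
that frame open — a crude but honest stand-in for purifying selection
against nonsense mutations. The conditioning has a visible cost: stop
codons are A-rich (TAA, TAG, AGA, AGG), so ORF-conditioned datasets run
~2% below the configured A frequency. Pipeline-level tests and the
acceptance run use this mode because they must pass QC; composition and
parameter-recovery tests use the unconditioned default.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: rate heterogeneity across sites (gamma),
base-composition bias in the substitution process itself, sequencing
error, heterospecific contamination, misidentified reference records (the
main real-world source of discordant clusters), and within-species
population structure beyond a two-lineage split.

## Statistical form of the generator checks

Two test-design points worth recording. Sequences within one simulated
dataset are correlated through the shared root and species tree, so the
composition check pools five independent simulations (600 sequences)
before asserting the 1%-absolute bound. Likewise, intraspecific pairs
sharing a specimen are correlated, so the depth-recovery check computes
its standard error over per-species means, not over pairs.

The delimitation-recovery experiment (20 seeds; one injected 8% cryptic
complex, one injected sub-threshold species pair; expected counts 18
candidates, 1 cryptic, 2 discordant-excluded) runs at `intra_depth =
0.002` — the low end of the typical 0–0.5% range — because at 0.5% the
exponential depth tails let large species (n up to 24) cross the 2%
max-intra rule on their own, and the constructed expectation would be
ill-defined. That is a property of a fixed 2% rule under heavy-tailed
intraspecific variation, worth knowing when interpreting real flags.

## Problem sizes

The acceptance script runs the full default simulation (29 species, 250
specimens, 600 bp) with 100 bootstrap pseudo-replicates; the pipeline's
own default remains 1000 replicates, the conventional choice for a
publication tree. The test suite uses 10–200 replicates and 3–30 taxa per
case, sizes at which every oracle (site-loop distances, four-point
additive trees, graph components) is exhaustively checkable.

## Known limitations

* Alignment is an input contract: the package refuses unequal-length
  sequences rather than aligning them.
* The BIN proxy is single linkage only; no RESL refinement, no ABGD/ASAP/
  GMYC-style model-based delimitation.
* K2P only; saturated pairs are reported as undefined rather than
  corrected with a better model.
* The stop-codon screen scans the three forward frames only (barcode
  amplicons are conventionally sense-strand) and treats any stop in a
  complete codon as a failure — for an amplicon internal to the gene a
  terminal stop is as anomalous as an internal one.
* Bootstrap supports on very shallow nodes (identical haplotypes) are
  tie-break-dependent and should be read as unresolved, not as evidence.
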