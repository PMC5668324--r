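# barcodeval

Evaluation of DNA barcode loci and their combinations for species
identification.

When a reference library is built for a small group of closely related
species — say, a handful of endangered congeners and the adulterant they
are traded as — the practical questions are always the same: *which locus,
or which combination of loci, separates the species? by how much? and can
the difference be turned into a cheap diagnostic assay?* `barcodeval`
implements the standard battery used to answer these questions for plant
barcoding reference libraries (core barcodes *rbcL* and *matK*,
supplementary *psbA-trnH*, *ITS*, *ITS2*), and a seeded simulator of
multi-locus barcode datasets so every stage is testable without downloads.
It is aimed at molecular ecologists and conservation geneticists working
with alignments of tens of individuals over a few loci.

## What it computes

* **Alignment characteristics** per locus: variable, parsimony-informative
  and conserved sites, indel events, mean pairwise identity
  (`alignment_stats()`, `dataset_stats()`).
* **K2P distances and the barcode gap.** With transition proportion *P*
  and transversion proportion *Q* over the compared sites (pairwise
  deletion of gaps/ambiguities),

  d = −½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q).

  Per species: maximum/mean intra-specific distance, nearest-neighbour
  (NN) distance, and the local barcode gap `max_intra < NN`
  (`k2p_matrix()`, `species_summaries()`, `distance_histogram()`,
  `plot_barcode_gap()`).
* **Distance-based identification** by Best Match, Best Close Match and
  All Species Barcodes, with leave-one-out
  correct/misidentified/not-identified rates and a data-driven
  intra-specific distance threshold (`classify_queries()`,
  `bcm_threshold()`, `identification_rates()`).
* **Character-based identification**: pure species-diagnostic nucleotides,
  deterministic conjunctive rule induction with 90% train / 10% test
  slicing, and CAPS assay design by degenerate restriction-site scanning
  around diagnostic SNPs (`find_diagnostic_characters()`,
  `induce_rules()`, `scan_restriction_sites()`, `design_caps()`).
* **Trees**: neighbour joining on K2P (negative branches clamped),
  maximum parsimony by exact branch and bound or seeded SPR hill-climbing,
  tree length with CI/RI/RC, strict consensus, bootstrap supports and
  species-monophyly tests (`nj_tree()`, `mp_search()`,
  `consistency_indices()`, `strict_consensus()`, `bootstrap_support()`,
  `is_species_monophyletic()`).
* **Simulation**: K2P forward evolution along a species tree with a star
  phylogeny within species, optional 1–3 bp indels, and injected
  species-specific SNPs (`sim_config()`, `simulate_dataset()`,
  `evolve_k2p()`).
* **Orchestration**: `barcode_report()` runs everything over all loci and
  their multi-locus combinations (five loci = 31 evaluated locus sets) and
  `write_report()` emits TSV/Newick/JSON.

See the vignette (`vignettes/barcode-evaluation.Rmd`) for the models,
parameter semantics and design choices.

## Worked example

Simulate a study-scale dataset — four species sampled 5/5/5/2 (17
individuals), five loci, an injected species-specific *matK* SNP at
position 230 — then evaluate it:

```r
library(barcodeval)

sim <- simulate_dataset(sim_config(
  seed = 42,
  injected_snps = data.frame(locus = "matK", position = 230,
                             species = "species2", state = "T")))
ds <- sim$dataset
ds
#> <barcode_dataset> 5 loci (rbcL, matK, psbA-trnH, ITS, ITS2), 17 individuals, 4 species

species_summaries(k2p_matrix(ds$loci$matK), ds$species_map)
#> # A tibble: 4 × 8
#>   species      n mean_intra max_intra nn_species nn_species_all nn_distance gap_present
#>   <chr>    <int>      <dbl>     <dbl> <chr>      <list>               <dbl> <lgl>
#> 1 species1     5      0         0     species2   <chr [1]>             3.83 TRUE
#> 2 species2     5      0.267     0.535 species1   <chr [1]>             3.83 TRUE
#> 3 species3     5      0.214     0.535 species4   <chr [1]>             4.25 TRUE
#> 4 species4     2      0         0     species3   <chr [1]>             4.25 TRUE
```

Every species shows a local barcode gap on *matK*: the largest
within-species K2P distance (0–0.54%) is far below the distance to the
nearest non-conspecific (3.8–4.3%). Leave-one-out identification on the
three-locus core barcode:

```r
identification_rates(ds, c("rbcL", "matK", "ITS"))
#> # A tibble: 3 × 6
#>   loci          method     n correct_pct misidentified_pct not_identified_pct
#>   <chr>         <chr>  <int>       <dbl>             <dbl>              <dbl>
#> 1 rbcL+matK+ITS BM        17       100                   0                0
#> 2 rbcL+matK+ITS BCM       17       100                   0                0
#> 3 rbcL+matK+ITS ASB       17        82.4                 0               17.6
```

Best Match and Best Close Match identify every individual; the stricter
All Species Barcodes criterion leaves 17.6% unidentified (queries whose
within-threshold set misses a conspecific), with no misidentifications.
The injected diagnostic SNP is recovered among the *matK* diagnostics for
its species:

```r
dc <- find_diagnostic_characters(ds$loci$matK, "species2")
dc[dc$position == 230, 1:5]
#> # A tibble: 1 × 5
#>   locus species  position position_ungapped state
#>   <chr> <chr>       <int>             <int> <chr>
#> 1 matK  species2      230               230 T
```

and `design_caps(ds$loci$matK)` reports which diagnostic SNPs fall inside
a restriction site of the BstXI/MnlI/HphI/AlwI panel (five assays for this
dataset, e.g. an HphI cut private to species1). Finally, parsimony on the
concatenation:

```r
mp_search(concat_loci(ds, c("rbcL", "matK", "ITS")),
          strategy = "hillclimb", seed = 1, replicates = 5)
#> <parsimony_result> 1 best tree(s), length = 238 steps
#>   CI = 0.9958, RI = 0.9986, RC = 0.9944 (200/2106 informative characters; hillclimb search)
```

The 2106-column concatenation (676 + 751 + 679) yields a most
parsimonious tree of 238 steps with almost no homoplasy (CI ≈ 1), on
which all species are monophyletic.

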