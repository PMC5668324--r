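---
title: "Evaluating DNA barcode loci with barcodeval: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating DNA barcode loci with barcodeval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodeval)
```

# What the package evaluates

DNA barcoding identifies specimens by comparing short standardized DNA
regions against a reference library. For plants, no single locus resolves
all groups: the core plastid barcodes *rbcL* and *matK* are typically
complemented by *psbA-trnH* and the nuclear spacers *ITS*/*ITS2*, and the
practical question for any new group is *which locus, or which combination
of loci, separates the species*. `barcodeval` implements the standard
evaluation battery used to answer that question for a small, densely
sampled reference library (a few species, a handful of individuals each):

1. per-locus alignment characteristics (variable, parsimony-informative
   and conserved sites, indel events, pairwise identity);
2. Kimura two-parameter (K2P) distance matrices and the *barcode gap*;
3. distance-based identification — Best Match (BM), Best Close Match (BCM)
   and All Species Barcodes (ASB) — scored by leave-one-out
   identification rates;
4. character-based identification — species-diagnostic nucleotides and
   conjunctive classification rules with train/test slicing — plus CAPS
   (cleaved amplified polymorphic sequence) assay design around diagnostic
   SNPs;
5. neighbour-joining and maximum-parsimony trees with consistency indices,
   bootstrap support and species-monophyly tests.

A seeded forward simulator generates multi-locus barcode datasets with the
statistical structure these analyses assume, so the whole pipeline is
testable end to end without any sequence downloads.

Alignment is an *input*: the package reads pre-aligned gapped FASTA and
never re-implements an aligner.

# The distance model

For two aligned sequences, sites where either carries a gap or an IUPAC
ambiguity code are excluded (*pairwise deletion*). With transition
proportion $P$ and transversion proportion $Q$ over the $n$ compared
sites, the K2P distance is

$$ d \;=\; -\tfrac{1}{2}\,\ln(1 - 2P - Q) \;-\; \tfrac{1}{4}\,\ln(1 - 2Q). $$

When $1-2P-Q \le 0$ or $1-2Q \le 0$ the pair is saturated: the distance is
recorded as `Inf` and flagged undefined — never silently zeroed. Undefined
pairs are excluded from means and nearest-neighbour searches but are
counted in reports. Distances are stored as proportions and rendered as
percentages (×100) in all summary tables.

## The barcode gap

The gap criterion is evaluated *per species* (the "local" gap): a species
shows a gap when its maximum intra-specific distance is smaller than its
nearest-neighbour (NN) distance, the minimum distance from any member to
any non-conspecific individual. This matches the usual 1:1-line scatter
reading (`plot_barcode_gap()`), and deliberately avoids claiming a single
global gap, since coalescent depths differ between species. Singleton
species have intra-specific spread 0 by definition. NN ties are reported
in full, alphabetically, with the first species as primary.

# Distance-based identification

All three criteria are run leave-one-out: each individual in turn is the
query, removed from the reference set. The BCM/ASB threshold, however, is
computed once on the full dataset, matching the batch behaviour of the
classical implementations.

* **BM** assigns the query from the set of references at minimum distance.
  Ties within a tolerance $\varepsilon$ (default $10^{-9}$ on the
  proportion scale, i.e. exact-tie semantics; configurable) are kept as a
  set: all conspecific → *correct*; all allospecific → *misidentified*;
  mixed → *ambiguous*.
* **BCM** additionally requires the best match to lie within a distance
  threshold; otherwise the query is *not identified* (no match).
* **ASB** is the strictest criterion: *correct* requires the
  within-threshold match set to contain **every** conspecific reference
  and (by default) **no** allospecific one. A lenient variant that
  tolerates allospecifics inside the threshold when they are strictly
  farther than all conspecifics is available via `asb_strict = FALSE`;
  the strict reading is the default because it is the variant under which
  ASB is meaningfully "stricter than BCM" for every dataset.

In aggregated rates, *ambiguous* and *no match* are pooled as
"not identified", so correct/misidentified/not-identified sum to 100%.

**Threshold.** The default threshold is the 95th percentile of all defined
intra-specific distances, with linear interpolation (the `type = 7`
quantile convention, R's default). The percentile is a tunable parameter
(`bcm_threshold(..., percentile = )`) because published analyses rarely
print the threshold they used; making it explicit is the only way a rate
table can be reproduced. Note a numerical subtlety of interpolated
percentiles: they are exactly invariant under duplication of the distance
multiset only in the large-sample limit, not at small $n$; we accept this
in exchange for the determinism of a standard, widely understood
definition.

# Character-based identification

A column is a **pure diagnostic character** for a species when every
member carries the same unambiguous base there and no non-member can carry
it. Member gaps or ambiguity codes disqualify the column; a non-member
ambiguity code whose state set contains the candidate base also
disqualifies it (conservative reading — an assay must not rely on a
position a non-target might share). Positions are reported as 1-based
alignment columns together with the coordinate in the species' own
gap-free consensus; for indel-free loci the two coincide.

**Rule induction** (`induce_rules()`) splits individuals per species into
a training slice (default 90%: `n_train = min(n - 1, ceiling(0.9 n))`, so
both slices are always non-empty) and induces, per species, a conjunction
of (position, state) pairs that covers every training member and matches
no training non-member. Single pure diagnostic characters are preferred;
failing that, the smallest conjunction is found exhaustively when a
species has at most 12 candidate pairs, and by greedy forward selection
(maximising non-member exclusion, ties broken by lowest position)
otherwise. The search is fully deterministic given the split seed — a
deliberate replacement of stochastic metaheuristics with identical rule
semantics, so that the same data always yield the same rules. Species with
a single individual cannot be sliced and are excluded with a warning.
Test individuals matching exactly one rule are assigned to it; multiple
matches are ambiguous and no match is unidentified, aggregated exactly as
in the distance-based rates.

**CAPS design** (`design_caps()`) asks which diagnostic SNPs can be typed
by restriction digestion. Per species, a majority-rule consensus is built
per column (ties leave the column unusable and poison any scanning window
that touches it — assays must rely on fixed differences); the gap-free
consensus around the SNP (site length − 1 on each side) is scanned for
degenerate recognition-site matches on both strands, and an assay is
emitted when site presence overlapping the SNP differs between the target
species and *every* other species. The built-in panel covers BstXI
(`CCANNNNNNTGG`), MnlI (`CCTC`), HphI (`GGTGA`) and AlwI (`GGATC`) and is
extensible from a TSV file. Because no cut offsets are configured for the
default panel, assays are reported as cut / no-cut patterns rather than
fragment sizes.

# Trees and parsimony diagnostics

Neighbour joining runs on the K2P matrix with negative branch lengths
clamped to zero; it refuses matrices with undefined entries. Maximum
parsimony uses equal-weights Fitch lengths with gaps treated as missing
data (ambiguity codes as partial state sets). Two search strategies are
offered: exact branch and bound (default up to 12 taxa, refused above 16
without `force = TRUE`) and a seeded hill-climb (random-addition starting
trees with SPR branch swapping to a local optimum, over a configurable
number of restarts, all equally-best trees retained). SPR was chosen as
the swap neighbourhood because at the scale this package targets
(≤ ~20 taxa) it reaches the same optima as wider neighbourhoods while
remaining fast and available in a mature search engine; the exact
branch-and-bound strategy provides the guarantee whenever the taxon count
permits.

Consistency diagnostics follow the classical conventions: per character,
minimum steps $m$ = distinct observed states − 1, maximum steps on a star
tree $g$ = taxa with data − frequency of the most common state, and
observed steps $l$ from Fitch; then CI $= M/L$, RI $= (G-L)/(G-M)$,
RC $=$ CI·RI over the summed quantities. Because reported values in the
literature differ in whether parsimony-uninformative characters are
included, both conventions are always computed; the headline `ci`/`ri`/
`rc` fields use all characters (constant characters contribute zeros, so
this equals the all-variable-characters convention). When $G = M$ (no
informative variation) the indices are returned as `NA`, flagged rather
than fabricated. Tree length is reported for the best binary trees; the
strict consensus is returned alongside but not assigned a length of its
own, since Fitch scores on polytomies are only upper bounds obtained by
arbitrary resolution.

Bootstrap support resamples alignment columns with replacement, rebuilds
each pseudo-replicate with the chosen builder (NJ, or one random-addition
+ SPR parsimony search per replicate), and reports the percentage of
replicates containing each original-tree bipartition. Everything is
driven by a single integer seed.

# The simulator: what it emulates, and what it does not

`simulate_dataset()` produces data under exactly the model the analyses
assume: a uniform-random root sequence per locus evolves along a species
tree under K2P (exact per-site transition probabilities, not a Bernoulli
approximation), and individuals radiate from their species ancestor on
independent branches of length `intra_divergence / 2` — a star phylogeny
within species, chosen over a coalescent because it matches the analyses'
assumptions and keeps divergence calibration closed-form: the expected
K2P distance between two conspecific individuals is then exactly
`intra_divergence`, and between individuals of sister species
`inter_divergence + intra_divergence` (each individual contributes its own
within-species branch). The default species tree is a ladder with every
edge `inter_divergence / 2`, so sister species sit at the configured
divergence and deeper pairs farther apart; any Newick species tree (edge
lengths in expected substitutions per site) may be supplied instead.

Defaults mirror a realistic small plant-barcoding study: four species
(three close congeners and one distant, outgroup-like taxon) sampled
5/5/5/2 for 17 individuals; loci `rbcL`/`matK`/`psbA-trnH`/`ITS`/`ITS2`
with aligned lengths 676/751/380/679/406 bp; indel events confined to the
nuclear spacers (expected 19 and 6 events of length 1–3, truncated
geometric); transition/transversion ratio $\kappa = 2$; intra-specific
divergence 0.2% (within the 0–0.3% band typical of such studies) and
sister-species divergence 3% (within the 0.4–12% band). Injected
species-specific SNPs are applied after evolution and guaranteed fixed in
the target species and absent elsewhere; a SNP whose state equals the
non-target consensus is rejected as inconsistent.

The simulator does **not** model rate heterogeneity across sites,
recombination, within-species coalescent structure, alignment error or
secondary-structure constraints on the spacers. Passing tests on
simulated data therefore demonstrate algorithmic correctness and
statistical calibration under the assumed model — not robustness to the
ways real loci violate it (e.g. *psbA-trnH* inversions, ITS paralogy).

# Numerical choices and degenerate inputs

* Tie tolerance for best-match sets: $10^{-9}$ on proportions.
* Saturated K2P pairs: `Inf` + flag; matrices with undefined entries are
  rejected by NJ and excluded from summaries.
* Pairwise identity: gap-vs-base counts as a compared mismatch by default
  (`gap_mode = "exclude"` drops such sites); gap-vs-gap is always
  excluded. Both conventions are exposed because published identity
  figures rarely state theirs.
* Indel events are maximal gap runs; runs with an identical (start, end)
  span in several sequences count once, since shared deletions are single
  evolutionary events.
* A column varying only by gaps is part of the indel accounting, never a
  variable site; ambiguity codes never contribute to variability.
* Empty match sets, single-species datasets, species without non-members,
  and zero-overlap sequence pairs raise informative errors rather than
  returning degenerate numbers.

# Validation strategy and problem sizes

The test suite checks every core computation against an independent
oracle: K2P against the closed form evaluated per pair (and against an
established distance implementation), Fitch lengths against exhaustive
internal-state enumeration on 5 taxa, branch-and-bound search against
all-topology enumeration on up to 7 taxa, diagnostic characters against a
direct column-by-column scan, restriction-site matching against a naive
sliding window, and strict consensus against brute-force bipartition
intersection. Statistical calibration uses 50 simulation replicates at
1000 bp for divergence recovery (agreement within three Monte-Carlo
standard errors), and 20 seeds for species-tree topology recovery by NJ
and MP when inter-specific divergence is ten times the intra-specific
one. These sizes were chosen to make Monte-Carlo error small relative to
the effects being checked while keeping the default suite quick to run.

# Known limitations

* The package evaluates reference libraries of modest size (tens of
  individuals, kilobase-scale concatenations); it is not engineered for
  thousands of sequences.
* Only the K2P model is implemented for distances, by design — the
  evaluation battery it supports is defined in terms of K2P.
* Likelihood and Bayesian tree inference are out of scope; parsimony and
  NJ cover the package's comparative purpose.
* CAPS assays are validated in silico against consensus sequences only;
  wet-lab validation (primer design, digestion efficiency) is beyond the
  package's remit.
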