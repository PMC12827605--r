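---
title: "Reconstructing gain, loss and transfer histories of carbon-fixation gene sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing gain, loss and transfer histories of carbon-fixation gene sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathtracer)
library(dplyr)
```

## The inference problem

Two carbon-fixation routes are built from overlapping multi-subunit machinery:
the Wood-Ljungdahl (WL) pathway, whose carbonyl branch requires the
five-subunit CODH/ACS complex (AcsA--AcsE), and the reductive glycine (rGly)
pathway, which runs the five-protein glycine cleavage system (GCS: P-protein
alpha and beta, T-, L- and H-proteins) in reverse. Both need formate
dehydrogenase (FDH), which occurs in two catalytic-subunit families
(cytoplasmic Fdh and FdhG). Given (i) protein similarity-search hit tables
against a set of genomes, (ii) per-gene maximum-likelihood trees, (iii) genome
annotation, and (iv) a species tree with clade labels, `pathtracer` infers
which species encode which pathway, which gene copies are operonic and hence
plausibly functional, which copies arrived by horizontal gene transfer (HGT),
and finally a per-branch gain/loss/transfer scenario for each gene set on the
species tree.

The pipeline is five deterministic stages, each usable on its own:

1. **Homolog screening** (`filter_hits`, `build_presence_matrix`): a hit
   counts as a homolog iff its e-value is strictly below `1e-5` *and* its
   query coverage is at least 70%. The bounds are deliberately asymmetric
   (strict vs inclusive) and exposed in `thresholds()`. Curation helpers
   implement the metagenome-assembled-genome (MAG) rule -- per query enzyme,
   only the best `ceiling(10%)` of MAG-derived hits by e-value survive -- and
   one-representative-per-taxid selection.
2. **Pathway calls** (`call_pathways`): WL is called iff FDH (either family)
   and all five CODH/ACS subunits are present; rGly iff FDH and all five GCS
   subunits are present. Downstream completeness (PFO + PSP + SHMT for the
   serine route, the five glycine reductase subunits for the alternative
   rGly exit) is reported alongside, and `autotrophy_consistency()` compares
   the calls with curated autotrophy flags without ever modifying them.
3. **Synteny** (`detect_cluster`): an AcsA copy is "clustered" iff a chain of
   CODH/ACS subunit genes can be grown from it with at most
   `cluster_max_gap = 2` intervening non-subunit genes between consecutive
   members, on one contig, strand ignored. Copies reaching three or more
   distinct partners are eligible for concatenated phylogenetics. Clustered
   copies are annotated "WL-candidate", unclustered ones "standalone
   CooS-like".
4. **Gene-tree screening** (`prune_long_branches`, `test_monophyly`,
   `split_focal_groups`, `classify_hgt`): leaves with pendant branches longer
   than 1.5 substitutions/site are pruned once (long internal branches are
   reported, never pruned); monophyly of the focal phylum is evaluated as an
   edge bipartition so no rooting is assumed; well-supported all-focal clades
   are numbered group 1, 2, ... by size; and each focal sequence is classified
   vertical / hgt_candidate / unresolved (below).
5. **Ancestral scenario** (`build_scenario`): Dollo parsimony per gene set,
   with transferred presence recoded before reconstruction and restored as
   explicit `hgt_gain` events.

## The HGT decision rule

The classification criterion is gene-tree/species-tree conflict: a focal
sequence that nests, with strong bootstrap support, inside a distantly
related clade was probably acquired horizontally. Making that verbal
criterion operational required three choices:

* A focal leaf inside the **largest all-focal bipartition side** is
  `vertical` -- it offers no conflict signal.
* Any other focal leaf is judged by the **smallest bipartition side that
  contains it together with at least one non-focal leaf**. If that side's
  support reaches `hgt_support_min` (default 95, the package-wide "strong
  support" level) and one foreign group holds a strict majority (fraction
  > 0.5 by default) of its non-focal leaves, the verdict is `hgt_candidate`
  with that group as donor.
* In every other case the verdict is `unresolved`. In particular, when the
  smallest enclosing mixed clade is poorly supported the rule does **not**
  escalate to a larger, better-supported clade: a weakly supported nesting is
  treated as no evidence, and no evidence must never silently become
  `vertical`. This conservatism costs sensitivity when only the innermost
  attachment edge is noisy, but it guarantees that degrading support can only
  move verdicts toward `unresolved`, never flip them between the two
  substantive classes.

One further numerical subtlety: in a rooted tree the two edges under the root
describe the same unrooted bipartition but can carry different labels. Sides
are therefore deduplicated by leaf set keeping the *minimum* support, again
the conservative direction.

## Dollo, not Fitch, as the scenario model

`build_scenario` reconstructs each gene set under Dollo parsimony: one gain,
on the stem of the most recent common ancestor of all carriers, and one loss
on the stem of every maximal carrier-free subtree below it. This matches the
biology of multi-subunit complexes -- independent re-invention is not
credible, re-appearance is explained only by transfer -- and it is exactly the
reasoning that places, on the shipped clade-level backbone
`(((((A,B),C),D),E),OUT)`, the CODH/ACS loss on the clade-A stem and the GCS
loss on the (A,B) stem with a PVC-donated regain on the A stem.

Unconstrained Fitch parsimony (`fitch_min_changes`) is retained as a
diagnostic: a trait whose Fitch minimum beats the single-gain optimum is
flagged as homoplastic and its Dollo scenario should be read with suspicion.
The Fitch implementation is checked against exhaustive minimization over all
internal labelings on every rooted six-leaf topology.

Transfer recoding happens *before* the Dollo step: species whose only copy is
horizontally acquired are set to absent, so transferred presence can never
drag the vertical gain upward -- this is what lets a complex be "lost in the
ancestor of clades A-B" even though clade A demonstrably carries the genes
today. `hgt_gain` events (with donor) are then placed on the stem of each
maximal recoded clade; a non-monophyletic recode set gets one event per
maximal sub-clade, with a warning.

Within one edge, replay order is gain, then loss, then `hgt_gain`; this makes
`ancestor_report()` exact at every node, including leaves, which is asserted
as an invariant.

## Tunable parameters

| name | default | unit | role |
|---|---|---|---|
| `evalue_max` | 1e-5 | — | homolog e-value bound (strict `<`) |
| `min_query_coverage` | 70 | % of query | homolog coverage bound (inclusive) |
| `mag_keep_fraction` | 0.10 | fraction | MAG hits kept per query (ceiling) |
| `long_branch_cutoff` | 1.5 | subst./site | pendant-branch exclusion (strict `>`) |
| `hgt_support_min` | 95 | bootstrap % | support needed for an HGT call |
| `group_support_min` | 95 | bootstrap % | support for a "distinct group" |
| `cluster_max_gap` | 2 | genes | intervening non-subunit genes in a chain |
| `cluster_min_partners` | 3 | subunits | concatenation eligibility |
| `hgt_majority` | 0.5 | fraction | strict donor-majority requirement |

The ceiling in the MAG rule guarantees at least one MAG hit survives whenever
any exist; ties in e-value break by descending bitscore then ascending
subject id, so reruns are byte-identical. Query coverage is accepted only on
the 0--100 scale; a column that looks like 0--1 fractions is rejected rather
than rescaled, because silent unit conversion is how screening thresholds go
wrong. Coordinates are 1-based inclusive throughout; the BED export converts
explicitly.

The synteny chain gap of 2 is a design choice, not a published number: the
published analysis was a manual inspection. Any small value reproduces the
two anchoring observations (a contiguous acsA--acsE run is clustered; an
AcsA alone on its contig is not); 2 tolerates small insertions while
excluding genome-distant copies, and it is exposed in `thresholds()` rather
than hard-coded. Likewise the paperless questions -- per-HSP vs aggregate
coverage, strandedness of cluster partners -- are resolved by recording
coverage as given and ignoring strand, both documented here rather than
buried in code.

## What the synthetic generator emulates

`simulate_dataset()` produces every input the pipeline consumes, plus ground
truth. The model: a random rooted binary species tree (`n_species = 55` by
default, matching a phylum-scale screen; exponential branch lengths) cut into
five monophyletic clades A--E; per trait, presence starts at the root and is
lost along edges by a Poisson draw with expectation `loss_rate = 1.5` per
tree, length-weighted, Dollo-style (no spontaneous regain); with expectation
`hgt_rate` per trait a lost lineage regains the trait from an external donor
group (PVC, Myxococcota or Nitrospirota). Gene trees are the species tree
restricted to surviving carriers, wrapped in an outgroup scaffold of donor
clades, with transferred copies grafted sister to a donor leaf; supports are
100 on true clades unless deliberately degraded. Hit tables give every
present cell a passing hit (e-value log-uniform in decades, so the cutoffs
are exercised densely on both sides) and absent cells decoys that fail
exactly one rule; MAG genomes add weaker passing hits for the curation stage.
Annotation tables lay acs genes out contiguously or dispersed per species.

The truth log stores the *identifiable* representation of each history: the
gain on the stem of the smallest clade containing all surviving vertical
carriers and the losses inside it. A loss that erased an entire flank above
that clade leaves no trace in any observable data and is therefore not
logged; no reconstruction method could recover it, and pretending otherwise
would make truth comparisons meaningless.

What the generator does **not** emulate: sequence-level evolution (no
alignments, no substitution models, no gene-tree estimation error beyond the
optional support degradation), compositional artifacts behind long-branch
attraction, partial-complex assembly, or annotation errors. Passing the
end-to-end identity tests therefore shows the *logic* of the pipeline is
lossless under clean evidence -- it says nothing about BLAST sensitivity or
tree-inference quality on real data, which enter upstream of this package.

## Numerical choices and degenerate inputs

* Fitch: soft polytomies are resolved arbitrarily (`ape::multi2di`) and
  flagged; ties in the top-down pass prefer presence at the root and parental
  state elsewhere, so the returned labeling is deterministic.
* Dollo with zero carriers returns an explicit `never_present` record, not an
  error; a single carrier places the gain on that pendant edge.
* Monophyly of the full leaf set is `monophyletic` by convention (no edge
  separates it, but no edge contradicts it either).
* Empty hit files parse to empty tables with a warning; malformed lines are
  skipped, counted and reported by line number so that
  `rows in = rows parsed + rows reported`.
* All subseeds derived from a user seed stay below 2^31.

## Problem sizes used by the test-suite

The shipped tests run the Fitch oracle on all 945 rooted six-leaf topologies
times all 64 leaf patterns against a 2^5 brute force; the monophyly oracle on
500 random 12-leaf trees; transfer recovery on 100 simulated gene trees of 20
species with one planted transfer each; and the end-to-end identity on a
noiseless 30-species, 12-trait dataset. These sizes were chosen to exhaust
the small cases completely (everything up to symmetry at six leaves) while
keeping a full test run around a minute; the package functions themselves
have no size limits beyond memory.

## A worked example

```{r example}
tr <- clade_backbone_tree()
scen <- build_scenario(tr, list(
  list(trait_id = "FdhG",
       leaf_states = c(A = TRUE, B = TRUE, C = TRUE, D = TRUE, E = TRUE,
                       OUT = FALSE)),
  list(trait_id = "CODH/ACS",
       leaf_states = c(A = FALSE, B = TRUE, C = TRUE, D = TRUE, E = TRUE,
                       OUT = FALSE)),
  list(trait_id = "GCS",
       leaf_states = c(A = TRUE, B = FALSE, C = TRUE, D = TRUE, E = TRUE,
                       OUT = FALSE),
       hgt_recode = tibble::tibble(species = "A", donor = "PVC"))
))
tidy(scen)
ancestor_report(scen, c("A", "B", "C", "D", "E"))
```

The phylum ancestor is reconstructed carrying all three key gene sets; clade
A lost CODH/ACS, clades A-B lost GCS, and clade A's extant GCS genes are a
PVC-group transfer -- which is exactly the narrative encoded by the event
table above.

## Known limitations

* The HGT rule is topological nestedness, not event-cost reconciliation; a
  DTL model could resolve cases this rule leaves `unresolved`, at the price
  of rate assumptions the data here cannot support.
* Scenario resolution is bounded by the species tree supplied; the shipped
  backbone is clade-level, so within-clade placements (e.g. a loss "after
  the first species of a clade split off") need a species-level tree.
* Pathway calls are gene-content statements. A complete gene set is not a
  demonstration of autotrophic growth, which is why heterotrophs with
  complete sets are reported as their own category rather than as errors.
* The MAG curation and representative selection act on hit tables only; they
  cannot rescue a genome whose genes were never predicted.
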