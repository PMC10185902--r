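---
title: "Screening clade-defining Y-chromosomal InDels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening clade-defining Y-chromosomal InDels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yindelscreen)
```

## The problem

The male-specific region of the Y chromosome is transmitted father to son
without recombination, so its variants accumulate along paternal lineages and
partition Y chromosomes into a nested hierarchy of haplogroups
(O → O1 → O1a → O1a1 …). Haplogroup-defining markers are overwhelmingly
SNPs; insertion/deletion polymorphisms (InDels) are equally stable but far
more convenient to type (fragment-length assays, small amplicons for degraded
DNA), and very few of them are anchored in the reference tree. This package
implements a screen that discovers *phylogenetically informative* InDels —
variants whose derived allele tracks exactly one clade — from a multi-sample
chromosome-Y VCF, plus everything needed to exercise the screen offline:
tree handling, a haplogroup caller, a seeded cohort simulator with a
planted-variant truth table, and a consistency validator.

## The statistic at the core

Write $S(C)$ for the samples whose called haplogroup lies in clade $C$
(i.e. at $C$ or any descendant), and $D$ for the carriers of a variant's
derived allele. The variant is **clade-exact** for $C$ iff

* **criterion 1** — every called member of $S(C)$ is in $D$
  (the derived state is fixed in the clade, so it is no private or
  recurrent mutation), and
* **criterion 2** — no called sample outside $S(C)$ is in $D$
  (the derived state is specific to the clade).

The screen proposes $C^\* = \mathrm{lca}\{ \text{called node of } s : s \in D\}$
and verifies both criteria against $S(C^\*)$; this is equivalent to scanning
every node for an exact census match (the test suite keeps that brute-force
scan as an oracle over all $2^6$ carrier subsets of a toy cohort) but costs
only one root path per variant.

Upstream of the criteria sit three filters, applied in order:

1. **bi-allelic InDel restriction** — exactly one ALT, pure ACGT alleles of
   unequal length; multi-allelic records are excluded, never split;
2. **callability** — at least `min_call_fraction` (default 0.9) of samples
   have a genotype at the site;
3. **focal restriction** ("polymorphic only in the focal clade") — one
   allele's carrier set is a non-empty subset of the focal clade's samples.
   Both orientations are supported: because the reference chromosome need
   not belong to the focal haplogroup, the clade-confined allele can surface
   as REF or as ALT, and the whole screen is invariant under REF/ALT
   relabeling (a property test flips every code and compares outputs).

Accepted candidates are finally compared against markers that already define
tree nodes: a match on (position, allele set) is annotated
`duplicate_of:<name>` and leaves the novel list; a position-only collision is
kept with a warning.

## Haplogroup assignment

Samples are placed on the tree by greedy descent on defining-marker states.
Each marker is scored ancestral/derived/missing against the matrix by
(position, allele-set) match — again orientation-aware. At each node a child
is *eligible* when its branch markers show `d >= 1` derived calls and
support `d/(d+a) > min_support`; descent follows the highest-support
eligible child (ties: larger `d`, then name) and stops when none qualifies.
The default `min_support = 0.5` (an exclusive strict majority) makes a
single-marker branch require exactly its one marker derived — the common
case in the packaged index, where several subclades are defined by one SNP.
Conflicting (ancestral) calls on the accepted path are counted and reported,
not fatal; there is no back-mutation model, so recurrent states simply
reduce support.

Heterozygous diploid encodings (`0/1`) are collapsed to *missing*, never to
a majority allele: a clean hemizygous locus cannot be heterozygous, and such
calls flag mapping artifacts.

## The synthetic cohort: what it emulates, and what a green test proves

The simulator emits a standard haploid VCF plus truth tables for a stated
world: a rooted haplogroup tree (random trees carry two outgroup clades
beside the focal subtree, 20% of the cohort by default — with a single
outgroup clade, a variant fixed outside the focal clade would be the exact
complement of it and indistinguishable from a focal-root marker); three
samples per node by default; one clean defining SNP per branch so the caller
can resolve every truth assignment; and InDels planted per category:
`clade_perfect` (about a quarter of them REF-oriented), `incomplete`,
`leaky`, `homoplasic`, `duplicate_known`, `outside_focal`, `snp_decoys`.
Violating categories are re-drawn until neither the carrier set nor its
complement coincides with any clade census, so every decoy is a decoy by
construction, not by luck.

Noise (`missing_rate`, `het_rate`) is applied per cell to the planted InDel
genotypes only, after construction; truth records pre-noise states. The
branch-defining SNP backbone stays clean deliberately: noise there moves
haplogroup calls toward the root, which changes every clade census and would
make recovery guarantees for the *screen* unfalsifiable. Consequently a
green recovery test establishes that the screen is exact when assignment is
exact, and that missing data can only cost a candidate its callability or
verifiability — it does not establish robustness to systematic
miscalling of the backbone, to reference bias, to alignment-induced indel
artifacts, or to any population-genetic realism (no coalescent, no mutation
rates, no homoplasy beyond the planted category).

The Table-1 replay fixture is the same machinery pointed at the packaged
O-M175 tree: the 22 published candidate InDels are planted clade-perfect on
their printed subclades at their printed GRCh38 positions, the nine known
InDel markers are planted on their nodes (the screen must re-discover and
then *deduplicate* them), and 23 seeded decoys span the violating
categories. The packaged marker index reconstructs only what is published by
name: topology from subclade nomenclature (a node's parent is its name minus
the trailing run of same-type characters), marker-to-node pairing, and
SNP-vs-InDel class; marker *positions and alleles* are synthetic stand-ins,
and the files ship with a `.synthetic.` suffix to say so.

## Numerical choices

* **Event notation → VCF.** Published events are printed as `X > -`
  (deletion) / `- > X` (insertion) at an event position; the fixture anchors
  them at that position with a synthetic anchor base chosen to differ from
  the event's first base, so the anchored representation is unambiguous and
  the dedup key (position, allele set) is stable. The input pipeline assumes
  left-normalized VCFs and does not re-normalize; indels whose REF/ALT share
  no leading base only raise a warning.
* **Missing-data policy.** Criteria are evaluated over *called* samples,
  gated by `min_call_fraction = 0.9`; `strict_missing = TRUE` instead
  rejects any candidate whose proposed clade contains an uncalled sample
  (`"unverifiable"`). The source data for the original screen were
  near-complete 30× genomes, so the default is permissive; the strict mode
  exists for sparser call sets.
* **Unresolved samples block subclades.** A sample called at an internal
  node (unresolved below it) belongs to that node's clade only; if it is
  ancestral at a variant, it vetoes candidacy of every subclade it might
  belong to — the conservative reading of "derived in **all** individuals
  of the clade".
* **Determinism.** Children are stored lexicographically; descent ties break
  by support, derived count, then name; the simulator consumes a single RNG
  stream in fixed construction order, so one seed yields byte-identical
  VCFs. Candidate tables sort by (clade depth, position).
* **Greedy descent vs. exhaustive oracle.** The two coincide whenever
  derived calls occur only on a sample's true lineage — guaranteed under
  the missing/het-only noise model, where the eligible branches form a chain.
  Under adversarial marker states (derived noise on disjoint branches) the
  greedy contract is the defined behavior; the oracle-equivalence tests
  therefore draw from the simulator, and the oracle asserts the chain
  property instead of silently tie-breaking.
* **Singleton clades** are legal candidates (the published panel contains a
  clade observed once); novel candidates resting on a clade census below 3
  are logged as low-evidence rather than dropped.

## Known limitations

* The published 614 → 22 reduction involved manual elimination of loci with
  high homology elsewhere in the genome or poor assay behavior; that step is
  non-algorithmic and out of scope — the screen stops at the deduplicated
  novel list.
* Reproducing the full published cascade (23,726 bi-allelic Y-InDels on
  1,233 chromosomes → 2,375 → 614 → 605) requires the 30× 1000 Genomes
  chromosome-Y release and a worldwide tree index that was never published;
  the package ships no claim about those counts.
* Two published loci (rs79011057, rs75465866) are reported as likely
  synchronized; the screen emits both — collapsing synchronized markers into
  one panel entry is a reporting concern left to the caller.
* `validate_consistency` checks candidates against calls from the *same*
  cohort; it is a screen invariant (and a cheap cross-check on real typing
  results), not an independent validation of the tree topology.
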