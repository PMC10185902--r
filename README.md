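# yindelscreen

Discovery of **phylogenetically informative Y-chromosomal InDels** — variants
whose derived allele coincides exactly with one haplogroup clade — from
multi-sample chromosome-Y VCF data.

The Y chromosome passes from father to son without recombination, so its
variants sort Y chromosomes into a nested haplogroup tree (O → O1 → O1a …).
The tree is defined almost entirely by SNPs; InDels are equally stable but
much easier to type (fragment-length assays, small amplicons), and hardly
any are anchored in the tree. Given a cohort of male chrY genotypes and a
labeled haplogroup tree with its marker index, this package

1. collapses genotypes to haploid 0/1/missing calls (heterozygous diploid
   encodings on the hemizygous Y are treated as no-calls),
2. assigns every sample to a haplogroup by greedy descent on derived-state
   defining markers,
3. computes per-clade derived-allele frequencies by direct counting,
4. screens bi-allelic InDels for **clade-exactness**: with $S(C)$ the
   samples of clade $C$ and $D$ the derived-allele carriers, a variant is
   informative for $C^\* = \mathrm{lca}(\text{nodes of } D)$ iff
   every called member of $S(C^\*)$ is in $D$ (criterion 1) and no called
   sample outside $S(C^\*)$ is (criterion 2) — applied after restricting to
   variants polymorphic only inside a focal clade (default `O`, either
   allele orientation), and
5. deduplicates hits against markers that already define tree nodes.

A seeded simulator (`simulate_cohort`) plants variants in controlled
categories (clade-perfect, incomplete, leaky, homoplasic, duplicates of
known markers, outside-focal, SNP decoys) with a truth table, so every stage
is testable offline; `table1_replay_fixture` rebuilds the published
22-marker discovery panel as a synthetic cohort on the packaged O-M175 tree.

## Worked example

```r
library(yindelscreen)

sim <- table1_replay_fixture(seed = 1)      # synthetic replay cohort
vcf <- tempfile(fileext = ".vcf"); writeLines(sim$vcf, vcf)
run <- run_screen(vcf, sim$tree, known = sim$known,
                  out_dir = "replay_out", focal = "O")
print(run$result)
#> <screen_result>
#>   records_seen = 122
#>    biallelic_indels = 49
#>    callable = 49
#>    focal_restricted = 46
#>    clade_exact = 31
#>    novel = 22
#>   novel candidates across 21 clades
head(run$result$novel[, c("rsid", "position", "mutation",
                          "assigned_clade", "carriers", "status")], 5)
#>          rsid position mutation assigned_clade carriers status
#> 2 rs200942940 12416056    C > -            O1b       60  novel
#> 3 rs201101541 16693737    - > C            O2a      102  novel
#> 5 rs201451931  7765543    T > -           O1b2       12  novel
#> 6  rs75465866 14101642    T > -           O1a1        9  novel
#> 7  rs79011057 15870505    C > -           O1a1        9  novel
```

Reading the counters: of 122 VCF records, 49 are bi-allelic InDels; all pass
the 90% callability gate; 46 are polymorphic only inside haplogroup O; 31
are clade-exact; 9 of those duplicate known tree-defining InDel markers
(M175, M111, A15721, M121, FGC12511, M134, M117, M133, M333 — annotated
`duplicate_of:` in `candidates.tsv`), leaving the 22 novel candidates, each
on its published subclade (e.g. the single-base deletion rs79011057 at
GRCh38 chrY:15,870,505 marks O1a1). `run_screen` also writes
`frequencies.tsv` (per-clade derived-allele counts), `calls.tsv`
(per-sample haplogroup paths) and `summary.json` under `out_dir`.

`validate_consistency(run$result$novel, run$matrix, run$calls, run$tree)`
cross-checks that each sample is derived at exactly the candidates whose
clade contains its called node (0 rows = no conflicting assignment).

## Command line

```sh
Rscript inst/cli/yindelscreen.R screen --vcf cohort.vcf \
    --tree tree.nwk --markers markers.tsv --known known.tsv \
    --focal O --out-dir out/
# other subcommands: simulate | assign | replay-table1 | validate
```

Logs go to stderr, results to `--out-dir`; exit codes distinguish parse (2),
config (3), contract (4), format (5) and lookup (6) failures.

## Packaged fixtures (`inst/extdata/`)

`table1_indels.tsv` carries the published 22-marker panel (clade, rsID,
GRCh38 position, event, samples tested). The tree, marker index and
known-InDel files are suffixed `.synthetic.`: topology and marker-to-node
pairing follow published names, but marker positions and alleles are
synthetic stand-ins — see the methods vignette
(`vignettes/informative-yindel-screening.Rmd`) for exactly what they do and
do not represent.
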