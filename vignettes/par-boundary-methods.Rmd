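---
title: "Methods: locating a pseudoautosomal boundary from segregation and wild polymorphism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: locating a pseudoautosomal boundary from segregation and wild polymorphism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parboundary)
```

## The inference problem

On a young sex-chromosome pair, three regimes of male recombination
coexist along the chromosome: none (the non-recombining Y region, NRY),
rare (a partially sex-linked "fuzzy boundary"), and free (the
pseudoautosomal region, PAR). A genetic cross of ~50 progeny resolves
"none/rare" from "free" but cannot distinguish zero from rare: a
recombination fraction of, say, $10^{-4}$ per meiosis is invisible in 52
meioses. Wild-sampled chromosomes, by contrast, descend through on the
order of the coalescent depth ($\sim 4N_e$) of male and female meioses,
so alleles that are strictly Y-linked in the cross but occasionally
recombine historically will occasionally be found on wild X chromosomes
— that is, in wild **females**.

`parboundary` combines the two sources: the cross defines candidate
Y-linked alleles; the wild panel tests whether they ever escape.

## The Y-SNP criterion

At a site in one gene, an allele $a$ is called a Y-SNP when:

1. the father carries $a$ heterozygously;
2. every son with a non-missing call carries $a$;
3. the mother lacks $a$, and every daughter with a non-missing call
   lacks $a$;
4. at least `min_complete_sons` (default 15 of 20) sons and
   `min_complete_daughters` (default 24 of 32, the same 75% proportion)
   daughters are called at the site — sites below the thresholds are
   skipped, not failed, so missing data cannot fabricate evidence.

Design choices worth stating:

* **Father-homozygous sites are excluded.** If the father is homozygous
  for $a$, the allele sits on both his X and his Y and X/Y phase is
  unresolvable, so such sites cannot be diagnostic.
* **Presence, not heterozygosity, is required of sons.** Whether the
  original criterion additionally demanded that sons be heterozygous
  (i.e. also express an X allele) is not determinable from the method's
  description; presence is the weaker and safer reading, and on
  simulated data the two coincide because every son carries a maternal
  X.
* **Single-generation operationalisation.** The pedigree criterion is
  applied to the observable father–offspring generation. A deeper
  pedigree would add female meioses and make the criterion stricter;
  the completeness thresholds compensate conservatively.
* At most one allele is emitted per site; the configuration where two
  alleles both qualify is reachable only through missing data, and the
  tie breaks to the lower allele index for determinism.

## The wild-female scan

For each called Y-SNP, the gene's evidence counts are: Y-SNPs with at
least one genotyped wild female (`y_snps_analyzed`); those whose Y
allele occurs in at least one wild female (`y_snps_in_females`); the
number of distinct carrier females (`n_females_with_y`). Y-SNPs seen in
wild males are reported as QC only — wild males are expected to carry
the Y allele, so their count should track `y_snps_analyzed` — and play
no role in classification. Genotype calls are taken as given; no
read-level or quality re-filtering is attempted.

## Classification and boundaries

Genes recombining in the cross are `PAR`. Sex-linked genes are split by
map position against three anchors: at or proximal to
`last_fully_X_cM` → `X`; up to `fuzzy_split_cM` → `fuzzy-I`; beyond,
but proximal to `first_PAR_cM` → `fuzzy-II`. Genes sharing a cM
position with an anchor go to the anchor's proximal side. Two modes
exist because fixing anchors from the same data that are being
classified would be circular for new datasets:

* **Anchor mode** uses published anchors (defaults 62.6, 63.0,
  64.8 cM) — the replication mode for the packaged gene table.
* **Data-driven mode** (`infer_boundaries`) places `first_PAR_cM` at
  the most proximal cross-recombining gene, `last_fully_X_cM` at the
  most distal gene proximal to all female-Y evidence, and
  `fuzzy_split_cM` by maximising a two-segment Poisson likelihood of
  the per-gene female-Y counts (segment means at their MLEs; ties to
  the most proximal split). The Poisson split mirrors the qualitative
  published distinction — "zero or one" versus "multiple" Y alleles in
  females — without hand-picking a threshold.

In strict mode a sex-linked gene mapping beyond `first_PAR_cM` is an
input inconsistency and errors; the simulated-data pipeline runs
non-strict, labelling such genes `fuzzy-II`, because a finite cross can
miss all recombinants of a genuinely pseudoautosomal gene (with the
default design this happens to a few percent of PAR genes).

## Diversity statistics

All statistics treat each diploid as two chromosomes, males included:
at sex-linked genes a male's X and Y copies are his two alleles, which
is precisely why gametolog divergence inflates male heterozygosity.

* **$\pi$** per site:
  $\pi = \frac{1}{L}\sum_s \sum_{i<j} n_i n_j / \binom{n}{2}$ over
  sites with complete calls in the group; the denominator stays at the
  gene length $L$ (window convention) rather than the callable length —
  the choice is exposed via `gene_length` should users prefer
  otherwise.
* **Weir–Cockerham $\theta$** between the sexes, from the 1984
  variance components $a$, $b$, $c$ per site and allele, aggregated as
  a ratio of sums $\sum a / \sum(a+b+c)$ (the windowed-estimator
  convention), raw value reported (slightly negative values are
  legitimate sampling outcomes).
* **Tajima's D** from genotype-derived chromosomes, not per-individual
  consensus sequences, avoiding any dependence on heterozygote encoding
  in FASTA. With missing data, $\hat k$ counts differences per
  chromosome pair at sites where both members are called (averaged over
  all $\binom{n}{2}$ pairs), $S$ counts sites with at least two called
  chromosomes, and the constants use the full $n$; D is reported absent
  (`NA`) when $S = 0$, never zero.
* **`compare_pi`** is the pooled-variance two-sample Student's t-test
  across the genes of a region; **`regress_d_on_distance`** is OLS of D
  on cM distance from the PAR boundary with the slope's t-test p-value
  (distance in cM from the first pseudoautosomal gene, the natural
  reading of "distance from the boundary" on a genetic map).

Each statistic is tested against an independent oracle computed by a
different route: brute-force enumeration of all chromosome pairs for
$\pi$ and $\hat k$, the nested-ANOVA sums-of-squares route for the
Weir–Cockerham components, and a constant-by-constant evaluation for D.

## The simulator and its calibration

`simulate_gene` draws, per gene: a neutral infinite-sites X background
(unlinked sites; derived-allele counts from the neutral frequency
spectrum, so $E[\pi] = \theta$ per site); a single Y lineage (zero
within-Y polymorphism) carrying Poisson($d_{xy}$) private Y-diagnostic
derived alleles; Mendelian transmission with per-meiosis male
recombination probability 0 in the NRY, `male_recomb_fuzzy` in the
fuzzy zone, and map-derived in the PAR; and a leak process in which
each wild-female X copy carries the Y allele at each diagnostic site
independently with probability `leak_prob`. Genes are mutually
independent (each is a separate analysis window), seeded
deterministically from the dataset seed and gene index.

One structural choice deserves emphasis: **the Y's neutral background
is the father's X haplotype**, so X and Y differ exactly at the
diagnostic sites. Current X polymorphism is younger than the X–Y split,
so a segregating X variant carries no information about Y linkage; a Y
background drawn independently (or as a consensus) would make the
family segregation criterion match ordinary X variants whenever the
mother and the father's X jointly miss an allele, producing spurious
Y-SNPs that no amount of thresholding removes. Folding the background
keeps the identifiable signal — X–Y divergence — and nothing else, at
the cost of slightly under-dispersing male neutral diversity (the
father's X is re-used as the Y background in wild males).

Defaults are the study conditions, fixed once from published
quantities:

| parameter | default | rationale |
|---|---|---|
| cross | 20 sons, 32 daughters | the mapping family design |
| wild panel | 3 males, 5 females | the wild transcriptome panel |
| genes | 28 NRY + 20 fuzzy + 38 PAR = 86 | the gene table layout |
| `theta` | 0.0025/site | wild-female diversity ~0.0025 |
| `d_xy` | NRY 7, fuzzy 14 per kb | from $\pi_m \approx 0.8\theta + 0.6\,d/L$ and the observed $\pi_m$ of 0.0064 (sex-linked) and 0.0105 (fuzzy) |
| `leak_prob` | fuzzy 0.02 | observed fraction of Y-SNPs in females ~0.2 $= 1-(1-p)^{10}$ over 10 wild-female X copies |
| `male_recomb_fuzzy` | $10^{-5}$ | leak fraction divided by coalescent depth; rare enough to be invisible in 52 meioses, as observed |
| PAR recombination | Haldane on a 10× male map | male crossovers are confined to, hence concentrated in, the PAR |
| `gene_length` | 1000 bp | typical transcript analysis window |

Note the divergence defaults follow the *observed* regional diversity
pattern (fuzzy above sex-linked), not a strict age ordering of strata.

## What the simulator does and does not emulate

It reproduces: X–Y divergence inflating male $\pi$ and between-sex
$F_{ST}$ in non-recombining regions; rare male recombination visible in
wild females but not in the cross; cross-recombination detection with
realistic failure modes (a PAR gene whose paternal haplotypes are
identical, or whose recombinants escape 52 meioses, segregates as
sex-linked). Passing tests therefore show the inference machinery is
correct under these mechanisms.

It does **not** emulate: linkage disequilibrium between genes or with
the sex-determining locus (genes are independent), so the published
elevation of PAR diversity ratios near the boundary (ratio ~2) and the
negative Tajima's-D gradient with distance from the boundary do not
arise — simulated PAR genes are plainly neutral (ratio ~1, flat D);
gene conversion between gametologs; selection of any kind; structural
variation; a second pedigree generation; read-level genotyping error.
Conclusions about those features of real data cannot be drawn from the
simulation tests; the regression machinery is instead validated on
constructed data with known slope.

## Numerical conventions and degenerate inputs

* VCF positions and internal site positions are 1-based; allele index 0
  is REF. Half-missing calls collapse to missing. Indels are dropped on
  import; multiallelic SNPs are kept and handled per allele.
* Monomorphic sites contribute zero to both $F_{ST}$ sums; a gene with
  no informative site returns `NA`, as does D when $S=0$.
* The change-point tie rule (most proximal maximiser), the best-hit tie
  rule (bitscore, then e-value, then lexicographic subject), and the
  one-allele-per-site rule make every output order-invariant and
  bit-reproducible; the pipeline manifest records seed, thresholds and
  output checksums.
* The aggregate row of the packaged gene table (36 unnamed
  pseudoautosomal genes) is expanded into labelled synthetic
  placeholder records with interpolated map positions so whole-table
  counts are computable; placeholders are flagged and excluded from
  per-gene label comparisons. Unreported evidence columns are `NA`,
  never zero.

## Problem sizes used by the test-suite experiments

Simulation-based checks run at the default design (86 genes, 60
individuals): 200 replicate datasets for boundary recovery (both region
breaks within one gene in ≥95% of replicates), 200 replicates for the
zero-false-positive property with leakage off, 25 replicates for the
regional diversity-ratio ordering, and 100–600 single-gene replicates
for the Monte-Carlo expectation checks; these sizes put the Monte-Carlo
standard errors well inside the asserted margins while keeping the
suite quick on a laptop.

## Known limitations

The anchor defaults are map positions of a specific published cross and
are meaningless for other maps — use `infer_boundaries` there. The
single-generation Y-SNP criterion is weaker than a two-generation
pedigree and relies on the completeness thresholds against artifacts.
Tajima's-D constants use the nominal chromosome count under
missingness, a mild approximation at the missing-data rates the
statistics are intended for. The change-point split assumes at most one
rate change within the fuzzy zone.
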