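# mmejscan

Genome-wide detection of microhomology-mediated end-joining (MMEJ)
signatures in insertion/deletion call sets from paired samples.

## The problem

When homologous recombination repair is impaired — as in EBV-transformed
B lymphocytes, where active STAT3 blunts Chk1 phosphorylation and RAD51
loading — cells fall back on error-prone MMEJ to repair double-strand
breaks. MMEJ leaves recognizable scars in the genome:

* **deletions with junction microhomology** — the deleted sequence and
  the retained downstream sequence share an identical prefix of
  *mh* ≥ 2 bp, the annealing tract of the repair;
* **templated small insertions (1–3 bp, "in trans")** — the junction
  word (≥ 2 nt of flank + insertion + ≥ 2 nt of flank) recurs nearby in
  the ±15 nt context with ≥ 1 nt separation, e.g. a junction reading
  `AGA·g·AAA` whose word `AGAGAAA` occurs again upstream;
* **snapback large insertions (≥ 18 nt, "in cis")** — the inserted
  sequence contains a ≥ 7 nt substring and its reverse complement,
  separated by ≥ 4 nt, the footprint of fold-back synthesis.

Given a "pre" sample (e.g. primary B cells) and a "post" sample (the
derived lymphoblastoid line) per subject, `mmejscan` partitions the
post-sample indel calls into *pre-existing* (the intersection of the two
call sets) and *new* (post-unique) sets and asks, for each signature and
each minimum-microhomology threshold *T* = 2…20, whether the fraction of
signature-positive events is higher among new indels. Each comparison is
a 2×2 contingency table tested with the continuity-corrected
two-proportion chi-squared statistic

    X² = N · (max(0, |ad − bc| − N/2))² / (r₁ r₂ c₁ c₂),   p = P(χ²₁ ≥ X²)

computed with an upper-tail survival function so p-values down to
10⁻⁷⁰ and beyond retain full relative accuracy.

The package is aimed at genomicists analysing paired pre-/post-
transformation (or pre-/post-treatment) whole-genome indel calls, and it
ships a synthetic-cohort simulator with exact ground truth so the whole
pipeline can be exercised and validated without any external data.

## Worked example

Simulate a cohort with planted signatures, partition it, and build the
threshold-stratified deletion report:

```r
library(mmejscan)

cfg <- simulationConfig(seed = 1)
sim <- simulateMMEJCohort(cfg, dir = "example-cohort")   # FASTA + VCFs + truth
part <- partitionPreNew(sim$bcell, sim$lcl, "subject1")
part
#> IndelPartition 'subject1': 1040 pre-existing, 1080 new

tab <- buildDeletionTable(part, sim$genome, sizeClass = "small")
head(tab[, c("minimum_mh", "pre_existing_deletions", "pre_with_mh",
             "pre_fraction", "new_deletions", "new_with_mh",
             "new_fraction", "p")], 4)
#>   minimum_mh pre_existing_deletions pre_with_mh pre_fraction new_deletions
#> 1          2                    800         623    0.7787500           800
#> 2          3                    778         399    0.5128535           786
#> 3          4                    748         256    0.3422460           764
#> 4          5                    711         170    0.2390999           736
#>   new_with_mh new_fraction       p
#> 1         683    0.8537500 1.4e-04
#> 2         417    0.5305344      NS
#> 3         287    0.3756545      NS
#> 4         187    0.2540761      NS
```

Reading the *T* = 2 row: of the 800 pre-existing small deletions, 623
(0.78) carry at least 2 bp of junction microhomology, versus 683 of 800
(0.85) among newly arisen deletions — the planted enrichment (the
generator's defaults plant 0.77 vs 0.84) — and the corrected test calls
the difference at p = 1.4e-04. Rows at higher thresholds only consider
deletions of length ≥ *T* and tighten the match requirement; with these
small per-class counts they are not significant (`NS`), which is the
display label for p ≥ 0.05.

Insertion summaries come from the same partition:

```r
ins <- buildInsertionTables(part, sim$genome)
ins$snapback[, c("n_pre", "pos_pre", "n_new", "pos_new", "p")]
#>   n_pre pos_pre n_new pos_new  p
#> 1    40      17    80      50 NS
```

Here 17/40 pre-existing versus 50/80 new large insertions contain an
internal inverted repeat (the generator plants 0.4 vs 0.6 rates).

For file-based cohorts, `runConfig()` + `runFullAnalysis()` run the full
chain — QUAL ≥ 40 filtering, known-variant exclusion, left-alignment,
cross-subject decontamination, partitioning, scoring, testing — and
write per-subject TSV reports plus a JSON run manifest. The same driver
is available from a shell via `inst/scripts/mmejscan` (subcommands
`run` and `simulate`).

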