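---
title: "Detecting MMEJ deletion and insertion signatures in paired indel call sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting MMEJ deletion and insertion signatures in paired indel call sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmejscan)
```

## The question the package answers

Cells that lose high-fidelity homologous recombination (HR) repair — for
example B lymphocytes transformed into lymphoblastoid cell lines, where
constitutively active STAT3 blunts Chk1 phosphorylation and RAD51
nucleation — come to rely on microhomology-mediated end-joining (MMEJ) to
repair double-strand breaks. MMEJ anneals short identical sequences
flanking a break and leaves characteristic scars: deletions whose deleted
sequence shares a short identical prefix with the retained downstream
sequence, and, because MMEJ's synthesis steps can misprime, insertions
that copy nearby template sequence (small, "in trans") or fold back on
the nascent strand (large "snapback" insertions containing inverted
repeats).

`mmejscan` asks whether these scars are *enriched* among indels that
arose after a defined event (e.g. viral transformation). The design
needs two call sets per subject: a "pre" sample (primary B cells) and a
"post" sample (the derived cell line). Indels present in both are taken
to predate the event (*pre-existing*); indels unique to the post sample
are taken to have arisen afterwards (*new*). If the post-event repair
environment favours MMEJ, the signature fraction should be higher in the
new set, which a two-proportion test can detect without any absolute
calibration of the variant caller.

## Input processing

Indel calls are read from per-sample VCFs. Multi-allelic rows are split
into one record per ALT before any filtering; symbolic (`<DEL>`-style)
and breakend alleles are skipped with a logged count. The only
variant-level quality filter is `QUAL >= 40` (the upstream caller's
recalibration is assumed to have run already); records with missing QUAL
are removed under the same rule, because an absent score cannot certify
quality. Known-variant catalogues supplied as exclusion files are read
without a QUAL filter — population resources typically carry none — and
matched by exact normalized key (`contig:pos:ref:alt`) by default;
position-only matching is available as an option because published
catalogues do not always normalize alleles the same way.

All records are reduced to anchor-base-minimal form and **left-aligned**
against the reference (the event string is rotated leftwards while the
base preceding the event equals its last base). Left-alignment matters
scientifically here, not just cosmetically: the microhomology of an MMEJ
deletion sits at the junction, and only a canonical alignment guarantees
that the homologous tract appears as a prefix of the deleted sequence
and of the downstream flank.

Calls shared between two or more *different subjects* are removed from
every set before partitioning: independent somatic events at identical
coordinates with identical alleles are far less likely than a shared
germline polymorphism or a systematic caller artefact. With a single
subject this step is skipped with a warning.

## Deletion junction microhomology

For a deletion of length $L$ (2–500 bp), the downstream reference flank
of length $\min(L, 20)$ starting at the first base after the deleted
interval is extracted, and the microhomology length is the longest
common prefix of the deleted sequence and that flank. `N` matches
nothing, so reference ambiguity can never manufacture homology. The
length is capped at 20 bp because no larger threshold is ever applied.
At a contig edge the flank is truncated rather than padded and the score
is capped by what is available; such deletions remain in the considered
counts.

Deletions are stratified into a *small* class (2–29 bp) and a *long*
class (30–500 bp), and for every minimum-microhomology threshold
$T = 2, \dots, 20$ the report counts, per set, the deletions considered
(those with $L \ge T$ — shorter events could not possibly carry a $T$ bp
match) and those with microhomology $\ge T$. Because every long-class
deletion exceeds the 20 bp cap, long-class totals are constant across
thresholds — a structural property the test suite asserts.

Orientation is a genuine design choice: we compare the *prefix* of the
deleted sequence against the *prefix* of the 3' flank. With left-aligned
records this is where annealing-derived homology accumulates; a
configuration switch (`orientation = "both"` in `scoreDeletions`)
additionally scores the mirrored 5' comparison and takes the maximum,
but the default — used by every reported analysis and every acceptance
check — is 3'-only.

## Insertion classification

**Templated small insertions (1–3 bp).** Let `L` and `R` be up to 15 nt
of reference immediately 5' and 3' of the insertion point. The call is
positive if the junction word — at least 2 nt of `L`, the full inserted
sequence, and at least 2 nt of `R` — occurs elsewhere in the context
`L + R`, with at least 1 nt between the occurrence's footprint and the
junction bases contributing the flanks. The canonical example is a
junction reading `AGA·g·AAA` whose word `AGAGAAA` recurs upstream: the
flank matches (P2 = `AGA`, mh2 = `AAA`) bracket the single inserted `G`.
The template copy may straddle the insertion point (the context omits
the insertion itself, so a straddling copy is still a legitimate
template); its side is reported by the midpoint of the occurrence. Among
positive candidates the match maximizing the total flank length
$k + m$ is reported, with deterministic tie-breaks (upstream side first,
then smallest gap, then largest 5' flank, then leftmost occurrence) so
outputs are order-independent. Insertions of 1–3 bp whose contig
position leaves fewer than 2 nt on either side are negative — the flank
minimums cannot be met. The search is plus-strand only: the canonical
worked junction is a plus-strand match, and searching the reference
context (not the insertion-bearing haplotype) mirrors how the context is
extracted.

**Snapback large insertions (>= 18 nt).** Only the inserted sequence is
examined: it is compared with its own reverse complement, and the call
is positive if some substring of at least 7 nt has its reverse
complement also present with non-overlapping footprints separated by at
least 4 nt. The separation is measured between footprints (end of the
first copy to start of the second), and "separated by at least 4 nt" is
read as a gap of $\ge 4$. Insertions shorter than
$2 \times 7 + 4 = 18$ nt cannot satisfy the rule and are *not evaluated*
(rejected with a logged reason) rather than counted as negative, which
would dilute the denominator with impossible cases. Reverse
complementation is strict A–T/C–G; any `N` disqualifies a candidate
substring. The implementation finds all maximal common substrings
between the insertion and its reverse complement by dynamic programming;
an overlapping or too-close pair is trimmed at the inner junction (each
trimmed base shortens the repeat by one and widens the gap by two), so a
long palindrome is correctly recognized as containing a valid shorter
snapback. The maximal repeat length is reported with smallest-start
tie-breaks.

Insertions of 4–17 bp belong to neither analysis; they are counted in a
logged "unclassified" bucket so that every insertion lands in exactly
one place.

## The statistical test

Each signature comparison is a 2x2 contingency table: signature-positive
and -negative counts in the pre-existing and new sets. The statistic is
the classical corrected chi-squared form

$$X^2 \;=\; \frac{N\,\big(\max(0,\ |ad - bc| - N/2)\big)^2}{r_1 r_2 c_1 c_2},$$

with the Yates continuity correction applied by default (dropping the
$N/2$ term when disabled), and the two-sided p-value is the upper tail
of $\chi^2_1$. Two numerical points matter. First, the tail is computed
with `pchisq(..., lower.tail = FALSE)`, which retains full relative
accuracy for extreme statistics — genome-wide tables reach p-values
around $10^{-50}$ to $10^{-70}$, where computing $1 - F(x)$ would
underflow. Second, the correction is clamped at zero so identical
proportions give a statistic of exactly 0 and p = 1. Degenerate tables
(a zero column marginal) return `NA` with a diagnostic. Reports display
p-values in a mixed style — scientific with three significant digits
below 0.001, three decimals otherwise, `NS` at or above 0.05 — while the
raw value is always emitted in a machine-readable column. No
multiple-testing correction is applied across threshold rows: rows of
the threshold table are nested views of the same events, not independent
hypotheses, and they are reported as-is.

## The synthetic cohort generator

Real genome-wide call sets cannot ship with a package, so every stage is
exercised against simulated cohorts with exact ground truth. The
generator emulates the statistical structure of the target data: an
i.i.d. reference at configurable GC content (default 0.41, human-like),
paired call sets sharing a pre-existing subset, deletions of 2–29 and
30–500 bp with a controllable fraction carrying planted junction
microhomology, 1–3 bp insertions with or without a nearby template copy,
and >= 18 nt insertions with or without an internal inverted repeat. The
default signature fractions for deletions (0.77 pre-existing vs 0.84
new at the 2 bp threshold) echo the magnitude of enrichment reported for
short deletions in transformed B-cell lines; planted microhomology
lengths decay geometrically (ratio 0.65 over 2–20 bp), echoing the
roughly geometric decline of observed junction-homology counts with
length.

Design choices worth recording:

* **Placement.** Events are laid out in disjoint variable-width slots (a
  random permutation of the roster laid end-to-end, each event's slot
  covering its own span plus slack, 50 bp contig margins). This is
  deterministic, collision-free by construction, and vectorizable; a
  genome too small for the roster raises a capacity error naming the
  shortfall. Planted events therefore never interact, and flank
  extraction is never truncated in tests.
* **Forced signatures.** An mh-deletion's downstream flank prefix is
  copied from its deletion prefix, with a forced mismatch immediately
  after the tract, so the recovered microhomology equals the planted
  length *exactly*. A templated insertion's junction word is written
  into the upstream context with the required gap. A snapback insertion
  is synthesized as pad–repeat–spacer–reverse-complement–pad.
  Signature-free ("plain") events get a forced first-base mismatch
  (deletions) or are rejection-sampled against the classifiers
  (insertions), so truth labels are exact and recovery assertions are
  deterministic given the seed.
* **Bernoulli assignment.** Whether an individual event carries the
  signature is Bernoulli at the configured fraction rather than an exact
  rounded count, so recovered fractions carry genuine binomial sampling
  noise — without it, null-calibration checks of the downstream test
  would be vacuous.
* **Alignment guards.** Each planted record's anchor base is forced to
  differ from the last event base, so every emitted record is already
  left-aligned and anchor-minimal, and the VCF round trip is the
  identity.
* **Seed whitening.** Replicated simulations are often seeded with
  consecutive small integers. Mersenne–Twister states initialized from
  consecutive seeds remain structurally correlated for thousands of
  draws, which shows up as spurious dependence between replicate call
  sets and distorts the null calibration of the downstream proportion
  test. The generator therefore hashes the user seed through one draw
  of the freshly seeded stream before use. Results remain fully
  deterministic per seed; the null-calibration check in the test suite
  guards against regressions here.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: realistic polymorphism spectra, caller
and sequencing error (false calls, genotyping noise), clustered or
repeat-associated indels, soft-masked or N-rich reference context, and
any correlation between event classes. The simulator validates the
*algorithmic* pipeline, not the variant calling upstream of it.

## Problem sizes and runtime choices

The packaged checks use cohorts of a few thousand events: parameter
recovery and null calibration run 2,000 deletions per set per replicate
on a 450 kb reference (100 replicates for the null), and the oracle
equivalence checks compare each matcher with exhaustive brute-force
enumeration on 500 random instances of length up to 40 nt. These sizes
give 3-sigma binomial resolution of about +/- 0.03 on recovered
fractions and decisive power (p far below 1e-10) for the 0.30 vs 0.60
contrast, while a full run of the suite stays in the minutes range on a
single core.

## Known limitations

* Microhomology is exact-match only; a single mismatch terminates the
  tract, and homology with indels inside the tract is out of scope.
* Deletions above 500 bp and symbolic structural-variant calls are not
  analyzed.
* The small-insertion template search does not consider the reverse
  strand or the insertion-bearing haplotype.
* Multi-step snapback histories (nested inverted-repeat sets in very
  large insertions) are reported only as a single best repeat pair.
* The two-proportion test treats calls as independent; regional
  clustering of indels would violate that assumption in real data.
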