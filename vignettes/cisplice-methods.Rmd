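---
title: "Identifying cis-acting splice-associated variants with cisplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying cis-acting splice-associated variants with cisplice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cisplice)
library(data.table)
```

## The problem

Somatic variants near exon edges can disrupt or create splice sites,
rerouting transcription through non-reference exon-exon junctions (cryptic
donors or acceptors, exon skipping) or shifting the balance between known
junctions. `cisplice` integrates per-sample somatic variant calls (VCF)
with splice junctions observed in RNA-seq alignments (SAM/BAM), against a
reference transcriptome (GTF) and genome (FASTA), to find such cis-acting
splice-associated variants, score variant-junction *events* across a
cohort, and rank genes for recurrent splice disruption. Single-cell data
fit the same machinery by treating each cell as an individual sample in
the cohort manifest.

## The pipeline

**Variant annotation.** Each variant is classified per overlapping
transcript under a *splice-variant window*: intronic positions within
`i` bases of an exon edge are `splicing_intronic`, exonic positions
within `e` bases are `splicing_exonic`; other positions are plain
`intronic`/`exonic`. The defaults `i = 2`, `e = 3` target the splice-site
dinucleotides plus the outermost exonic bases; `-I`/`-E` widen the search
to all intronic or all exonic variants (labels stay plain by design). The
reported distance is the minimum over the two edges of the associated
exon. Distances count from the edge: the exon-edge base has exonic
distance 1 and the first intronic base has intronic distance 1, so a
window of `e` or `i` bases covers exactly that many positions per edge —
this keeps the classifier and the gene-footprint computation (below)
mutually consistent. Indels are anchored at their leftmost
reference-affected base, which is deterministic because inputs must be
left-aligned and decomposed. Variants inside the edge window of a
transcript-terminal exon edge are still labeled `splicing_exonic` (the
permissive reading of "exon edge"); the recurrence footprint, by
contrast, counts only intron-adjacent edges, and this asymmetry is
deliberate and documented here.

**Junction extraction.** Junctions are inferred from `N` (skipped region)
CIGAR operators. Anchors are the reference-consuming spans
(match/mismatch/deletion) flanking each `N`; insertions and clips
contribute nothing. Counting deletions toward the anchor is a dialect
choice required for coordinate correctness when a deletion abuts the
junction. Observations aggregate by (contig, intron, strand) — junctions
on different strands, or with unknown strand, are distinct keys — with
the read count as score and the anchor union as the thick bounds. A
junction is kept if its maximal anchors reach 8 bases on both sides and
its intron length lies in [70, 500000]. Strand comes from the aligner's
XS-style tag (unstranded libraries) or from the read-pair orientation
(RF/FR). Duplicate-flagged and QC-fail reads are excluded by default.
Region-restricted extraction is an optimization only: every read
supporting a junction that overlaps the region also overlaps the region,
so restricted and whole-file extraction agree on the region's junctions
(tested).

**Junction annotation.** The donor is the 5' intron boundary with respect
to the transcribed strand, the acceptor the 3' one; both are matched
exactly (no fuzz window) against the annotated site catalogs, giving the
junction types `DA` (annotated intron), `NDA` (both sites known, pairing
novel), `D`/`A` (one site known), `N` (neither). Skipped donors,
acceptors and exons are counted as distinct annotated positions strictly
inside the intron, per overlapping same-strand gene, reporting the
maximum across genes — distinct-position counting avoids double-counting
sites shared between isoforms. Unknown-strand junctions are evaluated on
both strands and the higher class (DA > NDA > D = A > N) is adopted, ties
to `+`, which makes unstranded libraries usable.

**Splice-junction regions and events.** Each splice-relevant variant gets
a region within which junctions are associated with it: for
`splicing_exonic`/`splicing_intronic`/`exonic` annotations, from the 3'
end of the exon upstream of the variant-associated exon to the 5' end of
the downstream exon (for `splicing_intronic` variants the associated exon
is the one whose edge window captured the variant); for plain `intronic`
variants, the containing intron. Terminal exons clamp the region to the
transcript span rather than inventing flanking sequence. When several
transcripts yield regions, the union span is used. A fixed window (`-w`,
interpreted as a total size centered on the variant) can replace the
rule. An *event* is a (variant, junction) pair whose region and intron
span intersect.

## The cohort statistic

For one sample, a junction's `norm_score` in a region is its read count
divided by the summed counts of all junctions overlapping that region —
a usage fraction over whole junctions, similar in spirit to percent
spliced-in but measured on junctions rather than exon inclusion. Scores
over a region sum to 1 for samples with reads, else are 0.
`mean_norm_score` is the mean over the variant-containing samples (equal
to the single score when one sample carries the variant; membership is an
exact contig/pos/ref/alt match). The empirical p-value is the fraction of
non-variant samples whose `norm_score` is at least as high (ties count).
Non-variant samples with no reads in the region contribute score 0 and
stay in the null distribution; excluding them would bias p downward.

Events are analysed separately for known junctions (`DA`) and
non-reference junctions using at least one known site (`D`/`A`/`NDA`);
`N` junctions are never tested, nor are events with fewer than 5 reads of
evidence summed across variant-containing samples. Benjamini-Hochberg is
applied within each analysis (per cohort, per class set) and events with
adjusted p <= 0.05 are called significant.

The statistic is a rank statistic only when exactly one sample carries
the variant; with several variant samples, the mean of their scores is
less dispersed than a single draw, which makes the empirical p-value
conservative in the tails. The calibration check therefore uses
one-carrier events, where under exchangeability P(p <= alpha) equals
floor(alpha (m+1) + 1)/(m+1) over m non-variant samples — 0.05 exactly at
m = 19.

## Gene recurrence

A gene's *footprint* `s` is the number of distinct genomic positions in
any of its splice-variant windows: per intron-adjacent exon edge, `e`
bases into the exon and `i` bases into the intron, deduplicated across
transcripts and edges (whole exons/introns under `-E`/`-I`). The joint
probability that a window position harbors a variant that is
significantly splice-associated is estimated as the number of significant
splice-associated variants summed over cohort samples divided by the
genome-wide window footprint. The per-sample null probability of a gene
acquiring at least one such variant is

```
p_null = 1 - (1 - Pr(V and A))^s
```

evaluated in log space (`-expm1(s * log1p(-pr))`) so that tiny
probabilities against footprints up to 1e7 keep at least 12 significant
digits (checked against frozen arbitrary-precision values). Each gene
then gets a one-tailed binomial test — cohort size as attempts, success
when a sample has at least one significant splice-associated variant in
the gene — plus the plain fraction of samples as a second ranking metric.
Cohorts can be pooled by namespacing sample ids and summing attempts and
successes; genes are ranked, not thresholded. Because `p_null` grows with
`s`, the binomial metric deliberately penalizes genes with larger window
footprints; the two rankings can legitimately disagree. Success requires
the variant to come from a *significant* event (the stricter of two
possible readings of "has evidence of at least one splice-associated
variant"); the default class set for recurrence is `D`/`A`/`NDA`, with
`DA` available by flag.

## The synthetic-data generator

`sim_reference()` builds a random genome with multi-exon genes whose
introns all carry GT-AG dinucleotides on the transcribed strand, and per
gene plants a candidate variant at the last intronic base before the
affected exon together with the cryptic junction it would activate —
exon skipping (type `NDA`) or a cryptic acceptor inside the downstream
exon (type `D` on `+`, `A` on `-`). `sim_cohort()` emits per-sample
variant calls and junction evidence, either as reads with exact spliced
CIGARs (`output = "sam"`) or as aggregated junction counts in BED12
(`output = "bed"`).

The default conditions are 20 samples, 5 variant carriers, junction
depth 50 and effect fraction 0.5: variant carriers reroute half of the
affected molecules to the cryptic junction. Per gene and sample, the
molecule count is Binomial(2 x depth, 0.5) (mean = depth), the rerouted
count Binomial within it; an optional Beta-distributed baseline usage of
the cryptic junction in *all* samples models cross-sample splicing
variability and makes norm_scores effectively tie-free — it is what the
null-calibration and recurrence-competition scenarios use (means 0.3 and
0.05 respectively). All randomness descends from one seed (the cohort
stage offsets the same seed), so outputs are byte-deterministic.

What the generator does not emulate: sequencing errors and base
qualities (no operation depends on them), paired-end fragments,
realistic expression or fragment-length distributions, overlapping
genes, alternative isoforms beyond the planted junction. Passing tests
therefore demonstrate the correctness of the coordinate arithmetic,
classification logic and statistics — not robustness to alignment
artifacts in real tumor data.

Problem sizes used by the test-suite property checks and the acceptance
script, chosen to keep checks sharp at desk scale: extraction oracle on
~1100 randomized mixed-CIGAR reads; null calibration on a 220-gene
one-carrier cohort (>= 200 events); power and recurrence ranking on 20
seeds of a 51-gene cohort (1 planted gene against 50 null-variant
genes).

## Numerical and design choices

* Internal coordinates are 1-based inclusive throughout (the native
  R/Bioconductor convention); GTF and VCF are 1-based already and BED12
  converts at the I/O boundary. All interval logic (region overlap,
  "strictly inside" skipped-site counting) is closed-interval arithmetic
  equivalent to the half-open forms.
* Empirical p-value ties use plain `>=` on doubles; scores are exact
  ratios of integers, so equal usage compares equal.
* BH is `stats::p.adjust(method = "BH")` behind a validating wrapper;
  the binomial tail is `stats::pbinom(k - 1, n, p, lower.tail = FALSE)`.
* `identify` and the manual extract-annotate-associate chain write
  byte-identical event tables: associated junctions are renamed
  canonically (`JUNC000001`... in coordinate order) after association,
  since serial names from whole-file versus region-restricted extraction
  would otherwise differ.
* Degenerate inputs: a CIGAR whose `N` touches a read extremity (or
  another `N`) would have a zero-length anchor and the record is skipped
  with a warning; multi-allelic VCF records are rejected with an
  instruction to decompose; symbolic/structural alleles are dropped with
  a warning rather than guessed; junctions on contigs absent from the
  annotation are typed `N` with a warning.
* The cohort engine reads per-sample VCFs with a minimal sites-only
  reader (CHROM/POS/REF/ALT are all it consumes) for speed across
  hundreds of files; the annotated-VCF output path uses
  VariantAnnotation end to end.
* Read-through junctions whose donor and acceptor fall in different
  genes list all overlapping genes; prioritization is left to the
  analyst.

## Known limitations

Gene assignment of a variant follows transcript-span overlap, so
variants in overlapping genes are counted toward all of them. The
recurrence model treats samples as exchangeable attempts and ignores
per-sample mutation burden. No annotation against normal-tissue junction
compendia or external splice-effect predictors is performed; the event
table carries the columns such layers would key on.
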