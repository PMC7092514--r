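---
title: "Methods: characterizing an alternative-splicing landscape from PSI tables"
author: "spliceScape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing an alternative-splicing landscape from PSI tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceScape)
```

## The problem

Bulk RNA-seq splice-graph quantifiers such as Whippet summarize alternative
splicing as a percent-spliced-in (PSI) value per sample for every exonic
node, classified into eight event types: core exon (CE, the cassette-exon /
exon-skipping event), alternate acceptor (AA) and donor (AD), retained
intron (RI), tandem polyadenylation (TE) and transcription-start (TS) sites,
and alternative first/last exons (AF/AL). spliceScape implements the
*downstream* landscape analysis for a replicated multi-tissue design — the
motivating system is the hypothalamic–pituitary–gonadal (HPG) axis of a
bird under acute restraint stress, with two sexes, two treatments and up to
12 replicates per cell — and answers questions of the form: where does
differential splicing happen (tissue, event type, transcript region, GO
category), and does it happen more or less often than the genome would lead
one to expect?

Upstream read alignment and PSI quantification are out of scope: the
package consumes PSI tables, a GFF3 annotation, a genome FASTA, and
gene–GO associations. Everything it computes can therefore be exercised by
the bundled synthetic-data generator, with no downloads.

## Differential splicing calls

For a two-group comparison at one node, the effect estimate is the
difference of group-mean PSI,
$\Delta\Psi = \bar\Psi_A - \bar\Psi_B \in [-1, 1]$, over non-missing
replicates (missing PSI values are dropped, not imputed, matching the
per-event quantifiability of the upstream tool). The significance score is a
*probability*, not a p-value: the fraction of seeded bootstrap resamples —
replicates drawn with replacement independently within each group — whose
resampled $\Delta\Psi$ agrees in sign with the point estimate. Resampled
deltas of exactly zero count one half, and a point estimate of exactly zero
reports probability 0.5, the only symmetric convention. The default is
10,000 bootstrap replicates, which keeps the Monte-Carlo standard error
below 0.005 near the 0.95 decision threshold. Because the probability is a
Monte-Carlo estimate, swapping the groups negates $\Delta\Psi$ exactly but
reproduces the probability only up to that Monte-Carlo error.

The upstream quantifier's own `delta` script scores events by sampling
beta posteriors; our replicate bootstrap is a deliberate, documented
re-implementation that needs nothing beyond the PSI table. An optional
`method = "posterior"` mode instead draws each sample's PSI from a Beta
distribution matched to its point estimate and 95% CI width (CI width
$\approx 3.92\,\mathrm{sd}$), approximating that posterior behavior.

An event is called significant when `probability > 0.95` **and**
`|deltaPSI| >= 0.1` — strict on the probability, inclusive on the effect
size, exactly as the rule is stated. No multiple-testing correction is
applied by default (the landscape statistics are reported raw);
Benjamini–Hochberg filtering on $1-\mathrm{probability}$ is available
behind the `significance$fdr` config flag. A companion
`sensitivityRecall()` implements the relaxed "call everything with
$p \le 0.05$" probe: it returns the *additional* events with
$|\Delta\Psi| < 0.1$ that pass `probability >= 0.95`, quantifying how
strongly the effect-size cutoff biases PSI distributions toward bimodality.
Note these are sign-consistency probabilities, not calibrated p-values: with
12 replicates a true shift of about 0.05 already reaches probability 0.95
quite often, so the relaxed rule admits many low-effect events — the same
behavior the strict $|\Delta\Psi|$ cutoff exists to suppress.

## Landscape statistics

Counts of significant events are compared with chi-square goodness-of-fit
tests, either against a uniform null ("splicing events are evenly
distributed across tissues / treatments / types") or against
genome-derived expected proportions. For two cells the uniform statistic
reduces to $(a-b)^2/(a+b)$ with 1 df. Cells with expected counts below 5
produce a warning but the test still runs — sparse landscape cells are the
rule, so the caveat is surfaced rather than enforced. Percent changes
between counts are reported as
$100\,(a-b)/b$, rounded to whole percents.

### Transcript regions and genomic expectation

Each coding transcript is partitioned, in transcript orientation, into
5'UTR (bases 5' of the first CDS base), CDS, and 3'UTR. The genomic null
for "where could splicing happen" counts **possible splicing locations**
per region as exonic segments after region splitting: an exon lying across
a region boundary contributes one location to each region it touches. We
count locations rather than bases because splice-graph events address
exonic nodes, so the event-level observation should be compared with a
node-level expectation. Counts are per-transcript by default; a
`longest`-isoform policy is available because
annotation pipelines differ on whether genome-wide proportions should be
per-transcript or per-gene.
Non-coding transcripts have no region classes and are excluded from the
region expectation, but their exons still contribute to the genomic
exon-length sample.

Each significant event is assigned to the region with maximal base overlap
with its node; ties break CDS > 5'UTR > 3'UTR (deterministic, and CDS
precedence matches the observation that coding sequence dominates).
Expected counts per region are the assigned total times the genomic region
proportions; the reported deviation is $(O-E)/E$, so $-0.5$ reads as "50%
fewer events than genomic expectation". Each region is tested against its
complement with a 1-df chi-square, plus a 2-df omnibus across the three
regions — the df structure such landscape summaries report.
Expectation-weighted deviations sum to zero by construction.

### Exon lengths

Spliced-exon length distributions are compared to the genomic exon-length
distribution with a two-sided Mann–Whitney rank-sum test. When both
samples have at most 10 values the p-value is computed by exhaustive
enumeration over all labelings with midranks (so ties are exact); larger
samples use the tie-corrected normal approximation without continuity
correction.

### GO parent terms

Rather than a depth-wise enrichment test (which is often uninformative for
short spliced-gene lists), gene lists are *abstracted*: every GO annotation rolls
up to the depth-1 children of its namespace root — the "binding",
"catalytic activity" level of granularity — with multi-parent leaves
counting toward every reachable parent, and deduplication at the
gene-by-parent level. The genome expectation is the fraction of annotated
genes carrying each parent term; observed counts among spliced genes are
tested term-vs-complement with 1-df chi-squares, and the reported deviation
is $(O-E)/\text{total events in tissue}$, the convention used when such
deviations are drawn per tissue. Parent terms covering less than 2% of the genome are
excluded from reports (configurable). The abstraction depth is also
configurable. Ontologies are read from OBO restricted to `is_a` edges
(`part_of` optionally included); the reader is a minimal stanza parser
because the analysis needs nothing more than the hierarchy.

### Exclusive isoforms

An isoform is *exclusive* to a design group when its TPM is at least
`on_min` (default 1) in at least `min_frac` (default 75%) of the group's
samples and at most `off_max` (default 0.1) in **every** complement
sample. The thresholds are configuration-exposed and echoed in the output,
since no standard numeric rule exists; the defaults are
deliberately strict so that a flag means presence/absence, not dosage.

## Spliced-exon translation

Exon sequences are extracted strand-aware (minus strand = reverse
complement) and translated with GFF3 phase semantics: the phase is the
number of bases to skip before the first complete codon, taken from the
annotation rather than recomputed (the model validator cross-checks phases
against the recurrence
$\mathrm{phase}_{k+1} = (3 - ((\sum_{i\le k} \ell_i - \mathrm{phase}_1)
\bmod 3)) \bmod 3$). Stop codons render `*`, trailing partial codons are
dropped, and any codon containing `N` translates to `X` for draft-genome
tolerance. The first codon is never treated as an initiator (exon fragments
are internal sequence). For an exon spanning a CDS/UTR boundary the default
translates only the CDS-overlapping portion, with the frame offset derived
from the containing CDS span; a `whole`-exon mode exists because the source
doesn't specify the choice. UTR-only exons yield empty peptides. Motif
search against external databases (PFAM and friends) is out of scope; the
package defines the adapter contract and ships a toy regex scanner so the
interface is testable offline.

## The synthetic-data generator

`simulateGenomeAnnotation()` builds a toy genome in which every gene is a
coding transcript with 5–11 exons (mean near eight, the textbook per-gene
average), 5'UTR/CDS/3'UTR composition, valid phases, both strands, and a
CDS that is a genuine open reading frame (ATG, no internal stop, terminal
stop) — so phase- and strand-aware translation is verifiable end to end,
not just length-checked. It also emits a three-namespace toy ontology with
depth-1 parents, one deliberately rare parent (< 2% of genes) to exercise
the report filter, and a multi-parent leaf to exercise DAG semantics.

`simulatePsiTables()` emulates the study design: hypothalamus, pituitary
and gonad; two sexes; control and restraint-stress treatments; 12
replicates per cell (144 samples) by default. Every exon is a node with a
baseline PSI drawn uniformly from (0.15, 0.85); replicate noise is Beta
with the group mean and concentration 24, chosen so the replicate sd is
about 0.1 at PSI 0.5 — Beta respects the [0,1] support and is the
posterior family of the upstream tool. Eight percent of nodes carry a true
effect with $|\Delta\Psi|$ drawn from (0.15, 0.5), symmetric in sign.
Sex-effect nodes live in hypothalamus or pituitary (gonads are never
compared male-vs-female: ovary and testis differ inherently) and are
always active in the control stratum but remain active under stress only
with probability `convergenceFactor` (default 0.5) — reproducing, in
structure, the observed convergence of the sexes' splicing profiles under
stress. Treatment effects apply within one sex. Two percent of
measurements are set missing to exercise the missing-data path. Every
injected effect is recorded in a truth table, and all outputs are
byte-deterministic for a given seed.

What the generator does **not** emulate: realistic nucleotide composition,
linkage between nodes of one gene, event-type-dependent PSI behavior,
coverage-dependent CI widths, or any read-level process. Passing tests
therefore demonstrate the correctness and calibration of the downstream
statistics under the stated noise model, not performance on real
sequencing data.

## Numerical and design choices

* Coordinates are 1-based inclusive in all files (GFF3/GTF convention);
  interval splitting is done in transcript coordinates and converted back.
* Region assignment tie-break: CDS > 5'UTR > 3'UTR at equal overlap.
* Bootstrap delta of exactly zero: probability 0.5.
* Rank-sum: exact enumeration only when both $n \le 10$ (the enumeration is
  $\binom{n_1+n_2}{n_1}$); midranks throughout.
* Chi-square with an expected count of zero is an error; below 5, a
  warning.
* GO terms unknown to the ontology warn and are skipped; namespace roots
  abstract to the empty set.
* Pipeline seeds: each comparison's bootstrap is seeded as
  `seed + 97 * comparison_index`, so runs are reproducible and comparisons
  are decoupled.
* Problem sizes for the default pipeline run: 60 genes (about 480 nodes),
  144 samples, 10 comparisons, 10,000 bootstrap replicates — chosen so a
  complete run finishes in a couple of minutes on one CPU while keeping
  every per-cell replicate count at the study's n = 12.

## Known limitations

* The bootstrap probability with small replicate counts is coarse
  ($n^n$ distinct resamples per group) and conservative near 0.5.
* Region expectation treats every exonic segment as one potential splicing
  location regardless of length or type-specific accessibility.
* The GO rollup depends entirely on the supplied association table:
  genome expectations are computed from whatever association file is
  given, so results shift with the annotation snapshot.
* `exonPeptides()` uses the first annotated transcript of a gene whose
  exons best overlap the node; genes with many isoforms may be better
  served by the `longest` policy.
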