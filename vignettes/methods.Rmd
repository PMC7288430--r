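---
title: "Annotation-signature virus recovery: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotation-signature virus recovery: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viroscreen)
```

# The problem and the model

Assembled metagenomes interleave fragments of host chromosomes, plasmids
and viral genomes, and a sizeable fraction of viral sequence is integrated
into host scaffolds as proviruses. `viroscreen` classifies scaffolds from
their *protein annotation signatures* alone: no nucleotide composition, no
gene-density or strand-switching features, no integration-site motifs.
The premise is that a human curator separates viral from microbial
scaffolds by looking at what the proteins are annotated as, and that this
judgement can be quantified.

Two components carry that judgement:

1. **The v-score** assigns each HMM profile a virus-association weight.
   Given the number of significant hits $c$ of a profile against a large,
   dereplicated viral protein set,
   $$v = \min(c / 100,\; 10),$$
   with $v = 0$ for profiles that never hit a virus. Profile *names*
   then floor the score: KEGG/Pfam names containing "phage" with $v > 0$,
   and names in any collection containing a viral hallmark keyword
   (portal, terminase, spike, capsid, sheath, tail, coat, virion, lysin,
   holin, base plate / baseplate, lysozyme, head, structural) are raised
   to at least 1; hallmark names are additionally flagged. Names matching
   a small exclusion list of non-prokaryotic viruses (e.g. "reovirus")
   are exempt from the floors. The v-score deliberately measures
   *association*, not specificity: a ribonucleotide reductase shared by
   viruses and hosts still earns the weight its viral usage justifies,
   which is what lets horizontally transferred and auxiliary metabolic
   genes count in favour of a scaffold rather than against it.

2. **A multi-layer perceptron** (27 inputs, one hidden layer of 32
   logistic units, logistic output) maps per-scaffold annotation metrics
   to a virus probability. The model is intentionally small: with 27
   well-engineered inputs the class structure is nearly linearly
   separable, and a compact network trains in seconds and is stable
   across seeds.

Rule-based steps bracket the network. Before it, a *prefilter* removes
scaffolds that are confidently microbial (KEGG-annotated fraction > 0.5,
summed KEGG v below 0.1 per annotation, no hallmark). After it,
*curation* (a) reclassifies predicted viruses that carry plasmid
mobility/partitioning markers and no hallmark, (b) removes predicted
viruses in which more than 60% of proteins carry zero-v annotations and
no hallmark is present, and (c) rescues predicted non-viruses with at
least two hallmark annotations and at most 20% zero-v proteins. Rule (c)
dominates (a) and (b) by construction: a scaffold satisfying the rescue
conditions can never be flipped away from the virus class.

# The 27 metrics

The per-scaffold feature vector, in order (`featureNames()`): log10 of
the protein count; per database (KEGG, Pfam, VOG) the annotated-protein
count, summed v-score, zero-v count, v ≥ 1 count and maximum v;
unannotated-protein count; hallmark, replication, viral-integrase and
plasmid-marker annotation counts; proteins annotated by KEGG-not-VOG,
VOG-not-KEGG, and by all three; mean v over annotations; count of v ≥ 5
annotations; count of AMG-eligible KEGG annotations.

Count-type metrics are divided by the protein count so 3 kb and 15 kb
scaffolds are comparable; the first metric is log-scaled instead. The
per-database *maximum* v and the *mean* v over annotated proteins are
already scale-free and are deliberately **not** normalized: dividing them
by the protein count would make the vector depend on scaffold size in
exactly the way the normalization is meant to remove (concatenating a
scaffold with itself would halve them). This choice is pinned by a test:
self-concatenation must leave metrics 2–27 unchanged and add log10(2) to
metric 1.

The metric list is a named, ordered set so an alternative definition can
be swapped in without touching the classifier code, which validates
feature order against the model at prediction time.

# Provirus excision

Host regions inside a scaffold betray themselves as runs of
KEGG-annotated genes with low v-scores. The scanner marks a gene
*host-like* if it has a KEGG annotation with $v < 1$ and no hallmark
annotation from any database; every maximal run of ≥ 4 consecutive
host-like genes is a host span. Window length 4 and the v-cut of 1.0 are
configuration (`scanCutSites()` arguments): 4 consecutive confidently
microbial genes essentially never occur inside genuine phage sequence,
while shorter runs do (AMGs, moron genes), so shorter runs are not cut
sites. Only KEGG v-scores drive the scan — KEGG annotation is the
densest and most host-biased of the three collections, so it gives the
cleanest host signal; VOG participates only through the hallmark veto.

After removing host spans, each leftover block is trimmed to its first
and last gene carrying a virus-like annotation (any database v ≥ 1, or
hallmark); blocks with no virus-like annotation, or fewer than 4 genes
after trimming, are discarded. Fragment coordinates are the trimmed
boundary genes' coordinates (0-based half-open on the parent), so the
excised sequence always equals the parent substring exactly — string
equality is asserted in the tests. Every excised fragment is tagged
`origin = "excised"` and is by definition lysogenic downstream.

A known limitation, quantified on the synthetic harness: a host gene
that happens to lack a KEGG hit but carries a generic viral-family hit
(v ≥ 1) can anchor the trim a few genes before the true boundary. Under
the generator's default rates this costs roughly 4–5% of chimeras the
within-one-gene boundary recovery; the recovered fragment still contains
the complete provirus plus a short host overhang.

# Quality, circularity, lifestyle

A scaffold ≥ 1000 bp whose first 20 nt recur — as an exact string — at
any start position within its final 900 bp is a circular template
(`detectCircular()`, leftmost match reported, repeat reported but not
trimmed). Exact matching with no mismatch tolerance keeps the detector
equal to a brute-force windowed substring search, which the tests assert
on 1000 random sequences.

Non-circular viruses get a draft tier from VOG-based tallies
(`qualityRules()`): *high* needs ≥ 1 hallmark and ≥ 1 replication
annotation and VOG annotations on ≥ 33% of proteins; *medium* needs one
of hallmark/replication and ≥ 20% VOG; everything else is *low*. The
thresholds live in one rules function precisely because they are
judgement calls standing in for a curated rule table; the structural
property they must satisfy — the tier never improves as a genome is
truncated from 100% to 10% in 10% steps (`truncationHarness()`) — is
what the tests enforce, per genome, not the thresholds themselves.

Lifestyle: lysogenic iff excised or carrying a viral-like integrase
annotation; lytic otherwise.

# AMG profiling

A KEGG best hit on a viral scaffold is an auxiliary metabolic gene when
its ortholog maps to at least one pathway map in the "metabolic
pathways" category (or the sulfur relay system) and is not excluded.
The exclusion list (`amgExclusions()`) ships seeded with nrdA/nrdB and
thyA/thyX — genes viruses carry for their own replication, not host
metabolic reprogramming — plus a documented set of
nucleotide-interconversion orthologs, and is matched against both KO ids
and gene symbols in annotation names. The KO-to-pathway resource is a
user-supplied TSV because pathway content is licensed and versioned; a
small synthetic one ships under `inst/extdata` and the fixture generator
emits a matching one.

# Evaluation arithmetic

`computeMetrics()` implements recall, precision, accuracy, specificity,
F1 and MCC with the standard formulas, reporting `NA` where a
denominator vanishes. When the negative test set dwarfs the positive
one, `normalizeCounts()` scales FP and TN by n_virus/n_nonvirus before
the precision-family metrics — recall is untouched by construction.
Plasmid and genomic negatives are normalized jointly when combined.
`ratioReport()` reproduces per-dataset comparison ratios (rounded to 2
decimals, 1 for count ratios where so reported) and their cross-dataset
arithmetic means, computed over the rounded per-dataset ratios as
printed summary tables do.

# The synthetic-data generator

`makeProfileResource()` builds KEGG/Pfam/VOG-like collections whose
names and hit counts emulate real ones — housekeeping KEGG/Pfam profiles
with zero viral hits, a viral-associated minority, hallmark VOG names at
a configurable fraction — and derives their v-scores by running
`computeVScores()` on the drawn counts, so keyword floors hold by
construction. `makeLabeledScaffolds()` emits 3–15 kb scaffolds with
genes on alternating strands and class-conditional annotation rates
(`classSignatures()`):

* virus: VOG 0.85 per gene (25% hallmark, 15% replication among those),
  KEGG 0.20 (a fifth AMG-like), Pfam 0.30 — reference phage genomes
  annotate densely against viral-family collections;
* host: KEGG 0.90 and Pfam 0.60, all zero-v, VOG 0.03 — curated
  bacterial genomes are ~85–90% KEGG-annotatable;
* plasmid: KEGG 0.50 zero-v, plasmid mobility markers at 0.30 per gene,
  Pfam 0.40.

Chimeras default to a 14-gene host flank and 15-gene viral block; these
sizes make a detectable ≥ 4-run of host-like genes present with
probability ≈ 0.99 at the host annotation rate, so the boundary-recovery
harness measures the algorithm, not fixture starvation. The quality
fixture (`makeCompletePhage()`) places hallmark and replication genes at
fixed relative positions past the first 15% of the gene order, emulating
structural/replication modules sitting away from the genome start, which
gives the truncation harness a full high→medium→low trajectory.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: nucleotide composition and codon structure
(sequences are i.i.d. random; nothing downstream reads them except
circularity and excision arithmetic), annotation errors and chimeric
mis-assemblies, correlated annotation within operons, real e-value
distributions, and the long tail of genuinely unannotatable viral dark
matter. Accuracy numbers on these fixtures are upper bounds describing
the machinery, not field performance.

# Numerical and design choices

* Coordinates are 0-based half-open internally; predictor headers
  (1-based inclusive) are converted on parse and back on GenBank export.
* The e-value threshold is strict (< 1e-5); best-hit ties break by
  higher bitscore, then lexicographically smaller profile id, making
  annotation reduction fully deterministic.
* Training: `nnet` with weight decay 5e-4 and a seeded 10% holdout whose
  accuracy is stored on the model. `nnet` exposes no early-stopping
  hook, so regularization plays that role; determinism given the seed is
  contractual and tested (identical predictions, bit-identical
  round-trip through the model file).
* Virome mode (`virome = TRUE`): skips the prefilter and loosens the
  zero-v density cutoff from 0.6 to 0.8 — on data that is mostly viral,
  the prefilter's microbial prior is wrong and curation should hesitate
  before discarding. This is the minimal consistent interpretation of a
  mostly-viral-input mode and is isolated in `curationDefaults()`.
* Degenerate inputs: scaffolds with zero proteins are rejected at
  feature compilation; an empty post-filter set yields a valid empty
  result bundle; unknown profile lookups score 0 and increment a miss
  counter rather than failing a run.
* Problem sizes in the shipped tests and acceptance script — 1000
  random sequences for the circularity cross-check, 200 + 200 for the
  provirus harness, 1000 scaffolds per class end-to-end, 50 genomes for
  the truncation harness — were chosen as the sizes at which the
  binomial noise on each rate is comfortably below the margin being
  asserted.

# Known limitations

Tier thresholds, curation cutoffs and prefilter constants are defensible
defaults, not fitted quantities; they are all exposed as configuration.
The classifier must be trained by the user (or the fixture pipeline) —
no pretrained weights ship with the package, since they would only be
meaningful relative to a specific profile-collection version. Provirus
boundaries are gene-resolution by design; attachment-site detection is
out of scope. Completeness tiers are categorical proxies, not
percentage completeness estimates.
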