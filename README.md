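# viroscreen

Recovery, curation and functional profiling of bacterial and archaeal
viruses — free virions and host-integrated proviruses — from assembled
metagenomic scaffolds.

Metagenomic assemblies mix host chromosomes, plasmids and viral genomes.
`viroscreen` separates them using **protein annotation signatures** rather
than nucleotide features: every predicted protein is annotated against
three HMM profile collections (KEGG-, Pfam- and VOG-like), each profile
carries a **v-score** — a quantitative measure of its association with
known viruses — and a small neural network decides from 27 per-scaffold
annotation metrics whether a scaffold is viral, bracketed by rule-based
prefiltering and curation. The package is aimed at microbiome researchers
who want viral sequences, their genome quality, lifestyle and
auxiliary-metabolic-gene (AMG) content from an assembly in one pass.

## The method in brief

**v-score.** For each profile, count its significant hits (e-value
< 10⁻⁵) against a dereplicated viral protein set, then

    v = min(count / 100, 10)

with keyword floors: KEGG/Pfam names containing "phage" (and v > 0) and
names in any collection containing a viral hallmark keyword (*portal,
terminase, spike, capsid, sheath, tail, coat, virion, lysin, holin, base
plate, lysozyme, head, structural*) are floored at v = 1; hallmark names
are flagged. Profiles with no viral hits get v = 0. Thus low v ≈
host-like, high v ≈ virus-associated.

**Workflow.** read scaffolds and proteins → enforce ≥ 1000 bp and ≥ 4
ORFs → best hit per protein per database (e-value < 10⁻⁵, ties by
bitscore then profile id) → remove scaffolds dominated by zero-v KEGG
annotation (prefilter) → excise proviruses: any run of ≥ 4 consecutive
KEGG-annotated, v < 1, non-hallmark genes is a host region; cut there and
trim each fragment to its outermost virus-like annotation (v ≥ 1 or
hallmark) → compile 27 metrics (log₁₀ protein count; per-database
annotation counts, v-score sums, zero-v and v ≥ 1 counts, maxima;
hallmark/replication/integrase/plasmid-marker tallies; database overlaps;
mean v; AMG-eligible KEGG count — count metrics normalized by protein
count) → score with a 27→32→1 multi-layer perceptron (logistic output) →
curate: drop predicted viruses with plasmid markers and no hallmark, or
with > 60% zero-v proteins and no hallmark; rescue predicted non-viruses
with ≥ 2 hallmark annotations and ≤ 20% zero-v proteins → assess each
virus: circular template (first 20 nt recurring in the final 900 bp),
draft-quality tier from VOG/hallmark/replication tallies, lytic vs
lysogenic (excised or integrase-bearing ⇒ lysogenic) → flag AMGs: KEGG
orthologs mapping to a metabolic pathway (or sulfur relay system) and not
on the exclusion list.

A deterministic synthetic-data generator (`makeProfileResource()`,
`makeLabeledScaffolds()`, `makeChimera()`, `makeCompletePhage()`) emulates
profile collections and class-conditional annotation signatures so the
entire pipeline can be exercised — and is tested — without downloading any
real database. An evaluation module implements the benchmark statistics
(recall, precision, accuracy, specificity, F1, MCC) with negative-class
size normalization, and comparison-ratio arithmetic.

## Worked example

```r
library(viroscreen)

# 1. Synthetic profile resource (stands in for KEGG/Pfam/VOG + v-scores)
resource <- makeProfileResource(seed = 1)
resource$vtable
#> VScoreTable with 800 profiles; 32 hallmark, 110 replication

# 2. Train the classifier on labeled fixture scaffolds
train <- makeLabeledScaffolds(resource, 150, seed = 101)
amgKos <- unique(resource$pathway_map$ko_id[
  tolower(resource$pathway_map$category) %in%
    c("metabolic pathways", "sulfur relay system")])
feat  <- compileFeatureMatrix(train$proteins, train$annotations,
                              amgKos = amgKos)
model <- trainClassifier(feat, train$labels, seed = 42)
model
#> ClassifierModel: 27 -> 32 -> 1 MLP, seed 42 , holdout accuracy 1.000

# 3. Run the workflow on a fresh mixed community (incl. one provirus)
test <- makeLabeledScaffolds(resource, 50, seed = 7)
chim <- makeChimera(resource, seed = 8, id = "chimera1")
scaffolds <- ScaffoldSet(c(as.character(scaffoldSeqs(test$scaffolds)),
                           chimera1 = chim$seq))
proteins  <- rbind(test$proteins, chim$proteins)
hits <- rbind(annotationHits(test$annotations),
              annotationHits(chim$annotations))
annotations <- selectBestHits(hits, resource$vtable, proteins = proteins)

cfg <- runConfig(scaffolds, proteins, annotations, resource$vtable, model,
                 pathwayMap = resource$pathway_map, seed = 7)
result <- runPipeline(cfg)
#> filter: 151 in, 151 kept, 0 excluded
#> annotate: 1967 best hits
#> prefilter: 75 removed, 76 remain
#> excise: 1 provirus fragments, 3 scaffolds consumed as host
#> classify: 51 raw virus, 51 after curation
#> quality: high_draft=27, low_draft=4, medium_draft=20
```

The summary reads: of 151 input scaffolds, 75 host-dominated ones were
removed before classification, one provirus was excised out of the
host–virus chimera, and 51 viruses were called — the 50 planted viral
scaffolds plus the excised fragment, which is the single lysogenic entry
(`n_lysogenic = 1`); 34 AMGs were flagged on the viral set. Per-virus
detail lives in `result$quality`:

```r
head(result$quality[, c("scaffold_id", "circular", "tier", "lifestyle")])
#>   scaffold_id circular         tier lifestyle
#> 1     virus_1    FALSE medium_draft     lytic
#> 2     virus_2    FALSE   high_draft     lytic
#> 3     virus_3    FALSE   high_draft     lytic
#> ...
```

`writeRunOutputs(result, "outdir")` writes viral FASTA + GenBank,
prediction/annotation/quality/AMG/provirus TSVs and a JSON run summary.
A command-line wrapper with the same stages is at
`inst/scripts/viroscreen.R` (see its header for flags).

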