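# Shared fixtures: one profile resource and one trained model per test run.
test_resource <- makeProfileResource(seed = 1)

test_amg_kos <- unique(test_resource$pathway_map$ko_id[
  tolower(test_resource$pathway_map$category) %in%
    c("metabolic pathways", "sulfur relay system")])

test_model <- local({
  train <- makeLabeledScaffolds(test_resource, 150, seed = 101)
  feat <- compileFeatureMatrix(train$proteins, train$annotations,
                               amgKos = test_amg_kos)
  trainClassifier(feat, train$labels, seed = 42)
})

# write a FASTA file from a named character vector of sequences
write_fasta <- function(seqs, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    writeLines(substring(s, seq(1, nchar(s), width),
                         pmin(seq(width, nchar(s) + width - 1, width),
                              nchar(s))), con)
  }
  invisible(path)
}

# minimal protein table builder: n proteins on one scaffold, 0-based
# half-open coordinates with 900 bp genes and 30 bp gaps
make_proteins <- function(scaffold_id, n) {
  starts <- 30L + (seq_len(n) - 1L) * 930L
  data.frame(id = sprintf("%s_%d", scaffold_id, seq_len(n)),
             scaffold_id = scaffold_id, index = seq_len(n) - 1L,
             start = starts, stop = starts + 900L,
             strand = rep_len(c("+", "-"), n), aa_seq = "",
             stringsAsFactors = FALSE)
}

# build an AnnotationTable directly from minimal hit specs
make_annotation <- function(protein_id, scaffold_id, db, profile_id,
                            v = 0, hallmark = FALSE, replication = FALSE,
                            integrase_class = "none", name = "x",
                            evalue = 1e-10, bitscore = 50) {
  n <- length(protein_id)
  hits <- data.frame(protein_id = protein_id, scaffold_id = scaffold_id,
                     db = rep_len(db, n), profile_id = rep_len(profile_id, n),
                     name = rep_len(name, n), evalue = rep_len(evalue, n),
                     bitscore = rep_len(bitscore, n), v = rep_len(v, n),
                     hallmark = rep_len(hallmark, n),
                     replication = rep_len(replication, n),
                     integrase_class = rep_len(integrase_class, n),
                     stringsAsFactors = FALSE)
  new("AnnotationTable", hits = hits, evalueMax = 1e-5)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
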