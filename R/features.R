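#' Names of the 27 annotation-signature metrics, in order
#'
#' The classifier consumes one fixed, ordered set of 27 per-scaffold
#' metrics derived from KEGG/Pfam/VOG best-hit annotations and their
#' v-scores. Metric 1 is log10 of the protein count; count-type metrics are
#' normalized by the protein count so scaffolds of different sizes are
#' comparable; the per-database maximum v-score and the mean v-score over
#' annotated proteins are scale-free and reported unnormalized.
#'
#' @return character(27).
#' @export
featureNames <- function() {
  c("log_total_proteins",
    "frac_kegg", "frac_pfam", "frac_vog",
    "vsum_kegg", "vsum_pfam", "vsum_vog",
    "zero_v_kegg", "zero_v_pfam", "zero_v_vog",
    "v_ge1_kegg", "v_ge1_pfam", "v_ge1_vog",
    "vmax_kegg", "vmax_pfam", "vmax_vog",
    "frac_unannotated", "frac_hallmark", "frac_replication",
    "frac_viral_integrase", "frac_plasmid_marker",
    "frac_kegg_not_vog", "frac_vog_not_kegg", "frac_all_three",
    "mean_v_annotated", "frac_v_ge5", "frac_kegg_amg")
}

compileOneScaffold <- function(n, h, amgKos) {
  stopifnot(n > 0)
  out <- numeric(27)
  out[1] <- log10(n)
  dbs <- c("KEGG", "PFAM", "VOG")
  for (d in seq_along(dbs)) {
    sub <- h[h$db == dbs[d], , drop = FALSE]
    out[1 + d] <- nrow(sub) / n
    out[4 + d] <- sum(sub$v) / n
    out[7 + d] <- sum(sub$v == 0) / n
    out[10 + d] <- sum(sub$v >= 1) / n
    out[13 + d] <- if (nrow(sub)) max(sub$v) else 0
  }
  annotated <- unique(h$protein_id)
  out[17] <- (n - length(annotated)) / n
  out[18] <- sum(h$hallmark) / n
  out[19] <- sum(h$replication) / n
  out[20] <- sum(h$integrase_class == "viral_like") / n
  out[21] <- sum(h$integrase_class == "plasmid_like") / n
  keggP <- unique(h$protein_id[h$db == "KEGG"])
  pfamP <- unique(h$protein_id[h$db == "PFAM"])
  vogP <- unique(h$protein_id[h$db == "VOG"])
  out[22] <- length(setdiff(keggP, vogP)) / n
  out[23] <- length(setdiff(vogP, keggP)) / n
  out[24] <- length(intersect(intersect(keggP, pfamP), vogP)) / n
  out[25] <- if (nrow(h)) mean(h$v) else 0
  out[26] <- sum(h$v >= 5) / n
  out[27] <- sum(h$db == "KEGG" & h$profile_id %in% amgKos) / n
  out
}

#' Compile the 27 annotation-signature metrics for one scaffold
#'
#' @param scaffoldId scaffold id.
#' @param proteins protein `data.frame` (only rows for this scaffold are
#'   used; the protein count is taken from it).
#' @param annotations an [AnnotationTable].
#' @param amgKos character vector of AMG-eligible KEGG ortholog ids
#'   (metric 27); default empty.
#' @return named numeric(27) in [featureNames()] order.
#' @export
compileFeatures <- function(scaffoldId, proteins, annotations,
                            amgKos = character(0)) {
  n <- sum(proteins$scaffold_id == scaffoldId)
  if (n == 0L) stop("scaffold ", scaffoldId, " has zero proteins")
  h <- annotationHits(annotations)
  h <- h[h$scaffold_id == scaffoldId, , drop = FALSE]
  stats::setNames(compileOneScaffold(n, h, amgKos), featureNames())
}

#' Compile the feature matrix for many scaffolds
#'
#' @param proteins protein `data.frame`; every scaffold appearing here gets
#'   a row.
#' @param annotations an [AnnotationTable].
#' @param amgKos AMG-eligible KEGG ortholog ids.
#' @return `data.frame` with `scaffold_id` plus the 27 metric columns.
#' @export
compileFeatureMatrix <- function(proteins, annotations,
                                 amgKos = character(0)) {
  ids <- unique(proteins$scaffold_id)
  n <- table(proteins$scaffold_id)
  h <- annotationHits(annotations)
  hs <- split(h, factor(h$scaffold_id, levels = ids))
  mat <- t(vapply(ids, function(id)
    compileOneScaffold(as.integer(n[[id]]), hs[[id]], amgKos),
    numeric(27)))
  colnames(mat) <- featureNames()
  out <- data.frame(scaffold_id = ids, mat, stringsAsFactors = FALSE,
                    row.names = NULL, check.names = FALSE)
  out
}

#' Export a feature matrix (with optional labels) as TSV
#'
#' @param features `data.frame` from [compileFeatureMatrix()].
#' @param path output file.
#' @param labels optional named vector scaffold_id -> class label.
#' @return `path`, invisibly.
#' @export
writeFeatureMatrix <- function(features, path, labels = NULL) {
  if (!is.null(labels))
    features$label <- unname(labels[features$scaffold_id])
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
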