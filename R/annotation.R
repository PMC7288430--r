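#' Parse a HMMER3 per-target tabular output file
#'
#' Reads the `--tblout` dialect: whitespace-delimited columns with `#`
#' comment lines; the full-sequence e-value (column 5) and score (column 6)
#' are kept. By default the *target* is the protein and the *query* is the
#' profile, the orientation produced by searching profile HMMs against a
#' protein set; set `orientation = "query_is_protein"` for the reverse.
#'
#' @param path path to a tblout file.
#' @param db database label: `"KEGG"`, `"PFAM"` or `"VOG"`.
#' @param orientation `"target_is_protein"` (default) or
#'   `"query_is_protein"`.
#' @return `data.frame` of hits: `protein_id`, `profile_id`, `db`,
#'   `evalue`, `bitscore`.
#' @export
parseSearchTable <- function(path, db,
                             orientation = c("target_is_protein",
                                             "query_is_protein")) {
  orientation <- match.arg(orientation)
  db <- match.arg(db, c("KEGG", "PFAM", "VOG"))
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineNo <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  nf <- vapply(fields, length, 0L)
  if (any(nf < 18L))
    stop("malformed tblout line ", lineNo[which(nf < 18L)[1L]],
         ": expected >= 18 columns, got ", nf[which(nf < 18L)[1L]])
  target <- vapply(fields, `[[`, "", 1L)
  query <- vapply(fields, `[[`, "", 3L)
  evalue <- as.numeric(vapply(fields, `[[`, "", 5L))
  score <- as.numeric(vapply(fields, `[[`, "", 6L))
  if (anyNA(evalue) || anyNA(score))
    stop("non-numeric e-value/score at line ",
         lineNo[which(is.na(evalue) | is.na(score))[1L]])
  if (orientation == "target_is_protein")
    data.frame(protein_id = target, profile_id = query,
               db = rep(db, length(target)),
               evalue = evalue, bitscore = score, stringsAsFactors = FALSE)
  else
    data.frame(protein_id = query, profile_id = target,
               db = rep(db, length(target)),
               evalue = evalue, bitscore = score, stringsAsFactors = FALSE)
}

#' Reduce raw hits to the best significant annotation per protein and database
#'
#' Hits with e-value at or above `evalueMax` are discarded (the threshold is
#' strict: a hit must satisfy `evalue < evalueMax`). Among survivors, for
#' each (protein, db) pair the hit with the lowest e-value is kept; ties are
#' broken by higher bitscore, then by lexicographically smallest profile id.
#' Profile v-scores and flags are resolved through `vtable`.
#'
#' @param hits `data.frame` of hits as from [parseSearchTable()]; may mix
#'   databases (the `db` column tags each row).
#' @param vtable a [VScoreTable].
#' @param proteins optional protein `data.frame` used to attach
#'   `scaffold_id`; if missing, the scaffold id is derived by stripping the
#'   trailing `_<n>` counter from the protein id.
#' @param evalueMax significance threshold, default `1e-5`.
#' @return an [AnnotationTable].
#' @export
selectBestHits <- function(hits, vtable, proteins = NULL, evalueMax = 1e-5) {
  stopifnot(is(vtable, "VScoreTable"))
  h <- hits[hits$evalue < evalueMax, , drop = FALSE]
  if (nrow(h)) {
    ord <- order(h$protein_id, h$db, h$evalue, -h$bitscore, h$profile_id)
    h <- h[ord, , drop = FALSE]
    h <- h[!duplicated(paste(h$protein_id, h$db)), , drop = FALSE]
  }
  if (is.null(proteins)) {
    scaf <- sub("_[0-9]+$", "", h$protein_id)
  } else {
    scaf <- stats::setNames(proteins$scaffold_id, proteins$id)[h$protein_id]
  }
  res <- lookupVScore(vtable, h$profile_id)
  out <- data.frame(protein_id = h$protein_id,
                    scaffold_id = unname(scaf),
                    db = h$db, profile_id = h$profile_id,
                    name = res$name, evalue = h$evalue,
                    bitscore = h$bitscore, v = res$v,
                    hallmark = res$hallmark, replication = res$replication,
                    integrase_class = res$integrase_class,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  new("AnnotationTable", hits = out, evalueMax = evalueMax)
}

#' Per-scaffold summary of annotation signal
#'
#' Tallies, for each scaffold, the quantities consumed by the prefilter,
#' the curation rules and the quality module: per-database annotation
#' counts and v-score sums, hallmark/replication counts, integrase and
#' plasmid-marker counts, and the number of proteins carrying at least one
#' zero-v-score annotation.
#'
#' @param annotations an [AnnotationTable].
#' @param proteins protein `data.frame`; defines the scaffold universe and
#'   protein totals.
#' @return `data.frame` with one row per scaffold.
#' @export
annotationSummary <- function(annotations, proteins) {
  h <- annotationHits(annotations)
  ids <- unique(proteins$scaffold_id)
  nprot <- table(proteins$scaffold_id)
  base <- data.frame(scaffold_id = ids,
                     n_proteins = as.integer(nprot[ids]),
                     stringsAsFactors = FALSE)
  agg <- function(sub, f) {
    v <- rep(0, length(ids))
    sub <- sub[sub$scaffold_id %in% ids, , drop = FALSE]
    if (nrow(sub)) {
      t <- tapply(f(sub), sub$scaffold_id, sum)
      v[match(names(t), ids)] <- as.numeric(t)
    }
    v
  }
  kegg <- h[h$db == "KEGG", , drop = FALSE]
  base$kegg_n <- agg(kegg, function(s) rep(1, nrow(s)))
  base$kegg_vsum <- agg(kegg, function(s) s$v)
  base$vog_n <- agg(h[h$db == "VOG", , drop = FALSE],
                    function(s) rep(1, nrow(s)))
  base$hallmark_n <- agg(h, function(s) as.numeric(s$hallmark))
  base$replication_n <- agg(h[h$db == "VOG", , drop = FALSE],
                            function(s) as.numeric(s$replication))
  base$viral_integrase_n <- agg(h, function(s)
    as.numeric(s$integrase_class == "viral_like"))
  base$plasmid_marker_n <- agg(h, function(s)
    as.numeric(s$integrase_class == "plasmid_like"))
  zero <- h[h$v == 0, , drop = FALSE]
  zp <- unique(zero[, c("protein_id", "scaffold_id")])
  base$zero_v_proteins <- agg(zp, function(s) rep(1, nrow(s)))
  base
}

#' Export an annotation table as TSV
#'
#' @param annotations an [AnnotationTable].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeAnnotationTable <- function(annotations, path) {
  utils::write.table(annotationHits(annotations), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
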