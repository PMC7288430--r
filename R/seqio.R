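#' Read assembled scaffolds from a nucleotide FASTA file
#'
#' Ids are taken from the header up to the first whitespace and sanitized
#' for downstream formats (characters outside `[A-Za-z0-9._-]` become `_`;
#' the original header is kept in the returned mapping). Sequences are
#' upper-cased and `U` is converted to `T`, so RNA genomes supplied as
#' cDNA-style FASTA are handled by the DNA-only pipeline.
#'
#' @param path path to a FASTA file of nucleotide scaffolds.
#' @return a [ScaffoldSet]; the attribute `"id_map"` maps sanitized id to
#'   original header id.
#' @export
readScaffolds <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  # read as raw strings first: canonicalization and validation are ours
  seqs <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(seqs) == 0L) stop("no sequences in ", path)
  raw <- sub("\\s.*$", "", names(seqs))
  ids <- sanitizeIds(raw)
  chr <- toupper(as.character(seqs))
  chr <- chartr("U", "T", chr)
  bad <- grepl("[^ACGTRYSWKMBDHVN]", chr)
  if (any(bad))
    stop("non-nucleotide characters in record(s): ",
         paste(ids[bad], collapse = ", "))
  if (any(nchar(chr) == 0L))
    stop("empty sequence in record(s): ",
         paste(ids[nchar(chr) == 0L], collapse = ", "))
  names(chr) <- ids
  out <- ScaffoldSet(chr)
  attr(out, "id_map") <- stats::setNames(raw, ids)
  out
}

sanitizeIds <- function(ids) {
  out <- gsub("[^A-Za-z0-9._-]", "_", ids)
  make.unique(out, sep = "_")
}

#' Parse predicted proteins with Prodigal-style coordinate headers
#'
#' Protein FASTA headers of the form
#' `>scaffold_1 # 3 # 1001 # 1 # ...` carry the gene start/stop (1-based,
#' inclusive) and strand (`1`/`-1`). Coordinates are converted to the
#' package's internal 0-based half-open convention. The scaffold id is
#' recovered by stripping the trailing `_<n>` ORF counter from the protein
#' id, and a 0-based `index` is assigned per scaffold in file order.
#'
#' @param path path to a protein FASTA file.
#' @return a `data.frame` of protein records with columns `id`,
#'   `scaffold_id`, `index`, `start`, `stop`, `strand`, `aa_seq`.
#' @export
parseProteinHeaders <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- Biostrings::readAAStringSet(path, format = "fasta")
  if (length(seqs) == 0L) stop("no sequences in ", path)
  headers <- names(seqs)
  parts <- strsplit(headers, "#", fixed = TRUE)
  bad <- vapply(parts, length, 0L) < 4L
  if (any(bad))
    stop("protein header lacks coordinate fields: ",
         trimws(headers[which(bad)[1L]]))
  ids <- trimws(vapply(parts, `[[`, "", 1L))
  ids <- sub("\\s.*$", "", ids)
  start1 <- suppressWarnings(as.integer(trimws(vapply(parts, `[[`, "", 2L))))
  stop1 <- suppressWarnings(as.integer(trimws(vapply(parts, `[[`, "", 3L))))
  strandRaw <- trimws(vapply(parts, `[[`, "", 4L))
  if (anyNA(start1) || anyNA(stop1) || !all(strandRaw %in% c("1", "-1")))
    stop("malformed coordinate fields in protein header: ",
         trimws(headers[which(is.na(start1) | is.na(stop1) |
                              !(strandRaw %in% c("1", "-1")))[1L]]))
  scaffold <- sub("_[0-9]+$", "", ids)
  out <- data.frame(id = ids, scaffold_id = scaffold,
                    index = NA_integer_,
                    start = start1 - 1L, stop = stop1,
                    strand = ifelse(strandRaw == "1", "+", "-"),
                    aa_seq = as.character(seqs),
                    stringsAsFactors = FALSE)
  if (any(out$start >= out$stop)) stop("protein with start >= stop")
  out$index <- stats::ave(seq_len(nrow(out)), out$scaffold_id,
                          FUN = function(i) order(order(i)) - 1L)
  rownames(out) <- NULL
  out
}

#' Apply the minimum-input rules to candidate scaffolds
#'
#' The method requires enough coding signal to classify a scaffold: at least
#' `minLen` bp and at least `minOrfs` predicted proteins. Everything else is
#' excluded with a reason.
#'
#' @param scaffolds a [ScaffoldSet].
#' @param proteins protein `data.frame` (see [parseProteinHeaders()]).
#' @param minLen minimum scaffold length in bp (default 1000).
#' @param minOrfs minimum number of ORFs (default 4).
#' @return list with `kept` (a `ScaffoldSet`) and `excluded`
#'   (`data.frame` of `id`, `reason` in `too_short`/`too_few_orfs`).
#' @export
filterCandidates <- function(scaffolds, proteins, minLen = 1000L,
                             minOrfs = 4L) {
  info <- scaffoldInfo(scaffolds)
  if (nrow(proteins) &&
      !all(proteins$scaffold_id %in% info$id))
    stop("protein refers to unknown scaffold: ",
         setdiff(proteins$scaffold_id, info$id)[1L])
  counts <- table(proteins$scaffold_id)
  norf <- as.integer(counts[info$id])
  norf[is.na(norf)] <- 0L
  tooShort <- info$length < minLen
  tooFew <- !tooShort & norf < minOrfs
  keep <- !(tooShort | tooFew)
  excluded <- data.frame(
    id = info$id[!keep],
    reason = ifelse(tooShort[!keep], "too_short", "too_few_orfs"),
    stringsAsFactors = FALSE)
  list(kept = subsetScaffolds(scaffolds, info$id[keep]),
       excluded = excluded)
}

#' Write a ScaffoldSet to FASTA
#'
#' @param scaffolds a [ScaffoldSet].
#' @param path output file.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
writeScaffolds <- function(scaffolds, path, width = 70L) {
  Biostrings::writeXStringSet(scaffoldSeqs(scaffolds), path, width = width)
  invisible(path)
}

#' Write identified viral scaffolds as a minimal GenBank flat file
#'
#' One LOCUS per scaffold with CDS features taken from the protein table
#' (coordinates converted back to 1-based inclusive) and the sequence in
#' ORIGIN blocks. Deliberately minimal: enough structure for genome
#' browsers, not a full GenBank round-trip.
#'
#' @param scaffolds a [ScaffoldSet].
#' @param proteins protein `data.frame`.
#' @param path output file.
#' @param annotations optional [AnnotationTable]; best VOG/KEGG names are
#'   written as `/product` qualifiers.
#' @return `path`, invisibly.
#' @export
writeGenBank <- function(scaffolds, proteins, path, annotations = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  seqs <- as.character(scaffoldSeqs(scaffolds))
  info <- scaffoldInfo(scaffolds)
  prod <- NULL
  if (!is.null(annotations)) {
    h <- annotationHits(annotations)
    h <- h[order(match(h$db, c("VOG", "KEGG", "PFAM"))), ]
    prod <- stats::setNames(h$name, h$protein_id)[!duplicated(h$protein_id)]
  }
  for (i in seq_len(nrow(info))) {
    id <- info$id[i]
    writeLines(sprintf("LOCUS       %-16s %d bp    DNA     linear   %s",
                       substr(id, 1, 16), info$length[i],
                       format(Sys.Date(), "%d-%b-%Y")), con)
    writeLines(sprintf("DEFINITION  %s", id), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    p <- proteins[proteins$scaffold_id == id, , drop = FALSE]
    p <- p[order(p$index), , drop = FALSE]
    for (j in seq_len(nrow(p))) {
      loc <- sprintf("%d..%d", p$start[j] + 1L, p$stop[j])
      if (p$strand[j] == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     CDS             %s", loc), con)
      writeLines(sprintf("                     /locus_tag=\"%s\"", p$id[j]), con)
      nm <- if (!is.null(prod) && p$id[j] %in% names(prod))
        prod[[p$id[j]]] else "hypothetical protein"
      writeLines(sprintf("                     /product=\"%s\"", nm), con)
    }
    writeLines("ORIGIN", con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = 60L)
    for (st in starts) {
      chunk <- substr(s, st, min(st + 59L, nchar(s)))
      tens <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      writeLines(sprintf("%9d %s", st, paste(tolower(tens), collapse = " ")),
                 con)
    }
    writeLines("//", con)
  }
  invisible(path)
}
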