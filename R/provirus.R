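#' Find host-like annotation runs along a scaffold
#'
#' Integrated proviruses are flanked by host sequence, which shows up as
#' runs of KEGG-annotated proteins with low v-scores. A protein is
#' host-like when it carries a KEGG annotation with `v < vCut` and no
#' hallmark annotation from any database; every maximal run of at least
#' `window` consecutive host-like proteins is a host span (a cut site).
#'
#' @param proteinVscores `data.frame` with one row per protein in gene
#'   order: `index`, `kegg_v` (NA when the protein has no KEGG annotation)
#'   and `hallmark` (logical, any database).
#' @param window minimum run length (default 4).
#' @param vCut v-score cutoff (default 1.0, strict `<`).
#' @return `data.frame` of spans with `first`, `last` (protein indices,
#'   inclusive); zero rows when the scaffold has no host span.
#' @export
scanCutSites <- function(proteinVscores, window = 4L, vCut = 1.0) {
  p <- proteinVscores[order(proteinVscores$index), , drop = FALSE]
  hostLike <- !is.na(p$kegg_v) & p$kegg_v < vCut & !p$hallmark
  r <- rle(hostLike)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= window
  data.frame(first = p$index[starts[keep]], last = p$index[ends[keep]])
}

#' Trim a candidate viral span to its first and last virus-like annotation
#'
#' After cutting at host spans, the leftover fragments may still begin or
#' end with unannotated or weakly annotated host genes. The span is
#' advanced/retracted to the first/last protein carrying a virus-like
#' annotation (v >= 1 in any database, or a hallmark annotation).
#'
#' @param span integer vector of protein indices (the candidate span).
#' @param viralLike logical vector named by protein index: does the protein
#'   carry a virus-like annotation?
#' @return integer vector of retained indices, or `NULL` when the span has
#'   no virus-like annotation (fragment discarded).
#' @export
trimToViral <- function(span, viralLike) {
  vl <- viralLike[as.character(span)]
  vl[is.na(vl)] <- FALSE
  if (!any(vl)) return(NULL)
  span[min(which(vl)):max(which(vl))]
}

#' Excise putative provirus fragments from a scaffold
#'
#' Host spans found by [scanCutSites()] are removed; each surviving block
#' of proteins is trimmed to its outermost virus-like annotations and, if
#' it still has at least `minOrfs` proteins, converted into an excised
#' fragment whose nucleotide coordinates run from the start of its first
#' gene to the stop of its last gene (0-based half-open on the parent). A
#' scaffold with no host span is reported intact (zero regions).
#'
#' @param scaffoldSeq character, the parent nucleotide sequence.
#' @param scaffoldId parent scaffold id.
#' @param proteins protein `data.frame` rows for this scaffold.
#' @param annotations an [AnnotationTable].
#' @param minOrfs minimum proteins per fragment (default 4).
#' @param window,vCut passed to [scanCutSites()].
#' @return list with `regions` (`data.frame`: `parent_id`, `fragment_id`,
#'   `first_protein`, `last_protein`, `nt_start`, `nt_stop`, `seq`) and
#'   `has_host_span` (logical).
#' @export
exciseProvirus <- function(scaffoldSeq, scaffoldId, proteins, annotations,
                           minOrfs = 4L, window = 4L, vCut = 1.0) {
  p <- proteins[order(proteins$index), , drop = FALSE]
  h <- annotationHits(annotations)
  h <- h[h$scaffold_id == scaffoldId, , drop = FALSE]
  keggV <- rep(NA_real_, nrow(p))
  kh <- h[h$db == "KEGG", , drop = FALSE]
  keggV[match(kh$protein_id, p$id)] <- kh$v
  hallmark <- p$id %in% h$protein_id[h$hallmark]
  pv <- data.frame(index = p$index, kegg_v = keggV, hallmark = hallmark)
  spans <- scanCutSites(pv, window = window, vCut = vCut)
  empty <- data.frame(parent_id = character(0), fragment_id = character(0),
                      first_protein = integer(0), last_protein = integer(0),
                      nt_start = integer(0), nt_stop = integer(0),
                      seq = character(0), stringsAsFactors = FALSE)
  if (nrow(spans) == 0L)
    return(list(regions = empty, has_host_span = FALSE))
  inHost <- rep(FALSE, nrow(p))
  for (i in seq_len(nrow(spans)))
    inHost[p$index >= spans$first[i] & p$index <= spans$last[i]] <- TRUE
  # proteins with any v>=1 annotation or a hallmark annotation are viral-like
  viralProt <- unique(h$protein_id[h$v >= 1 | h$hallmark])
  viralLike <- stats::setNames(p$id %in% viralProt, p$index)
  blocks <- split(p$index[!inHost], cumsum(inHost)[!inHost])
  regions <- empty
  k <- 0L
  for (b in blocks) {
    trimmed <- trimToViral(b, viralLike)
    if (is.null(trimmed) || length(trimmed) < minOrfs) next
    k <- k + 1L
    first <- min(trimmed); last <- max(trimmed)
    ntStart <- p$start[p$index == first]
    ntStop <- p$stop[p$index == last]
    frag <- substr(scaffoldSeq, ntStart + 1L, ntStop)
    regions <- rbind(regions, data.frame(
      parent_id = scaffoldId,
      fragment_id = sprintf("%s_fragment_%d", scaffoldId, k),
      first_protein = first, last_protein = last,
      nt_start = ntStart, nt_stop = ntStop, seq = frag,
      stringsAsFactors = FALSE))
  }
  list(regions = regions, has_host_span = TRUE)
}

#' Excise proviruses across a scaffold set
#'
#' Applies [exciseProvirus()] to every scaffold. Scaffolds with at least
#' one host span are replaced by their excised fragments (which may be
#' none, when no block retains a virus-like annotation and `minOrfs`
#' proteins); scaffolds without host spans pass through intact. Fragment
#' proteins are re-indexed from 0 with coordinates shifted onto the
#' fragment.
#'
#' @param scaffolds a [ScaffoldSet].
#' @param proteins protein `data.frame`.
#' @param annotations an [AnnotationTable].
#' @param minOrfs,window,vCut see [exciseProvirus()].
#' @return list with `scaffolds` (post-excision [ScaffoldSet]), `proteins`
#'   (post-excision protein table), `regions` (all excised-region rows) and
#'   `dropped_hosts` (ids of scaffolds consumed entirely by host spans).
#' @export
exciseAll <- function(scaffolds, proteins, annotations, minOrfs = 4L,
                      window = 4L, vCut = 1.0) {
  info <- scaffoldInfo(scaffolds)
  seqs <- as.character(scaffoldSeqs(scaffolds))
  keepIds <- character(0)
  dropped <- character(0)
  fragSeq <- character(0)
  fragInfo <- list()
  fragProt <- list()
  allRegions <- list()
  for (i in seq_len(nrow(info))) {
    id <- info$id[i]
    p <- proteins[proteins$scaffold_id == id, , drop = FALSE]
    res <- exciseProvirus(seqs[[i]], id, p, annotations, minOrfs = minOrfs,
                          window = window, vCut = vCut)
    if (!res$has_host_span) {
      keepIds <- c(keepIds, id)
      next
    }
    if (nrow(res$regions) == 0L) {
      dropped <- c(dropped, id)
      next
    }
    allRegions[[length(allRegions) + 1L]] <- res$regions
    for (j in seq_len(nrow(res$regions))) {
      r <- res$regions[j, ]
      fragSeq[r$fragment_id] <- r$seq
      fragInfo[[r$fragment_id]] <- data.frame(
        id = r$fragment_id, length = nchar(r$seq), origin = "excised",
        parent_id = id, parent_start = r$nt_start, parent_stop = r$nt_stop,
        stringsAsFactors = FALSE)
      fp <- p[p$index >= r$first_protein & p$index <= r$last_protein, ,
              drop = FALSE]
      fp <- fp[order(fp$index), , drop = FALSE]
      fp$scaffold_id <- r$fragment_id
      fp$start <- fp$start - r$nt_start
      fp$stop <- fp$stop - r$nt_start
      fp$index <- seq_len(nrow(fp)) - 1L
      fragProt[[r$fragment_id]] <- fp
    }
  }
  keep <- subsetScaffolds(scaffolds, keepIds)
  outSeqs <- c(scaffoldSeqs(keep), Biostrings::DNAStringSet(fragSeq))
  outInfo <- rbind(scaffoldInfo(keep), do.call(rbind, fragInfo))
  rownames(outInfo) <- NULL
  outProt <- rbind(proteins[proteins$scaffold_id %in% keepIds, ,
                            drop = FALSE],
                   do.call(rbind, fragProt))
  rownames(outProt) <- NULL
  list(scaffolds = new("ScaffoldSet", seqs = outSeqs, info = outInfo),
       proteins = outProt,
       regions = if (length(allRegions)) do.call(rbind, allRegions)[,
         c("parent_id", "fragment_id", "first_protein", "last_protein",
           "nt_start", "nt_stop")] else
           data.frame(parent_id = character(0), fragment_id = character(0),
                      first_protein = integer(0), last_protein = integer(0),
                      nt_start = integer(0), nt_stop = integer(0)),
       dropped_hosts = dropped)
}

#' Re-home annotation hits after excision
#'
#' Fragments keep their parent's protein ids but live on a new scaffold;
#' this drops hits whose protein was removed and points the rest at the
#' protein's current scaffold.
#'
#' @param annotations an [AnnotationTable].
#' @param proteins post-excision protein `data.frame`.
#' @return an [AnnotationTable].
#' @export
remapAnnotations <- function(annotations, proteins) {
  h <- annotationHits(annotations)
  m <- match(h$protein_id, proteins$id)
  h <- h[!is.na(m), , drop = FALSE]
  h$scaffold_id <- proteins$scaffold_id[m[!is.na(m)]]
  new("AnnotationTable", hits = h, evalueMax = annotations@evalueMax)
}
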