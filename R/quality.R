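#' Detect a circular genome template via a terminal k-mer match
#'
#' A scaffold assembled from a circular genome carries its start again near
#' its end. The first 20 nt are searched, as an exact string, at every
#' start position within the final 900 bp; the leftmost in-window match is
#' reported. Sequences shorter than 1000 bp are never called circular.
#'
#' @param seq character, nucleotide sequence.
#' @param k length of the probe k-mer (default 20).
#' @param window terminal window searched, in bp (default 900).
#' @return list with `circular` (logical) and `match_position` (1-based
#'   start of the leftmost in-window match, or `NA`).
#' @export
detectCircular <- function(seq, k = 20L, window = 900L) {
  L <- nchar(seq)
  if (L < 1000L) return(list(circular = FALSE, match_position = NA_integer_))
  probe <- substr(seq, 1L, k)
  winStart <- L - window + 1L
  tail <- substr(seq, winStart, L)
  hit <- regexpr(probe, tail, fixed = TRUE)
  if (hit == -1L)
    return(list(circular = FALSE, match_position = NA_integer_))
  list(circular = TRUE, match_position = winStart + as.integer(hit) - 1L)
}

#' Assign a draft-quality tier from annotation tallies
#'
#' Completeness of a viral scaffold is proxied by circularity and by VOG
#' annotation content: a circular sequence is a complete circular genome;
#' otherwise a sequence with at least one hallmark and one
#' nucleotide-replication annotation and VOG annotations on at least a
#' third of its proteins is a high-quality draft; with at least one of
#' hallmark/replication and a fifth of proteins VOG-annotated, a
#' medium-quality draft; anything else a low-quality draft.
#'
#' @param tallies list or one-row `data.frame` with `vog_annotated`,
#'   `replication`, `hallmark`, `total_proteins`.
#' @param circular logical.
#' @param rules threshold list, see [qualityRules()].
#' @return character tier: `"complete_circular"`, `"high_draft"`,
#'   `"medium_draft"` or `"low_draft"`.
#' @export
assessQuality <- function(tallies, circular, rules = qualityRules()) {
  if (circular) return("complete_circular")
  frac <- tallies$vog_annotated / tallies$total_proteins
  if (tallies$hallmark >= rules$high_hallmark_min &&
      tallies$replication >= rules$high_replication_min &&
      frac >= rules$high_vog_frac) return("high_draft")
  if ((tallies$hallmark >= 1 || tallies$replication >= 1) &&
      frac >= rules$medium_vog_frac) return("medium_draft")
  "low_draft"
}

#' Draft-quality rule thresholds
#'
#' @return named list: `high_vog_frac` (0.33), `medium_vog_frac` (0.20),
#'   `high_hallmark_min` (1), `high_replication_min` (1).
#' @export
qualityRules <- function() {
  list(high_vog_frac = 0.33, medium_vog_frac = 0.20,
       high_hallmark_min = 1L, high_replication_min = 1L)
}

qualityTiers <- function() {
  c("low_draft", "medium_draft", "high_draft", "complete_circular")
}

#' Assess quality and lifestyle for every scaffold
#'
#' @param scaffolds a [ScaffoldSet] (post-excision).
#' @param proteins protein `data.frame`.
#' @param annotations an [AnnotationTable] (re-homed after excision).
#' @param rules see [qualityRules()].
#' @return `data.frame` per scaffold: `scaffold_id`, `circular`, `tier`,
#'   `lifestyle`, and the tallies.
#' @export
assessAllQuality <- function(scaffolds, proteins, annotations,
                             rules = qualityRules()) {
  info <- scaffoldInfo(scaffolds)
  seqs <- as.character(scaffoldSeqs(scaffolds))
  s <- annotationSummary(annotations, proteins)
  m <- match(info$id, s$scaffold_id)
  out <- data.frame(scaffold_id = info$id,
                    circular = FALSE, tier = NA_character_,
                    lifestyle = NA_character_,
                    vog_annotated = s$vog_n[m],
                    replication = s$replication_n[m],
                    hallmark = s$hallmark_n[m],
                    total_proteins = s$n_proteins[m],
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(info))) {
    circ <- detectCircular(seqs[[i]])$circular
    out$circular[i] <- circ
    out$tier[i] <- assessQuality(
      list(vog_annotated = out$vog_annotated[i],
           replication = out$replication[i],
           hallmark = out$hallmark[i],
           total_proteins = out$total_proteins[i]),
      circ, rules)
    out$lifestyle[i] <- assignLifestyle(
      info$origin[i],
      viralIntegrase = anyViralIntegrase(annotations, info$id[i]))
  }
  out
}

anyViralIntegrase <- function(annotations, scaffoldId) {
  h <- annotationHits(annotations)
  any(h$scaffold_id == scaffoldId & h$integrase_class == "viral_like")
}

#' Label a viral scaffold lytic or lysogenic
#'
#' A virus is lysogenic when it was excised from a host scaffold (an
#' integrated provirus by definition) or carries a viral-like integrase;
#' otherwise lytic.
#'
#' @param origin `"input"` or `"excised"`.
#' @param viralIntegrase logical: any viral-like integrase annotation.
#' @return `"lytic"` or `"lysogenic"`.
#' @export
assignLifestyle <- function(origin, viralIntegrase = FALSE) {
  if (origin == "excised" || isTRUE(viralIntegrase)) "lysogenic" else "lytic"
}

#' Tier trajectory of a genome under stepwise truncation
#'
#' The genome is truncated to 100%, 90%, ..., 10% of its length (kept from
#' the start); at each step only genes lying entirely inside the truncated
#' sequence keep their annotations, tallies are recomputed and a tier
#' assigned. Mirrors the benchmark of running quality estimation on
#' increasingly incomplete genomes.
#'
#' @param seq character, full nucleotide sequence.
#' @param proteins protein `data.frame` rows for this genome.
#' @param annotations an [AnnotationTable].
#' @param scaffoldId genome id.
#' @param steps completeness fractions (default `seq(1, 0.1, by = -0.1)`).
#' @param rules see [qualityRules()].
#' @return `data.frame`: `completeness`, `n_proteins`, `tier`.
#' @export
truncationHarness <- function(seq, proteins, annotations, scaffoldId,
                              steps = seq(1, 0.1, by = -0.1),
                              rules = qualityRules()) {
  h <- annotationHits(annotations)
  h <- h[h$scaffold_id == scaffoldId, , drop = FALSE]
  p <- proteins[proteins$scaffold_id == scaffoldId, , drop = FALSE]
  L <- nchar(seq)
  out <- data.frame(completeness = steps, n_proteins = NA_integer_,
                    tier = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(steps)) {
    keepLen <- floor(L * steps[i])
    keep <- p$stop <= keepLen
    ids <- p$id[keep]
    hh <- h[h$protein_id %in% ids, , drop = FALSE]
    n <- sum(keep)
    out$n_proteins[i] <- n
    if (n == 0L) {
      out$tier[i] <- "low_draft"
      next
    }
    circ <- if (steps[i] >= 1) detectCircular(substr(seq, 1, keepLen))$circular
      else FALSE
    out$tier[i] <- assessQuality(
      list(vog_annotated = sum(hh$db == "VOG"),
           replication = sum(hh$db == "VOG" & hh$replication),
           hallmark = sum(hh$hallmark),
           total_proteins = n),
      circ, rules)
  }
  out
}

#' Write the quality report as TSV
#'
#' @param quality `data.frame` from [assessAllQuality()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeQualityTable <- function(quality, path) {
  utils::write.table(quality, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
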