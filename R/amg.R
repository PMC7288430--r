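#' Load a KEGG ortholog to pathway-map resource
#'
#' TSV with columns `ko_id`, `map_id`, `map_name`, `category` (one row per
#' KO-map membership). A KO is AMG-eligible when at least one of its maps
#' belongs to the "metabolic pathways" category or to the "sulfur relay
#' system". The resource is user-suppliable; a small synthetic version
#' ships under `inst/extdata` for examples and tests.
#'
#' @param path TSV file.
#' @return `data.frame` of the resource.
#' @export
loadPathwayMap <- function(path) {
  if (!file.exists(path)) stop("pathway-map resource not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  need <- c("ko_id", "map_id", "map_name", "category")
  if (!all(need %in% names(tab)))
    stop("pathway-map resource needs columns: ",
         paste(need, collapse = ", "))
  tab
}

#' Default AMG exclusion list
#'
#' Annotations removed from AMG consideration: ribonucleotide reductases
#' (nrdA/nrdB) and thymidylate synthases (thyA/thyX), which viruses carry
#' for their own genome replication, plus KOs performing direct
#' nucleotide-to-nucleotide conversions. Editable: pass your own vector of
#' KO ids and/or gene symbols.
#'
#' @return character vector of excluded identifiers (KO ids or gene
#'   symbols, matched against both).
#' @export
amgExclusions <- function() {
  c("nrdA", "nrdB", "thyA", "thyX",
    # ribonucleotide reductase / thymidylate KOs
    "K00525", "K00526", "K10807", "K10808", "K00560", "K03465",
    # nucleotide interconversion KOs (kinases/deaminases among NMP/NDP/NTP)
    "K00857", "K00560", "K00943", "K01520", "K01493")
}

#' Identify auxiliary metabolic genes among KEGG annotations
#'
#' A KEGG best-hit annotation on a viral scaffold is an AMG when its KO
#' maps to at least one eligible pathway map (the "metabolic pathways"
#' category, or the "sulfur relay system") and is not on the exclusion
#' list (matched by KO id or by gene symbol in the annotation name).
#'
#' @param annotations an [AnnotationTable] restricted to viral scaffolds.
#' @param pathwayMap `data.frame` from [loadPathwayMap()].
#' @param exclusions character vector, see [amgExclusions()].
#' @return `data.frame` of AMG records: `protein_id`, `scaffold_id`,
#'   `ko_id`, `pathway_maps` (comma-joined), `category`.
#' @export
identifyAmgs <- function(annotations, pathwayMap,
                         exclusions = amgExclusions()) {
  eligible <- pathwayMap[
    tolower(pathwayMap$category) == "metabolic pathways" |
    tolower(pathwayMap$map_name) == "sulfur relay system" |
    tolower(pathwayMap$category) == "sulfur relay system", , drop = FALSE]
  h <- annotationHits(annotations)
  h <- h[h$db == "KEGG", , drop = FALSE]
  h <- h[h$profile_id %in% eligible$ko_id, , drop = FALSE]
  excl <- h$profile_id %in% exclusions
  for (sym in exclusions)
    excl <- excl | grepl(paste0("\\b", sym, "\\b"), h$name)
  h <- h[!excl, , drop = FALSE]
  if (nrow(h) == 0L)
    return(data.frame(protein_id = character(0), scaffold_id = character(0),
                      ko_id = character(0), pathway_maps = character(0),
                      category = character(0), stringsAsFactors = FALSE))
  maps <- vapply(h$profile_id, function(ko) {
    sub <- eligible[eligible$ko_id == ko, , drop = FALSE]
    paste(sort(unique(sub$map_id)), collapse = ",")
  }, "")
  cat_ <- vapply(h$profile_id, function(ko) {
    sub <- eligible[eligible$ko_id == ko, , drop = FALSE]
    sort(unique(sub$category))[1L]
  }, "")
  out <- data.frame(protein_id = h$protein_id, scaffold_id = h$scaffold_id,
                    ko_id = h$profile_id, pathway_maps = unname(maps),
                    category = unname(cat_), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Summarize AMG records by category and pathway, and compare groups
#'
#' `summarizeAmgs()` tallies records per KEGG category and per pathway map.
#' `compareAmgGroups()` computes the shared and unique non-redundant KO
#' sets between two groups of records (the usual Venn structure).
#'
#' @param records `data.frame` from [identifyAmgs()].
#' @return `summarizeAmgs()`: list with `by_category` and `by_pathway`
#'   count tables (`data.frame`s).
#' @export
summarizeAmgs <- function(records) {
  countTable <- function(x, col) {
    if (length(x) == 0L) {
      out <- data.frame(a = character(0), n = integer(0))
    } else {
      t <- table(x)
      out <- data.frame(a = names(t), n = as.integer(t),
                        stringsAsFactors = FALSE)
    }
    names(out)[1] <- col
    out
  }
  list(by_category = countTable(records$category, "category"),
       by_pathway = countTable(unlist(strsplit(records$pathway_maps, ",")),
                               "map_id"))
}

#' @rdname summarizeAmgs
#' @param recordsA,recordsB AMG record `data.frame`s for the two groups.
#' @return `compareAmgGroups()`: list with `shared`, `unique_a`,
#'   `unique_b` (character KO sets) and the corresponding counts.
#' @export
compareAmgGroups <- function(recordsA, recordsB) {
  a <- unique(recordsA$ko_id)
  b <- unique(recordsB$ko_id)
  shared <- intersect(a, b)
  list(shared = sort(shared),
       unique_a = sort(setdiff(a, b)),
       unique_b = sort(setdiff(b, a)),
       n_shared = length(shared),
       n_unique_a = length(setdiff(a, b)),
       n_unique_b = length(setdiff(b, a)),
       n_a = length(a), n_b = length(b))
}

#' Write AMG records as TSV
#'
#' @param records `data.frame` from [identifyAmgs()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeAmgTable <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
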