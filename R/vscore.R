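#' Keyword rule sets behind v-score floors and flags
#'
#' The hallmark keywords are the virus-diagnostic gene names that receive a
#' v-score floor of 1 in every database ("base plate" and "baseplate" both
#' match). Replication keywords flag nucleotide-replication profiles;
#' plasmid keywords flag plasmid-like mobility markers; the exclusion list
#' names non-prokaryotic-virus annotations whose keyword floors are not
#' applied.
#'
#' @return named list of character vectors: `hallmark`, `replication`,
#'   `plasmid`, `exclude`.
#' @export
vscoreKeywords <- function() {
  list(
    hallmark = c("portal", "terminase", "spike", "capsid", "sheath", "tail",
                 "coat", "virion", "lysin", "holin", "base ?plate",
                 "lysozyme", "head", "structural"),
    replication = c("polymerase", "helicase", "primase", "nuclease",
                    "ligase", "topoisomerase", "ribonucleotide reductase",
                    "single[- ]strand(ed)? (DNA )?binding"),
    plasmid = c("relaxase", "mobilization", "conjugal", "partitioning"),
    exclude = c("reovirus", "herpes", "baculovirus", "adenovirus",
                "poxvirus", "retrovirus")
  )
}

matchAnyKeyword <- function(names, keywords) {
  hit <- rep(FALSE, length(names))
  for (kw in keywords) hit <- hit | grepl(kw, names, ignore.case = TRUE)
  hit
}

classifyProfileNames <- function(names, keywords = vscoreKeywords()) {
  excluded <- matchAnyKeyword(names, keywords$exclude)
  hallmark <- matchAnyKeyword(names, keywords$hallmark) & !excluded
  replication <- matchAnyKeyword(names, keywords$replication) & !excluded
  integrase <- rep("none", length(names))
  integrase[matchAnyKeyword(names, keywords$plasmid)] <- "plasmid_like"
  integrase[grepl("integrase", names, ignore.case = TRUE) & !excluded] <-
    "viral_like"
  list(excluded = excluded, hallmark = hallmark, replication = replication,
       integrase_class = integrase)
}

#' Compute v-scores for a profile collection from viral hit counts
#'
#' Each profile's v-score is its number of significant hits against a
#' dereplicated viral protein set divided by 100, capped at 10; profiles
#' with no hits score 0. Two keyword floors are then applied to the profile
#' *name*: for KEGG and Pfam, a name containing "phage" with a v-score
#' above zero is floored at 1; in all three databases a name containing a
#' viral hallmark keyword (portal, terminase, spike, capsid, sheath, tail,
#' coat, virion, lysin, holin, base plate, lysozyme, head, structural) is
#' floored at 1 and flagged as hallmark. Names on the non-prokaryotic-virus
#' exclusion list are exempt from the floors.
#'
#' @param hitCounts named integer vector: profile id -> significant hit
#'   count against the viral protein set.
#' @param names named character vector: profile id -> annotation name.
#' @param db database label (`"KEGG"`, `"PFAM"`, `"VOG"`), recycled, or a
#'   vector parallel to `hitCounts`.
#' @param keywords keyword rule set, see [vscoreKeywords()].
#' @return a [VScoreTable].
#' @export
computeVScores <- function(hitCounts, names, db,
                           keywords = vscoreKeywords()) {
  ids <- base::names(hitCounts)
  if (is.null(ids)) stop("hitCounts must be named by profile id")
  counts <- as.numeric(hitCounts)
  if (any(counts < 0)) stop("negative hit counts")
  nm <- unname(names[ids])
  db <- rep_len(match.arg(db, c("KEGG", "PFAM", "VOG"), several.ok = TRUE),
                length(ids))
  v <- pmin(counts / 100, 10)
  cls <- classifyProfileNames(nm, keywords)
  phage <- grepl("phage", nm, ignore.case = TRUE) & !cls$excluded
  floorPhage <- db %in% c("KEGG", "PFAM") & phage & v > 0
  v[floorPhage] <- pmax(v[floorPhage], 1)
  v[cls$hallmark] <- pmax(v[cls$hallmark], 1)
  tab <- data.frame(profile_id = ids, db = db, name = nm, v = v,
                    hallmark = cls$hallmark, replication = cls$replication,
                    integrase_class = cls$integrase_class,
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  newVScoreTable(tab)
}

newVScoreTable <- function(tab) {
  misses <- new.env(parent = emptyenv())
  misses$n <- 0L
  new("VScoreTable", table = tab, misses = misses)
}

#' Read / write a v-score table as TSV
#'
#' Columns: `profile_id`, `db`, `name`, `v`, `hallmark`, `replication`,
#' `integrase_class`. Duplicate profile ids are an error.
#'
#' @param path TSV file.
#' @return [loadVScoreTable()] returns a [VScoreTable];
#'   [writeVScoreTable()] returns `path` invisibly.
#' @export
loadVScoreTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           quote = "", comment.char = "",
                           stringsAsFactors = FALSE)
  if (anyDuplicated(tab$profile_id))
    stop("duplicate profile id in ", path, ": ",
         tab$profile_id[duplicated(tab$profile_id)][1L])
  tab$hallmark <- as.logical(tab$hallmark)
  tab$replication <- as.logical(tab$replication)
  newVScoreTable(tab)
}

#' @rdname loadVScoreTable
#' @param vtable a [VScoreTable].
#' @export
writeVScoreTable <- function(vtable, path) {
  utils::write.table(vscoreTable(vtable), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Look up profiles in a v-score table
#'
#' Unknown profile ids resolve to a v-score of 0 (no flags) and increment
#' the table's miss counter, readable with [vscoreMisses()].
#'
#' @param vtable a [VScoreTable].
#' @param profileIds character vector of profile ids.
#' @return `data.frame` with `v`, `name`, `hallmark`, `replication`,
#'   `integrase_class` parallel to `profileIds`.
#' @export
lookupVScore <- function(vtable, profileIds) {
  tab <- vscoreTable(vtable)
  idx <- match(profileIds, tab$profile_id)
  miss <- is.na(idx)
  if (any(miss))
    vtable@misses$n <- vtable@misses$n + sum(miss)
  out <- data.frame(
    v = ifelse(miss, 0, tab$v[idx]),
    name = ifelse(miss, NA_character_, tab$name[idx]),
    hallmark = ifelse(miss, FALSE, tab$hallmark[idx]),
    replication = ifelse(miss, FALSE, tab$replication[idx]),
    integrase_class = ifelse(miss, "none", tab$integrase_class[idx]),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @rdname lookupVScore
#' @export
vscoreMisses <- function(vtable) vtable@misses$n
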