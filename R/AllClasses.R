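#' @import methods
#' @importFrom Biostrings DNAStringSet readDNAStringSet readAAStringSet
#'   writeXStringSet width subseq
NULL

#' ScaffoldSet: assembled nucleotide scaffolds with excision provenance
#'
#' A thin container around a [Biostrings::DNAStringSet] that additionally
#' tracks, for every record, whether it was part of the original assembly
#' (`origin = "input"`) or was excised from a host scaffold as a putative
#' provirus (`origin = "excised"`), and in the latter case the parent
#' scaffold id and the 0-based half-open coordinates of the fragment on the
#' parent.
#'
#' @slot seqs a `DNAStringSet`, one entry per scaffold.
#' @slot info a `data.frame` with one row per scaffold and columns
#'   `id`, `length`, `origin`, `parent_id`, `parent_start`, `parent_stop`.
#'
#' @exportClass ScaffoldSet
setClass("ScaffoldSet",
  representation(seqs = "DNAStringSet", info = "data.frame"))

setValidity("ScaffoldSet", function(object) {
  msg <- character(0)
  info <- object@info
  need <- c("id", "length", "origin", "parent_id", "parent_start", "parent_stop")
  if (!all(need %in% names(info)))
    return(paste("info must have columns:", paste(need, collapse = ", ")))
  if (length(object@seqs) != nrow(info))
    msg <- c(msg, "seqs and info disagree in length")
  else {
    if (nrow(info) && !identical(names(object@seqs), info$id))
      msg <- c(msg, "names(seqs) must equal info$id")
    if (!all(Biostrings::width(object@seqs) == info$length))
      msg <- c(msg, "info$length must equal sequence widths")
    if (any(info$length == 0))
      msg <- c(msg, "zero-length scaffold")
    if (!all(info$origin %in% c("input", "excised")))
      msg <- c(msg, "origin must be 'input' or 'excised'")
    ex <- info$origin == "excised"
    if (any(ex)) {
      ok <- !is.na(info$parent_id[ex]) & !is.na(info$parent_start[ex]) &
        !is.na(info$parent_stop[ex]) & info$parent_start[ex] >= 0 &
        info$parent_start[ex] < info$parent_stop[ex]
      if (!all(ok))
        msg <- c(msg, "excised records need parent_id and 0 <= parent_start < parent_stop")
    }
  }
  if (length(msg)) msg else TRUE
})

#' VScoreTable: per-profile virus-association scores
#'
#' Maps each HMM profile id to its v-score (significant hits against a
#' dereplicated viral protein set / 100, capped at 10, with keyword floors),
#' plus flags for viral hallmark profiles, nucleotide-replication profiles
#' and integrase class. Lookups of unknown profiles return 0 and increment a
#' miss counter kept in an environment so it survives pass-by-value.
#'
#' @slot table `data.frame` with columns `profile_id`, `db`, `name`, `v`,
#'   `hallmark`, `replication`, `integrase_class`.
#' @slot misses environment holding the unknown-lookup counter `n`.
#'
#' @exportClass VScoreTable
setClass("VScoreTable",
  representation(table = "data.frame", misses = "environment"))

setValidity("VScoreTable", function(object) {
  tab <- object@table
  need <- c("profile_id", "db", "name", "v", "hallmark", "replication",
            "integrase_class")
  if (!all(need %in% names(tab)))
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  msg <- character(0)
  if (anyDuplicated(tab$profile_id))
    msg <- c(msg, "duplicate profile ids")
  if (nrow(tab)) {
    if (any(tab$v < 0 | tab$v > 10)) msg <- c(msg, "v-scores must lie in [0, 10]")
    if (any(tab$hallmark & tab$v < 1)) msg <- c(msg, "hallmark profiles must have v >= 1")
    if (!all(tab$integrase_class %in% c("none", "viral_like", "plasmid_like")))
      msg <- c(msg, "bad integrase_class")
  }
  if (length(msg)) msg else TRUE
})

#' AnnotationTable: best profile hit per protein per database
#'
#' Holds at most one hit per (protein, database) pair, each below the
#' significance threshold, with the profile's v-score and flags resolved
#' from a [VScoreTable].
#'
#' @slot hits `data.frame` with columns `protein_id`, `scaffold_id`, `db`,
#'   `profile_id`, `name`, `evalue`, `bitscore`, `v`, `hallmark`,
#'   `replication`, `integrase_class`.
#' @slot evalueMax numeric significance threshold (strict `<`).
#'
#' @exportClass AnnotationTable
setClass("AnnotationTable",
  representation(hits = "data.frame", evalueMax = "numeric"))

setValidity("AnnotationTable", function(object) {
  h <- object@hits
  need <- c("protein_id", "scaffold_id", "db", "profile_id", "name",
            "evalue", "bitscore", "v", "hallmark", "replication",
            "integrase_class")
  if (!all(need %in% names(h)))
    return(paste("hits must have columns:", paste(need, collapse = ", ")))
  msg <- character(0)
  if (nrow(h)) {
    if (anyDuplicated(paste(h$protein_id, h$db)))
      msg <- c(msg, "more than one best hit for a (protein, db) pair")
    if (any(h$evalue >= object@evalueMax))
      msg <- c(msg, "stored hit at or above the e-value threshold")
    if (!all(h$db %in% c("KEGG", "PFAM", "VOG")))
      msg <- c(msg, "db must be KEGG, PFAM or VOG")
  }
  if (length(msg)) msg else TRUE
})

#' ClassifierModel: the trained neural-network virus classifier
#'
#' A single-hidden-layer perceptron (logistic activations, logistic output)
#' over the 27 annotation-signature metrics, together with the feature
#' standardization learned from the training set, the feature order it
#' expects, the training seed and the decision threshold.
#'
#' @slot fit the fitted `nnet` object.
#' @slot featureOrder character(27), names of the metrics in order.
#' @slot center,scale numeric(27) standardization parameters.
#' @slot hidden integer, hidden-layer size.
#' @slot seed integer training seed.
#' @slot threshold numeric decision threshold on the virus score.
#' @slot holdoutAccuracy numeric accuracy on the internal holdout split.
#' @slot version character container version stamp.
#'
#' @exportClass ClassifierModel
setClass("ClassifierModel",
  representation(fit = "ANY", featureOrder = "character", center = "numeric",
                 scale = "numeric", hidden = "integer", seed = "integer",
                 threshold = "numeric", holdoutAccuracy = "numeric",
                 version = "character"))

setValidity("ClassifierModel", function(object) {
  if (length(object@featureOrder) != 27L)
    return("featureOrder must name exactly 27 metrics")
  if (length(object@center) != 27L || length(object@scale) != 27L)
    return("center/scale must be length 27")
  TRUE
})

setMethod("show", "ScaffoldSet", function(object) {
  cat("ScaffoldSet with", length(object@seqs), "scaffolds (",
      sum(object@info$origin == "excised"), "excised )\n")
  if (nrow(object@info))
    cat("  lengths:", min(object@info$length), "-", max(object@info$length), "bp\n")
})

setMethod("show", "VScoreTable", function(object) {
  tab <- object@table
  cat("VScoreTable with", nrow(tab), "profiles;",
      sum(tab$hallmark), "hallmark,", sum(tab$replication), "replication\n")
})

setMethod("show", "AnnotationTable", function(object) {
  cat("AnnotationTable:", nrow(object@hits), "best hits over",
      length(unique(object@hits$protein_id)), "proteins (e-value <",
      format(object@evalueMax), ")\n")
})

setMethod("show", "ClassifierModel", function(object) {
  cat("ClassifierModel: 27 ->", object@hidden, "-> 1 MLP, seed",
      object@seed, ", holdout accuracy",
      sprintf("%.3f", object@holdoutAccuracy), "\n")
})

#' @describeIn ScaffoldSet number of scaffolds
#' @param x a `ScaffoldSet`
#' @export
setMethod("length", "ScaffoldSet", function(x) length(x@seqs))

#' Accessors for ScaffoldSet
#'
#' `scaffoldSeqs()` returns the underlying `DNAStringSet`; `scaffoldInfo()`
#' the provenance table; `scaffoldIds()` the ids.
#'
#' @param x a `ScaffoldSet`
#' @return `DNAStringSet`, `data.frame`, or `character` respectively.
#' @export
scaffoldSeqs <- function(x) x@seqs

#' @rdname scaffoldSeqs
#' @export
scaffoldInfo <- function(x) x@info

#' @rdname scaffoldSeqs
#' @export
scaffoldIds <- function(x) x@info$id

#' Accessors for VScoreTable and AnnotationTable
#'
#' @param x a `VScoreTable` or `AnnotationTable`
#' @return the underlying `data.frame`.
#' @export
vscoreTable <- function(x) x@table

#' @rdname vscoreTable
#' @export
annotationHits <- function(x) x@hits

#' Subset a ScaffoldSet by scaffold id
#'
#' @param x a `ScaffoldSet`
#' @param ids character vector of scaffold ids to keep
#' @return a `ScaffoldSet`
#' @export
subsetScaffolds <- function(x, ids) {
  keep <- x@info$id %in% ids
  new("ScaffoldSet", seqs = x@seqs[keep],
      info = x@info[keep, , drop = FALSE])
}

emptyScaffoldInfo <- function(n = 0L) {
  data.frame(id = character(n), length = integer(n),
             origin = character(n), parent_id = rep(NA_character_, n),
             parent_start = rep(NA_integer_, n),
             parent_stop = rep(NA_integer_, n),
             stringsAsFactors = FALSE)
}

#' Construct a ScaffoldSet from sequences
#'
#' @param seqs named character vector or `DNAStringSet`
#' @param origin "input" or "excised" (recycled)
#' @param parent_id,parent_start,parent_stop provenance for excised records
#'   (`parent_start`/`parent_stop` are 0-based half-open on the parent)
#' @return a `ScaffoldSet`
#' @export
ScaffoldSet <- function(seqs, origin = "input", parent_id = NA_character_,
                        parent_start = NA_integer_, parent_stop = NA_integer_) {
  if (!is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  n <- length(seqs)
  if (n == 0L)
    return(new("ScaffoldSet", seqs = seqs, info = emptyScaffoldInfo()))
  info <- data.frame(id = names(seqs), length = Biostrings::width(seqs),
                     origin = rep_len(origin, n),
                     parent_id = rep_len(parent_id, n),
                     parent_start = rep_len(as.integer(parent_start), n),
                     parent_stop = rep_len(as.integer(parent_stop), n),
                     stringsAsFactors = FALSE)
  new("ScaffoldSet", seqs = seqs, info = info)
}
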