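#' Assemble a run configuration
#'
#' Bundles the inputs and thresholds for [runPipeline()]. The method
#' floors (`minLen >= 1000`, `minOrfs >= 4`) are enforced: the workflow
#' needs at least four open reading frames of annotation signal per
#' scaffold to make a defensible call.
#'
#' @param scaffolds a [ScaffoldSet] (e.g. from [readScaffolds()]).
#' @param proteins protein `data.frame` (e.g. from
#'   [parseProteinHeaders()]).
#' @param hits raw hit `data.frame` (e.g. rows from [parseSearchTable()]
#'   over the three databases), or an [AnnotationTable] already reduced to
#'   best hits.
#' @param vtable a [VScoreTable].
#' @param model a [ClassifierModel].
#' @param pathwayMap AMG pathway-map resource `data.frame`, or `NULL` to
#'   skip AMG profiling.
#' @param minLen,minOrfs input filters (floors 1000 bp / 4 ORFs).
#' @param virome virome mode: skip the prefilter and loosen the
#'   zero-density curation rule (input is mostly viral already).
#' @param seed RNG seed recorded in the run summary.
#' @return a `RunConfig` list.
#' @export
runConfig <- function(scaffolds, proteins, hits, vtable, model,
                      pathwayMap = NULL, minLen = 1000L, minOrfs = 4L,
                      virome = FALSE, seed = 1L) {
  if (minLen < 1000L) stop("minLen below the method floor of 1000 bp")
  if (minOrfs < 4L) stop("minOrfs below the method floor of 4")
  structure(list(scaffolds = scaffolds, proteins = proteins, hits = hits,
                 vtable = vtable, model = model, pathwayMap = pathwayMap,
                 minLen = as.integer(minLen), minOrfs = as.integer(minOrfs),
                 virome = isTRUE(virome), seed = as.integer(seed)),
            class = "RunConfig")
}

#' Run the full virus-recovery workflow
#'
#' Stages, in order: input filters, best-hit annotation, prefilter,
#' provirus excision, feature compilation, neural-network classification,
#' curation, quality/lifestyle assessment, AMG profiling. Each stage logs
#' counts in and out; the result bundle carries every intermediate table
#' plus an exit summary.
#'
#' @param config a `RunConfig` from [runConfig()].
#' @param quiet suppress stage logging.
#' @return list with `predictions`, `viruses` (a [ScaffoldSet]),
#'   `proteins`, `annotations`, `regions`, `quality`, `amgs`, `excluded`,
#'   `summary`.
#' @export
runPipeline <- function(config, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  set.seed(config$seed)

  flt <- filterCandidates(config$scaffolds, config$proteins,
                          minLen = config$minLen, minOrfs = config$minOrfs)
  scaffolds <- flt$kept
  proteins <- config$proteins[config$proteins$scaffold_id %in%
                                scaffoldIds(scaffolds), , drop = FALSE]
  say("filter: %d in, %d kept, %d excluded", length(config$scaffolds),
      length(scaffolds), nrow(flt$excluded))

  annotations <- if (is(config$hits, "AnnotationTable")) config$hits
    else selectBestHits(config$hits, config$vtable, proteins = proteins)
  say("annotate: %d best hits", nrow(annotationHits(annotations)))

  cfg <- curationDefaults(virome = config$virome)
  summ <- annotationSummary(annotations, proteins)
  pf <- prefilterScaffolds(summ, cfg)
  removedPre <- pf$scaffold_id[!pf$pass]
  scaffolds <- subsetScaffolds(scaffolds,
                               setdiff(scaffoldIds(scaffolds), removedPre))
  proteins <- proteins[proteins$scaffold_id %in% scaffoldIds(scaffolds), ,
                       drop = FALSE]
  say("prefilter: %d removed, %d remain", length(removedPre),
      length(scaffolds))

  exc <- exciseAll(scaffolds, proteins, annotations,
                   minOrfs = config$minOrfs)
  scaffolds <- exc$scaffolds
  proteins <- exc$proteins
  annotations <- remapAnnotations(annotations, proteins)
  say("excise: %d provirus fragments, %d scaffolds consumed as host",
      nrow(exc$regions), length(exc$dropped_hosts))

  if (length(scaffolds) == 0L) {
    say("no candidates remain after filtering")
    return(emptyRunResult(config, flt$excluded, removedPre,
                          exc$dropped_hosts))
  }

  amgKos <- if (is.null(config$pathwayMap)) character(0) else
    unique(config$pathwayMap$ko_id[
      tolower(config$pathwayMap$category) %in%
        c("metabolic pathways", "sulfur relay system") |
      tolower(config$pathwayMap$map_name) == "sulfur relay system"])
  features <- compileFeatureMatrix(proteins, annotations, amgKos = amgKos)
  pred <- predictVirus(config$model, features)
  summ2 <- annotationSummary(annotations, proteins)
  pred <- curatePredictions(pred, summ2, cfg)
  say("classify: %d raw virus, %d after curation",
      sum(pred$raw_label == "virus"), sum(pred$final_label == "virus"))

  virusIds <- pred$scaffold_id[pred$final_label == "virus"]
  viruses <- subsetScaffolds(scaffolds, virusIds)
  vProteins <- proteins[proteins$scaffold_id %in% virusIds, , drop = FALSE]
  vAnnotations <- remapAnnotations(annotations, vProteins)
  quality <- if (length(viruses))
    assessAllQuality(viruses, vProteins, vAnnotations) else NULL
  amgs <- if (!is.null(config$pathwayMap) && length(viruses))
    identifyAmgs(vAnnotations, config$pathwayMap) else NULL
  say("quality: %s", if (is.null(quality)) "no viruses" else
    paste(names(table(quality$tier)), table(quality$tier),
          sep = "=", collapse = ", "))

  prefRows <- prefilterRows(c(removedPre, exc$dropped_hosts))
  predictions <- rbind(pred, prefRows)
  summary <- list(
    n_input = length(config$scaffolds),
    n_excluded = nrow(flt$excluded),
    n_prefilter_removed = length(removedPre),
    n_proviruses = nrow(exc$regions),
    n_viruses = length(viruses),
    n_lysogenic = if (is.null(quality)) 0L else
      sum(quality$lifestyle == "lysogenic"),
    tiers = if (is.null(quality)) list() else
      as.list(table(quality$tier)),
    n_amgs = if (is.null(amgs)) 0L else nrow(amgs),
    virome = config$virome, seed = config$seed)
  list(predictions = predictions, viruses = viruses, proteins = vProteins,
       annotations = vAnnotations, regions = exc$regions,
       quality = quality, amgs = amgs, excluded = flt$excluded,
       summary = summary)
}

prefilterRows <- function(ids) {
  n <- length(ids)
  data.frame(scaffold_id = ids, score = rep(NA_real_, n),
             raw_label = rep("nonvirus", n),
             final_label = rep("nonvirus", n),
             curation_reason = rep("prefilter_removed", n),
             stringsAsFactors = FALSE)
}

emptyRunResult <- function(config, excluded, removedPre, droppedHosts) {
  predictions <- prefilterRows(c(removedPre, droppedHosts))
  list(predictions = predictions,
       viruses = ScaffoldSet(Biostrings::DNAStringSet()),
       proteins = config$proteins[0, , drop = FALSE],
       annotations = new("AnnotationTable", hits = emptyHits(),
                         evalueMax = 1e-5),
       regions = data.frame(), quality = NULL, amgs = NULL,
       excluded = excluded,
       summary = list(n_input = length(config$scaffolds),
                      n_excluded = nrow(excluded),
                      n_prefilter_removed = length(removedPre),
                      n_proviruses = 0L, n_viruses = 0L, n_lysogenic = 0L,
                      tiers = list(), n_amgs = 0L,
                      virome = config$virome, seed = config$seed))
}

#' Write the result bundle to an output directory
#'
#' Produces the user-facing files: viral FASTA and GenBank, prediction,
#' annotation, quality, AMG and exclusion TSVs, provirus coordinates and a
#' machine-readable JSON run summary.
#'
#' @param result bundle from [runPipeline()].
#' @param dir output directory (created if absent).
#' @param prefix file-name prefix (default `"viroscreen"`).
#' @return character vector of the files written, invisibly.
#' @export
writeRunOutputs <- function(result, dir, prefix = "viroscreen") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(x) file.path(dir, paste0(prefix, x))
  files <- character(0)
  if (length(result$viruses)) {
    writeScaffolds(result$viruses, f("_viruses.fna"))
    writeGenBank(result$viruses, result$proteins, f("_viruses.gbk"),
                 annotations = result$annotations)
    files <- c(files, f("_viruses.fna"), f("_viruses.gbk"))
  }
  utils::write.table(result$predictions, f("_predictions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- c(files, f("_predictions.tsv"))
  writeAnnotationTable(result$annotations, f("_annotations.tsv"))
  files <- c(files, f("_annotations.tsv"))
  if (!is.null(result$quality)) {
    writeQualityTable(result$quality, f("_quality.tsv"))
    files <- c(files, f("_quality.tsv"))
  }
  if (!is.null(result$amgs)) {
    writeAmgTable(result$amgs, f("_amgs.tsv"))
    files <- c(files, f("_amgs.tsv"))
  }
  if (nrow(result$regions)) {
    utils::write.table(result$regions, f("_proviruses.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files <- c(files, f("_proviruses.tsv"))
  }
  utils::write.table(result$excluded, f("_excluded.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- c(files, f("_excluded.tsv"))
  jsonlite::write_json(result$summary, f("_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, f("_summary.json"))
  invisible(files)
}
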