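#' Train the neural-network virus classifier
#'
#' Fits a single-hidden-layer perceptron (logistic hidden units, logistic
#' output, weight decay) on labeled 27-metric feature vectors. A seeded 10%
#' split is held out and the model's accuracy on it is stored in the
#' returned object. Training is deterministic given `seed`.
#'
#' @param features `data.frame` from [compileFeatureMatrix()].
#' @param labels vector of class labels (`"virus"`/`"nonvirus"`), parallel
#'   to `features` rows or named by scaffold id.
#' @param hidden hidden-layer size (default 32).
#' @param seed RNG seed for weight initialization and the holdout split.
#' @param decay weight-decay regularization (default 5e-4).
#' @param maxit maximum optimizer iterations.
#' @return a [ClassifierModel].
#' @export
trainClassifier <- function(features, labels, hidden = 32L, seed = 42L,
                            decay = 5e-4, maxit = 300L) {
  x <- as.matrix(features[, featureNames(), drop = FALSE])
  if (!is.null(names(labels))) labels <- labels[features$scaffold_id]
  y <- as.integer(labels == "virus")
  if (length(unique(y)) < 2L)
    stop("training data must contain both classes")
  if (min(table(y)) < 50L)
    stop("need at least 50 examples per class")
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")
  set.seed(seed)
  holdout <- sample(nrow(xs), max(1L, round(0.1 * nrow(xs))))
  fit <- nnet::nnet(xs[-holdout, , drop = FALSE], y[-holdout],
                    size = hidden, decay = decay, maxit = maxit,
                    entropy = TRUE, trace = FALSE, MaxNWts = 10000L)
  pred <- as.numeric(stats::predict(fit, xs[holdout, , drop = FALSE]))
  acc <- mean((pred >= 0.5) == (y[holdout] == 1L))
  new("ClassifierModel", fit = fit, featureOrder = featureNames(),
      center = center, scale = scale, hidden = as.integer(hidden),
      seed = as.integer(seed), threshold = 0.5, holdoutAccuracy = acc,
      version = "viroscreen-model-1")
}

#' Score scaffolds with a trained classifier
#'
#' @param model a [ClassifierModel].
#' @param features `data.frame` from [compileFeatureMatrix()].
#' @return `data.frame` with `scaffold_id`, `score` (probability of the
#'   virus class) and `raw_label`.
#' @export
predictVirus <- function(model, features) {
  x <- as.matrix(features[, model@featureOrder, drop = FALSE])
  xs <- sweep(sweep(x, 2, model@center), 2, model@scale, "/")
  score <- as.numeric(stats::predict(model@fit, xs))
  data.frame(scaffold_id = features$scaffold_id, score = score,
             raw_label = ifelse(score >= model@threshold,
                                "virus", "nonvirus"),
             stringsAsFactors = FALSE)
}

#' Save / load a classifier model file
#'
#' The model is written as a portable serialized container carrying a
#' version stamp; loading verifies the stamp.
#'
#' @param model a [ClassifierModel].
#' @param path model file.
#' @return [loadClassifier()] returns the [ClassifierModel].
#' @export
saveClassifier <- function(model, path) {
  saveRDS(model, path, version = 2)
  invisible(path)
}

#' @rdname saveClassifier
#' @export
loadClassifier <- function(path) {
  model <- readRDS(path)
  if (!is(model, "ClassifierModel") ||
      !startsWith(model@version, "viroscreen-model"))
    stop("not a classifier model file: ", path)
  model
}

#' Default thresholds for the prefilter and curation rules
#'
#' All cutoffs bracketing the classifier are configuration, not code:
#' `prefilter_kegg_frac` (fraction of proteins KEGG-annotated above which a
#' scaffold is examined), `prefilter_v_per_kegg` (mean KEGG v-score below
#' which it is removed), `curation_zero_frac` (zero-v-score protein density
#' above which a predicted virus with no hallmark is removed; loosened to
#' `virome_zero_frac` in virome mode), `rescue_hallmark_min` and
#' `rescue_zero_max` (the hallmark-rescue rule).
#'
#' @param virome logical: virome mode loosens the zero-density rule and
#'   skips the prefilter.
#' @return named list of thresholds.
#' @export
curationDefaults <- function(virome = FALSE) {
  list(prefilter_kegg_frac = 0.5,
       prefilter_v_per_kegg = 0.1,
       curation_zero_frac = if (virome) 0.8 else 0.6,
       rescue_hallmark_min = 2L,
       rescue_zero_max = 0.2,
       virome = virome)
}

#' Remove scaffolds dominated by confident non-viral signal before the model
#'
#' A scaffold is removed when more than half of its proteins carry KEGG
#' annotations, the summed KEGG v-score is below 0.1 per KEGG annotation,
#' and it has no hallmark annotation. Scaffolds with no annotations pass
#' (the model decides). In virome mode the prefilter is skipped entirely.
#'
#' @param summary per-scaffold `data.frame` from [annotationSummary()].
#' @param config threshold list from [curationDefaults()].
#' @return `data.frame` with `scaffold_id`, `pass` (logical), `reason`.
#' @export
prefilterScaffolds <- function(summary, config = curationDefaults()) {
  if (isTRUE(config$virome)) {
    remove <- rep(FALSE, nrow(summary))
  } else {
    remove <- summary$kegg_n / summary$n_proteins > config$prefilter_kegg_frac &
      summary$kegg_vsum < config$prefilter_v_per_kegg * summary$kegg_n &
      summary$hallmark_n == 0
  }
  data.frame(scaffold_id = summary$scaffold_id, pass = !remove,
             reason = ifelse(remove, "prefilter_removed", "pass"),
             stringsAsFactors = FALSE)
}

#' Curate raw classifier predictions with annotation-based rules
#'
#' Applied in order: (a) a predicted virus carrying plasmid-like
#' integrase/mobility markers and no hallmark annotation becomes nonvirus;
#' (b) a predicted virus where more than 60% of proteins carry zero-v-score
#' annotations and no hallmark becomes nonvirus; (c) a predicted nonvirus
#' with at least two hallmark annotations and at most 20% zero-v-score
#' proteins is rescued to virus. A scaffold satisfying the rescue
#' conditions is never flipped to nonvirus.
#'
#' @param predictions `data.frame` from [predictVirus()].
#' @param summary per-scaffold `data.frame` from [annotationSummary()].
#' @param config threshold list from [curationDefaults()].
#' @return `predictions` with added `final_label` and `curation_reason`.
#' @export
curatePredictions <- function(predictions, summary,
                              config = curationDefaults()) {
  m <- match(predictions$scaffold_id, summary$scaffold_id)
  s <- summary[m, , drop = FALSE]
  zeroFrac <- s$zero_v_proteins / s$n_proteins
  final <- predictions$raw_label
  reason <- rep("unchanged", nrow(predictions))
  isVirus <- final == "virus"
  ruleA <- isVirus & s$plasmid_marker_n >= 1 & s$hallmark_n == 0
  final[ruleA] <- "nonvirus"; reason[ruleA] <- "plasmid_integrase_removed"
  ruleB <- final == "virus" & zeroFrac > config$curation_zero_frac &
    s$hallmark_n == 0
  final[ruleB] <- "nonvirus"; reason[ruleB] <- "zero_density_removed"
  ruleC <- final == "nonvirus" & reason == "unchanged" &
    s$hallmark_n >= config$rescue_hallmark_min &
    zeroFrac <= config$rescue_zero_max
  final[ruleC] <- "virus"; reason[ruleC] <- "hallmark_rescued"
  predictions$final_label <- final
  predictions$curation_reason <- reason
  predictions
}
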