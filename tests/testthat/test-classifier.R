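gaussian_clouds <- function(nPerClass, sep = 6, seed = 7) {
  set.seed(seed)
  n <- 2 * nPerClass
  x <- matrix(rnorm(n * 27), n, 27)
  x[seq_len(nPerClass), 1:5] <- x[seq_len(nPerClass), 1:5] + sep
  colnames(x) <- featureNames()
  list(features = data.frame(scaffold_id = sprintf("g%d", seq_len(n)), x,
                             check.names = FALSE),
       labels = rep(c("virus", "nonvirus"), each = nPerClass))
}

test_that("well-separated clouds are learned almost perfectly", {
  d <- gaussian_clouds(500, sep = 6, seed = 7)
  m <- trainClassifier(d$features, d$labels, seed = 7)
  expect_gte(m@holdoutAccuracy, 0.99)
})

test_that("permuted labels give chance-level holdout accuracy", {
  d <- gaussian_clouds(500, sep = 6, seed = 7)
  set.seed(8)
  m <- trainClassifier(d$features, sample(d$labels), seed = 7)
  expect_lt(abs(m@holdoutAccuracy - 0.5), 0.1)
})

test_that("training is deterministic given the seed", {
  d <- gaussian_clouds(100, sep = 4, seed = 9)
  probe <- gaussian_clouds(50, sep = 4, seed = 10)$features
  m1 <- trainClassifier(d$features, d$labels, seed = 123)
  m2 <- trainClassifier(d$features, d$labels, seed = 123)
  expect_identical(predictVirus(m1, probe), predictVirus(m2, probe))
})

test_that("single-class or tiny training sets are rejected", {
  d <- gaussian_clouds(100)
  expect_error(trainClassifier(d$features, rep("virus", 200)), "both classes")
  expect_error(trainClassifier(d$features[1:60, ],
                               rep(c("virus", "nonvirus"), each = 30)),
               "at least 50")
})

test_that("model files round-trip to bit-identical predictions", {
  d <- gaussian_clouds(100, sep = 4, seed = 11)
  m <- trainClassifier(d$features, d$labels, seed = 5)
  path <- withr::local_tempfile(fileext = ".rds")
  saveClassifier(m, path)
  m2 <- loadClassifier(path)
  probe <- gaussian_clouds(50, sep = 4, seed = 12)$features
  expect_identical(predictVirus(m2, probe), predictVirus(m, probe))
  # wrong payload is refused
  saveRDS(list(1), path)
  expect_error(loadClassifier(path), "not a classifier model")
})

prefilter_summary <- function(n, kegg_n, kegg_vsum, hallmark_n,
                              zero_v = kegg_n) {
  data.frame(scaffold_id = "s", n_proteins = n, kegg_n = kegg_n,
             kegg_vsum = kegg_vsum, vog_n = 0, hallmark_n = hallmark_n,
             replication_n = 0, viral_integrase_n = 0, plasmid_marker_n = 0,
             zero_v_proteins = zero_v)
}

test_that("the prefilter removes dense zero-v KEGG scaffolds only", {
  # 16/20 KEGG-annotated, all v = 0, no hallmark -> removed
  expect_false(prefilterScaffolds(prefilter_summary(20, 16, 0, 0))$pass)
  # same but 3 hallmark annotations -> kept
  expect_true(prefilterScaffolds(prefilter_summary(20, 16, 0, 3))$pass)
  # no annotation at all -> the model decides
  expect_true(prefilterScaffolds(prefilter_summary(20, 0, 0, 0, 0))$pass)
  # virome mode skips the prefilter
  expect_true(prefilterScaffolds(prefilter_summary(20, 16, 0, 0),
                                 curationDefaults(virome = TRUE))$pass)
})

curate_one <- function(raw, n, hallmark_n, zero_v, plasmid_n = 0,
                       config = curationDefaults()) {
  pred <- data.frame(scaffold_id = "s", score = 0.5, raw_label = raw,
                     stringsAsFactors = FALSE)
  s <- prefilter_summary(n, 0, 0, hallmark_n, zero_v)
  s$plasmid_marker_n <- plasmid_n
  curatePredictions(pred, s, config)
}

test_that("curation rules flip predictions for the stated reasons", {
  # (a) plasmid markers, no hallmark
  r <- curate_one("virus", 10, 0, 0, plasmid_n = 2)
  expect_equal(r$final_label, "nonvirus")
  expect_equal(r$curation_reason, "plasmid_integrase_removed")
  # (b) zero-v density 8/10, no hallmark
  r <- curate_one("virus", 10, 0, 8)
  expect_equal(r$final_label, "nonvirus")
  expect_equal(r$curation_reason, "zero_density_removed")
  # virome mode loosens (b): 7/10 passes at the 0.8 cutoff
  r <- curate_one("virus", 10, 0, 7, config = curationDefaults(TRUE))
  expect_equal(r$final_label, "virus")
  # (c) hallmark rescue of a raw nonvirus
  r <- curate_one("nonvirus", 4, 2, 0)
  expect_equal(r$final_label, "virus")
  expect_equal(r$curation_reason, "hallmark_rescued")
  # untouched prediction
  r <- curate_one("virus", 10, 3, 1)
  expect_equal(r$final_label, "virus")
  expect_equal(r$curation_reason, "unchanged")
})

test_that("curation never demotes a hallmark-rich, low-zero scaffold", {
  set.seed(40)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    hall <- sample(2:5, 1)
    zero <- sample(0:floor(0.2 * n), 1)
    plas <- sample(0:3, 1)
    r <- curate_one(sample(c("virus", "nonvirus"), 1), n, hall, zero,
                    plasmid_n = plas)
    expect_equal(r$final_label, "virus")
  }
})
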