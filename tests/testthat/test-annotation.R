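test_that("tblout parsing extracts full-sequence e-value and score", {
  path <- withr::local_tempfile(fileext = ".tbl")
  writeLines(c(
    "# comment line",
    paste("p1 - PF00001.1 - 1e-10 55.2 0.1 1e-10 55.2 0.1",
          "1.0 1 1 0 1 1 1 1 some description"),
    paste("p2 - PF00002.1 - 2.5e-07 33.0 0.0 2.5e-07 33.0 0.0",
          "1.0 1 1 0 1 1 1 1 -")), path)
  hits <- parseSearchTable(path, "PFAM")
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$protein_id, c("p1", "p2"))
  expect_equal(hits$profile_id, c("PF00001.1", "PF00002.1"))
  expect_equal(hits$evalue, c(1e-10, 2.5e-07))
  expect_equal(hits$bitscore, c(55.2, 33.0))
  expect_equal(unique(hits$db), "PFAM")
})

test_that("tblout parsing handles empty files and reports bad lines", {
  path <- withr::local_tempfile(fileext = ".tbl")
  writeLines(c("# only", "# comments"), path)
  expect_equal(nrow(parseSearchTable(path, "KEGG")), 0L)
  writeLines(c("# ok", "p1 - K00001 - 1e-10"), path)
  expect_error(parseSearchTable(path, "KEGG"), "line 2")
})

test_that("tblout round trip through the fixture writer", {
  h <- annotationHits(make_annotation(
    protein_id = c("a_1", "a_2"), scaffold_id = "a", db = "VOG",
    profile_id = c("VOG00001", "VOG00002"), evalue = c(1e-12, 1e-20),
    bitscore = c(80, 120)))
  path <- withr::local_tempfile(fileext = ".tbl")
  writeTblout(h, path)
  back <- parseSearchTable(path, "VOG")
  expect_equal(back$protein_id, h$protein_id)
  expect_equal(back$profile_id, h$profile_id)
  expect_equal(back$evalue, h$evalue)
})

test_that("best-hit selection applies the strict threshold and tie-breaks", {
  vt <- test_resource$vtable
  base <- data.frame(protein_id = "p1", db = "KEGG", stringsAsFactors = FALSE)
  # at/above threshold: discarded
  h <- cbind(base, profile_id = "K00001", evalue = 1e-4, bitscore = 50)
  expect_equal(nrow(annotationHits(selectBestHits(h, vt))), 0L)
  h$evalue <- 1e-5
  expect_equal(nrow(annotationHits(selectBestHits(h, vt))), 0L)
  # minimum e-value wins
  h2 <- data.frame(protein_id = "p1", db = "KEGG",
                   profile_id = c("K00002", "K00003"),
                   evalue = c(1e-8, 1e-10), bitscore = c(90, 40))
  expect_equal(annotationHits(selectBestHits(h2, vt))$profile_id, "K00003")
  # e-value tie: higher bitscore
  h3 <- data.frame(protein_id = "p1", db = "KEGG",
                   profile_id = c("K00004", "K00005"),
                   evalue = 1e-9, bitscore = c(40, 60))
  expect_equal(annotationHits(selectBestHits(h3, vt))$profile_id, "K00005")
  # full tie: lexicographically smallest profile
  h4 <- data.frame(protein_id = "p1", db = "KEGG",
                   profile_id = c("K00007", "K00006"),
                   evalue = 1e-9, bitscore = 60)
  expect_equal(annotationHits(selectBestHits(h4, vt))$profile_id, "K00006")
})

test_that("best-hit selection matches a brute-force argmin", {
  set.seed(10)
  vt <- test_resource$vtable
  for (rep in 1:5) {
    hits <- data.frame(
      protein_id = sample(sprintf("s%d_%d", sample(1:3, 40, TRUE),
                                  sample(1:6, 40, TRUE))),
      db = sample(c("KEGG", "PFAM", "VOG"), 40, TRUE),
      profile_id = sprintf("X%05d", sample(1:30, 40, TRUE)),
      evalue = 10^-runif(40, 2, 20),
      bitscore = round(runif(40, 10, 200), 1),
      stringsAsFactors = FALSE)
    got <- annotationHits(selectBestHits(hits, vt))
    # brute force: filter then per-(protein, db) scan
    keep <- hits[hits$evalue < 1e-5, ]
    for (key in unique(paste(keep$protein_id, keep$db))) {
      sub <- keep[paste(keep$protein_id, keep$db) == key, ]
      sub <- sub[order(sub$evalue, -sub$bitscore, sub$profile_id), ]
      row <- got[paste(got$protein_id, got$db) == key, ]
      expect_equal(nrow(row), 1L)
      expect_equal(row$profile_id, sub$profile_id[1])
      expect_equal(row$evalue, sub$evalue[1])
    }
    expect_equal(nrow(got), length(unique(paste(keep$protein_id, keep$db))))
  }
})

test_that("raising the e-value ceiling never loses annotated proteins", {
  set.seed(11)
  vt <- test_resource$vtable
  hits <- data.frame(protein_id = sprintf("s1_%d", sample(1:20, 60, TRUE)),
                     db = "VOG",
                     profile_id = sprintf("VOG%05d", sample(1:50, 60, TRUE)),
                     evalue = 10^-runif(60, 2, 12),
                     bitscore = runif(60, 10, 100), stringsAsFactors = FALSE)
  ns <- vapply(c(1e-8, 1e-6, 1e-5, 1e-4),
               function(e) length(unique(annotationHits(
                 selectBestHits(hits, vt, evalueMax = e))$protein_id)), 0)
  expect_true(all(diff(ns) >= 0))
})

test_that("annotation summary tallies per-scaffold signal", {
  ann <- make_annotation(
    protein_id = c("s_1", "s_2", "s_2", "s_3"),
    scaffold_id = "s", db = c("KEGG", "KEGG", "VOG", "VOG"),
    profile_id = c("K1", "K2", "V1", "V2"),
    v = c(0, 2, 1, 5), hallmark = c(FALSE, FALSE, FALSE, TRUE),
    replication = c(FALSE, FALSE, TRUE, FALSE))
  s <- annotationSummary(ann, make_proteins("s", 5))
  expect_equal(s$n_proteins, 5L)
  expect_equal(s$kegg_n, 2)
  expect_equal(s$kegg_vsum, 2)
  expect_equal(s$vog_n, 2)
  expect_equal(s$hallmark_n, 1)
  expect_equal(s$replication_n, 1)
  expect_equal(s$zero_v_proteins, 1)
})
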