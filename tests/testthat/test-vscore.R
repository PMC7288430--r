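test_that("v-score formula and keyword floors follow the stated rules", {
  counts <- c(A = 0, B = 50, C = 1500, D = 10, E = 0, F = 120)
  names <- c(A = "ABC transporter", B = "oxidoreductase",
             C = "uncharacterized", D = "phage repressor",
             E = "major capsid protein", F = "DNA polymerase")
  vt <- vscoreTable(computeVScores(counts, names, "KEGG"))
  v <- setNames(vt$v, vt$profile_id)
  expect_equal(v[["A"]], 0)        # no hits -> zero
  expect_equal(v[["B"]], 0.5)      # 50 / 100
  expect_equal(v[["C"]], 10)       # capped at 10
  expect_equal(v[["D"]], 1)        # phage floor (v > 0, KEGG)
  expect_equal(v[["E"]], 1)        # hallmark floor, even at zero hits
  expect_true(vt$hallmark[vt$profile_id == "E"])
  expect_true(vt$replication[vt$profile_id == "F"])
  expect_equal(v[["F"]], 1.2)      # replication flag does not floor
})

test_that("the phage floor needs a positive v-score; VOG names skip it", {
  # zero-hit phage name stays 0 in KEGG
  vt <- vscoreTable(computeVScores(c(P = 0), c(P = "phage tail protein x"),
                                   "KEGG"))
  # but "tail" is a hallmark keyword -> floored anyway; use non-hallmark
  vt2 <- vscoreTable(computeVScores(c(P = 0), c(P = "phage repressor"),
                                    "KEGG"))
  expect_equal(vt2$v, 0)
  # VOG gets no phage floor: v stays at count/100
  vt3 <- vscoreTable(computeVScores(c(P = 20), c(P = "phage repressor"),
                                    "VOG"))
  expect_equal(vt3$v, 0.2)
  expect_equal(vt$v, 1)
})

test_that("v-scores equal the brute-force formula on random count tables", {
  set.seed(20)
  kw <- vscoreKeywords()
  pool <- c("ABC transporter", "major capsid protein", "phage integrase x",
            "baseplate wedge", "base plate subunit", "DNA polymerase",
            "terminase small subunit", "hypothetical protein",
            "reovirus core-spike protein", "tail tube protein")
  for (db in c("KEGG", "PFAM", "VOG")) {
    for (rep in 1:10) {
      n <- 50
      ids <- sprintf("%s%04d", db, seq_len(n))
      counts <- setNames(sample(0:2000, n, TRUE), ids)
      nm <- setNames(sample(pool, n, TRUE), ids)
      got <- vscoreTable(computeVScores(counts, nm, db))
      # independent brute-force re-derivation
      expected <- pmin(counts / 100, 10)
      for (i in seq_len(n)) {
        name <- nm[[i]]
        excluded <- any(vapply(kw$exclude, function(k)
          grepl(k, name, ignore.case = TRUE), TRUE))
        hall <- !excluded && any(vapply(kw$hallmark, function(k)
          grepl(k, name, ignore.case = TRUE), TRUE))
        phage <- !excluded && grepl("phage", name, ignore.case = TRUE)
        v <- expected[[i]]
        if (db %in% c("KEGG", "PFAM") && phage && v > 0) v <- max(v, 1)
        if (hall) v <- max(v, 1)
        expect_identical(got$v[i], unname(v))
        expect_identical(got$hallmark[i], hall)
      }
    }
  }
})

test_that("hallmark matching is case-insensitive and accepts both baseplate spellings", {
  vt <- vscoreTable(computeVScores(
    c(a = 0, b = 0, c = 0),
    c(a = "BasePlate protein", b = "base plate hub", c = "CAPSID protein"),
    "VOG"))
  expect_true(all(vt$hallmark))
  expect_true(all(vt$v >= 1))
})

test_that("excluded non-prokaryotic names get no keyword floor", {
  vt <- vscoreTable(computeVScores(c(x = 0), c(x = "reovirus core-spike protein"),
                                   "VOG"))
  expect_equal(vt$v, 0)
  expect_false(vt$hallmark)
})

test_that("negative counts are rejected and zero profiles give an empty table", {
  expect_error(computeVScores(c(a = -1), c(a = "x"), "KEGG"), "negative")
  empty <- computeVScores(setNames(numeric(0), character(0)),
                          setNames(character(0), character(0)), "KEGG")
  expect_s4_class(empty, "VScoreTable")
  expect_equal(nrow(vscoreTable(empty)), 0L)
})

test_that("v-score tables round-trip through TSV and reject duplicates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeVScoreTable(test_resource$vtable, path)
  back <- loadVScoreTable(path)
  expect_equal(vscoreTable(back), vscoreTable(test_resource$vtable))
  tab <- vscoreTable(test_resource$vtable)
  utils::write.table(rbind(tab, tab[1, ]), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(loadVScoreTable(path), "duplicate")
})

test_that("unknown profile lookups return 0 and are counted", {
  vt <- computeVScores(c(VOG1 = 1000), c(VOG1 = "terminase large subunit"),
                       "VOG")
  expect_equal(lookupVScore(vt, "VOG1")$v, 10)
  expect_equal(vscoreMisses(vt), 0L)
  res <- lookupVScore(vt, c("absent1", "VOG1", "absent2"))
  expect_equal(res$v, c(0, 10, 0))
  expect_equal(vscoreMisses(vt), 2L)
})
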