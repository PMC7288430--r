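test_that("scaffold FASTA reading canonicalizes sequences", {
  set.seed(1)
  path <- withr::local_tempfile(fileext = ".fna")
  seqs <- c(s1 = random_dna(1500), s2 = tolower(random_dna(1200)))
  write_fasta(seqs, path)
  sc <- readScaffolds(path)
  expect_s4_class(sc, "ScaffoldSet")
  expect_equal(scaffoldIds(sc), c("s1", "s2"))
  expect_equal(scaffoldInfo(sc)$length, c(1500L, 1200L))
  expect_identical(as.character(scaffoldSeqs(sc))[["s2"]],
                   toupper(seqs[["s2"]]))

  # RNA-style input: U becomes T
  write_fasta(c(r1 = paste0("ACGU", random_dna(1000))), path)
  expect_identical(
    substr(as.character(scaffoldSeqs(readScaffolds(path)))[[1]], 1, 4),
    "ACGT")

  # id taken up to first whitespace
  writeLines(c(">s3 description here", "ACGTACGTACGT"), path)
  expect_equal(scaffoldIds(readScaffolds(path)), "s3")
})

test_that("scaffold reading rejects empty and non-nucleotide input", {
  path <- withr::local_tempfile(fileext = ".fna")
  writeLines(character(0), path)
  expect_error(readScaffolds(path), "no sequences")
  writeLines(c(">bad", "ACGTXZACGT"), path)
  expect_error(readScaffolds(path), "bad")
})

test_that("read-write round trip preserves ids and sequences", {
  set.seed(2)
  p1 <- withr::local_tempfile(fileext = ".fna")
  p2 <- withr::local_tempfile(fileext = ".fna")
  seqs <- setNames(vapply(1:5, function(i) random_dna(2000), ""),
                   paste0("scaf", 1:5))
  write_fasta(seqs, p1)
  sc <- readScaffolds(p1)
  writeScaffolds(sc, p2)
  sc2 <- readScaffolds(p2)
  expect_identical(as.character(scaffoldSeqs(sc2)),
                   as.character(scaffoldSeqs(sc)))
  expect_identical(scaffoldIds(sc2), scaffoldIds(sc))
})

test_that("protein headers parse to 0-based half-open records", {
  path <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">s1_1 # 3 # 1001 # 1 # ID=1_1;partial=00", "MKT",
               ">s1_2 # 1100 # 2200 # -1 # ID=1_2", "MVA",
               ">other_7_1 # 10 # 400 # 1 # x", "MM"), path)
  p <- parseProteinHeaders(path)
  expect_equal(p$scaffold_id, c("s1", "s1", "other_7"))
  expect_equal(p$index, c(0L, 1L, 0L))
  # 1-based inclusive (3, 1001) -> 0-based half-open [2, 1001)
  expect_equal(p$start[1], 2L)
  expect_equal(p$stop[1], 1001L)
  expect_equal(p$strand, c("+", "-", "+"))
  expect_equal(p$aa_seq[1], "MKT")
})

test_that("malformed protein headers are rejected by record", {
  path <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">s1_1 # 3 # 1001 # 1 #", "MKT", ">s1_2", "MVA"), path)
  expect_error(parseProteinHeaders(path), "s1_2")
})

test_that("candidate filter enforces length and ORF minima", {
  set.seed(3)
  seqs <- c(short = random_dna(900), feworf = random_dna(5000),
            boundary = random_dna(1000), good = random_dna(6000))
  sc <- ScaffoldSet(seqs)
  prot <- rbind(make_proteins("short", 5)[, ],
                make_proteins("feworf", 3),
                within(make_proteins("boundary", 4),
                       { start <- start %/% 10; stop <- start + 50L }),
                make_proteins("good", 6))
  flt <- filterCandidates(sc, prot)
  expect_setequal(scaffoldIds(flt$kept), c("boundary", "good"))
  expect_equal(flt$excluded$reason[flt$excluded$id == "short"], "too_short")
  expect_equal(flt$excluded$reason[flt$excluded$id == "feworf"],
               "too_few_orfs")
  # conservation and idempotence
  expect_equal(length(flt$kept) + nrow(flt$excluded), length(sc))
  again <- filterCandidates(flt$kept,
                            prot[prot$scaffold_id %in%
                                   scaffoldIds(flt$kept), ])
  expect_identical(scaffoldIds(again$kept), scaffoldIds(flt$kept))
  expect_equal(nrow(again$excluded), 0L)
  # unknown scaffold reference is an error
  badprot <- make_proteins("ghost", 4)
  expect_error(filterCandidates(sc, badprot), "ghost")
})

test_that("GenBank output has one locus per scaffold with CDS features", {
  set.seed(4)
  sc <- ScaffoldSet(c(v1 = random_dna(2000)))
  prot <- make_proteins("v1", 2)
  prot$stop <- pmin(prot$stop, 2000L)
  path <- withr::local_tempfile(fileext = ".gbk")
  writeGenBank(sc, prot, path)
  lines <- readLines(path)
  expect_length(grep("^LOCUS", lines), 1L)
  expect_length(grep("^     CDS", lines), 2L)
  expect_true(any(grepl("complement\\(", lines)))
  expect_identical(lines[length(lines)], "//")
})
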