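# independent oracle: quadratic scan for runs of >= window host-like genes
brute_spans <- function(keggV, hallmark, window = 4, vCut = 1) {
  hostLike <- !is.na(keggV) & keggV < vCut & !hallmark
  spans <- list()
  i <- 1
  while (i <= length(hostLike)) {
    if (hostLike[i]) {
      j <- i
      while (j < length(hostLike) && hostLike[j + 1]) j <- j + 1
      if (j - i + 1 >= window)
        spans[[length(spans) + 1]] <- c(i - 1, j - 1)  # 0-based indices
      i <- j + 1
    } else i <- i + 1
  }
  if (length(spans)) do.call(rbind, spans) else
    matrix(numeric(0), ncol = 2)
}

pv <- function(keggV, hallmark = rep(FALSE, length(keggV))) {
  data.frame(index = seq_along(keggV) - 1L, kegg_v = keggV,
             hallmark = hallmark)
}

test_that("host-span scanning finds low-v runs and nothing else", {
  # all hallmark: nothing below cutoff
  s <- scanCutSites(pv(rep(1, 10), rep(TRUE, 10)))
  expect_equal(nrow(s), 0L)
  # proteins 0-7 at v 0, 8-19 hallmark -> single span 0-7
  s <- scanCutSites(pv(c(rep(0, 8), rep(1, 12)),
                       c(rep(FALSE, 8), rep(TRUE, 12))))
  expect_equal(nrow(s), 1L)
  expect_equal(c(s$first, s$last), c(0L, 7L))
  # alternating 0 / 5: no 4-run
  s <- scanCutSites(pv(rep(c(0, 5), 6)))
  expect_equal(nrow(s), 0L)
  # unannotated proteins (NA) break runs
  s <- scanCutSites(pv(c(0, 0, NA, 0, 0, 0, 0, 5)))
  expect_equal(c(s$first, s$last), c(3L, 6L))
  # a hallmark annotation vetoes membership even at low KEGG v
  s <- scanCutSites(pv(rep(0, 8), c(rep(FALSE, 4), TRUE, rep(FALSE, 3))))
  expect_equal(c(s$first, s$last), c(0L, 3L))
})

test_that("host-span scanning matches the brute-force run scan", {
  set.seed(50)
  for (rep in 1:100) {
    n <- sample(4:40, 1)
    keggV <- ifelse(runif(n) < 0.3, NA,
                    sample(c(0, 0, 0.5, 1, 5), n, TRUE))
    hall <- runif(n) < 0.15
    got <- scanCutSites(pv(keggV, hall))
    want <- brute_spans(keggV, hall)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$first, want[, 1])
      expect_equal(got$last, want[, 2])
    }
  }
})

test_that("trimming advances to the first virus-like annotation", {
  viral <- setNames(rep(FALSE, 20), 0:19)
  viral[c("10", "15", "19")] <- TRUE
  # span 8-19 with 8-9 unannotated, 10 viral -> trimmed to 10-19
  expect_equal(trimToViral(8:19, viral), 10:19)
  # span already starting viral: unchanged
  expect_equal(trimToViral(10:19, viral), 10:19)
  # no virus-like annotation: discarded
  expect_null(trimToViral(0:7, viral))
  # end retracts too
  expect_equal(trimToViral(8:17, viral), 10:15)
})

test_that("chimera excision recovers the planted provirus", {
  ch <- makeChimera(test_resource, seed = 60, id = "chim")
  e <- exciseProvirus(ch$seq, "chim", ch$proteins, ch$annotations)
  expect_true(e$has_host_span)
  expect_equal(nrow(e$regions), 1L)
  expect_lte(abs(e$regions$first_protein - ch$boundaries$gene_index), 1L)
  # excised sequence equals the parent substring exactly
  expect_identical(
    substr(ch$seq, e$regions$nt_start + 1, e$regions$nt_stop),
    e$regions$seq)
  # coordinates sit on the boundary genes
  p <- ch$proteins
  expect_equal(e$regions$nt_start,
               p$start[p$index == e$regions$first_protein])
  expect_equal(e$regions$nt_stop,
               p$stop[p$index == e$regions$last_protein])
})

test_that("uniformly viral scaffolds are returned intact", {
  s <- makeLabeledScaffolds(test_resource, 1, seed = 61, classes = "virus")
  id <- scaffoldIds(s$scaffolds)[1]
  e <- exciseProvirus(as.character(scaffoldSeqs(s$scaffolds))[1], id,
                      s$proteins, s$annotations)
  expect_false(e$has_host_span)
  expect_equal(nrow(e$regions), 0L)
})

test_that("a host-virus-host sandwich yields only the middle block", {
  ch <- makeChimera(test_resource, layout = c("host", "virus", "host"),
                    seed = 62, id = "sw")
  e <- exciseProvirus(ch$seq, "sw", ch$proteins, ch$annotations)
  expect_equal(nrow(e$regions), 1L)
  expect_lte(abs(e$regions$first_protein - ch$boundaries$gene_index), 1L)
  expect_lte(abs(e$regions$last_protein - ch$boundaries$gene_end), 1L)
})

test_that("excision across a set rehomes fragments and annotations", {
  ch <- makeChimera(test_resource, seed = 63, id = "chimA")
  sc <- ScaffoldSet(setNames(ch$seq, "chimA"))
  e <- exciseAll(sc, ch$proteins, ch$annotations)
  info <- scaffoldInfo(e$scaffolds)
  expect_equal(info$origin, "excised")
  expect_equal(info$parent_id, "chimA")
  expect_true(validObject(e$scaffolds))
  # fragment protein coordinates are shifted onto the fragment
  expect_equal(min(e$proteins$start), 0L + ch$proteins$start[
    ch$proteins$index == e$regions$first_protein] - e$regions$nt_start)
  ann <- remapAnnotations(ch$annotations, e$proteins)
  expect_true(all(annotationHits(ann)$scaffold_id == info$id))
  # fragment sequence matches parent coordinates
  expect_identical(
    as.character(scaffoldSeqs(e$scaffolds))[[1]],
    substr(ch$seq, info$parent_start + 1, info$parent_stop))
})
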