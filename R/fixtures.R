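#' Generate a mock profile collection with v-scores
#'
#' Builds synthetic KEGG/Pfam/VOG profile lists whose names and viral hit
#' counts emulate real collections: most KEGG/Pfam profiles are host
#' housekeeping functions with no viral hits (v-score 0), a configurable
#' fraction of VOG profiles carry hallmark keywords, replication and
#' integrase/plasmid-marker names are present, and v-scores are produced by
#' running [computeVScores()] on the drawn counts so all keyword floors
#' hold by construction. Also emits a matching synthetic KO-to-pathway-map
#' resource for the AMG module.
#'
#' @param nKegg,nPfam,nVog profiles per database.
#' @param hallmarkFraction fraction of VOG profiles given hallmark names
#'   (default 0.1).
#' @param seed RNG seed; identical seeds give identical resources.
#' @return list with `vtable` (a [VScoreTable]), `groups` (named list of
#'   profile-id pools used by the scaffold generator), and `pathway_map`
#'   (`data.frame` resource for [identifyAmgs()]).
#' @export
makeProfileResource <- function(nKegg = 240L, nPfam = 240L, nVog = 320L,
                                hallmarkFraction = 0.1, seed = 1L) {
  set.seed(seed)
  hostNames <- c("ABC transporter ATP-binding protein",
                 "30S ribosomal protein S%d", "cell division protein FtsZ",
                 "two-component sensor histidine kinase",
                 "peptidoglycan glycosyltransferase",
                 "NADH-quinone oxidoreductase subunit %d",
                 "elongation factor Tu", "chaperonin GroEL",
                 "citrate synthase", "succinate dehydrogenase subunit %d")
  hallmarkNames <- c("portal protein", "terminase large subunit",
                     "major capsid protein", "tail fiber protein",
                     "baseplate assembly protein", "holin",
                     "N-acetylmuramoyl-L-alanine amidase lysin",
                     "head-tail connector protein",
                     "virion structural protein", "coat protein",
                     "tail sheath protein", "spike protein", "lysozyme")
  replNames <- c("DNA polymerase", "replicative DNA helicase",
                 "DNA primase", "exonuclease", "DNA ligase",
                 "DNA topoisomerase", "ribonucleotide reductase subunit",
                 "single-strand DNA binding protein")
  plasmidNames <- c("conjugal transfer protein TraG",
                    "mobilization protein MobA", "relaxase",
                    "plasmid partitioning protein ParA")
  amgNames <- c("GTP cyclohydrolase I folE",
                "6-pyruvoyltetrahydropterin synthase queD",
                "7-carboxy-7-deazaguanine synthase queE",
                "7-cyano-7-deazaguanine synthase queC",
                "phosphoadenosine phosphosulfate reductase cysH",
                "DNA (cytosine-5)-methyltransferase dcm",
                "2-polyprenyl-6-methoxyphenol hydroxylase ubiG",
                "demethylmenaquinone methyltransferase ubiE")
  fill <- function(pool, n) {
    nm <- sample(pool, n, replace = TRUE)
    vapply(nm, function(x)
      if (grepl("%d", x, fixed = TRUE)) sprintf(x, sample(1:20, 1)) else x,
      "", USE.NAMES = FALSE)
  }

  # --- KEGG: housekeeping majority, a viral-associated minority, AMG KOs
  keggIds <- sprintf("K%05d", seq_len(nKegg))
  nAmg <- length(amgNames)
  nKeggViral <- max(10L, round(0.15 * nKegg))
  nKeggPhage <- 6L
  keggNames <- c(amgNames,
                 rep("phage repressor protein", nKeggPhage),
                 fill(replNames, nKeggViral),
                 fill(hostNames, nKegg - nAmg - nKeggPhage - nKeggViral))
  keggCounts <- c(sample(30:400, nAmg, replace = TRUE),
                  sample(10:80, nKeggPhage, replace = TRUE),
                  sample(50:1500, nKeggViral, replace = TRUE),
                  integer(nKegg - nAmg - nKeggPhage - nKeggViral))
  keggTab <- computeVScores(stats::setNames(keggCounts, keggIds),
                            stats::setNames(keggNames, keggIds), "KEGG")

  # --- Pfam: similar split plus plasmid markers
  pfamIds <- sprintf("PF%05d.1", seq_len(nPfam))
  nPlas <- 8L
  nPfamViral <- max(10L, round(0.15 * nPfam))
  pfamNames <- c(fill(plasmidNames, nPlas),
                 fill(replNames, nPfamViral),
                 fill(hostNames, nPfam - nPlas - nPfamViral))
  pfamCounts <- c(integer(nPlas),
                  sample(50:1500, nPfamViral, replace = TRUE),
                  integer(nPfam - nPlas - nPfamViral))
  pfamTab <- computeVScores(stats::setNames(pfamCounts, pfamIds),
                            stats::setNames(pfamNames, pfamIds), "PFAM")

  # --- VOG: hallmark fraction, replication, integrase, generic viral
  vogIds <- sprintf("VOG%05d", seq_len(nVog))
  nHall <- round(hallmarkFraction * nVog)
  nRepl <- round(0.12 * nVog)
  nInt <- 4L
  vogNames <- c(fill(hallmarkNames, nHall), fill(replNames, nRepl),
                rep("integrase", nInt),
                sprintf("uncharacterized viral protein %d",
                        seq_len(nVog - nHall - nRepl - nInt)))
  vogCounts <- sample(100:1500, nVog, replace = TRUE)
  vogTab <- computeVScores(stats::setNames(vogCounts, vogIds),
                           stats::setNames(vogNames, vogIds), "VOG")

  tab <- rbind(vscoreTable(keggTab), vscoreTable(pfamTab),
               vscoreTable(vogTab))
  rownames(tab) <- NULL
  vtable <- newVScoreTable(tab)

  amgKos <- keggIds[seq_len(nAmg)]
  ineligible <- keggIds[nAmg + seq_len(nKeggPhage)]
  pathwayMap <- rbind(
    data.frame(ko_id = amgKos,
               map_id = sprintf("map%05d", 700 + seq_along(amgKos)),
               map_name = c(rep("Folate biosynthesis", 4),
                            "Sulfur relay system", "Cysteine metabolism",
                            "Ubiquinone biosynthesis",
                            "Ubiquinone biosynthesis"),
               category = c(rep("Metabolic pathways", 4),
                            "Sulfur relay system",
                            rep("Metabolic pathways", 3)),
               stringsAsFactors = FALSE),
    data.frame(ko_id = ineligible,
               map_id = sprintf("map%05d", 3000 + seq_along(ineligible)),
               map_name = "Transcription machinery",
               category = "Genetic information processing",
               stringsAsFactors = FALSE))

  groups <- list(
    kegg_zero = keggIds[tab$v[match(keggIds, tab$profile_id)] == 0],
    kegg_viral = keggIds[tab$v[match(keggIds, tab$profile_id)] >= 1],
    kegg_amg = amgKos,
    pfam_zero = pfamIds[tab$v[match(pfamIds, tab$profile_id)] == 0 &
                        tab$integrase_class[match(pfamIds,
                                                  tab$profile_id)] == "none"],
    pfam_viral = pfamIds[tab$v[match(pfamIds, tab$profile_id)] >= 1],
    plasmid_marker = pfamIds[tab$integrase_class[
      match(pfamIds, tab$profile_id)] == "plasmid_like"],
    vog_hallmark = vogIds[tab$hallmark[match(vogIds, tab$profile_id)]],
    vog_replication = vogIds[tab$replication[match(vogIds,
                                                   tab$profile_id)] &
                             !tab$hallmark[match(vogIds, tab$profile_id)]],
    vog_generic = vogIds[!tab$hallmark[match(vogIds, tab$profile_id)] &
                         !tab$replication[match(vogIds, tab$profile_id)] &
                         tab$integrase_class[match(vogIds,
                                                   tab$profile_id)] == "none"],
    vog_integrase = vogIds[tab$integrase_class[
      match(vogIds, tab$profile_id)] == "viral_like"])
  list(vtable = vtable, groups = groups, pathway_map = pathwayMap)
}

#' Per-class annotation-signature rates used by the scaffold generator
#'
#' Virus-class scaffolds have high VOG/hallmark annotation rates and few,
#' mostly virus-associated KEGG hits; host-class scaffolds have dense
#' zero-v-score KEGG/Pfam annotation; plasmid-class scaffolds carry
#' plasmid mobility markers over a host-like background.
#'
#' @return nested list of per-class rates.
#' @export
classSignatures <- function() {
  list(
    virus = list(vog = 0.85, vog_hallmark = 0.25, vog_replication = 0.15,
                 kegg = 0.20, kegg_amg = 0.20, pfam = 0.30),
    host = list(vog = 0.03, kegg = 0.90, pfam = 0.60),
    plasmid = list(vog = 0.02, kegg = 0.50, plasmid_marker = 0.30,
                   pfam = 0.40))
}

randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

geneLayout <- function(scaffoldId, len, nGenes = NULL, gap = 30L) {
  if (is.null(nGenes)) nGenes <- max(4L, as.integer(len %/% 1000L))
  geneLen <- (len - (nGenes + 1L) * gap) %/% nGenes
  geneLen <- (geneLen %/% 3L) * 3L
  starts <- gap + (seq_len(nGenes) - 1L) * (geneLen + gap)
  data.frame(id = sprintf("%s_%d", scaffoldId, seq_len(nGenes)),
             scaffold_id = scaffoldId, index = seq_len(nGenes) - 1L,
             start = starts, stop = starts + geneLen,
             strand = rep_len(c("+", "-"), nGenes), aa_seq = "",
             stringsAsFactors = FALSE)
}

makeHits <- function(proteinIds, scaffoldIds, profileIds, db, vtable) {
  if (length(proteinIds) == 0L) return(NULL)
  res <- lookupVScore(vtable, profileIds)
  data.frame(protein_id = proteinIds, scaffold_id = scaffoldIds, db = db,
             profile_id = profileIds, name = res$name,
             evalue = 10^-stats::runif(length(proteinIds), 6, 30),
             bitscore = round(stats::runif(length(proteinIds), 30, 300), 1),
             v = res$v, hallmark = res$hallmark,
             replication = res$replication,
             integrase_class = res$integrase_class, stringsAsFactors = FALSE)
}

poolSample <- function(pool, n) {
  if (n == 0L) character(0) else sample(pool, n, replace = TRUE)
}

annotateBlock <- function(proteins, class, resource, sig = classSignatures()) {
  g <- resource$groups
  vtable <- resource$vtable
  s <- sig[[class]]
  n <- nrow(proteins)
  out <- list()
  if (class == "virus") {
    vogMask <- stats::runif(n) < s$vog
    u <- stats::runif(n)
    vogProfile <- character(n)
    hall <- vogMask & u < s$vog_hallmark
    repl <- vogMask & !hall & u < s$vog_hallmark + s$vog_replication
    gen <- vogMask & !hall & !repl
    vogProfile[hall] <- poolSample(g$vog_hallmark, sum(hall))
    vogProfile[repl] <- poolSample(g$vog_replication, sum(repl))
    vogProfile[gen] <- poolSample(g$vog_generic, sum(gen))
    out$vog <- makeHits(proteins$id[vogMask], proteins$scaffold_id[vogMask],
                        vogProfile[vogMask], "VOG", vtable)
    keggMask <- stats::runif(n) < s$kegg
    amg <- keggMask & stats::runif(n) < s$kegg_amg
    keggProfile <- character(n)
    keggProfile[amg] <- poolSample(g$kegg_amg, sum(amg))
    keggProfile[keggMask & !amg] <- poolSample(g$kegg_viral,
                                               sum(keggMask & !amg))
    out$kegg <- makeHits(proteins$id[keggMask],
                         proteins$scaffold_id[keggMask],
                         keggProfile[keggMask], "KEGG", vtable)
    pfamMask <- stats::runif(n) < s$pfam
    out$pfam <- makeHits(proteins$id[pfamMask],
                         proteins$scaffold_id[pfamMask],
                         poolSample(g$pfam_viral, sum(pfamMask)),
                         "PFAM", vtable)
  } else {
    keggMask <- stats::runif(n) < s$kegg
    out$kegg <- makeHits(proteins$id[keggMask],
                         proteins$scaffold_id[keggMask],
                         poolSample(g$kegg_zero, sum(keggMask)),
                         "KEGG", vtable)
    if (class == "plasmid") {
      marker <- stats::runif(n) < s$plasmid_marker
      pfamMask <- !marker & stats::runif(n) < s$pfam
      pfamProfile <- character(n)
      pfamProfile[marker] <- poolSample(g$plasmid_marker, sum(marker))
      pfamProfile[pfamMask] <- poolSample(g$pfam_zero, sum(pfamMask))
      sel <- marker | pfamMask
      out$pfam <- makeHits(proteins$id[sel], proteins$scaffold_id[sel],
                           pfamProfile[sel], "PFAM", vtable)
    } else {
      pfamMask <- stats::runif(n) < s$pfam
      out$pfam <- makeHits(proteins$id[pfamMask],
                           proteins$scaffold_id[pfamMask],
                           poolSample(g$pfam_zero, sum(pfamMask)),
                           "PFAM", vtable)
    }
    vogMask <- stats::runif(n) < s$vog
    out$vog <- makeHits(proteins$id[vogMask], proteins$scaffold_id[vogMask],
                        poolSample(g$vog_generic, sum(vogMask)),
                        "VOG", vtable)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out)) do.call(rbind, out) else NULL
}

emptyHits <- function() {
  data.frame(protein_id = character(0), scaffold_id = character(0),
             db = character(0), profile_id = character(0),
             name = character(0), evalue = numeric(0),
             bitscore = numeric(0), v = numeric(0), hallmark = logical(0),
             replication = logical(0), integrase_class = character(0),
             stringsAsFactors = FALSE)
}

#' Generate labeled scaffolds with class-conditional annotation signatures
#'
#' Emulates 3-15 kb metagenome-assembled scaffolds: random nucleotide
#' sequences with regularly spaced genes on alternating strands, annotated
#' according to the per-class signatures of [classSignatures()]. The
#' classifier never reads the nucleotides, so no codon realism is
#' attempted; sequences exist to exercise IO, excision arithmetic and
#' circularity.
#'
#' @param resource profile resource from [makeProfileResource()].
#' @param nPerClass scaffolds per class.
#' @param seed RNG seed; identical seeds give identical output.
#' @param classes subset of `c("virus", "host", "plasmid")`.
#' @param lenRange scaffold length range in bp (default 3000-15000).
#' @return list with `scaffolds` ([ScaffoldSet]), `proteins`
#'   (`data.frame`), `annotations` ([AnnotationTable]) and `labels`
#'   (named `"virus"`/`"nonvirus"` vector keyed by scaffold id).
#' @export
makeLabeledScaffolds <- function(resource, nPerClass, seed = 1L,
                                 classes = c("virus", "host", "plasmid"),
                                 lenRange = c(3000L, 15000L)) {
  set.seed(seed)
  seqs <- character(0)
  prot <- list()
  hits <- list()
  labels <- character(0)
  for (class in classes) {
    for (i in seq_len(nPerClass)) {
      id <- sprintf("%s_%d", class, i)
      len <- sample(lenRange[1]:lenRange[2], 1)
      seqs[id] <- randomDna(len)
      p <- geneLayout(id, len)
      prot[[id]] <- p
      h <- annotateBlock(p, class, resource)
      if (!is.null(h)) hits[[id]] <- h
      labels[id] <- if (class == "virus") "virus" else "nonvirus"
    }
  }
  proteins <- do.call(rbind, prot)
  rownames(proteins) <- NULL
  allHits <- if (length(hits)) do.call(rbind, hits) else emptyHits()
  rownames(allHits) <- NULL
  list(scaffolds = ScaffoldSet(seqs), proteins = proteins,
       annotations = new("AnnotationTable", hits = allHits,
                         evalueMax = 1e-5),
       labels = labels)
}

#' Generate a host-virus chimera with a known integration boundary
#'
#' Concatenates host-class and virus-class gene blocks on one scaffold and
#' records the planted boundaries (gene index and nucleotide position of
#' the first gene of every virus block), the ground truth for the provirus
#' excision harness.
#'
#' @param resource profile resource from [makeProfileResource()].
#' @param layout character vector of blocks in order, e.g.
#'   `c("host", "virus")` or `c("host", "virus", "host")`; must contain
#'   both classes.
#' @param blockGenes genes per block, recycled along `layout` (defaults:
#'   14 for host blocks, 15 for virus blocks).
#' @param seed RNG seed.
#' @param id scaffold id.
#' @return list with `seq`, `proteins`, `annotations`, and `boundaries`
#'   (`data.frame`: `block`, `gene_index`, `nt_start` of each virus
#'   block's first gene, plus `gene_end`, `nt_stop` of its last gene).
#' @export
makeChimera <- function(resource, layout = c("host", "virus"),
                        blockGenes = NULL, seed = 1L, id = "chimera") {
  if (!all(c("host", "virus") %in% layout))
    stop("a chimera needs both host and virus blocks")
  set.seed(seed)
  if (is.null(blockGenes))
    blockGenes <- ifelse(layout == "host", 14L, 15L)
  blockGenes <- rep_len(blockGenes, length(layout))
  if (any(blockGenes < 4L)) stop("blocks need at least 4 genes")
  nGenes <- sum(blockGenes)
  gap <- 30L
  geneLen <- 900L
  len <- (nGenes + 1L) * gap + nGenes * geneLen
  seq <- randomDna(len)
  p <- geneLayout(id, len, nGenes = nGenes, gap = gap)
  blockOf <- rep(seq_along(layout), blockGenes)
  hits <- list()
  bounds <- list()
  for (b in seq_along(layout)) {
    rows <- p[blockOf == b, , drop = FALSE]
    h <- annotateBlock(rows, layout[b], resource)
    if (!is.null(h)) hits[[b]] <- h
    if (layout[b] == "virus")
      bounds[[b]] <- data.frame(
        block = b, gene_index = rows$index[1L], nt_start = rows$start[1L],
        gene_end = rows$index[nrow(rows)], nt_stop = rows$stop[nrow(rows)])
  }
  allHits <- if (length(hits)) do.call(rbind, hits) else emptyHits()
  rownames(allHits) <- NULL
  list(seq = seq, proteins = p,
       annotations = new("AnnotationTable", hits = allHits,
                         evalueMax = 1e-5),
       boundaries = do.call(rbind, bounds))
}

#' Generate one complete-phage fixture genome for the quality harness
#'
#' Every gene is VOG-annotated with probability `vogRate`; hallmark and
#' replication annotations are placed at fixed relative positions past the
#' first 15% of the gene order (emulating structural/replication modules
#' sitting away from the genome start), so the stepwise truncation
#' trajectory degrades through the tiers. Optionally plants a terminal
#' 20-mer repeat so the full-length genome is a circular template.
#'
#' @param resource profile resource from [makeProfileResource()].
#' @param nGenes number of genes (default 40).
#' @param vogRate VOG annotation rate for non-module genes (default 0.85).
#' @param circular plant a terminal repeat (default FALSE).
#' @param seed RNG seed.
#' @param id genome id.
#' @return list with `seq`, `proteins`, `annotations`.
#' @export
makeCompletePhage <- function(resource, nGenes = 40L, vogRate = 0.85,
                              circular = FALSE, seed = 1L, id = "phage") {
  set.seed(seed)
  gap <- 30L
  geneLen <- 900L
  len <- (nGenes + 1L) * gap + nGenes * geneLen
  seq <- randomDna(len)
  if (circular)
    seq <- paste0(seq, substr(seq, 1L, 20L))
  p <- geneLayout(id, nchar(seq), nGenes = nGenes, gap = gap)
  g <- resource$groups
  hallAt <- unique(pmax(ceiling(nGenes * c(0.2, 0.4, 0.6, 0.8)), 7L))
  replAt <- setdiff(unique(pmax(ceiling(nGenes * c(0.3, 0.55, 0.75)), 8L)),
                    hallAt)
  profile <- character(nGenes)
  profile[hallAt] <- poolSample(g$vog_hallmark, length(hallAt))
  profile[replAt] <- poolSample(g$vog_replication, length(replAt))
  rest <- setdiff(seq_len(nGenes), c(hallAt, replAt))
  genOn <- rest[stats::runif(length(rest)) < vogRate]
  profile[genOn] <- poolSample(g$vog_generic, length(genOn))
  sel <- nzchar(profile)
  allHits <- makeHits(p$id[sel], rep(id, sum(sel)), profile[sel], "VOG",
                      resource$vtable)
  if (is.null(allHits)) allHits <- emptyHits()
  rownames(allHits) <- NULL
  list(seq = seq, proteins = p,
       annotations = new("AnnotationTable", hits = allHits,
                         evalueMax = 1e-5))
}

#' Write hits as a HMMER3-style per-target table
#'
#' Produces the `--tblout` dialect (18 stat columns plus description) so
#' the parser can be exercised round-trip on fixture data.
#'
#' @param hits `data.frame` with `protein_id`, `profile_id`, `evalue`,
#'   `bitscore` (e.g. rows of [annotationHits()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTblout <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#                 --- full sequence ---- (synthetic)",
               "# target name  accession  query name  accession  E-value  score  bias ..."),
             con)
  for (i in seq_len(nrow(hits))) {
    writeLines(paste(hits$protein_id[i], "-", hits$profile_id[i], "-",
                     format(hits$evalue[i], scientific = TRUE),
                     hits$bitscore[i], "0.1",
                     format(hits$evalue[i], scientific = TRUE),
                     hits$bitscore[i], "0.1",
                     "1.0", "1", "1", "0", "1", "1", "1", "1",
                     "synthetic fixture hit"), con)
  }
  invisible(path)
}
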