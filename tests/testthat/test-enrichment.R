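test_that("GMT parsing dedups members and rejects malformed lines", {
  p <- tempfile(fileext = ".gmt")
  writeLines(c("SETA\tdesc\tG1\tG2\tG2", "SETB\tdesc\tG3"), p)
  gmt <- readGmt(p)
  expect_equal(names(gmt), c("SETA", "SETB"))
  expect_equal(gmt$SETA$members, c("G1", "G2"))

  writeLines("SETA\tdesc", p)
  expect_error(readGmt(p), "line 1")
  writeLines(c("SETA\td\tG1", "SETA\td\tG2"), p)
  expect_error(readGmt(p), "duplicate")
  file.create(p)
  expect_length(readGmt(p), 0)
})

test_that("GMT write -> read round-trips membership exactly", {
  gmt <- list(
    A = list(name = "A", description = "d1", members = c("G1", "G2")),
    B = list(name = "B", description = "d2", members = c("G3", "G4", "G5")))
  p1 <- tempfile(); p2 <- tempfile()
  writeGmt(gmt, p1)
  back <- readGmt(p1)
  expect_equal(back, gmt)
  writeGmt(back, p2)
  expect_identical(fileBytes(p1), fileBytes(p2))
})

test_that("gene sets project onto transcripts of the requested stratum", {
  dict <- tinyDict()  # TXA1 protein_coding, TXA2 retained_intron, TXB1 lncRNA
  gmt <- list(S1 = list(name = "S1", description = "d",
                        members = c("AlphA", "BetA", "NOSUCH")))
  pc <- suppressMessages(expandGeneSets(gmt, dict, "protein_coding", 1))
  expect_equal(pc$sets$S1, "TXA1.1")
  nc <- suppressMessages(expandGeneSets(gmt, dict, "non_coding_group", 1))
  expect_equal(nc$sets$S1, "TXA2.1")
  ln <- suppressMessages(expandGeneSets(gmt, dict, "lncRNA", 1))
  expect_equal(ln$sets$S1, "TXB1.2")
  # min size filter drops sets with too few surviving transcripts
  dropped <- suppressMessages(expandGeneSets(gmt, dict, "lncRNA", 2))
  expect_length(dropped$sets, 0)
  # gene ids (version stripped) are accepted as members too
  byId <- list(S1 = list(name = "S1", description = "d", members = "GA"))
  expect_equal(
    suppressMessages(expandGeneSets(byId, dict, "protein_coding", 1))$sets$S1,
    "TXA1.1")
})

test_that("ranking is by fold-change with deterministic tie-breaking", {
  ann <- data.frame(
    transcript_id = c("T1", "T2", "T3", "T4", "T5"),
    log2fc = c(2, -1, 0.5, 1, 1),
    qvalue = c(0.5, 0.5, 0.5, 0.04, 0.01),
    biotype_category = "protein_coding", stringsAsFactors = FALSE)
  r <- rankTranscripts(ann, "protein_coding")
  expect_equal(r$stat, c(2, 1, 1, 0.5, -1))
  # tie at 1 broken by ascending q-value: T5 before T4
  expect_equal(r$transcript_id[2:3], c("T5", "T4"))
  expect_equal(nrow(rankTranscripts(ann, "lncRNA")), 0)
})

test_that("enrichment score matches hand-enumerated walks", {
  ranked <- data.frame(transcript_id = c("A", "B", "C"),
                       stat = c(3, 2, 1), stringsAsFactors = FALSE)
  top <- enrichmentScore(ranked, "A", weightExponent = 0)
  expect_equal(top$runningSum, c(1, 0.5, 0))
  expect_equal(top$es, 1)
  bottom <- enrichmentScore(ranked, "C", weightExponent = 0)
  expect_equal(bottom$runningSum, c(-0.5, -1, 0))
  expect_equal(bottom$es, -1)
  expect_error(enrichmentScore(ranked, c("A", "B", "C")), "whole")
  expect_error(enrichmentScore(ranked, "ZZZ"), "no set member")
})

test_that("walk score equals the brute-force oracle exactly on random instances", {
  set.seed(501)
  for (i in 1:250) {
    n <- sample(5:50, 1)
    k <- sample(seq_len(n - 1), 1)
    p <- sample(c(0, 1), 1)
    ranked <- randomRanked(n)
    members <- sample(ranked$transcript_id, k)
    got <- enrichmentScore(ranked, members, p)
    isHit <- ranked$transcript_id %in% members
    expect_identical(got$runningSum, oracleRunningSum(ranked$stat, isHit, p))
    expect_identical(got$es, oracleEs(ranked$stat, isHit, p))
  }
})

test_that("the permutation-null score path is bit-identical to the full walk", {
  set.seed(502)
  for (i in 1:100) {
    n <- sample(10:200, 1)
    k <- sample(seq_len(n - 1), 1)
    p <- sample(c(0, 1, 2), 1)
    ranked <- randomRanked(n)
    members <- sample(ranked$transcript_id, k)
    full <- enrichmentScore(ranked, members, p)
    w <- abs(ranked$stat)^p
    expect_identical(isoscope:::.esFromHits(which(full$hits), w, n),
                     full$es)
  }
})

test_that("a set and its complement mirror each other at p = 0", {
  set.seed(503)
  for (i in 1:50) {
    n <- sample(6:60, 1)
    k <- sample(seq_len(n - 1), 1)
    ranked <- randomRanked(n)
    members <- sample(ranked$transcript_id, k)
    complement <- setdiff(ranked$transcript_id, members)
    esA <- enrichmentScore(ranked, members, 0)$es
    esB <- enrichmentScore(ranked, complement, 0)$es
    expect_identical(esA, -esB)
  }
})

test_that("implementation agrees with an independent library on the statistic", {
  skip_if_not_installed("fgsea")
  set.seed(504)
  for (i in 1:25) {
    n <- sample(20:100, 1)
    k <- sample(2:10, 1)
    ranked <- randomRanked(n)
    members <- sample(ranked$transcript_id, k)
    mine <- enrichmentScore(ranked, members, 1)$es
    stats <- stats::setNames(ranked$stat, ranked$transcript_id)
    ref <- fgsea::calcGseaStat(stats, which(ranked$transcript_id %in% members),
                               gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("permutation p-values are reproducible and exhaustively calibrated", {
  set.seed(505)
  ranked <- randomRanked(6)
  members <- ranked$transcript_id[c(1, 2)]
  a <- permutationPvalue(ranked, members, 1, nPerm = 500, seed = 99)
  b <- permutationPvalue(ranked, members, 1, nPerm = 500, seed = 99)
  expect_identical(a, b)

  # exhaustive null over all 15 same-size sets
  combos <- utils::combn(6, 2)
  nullEs <- apply(combos, 2, function(ix)
    enrichmentScore(ranked, ranked$transcript_id[ix], 1)$es)
  obs <- enrichmentScore(ranked, members, 1)$es
  matching <- sign(nullEs) == sign(obs)
  pExh <- sum(matching & abs(nullEs) >= abs(obs)) / sum(matching)
  mc <- permutationPvalue(ranked, members, 1, nPerm = 50000, seed = 7)
  expect_lt(abs(mc$pvalue - pExh), 0.01)
})

test_that("stratified enrichment recovers a planted set and is deterministic", {
  cfg <- simulationConfig(seed = 21)
  ann <- simulateAnnotation(cfg)
  de <- simulateDeTables(ann$truth, cfg)
  gmtSim <- simulateGmt(ann$truth, de, cfg)
  dict <- makeTxToGene(fasta = parseFastaHeaders({
    p <- tempfile(); writeLines(ann$fasta, p); p
  }))
  annotated <- annotateDeTable(
    data.frame(feature_id = de$tx$transcript_id, de$tx[-1]), dict)
  res <- suppressMessages(runEnrichment(annotated, gmtSim$gmt, dict,
                                        strata = "protein_coding",
                                        nPerm = 500, seed = 31))
  pc <- res[res$stratum == "protein_coding", ]
  expect_equal(pc$padj[pc$pathway == gmtSim$plantedSet], min(pc$padj))
  # leading edge of the planted set contains the planted transcripts
  lead <- strsplit(pc$leading_edge[pc$pathway == gmtSim$plantedSet], ",")[[1]]
  expect_true(all(de$switchTruth$transcript_id %in% lead))
  res2 <- suppressMessages(runEnrichment(annotated, gmtSim$gmt, dict,
                                         strata = "protein_coding",
                                         nPerm = 500, seed = 31))
  expect_identical(res, res2)
  # empty GMT gives an empty result
  expect_equal(nrow(suppressMessages(
    runEnrichment(annotated, list(), dict, "protein_coding"))), 0)
})

test_that("BH adjustment is monotone in p within each stratum", {
  cfg <- simulationConfig(nGenes = 60, nSwitchGenes = 5, nGeneSets = 12,
                          seed = 77)
  ann <- simulateAnnotation(cfg)
  de <- simulateDeTables(ann$truth, cfg)
  gmtSim <- simulateGmt(ann$truth, de, cfg)
  fa <- tempfile(); writeLines(ann$fasta, fa)
  dict <- makeTxToGene(fasta = parseFastaHeaders(fa))
  annotated <- annotateDeTable(
    data.frame(feature_id = de$tx$transcript_id, de$tx[-1]), dict)
  res <- suppressMessages(suppressWarnings(
    runEnrichment(annotated, gmtSim$gmt, dict,
                  strata = c("protein_coding", "non_coding_group", "lncRNA"),
                  minSize = 3, nPerm = 200, seed = 5)))
  expect_true(all(res$padj <= 1 & res$padj >= res$pvalue))
  for (s in unique(res$stratum)) {
    sub <- res[res$stratum == s, ]
    o <- order(sub$pvalue)
    expect_true(all(diff(sub$padj[o]) >= -1e-12))
  }
})
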