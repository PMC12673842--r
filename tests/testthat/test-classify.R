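annotatedRows <- function(log2fc, qvalue, category) {
  data.frame(transcript_id = sprintf("T%03d", seq_along(log2fc)),
             log2fc = log2fc, qvalue = qvalue,
             biotype_category = category, stringsAsFactors = FALSE)
}

test_that("significance boundaries are inclusive on fold-change, strict on q", {
  rows <- annotatedRows(
    log2fc = c(1.0, 0.6, 0.6, 1.5, 1.0),
    qvalue = c(0.049, 0.01, 0.01, 0.05, 0.05),
    category = c("protein_coding", "lncRNA", "protein_coding",
                 "protein_coding", "lncRNA"))
  out <- flagSignificance(rows)
  # |lfc| = 1 exactly with q = 0.049 passes for mRNA
  expect_true(out$is_significant[1])
  # lncRNA relaxed bound admits 0.6; protein_coding with same values does not
  expect_true(out$is_significant[2])
  expect_false(out$is_significant[3])
  # q = 0.05 exactly fails everywhere
  expect_false(out$is_significant[4])
  expect_false(out$is_significant[5])
})

test_that("missing q-values are flagged not significant with a warning", {
  rows <- annotatedRows(c(2, 2), c(NA, 0.01), "protein_coding")
  expect_warning(out <- flagSignificance(rows), "missing")
  expect_equal(out$is_significant, c(FALSE, TRUE))
})

test_that("flags agree exactly with a row-by-row oracle on random tables", {
  set.seed(401)
  n <- 10000
  cats <- sample(c("protein_coding", "lncRNA", "retained_intron",
                   "nonsense_mediated_decay", "CDS_undefined", "mystery"),
                 n, replace = TRUE)
  rows <- annotatedRows(stats::rnorm(n, 0, 1), stats::runif(n), cats)
  out <- flagSignificance(rows)
  oracle <- vapply(seq_len(n), function(i) {
    lim <- if (cats[i] == "lncRNA") 0.5 else 1
    abs(rows$log2fc[i]) >= lim && rows$qvalue[i] < 0.05
  }, logical(1))
  expect_identical(out$is_significant, oracle)
})

test_that("raising a fold-change threshold never adds significant rows", {
  set.seed(402)
  rows <- annotatedRows(stats::rnorm(300, 0, 1.5), stats::runif(300),
                        sample(c("protein_coding", "lncRNA"), 300, TRUE))
  grid <- seq(0, 2.5, by = 0.25)
  counts <- vapply(grid, function(th) {
    pol <- thresholdPolicy(data.frame(
      category = c("protein_coding", "lncRNA", "other"),
      min_abs_log2fc = th, max_qvalue = 0.05))
    sum(flagSignificance(rows, pol)$is_significant)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("annotation join strips versions and labels unmatched rows", {
  dict <- tinyDict()
  de <- data.frame(feature_id = c("TXA1", "TXA2.9", "TXZZ.1"),
                   log2fc = c(2, 0.7, 5), pvalue = 0.001,
                   qvalue = c(0.001, 0.001, 0.001),
                   stringsAsFactors = FALSE)
  ann <- suppressMessages(annotateDeTable(de, dict))
  expect_equal(ann$gene_name, c("AlphA", "AlphA", NA))
  expect_equal(ann$biotype_category,
               c("protein_coding", "retained_intron", "unannotated"))
  # unannotated rows are still flagged, under the fallback thresholds
  expect_equal(ann$is_significant, c(TRUE, FALSE, TRUE))
  smallMatch <- data.frame(feature_id = c("TXA1.1", "NOPE1", "NOPE2"),
                           log2fc = 0, pvalue = 1, qvalue = 1)
  expect_warning(annotateDeTable(smallMatch, dict), "right reference")
})

test_that("cluster removal drops exactly the collapsed transcripts", {
  de <- data.frame(feature_id = sprintf("TX%02d.1", 1:10),
                   log2fc = 0, pvalue = 1, qvalue = 1,
                   stringsAsFactors = FALSE)
  member <- data.frame(transcript_id = c("TX01.1", "TX05", "TX09.2"),
                       cluster_id = "c1", stringsAsFactors = FALSE)
  out <- suppressMessages(removeCollapsedClusters(de, member))
  expect_equal(nrow(out), 7)
  expect_false(any(c("TX01.1", "TX05.1", "TX09.1") %in% out$feature_id))
  expect_equal(suppressMessages(removeCollapsedClusters(de, NULL)), de)
  ghost <- data.frame(transcript_id = c("TX01.1", "TX05.1", "TX09.1",
                                        "GHOST.1"), cluster_id = "c")
  expect_warning(out2 <- suppressMessages(removeCollapsedClusters(de, ghost)),
                 "ignored")
  expect_equal(nrow(out2), 7)
})

test_that("switch candidates are significant transcripts of non-DE genes", {
  tx <- data.frame(
    transcript_id = c("T1", "T2", "T3", "T4"),
    gene_id = c("G1", "G2", "G3", "G1"),
    gene_name = "g", transcript_name = "t", biotype = "b",
    log2fc = c(2, 2, 2, 0.1), qvalue = 0.001,
    is_significant = c(TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  genes <- data.frame(feature_id = c("G1", "G2"), log2fc = c(0.1, 3),
                      qvalue = c(0.9, 0.001),
                      is_significant = c(FALSE, TRUE),
                      stringsAsFactors = FALSE)
  out <- detWithoutDeg(tx, genes)
  # T1: gene not DE -> in; T2: gene DE -> out; T3: gene untested -> in;
  # T4: transcript itself not significant -> out
  expect_equal(out$transcript_id, c("T1", "T3"))
  expect_equal(out$gene_is_significant, c("no", "untested"))
  expect_equal(out$gene_log2fc, c(0.1, NA))
})

test_that("switch detection partitions the significant transcripts", {
  set.seed(403)
  nGenes <- 40
  tx <- data.frame(
    transcript_id = sprintf("T%03d", 1:200),
    gene_id = sample(sprintf("G%02d", 1:nGenes), 200, TRUE),
    gene_name = "g", transcript_name = "t", biotype = "b",
    log2fc = stats::rnorm(200, 0, 1.5), qvalue = stats::runif(200),
    stringsAsFactors = FALSE)
  tx$biotype_category <- "protein_coding"
  tx <- flagSignificance(tx)
  genes <- data.frame(feature_id = sprintf("G%02d", 1:(nGenes - 5)),
                      log2fc = stats::rnorm(nGenes - 5, 0, 1.5),
                      qvalue = stats::runif(nGenes - 5),
                      stringsAsFactors = FALSE)
  genes$biotype_category <- "protein_coding"
  genes <- flagSignificance(genes)
  out <- detWithoutDeg(tx, genes)
  expect_true(all(out$transcript_id %in% tx$transcript_id[tx$is_significant]))
  rest <- setdiff(tx$transcript_id[tx$is_significant], out$transcript_id)
  sigGenes <- genes$feature_id[genes$is_significant]
  expect_true(all(tx$gene_id[tx$transcript_id %in% rest] %in% sigGenes))
})

test_that("contrast labels partition switch detection", {
  tx <- data.frame(
    transcript_id = c("T1", "T1"), gene_id = c("G1", "G1"),
    gene_name = "g", transcript_name = "t", biotype = "b",
    log2fc = 2, qvalue = 0.001, is_significant = TRUE,
    contrast = c("c1", "c2"), stringsAsFactors = FALSE)
  genes <- data.frame(feature_id = c("G1", "G1"), log2fc = c(3, 0),
                      qvalue = c(0.001, 0.9),
                      is_significant = c(TRUE, FALSE),
                      contrast = c("c1", "c2"), stringsAsFactors = FALSE)
  out <- detWithoutDeg(tx, genes)
  expect_equal(out$contrast, "c2")
})
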