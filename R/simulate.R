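#' Build a simulation configuration
#'
#' Defaults describe a desk-scale synthetic study: 150 genes on two
#' synthetic chromosomes with 2-5 annotated isoforms each, biotype
#' proportions loosely following the GENCODE composition of a
#' transcript-level DE table at a coding locus, 20 genes carrying a planted
#' isoform switch of log2 fold-change 3, a 25-set gene-level GMT (one set
#' planted on the switch genes), and 5 samples per group.  Every generated
#' artifact is byte-deterministic given the seed.
#'
#' @param nGenes number of genes.
#' @param txPerGene integer range (length 2) of transcripts per gene.
#' @param biotypeProps named proportions of transcript biotypes, summing
#'   to 1.  The first transcript of every gene is always protein_coding (a
#'   gene's canonical isoform); the proportions apply to the remaining
#'   transcripts.
#' @param nSwitchGenes genes with a planted isoform switch.
#' @param switchEffect planted log2 fold-change of the switching isoform
#'   (positive: the switching isoform is up-regulated).
#' @param nGeneSets number of gene sets in the simulated GMT.
#' @param samplesPerGroup samples per group in the TPM matrix.
#' @param seed mandatory integer seed.
#' @return a [SimulationConfig-class].
#' @export
simulationConfig <- function(nGenes = 150, txPerGene = c(2, 5),
                             biotypeProps = c(protein_coding = 0.45,
                                              lncRNA = 0.20,
                                              retained_intron = 0.15,
                                              nonsense_mediated_decay = 0.10,
                                              protein_coding_CDS_not_defined = 0.10),
                             nSwitchGenes = 20, switchEffect = 3,
                             nGeneSets = 25, samplesPerGroup = 5, seed) {
  if (missing(seed))
    stop("seed is mandatory")
  methods::new("SimulationConfig",
               n_genes = as.integer(nGenes),
               tx_per_gene = as.integer(txPerGene),
               biotype_props = biotypeProps,
               n_switch_genes = as.integer(nSwitchGenes),
               switch_effect = as.numeric(switchEffect),
               n_gene_sets = as.integer(nGeneSets),
               samples_per_group = as.integer(samplesPerGroup),
               seed = as.integer(seed))
}

#' Simulate a GENCODE-like annotation
#'
#' Places genes on two synthetic chromosomes with alternating strands.
#' Each gene gets a skeleton of up to 8 non-overlapping exons; each
#' transcript uses a sorted subset of the skeleton, so isoforms of a gene
#' share coordinates but differ in exon composition.  The GTF text and the
#' pipe-delimited FASTA headers are mutually consistent: every FASTA header
#' length equals the sum of that transcript's exon lengths in the GTF.
#'
#' @param config a [SimulationConfig-class].
#' @return list with elements \code{gtf} (character vector of GTF lines),
#'   \code{fasta} (character vector of FASTA lines; headers plus a dummy
#'   sequence body), and \code{truth} (data.frame of every planted
#'   transcript attribute: ids, names, biotype, chrom, strand, exon count,
#'   length, transcript start).
#' @export
simulateAnnotation <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  .withSeed(config@seed, {
    nG <- config@n_genes
    cursors <- c(chrSimA = 1000L, chrSimB = 1000L)
    gtf <- character(0); fasta <- character(0)
    truth <- vector("list", nG)
    txCounter <- 0L
    for (i in seq_len(nG)) {
      geneName <- sprintf("GENE%03d", i)
      geneId <- sprintf("SYNG%07d.1", i)
      chrom <- if (i %% 2 == 1) "chrSimA" else "chrSimB"
      strand <- if ((i %/% 2) %% 2 == 0) "+" else "-"
      widths <- sample(100:500, 8, replace = TRUE)
      gaps <- sample(200:2000, 7, replace = TRUE)
      skelStart <- cursors[[chrom]] + cumsum(c(0L, widths[-8] + gaps))
      skelEnd <- skelStart + widths - 1L
      cursors[[chrom]] <- max(skelEnd) + 10000L
      nTx <- sample(seq(config@tx_per_gene[1], config@tx_per_gene[2]), 1)
      for (j in seq_len(nTx)) {
        txCounter <- txCounter + 1L
        txId <- sprintf("SYNT%07d.1", txCounter)
        txName <- sprintf("%s-%d", geneName, 200 + j)
        biotype <- if (j == 1) "protein_coding" else
          sample(names(config@biotype_props), 1, prob = config@biotype_props)
        k <- sample(1:8, 1)
        use <- sort(sample(8, k))
        exS <- skelStart[use]; exE <- skelEnd[use]
        len <- sum(exE - exS + 1L)
        attrBase <- .gtfAttr(geneId, txId, geneName, txName, biotype)
        gtf <- c(gtf, sprintf(
          "%s\tsynthetic\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
          chrom, min(exS), max(exE), strand, attrBase))
        exonNums <- if (strand == "+") seq_len(k) else rev(seq_len(k))
        gtf <- c(gtf, sprintf(
          "%s\tsynthetic\texon\t%d\t%d\t.\t%s\t.\t%s exon_number %d;",
          chrom, exS, exE, strand, attrBase, exonNums))
        fasta <- c(fasta,
                   sprintf(">%s|%s|-|-|%s|%s|%d|%s|", txId, geneId, txName,
                           geneName, len, biotype),
                   "ACGTACGTACGT")
        truth[[txCounter]] <- data.frame(
          transcript_id = txId, gene_id = geneId, gene_name = geneName,
          transcript_name = txName, biotype = biotype, chrom = chrom,
          strand = strand, n_exons = k, length = len,
          tx_start = min(exS), stringsAsFactors = FALSE)
      }
    }
    list(gtf = gtf, fasta = fasta, truth = do.call(rbind, truth))
  })
}

#' Simulate transcript- and gene-level DE tables with planted switches
#'
#' Chooses `n_switch_genes` multi-isoform genes and plants an isoform
#' switch in each: the gene's canonical (protein_coding) isoform gets a
#' log2 fold-change of at least the configured effect with q < 0.01, while
#' the gene-level row stays null (log2FC near 0, q > 0.5).  All remaining
#' rows draw null log2 fold-changes from Normal(0, 0.2) and q-values
#' uniform on (0.05, 1], which keeps chance significance off the decision
#' boundary by construction; boundary behaviour is exercised separately
#' with hand-written rows.
#'
#' @param truth annotation truth table from [simulateAnnotation()].
#' @param config a [SimulationConfig-class].
#' @return list with elements \code{tx} (data.frame: transcript_id, log2fc,
#'   pvalue, qvalue), \code{gene} (data.frame: gene_id, log2fc, pvalue,
#'   qvalue) and \code{switchTruth} (data.frame of the planted switch
#'   transcripts and their genes).
#' @export
simulateDeTables <- function(truth, config) {
  stopifnot(is(config, "SimulationConfig"))
  geneIdsU <- unique(truth$gene_id)
  if (config@n_switch_genes > length(geneIdsU))
    stop("n_switch_genes exceeds the number of simulated genes")
  .withSeed(config@seed + 1L, {
    txPerGene <- table(truth$gene_id)
    eligible <- geneIdsU[txPerGene[geneIdsU] >= 2]
    if (config@n_switch_genes > length(eligible))
      stop("not enough multi-isoform genes to plant switches")
    switchGenes <- sort(sample(eligible, config@n_switch_genes))
    # canonical isoform = first transcript of the gene (protein_coding)
    planted <- vapply(switchGenes, function(g)
      truth$transcript_id[truth$gene_id == g][1], character(1))
    n <- nrow(truth)
    txTab <- data.frame(
      transcript_id = truth$transcript_id,
      log2fc = stats::rnorm(n, 0, 0.2),
      qvalue = stats::runif(n, 0.05, 1),
      stringsAsFactors = FALSE)
    hit <- match(planted, txTab$transcript_id)
    txTab$log2fc[hit] <- config@switch_effect + stats::runif(length(hit), 0, 0.5)
    txTab$qvalue[hit] <- stats::runif(length(hit), 1e-4, 0.009)
    txTab$pvalue <- txTab$qvalue * 0.8
    txTab <- txTab[, c("transcript_id", "log2fc", "pvalue", "qvalue")]
    gTab <- data.frame(
      gene_id = geneIdsU,
      log2fc = stats::rnorm(length(geneIdsU), 0, 0.2),
      qvalue = stats::runif(length(geneIdsU), 0.05, 1),
      stringsAsFactors = FALSE)
    sw <- gTab$gene_id %in% switchGenes
    gTab$log2fc[sw] <- stats::rnorm(sum(sw), 0, 0.05)
    gTab$qvalue[sw] <- stats::runif(sum(sw), 0.5, 1)
    gTab$pvalue <- gTab$qvalue * 0.8
    gTab <- gTab[, c("gene_id", "log2fc", "pvalue", "qvalue")]
    switchTruth <- data.frame(
      gene_id = switchGenes,
      gene_name = truth$gene_name[match(switchGenes, truth$gene_id)],
      transcript_id = planted, stringsAsFactors = FALSE)
    rownames(switchTruth) <- NULL
    list(tx = txTab, gene = gTab, switchTruth = switchTruth)
  })
}

#' Simulate a TPM matrix with group-separated switch isoforms
#'
#' Baseline abundances are log-normal per transcript; samples add
#' multiplicative log-normal noise.  Planted switch isoforms have their
#' case-group mean multiplied by `2^switch_effect`, so the group-mean
#' separation matches the planted fold-change in linear space.
#'
#' @param truth annotation truth table from [simulateAnnotation()].
#' @param deTruth result of [simulateDeTables()] (its \code{switchTruth}
#'   names the planted isoforms).
#' @param config a [SimulationConfig-class].
#' @return list with elements \code{tpm} (matrix, transcripts x samples),
#'   \code{sampleGroups} (data.frame: sample, group; control first) and
#'   \code{groupMeans} (data.frame of the planted per-group means).
#' @export
simulateTpm <- function(truth, deTruth, config) {
  stopifnot(is(config, "SimulationConfig"))
  .withSeed(config@seed + 2L, {
    n <- nrow(truth)
    nS <- config@samples_per_group
    base <- exp(stats::rnorm(n, log(50), 1))
    caseMean <- base
    hit <- match(deTruth$switchTruth$transcript_id, truth$transcript_id)
    caseMean[hit] <- base[hit] * 2^config@switch_effect
    samples <- c(sprintf("ctrl_%d", seq_len(nS)),
                 sprintf("case_%d", seq_len(nS)))
    means <- cbind(matrix(rep(base, nS), ncol = nS),
                   matrix(rep(caseMean, nS), ncol = nS))
    noise <- matrix(exp(stats::rnorm(n * 2 * nS, 0, 0.2)), nrow = n)
    tpm <- means * noise
    dimnames(tpm) <- list(truth$transcript_id, samples)
    sampleGroups <- data.frame(
      sample = samples,
      group = rep(c("control", "case"), each = nS),
      stringsAsFactors = FALSE)
    groupMeans <- data.frame(transcript_id = truth$transcript_id,
                             control = base, case = caseMean,
                             stringsAsFactors = FALSE)
    list(tpm = tpm, sampleGroups = sampleGroups, groupMeans = groupMeans)
  })
}

#' Simulate a gene-level GMT with one planted set
#'
#' The planted set contains exactly the switch genes, so after
#' [simulateDeTables()] its transcripts occupy the top of the
#' protein-coding ranking; the remaining sets draw 10-50 genes uniformly
#' from the simulated universe.
#'
#' @param truth annotation truth table from [simulateAnnotation()].
#' @param deTruth result of [simulateDeTables()].
#' @param config a [SimulationConfig-class].
#' @return list with elements \code{gmt} (named list of sets in the
#'   [readGmt()] shape) and \code{plantedSet} (the planted set's name).
#' @export
simulateGmt <- function(truth, deTruth, config) {
  stopifnot(is(config, "SimulationConfig"))
  .withSeed(config@seed + 3L, {
    universe <- unique(truth$gene_name)
    gmt <- list()
    plantedName <- "PLANTED_SWITCH_SET"
    gmt[[plantedName]] <- list(
      name = plantedName, description = "synthetic planted switch genes",
      members = deTruth$switchTruth$gene_name)
    nOther <- max(config@n_gene_sets - 1L, 0L)
    for (i in seq_len(nOther)) {
      nm <- sprintf("RANDOM_SET_%02d", i)
      size <- sample(10:50, 1)
      gmt[[nm]] <- list(name = nm, description = "synthetic random set",
                        members = sort(sample(universe, min(size, length(universe)))))
    }
    list(gmt = gmt, plantedSet = plantedName)
  })
}

#' Write a full fixture directory
#'
#' Materializes one simulated study on disk in the same formats the real
#' pipeline reads: \code{reference.gtf}, \code{transcripts.fa},
#' \code{tx_de.tsv}, \code{gene_de.tsv}, \code{tpm.tsv},
#' \code{sample_groups.tsv}, \code{gene_sets.gmt}, and the truth tables
#' (\code{truth_annotation.tsv}, \code{truth_switches.tsv}).  Truth tables
#' are first-class outputs so downstream checks never have to re-derive the
#' planted signal from the data.
#'
#' @param config a [SimulationConfig-class].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
writeFixtureDir <- function(config, dir) {
  stopifnot(is(config, "SimulationConfig"))
  if (!dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  ann <- simulateAnnotation(config)
  de <- simulateDeTables(ann$truth, config)
  tpm <- simulateTpm(ann$truth, de, config)
  gmt <- simulateGmt(ann$truth, de, config)
  paths <- c(
    gtf = file.path(dir, "reference.gtf"),
    fasta = file.path(dir, "transcripts.fa"),
    tx_de = file.path(dir, "tx_de.tsv"),
    gene_de = file.path(dir, "gene_de.tsv"),
    tpm = file.path(dir, "tpm.tsv"),
    groups = file.path(dir, "sample_groups.tsv"),
    gmt = file.path(dir, "gene_sets.gmt"),
    truth_annotation = file.path(dir, "truth_annotation.tsv"),
    truth_switches = file.path(dir, "truth_switches.tsv"))
  writeLines(ann$gtf, paths[["gtf"]])
  writeLines(ann$fasta, paths[["fasta"]])
  .writeTsv(de$tx, paths[["tx_de"]])
  .writeTsv(de$gene, paths[["gene_de"]])
  tpmDf <- data.frame(transcript_id = rownames(tpm$tpm),
                      tpm$tpm, check.names = FALSE,
                      stringsAsFactors = FALSE)
  .writeTsv(tpmDf, paths[["tpm"]])
  .writeTsv(tpm$sampleGroups, paths[["groups"]])
  writeGmt(gmt$gmt, paths[["gmt"]])
  .writeTsv(ann$truth, paths[["truth_annotation"]])
  .writeTsv(de$switchTruth, paths[["truth_switches"]])
  invisible(paths)
}
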