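# Shared fixture builders and independent oracles, built in code at test time.

# Independent brute-force oracle for the running-sum enrichment statistic:
# materializes the full walk step by step with scalar updates, independent
# of the implementation's vectorized path.
oracleRunningSum <- function(stats, isHit, p) {
  n <- length(stats)
  nh <- sum(isHit)
  nr <- sum(abs(stats[isHit])^p)
  rs <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    cur <- if (isHit[i]) cur + abs(stats[i])^p / nr else cur - 1 / (n - nh)
    rs[i] <- cur
  }
  rs
}

oracleEs <- function(stats, isHit, p) {
  rs <- oracleRunningSum(stats, isHit, p)
  rs[which.max(abs(rs))]
}

# A tiny hand-written annotation: 2 genes, 3 transcripts, both strands.
tinyFastaRecords <- function() {
  data.frame(
    transcript_id = c("TXA1.1", "TXA2.1", "TXB1.2"),
    gene_id = c("GA.1", "GA.1", "GB.3"),
    transcript_name = c("AlphA-201", "AlphA-202", "BetA-201"),
    gene_name = c("AlphA", "AlphA", "BetA"),
    length = c(202L, 101L, 150L),
    biotype = c("protein_coding", "retained_intron", "lncRNA"),
    stringsAsFactors = FALSE)
}

tinyDict <- function() {
  makeTxToGene(fasta = tinyFastaRecords())
}

tinyGtfLines <- function() {
  a <- function(tx, gene, gname, tname, type, extra = "")
    sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s"; transcript_name "%s"; transcript_type "%s";%s',
            gene, tx, gname, tname, type, extra)
  c(
    "##format: gtf",
    paste("chr1\tsrc\ttranscript\t100\t400\t.\t+\t.",
          a("TXA1.1", "GA.1", "AlphA", "AlphA-201", "protein_coding"),
          sep = "\t"),
    paste("chr1\tsrc\texon\t100\t200\t.\t+\t.",
          a("TXA1.1", "GA.1", "AlphA", "AlphA-201", "protein_coding",
            " exon_number 1;"), sep = "\t"),
    paste("chr1\tsrc\texon\t300\t400\t.\t+\t.",
          a("TXA1.1", "GA.1", "AlphA", "AlphA-201", "protein_coding",
            " exon_number 2;"), sep = "\t"),
    paste("chr1\tsrc\ttranscript\t100\t200\t.\t+\t.",
          a("TXA2.1", "GA.1", "AlphA", "AlphA-202", "retained_intron"),
          sep = "\t"),
    paste("chr1\tsrc\texon\t100\t200\t.\t+\t.",
          a("TXA2.1", "GA.1", "AlphA", "AlphA-202", "retained_intron",
            " exon_number 1;"), sep = "\t"),
    paste("chr1\tsrc\ttranscript\t500\t800\t.\t-\t.",
          a("TXB1.2", "GB.3", "BetA", "BetA-201", "lncRNA"), sep = "\t"),
    paste("chr1\tsrc\texon\t500\t600\t.\t-\t.",
          a("TXB1.2", "GB.3", "BetA", "BetA-201", "lncRNA"), sep = "\t"),
    paste("chr1\tsrc\texon\t700\t800\t.\t-\t.",
          a("TXB1.2", "GB.3", "BetA", "BetA-201", "lncRNA"), sep = "\t"))
}

writeTinyGtf <- function(lines = tinyGtfLines()) {
  path <- tempfile(fileext = ".gtf")
  writeLines(lines, path)
  path
}

writeTinyFasta <- function() {
  rec <- tinyFastaRecords()
  path <- tempfile(fileext = ".fa")
  writeLines(as.vector(rbind(
    sprintf(">%s|%s|-|-|%s|%s|%d|%s|", rec$transcript_id, rec$gene_id,
            rec$transcript_name, rec$gene_name, rec$length, rec$biotype),
    "ACGT")), path)
  path
}

# A ranked list with unique random statistics, head-of-list first.
randomRanked <- function(n) {
  data.frame(transcript_id = sprintf("T%05d", seq_len(n)),
             stat = sort(stats::rnorm(n), decreasing = TRUE),
             stringsAsFactors = FALSE)
}

fileBytes <- function(path) readBin(path, "raw", file.size(path))
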