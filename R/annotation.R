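#' Strip the version suffix from an accession
#'
#' Removes a trailing `.N` (N numeric) from versioned accessions such as
#' `ENST00000456328.2`.  Used for the version-insensitive joins between
#' differential-expression tables and the annotation dictionary.
#'
#' @param ids character vector of accessions.
#' @return character vector of version-stripped accessions.
#' @examples
#' stripVersion(c("ENST00000456328.2", "ENSG00000223972"))
#' @export
stripVersion <- function(ids) {
  sub("\\.[0-9]+$", "", ids)
}

#' Default biotype-to-category mapping
#'
#' Loads the editable mapping table shipped with the package that collapses
#' GENCODE transcript biotype tokens into the categories used throughout the
#' toolkit (protein_coding, lncRNA, retained_intron, nonsense_mediated_decay,
#' CDS_undefined).  Biotypes absent from the table fall back to category
#' `"other"` at classification time.  Different GENCODE releases spell the
#' CDS-undefined biotype differently (`processed_transcript` in older
#' releases, `protein_coding_CDS_not_defined` in newer ones); both map to
#' `CDS_undefined` here.
#'
#' @param path optional path to a replacement two-column TSV
#'   (\code{biotype}, \code{category}).
#' @return data.frame with columns \code{biotype} and \code{category}.
#' @export
defaultBiotypeCategories <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "biotype_categories.tsv",
                        package = "isoscope", mustWork = TRUE)
  map <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("biotype", "category") %in% names(map)))
  map
}

#' Map biotype tokens to normalized categories
#'
#' @param biotypes character vector of GENCODE biotype tokens.
#' @param categoryMap mapping table as returned by
#'   [defaultBiotypeCategories()].
#' @return character vector of categories; unmapped biotypes become
#'   \code{"other"}.
#' @export
categorizeBiotype <- function(biotypes, categoryMap = defaultBiotypeCategories()) {
  idx <- match(biotypes, categoryMap$biotype)
  out <- categoryMap$category[idx]
  out[is.na(idx)] <- "other"
  out
}

#' The biotype categories forming the non-coding (alternative-processing) group
#'
#' Retained-intron, nonsense-mediated-decay and CDS-undefined transcripts are
#' the three main isoform classes produced by alternative mRNA processing at
#' coding loci; they are pooled into one stratum for enrichment analyses that
#' contrast coding against non-coding isoform behaviour.
#'
#' @return character vector of category labels.
#' @export
nonCodingGroupCategories <- function() {
  c("retained_intron", "nonsense_mediated_decay", "CDS_undefined")
}

#' Parse GENCODE transcript FASTA headers
#'
#' Reads the pipe-delimited headers of a GENCODE transcripts FASTA
#' (`>txid|geneid|havana_gene|havana_tx|txname|genename|length|biotype|`)
#' into one transcript record per sequence.  Sequence bodies are not loaded;
#' the HAVANA placeholder fields are discarded.
#'
#' @param path path to an (uncompressed or gzipped) FASTA file.
#' @return data.frame with columns \code{transcript_id}, \code{gene_id},
#'   \code{transcript_name}, \code{gene_name}, \code{length},
#'   \code{biotype}.
#' @export
parseFastaHeaders <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0)
    return(.emptyTxRecords())
  idx <- Biostrings::fasta.index(path)
  if (nrow(idx) == 0)
    return(.emptyTxRecords())
  headers <- idx$desc
  fields <- strsplit(headers, "|", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 8)) {
    bad <- which(nf < 8)[1]
    stop(sprintf(
      "FASTA record %d: header has %d pipe-delimited fields, expected >= 8: %s",
      bad, nf[bad], headers[bad]))
  }
  lens <- vapply(fields, `[`, character(1), 7L)
  leni <- suppressWarnings(as.integer(lens))
  if (anyNA(leni)) {
    bad <- which(is.na(leni))[1]
    stop(sprintf("FASTA record %d: length field '%s' is not an integer",
                 bad, lens[bad]))
  }
  data.frame(
    transcript_id = vapply(fields, `[`, character(1), 1L),
    gene_id = vapply(fields, `[`, character(1), 2L),
    transcript_name = vapply(fields, `[`, character(1), 5L),
    gene_name = vapply(fields, `[`, character(1), 6L),
    length = leni,
    biotype = vapply(fields, `[`, character(1), 8L),
    stringsAsFactors = FALSE
  )
}

.emptyTxRecords <- function() {
  data.frame(transcript_id = character(0), gene_id = character(0),
             transcript_name = character(0), gene_name = character(0),
             length = integer(0), biotype = character(0),
             stringsAsFactors = FALSE)
}

#' Parse a GTF/GFF3 annotation into transcript and exon tables
#'
#' Validates the file line by line (9 tab-separated columns, start <= end,
#' transcript_id present on every requested feature) so that malformed input
#' is reported with its line number, then imports the file with
#' \pkg{rtracklayer}.  Coordinates are kept exactly as the GTF convention
#' gives them: 1-based, inclusive at both ends; GFF3 input is normalized to
#' the same convention on import.
#'
#' @param path path to a GTF or GFF3 file (optionally gzipped).
#' @param featureKinds subset of \code{c("transcript", "exon")}: which
#'   feature rows to extract.
#' @param format \code{"auto"} (detect from the attribute dialect),
#'   \code{"gtf"} or \code{"gff3"}.
#' @return list with elements \code{transcripts} (data.frame of transcript
#'   records; \code{length} is the sum of the transcript's exon lengths when
#'   exons were parsed, \code{NA} otherwise) and \code{exons} (a
#'   [GenomicRanges::GRanges] with metadata columns \code{transcript_id},
#'   \code{gene_name}, \code{exon_number}, and \code{transcript_name} /
#'   \code{biotype} when available).  Exon numbers absent from the file are
#'   assigned in 5'-to-3' order along the strand.
#' @export
parseGtf <- function(path, featureKinds = c("transcript", "exon"),
                     format = c("auto", "gtf", "gff3")) {
  stopifnot(file.exists(path))
  format <- match.arg(format)
  featureKinds <- match.arg(featureKinds, several.ok = TRUE)

  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  dataIdx <- which(keep)
  if (length(dataIdx) == 0) {
    return(list(transcripts = .emptyTxRecords(), exons = .emptyExons()))
  }
  parts <- strsplit(lines[dataIdx], "\t", fixed = TRUE)
  ncol9 <- lengths(parts)
  if (any(ncol9 != 9)) {
    bad <- which(ncol9 != 9)[1]
    stop(sprintf("line %d: expected 9 tab-separated columns, found %d",
                 dataIdx[bad], ncol9[bad]))
  }
  starts <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 4L)))
  ends <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 5L)))
  if (anyNA(starts) || anyNA(ends)) {
    bad <- which(is.na(starts) | is.na(ends))[1]
    stop(sprintf("line %d: non-numeric start/end", dataIdx[bad]))
  }
  if (any(starts > ends)) {
    bad <- which(starts > ends)[1]
    stop(sprintf("line %d: start (%d) > end (%d)",
                 dataIdx[bad], starts[bad], ends[bad]))
  }
  feats <- vapply(parts, `[`, character(1), 3L)
  attrs <- vapply(parts, `[`, character(1), 9L)
  requested <- feats %in% featureKinds
  noTx <- requested & !grepl("transcript_id", attrs, fixed = TRUE)
  if (any(noTx)) {
    bad <- which(noTx)[1]
    stop(sprintf("line %d: %s feature lacks a transcript_id attribute",
                 dataIdx[bad], feats[bad]))
  }

  if (format == "auto") {
    a <- attrs[1]
    format <- if (grepl("=", a, fixed = TRUE) && !grepl("\"", a, fixed = TRUE))
      "gff3" else "gtf"
  }
  gr <- rtracklayer::import(path, format = format)
  mc <- S4Vectors::mcols(gr)
  biocol <- intersect(c("transcript_type", "transcript_biotype", "biotype"),
                      names(mc))
  getAttr <- function(g, col, fallback = NA_character_) {
    m <- S4Vectors::mcols(g)
    if (col %in% names(m)) as.character(m[[col]])
    else rep(fallback, length(g))
  }

  txs <- .emptyTxRecords()
  exons <- .emptyExons()

  if ("exon" %in% featureKinds) {
    ex <- gr[mc$type == "exon"]
    if (length(ex) > 0) {
      txid <- getAttr(ex, "transcript_id")
      en <- suppressWarnings(as.integer(getAttr(ex, "exon_number")))
      ord <- order(txid, GenomicRanges::start(ex))
      ex <- ex[ord]; txid <- txid[ord]; en <- en[ord]
      if (anyNA(en)) {
        # assign 5'->3': ascending start on +, descending on -
        en <- unlist(lapply(split(seq_along(ex), txid)[unique(txid)],
          function(i) {
            if (as.character(GenomicRanges::strand(ex[i[1]])) == "-")
              rev(seq_along(i)) else seq_along(i)
          }), use.names = FALSE)
      }
      exons <- GenomicRanges::GRanges(
        seqnames = GenomicRanges::seqnames(ex),
        ranges = IRanges::IRanges(GenomicRanges::start(ex),
                                  GenomicRanges::end(ex)),
        strand = GenomicRanges::strand(ex),
        transcript_id = txid,
        gene_name = getAttr(ex, "gene_name"),
        exon_number = en,
        transcript_name = getAttr(ex, "transcript_name"),
        biotype = if (length(biocol)) getAttr(ex, biocol[1]) else
          rep(NA_character_, length(ex))
      )
      .warnOverlappingExons(exons)
    }
  }

  if ("transcript" %in% featureKinds) {
    tx <- gr[mc$type == "transcript"]
    if (length(tx) > 0) {
      txid <- getAttr(tx, "transcript_id")
      lens <- rep(NA_integer_, length(tx))
      if (length(exons) > 0) {
        sums <- tapply(GenomicRanges::width(exons),
                       S4Vectors::mcols(exons)$transcript_id, sum)
        hit <- match(txid, names(sums))
        lens[!is.na(hit)] <- as.integer(sums[hit[!is.na(hit)]])
      }
      txname <- getAttr(tx, "transcript_name")
      txname[is.na(txname)] <- txid[is.na(txname)]
      txs <- data.frame(
        transcript_id = txid,
        gene_id = getAttr(tx, "gene_id"),
        transcript_name = txname,
        gene_name = getAttr(tx, "gene_name"),
        length = lens,
        biotype = if (length(biocol)) getAttr(tx, biocol[1]) else
          rep(NA_character_, length(tx)),
        stringsAsFactors = FALSE
      )
    }
  }

  list(transcripts = txs, exons = exons)
}

.emptyExons <- function() {
  GenomicRanges::GRanges(
    seqnames = character(0), ranges = IRanges::IRanges(),
    strand = character(0), transcript_id = character(0),
    gene_name = character(0), exon_number = integer(0),
    transcript_name = character(0), biotype = character(0))
}

.warnOverlappingExons <- function(exons) {
  byTx <- split(IRanges::ranges(exons), S4Vectors::mcols(exons)$transcript_id)
  nOv <- sum(vapply(byTx, function(r) {
    length(r) > 1 && !IRanges::isDisjoint(r)
  }, logical(1)))
  if (nOv > 0)
    warning(sprintf("%d transcript(s) have overlapping exons", nOv))
  invisible(NULL)
}

#' Build a transcript-to-gene dictionary
#'
#' Combines transcript records parsed from FASTA headers and/or a GTF/GFF3
#' annotation into a deduplicated [TxDictionary-class] with a
#' version-insensitive lookup index.  When both sources describe the same
#' transcript and disagree on its biotype, the GTF annotation wins and a
#' warning reports how many records were overridden.
#'
#' @param fasta transcript records from [parseFastaHeaders()] (or `NULL`).
#' @param gtf transcript records from [parseGtf()]`$transcripts` (or `NULL`).
#' @param categoryMap biotype-to-category mapping table
#'   (see [defaultBiotypeCategories()]).
#' @return a [TxDictionary-class].
#' @export
makeTxToGene <- function(fasta = NULL, gtf = NULL,
                         categoryMap = defaultBiotypeCategories()) {
  if (is.null(fasta) && is.null(gtf))
    stop("at least one of 'fasta' or 'gtf' records is required")
  cols <- names(.emptyTxRecords())
  rec <- if (!is.null(fasta)) fasta[, cols] else .emptyTxRecords()
  if (!is.null(gtf) && nrow(gtf) > 0) {
    gtf <- gtf[, cols]
    hit <- match(gtf$transcript_id, rec$transcript_id)
    upd <- which(!is.na(hit))
    if (length(upd) > 0) {
      conflict <- rec$biotype[hit[upd]] != gtf$biotype[upd] &
        !is.na(gtf$biotype[upd])
      if (any(conflict)) {
        warning(sprintf(
          "%d transcript(s) have conflicting biotypes between FASTA and GTF; keeping the GTF biotype",
          sum(conflict)))
        rec$biotype[hit[upd][conflict]] <- gtf$biotype[upd][conflict]
      }
    }
    rec <- rbind(rec, gtf[is.na(hit), , drop = FALSE])
  }
  rec <- unique(rec)
  dup <- rec$transcript_id[duplicated(rec$transcript_id)]
  if (length(dup) > 0) {
    # same id surviving unique() means contradictory metadata
    offender <- rec[rec$transcript_id %in% dup, c("transcript_id", "gene_id")]
    multiGene <- unique(offender$transcript_id[
      ave(offender$gene_id, offender$transcript_id,
          FUN = function(g) length(unique(g))) > 1])
    if (length(multiGene) > 0)
      stop("transcript(s) mapped to more than one gene: ",
           paste(multiGene, collapse = ", "))
    # otherwise keep the first occurrence (e.g. differing display names)
    rec <- rec[!duplicated(rec$transcript_id), , drop = FALSE]
  }
  g <- tapply(rec$gene_id, rec$transcript_id, function(x) length(unique(x)))
  if (any(g > 1))
    stop("transcript(s) mapped to more than one gene: ",
         paste(names(g)[g > 1], collapse = ", "))
  stripped <- stripVersion(rec$transcript_id)
  if (anyDuplicated(stripped))
    stop("version-stripped transcript accessions collide: ",
         paste(unique(stripped[duplicated(stripped)]), collapse = ", "))
  rec$biotype_category <- categorizeBiotype(rec$biotype, categoryMap)
  rownames(rec) <- NULL
  idx <- seq_len(nrow(rec))
  names(idx) <- stripped
  methods::new("TxDictionary", records = rec, index = idx)
}

#' Look up transcripts in a dictionary, ignoring accession versions
#'
#' @param dict a [TxDictionary-class].
#' @param ids transcript accessions, with or without version suffix.
#' @return data.frame of dictionary records aligned to `ids`; rows of
#'   unknown accessions are `NA`.
#' @export
txLookup <- function(dict, ids) {
  stopifnot(is(dict, "TxDictionary"))
  rows <- dict@index[stripVersion(ids)]
  out <- dict@records[rows, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a dictionary to TSV
#'
#' Columns: transcript_id, gene_id, transcript_name, gene_name, length,
#' transcript_type.  The export round-trips bit-exactly through
#' [readTxDictionary()].
#'
#' @param dict a [TxDictionary-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTxDictionary <- function(dict, path) {
  stopifnot(is(dict, "TxDictionary"))
  out <- dict@records[, c("transcript_id", "gene_id", "transcript_name",
                          "gene_name", "length", "biotype")]
  names(out)[names(out) == "biotype"] <- "transcript_type"
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a dictionary written by [writeTxDictionary()]
#'
#' @param path TSV path.
#' @param categoryMap biotype-to-category mapping table.
#' @return a [TxDictionary-class].
#' @export
readTxDictionary <- function(path, categoryMap = defaultBiotypeCategories()) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(length = "integer"))
  need <- c("transcript_id", "gene_id", "transcript_name", "gene_name",
            "length", "transcript_type")
  if (!all(need %in% names(tab)))
    stop("dictionary TSV must have columns: ", paste(need, collapse = ", "))
  names(tab)[names(tab) == "transcript_type"] <- "biotype"
  makeTxToGene(fasta = tab, categoryMap = categoryMap)
}

#' Select and order exons for a set of genes
#'
#' Returns the exons of all transcripts of the requested genes, sorted by
#' gene, transcript and genomic start, ready for the genomic-context plot
#' model.
#'
#' @param exons exon [GenomicRanges::GRanges] from [parseGtf()].
#' @param geneNames non-empty character vector of gene display names.
#' @return [GenomicRanges::GRanges] of the selected exons.
#' @export
prepareExonAnnotation <- function(exons, geneNames) {
  stopifnot(is(exons, "GRanges"), length(geneNames) > 0)
  have <- unique(S4Vectors::mcols(exons)$gene_name)
  missing <- setdiff(geneNames, have)
  if (length(missing) > 0)
    stop("gene(s) not present in exon annotation: ",
         paste(missing, collapse = ", "))
  sel <- exons[S4Vectors::mcols(exons)$gene_name %in% geneNames]
  mc <- S4Vectors::mcols(sel)
  sel[order(mc$gene_name, mc$transcript_id, GenomicRanges::start(sel))]
}

# Canonical GTF serialization: one transcript feature (spanning its exons)
# followed by its exons in ascending genomic order, attributes in fixed
# order.  Both the simulator and writeGtf() emit this layout, so fixture
# GTFs round-trip byte-exactly through parseGtf().
.gtfAttr <- function(geneId, txId, geneName, txName, biotype) {
  sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s"; transcript_name "%s"; transcript_type "%s";',
          geneId, txId, geneName, txName, biotype)
}

.gtfLinesForTx <- function(txRec, ex, source) {
  ex <- ex[order(GenomicRanges::start(ex))]
  mc <- S4Vectors::mcols(ex)
  chrom <- as.character(GenomicRanges::seqnames(ex))[1]
  strand <- as.character(GenomicRanges::strand(ex))[1]
  attr <- .gtfAttr(txRec$gene_id, txRec$transcript_id, txRec$gene_name,
                   txRec$transcript_name, txRec$biotype)
  c(sprintf("%s\t%s\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
            chrom, source, min(GenomicRanges::start(ex)),
            max(GenomicRanges::end(ex)), strand, attr),
    sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s exon_number %d;",
            chrom, source, GenomicRanges::start(ex),
            GenomicRanges::end(ex), strand, attr, mc$exon_number))
}

#' Write transcripts and exons back to GTF
#'
#' Serializes the canonical layout produced by the fixture simulator:
#' transcripts in table order, each followed by its exons in ascending
#' genomic order, with attributes in a fixed order.  Transcript feature
#' coordinates span the transcript's exons.
#'
#' @param transcripts transcript records (as from [parseGtf()]`$transcripts`).
#' @param exons exon [GenomicRanges::GRanges] (as from [parseGtf()]`$exons`).
#' @param path output path.
#' @param source value for the GTF source column.
#' @return `path`, invisibly.
#' @export
writeGtf <- function(transcripts, exons, path, source = "isoscope") {
  mc <- S4Vectors::mcols(exons)
  lines <- unlist(lapply(seq_len(nrow(transcripts)), function(i) {
    txRec <- transcripts[i, ]
    ex <- exons[mc$transcript_id == txRec$transcript_id]
    if (length(ex) == 0)
      stop("no exons for transcript ", txRec$transcript_id)
    .gtfLinesForTx(txRec, ex, source)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Deterministic GENCODE archive URL
#'
#' Pure function of (species, release, kind); performs no network activity.
#'
#' @param species `"human"` or `"mouse"`.
#' @param release GENCODE release label, e.g. `"44"` (human) or `"M33"`
#'   (mouse; a bare number is prefixed with `M`).
#' @param kind `"gtf"`, `"gff3"` or `"transcripts_fasta"`.
#' @return URL string.
#' @export
gencodeReferenceUrl <- function(species = c("human", "mouse"), release,
                                kind = c("gtf", "gff3", "transcripts_fasta")) {
  species <- match.arg(species)
  kind <- match.arg(kind)
  release <- as.character(release)
  if (species == "mouse" && !grepl("^M", release))
    release <- paste0("M", release)
  base <- sprintf(
    "https://ftp.ebi.ac.uk/pub/databases/gencode/Gencode_%s/release_%s",
    species, release)
  file <- switch(kind,
    gtf = sprintf("gencode.v%s.annotation.gtf.gz", release),
    gff3 = sprintf("gencode.v%s.annotation.gff3.gz", release),
    transcripts_fasta = sprintf("gencode.v%s.transcripts.fa.gz", release))
  paste(base, file, sep = "/")
}

#' Fetch a GENCODE reference file, with caching
#'
#' Downloads the requested annotation artifact to `cacheDir` unless a file
#' of the same name is already cached, in which case the cached path is
#' returned with no network activity.  Best-effort plumbing: the rest of the
#' toolkit never requires the network.
#'
#' @inheritParams gencodeReferenceUrl
#' @param cacheDir directory for downloaded files (created if absent).
#' @return local file path of the (possibly cached) reference.
#' @export
fetchReference <- function(species = c("human", "mouse"), release,
                           kind = c("gtf", "gff3", "transcripts_fasta"),
                           cacheDir = tempdir()) {
  species <- match.arg(species)
  kind <- match.arg(kind)
  url <- gencodeReferenceUrl(species, release, kind)
  if (!dir.exists(cacheDir))
    dir.create(cacheDir, recursive = TRUE)
  dest <- file.path(cacheDir, basename(url))
  if (file.exists(dest))
    return(dest)
  status <- tryCatch(
    utils::download.file(url, dest, mode = "wb", quiet = TRUE),
    error = function(e) e, warning = function(w) w)
  if (!identical(status, 0L) || !file.exists(dest)) {
    if (file.exists(dest)) unlink(dest)
    stop("failed to download reference from ", url)
  }
  dest
}
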