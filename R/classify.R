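#' Construct a significance threshold policy
#'
#' By default, transcripts at coding loci (protein_coding, retained_intron,
#' nonsense_mediated_decay, CDS_undefined) require an absolute log2
#' fold-change of at least 1 and a q-value below 0.05, while lncRNA
#' transcripts use the relaxed fold-change bound of 0.5 (lncRNAs are
#' expressed at lower levels than mRNAs, and the strict bound would discard
#' biologically relevant isoforms).  Unlisted categories fall back to the
#' `"other"` row, which carries the coding defaults.
#'
#' @param overrides optional data.frame with columns \code{category},
#'   \code{min_abs_log2fc}, \code{max_qvalue}; listed categories replace or
#'   extend the defaults.
#' @return a [ThresholdPolicy-class].
#' @export
thresholdPolicy <- function(overrides = NULL) {
  th <- data.frame(
    category = c("protein_coding", "retained_intron",
                 "nonsense_mediated_decay", "CDS_undefined", "lncRNA",
                 "other"),
    min_abs_log2fc = c(1, 1, 1, 1, 0.5, 1),
    max_qvalue = rep(0.05, 6),
    stringsAsFactors = FALSE)
  if (!is.null(overrides)) {
    stopifnot(all(c("category", "min_abs_log2fc", "max_qvalue") %in%
                    names(overrides)))
    hit <- match(overrides$category, th$category)
    th[hit[!is.na(hit)], c("min_abs_log2fc", "max_qvalue")] <-
      overrides[!is.na(hit), c("min_abs_log2fc", "max_qvalue")]
    extra <- overrides[is.na(hit),
                       c("category", "min_abs_log2fc", "max_qvalue")]
    th <- rbind(th, extra)
  }
  methods::new("ThresholdPolicy", thresholds = th)
}

#' Thresholds for a vector of categories
#'
#' @param policy a [ThresholdPolicy-class].
#' @param categories character vector of biotype categories; unknown
#'   categories use the `"other"` row.
#' @return data.frame with columns \code{min_abs_log2fc},
#'   \code{max_qvalue} aligned to `categories`.
#' @export
policyFor <- function(policy, categories) {
  stopifnot(is(policy, "ThresholdPolicy"))
  th <- policy@thresholds
  idx <- match(categories, th$category)
  idx[is.na(idx)] <- match("other", th$category)
  th[idx, c("min_abs_log2fc", "max_qvalue"), drop = FALSE]
}

#' Read a differential-expression table from TSV
#'
#' Expects columns \code{transcript_id} (or \code{gene_id} for gene-level
#' tables, exposed as \code{feature_id}), \code{log2fc}, \code{pvalue},
#' \code{qvalue}, and optionally \code{contrast}.  Lines starting with `#`
#' (provenance headers) are skipped.
#'
#' @param path TSV path.
#' @param feature \code{"transcript"} or \code{"gene"}: which id column to
#'   expect.
#' @return data.frame with a \code{feature_id} column first.
#' @export
readDeTable <- function(path, feature = c("transcript", "gene")) {
  feature <- match.arg(feature)
  idcol <- paste0(feature, "_id")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c(idcol, "log2fc", "qvalue")
  if (!all(need %in% names(tab)))
    stop("DE table must have columns: ", paste(need, collapse = ", "))
  names(tab)[names(tab) == idcol] <- "feature_id"
  tab
}

#' Drop transcripts collapsed into equivalence clusters
#'
#' Transcripts that an upstream collapser grouped into near-identical
#' clusters (because short reads cannot distinguish them) are removed from
#' the DE input before interpretation, avoiding spurious transcript-level
#' calls.  Membership ids absent from the table are ignored with a warning.
#'
#' @param deRows DE table with a \code{feature_id} column.
#' @param clusterMembership data.frame with columns \code{transcript_id},
#'   \code{cluster_id} (or `NULL` / empty for a no-op).
#' @return the filtered DE table; a removal report (rows dropped / kept) is
#'   emitted as a message.
#' @export
removeCollapsedClusters <- function(deRows, clusterMembership = NULL) {
  stopifnot("feature_id" %in% names(deRows))
  if (is.null(clusterMembership) || nrow(clusterMembership) == 0) {
    message("cluster removal: 0 rows dropped, ", nrow(deRows), " kept")
    return(deRows)
  }
  stopifnot("transcript_id" %in% names(clusterMembership))
  member <- unique(stripVersion(clusterMembership$transcript_id))
  hit <- stripVersion(deRows$feature_id) %in% member
  absent <- setdiff(member, stripVersion(deRows$feature_id))
  if (length(absent) > 0)
    warning(sprintf(
      "%d clustered transcript(s) not present in the DE table were ignored",
      length(absent)))
  out <- deRows[!hit, , drop = FALSE]
  message(sprintf("cluster removal: %d rows dropped, %d kept",
                  sum(hit), nrow(out)))
  rownames(out) <- NULL
  out
}

#' Flag significance under a biotype-aware threshold policy
#'
#' A row is significant when its absolute log2 fold-change reaches the
#' category's bound (inclusive) and its q-value is strictly below the
#' category's q-value bound.  Rows with a missing q-value are flagged not
#' significant and counted in a warning.
#'
#' @param rows data.frame with columns \code{log2fc}, \code{qvalue} and
#'   \code{biotype_category} (absent categories are treated as `"other"`).
#' @param policy a [ThresholdPolicy-class].
#' @return `rows` with a logical \code{is_significant} column set.
#' @export
flagSignificance <- function(rows, policy = thresholdPolicy()) {
  stopifnot(all(c("log2fc", "qvalue") %in% names(rows)))
  cat <- if ("biotype_category" %in% names(rows)) rows$biotype_category
         else rep("other", nrow(rows))
  cat[is.na(cat)] <- "other"
  th <- policyFor(policy, cat)
  sig <- abs(rows$log2fc) >= th$min_abs_log2fc & rows$qvalue < th$max_qvalue
  nNA <- sum(is.na(sig))
  if (nNA > 0) {
    warning(sprintf(
      "%d row(s) with missing log2fc/qvalue flagged not significant", nNA))
    sig[is.na(sig)] <- FALSE
  }
  rows$is_significant <- sig
  rows
}

#' Join a transcript DE table to the annotation dictionary
#'
#' Matches transcript accessions through the dictionary's version-stripped
#' index, attaches gene ids, display names and biotype categories, then
#' applies [flagSignificance()].  Transcripts absent from the dictionary get
#' the category `"unannotated"` (flagged under the `"other"` thresholds); if
#' more than half of the rows fail to match, a loud warning suggests the
#' wrong reference was used.
#'
#' @param deRows DE table with a \code{feature_id} column (transcript
#'   accessions).
#' @param dict a [TxDictionary-class].
#' @param policy a [ThresholdPolicy-class].
#' @return data.frame of annotated DE records: the DE columns plus
#'   \code{transcript_id}, \code{gene_id}, \code{gene_name},
#'   \code{transcript_name}, \code{biotype}, \code{biotype_category},
#'   \code{is_significant}.
#' @export
annotateDeTable <- function(deRows, dict, policy = thresholdPolicy()) {
  stopifnot("feature_id" %in% names(deRows), is(dict, "TxDictionary"))
  ann <- txLookup(dict, deRows$feature_id)
  unmatched <- is.na(ann$transcript_id)
  if (any(unmatched)) {
    frac <- mean(unmatched)
    msg <- sprintf("%d/%d DE transcript(s) not found in the dictionary",
                   sum(unmatched), nrow(deRows))
    if (frac > 0.5)
      warning(msg, " (more than half unmatched: is this the right reference?)")
    else
      message(msg)
  }
  out <- deRows
  out$transcript_id <- deRows$feature_id
  out$gene_id <- ann$gene_id
  out$gene_name <- ann$gene_name
  out$transcript_name <- ann$transcript_name
  out$biotype <- ann$biotype
  out$biotype_category <- ann$biotype_category
  out$biotype_category[unmatched] <- "unannotated"
  flagSignificance(out, policy)
}

#' Isoform-switch candidates: significant transcripts of non-significant genes
#'
#' Emits the transcript rows flagged significant whose parent gene is not
#' flagged significant in the gene-level table — the signature of an isoform
#' switch or transcript-level regulatory event invisible to gene-level
#' analysis.  Genes absent from the gene table are treated as not
#' differentially expressed but recorded as `"untested"` so users can
#' filter.  When a \code{contrast} column is present in both tables the
#' comparison is made per contrast.
#'
#' @param txRows annotated transcript table from [annotateDeTable()]
#'   (\code{is_significant} set).
#' @param geneRows gene-level DE table with \code{feature_id},
#'   \code{log2fc}, \code{qvalue} and \code{is_significant} (flag it with
#'   [flagSignificance()]; genes conventionally use the coding-locus
#'   thresholds).
#' @return data.frame with columns \code{transcript_id}, \code{gene_id},
#'   \code{gene_name}, \code{transcript_name}, \code{biotype},
#'   \code{log2fc}, \code{qvalue}, \code{gene_log2fc}, \code{gene_qvalue},
#'   \code{gene_is_significant} (\code{"yes"}, \code{"no"} or
#'   \code{"untested"}) and \code{contrast}; only rows with
#'   \code{gene_is_significant != "yes"} are returned.
#' @export
detWithoutDeg <- function(txRows, geneRows) {
  stopifnot("is_significant" %in% names(txRows),
            "is_significant" %in% names(geneRows))
  hasContrast <- "contrast" %in% names(txRows) &&
    "contrast" %in% names(geneRows)
  txKey <- stripVersion(txRows$gene_id)
  gKey <- stripVersion(geneRows$feature_id)
  if (hasContrast) {
    txKey <- paste(txKey, txRows$contrast, sep = "\r")
    gKey <- paste(gKey, geneRows$contrast, sep = "\r")
  }
  hit <- match(txKey, gKey)
  geneSig <- ifelse(is.na(hit), "untested",
                    ifelse(geneRows$is_significant[hit], "yes", "no"))
  keep <- txRows$is_significant & geneSig != "yes"
  out <- data.frame(
    transcript_id = txRows$transcript_id[keep],
    gene_id = txRows$gene_id[keep],
    gene_name = txRows$gene_name[keep],
    transcript_name = txRows$transcript_name[keep],
    biotype = txRows$biotype[keep],
    log2fc = txRows$log2fc[keep],
    qvalue = txRows$qvalue[keep],
    gene_log2fc = geneRows$log2fc[hit[keep]],
    gene_qvalue = geneRows$qvalue[hit[keep]],
    gene_is_significant = geneSig[keep],
    contrast = if (hasContrast) txRows$contrast[keep]
               else rep(NA_character_, sum(keep)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
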