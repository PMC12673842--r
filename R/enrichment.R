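#' Read a GMT gene-set file
#'
#' One set per tab-separated line: name, description, then member genes.
#' Duplicate members within a line are deduplicated and empty member tokens
#' dropped.
#'
#' @param path GMT path.
#' @return named list of gene sets, each a list with elements \code{name},
#'   \code{description}, \code{members} (character vector).
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(structure(list(), names = character(0)))
  out <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop(sprintf("GMT line %d: expected >= 3 tab-separated fields, found %d",
                   i, length(fields)))
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0)
      stop(sprintf("GMT line %d: set '%s' has no members", i, fields[1]))
    nms[i] <- fields[1]
    out[[i]] <- list(name = fields[1], description = fields[2],
                     members = members)
  }
  if (anyDuplicated(nms))
    stop("duplicate gene-set name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(out) <- nms
  out
}

#' Write gene sets to GMT
#'
#' @param gmt named list of sets as returned by [readGmt()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGmt <- function(gmt, path) {
  lines <- vapply(gmt, function(s)
    paste(c(s$name, s$description, s$members), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Categories composing an enrichment stratum
#'
#' Strata are single biotype categories, except \code{"non_coding_group"},
#' which pools the three alternative-processing categories
#' (see [nonCodingGroupCategories()]).
#'
#' @param stratum stratum label.
#' @return character vector of biotype categories.
#' @export
stratumCategories <- function(stratum) {
  known <- c("protein_coding", "retained_intron", "nonsense_mediated_decay",
             "CDS_undefined", "lncRNA", "other")
  if (stratum == "non_coding_group")
    return(nonCodingGroupCategories())
  if (!stratum %in% known)
    stop("unknown stratum: ", stratum)
  stratum
}

#' Project gene-level sets onto transcripts of one biotype stratum
#'
#' Each gene set's members (gene symbols or gene accessions, versioned or
#' not) are replaced by all transcripts of those genes whose biotype
#' category belongs to the stratum.  Sets retaining fewer than `minSize`
#' transcripts are dropped; member symbols matching nothing in the
#' dictionary are skipped per set and counted globally in a message.
#'
#' @param gmt named list of gene sets from [readGmt()].
#' @param dict a [TxDictionary-class].
#' @param stratum stratum label (a biotype category or
#'   \code{"non_coding_group"}).
#' @param minSize minimum surviving transcripts per set (>= 1).
#' @return list with elements \code{stratum} and \code{sets} (named list of
#'   transcript-id character vectors).
#' @export
expandGeneSets <- function(gmt, dict, stratum, minSize = 5) {
  stopifnot(is(dict, "TxDictionary"), minSize >= 1)
  cats <- stratumCategories(stratum)
  rec <- dict@records
  inStratum <- rec$biotype_category %in% cats
  geneKeys <- c(rec$gene_name, stripVersion(rec$gene_id))
  nUnmatched <- 0L
  sets <- list()
  dropped <- character(0)
  for (s in gmt) {
    hitName <- s$members %in% rec$gene_name |
      stripVersion(s$members) %in% stripVersion(rec$gene_id)
    nUnmatched <- nUnmatched + sum(!hitName)
    genes <- s$members[hitName]
    sel <- inStratum & (rec$gene_name %in% genes |
                          stripVersion(rec$gene_id) %in% stripVersion(genes))
    txs <- rec$transcript_id[sel]
    if (length(txs) >= minSize)
      sets[[s$name]] <- txs
    else
      dropped <- c(dropped, s$name)
  }
  if (nUnmatched > 0)
    message(sprintf("%d gene symbol(s) across sets matched nothing in the dictionary",
                    nUnmatched))
  if (length(dropped) > 0)
    message(sprintf("stratum %s: dropped %d set(s) below min size %d",
                    stratum, length(dropped), minSize))
  list(stratum = stratum, sets = sets)
}

#' Rank the transcripts of a stratum for preranked enrichment
#'
#' Restricts the annotated DE table to the stratum's biotype categories and
#' orders it by log2 fold-change (descending), breaking ties by ascending
#' q-value and then lexicographic transcript id, so the ranking is fully
#' deterministic.  All tested transcripts of the stratum enter the list —
#' a preranked walk needs the full background, not only the significant
#' rows.
#'
#' @param annotated annotated DE table from [annotateDeTable()].
#' @param stratum stratum label.
#' @return data.frame with columns \code{transcript_id}, \code{stat}
#'   (the log2 fold-change), ordered head-of-list first; empty when the
#'   stratum has no rows.
#' @export
rankTranscripts <- function(annotated, stratum) {
  stopifnot(all(c("transcript_id", "log2fc", "qvalue") %in% names(annotated)))
  cats <- stratumCategories(stratum)
  rows <- annotated[annotated$biotype_category %in% cats, , drop = FALSE]
  if (nrow(rows) == 0)
    return(data.frame(transcript_id = character(0), stat = numeric(0),
                      stringsAsFactors = FALSE))
  ord <- order(-rows$log2fc, rows$qvalue, rows$transcript_id,
               method = "radix")
  out <- data.frame(transcript_id = rows$transcript_id[ord],
                    stat = rows$log2fc[ord], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list once: at each set member ("hit") the running sum
#' increases by \eqn{|s_i|^p / \sum_{hits} |s|^p}, at each non-member it
#' decreases by \eqn{1 / (N - N_h)}.  With `weightExponent = 0` every hit
#' contributes \eqn{1 / N_h}.  The enrichment score is the running-sum value
#' of maximal absolute deviation from zero (signed; the first such position
#' on ties).
#'
#' @param ranked data.frame from [rankTranscripts()] (columns
#'   \code{transcript_id}, \code{stat}).
#' @param memberIds transcript ids of the set (versions ignored for
#'   matching).
#' @param weightExponent non-negative hit weight exponent (default 1).
#' @return list with elements \code{es}, \code{runningSum} (length-N
#'   profile), \code{hits} (logical length-N), \code{peak} (index of the
#'   extreme).
#' @export
enrichmentScore <- function(ranked, memberIds, weightExponent = 1) {
  stopifnot(weightExponent >= 0)
  n <- nrow(ranked)
  hits <- stripVersion(ranked$transcript_id) %in%
    unique(stripVersion(memberIds))
  nh <- sum(hits)
  if (nh == 0)
    stop("no set member present in the ranked list")
  if (nh == n)
    stop("set covers the whole ranked list; miss decrement undefined")
  w <- abs(ranked$stat)^weightExponent
  nr <- sum(w[hits])
  if (nr == 0)
    stop("all hit statistics are zero; hit increment undefined")
  inc <- rep(-1 / (n - nh), n)
  inc[hits] <- w[hits] / nr
  rs <- .walkRunningSum(inc)
  peak <- which.max(abs(rs))
  list(es = rs[peak], runningSum = rs, hits = hits, peak = peak)
}

# ES from sorted hit positions; delegates to the compiled walk, whose
# arithmetic is bit-identical to enrichmentScore(), so null and observed
# scores are directly comparable without tolerance.
.esFromHits <- function(hitPos, w, n) {
  .walkEsFromHits(as.integer(hitPos), w, as.integer(n))
}

#' Permutation p-value and normalized enrichment score
#'
#' The null distribution is built from `nPerm` random member sets of the
#' same size drawn without replacement from the ranked list.  The p-value is
#' one-sided on the observed score's sign with +1 smoothing:
#' \eqn{p = (1 + b) / (1 + B_s)} where \eqn{B_s} counts null scores of
#' matching sign and \eqn{b} those among them at least as extreme.  NES is
#' the observed score divided by the mean magnitude of the matching-sign
#' null scores, and is reported missing when that null is empty.
#'
#' @inheritParams enrichmentScore
#' @param nPerm number of permutations (>= 1).
#' @param seed integer seed, or `NULL` to draw from the current RNG state
#'   (used by [runEnrichment()], which seeds once per run).
#' @return list with elements \code{es}, \code{pvalue}, \code{nes},
#'   \code{nPerm}, \code{nMatchingSign}.
#' @export
permutationPvalue <- function(ranked, memberIds, weightExponent = 1,
                              nPerm = 1000, seed = NULL) {
  stopifnot(nPerm >= 1)
  obs <- enrichmentScore(ranked, memberIds, weightExponent)
  n <- nrow(ranked)
  k <- sum(obs$hits)
  w <- abs(ranked$stat)^weightExponent
  runPerms <- function() {
    vapply(seq_len(nPerm), function(i) {
      pos <- sort.int(sample.int(n, k))
      .esFromHits(pos, w, n)
    }, numeric(1))
  }
  nullEs <- if (is.null(seed)) runPerms() else .withSeed(seed, runPerms())
  if (obs$es == 0) {
    return(list(es = 0, pvalue = 1, nes = NA_real_, nPerm = nPerm,
                nMatchingSign = 0L))
  }
  matching <- sign(nullEs) == sign(obs$es)
  b <- sum(matching & abs(nullEs) >= abs(obs$es))
  bs <- sum(matching)
  pvalue <- (1 + b) / (1 + bs)
  nes <- if (bs > 0) obs$es / mean(abs(nullEs[matching])) else NA_real_
  list(es = obs$es, pvalue = pvalue, nes = nes, nPerm = nPerm,
       nMatchingSign = as.integer(bs))
}

#' Transcript-type-stratified preranked enrichment
#'
#' For each requested stratum: projects the gene-level sets onto the
#' stratum's transcripts ([expandGeneSets()]), ranks all tested transcripts
#' of the stratum by log2 fold-change ([rankTranscripts()]), scores every
#' surviving set with the running-sum statistic, computes permutation
#' p-values, and adjusts them with Benjamini-Hochberg within the stratum
#' (strata answer different questions, so adjustment is not pooled across
#' them).  Sets whose intersection with the ranked list falls below
#' `minSize` (or covers the whole list) are skipped.
#'
#' @param annotated annotated DE table from [annotateDeTable()].
#' @param gmt named list of gene sets from [readGmt()].
#' @param dict a [TxDictionary-class].
#' @param strata character vector of stratum labels.
#' @param minSize minimum set size after expansion and intersection.
#' @param weightExponent hit weight exponent (default 1).
#' @param nPerm permutations per set.
#' @param seed integer seed; one RNG stream drives the whole run, so
#'   identical calls give identical tables.
#' @return data.frame with columns \code{stratum}, \code{pathway},
#'   \code{size}, \code{es}, \code{nes}, \code{pvalue}, \code{padj},
#'   \code{leading_edge} (comma-joined transcript ids), sorted by
#'   (stratum, padj, pathway).
#' @export
runEnrichment <- function(annotated, gmt, dict, strata = "protein_coding",
                          minSize = 5, weightExponent = 1, nPerm = 1000,
                          seed = 1) {
  stopifnot(length(strata) > 0)
  empty <- data.frame(stratum = character(0), pathway = character(0),
                      size = integer(0), es = numeric(0), nes = numeric(0),
                      pvalue = numeric(0), padj = numeric(0),
                      leading_edge = character(0), stringsAsFactors = FALSE)
  if (length(gmt) == 0)
    return(empty)
  .withSeed(seed, {
    res <- lapply(strata, function(stratum) {
      ranked <- rankTranscripts(annotated, stratum)
      if (nrow(ranked) == 0) {
        warning("stratum ", stratum, " has no ranked transcripts; skipping")
        return(empty)
      }
      expanded <- expandGeneSets(gmt, dict, stratum, minSize)
      rankedKeys <- stripVersion(ranked$transcript_id)
      rows <- lapply(names(expanded$sets), function(nm) {
        memberKeys <- unique(stripVersion(expanded$sets[[nm]]))
        sizeUsed <- sum(rankedKeys %in% memberKeys)
        if (sizeUsed < minSize || sizeUsed >= nrow(ranked))
          return(NULL)
        pp <- permutationPvalue(ranked, expanded$sets[[nm]],
                                weightExponent, nPerm, seed = NULL)
        sc <- enrichmentScore(ranked, expanded$sets[[nm]], weightExponent)
        hitPos <- which(sc$hits)
        lead <- if (sc$es >= 0) hitPos[hitPos <= sc$peak]
                else hitPos[hitPos >= sc$peak]
        data.frame(stratum = stratum, pathway = nm, size = sizeUsed,
                   es = sc$es, nes = pp$nes, pvalue = pp$pvalue,
                   padj = NA_real_,
                   leading_edge = paste(ranked$transcript_id[lead],
                                        collapse = ","),
                   stringsAsFactors = FALSE)
      })
      rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
      if (is.null(rows) || nrow(rows) == 0)
        return(empty)
      rows$padj <- stats::p.adjust(rows$pvalue, method = "BH")
      rows
    })
    out <- do.call(rbind, res)
    if (is.null(out) || nrow(out) == 0) {
      empty
    } else {
      out <- out[order(out$stratum, out$padj, out$pathway,
                       method = "radix"), , drop = FALSE]
      rownames(out) <- NULL
      out
    }
  })
}

#' Write an enrichment table to TSV
#'
#' @param res data.frame from [runEnrichment()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEnrichmentTable <- function(res, path) {
  utils::write.table(res, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
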