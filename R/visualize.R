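#' @importFrom rlang .data
NULL

.markRow <- function(mark_type, x, xend = x, y = 0, yend = y,
                     color_key = "default", opacity = 1, row = 0L,
                     label = NA_character_, facet = NA_character_) {
  data.frame(mark_type = mark_type, x = as.numeric(x),
             xend = as.numeric(xend), y = as.numeric(y),
             yend = as.numeric(yend), color_key = color_key,
             opacity = as.numeric(opacity), row = as.integer(row),
             label = label, facet = facet, stringsAsFactors = FALSE)
}

.newPlotModel <- function(kind, marks, legend = character(0), meta = list()) {
  rownames(marks) <- NULL
  methods::new("PlotModel", kind = kind, marks = marks, legend = legend,
               meta = meta)
}

#' Fold-change profile model for one gene
#'
#' One bar per isoform plus one bar for the gene itself, showing the log2
#' fold-change of each.  Bars are coloured by biotype category (the gene bar
#' uses the reserved key `"gene"`); non-significant bars are drawn at
#' opacity 0.3 against 1.0 for significant ones, so significance is read
#' directly off the display.  When the tables carry a \code{contrast}
#' column, one facet is built per contrast.  A gene present in the
#' transcript table but absent from the gene-level table is drawn as a
#' zero-height bar with the distinct key `"gene_untested"`.
#'
#' @param geneName gene display name.
#' @param txRows annotated transcript DE table ([annotateDeTable()] output).
#' @param geneRows gene-level DE table flagged by [flagSignificance()]
#'   (column \code{feature_id} holds gene accessions).
#' @return a [PlotModel-class] of kind `"fc_profile"`.
#' @export
buildFcProfileModel <- function(geneName, txRows, geneRows) {
  stopifnot(all(c("gene_name", "transcript_name", "biotype_category",
                  "log2fc", "is_significant") %in% names(txRows)))
  sub <- txRows[!is.na(txRows$gene_name) & txRows$gene_name == geneName, ,
                drop = FALSE]
  if (nrow(sub) == 0)
    stop("gene not present in the transcript table: ", geneName)
  hasContrast <- "contrast" %in% names(sub)
  facets <- if (hasContrast) unique(sub$contrast) else NA_character_
  geneKey <- unique(stripVersion(sub$gene_id))
  marks <- do.call(rbind, lapply(facets, function(fc) {
    rows <- if (hasContrast) sub[sub$contrast == fc, , drop = FALSE] else sub
    rows <- rows[order(rows$transcript_name, method = "radix"), ,
                 drop = FALSE]
    iso <- .markRow("bar",
                    x = seq_len(nrow(rows)), y = 0, yend = rows$log2fc,
                    color_key = rows$biotype_category,
                    opacity = ifelse(rows$is_significant, 1, 0.3),
                    label = rows$transcript_name, facet = fc)
    g <- geneRows
    if (hasContrast && "contrast" %in% names(g))
      g <- g[g$contrast == fc, , drop = FALSE]
    hit <- match(geneKey, stripVersion(g$feature_id))
    gbar <- if (!is.na(hit)) {
      .markRow("bar", x = nrow(rows) + 1, y = 0, yend = g$log2fc[hit],
               color_key = "gene",
               opacity = if (g$is_significant[hit]) 1 else 0.3,
               label = geneName, facet = fc)
    } else {
      .markRow("bar", x = nrow(rows) + 1, y = 0, yend = 0,
               color_key = "gene_untested", opacity = 1,
               label = geneName, facet = fc)
    }
    rbind(iso, gbar)
  }))
  keys <- setdiff(unique(marks$color_key), character(0))
  legend <- stats::setNames(keys, keys)
  .newPlotModel("fc_profile", marks, legend,
                meta = list(gene = geneName, ylab = "log2 fold-change"))
}

#' Expression (TPM) profile model for one gene
#'
#' For every isoform of the gene present in the TPM matrix, computes the
#' mean TPM per sample group and the sample standard deviation (n-1
#' denominator), and emits one polyline per isoform connecting the group
#' means plus one vertical whisker per (isoform, group) spanning mean
#' plus/minus one SD.  Groups appear in the order given by `sampleGroups`.
#'
#' @param geneName gene display name.
#' @param tpm numeric matrix, transcripts in rows (rownames are transcript
#'   accessions), samples in columns.
#' @param sampleGroups data.frame with columns \code{sample}, \code{group};
#'   every column of `tpm` must be assigned to a group.
#' @param dict a [TxDictionary-class], used to find the gene's isoforms.
#' @return a [PlotModel-class] of kind `"expression_profile"`.
#' @export
buildExpressionProfileModel <- function(geneName, tpm, sampleGroups, dict) {
  stopifnot(is.matrix(tpm), all(c("sample", "group") %in% names(sampleGroups)))
  unmapped <- setdiff(colnames(tpm), sampleGroups$sample)
  if (length(unmapped) > 0)
    stop("sample(s) in the TPM matrix missing from the group map: ",
         paste(unmapped, collapse = ", "))
  ann <- txLookup(dict, rownames(tpm))
  sel <- which(!is.na(ann$gene_name) & ann$gene_name == geneName)
  if (length(sel) == 0)
    stop("no isoform of gene ", geneName, " in the TPM matrix")
  groups <- unique(sampleGroups$group)
  marks <- do.call(rbind, lapply(sel, function(i) {
    key <- ann$transcript_name[i]
    mns <- numeric(length(groups)); sds <- numeric(length(groups))
    for (g in seq_along(groups)) {
      samp <- sampleGroups$sample[sampleGroups$group == groups[g]]
      vals <- tpm[i, intersect(colnames(tpm), samp)]
      mns[g] <- mean(vals)
      sds[g] <- if (length(vals) > 1) stats::sd(vals) else 0
    }
    segs <- if (length(groups) > 1) {
      .markRow("line", x = seq_len(length(groups) - 1), y = mns[-length(mns)],
               xend = seq(2, length(groups)), yend = mns[-1],
               color_key = key, label = key)
    } else NULL
    whisk <- .markRow("whisker", x = seq_along(groups), y = mns - sds,
                      yend = mns + sds, color_key = key, label = key)
    rbind(segs, whisk)
  }))
  legend <- stats::setNames(ann$transcript_name[sel],
                            ann$transcript_name[sel])
  .newPlotModel("expression_profile", marks, legend,
                meta = list(gene = geneName, groups = groups,
                            ylab = "TPM"))
}

#' Genomic-context model: exon/intron structure of transcripts
#'
#' One horizontal row per transcript: exons as rectangles at their genomic
#' coordinates and introns as line segments spanning the gap between
#' consecutive exons (sorted by start).  Rows are ordered by transcript
#' genomic start, ascending — plus-strand models therefore read left to
#' right while minus-strand models have their 5' ends at the right — and
#' each row carries a label mark with the transcript name and biotype.
#'
#' @param exons exon [GenomicRanges::GRanges] (typically from
#'   [prepareExonAnnotation()]), single chromosome, non-empty.
#' @return a [PlotModel-class] of kind `"tx_context"`.
#' @export
buildTxContextModel <- function(exons) {
  stopifnot(is(exons, "GRanges"))
  if (length(exons) == 0)
    stop("no exons to plot")
  if (length(unique(as.character(GenomicRanges::seqnames(exons)))) > 1)
    stop("exons span more than one chromosome")
  mc <- S4Vectors::mcols(exons)
  txids <- unique(mc$transcript_id)
  txStart <- vapply(txids, function(tx)
    min(GenomicRanges::start(exons[mc$transcript_id == tx])), numeric(1))
  ord <- order(txStart, txids, method = "radix")
  txids <- txids[ord]
  marks <- do.call(rbind, lapply(seq_along(txids), function(r) {
    ex <- exons[mc$transcript_id == txids[r]]
    ex <- ex[order(GenomicRanges::start(ex))]
    exmc <- S4Vectors::mcols(ex)
    bt <- exmc$biotype[1]
    nm <- exmc$transcript_name[1]
    if (is.null(nm) || is.na(nm)) nm <- txids[r]
    key <- if (!is.null(bt) && !is.na(bt)) bt else "exon"
    row <- r - 1L
    rects <- .markRow("rect", x = GenomicRanges::start(ex),
                      xend = GenomicRanges::end(ex),
                      y = row - 0.35, yend = row + 0.35,
                      color_key = key, row = row)
    segs <- if (length(ex) > 1) {
      .markRow("segment",
               x = GenomicRanges::end(ex)[-length(ex)],
               xend = GenomicRanges::start(ex)[-1],
               y = row, yend = row, color_key = key, row = row)
    } else NULL
    strand <- as.character(GenomicRanges::strand(ex))[1]
    lab <- .markRow("label", x = min(GenomicRanges::start(ex)),
                    y = row + 0.45, color_key = key, row = row,
                    label = sprintf("%s (%s, %s)", nm, key, strand))
    rbind(rects, segs, lab)
  }))
  chrom <- as.character(GenomicRanges::seqnames(exons))[1]
  keys <- unique(marks$color_key)
  .newPlotModel("tx_context", marks, stats::setNames(keys, keys),
                meta = list(chrom = chrom, xlab = chrom))
}

#' Serialize a plot model to JSON
#'
#' @param model a [PlotModel-class].
#' @param path optional output path; when `NULL` the JSON string is
#'   returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
plotModelToJson <- function(model, path = NULL) {
  stopifnot(is(model, "PlotModel"))
  obj <- list(kind = model@kind, marks = model@marks,
              legend = as.list(model@legend), meta = model@meta)
  js <- jsonlite::toJSON(obj, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  if (is.null(path))
    return(js)
  writeLines(js, path)
  invisible(path)
}

#' Render a plot model to an image file
#'
#' A pure function of the model: no statistics are recomputed here; the
#' marks are translated one-to-one into \pkg{ggplot2} layers and written to
#' disk.
#'
#' @param model a [PlotModel-class] with at least one mark.
#' @param path output file path.
#' @param format `"png"`, `"svg"` or `"pdf"`.
#' @param width,height device size in inches.
#' @return `path`, invisibly.
#' @export
renderPlotModel <- function(model, path, format = c("png", "svg", "pdf"),
                            width = 7, height = 5) {
  stopifnot(is(model, "PlotModel"))
  format <- match.arg(format)
  m <- model@marks
  if (nrow(m) == 0)
    stop("cannot render a plot model with zero marks")
  p <- ggplot2::ggplot()
  bars <- m[m$mark_type == "bar", , drop = FALSE]
  if (nrow(bars) > 0)
    p <- p + ggplot2::geom_rect(
      data = bars,
      ggplot2::aes(xmin = .data$x - 0.4, xmax = .data$x + 0.4,
                   ymin = .data$y, ymax = .data$yend,
                   fill = .data$color_key, alpha = .data$opacity))
  rects <- m[m$mark_type == "rect", , drop = FALSE]
  if (nrow(rects) > 0)
    p <- p + ggplot2::geom_rect(
      data = rects,
      ggplot2::aes(xmin = .data$x, xmax = .data$xend, ymin = .data$y,
                   ymax = .data$yend, fill = .data$color_key,
                   alpha = .data$opacity))
  segs <- m[m$mark_type %in% c("line", "segment", "whisker"), , drop = FALSE]
  if (nrow(segs) > 0)
    p <- p + ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$y,
                   yend = .data$yend, colour = .data$color_key,
                   alpha = .data$opacity))
  labs <- m[m$mark_type == "label", , drop = FALSE]
  if (nrow(labs) > 0)
    p <- p + ggplot2::geom_text(
      data = labs,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
      hjust = 0, size = 3)
  p <- p + ggplot2::scale_alpha_identity() + ggplot2::theme_minimal()
  nFacet <- length(unique(m$facet[!is.na(m$facet)]))
  if (nFacet > 1)
    p <- p + ggplot2::facet_wrap(~facet)
  if (!is.null(model@meta$ylab))
    p <- p + ggplot2::ylab(model@meta$ylab)
  dev <- switch(format,
    png = function(f) grDevices::png(f, width = width, height = height,
                                     units = "in", res = 150),
    svg = function(f) grDevices::svg(f, width = width, height = height),
    pdf = function(f) grDevices::pdf(f, width = width, height = height))
  dev(path)
  tryCatch(print(p), finally = grDevices::dev.off())
  if (!file.exists(path))
    stop("failed to write image to ", path)
  invisible(path)
}
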