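#' @import methods
#' @importFrom S4Vectors mcols mcols<-
#' @importFrom Rcpp evalCpp
#' @useDynLib isoscope, .registration = TRUE
NULL

#' Transcript-to-gene dictionary
#'
#' An ordered table of transcript records (one row per transcript) together
#' with a version-insensitive lookup index.  Records carry the versioned
#' transcript and gene accessions, display names, transcript length in
#' nucleotides and the annotated transcript biotype, plus the normalized
#' biotype category used by the significance and enrichment machinery.
#'
#' Accession versions (the trailing \code{.N}) are preserved in storage; all
#' joins against the dictionary go through a secondary index keyed by the
#' version-stripped accession, because differential-expression tools variably
#' strip versions.
#'
#' @slot records data.frame with columns \code{transcript_id},
#'   \code{gene_id}, \code{transcript_name}, \code{gene_name}, \code{length},
#'   \code{biotype}, \code{biotype_category}.
#' @slot index named integer vector mapping version-stripped transcript
#'   accessions to row numbers of \code{records}.
#'
#' @seealso [makeTxToGene()], [txLookup()], [writeTxDictionary()]
#' @export
setClass("TxDictionary",
  representation(records = "data.frame", index = "integer"),
  validity = function(object) {
    rec <- object@records
    need <- c("transcript_id", "gene_id", "transcript_name", "gene_name",
              "length", "biotype", "biotype_category")
    if (!all(need %in% names(rec)))
      return(paste("records must have columns:", paste(need, collapse = ", ")))
    if (anyDuplicated(rec$transcript_id))
      return("duplicated transcript_id in dictionary")
    if (nrow(rec) > 0 && any(!nzchar(rec$transcript_id)))
      return("empty transcript_id")
    if (length(object@index) != nrow(rec))
      return("index length must equal number of records")
    TRUE
  }
)

#' Per-category significance thresholds
#'
#' Holds, for each transcript biotype category, the minimum absolute log2
#' fold-change and the maximum q-value a row must satisfy to be called
#' significant.  The boundary semantics are fixed: the fold-change bound is
#' inclusive (\eqn{|log2FC| \ge} threshold) and the q-value bound is strict
#' (\eqn{q <} threshold).
#'
#' @slot thresholds data.frame with columns \code{category},
#'   \code{min_abs_log2fc}, \code{max_qvalue}; must contain a row for
#'   category \code{"other"}, the fallback for categories not listed.
#'
#' @seealso [thresholdPolicy()], [flagSignificance()]
#' @export
setClass("ThresholdPolicy",
  representation(thresholds = "data.frame"),
  validity = function(object) {
    th <- object@thresholds
    need <- c("category", "min_abs_log2fc", "max_qvalue")
    if (!all(need %in% names(th)))
      return(paste("thresholds must have columns:", paste(need, collapse = ", ")))
    if (anyDuplicated(th$category))
      return("duplicated category in threshold table")
    if (!"other" %in% th$category)
      return("threshold table must include fallback category 'other'")
    if (any(th$min_abs_log2fc < 0))
      return("min_abs_log2fc must be >= 0")
    if (any(th$max_qvalue <= 0 | th$max_qvalue > 1))
      return("max_qvalue must be in (0, 1]")
    TRUE
  }
)

#' Declarative plot model
#'
#' A backend-agnostic description of one display: an ordered table of marks
#' (bars, line segments, whiskers, rectangles, labels) with geometry in data
#' units, a colour key, an opacity and a row index, plus optional facet
#' labels and a legend.  Statistics are computed when the model is built;
#' rendering is a pure function of the model.
#'
#' @slot kind one of \code{"fc_profile"}, \code{"expression_profile"},
#'   \code{"tx_context"}.
#' @slot marks data.frame with columns \code{mark_type} (bar, line, whisker,
#'   rect, segment, label), \code{x}, \code{xend}, \code{y}, \code{yend},
#'   \code{color_key}, \code{opacity}, \code{row}, \code{label},
#'   \code{facet}.
#' @slot legend named character vector mapping colour keys to display names.
#' @slot meta list of axis titles and other presentation hints.
#'
#' @seealso [buildFcProfileModel()], [buildExpressionProfileModel()],
#'   [buildTxContextModel()], [renderPlotModel()]
#' @export
setClass("PlotModel",
  representation(kind = "character", marks = "data.frame",
                 legend = "character", meta = "list"),
  validity = function(object) {
    if (length(object@kind) != 1L ||
        !object@kind %in% c("fc_profile", "expression_profile", "tx_context"))
      return("kind must be one of fc_profile, expression_profile, tx_context")
    m <- object@marks
    need <- c("mark_type", "x", "xend", "y", "yend", "color_key", "opacity",
              "row", "label", "facet")
    if (!all(need %in% names(m)))
      return(paste("marks must have columns:", paste(need, collapse = ", ")))
    if (nrow(m) > 0) {
      if (!all(m$mark_type %in% c("bar", "line", "whisker", "rect",
                                  "segment", "label")))
        return("unknown mark_type")
      geom <- c(m$x, m$xend, m$y, m$yend)
      if (any(!is.finite(geom)))
        return("mark geometry must be finite")
      if (any(m$opacity <= 0 | m$opacity > 1))
        return("opacity must be in (0, 1]")
      rows <- sort(unique(m$row))
      if (!identical(rows, seq_along(rows) - 1L) && !identical(rows, 0L))
        return("row indices must be contiguous from 0")
    }
    TRUE
  }
)

#' Simulation configuration for synthetic fixtures
#'
#' Parameters of the synthetic GENCODE-like reference, DE tables, TPM matrix
#' and GMT file generated by the fixtures simulator.  The seed is mandatory:
#' every simulator output is byte-deterministic given the configuration.
#'
#' @slot n_genes number of genes.
#' @slot tx_per_gene integer range (length 2) of transcripts per gene.
#' @slot biotype_props named numeric vector of biotype proportions summing
#'   to 1 (names are GENCODE biotype tokens).
#' @slot n_switch_genes number of genes with a planted isoform switch.
#' @slot switch_effect planted log2 fold-change of the switching isoform.
#' @slot n_gene_sets number of gene sets in the simulated GMT (including the
#'   planted switch set).
#' @slot samples_per_group samples per group in the TPM matrix.
#' @slot seed integer RNG seed.
#'
#' @seealso [simulationConfig()], [simulateAnnotation()]
#' @export
setClass("SimulationConfig",
  representation(n_genes = "integer", tx_per_gene = "integer",
                 biotype_props = "numeric", n_switch_genes = "integer",
                 switch_effect = "numeric", n_gene_sets = "integer",
                 samples_per_group = "integer", seed = "integer"),
  validity = function(object) {
    if (abs(sum(object@biotype_props) - 1) > 1e-9)
      return("biotype proportions must sum to 1")
    if (is.null(names(object@biotype_props)) ||
        any(!nzchar(names(object@biotype_props))))
      return("biotype proportions must be named by biotype")
    if (length(object@tx_per_gene) != 2L ||
        object@tx_per_gene[1] > object@tx_per_gene[2] ||
        object@tx_per_gene[1] < 1L)
      return("tx_per_gene must be an increasing integer range >= 1")
    if (object@n_genes < 1L || object@n_switch_genes < 0L ||
        object@n_gene_sets < 0L || object@samples_per_group < 1L)
      return("counts must be non-negative (n_genes, samples_per_group >= 1)")
    if (length(object@seed) != 1L || is.na(object@seed))
      return("seed is mandatory")
    TRUE
  }
)

setMethod("show", "TxDictionary", function(object) {
  rec <- object@records
  cat(sprintf("TxDictionary with %d transcripts / %d genes\n",
              nrow(rec), length(unique(rec$gene_id))))
  if (nrow(rec) > 0) {
    tab <- sort(table(rec$biotype_category), decreasing = TRUE)
    cat("  categories:",
        paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(object)
})

setMethod("show", "ThresholdPolicy", function(object) {
  cat("ThresholdPolicy (|log2FC| >= min, q < max):\n")
  print(object@thresholds, row.names = FALSE)
  invisible(object)
})

setMethod("show", "PlotModel", function(object) {
  cat(sprintf("PlotModel <%s>: %d marks", object@kind, nrow(object@marks)))
  fac <- unique(object@marks$facet)
  fac <- fac[!is.na(fac)]
  if (length(fac) > 0)
    cat(sprintf(", %d facet(s)", length(fac)))
  cat("\n")
  invisible(object)
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %d genes (%d-%d tx each), %d switch genes (log2FC %.1f), %d gene sets, %d samples/group, seed %d\n",
    object@n_genes, object@tx_per_gene[1], object@tx_per_gene[2],
    object@n_switch_genes, object@switch_effect, object@n_gene_sets,
    object@samples_per_group, object@seed))
  invisible(object)
})

#' Number of transcripts in a dictionary
#' @param x a [TxDictionary-class]
#' @return integer
#' @export
setMethod("length", "TxDictionary", function(x) nrow(x@records))

#' Dictionary records as a data.frame
#' @param x a [TxDictionary-class]
#' @param ... ignored
#' @return data.frame of transcript records
#' @export
setMethod("as.data.frame", "TxDictionary",
          function(x, ...) x@records)

#' Accessors for dictionary columns
#'
#' @param x a [TxDictionary-class]
#' @return character vector over the dictionary's records
#' @name dictionary-accessors
NULL

#' @rdname dictionary-accessors
#' @export
txIds <- function(x) x@records$transcript_id

#' @rdname dictionary-accessors
#' @export
geneIds <- function(x) x@records$gene_id

#' @rdname dictionary-accessors
#' @export
txCategories <- function(x) x@records$biotype_category

#' Marks of a plot model
#' @param model a [PlotModel-class]
#' @return data.frame of marks
#' @export
plotMarks <- function(model) {
  stopifnot(is(model, "PlotModel"))
  model@marks
}

#' Kind of a plot model
#' @param model a [PlotModel-class]
#' @return character scalar
#' @export
plotKind <- function(model) {
  stopifnot(is(model, "PlotModel"))
  model@kind
}
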