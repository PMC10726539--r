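# Accessors and show methods for the core classes.

#' @rdname FusionCallSet-class
#' @param object,x a FusionCallSet.
#' @export
setGeneric("fusionCalls", function(x) standardGeneric("fusionCalls"))

#' @rdname FusionCallSet-class
#' @export
setMethod("fusionCalls", "FusionCallSet", function(x) x@calls)

#' @rdname FusionCallSet-class
#' @export
setGeneric("caller", function(x) standardGeneric("caller"))

#' @rdname FusionCallSet-class
#' @export
setMethod("caller", "FusionCallSet", function(x) x@caller)

#' @rdname FusionCallSet-class
#' @export
setMethod("length", "FusionCallSet", function(x) nrow(x@calls))

#' @rdname FusionCallSet-class
#' @param i row index.
#' @param j,drop ignored.
#' @param ... ignored.
#' @export
setMethod("[", "FusionCallSet", function(x, i, j, ..., drop = FALSE) {
  initialize(x, calls = x@calls[i, , drop = FALSE], caller = x@caller)
})

setMethod("show", "FusionCallSet", function(object) {
  cat(sprintf("FusionCallSet with %d calls (%s)\n",
              length(object), object@caller))
  if (length(object)) {
    df <- object@calls
    cat(sprintf("  samples: %d | partner pairs: %d\n",
                length(unique(df$sample_id)),
                nrow(unique(df[, c("gene5", "gene3")]))))
  }
})

#' @rdname GeneAnnotation-class
#' @param x,object a GeneAnnotation.
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))

#' @rdname GeneAnnotation-class
#' @export
setMethod("geneRanges", "GeneAnnotation", function(x) x@genes)

#' @rdname GeneAnnotation-class
#' @export
setGeneric("exonsBySymbol", function(x) standardGeneric("exonsBySymbol"))

#' @rdname GeneAnnotation-class
#' @export
setMethod("exonsBySymbol", "GeneAnnotation", function(x) x@exons)

#' @rdname GeneAnnotation-class
#' @export
setMethod("length", "GeneAnnotation", function(x) length(x@genes))

setMethod("show", "GeneAnnotation", function(object) {
  cat(sprintf("GeneAnnotation with %d genes on %d sequence(s)\n",
              length(object@genes),
              length(GenomeInfoDb::seqlevels(object@genes))))
})

#' Look up one gene model by symbol
#'
#' @param annotation a [GeneAnnotation-class].
#' @param symbol gene symbol.
#' @return A length-1 GRanges for the gene (mcols carry flags and CDS
#'   bounds); errors if the symbol is unknown.
#' @export
lookupGene <- function(annotation, symbol) {
  g <- annotation@genes
  hit <- which(S4Vectors::mcols(g)$symbol == symbol)
  if (!length(hit))
    stop(sprintf("gene symbol not found in annotation: %s", symbol))
  g[hit[1L]]
}

setMethod("show", "FusionSimulation", function(object) {
  cat(sprintf(
    "FusionSimulation: %d chromosome(s) x %s bp, %d genes, %d planted fusions\n",
    length(object@genome),
    format(object@config@chrom_length, big.mark = ","),
    length(object@annotation), nrow(object@truth)))
})

setMethod("show", "ModelBundle", function(object) {
  cat(sprintf(
    "ModelBundle: %d encoded features, threshold %.3f, %d tuning candidates\n",
    length(object@feature_names), object@threshold, nrow(object@tuning)))
})

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport\n")
  cat(sprintf("  confusion: TP=%d FN=%d FP=%d TN=%d\n",
              object@tp, object@fn, object@fp, object@tn))
  cat(sprintf(
    "  precision=%.3f recall=%.3f specificity=%.3f accuracy=%.3f f1=%.3f kappa=%.3f\n",
    object@precision, object@recall, object@specificity, object@accuracy,
    object@f1, object@kappa))
  if (object@has_probabilities)
    cat(sprintf("  log_loss=%.3f roc_auc=%.3f pr_auc=%.3f brier=%.3f\n",
                object@log_loss, object@roc_auc, object@pr_auc, object@brier))
  if (length(object@degenerate))
    cat(sprintf("  defined-0 metrics: %s\n",
                paste(object@degenerate, collapse = ", ")))
})

#' Flatten a MetricsReport to a one-row data.frame
#'
#' @param x a [MetricsReport-class].
#' @param row.names,optional,... passed conventions of as.data.frame;
#'   ignored.
#' @return One-row data.frame of all metric fields.
#' @export
as.data.frame.MetricsReport <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  data.frame(
    tp = x@tp, fn = x@fn, fp = x@fp, tn = x@tn,
    precision = x@precision, recall = x@recall,
    specificity = x@specificity, accuracy = x@accuracy,
    f1 = x@f1, kappa = x@kappa, log_loss = x@log_loss,
    roc_auc = x@roc_auc, pr_auc = x@pr_auc, brier = x@brier,
    stringsAsFactors = FALSE)
}
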