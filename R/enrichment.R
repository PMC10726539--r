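# Binomial (sampling-with-replacement) gene-set over-representation for
# fusion partner genes. The same gene can recur across fusion events, so
# the draw is modeled with replacement -- a binomial tail -- rather than
# the hypergeometric of classic over-representation tests.

#' Define the expressed-gene universe
#'
#' A gene enters the universe iff its per-gene FPKM quantile across
#' samples, at the given percentile (linear interpolation), reaches
#' `min_fpkm`.
#'
#' @param expression FPKM matrix or data.frame, genes in rows (rownames =
#'   symbols), samples in columns.
#' @param percentile percentile in (0, 100] (default 95).
#' @param min_fpkm inclusion threshold (default 1.0).
#' @return Character vector of gene symbols.
#' @export
defineUniverse <- function(expression, percentile = 95, min_fpkm = 1.0) {
  expr <- as.matrix(expression)
  if (!nrow(expr) || !ncol(expr)) stop("empty expression table")
  q <- apply(expr, 1L, stats::quantile, probs = percentile / 100,
             names = FALSE, type = 7)
  rownames(expr)[q >= min_fpkm]
}

#' Binomial gene-set over-representation
#'
#' For a gene list drawn with multiplicity (one entry per fusion event a
#' gene participates in), each set's hit probability is its share of the
#' universe, `p_set = |set ∩ universe| / |universe|`; the list's `k` hits
#' among its `n` entries are then tested against the upper binomial tail
#' `P(X >= k), X ~ Binomial(n, p_set)`. Benjamini-Hochberg correction is
#' applied across the sets of each call (run strata -- cancer type by
#' fusion-partner side -- as separate calls). List entries outside the
#' universe are dropped with a message.
#'
#' @param gene_list character vector with multiplicity.
#' @param gene_sets named list of character vectors.
#' @param universe character vector from [defineUniverse()].
#' @return data.frame: `set`, `k`, `n`, `p_set`, `p_value`, `q_value`.
#' @export
binomialEnrichment <- function(gene_list, gene_sets, universe) {
  if (!length(universe)) stop("empty universe")
  if (!length(gene_list)) stop("empty gene list")
  universe <- unique(universe)
  outside <- !(gene_list %in% universe)
  if (any(outside)) {
    message(sprintf("dropping %d gene-list entries outside the universe",
                    sum(outside)))
    gene_list <- gene_list[!outside]
    if (!length(gene_list)) stop("no gene-list entries left in universe")
  }
  n <- length(gene_list)
  rows <- lapply(names(gene_sets), function(nm) {
    set_in_u <- intersect(unique(gene_sets[[nm]]), universe)
    p_set <- length(set_in_u) / length(universe)
    k <- sum(gene_list %in% set_in_u)
    p <- if (k == 0L) 1 else stats::pbinom(k - 1L, n, p_set,
                                           lower.tail = FALSE)
    data.frame(set = nm, k = k, n = n, p_set = p_set, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Read gene sets from a GMT file
#'
#' @param path GMT path (set name, description, then member genes,
#'   tab-separated).
#' @return Named list of character vectors.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])),
                  vapply(parts, `[`, character(1), 1L))
}
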