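# RNA-only feature construction for classification. Three feature
# categories: chimeric-mRNA evidence from the caller, expression of the
# two partners, and general genomic annotation. No WGS-derived field may
# appear here -- the whole point is that the classifier runs on samples
# without WGS data.

#' Build RNA-only feature vectors for a call set
#'
#' One row per call. Missing information stays `NA` (never silently 0):
#' expression is `NA` when a partner is absent from the table,
#' `genomic_distance` exists only for same-chromosome fusions, and
#' annotation-derived fields are `NA` when a partner symbol cannot be
#' resolved (such rows are flagged `incomplete`).
#'
#' @param x a [FusionCallSet-class] (pre-filtered).
#' @param annotation a [GeneAnnotation-class].
#' @param expression FPKM matrix (genes x samples) or data.frame with
#'   rownames = gene symbols; the column matching each call's sample is
#'   used, falling back to the first column.
#' @param repeats GRanges repeat track (mcols `repeat_class`) or NULL.
#' @param epsilon pseudo-count for the log2 expression ratio
#'   (default 0.01).
#' @param repeat_window bp around the junction checked for repeat overlap
#'   (default 10).
#' @return data.frame of feature columns plus a list column `tags`; the
#'   `confidence` column is kept only for arriba-like call sets.
#' @export
buildFeatureVectors <- function(x, annotation, expression = NULL,
                                repeats = NULL, epsilon = 0.01,
                                repeat_window = 10) {
  df <- fusionCalls(x)
  n <- nrow(df)
  genes <- geneRanges(annotation)
  mc <- S4Vectors::mcols(genes)
  gidx <- function(sym) match(sym, mc$symbol)
  i5 <- gidx(df$gene5); i3 <- gidx(df$gene3)
  incomplete <- is.na(i5) | is.na(i3)

  fpkm_of <- function(sym, sample) {
    if (is.null(expression)) return(rep(NA_real_, length(sym)))
    expr <- as.matrix(expression)
    col <- match(sample, colnames(expr))
    col[is.na(col)] <- 1L
    ridx <- match(sym, rownames(expr))
    out <- rep(NA_real_, length(sym))
    ok <- !is.na(ridx)
    out[ok] <- expr[cbind(ridx[ok], col[ok])]
    out
  }
  fpkm5 <- fpkm_of(df$gene5, df$sample_id)
  fpkm3 <- fpkm_of(df$gene3, df$sample_id)

  gene_field <- function(idx, getter) {
    out <- rep(NA, length(idx))
    ok <- !is.na(idx)
    out[ok] <- getter(idx[ok])
    out
  }
  glen <- GenomicRanges::width(genes)
  nexon <- vapply(mc$symbol, function(s)
    length(annotation@exons[[s]]), integer(1))

  rep_overlap <- function(chrom, pos) {
    if (is.null(repeats)) return(rep(NA, length(pos)))
    gr <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(pmax(1, pos - repeat_window),
                              pos + repeat_window))
    GenomeInfoDb::seqlevels(gr) <-
      union(GenomeInfoDb::seqlevels(gr), GenomeInfoDb::seqlevels(repeats))
    IRanges::overlapsAny(gr, repeats)
  }

  same_chrom <- df$chrom5 == df$chrom3
  out <- data.frame(
    sample_id = df$sample_id, gene5 = df$gene5, gene3 = df$gene3,
    spanning_pairs = df$spanning_pairs,
    spanning_unique_reads = df$spanning_unique_reads,
    longest_anchor = df$longest_anchor,
    predicted_effect = df$predicted_effect,
    n_remaining_tags = vapply(df$tags, length, integer(1)),
    known_db_flag = vapply(df$tags, function(t)
      any(tolower(t) %in% c("known", "cosmic", "chimerdb", "cgp", "ticdb",
                            "oncogene", "18cancers")), logical(1)),
    fpkm5 = fpkm5, fpkm3 = fpkm3,
    log_expr_ratio = log2((fpkm5 + epsilon) / (fpkm3 + epsilon)),
    same_chromosome = same_chrom,
    genomic_distance = ifelse(same_chrom, abs(df$pos3 - df$pos5),
                              NA_integer_),
    strand_combination = paste0(df$strand5, df$strand3),
    gene_length5 = gene_field(i5, function(i) glen[i]),
    gene_length3 = gene_field(i3, function(i) glen[i]),
    n_exons5 = gene_field(i5, function(i) nexon[i]),
    n_exons3 = gene_field(i3, function(i) nexon[i]),
    in_cosmic5 = gene_field(i5, function(i) mc$in_cosmic[i]),
    in_cosmic3 = gene_field(i3, function(i) mc$in_cosmic[i]),
    is_mirna_host5 = gene_field(i5, function(i) mc$is_mirna_host[i]),
    is_mirna_host3 = gene_field(i3, function(i) mc$is_mirna_host[i]),
    is_snorna_host5 = gene_field(i5, function(i) mc$is_snorna_host[i]),
    is_snorna_host3 = gene_field(i3, function(i) mc$is_snorna_host[i]),
    repeat_overlap5 = rep_overlap(df$chrom5, df$pos5),
    repeat_overlap3 = rep_overlap(df$chrom3, df$pos3),
    incomplete = incomplete,
    stringsAsFactors = FALSE)
  if (caller(x) == "arriba-like") out$confidence <- df$confidence
  out$tags <- df$tags
  out
}

#' Assemble the labeled feature table
#'
#' Expands the multi-categorical `tags` list column into one 0/1
#' indicator per observed tag and removes zero-variance columns (their
#' names are kept in the `"dropped"` attribute). Row order is preserved;
#' the assembly is a pure function of its inputs.
#'
#' @param vectors data.frame from [buildFeatureVectors()].
#' @param labels logical vector (TRUE = validated) of the same length.
#' @param groups character vector of group names (e.g. cancer type) of
#'   the same length.
#' @return data.frame with `label`, `group` and the surviving feature
#'   columns; attribute `dropped` lists removed constant columns.
#' @export
assembleFeatureTable <- function(vectors, labels, groups) {
  n <- nrow(vectors)
  if (length(labels) != n || length(groups) != n)
    stop("vectors, labels and groups must have matching lengths")
  if (!is.logical(labels)) stop("labels must be logical")
  if (any(!nzchar(groups))) stop("groups must be non-empty strings")
  df <- vectors
  if (!is.null(df$tags)) {
    all_tags <- sort(unique(unlist(df$tags)))
    for (tg in all_tags) {
      df[[paste0("tag_", gsub("[^A-Za-z0-9]", "_", tg))]] <-
        vapply(df$tags, function(t) as.integer(tg %in% t), integer(1))
    }
    df$tags <- NULL
  }
  id_cols <- intersect(c("sample_id", "gene5", "gene3"), names(df))
  feat_cols <- setdiff(names(df), id_cols)
  # NA counts as a value: a column that is one constant plus NAs still
  # carries information through its missingness pattern
  constant <- vapply(df[feat_cols], function(col)
    length(unique(col)) <= 1L, logical(1))
  dropped <- feat_cols[constant]
  df <- df[, c(id_cols, setdiff(feat_cols, dropped)), drop = FALSE]
  out <- cbind(data.frame(label = labels, group = groups,
                          stringsAsFactors = FALSE), df)
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}
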