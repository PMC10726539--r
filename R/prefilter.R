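# Tag-based and read-evidence pre-filtering of caller output, applied
# before DNA-level validation or classification.

#' Default banned-tag set
#'
#' Caller-assigned annotation tags that mark a fusion prediction as a
#' likely false positive (known healthy-tissue fusions, adjacent or
#' overlapping genes, paralogs, rRNA/mitochondrial artifacts, and so on).
#' Matching is case-insensitive and exact-string.
#'
#' @return Character vector of tags.
#' @export
bannedTags <- function() {
  c("1000genomes", "1K<gap<10K", "adjacent", "ambiguous", "duplicates",
    "ensembl_partially_overlapping", "gap<1K", "gencode_fully_overlapping",
    "gencode_partially_overlapping", "gencode_same_strand_overlapping",
    "healthy", "m0", "multi", "non_cancer_tissues", "non_tumor_cells",
    "refseq_partially_overlapping", "tcga-normal",
    "ucsc_partially_overlapping", "banned", "bodymap2", "cacg", "conjoing",
    "cta_gene", "ctb_gene", "ctc_gene", "ctd_gene", "distance1000bp",
    "ensembl_fully_overlapping", "ensembl_same_strand_overlapping", "gtex",
    "hpa", "mt", "pair_pseudo_genes", "paralogs", "readthrough",
    "refseq_fully_overlapping", "refseq_same_strand_overlapping", "rp_gene",
    "rp11_gene", "rrna", "similar_reads", "similar_symbols",
    "ucsc_fully_overlapping", "ucsc_same_strand_overlapping")
}

#' Pre-filter fusion calls on banned tags and common-mapping reads
#'
#' A call is removed iff it carries at least one banned tag or its count
#' of reads mapping to both partner genes exceeds `max_common_mapping`.
#' Tag matching is exact-string after lowercasing (never substring), so
#' e.g. `mt` does not match `mt-like`. Each removed call is annotated with
#' the first matching reason; kept and removed sets partition the input.
#' The operation is idempotent.
#'
#' @param x a [FusionCallSet-class].
#' @param banned character vector of banned tags
#'   (default [bannedTags()]).
#' @param max_common_mapping maximum tolerated common-mapping read count
#'   (default 0).
#' @return List with elements `kept` (FusionCallSet) and `removed`
#'   (FusionCallSet) plus `reasons` (character, one per removed call).
#' @export
applyPrefilter <- function(x, banned = bannedTags(), max_common_mapping = 0) {
  df <- fusionCalls(x)
  if (nrow(df) == 0L)
    return(list(kept = x, removed = x[integer(0)], reasons = character(0)))
  banned_lc <- tolower(banned)
  first_banned <- vapply(df$tags, function(t) {
    hit <- tolower(t) %in% banned_lc
    if (any(hit)) t[which(hit)[1L]] else NA_character_
  }, character(1))
  too_common <- df$common_mapping_reads > max_common_mapping
  drop <- !is.na(first_banned) | too_common
  reasons <- ifelse(!is.na(first_banned),
                    sprintf("banned tag: %s", first_banned),
                    sprintf("common mapping reads > %d", max_common_mapping))
  list(kept = x[!drop], removed = x[drop], reasons = reasons[drop])
}

#' Jaccard index of two fusion-call sets
#'
#' Intersection over union of the sets of fusion keys. The default key is
#' the unordered partner-symbol pair, so reciprocal calls (A-B vs B-A)
#' match; `ordered = TRUE` keys on the ordered pair.
#'
#' @param a,b [FusionCallSet-class] objects (or data.frames with
#'   `gene5`/`gene3` columns).
#' @param ordered key on ordered partner pairs (default FALSE).
#' @return Jaccard fraction in `[0, 1]`; 0 when both sets are empty.
#' @export
fusionSetJaccard <- function(a, b, ordered = FALSE) {
  key <- function(x) {
    df <- if (methods::is(x, "FusionCallSet")) fusionCalls(x) else x
    if (nrow(df) == 0L) return(character(0))
    if (ordered) unique(paste(df$gene5, df$gene3, sep = "|"))
    else unique(paste(pmin(df$gene5, df$gene3),
                      pmax(df$gene5, df$gene3), sep = "|"))
  }
  ka <- key(a); kb <- key(b)
  u <- length(union(ka, kb))
  if (u == 0L) return(0)
  length(intersect(ka, kb)) / u
}
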