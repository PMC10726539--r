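# Readers and writers for the caller-output dialects, gene models and
# sequence access. All internal coordinates are 1-based inclusive; the
# only 0-based format touched (BED) is converted on ingest by rtracklayer.

#' @importFrom utils read.delim write.table
NULL

# canonical FusionCatcher-style headers plus aliases seen across versions
.FC_ALIASES <- list(
  gene5 = c("Gene_1_symbol(5end_fusion_partner)", "Gene_1_symbol"),
  gene3 = c("Gene_2_symbol(3end_fusion_partner)", "Gene_2_symbol"),
  junction5 = c("Fusion_point_for_gene_1(5end_fusion_partner)",
                "Fusion_point_for_gene_1"),
  junction3 = c("Fusion_point_for_gene_2(3end_fusion_partner)",
                "Fusion_point_for_gene_2"),
  spanning_pairs = c("Spanning_pairs"),
  spanning_unique_reads = c("Spanning_unique_reads"),
  longest_anchor = c("Longest_anchor_found", "Longest_anchor"),
  tags = c("Fusion_description", "Description"),
  common_mapping_reads = c("Counts_of_common_mapping_reads",
                           "Common_mapping_reads"),
  predicted_effect = c("Predicted_effect")
)

.AR_ALIASES <- list(
  gene5 = c("#gene1", "gene1"),
  gene3 = c("gene2"),
  strand5 = c("strand1(gene/fusion)", "strand1"),
  strand3 = c("strand2(gene/fusion)", "strand2"),
  junction5 = c("breakpoint1"),
  junction3 = c("breakpoint2"),
  split_reads1 = c("split_reads1"),
  split_reads2 = c("split_reads2"),
  discordant_mates = c("discordant_mates"),
  confidence = c("confidence"),
  reading_frame = c("reading_frame"),
  tags = c("tags")
)

.resolve_columns <- function(header, aliases, mandatory, dialect) {
  idx <- vapply(aliases, function(cands) {
    hit <- which(header %in% cands)
    if (length(hit)) hit[1L] else NA_integer_
  }, integer(1))
  missing <- names(aliases)[is.na(idx) & names(aliases) %in% mandatory]
  if (length(missing))
    stop(sprintf("%s table is missing mandatory column(s): %s",
                 dialect, paste(missing, collapse = ", ")))
  idx
}

# "chrom:pos:strand" or "chrom:pos" (+ separate strand); row-aware errors
.parse_junction <- function(x, lines, has_strand = TRUE) {
  parts <- strsplit(x, ":", fixed = TRUE)
  nfield <- if (has_strand) 3L else 2L
  bad <- vapply(parts, length, integer(1)) != nfield
  pos <- suppressWarnings(
    as.integer(vapply(parts, function(p)
      if (length(p) >= 2L) p[2L] else NA_character_, character(1))))
  bad <- bad | is.na(pos) | pos < 1L
  if (any(bad))
    stop(sprintf("unparseable fusion coordinate '%s' at line %d",
                 x[which(bad)[1L]], lines[which(bad)[1L]]))
  list(chrom = vapply(parts, `[`, character(1), 1L),
       pos = pos,
       strand = if (has_strand) vapply(parts, `[`, character(1), 3L)
                else rep(NA_character_, length(parts)))
}

.split_tags <- function(x) {
  lapply(strsplit(ifelse(is.na(x) | x == "", "", x), ","), function(t) {
    t <- trimws(t)
    t[nzchar(t)]
  })
}

#' Read a FusionCatcher-style fusion table
#'
#' Parses the tab-separated output dialect of FusionCatcher-like callers
#' into a normalized [FusionCallSet-class]. Column naming drifts across
#' caller versions, so headers are matched through an alias map.
#'
#' @param path path to the TSV file.
#' @param sample_id sample identifier attached to every call.
#' @param aliases alias map from canonical field names to accepted header
#'   strings; extend to absorb new caller versions.
#' @return A [FusionCallSet-class] with `caller = "fusioncatcher-like"`.
#'   Tag strings are split on commas into sets; junction coordinates are
#'   parsed from `chrom:pos:strand`.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeFusionCatcher(FusionCallSet(data.frame(
#'   sample_id = "s1", gene5 = "A", gene3 = "B",
#'   chrom5 = "chr1", pos5 = 100L, strand5 = "+",
#'   chrom3 = "chr2", pos3 = 200L, strand3 = "-")), tsv)
#' readFusionCatcher(tsv, "s1")
#' @export
readFusionCatcher <- function(path, sample_id,
                              aliases = .FC_ALIASES) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  idx <- .resolve_columns(
    names(df), aliases,
    mandatory = c("gene5", "gene3", "junction5", "junction3",
                  "spanning_pairs", "longest_anchor", "tags"),
    dialect = "fusioncatcher-like")
  n <- nrow(df)
  if (n == 0L) return(FusionCallSet(caller = "fusioncatcher-like"))
  lines <- seq_len(n) + 1L  # header is line 1
  j5 <- .parse_junction(as.character(df[[idx["junction5"]]]), lines)
  j3 <- .parse_junction(as.character(df[[idx["junction3"]]]), lines)
  grab_int <- function(key, default = 0L) {
    if (is.na(idx[key])) rep(default, n)
    else {
      v <- suppressWarnings(as.integer(df[[idx[key]]]))
      ifelse(is.na(v), default, v)
    }
  }
  effect <- if (is.na(idx["predicted_effect"])) rep("unknown", n)
            else as.character(df[[idx["predicted_effect"]]])
  effect[!effect %in% .PREDICTED_EFFECTS] <- "unknown"
  calls <- data.frame(
    sample_id = sample_id,
    gene5 = as.character(df[[idx["gene5"]]]),
    gene3 = as.character(df[[idx["gene3"]]]),
    chrom5 = j5$chrom, pos5 = j5$pos, strand5 = j5$strand,
    chrom3 = j3$chrom, pos3 = j3$pos, strand3 = j3$strand,
    spanning_pairs = grab_int("spanning_pairs"),
    spanning_unique_reads = grab_int("spanning_unique_reads"),
    longest_anchor = grab_int("longest_anchor", NA_integer_),
    common_mapping_reads = grab_int("common_mapping_reads"),
    predicted_effect = effect,
    confidence = "none",
    stringsAsFactors = FALSE)
  calls$tags <- .split_tags(as.character(df[[idx["tags"]]]))
  FusionCallSet(calls, caller = "fusioncatcher-like")
}

#' Read an Arriba-style fusion table
#'
#' @inheritParams readFusionCatcher
#' @return A [FusionCallSet-class] with `caller = "arriba-like"`. Arriba's
#'   discordant-mate count is stored in `spanning_pairs`, split-read
#'   support in `spanning_unique_reads`, the reading frame is mapped onto
#'   `predicted_effect`, and the confidence label is kept.
#' @export
readArriba <- function(path, sample_id, aliases = .AR_ALIASES) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   na.strings = c("NA", ""), comment.char = "")
  idx <- .resolve_columns(
    names(df), aliases,
    mandatory = c("gene5", "gene3", "junction5", "junction3",
                  "confidence", "discordant_mates", "reading_frame"),
    dialect = "arriba-like")
  n <- nrow(df)
  if (n == 0L) return(FusionCallSet(caller = "arriba-like"))
  lines <- seq_len(n) + 1L
  j5 <- .parse_junction(as.character(df[[idx["junction5"]]]), lines,
                        has_strand = FALSE)
  j3 <- .parse_junction(as.character(df[[idx["junction3"]]]), lines,
                        has_strand = FALSE)
  # strand columns are "gene/fusion"; the fusion strand (after the slash)
  # is the transcribed orientation of the junction
  fus_strand <- function(x) {
    s <- vapply(strsplit(as.character(x), "/", fixed = TRUE), function(p)
      p[length(p)], character(1))
    ifelse(s %in% c("+", "-"), s, "+")
  }
  strand5 <- if (is.na(idx["strand5"])) rep("+", n)
             else fus_strand(df[[idx["strand5"]]])
  strand3 <- if (is.na(idx["strand3"])) rep("+", n)
             else fus_strand(df[[idx["strand3"]]])
  conf <- tolower(as.character(df[[idx["confidence"]]]))
  conf[!conf %in% c("high", "medium", "low")] <- "low"
  frame <- tolower(as.character(df[[idx["reading_frame"]]]))
  effect <- rep("unknown", n)
  effect[frame %in% c("in-frame", "inframe")] <- "in-frame"
  effect[frame %in% c("out-of-frame", "stop-codon")] <- "out-of-frame"
  effect[frame %in% c("5'-5'", "intronic", "utr", "intergenic")] <-
    "UTR/intronic"
  sr1 <- if (is.na(idx["split_reads1"])) rep(0L, n)
         else as.integer(df[[idx["split_reads1"]]])
  sr2 <- if (is.na(idx["split_reads2"])) rep(0L, n)
         else as.integer(df[[idx["split_reads2"]]])
  calls <- data.frame(
    sample_id = sample_id,
    gene5 = as.character(df[[idx["gene5"]]]),
    gene3 = as.character(df[[idx["gene3"]]]),
    chrom5 = j5$chrom, pos5 = j5$pos, strand5 = strand5,
    chrom3 = j3$chrom, pos3 = j3$pos, strand3 = strand3,
    spanning_pairs = as.integer(df[[idx["discordant_mates"]]]),
    spanning_unique_reads = ifelse(is.na(sr1), 0L, sr1) +
      ifelse(is.na(sr2), 0L, sr2),
    longest_anchor = NA_integer_,
    common_mapping_reads = 0L,
    predicted_effect = effect,
    confidence = conf,
    stringsAsFactors = FALSE)
  calls$tags <- if (is.na(idx["tags"]))
    replicate(n, character(0), simplify = FALSE)
  else .split_tags(as.character(df[[idx["tags"]]]))
  FusionCallSet(calls, caller = "arriba-like")
}

#' Write a FusionCallSet in the FusionCatcher-style dialect
#'
#' @param x a [FusionCallSet-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeFusionCatcher <- function(x, path) {
  df <- fusionCalls(x)
  out <- data.frame(
    check.names = FALSE, stringsAsFactors = FALSE,
    `Gene_1_symbol(5end_fusion_partner)` = df$gene5,
    `Gene_2_symbol(3end_fusion_partner)` = df$gene3,
    `Fusion_description` = vapply(df$tags, paste, character(1),
                                  collapse = ","),
    `Counts_of_common_mapping_reads` = df$common_mapping_reads,
    `Spanning_pairs` = df$spanning_pairs,
    `Spanning_unique_reads` = df$spanning_unique_reads,
    `Longest_anchor_found` = df$longest_anchor,
    `Fusion_point_for_gene_1(5end_fusion_partner)` =
      sprintf("%s:%d:%s", df$chrom5, df$pos5, df$strand5),
    `Fusion_point_for_gene_2(3end_fusion_partner)` =
      sprintf("%s:%d:%s", df$chrom3, df$pos3, df$strand3),
    `Predicted_effect` = df$predicted_effect)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a FusionCallSet in the Arriba-style dialect
#'
#' @inheritParams writeFusionCatcher
#' @return `path`, invisibly.
#' @export
writeArriba <- function(x, path) {
  df <- fusionCalls(x)
  frame <- c(`in-frame` = "in-frame", `out-of-frame` = "out-of-frame",
             `UTR/intronic` = "intronic", unknown = ".")[df$predicted_effect]
  half <- ceiling(df$spanning_unique_reads / 2)
  out <- data.frame(
    check.names = FALSE, stringsAsFactors = FALSE,
    `#gene1` = df$gene5, gene2 = df$gene3,
    `strand1(gene/fusion)` = sprintf("%s/%s", df$strand5, df$strand5),
    `strand2(gene/fusion)` = sprintf("%s/%s", df$strand3, df$strand3),
    breakpoint1 = sprintf("%s:%d", df$chrom5, df$pos5),
    breakpoint2 = sprintf("%s:%d", df$chrom3, df$pos3),
    type = ifelse(df$chrom5 == df$chrom3, "duplication", "translocation"),
    split_reads1 = half,
    split_reads2 = df$spanning_unique_reads - half,
    discordant_mates = df$spanning_pairs,
    confidence = ifelse(df$confidence == "none", "low", df$confidence),
    reading_frame = unname(frame),
    tags = vapply(df$tags, paste, character(1), collapse = ","))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Load gene models from GTF with gene-list flags
#'
#' Builds a [GeneAnnotation-class] from a GTF file (gene and exon
#' features). Per-gene boolean flags are set from the supplied gene-symbol
#' lists; genes absent from a list get `FALSE`. CDS bounds are taken from
#' CDS features when present, otherwise approximated as the span between
#' the midpoints of the terminal exons.
#'
#' @param gtf_path path to a GTF file.
#' @param mirna_hosts,snorna_hosts,cosmic,kinases character vectors of gene
#'   symbols (may be empty).
#' @param seqlengths optional named integer vector of chromosome lengths;
#'   taken from the GTF seqinfo when absent.
#' @return A [GeneAnnotation-class].
#' @export
readGeneModels <- function(gtf_path, mirna_hosts = character(),
                           snorna_hosts = character(),
                           cosmic = character(), kinases = character(),
                           seqlengths = NULL) {
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  sym_col <- if ("gene_name" %in% names(mc)) "gene_name" else "gene_id"
  genes <- gr[mc$type == "gene"]
  exons <- gr[mc$type == "exon"]
  cds <- gr[mc$type == "CDS"]
  if (!length(genes)) stop("GTF contains no gene features")
  gsym <- as.character(S4Vectors::mcols(genes)[[sym_col]])
  esym <- as.character(S4Vectors::mcols(exons)[[sym_col]])
  csym <- as.character(S4Vectors::mcols(cds)[[sym_col]])
  exon_list <- vector("list", length(genes))
  names(exon_list) <- gsym
  cds_start <- cds_end <- integer(length(genes))
  for (i in seq_along(genes)) {
    ex <- exons[esym == gsym[i]]
    if (!length(ex)) {
      warning(sprintf(
        "gene %s has no exon features; using a single-exon fallback",
        gsym[i]))
      ex <- genes[i]
    }
    ex <- sort(ex)
    if (any(GenomicRanges::start(ex) < GenomicRanges::start(genes[i])) ||
        any(GenomicRanges::end(ex) > GenomicRanges::end(genes[i])))
      stop(sprintf("exon outside gene bounds for %s", gsym[i]))
    exon_list[[i]] <- GenomicRanges::granges(ex)
    cg <- cds[csym == gsym[i]]
    if (length(cg)) {
      cds_start[i] <- min(GenomicRanges::start(cg))
      cds_end[i] <- max(GenomicRanges::end(cg))
    } else {
      cds_start[i] <- GenomicRanges::start(ex)[1L] +
        floor(GenomicRanges::width(ex)[1L] / 2)
      cds_end[i] <- GenomicRanges::end(ex)[length(ex)] -
        floor(GenomicRanges::width(ex)[length(ex)] / 2)
    }
  }
  genes <- GenomicRanges::granges(genes)
  S4Vectors::mcols(genes) <- S4Vectors::DataFrame(
    gene_id = as.character(S4Vectors::mcols(gr[mc$type == "gene"])$gene_id),
    symbol = gsym,
    biotype = {
      bt <- S4Vectors::mcols(gr[mc$type == "gene"])$gene_biotype
      if (is.null(bt)) rep("protein_coding", length(genes))
      else as.character(bt)
    },
    cds_start = cds_start, cds_end = cds_end,
    is_mirna_host = gsym %in% mirna_hosts,
    is_snorna_host = gsym %in% snorna_hosts,
    in_cosmic = gsym %in% cosmic,
    is_kinase = gsym %in% kinases)
  if (!is.null(seqlengths))
    GenomeInfoDb::seqlengths(genes) <-
      seqlengths[GenomeInfoDb::seqlevels(genes)]
  new("GeneAnnotation", genes = genes,
      exons = GenomicRanges::GRangesList(exon_list))
}

#' Read a repeat-annotation BED file
#'
#' BED intervals (0-based half-open on disk) are converted to 1-based
#' inclusive GRanges on ingest; the name field, when present, is kept as
#' `repeat_class`.
#'
#' @param path path to a BED file.
#' @return GRanges with an mcols column `repeat_class`.
#' @export
readRepeatBed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  cls <- S4Vectors::mcols(gr)$name
  if (is.null(cls)) cls <- rep("repeat", length(gr))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(repeat_class = cls)
  gr
}

#' Fetch genomic sequence, strand-aware
#'
#' @param reference a DNAStringSet (named by chromosome), an Rsamtools
#'   FaFile, or a path to an indexed FASTA.
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param strand `"+"` (default) or `"-"`; minus returns the reverse
#'   complement.
#' @return Uppercase character string of length `end - start + 1`.
#' @export
fetchSequence <- function(reference, chrom, start, end, strand = "+") {
  if (is.character(reference)) reference <- Rsamtools::FaFile(reference)
  if (start < 1 || end < start)
    stop(sprintf("invalid sequence range %d-%d", start, end))
  if (methods::is(reference, "DNAStringSet")) {
    if (!chrom %in% names(reference))
      stop(sprintf("chromosome not in reference: %s", chrom))
    len <- Biostrings::width(reference)[match(chrom, names(reference))]
    if (end > len)
      stop(sprintf("range %d-%d beyond end of %s (%d)", start, end, chrom,
                   len))
    seq <- Biostrings::subseq(reference[[chrom]], start, end)
  } else {
    si <- GenomeInfoDb::seqinfo(reference)
    if (!chrom %in% GenomeInfoDb::seqnames(si))
      stop(sprintf("chromosome not in reference: %s", chrom))
    len <- GenomeInfoDb::seqlengths(si)[[chrom]]
    if (end > len)
      stop(sprintf("range %d-%d beyond end of %s (%d)", start, end, chrom,
                   len))
    seq <- Rsamtools::scanFa(
      reference, GenomicRanges::GRanges(chrom, IRanges::IRanges(start,
                                                                end)))[[1L]]
  }
  if (strand == "-") seq <- Biostrings::reverseComplement(seq)
  toupper(as.character(seq))
}
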