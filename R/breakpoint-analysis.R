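# Mechanism analyses at validated genomic breakpoints: junction
# microhomology against simulated control breakpoints, depth-ratio
# profiles across the breakpoint, genomic-context annotation with a
# length-expectation chi-square, exon-level expression contrasts, and
# kinase-fusion classification.

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

.seq_chars <- function(reference, chrom, start, end) {
  strsplit(fetchSequence(reference, chrom, start, end, "+"), "")[[1L]]
}

.chrom_length <- function(reference, chrom) {
  if (methods::is(reference, "DNAStringSet"))
    Biostrings::width(reference)[match(chrom, names(reference))]
  else {
    if (is.character(reference)) reference <- Rsamtools::FaFile(reference)
    GenomeInfoDb::seqlengths(GenomeInfoDb::seqinfo(reference))[[chrom]]
  }
}

# flank read outward from the junction, junction-adjacent base first
.flank_outward <- function(reference, chrom, pos, strand, k, lost_side) {
  len <- .chrom_length(reference, chrom)
  truncated <- FALSE
  if (!lost_side) {
    # retained 5' tail: base at the junction, then moving away from it
    if (strand == "+") {
      lo <- pos - k + 1L
      if (lo < 1L) { lo <- 1L; truncated <- TRUE }
      out <- rev(.seq_chars(reference, chrom, lo, pos))
    } else {
      hi <- pos + k - 1L
      if (hi > len) { hi <- len; truncated <- TRUE }
      out <- unname(.COMPLEMENT[.seq_chars(reference, chrom, pos, hi)])
    }
  } else {
    # lost tail just upstream (transcript sense) of the 3' breakpoint
    if (strand == "+") {
      lo <- pos - k
      if (lo < 1L) { lo <- 1L; truncated <- TRUE }
      if (pos - 1L < lo) out <- character(0)
      else out <- rev(.seq_chars(reference, chrom, lo, pos - 1L))
    } else {
      hi <- pos + k
      if (hi > len) { hi <- len; truncated <- TRUE }
      if (pos + 1L > hi) out <- character(0)
      else out <- unname(.COMPLEMENT[.seq_chars(reference, chrom, pos + 1L,
                                                hi)])
    }
  }
  list(chars = out, truncated = truncated)
}

#' Junction microhomology between the two fusion partners
#'
#' Compares the retained 5'-partner tail (the sequence ending at the 5'
#' breakpoint) with the just-lost tail upstream of the 3' breakpoint,
#' both read outward from the junction in transcript orientation. Their
#' exact common-prefix length is the homology: if it equals h, the
#' junction could equally have been placed h bases further upstream,
#' the classic signature of microhomology-mediated (Alt-NHEJ) joining.
#' Breakpoints are labeled `none` (0), `microhomologous` (1-5 nt) or
#' `homologous` (>5 nt). With `orientation = "reference"` both flanks
#' are read on the plus strand regardless of the stated strands.
#'
#' @param reference genome (DNAStringSet, FaFile or FASTA path).
#' @param chrom5,pos5,strand5 5'-partner breakpoint.
#' @param chrom3,pos3,strand3 3'-partner breakpoint.
#' @param max_checked maximum homology length checked (default 20 nt).
#' @param orientation `"transcript"` (default) or `"reference"`.
#' @return List: `homology_len`, `label`, `truncated` (TRUE when a flank
#'   hit a chromosome end and the comparison was shortened).
#' @export
microhomologyAtBreakpoint <- function(reference, chrom5, pos5, strand5,
                                      chrom3, pos3, strand3,
                                      max_checked = 20,
                                      orientation = c("transcript",
                                                      "reference")) {
  orientation <- match.arg(orientation)
  if (orientation == "reference") strand5 <- strand3 <- "+"
  f5 <- .flank_outward(reference, chrom5, pos5, strand5, max_checked,
                       lost_side = FALSE)
  f3 <- .flank_outward(reference, chrom3, pos3, strand3, max_checked,
                       lost_side = TRUE)
  k <- min(length(f5$chars), length(f3$chars))
  h <- 0L
  while (h < k && f5$chars[h + 1L] == f3$chars[h + 1L]) h <- h + 1L
  label <- if (h == 0L) "none" else if (h <= 5L) "microhomologous"
           else "homologous"
  list(homology_len = h, label = label,
       truncated = f5$truncated || f3$truncated)
}

#' Simulate control breakpoints near an observed pair
#'
#' Draws uniform positions within +/- `window` of each observed
#' breakpoint, shifting the two partners independently; a draw equal to
#' the observed pair is rejected. Positions falling outside the
#' chromosome are drawn from the clipped bounds.
#'
#' @param chrom5,pos5,chrom3,pos3 observed breakpoint pair.
#' @param chrlen5,chrlen3 chromosome lengths.
#' @param window shift window in bp (default 1000).
#' @param n_controls controls to draw (default 10).
#' @param seed RNG seed.
#' @return data.frame: `pos5`, `pos3` (n_controls rows).
#' @export
simulateControlBreakpoints <- function(chrom5, pos5, chrom3, pos3,
                                       chrlen5, chrlen3, window = 1000,
                                       n_controls = 10, seed = 1L) {
  if (window <= 0) stop("window must be positive")
  if (n_controls < 1) stop("n_controls must be >= 1")
  set.seed(seed)
  lo5 <- max(2L, pos5 - window); hi5 <- min(chrlen5 - 1L, pos5 + window)
  lo3 <- max(2L, pos3 - window); hi3 <- min(chrlen3 - 1L, pos3 + window)
  out <- matrix(NA_integer_, n_controls, 2L)
  for (i in seq_len(n_controls)) {
    repeat {
      p5 <- sample(lo5:hi5, 1L)
      p3 <- sample(lo3:hi3, 1L)
      if (p5 != pos5 || p3 != pos3) break
    }
    out[i, ] <- c(p5, p3)
  }
  data.frame(pos5 = out[, 1L], pos3 = out[, 2L])
}

#' Rank-sum test of observed versus control homology lengths
#'
#' One-sided Mann-Whitney U (observed greater), tie-corrected via the
#' normal approximation with continuity correction. Two identical
#' constant samples return p = 1 by convention.
#'
#' @param observed,control numeric homology lengths (both non-empty).
#' @return One-sided p-value.
#' @export
microhomologyTest <- function(observed, control) {
  if (!length(observed) || !length(control))
    stop("both samples must be non-empty")
  if (length(unique(c(observed, control))) == 1L) return(1)
  suppressWarnings(stats::wilcox.test(
    observed, control, alternative = "greater", exact = FALSE,
    correct = TRUE)$p.value)
}

#' Depth-ratio profile across a breakpoint
#'
#' Per-base depth over +/- `flank` bp around the breakpoint, divided by
#' the global mean depth. Offsets are flipped so that the fusion-retained
#' side always sits at negative offsets (upstream in the plot), whatever
#' its genomic orientation.
#'
#' @param bam indexed BAM.
#' @param chrom,pos breakpoint.
#' @param retained `"left"` if the retained side is at lower genomic
#'   coordinates, `"right"` otherwise.
#' @param global_depth mean genome-wide depth from [globalDepth()]
#'   (must be > 0).
#' @param flank half-window in bp (default 100).
#' @return data.frame: `offset` (-flank..flank, retained side negative),
#'   `ratio`; attribute `truncated` flags a chromosome-edge profile
#'   shorter than 2*flank+1.
#' @export
depthProfile <- function(bam, chrom, pos, retained = c("left", "right"),
                         global_depth, flank = 100) {
  retained <- match.arg(retained)
  if (global_depth <= 0) stop("global_depth must be positive")
  bf <- if (methods::is(bam, "BamFile")) bam else Rsamtools::BamFile(bam)
  len <- GenomeInfoDb::seqlengths(GenomeInfoDb::seqinfo(bf))[[chrom]]
  lo <- max(1L, pos - as.integer(flank))
  hi <- min(len, pos + as.integer(flank))
  truncated <- (hi - lo) < 2L * flank
  aln <- GenomicAlignments::readGAlignments(
    bf, param = Rsamtools::ScanBamParam(
      which = GenomicRanges::GRanges(chrom, IRanges::IRanges(lo, hi)),
      flag = Rsamtools::scanBamFlag(
        isSecondaryAlignment = FALSE,
        isDuplicate = FALSE, isUnmappedQuery = FALSE)))
  cov <- GenomicRanges::coverage(aln)[[chrom]]
  depth <- as.numeric(cov[lo:hi])
  genomic_offset <- (lo:hi) - pos
  offset <- if (retained == "left") genomic_offset else -genomic_offset
  out <- data.frame(offset = offset, ratio = depth / global_depth)
  out <- out[order(out$offset), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "truncated") <- truncated
  out
}

#' Genomic context of breakpoints, with a length-expectation chi-square
#'
#' Each breakpoint is classed by priority CDS > UTR > intron inside its
#' gene, or intergenic outside any gene; the first overlapping repeat
#' interval, if any, is reported as `repeat_class`.
#'
#' @param bp data.frame with `chrom`, `pos`.
#' @param annotation a [GeneAnnotation-class].
#' @param repeats GRanges repeat track or NULL.
#' @return data.frame: `chrom`, `pos`, `gene`, `region_class`,
#'   `repeat_class`.
#' @export
annotateBreakpointContext <- function(bp, annotation, repeats = NULL) {
  genes <- geneRanges(annotation)
  mc <- S4Vectors::mcols(genes)
  gr <- GenomicRanges::GRanges(bp$chrom, IRanges::IRanges(bp$pos, bp$pos))
  GenomeInfoDb::seqlevels(gr) <- union(GenomeInfoDb::seqlevels(gr),
                                       GenomeInfoDb::seqlevels(genes))
  gene_hit <- GenomicRanges::findOverlaps(gr, genes, select = "first")
  out <- data.frame(chrom = bp$chrom, pos = bp$pos,
                    gene = mc$symbol[gene_hit],
                    region_class = "intergenic",
                    repeat_class = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in which(!is.na(gene_hit))) {
    gi <- gene_hit[i]
    ex <- annotation@exons[[mc$symbol[gi]]]
    in_exon <- any(bp$pos[i] >= GenomicRanges::start(ex) &
                     bp$pos[i] <= GenomicRanges::end(ex))
    out$region_class[i] <- if (!in_exon) "intron"
      else if (bp$pos[i] >= mc$cds_start[gi] &&
               bp$pos[i] <= mc$cds_end[gi]) "CDS" else "UTR"
  }
  if (!is.null(repeats)) {
    GenomeInfoDb::seqlevels(gr) <- union(GenomeInfoDb::seqlevels(gr),
                                         GenomeInfoDb::seqlevels(repeats))
    rhit <- GenomicRanges::findOverlaps(gr, repeats, select = "first")
    out$repeat_class <- S4Vectors::mcols(repeats)$repeat_class[rhit]
  }
  out
}

#' Chi-square of breakpoint context counts against length expectation
#'
#' Expected class proportions are the summed genomic lengths of CDS-exon,
#' UTR-exon and intron within the supplied (fused) genes -- breakpoints
#' are constrained to search regions, so genome-wide lengths would be the
#' wrong null.
#'
#' @param context data.frame from [annotateBreakpointContext()]
#'   (intergenic rows are excluded from the test).
#' @param annotation a [GeneAnnotation-class].
#' @param genes gene symbols defining the length expectation (default:
#'   the genes hit by the breakpoints).
#' @return `htest` from [stats::chisq.test()] with observed counts and
#'   length-proportional expected probabilities.
#' @export
contextChisq <- function(context, annotation, genes = NULL) {
  ctx <- context[context$region_class != "intergenic", , drop = FALSE]
  if (!nrow(ctx)) stop("no genic breakpoints to test")
  if (is.null(genes)) genes <- unique(ctx$gene)
  ga <- geneRanges(annotation)
  mc <- S4Vectors::mcols(ga)
  lens <- c(CDS = 0, UTR = 0, intron = 0)
  for (g in genes) {
    gi <- match(g, mc$symbol)
    if (is.na(gi)) next
    ex <- annotation@exons[[g]]
    exon_total <- sum(GenomicRanges::width(ex))
    cds_ir <- IRanges::IRanges(mc$cds_start[gi], mc$cds_end[gi])
    cds_len <- sum(IRanges::width(IRanges::intersect(
      IRanges::ranges(ex), cds_ir)))
    lens["CDS"] <- lens["CDS"] + cds_len
    lens["UTR"] <- lens["UTR"] + exon_total - cds_len
    lens["intron"] <- lens["intron"] +
      GenomicRanges::width(ga[gi]) - exon_total
  }
  obs <- table(factor(ctx$region_class, levels = names(lens)))
  keep <- lens > 0
  stats::chisq.test(as.integer(obs[keep]), p = lens[keep] / sum(lens[keep]))
}

#' Exon-expression contrast between in-fusion and out-of-fusion exons
#'
#' For each validated fusion partner, exons retained in the fusion
#' transcript (upstream of the 5' junction, downstream of the 3'
#' junction, in transcript orientation) are tagged; the per-gene fold
#' change is mean(tagged) / mean(untagged) and a paired t-test compares
#' per-gene log fold changes against zero, separately for the 5' and 3'
#' sides. Genes lacking a tagged or untagged exon are skipped with a
#' message.
#'
#' @param fusions data.frame with `gene5`, `gene3`, `pos5`, `pos3`.
#' @param annotation a [GeneAnnotation-class].
#' @param exon_expr data.frame with `gene`, `exon_start`, `exon_end`,
#'   `expr`.
#' @param epsilon guard used when the untagged mean is zero
#'   (default 0.01).
#' @return List with elements `per_gene` (side, gene, fold),
#'   `mean_fold5`, `mean_fold3`, `p5`, `p3`.
#' @export
exonExpressionContrast <- function(fusions, annotation, exon_expr,
                                   epsilon = 0.01) {
  genes <- geneRanges(annotation)
  mc <- S4Vectors::mcols(genes)
  rows <- list(); ri <- 0L
  for (i in seq_len(nrow(fusions))) {
    for (side in c("5", "3")) {
      sym <- fusions[[paste0("gene", side)]][i]
      pos <- fusions[[paste0("pos", side)]][i]
      gi <- match(sym, mc$symbol)
      if (is.na(gi)) next
      strand <- as.character(GenomicRanges::strand(genes))[gi]
      ee <- exon_expr[exon_expr$gene == sym, , drop = FALSE]
      if (!nrow(ee)) next
      upstream <- ee$exon_start <= pos  # genomic-left exons
      retained <- if (side == "5") (strand == "+") == upstream
                  else (strand == "+") != upstream
      # the junction exon itself is part of the transcript
      retained <- retained | (ee$exon_start <= pos & ee$exon_end >= pos)
      if (!any(retained) || all(retained)) {
        message(sprintf(
          "skipping %s' partner %s: no tagged/untagged exon split", side,
          sym))
        next
      }
      mt <- mean(ee$expr[retained]); mu <- mean(ee$expr[!retained])
      fold <- mt / if (mu > 0) mu else epsilon
      ri <- ri + 1L
      rows[[ri]] <- data.frame(side = side, gene = sym, fold = fold,
                               stringsAsFactors = FALSE)
    }
  }
  if (!ri) stop("no eligible genes for the exon-expression contrast")
  pg <- do.call(rbind, rows)
  test_side <- function(s) {
    f <- pg$fold[pg$side == s]
    if (length(f) < 2L) return(list(mean_fold = mean(f), p = NA_real_))
    lf <- log(f)
    p <- if (stats::sd(lf) == 0) {
      if (all(lf == 0)) 1 else 0
    } else stats::t.test(lf, mu = 0)$p.value
    list(mean_fold = exp(mean(lf)), p = p)
  }
  t5 <- test_side("5"); t3 <- test_side("3")
  list(per_gene = pg, mean_fold5 = t5$mean_fold, mean_fold3 = t3$mean_fold,
       p5 = t5$p, p3 = t3$p)
}

#' Classify kinase involvement of fusion calls
#'
#' `in_frame_kinase` when the predicted effect is in-frame and either
#' partner is a kinase; `promoter_swap_kinase` when the 3' partner is a
#' kinase and its junction lies at or upstream (in transcript
#' orientation) of the kinase CDS start, so the 5' partner contributes
#' promoter but no coding sequence; otherwise `none`. Calls with a
#' partner missing from the annotation return `none` with a warning.
#'
#' @param x a [FusionCallSet-class] or data.frame of calls.
#' @param annotation a [GeneAnnotation-class] with kinase flags.
#' @return Character vector: `in_frame_kinase`, `promoter_swap_kinase`
#'   or `none`.
#' @export
classifyKinaseFusion <- function(x, annotation) {
  df <- if (methods::is(x, "FusionCallSet")) fusionCalls(x) else x
  genes <- geneRanges(annotation)
  mc <- S4Vectors::mcols(genes)
  i5 <- match(df$gene5, mc$symbol)
  i3 <- match(df$gene3, mc$symbol)
  if (anyNA(i5) || anyNA(i3))
    warning("some partners missing from annotation; classified as none")
  kin5 <- !is.na(i5) & mc$is_kinase[pmax(i5, 1L)]
  kin3 <- !is.na(i3) & mc$is_kinase[pmax(i3, 1L)]
  out <- rep("none", nrow(df))
  strand3 <- ifelse(is.na(i3), "+",
                    as.character(GenomicRanges::strand(genes))[pmax(i3, 1L)])
  cds_lo <- ifelse(is.na(i3), NA_integer_, mc$cds_start[pmax(i3, 1L)])
  cds_hi <- ifelse(is.na(i3), NA_integer_, mc$cds_end[pmax(i3, 1L)])
  upstream_of_cds <- !is.na(i3) &
    ifelse(strand3 == "+", df$pos3 <= cds_lo, df$pos3 >= cds_hi)
  out[kin3 & upstream_of_cds & df$predicted_effect != "in-frame"] <-
    "promoter_swap_kinase"
  out[df$predicted_effect == "in-frame" & (kin5 | kin3)] <-
    "in_frame_kinase"
  out
}
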