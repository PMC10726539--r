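# DNA-level validation of fusion transcripts: discordant read pairs are
# extracted from per-partner search regions and genomic breakpoints are
# localized from locally re-aligned soft-clipped read ends. Plus the
# unbiased genome-wide discordant scan, the subsampling harness, and the
# summary/crosstab reports.

.flag_bit <- function(flag, bit) bitwAnd(flag, bit) != 0L

.scan_region <- function(bam, region, what = c("qname", "flag", "rname",
                                               "strand", "pos", "mapq",
                                               "mrnm", "mpos")) {
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(
      isUnmappedQuery = FALSE, hasUnmappedMate = FALSE,
      isSecondaryAlignment = FALSE, isSupplementaryAlignment = FALSE,
      isDuplicate = FALSE),
    what = what, which = region)
  res_list <- Rsamtools::scanBam(bam, param = param)
  dfs <- lapply(res_list, function(res) {
    df <- data.frame(qname = res$qname, flag = res$flag,
                     rname = as.character(res$rname),
                     strand = as.character(res$strand),
                     pos = res$pos, mapq = res$mapq,
                     stringsAsFactors = FALSE)
    if ("mrnm" %in% what) df$mrnm <- as.character(res$mrnm)
    if ("mpos" %in% what) df$mpos <- res$mpos
    if ("cigar" %in% what) df$cigar <- res$cigar
    if ("seq" %in% what) df$seq <- as.character(res$seq)
    if ("qual" %in% what) df$qual <- as.character(res$qual)
    df
  })
  unique(do.call(rbind, dfs))
}

#' Define per-partner search regions for one fusion
#'
#' For each partner the region spans from the gene boundary on the
#' transcribed (retained) side of the junction to the junction plus
#' `region_padding` past it, clipped at chromosome bounds. The retained
#' side is taken from the call's junction strand: upstream of the
#' junction for the 5' partner, downstream for the 3' partner.
#'
#' @param call one fusion call: a one-row data.frame (or list) with
#'   `gene5`, `gene3`, `chrom5`, `pos5`, `strand5`, `chrom3`, `pos3`,
#'   `strand3`.
#' @param annotation a [GeneAnnotation-class] resolving both partners.
#' @param config a [ValidationConfig-class].
#' @return GRanges of length 2, names `region5` and `region3`.
#' @export
defineSearchRegions <- function(call, annotation,
                                config = validationConfig()) {
  pad <- config@region_padding
  one <- function(symbol, chrom, pos, strand, is_five) {
    g <- lookupGene(annotation, symbol)
    gstart <- GenomicRanges::start(g); gend <- GenomicRanges::end(g)
    sl <- GenomeInfoDb::seqlengths(geneRanges(annotation))[chrom]
    if (is.na(sl)) sl <- .Machine$integer.max
    if (pos < gstart - pad || pos > gend + pad) {
      warning(sprintf(
        "junction %s:%d outside gene %s +/- padding; centering region on junction",
        chrom, pos, symbol))
      lo <- pos - pad; hi <- pos + pad
    } else if (is_five == (strand == "+")) {
      # retained side is upstream in genomic coordinates
      lo <- gstart; hi <- pos + pad
    } else {
      lo <- pos - pad; hi <- gend
    }
    GenomicRanges::GRanges(chrom,
                           IRanges::IRanges(max(1L, lo), min(sl, hi)))
  }
  r5 <- one(call$gene5, call$chrom5, call$pos5, call$strand5, TRUE)
  r3 <- one(call$gene3, call$chrom3, call$pos3, call$strand3, FALSE)
  out <- suppressWarnings(c(r5, r3))
  names(out) <- c("region5", "region3")
  out
}

#' Extract discordant read pairs linking the two search regions
#'
#' Returns read pairs with one mate mapped inside `region5` and the other
#' inside `region3`, where both mates pass the mapping-quality cutoff and
#' neither is a duplicate, secondary, supplementary or unmapped record.
#' Pairs flagged as proper (concordant insert on the same chromosome) are
#' excluded; each read name is counted once even when the regions
#' overlap.
#'
#' @param bam path to a coordinate-sorted, indexed BAM (or a
#'   `BamFile`).
#' @param regions GRanges of length 2 from [defineSearchRegions()].
#' @param config a [ValidationConfig-class].
#' @return data.frame: `read_name`, `pos5`, `pos3`, `mapq5`, `mapq3`,
#'   `orient5`, `orient3`.
#' @export
extractDiscordantPairs <- function(bam, regions,
                                   config = validationConfig()) {
  r5 <- .scan_region(bam, regions["region5"])
  r3 <- .scan_region(bam, regions["region3"])
  prep <- function(df) {
    df <- df[!is.na(df$mapq) & df$mapq >= config@min_mapq, , drop = FALSE]
    df$first <- .flag_bit(df$flag, 64L)
    df$proper <- .flag_bit(df$flag, 2L)
    df
  }
  r5 <- prep(r5); r3 <- prep(r3)
  if (!nrow(r5) || !nrow(r3))
    return(data.frame(read_name = character(0), pos5 = integer(0),
                      pos3 = integer(0), mapq5 = integer(0),
                      mapq3 = integer(0), orient5 = character(0),
                      orient3 = character(0)))
  m <- merge(r5, r3, by = "qname", suffixes = c("5", "3"))
  # the two records must be the two mates, not one record seen twice
  m <- m[m$first5 != m$first3 & !m$proper5 & !m$proper3, , drop = FALSE]
  m <- m[!duplicated(m$qname), , drop = FALSE]
  data.frame(read_name = m$qname, pos5 = m$pos5, pos3 = m$pos3,
             mapq5 = m$mapq5, mapq3 = m$mapq3,
             orient5 = m$strand5, orient3 = m$strand3,
             stringsAsFactors = FALSE)
}

.clip_info <- function(cigar) {
  left <- rep(0L, length(cigar))
  hasl <- grepl("^[0-9]+S", cigar)
  left[hasl] <- as.integer(sub("^([0-9]+)S.*", "\\1", cigar[hasl]))
  right <- rep(0L, length(cigar))
  hasr <- grepl("[0-9]+S$", cigar)
  right[hasr] <- as.integer(sub(".*[^0-9]([0-9]+)S$", "\\1", cigar[hasr]))
  refw <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
  list(left = left, right = right, refw = refw)
}

.mean_baseq <- function(qual) {
  if (!nchar(qual) || qual == "*") return(Inf)
  mean(utf8ToInt(qual)) - 33
}

.revcomp_chr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# local alignment of a clipped segment against the partner-region
# sequence, both orientations; returns NULL when below thresholds
.align_clip <- function(clipseq, region_seq, config) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -4,
                                                  baseOnly = FALSE)
  best <- NULL
  for (orient in c("+", "-")) {
    pat <- if (orient == "+") clipseq else .revcomp_chr(clipseq)
    aln <- Biostrings::pairwiseAlignment(
      pat, region_seq, type = "local", substitutionMatrix = mat,
      gapOpening = 6, gapExtension = 1)
    score <- Biostrings::score(aln)
    if (is.null(best) || score > best$score) {
      alen <- Biostrings::nchar(aln)
      best <- list(score = score, orient = orient,
                   identity = Biostrings::nmatch(aln) / alen,
                   alen = alen,
                   sub_start = Biostrings::start(
                     Biostrings::subject(aln)@range),
                   sub_end = Biostrings::end(
                     Biostrings::subject(aln)@range))
    }
  }
  if (best$identity >= config@min_align_identity &&
      best$alen >= config@min_align_len) best else NULL
}

#' Locate genomic breakpoints from soft-clipped read ends
#'
#' High-quality soft-clipped reads within `clip_search_window` of any
#' discordant-mate position are collected from both search regions; each
#' clipped segment is locally aligned against the opposite partner's
#' region sequence (both orientations; the better-scoring one wins, ties
#' fall to plus). A clip passing the identity and length thresholds
#' yields a candidate breakpoint at the clip boundary on its own partner
#' and at the junction-facing end of the local alignment on the other.
#' Candidates within `breakpoint_cluster_radius` on both coordinates are
#' merged; the representative position is the support-weighted mode with
#' ties broken toward the smaller coordinate.
#'
#' @inheritParams extractDiscordantPairs
#' @param pairs data.frame from [extractDiscordantPairs()].
#' @param reference genome as DNAStringSet, FaFile or FASTA path.
#' @return data.frame sorted by support (descending): `chrom5`, `bp5`,
#'   `chrom3`, `bp3`, `support`, `clip_side5`, `clip_side3`.
#' @export
findBreakpoints <- function(bam, pairs, regions, reference,
                            config = validationConfig()) {
  empty <- data.frame(chrom5 = character(0), bp5 = integer(0),
                      chrom3 = character(0), bp3 = integer(0),
                      support = integer(0), clip_side5 = character(0),
                      clip_side3 = character(0), stringsAsFactors = FALSE)
  if (is.null(pairs) || nrow(pairs) == 0L) return(empty)
  win <- config@clip_search_window
  chrom5 <- as.character(GenomicRanges::seqnames(regions["region5"]))
  chrom3 <- as.character(GenomicRanges::seqnames(regions["region3"]))
  windows <- function(pos, region) {
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      as.character(GenomicRanges::seqnames(region)),
      IRanges::IRanges(pmax(1L, pos - win), pos + win)))
    GenomicRanges::intersect(gr, region)
  }
  w5 <- windows(pairs$pos5, regions["region5"])
  w3 <- windows(pairs$pos3, regions["region3"])
  region_seq <- list(
    "5" = fetchSequence(reference, chrom5,
                        GenomicRanges::start(regions["region5"]),
                        GenomicRanges::end(regions["region5"])),
    "3" = fetchSequence(reference, chrom3,
                        GenomicRanges::start(regions["region3"]),
                        GenomicRanges::end(regions["region3"])))
  region_start <- c(
    "5" = GenomicRanges::start(regions["region5"]),
    "3" = GenomicRanges::start(regions["region3"]))

  cands <- list(); ci <- 0L
  for (side in c("5", "3")) {
    w <- if (side == "5") w5 else w3
    if (!length(w)) next
    reads <- unique(.scan_region(
      bam, w, what = c("qname", "flag", "rname", "strand", "pos", "mapq",
                       "cigar", "seq", "qual")))
    reads <- reads[!is.na(reads$mapq) & reads$mapq >= config@min_mapq, ,
                   drop = FALSE]
    if (!nrow(reads)) next
    info <- .clip_info(reads$cigar)
    other <- if (side == "5") "3" else "5"
    for (i in seq_len(nrow(reads))) {
      for (clip_side in c("left", "right")) {
        clen <- if (clip_side == "left") info$left[i] else info$right[i]
        if (clen < config@min_clip_len) next
        n <- nchar(reads$seq[i])
        if (clip_side == "left") {
          clipseq <- substr(reads$seq[i], 1L, clen)
          clipqual <- substr(reads$qual[i], 1L, clen)
          boundary <- reads$pos[i]
        } else {
          clipseq <- substr(reads$seq[i], n - clen + 1L, n)
          clipqual <- substr(reads$qual[i], n - clen + 1L, n)
          boundary <- reads$pos[i] + info$refw[i] - 1L
        }
        if (.mean_baseq(clipqual) < config@min_clip_baseq) next
        hit <- .align_clip(clipseq, region_seq[[other]], config)
        if (is.null(hit)) next
        # junction-adjacent end of the clip: first base for a right clip,
        # last base for a left clip; map it through the alignment
        at_start <- (clip_side == "right") == (hit$orient == "+")
        partner_bp <- region_start[[other]] +
          (if (at_start) hit$sub_start else hit$sub_end) - 1L
        ci <- ci + 1L
        cands[[ci]] <- if (side == "5")
          data.frame(bp5 = boundary, bp3 = partner_bp,
                     clip_side5 = clip_side, clip_side3 = NA_character_,
                     stringsAsFactors = FALSE)
        else
          data.frame(bp5 = partner_bp, bp3 = boundary,
                     clip_side5 = NA_character_, clip_side3 = clip_side,
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (!ci) return(empty)
  cand <- do.call(rbind, cands)
  # greedy clustering on both coordinates
  radius <- config@breakpoint_cluster_radius
  cand <- cand[order(cand$bp5, cand$bp3), , drop = FALSE]
  cluster <- integer(nrow(cand))
  centers <- list()
  for (i in seq_len(nrow(cand))) {
    assigned <- FALSE
    for (k in seq_along(centers)) {
      if (abs(cand$bp5[i] - centers[[k]][1]) <= radius &&
          abs(cand$bp3[i] - centers[[k]][2]) <= radius) {
        cluster[i] <- k; assigned <- TRUE; break
      }
    }
    if (!assigned) {
      centers[[length(centers) + 1L]] <- c(cand$bp5[i], cand$bp3[i])
      cluster[i] <- length(centers)
    }
  }
  wmode <- function(x) {
    tab <- table(x)
    as.integer(names(tab)[which.max(tab)])  # ties: smaller (names sorted)
  }
  smode <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_character_)
    tab <- table(x)
    names(tab)[which.max(tab)]
  }
  out <- do.call(rbind, lapply(split(cand, cluster), function(cl)
    data.frame(chrom5 = chrom5, bp5 = wmode(cl$bp5),
               chrom3 = chrom3, bp3 = wmode(cl$bp3),
               support = nrow(cl),
               clip_side5 = smode(cl$clip_side5),
               clip_side3 = smode(cl$clip_side3),
               stringsAsFactors = FALSE)))
  out <- out[order(-out$support, out$bp5), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Validate one fusion call in WGS alignments
#'
#' Orchestrates [defineSearchRegions()], [extractDiscordantPairs()] and
#' [findBreakpoints()]. A fusion with fewer than `min_discordant_pairs`
#' discordant pairs is `not_validated`; with enough pairs but no
#' qualifying soft-clip evidence it is `validated`; with at least one
#' localized breakpoint it is `validated_with_breakpoint`.
#'
#' @inheritParams findBreakpoints
#' @param call one fusion call (one-row data.frame or list).
#' @param annotation a [GeneAnnotation-class].
#' @return List: `call`, `n_discordant`, `pairs`, `breakpoints`, `status`.
#' @export
validateFusion <- function(call, bam, reference, annotation,
                           config = validationConfig()) {
  regions <- defineSearchRegions(call, annotation, config)
  pairs <- extractDiscordantPairs(bam, regions, config)
  n <- nrow(pairs)
  if (n < config@min_discordant_pairs)
    return(list(call = call, n_discordant = n, pairs = pairs,
                breakpoints = NULL, status = "not_validated"))
  bps <- findBreakpoints(bam, pairs, regions, reference, config)
  status <- if (nrow(bps)) "validated_with_breakpoint" else "validated"
  list(call = call, n_discordant = n, pairs = pairs, breakpoints = bps,
       status = status)
}

#' Validate a whole call set; per-fusion failures do not stop the batch
#'
#' @inheritParams validateFusion
#' @param x a [FusionCallSet-class] (pre-filtered calls).
#' @return data.frame, one row per call: sample and partners,
#'   `n_discordant`, top breakpoint (`bp5`, `bp3`, `bp_support`),
#'   `n_breakpoints`, `status`, `error` (NA unless that fusion failed).
#' @export
validateFusions <- function(x, bam, reference, annotation,
                            config = validationConfig()) {
  df <- fusionCalls(x)
  rows <- lapply(seq_len(nrow(df)), function(i) {
    call <- df[i, ]
    out <- data.frame(
      sample_id = call$sample_id, gene5 = call$gene5, gene3 = call$gene3,
      n_discordant = 0L, bp5_chrom = NA_character_, bp5 = NA_integer_,
      bp3_chrom = NA_character_, bp3 = NA_integer_,
      bp_support = NA_integer_, n_breakpoints = 0L,
      status = "not_validated", error = NA_character_,
      stringsAsFactors = FALSE)
    res <- tryCatch(
      validateFusion(call, bam, reference, annotation, config),
      error = function(e) e)
    if (inherits(res, "error")) {
      out$error <- conditionMessage(res)
      return(out)
    }
    out$n_discordant <- res$n_discordant
    out$status <- res$status
    if (!is.null(res$breakpoints) && nrow(res$breakpoints)) {
      out$bp5_chrom <- res$breakpoints$chrom5[1L]
      out$bp5 <- res$breakpoints$bp5[1L]
      out$bp3_chrom <- res$breakpoints$chrom3[1L]
      out$bp3 <- res$breakpoints$bp3[1L]
      out$bp_support <- res$breakpoints$support[1L]
      out$n_breakpoints <- nrow(res$breakpoints)
    }
    out
  })
  do.call(rbind, rows)
}

#' Mean genome-wide sequencing depth from strided sampling
#'
#' Depth is taken at positions 1, 1+stride, 1+2*stride, ... on every
#' chromosome and pooled into one mean.
#'
#' @param bam path to an indexed BAM (or BamFile).
#' @param stride sampling stride in bp (default 100).
#' @return Mean depth (reads per sampled base) as a double; 0 with a
#'   warning for an empty alignment file.
#' @export
globalDepth <- function(bam, stride = 100) {
  # supplementary (split-read) alignments are counted, matching how
  # samtools depth filters by default
  aln <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(flag = Rsamtools::scanBamFlag(
      isSecondaryAlignment = FALSE,
      isDuplicate = FALSE, isUnmappedQuery = FALSE)))
  if (!length(aln)) {
    warning("no aligned reads; global depth is 0")
    return(0)
  }
  cov <- GenomicRanges::coverage(aln)
  sls <- GenomeInfoDb::seqlengths(aln)
  vals <- unlist(lapply(names(cov), function(cn) {
    len <- sls[[cn]]
    if (is.na(len)) len <- length(cov[[cn]])
    at <- seq(1L, len, by = as.integer(stride))
    as.numeric(cov[[cn]][at])
  }))
  mean(vals)
}

#' Re-validate after read-name-level subsampling
#'
#' Each read name is assigned one uniform draw under `seed`; a pair is
#' kept at fraction f iff its draw is below f, so both mates survive or
#' drop together and smaller fractions are nested inside larger ones.
#' Subsampling happens before any filtering. Retention at f is the
#' proportion of fusions validated on the full data that are still
#' validated on the subsample.
#'
#' @inheritParams validateFusions
#' @param fractions subsampling fractions in (0, 1].
#' @param seed RNG seed for the read-name draws (default: config's
#'   `subsample_seed`).
#' @return data.frame: `fraction`, `n_validated`, `retention`.
#' @export
subsampleValidate <- function(x, bam, reference, annotation,
                              config = validationConfig(),
                              fractions = config@subsample_fractions,
                              seed = config@subsample_seed) {
  if (any(fractions <= 0) || any(fractions > 1))
    stop("fractions must be in (0, 1]")
  full <- validateFusions(x, bam, reference, annotation, config)
  v0 <- full$status != "not_validated"
  key0 <- paste(full$sample_id, full$gene5, full$gene3)[v0]
  qn <- unique(Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(what = "qname"))[[1L]]$qname)
  set.seed(seed)
  u <- stats::setNames(stats::runif(length(qn)), qn)
  out <- lapply(sort(fractions), function(f) {
    if (f == 1) {
      nv <- sum(v0)
      return(data.frame(fraction = 1, n_validated = nv, retention = 1))
    }
    keep <- names(u)[u < f]
    dest <- tempfile(fileext = ".bam")
    keep_env <- new.env(hash = TRUE, size = length(keep))
    for (k in keep) assign(k, TRUE, envir = keep_env)
    rule <- S4Vectors::FilterRules(list(sub = function(df)
      vapply(df$qname, function(q) exists(q, envir = keep_env,
                                          inherits = FALSE), logical(1))))
    Rsamtools::filterBam(bam, dest, filter = rule,
                         param = Rsamtools::ScanBamParam(what = "qname"),
                         indexDestination = TRUE)
    sub <- validateFusions(x, dest, reference, annotation, config)
    vs <- sub$status != "not_validated"
    keys <- paste(sub$sample_id, sub$gene5, sub$gene3)[vs]
    data.frame(fraction = f, n_validated = sum(vs),
               retention = if (length(key0))
                 mean(key0 %in% keys) else NA_real_)
  })
  do.call(rbind, out)
}

#' Unbiased genome-wide scan for discordant gene-linking read pairs
#'
#' Counts discordant read pairs (same quality control as
#' [extractDiscordantPairs()]) whose two mates fall into two different
#' annotated genes, regardless of any fusion call. Intra-gene pairs are
#' ignored.
#'
#' @inheritParams globalDepth
#' @param annotation a [GeneAnnotation-class].
#' @param config a [ValidationConfig-class].
#' @return data.frame: `gene_a`, `gene_b` (unordered pair), `n`, sorted
#'   by count descending.
#' @export
unbiasedDiscordantScan <- function(bam, annotation,
                                   config = validationConfig()) {
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(
      isUnmappedQuery = FALSE, hasUnmappedMate = FALSE,
      isSecondaryAlignment = FALSE, isSupplementaryAlignment = FALSE,
      isDuplicate = FALSE, isNotPassingQualityControls = FALSE,
      isProperPair = FALSE),
    what = c("qname", "flag", "rname", "pos", "mapq"))
  res <- Rsamtools::scanBam(bam, param = param)[[1L]]
  empty <- data.frame(gene_a = character(0), gene_b = character(0),
                      n = integer(0), stringsAsFactors = FALSE)
  if (!length(res$qname)) return(empty)
  df <- data.frame(qname = res$qname, flag = res$flag,
                   rname = as.character(res$rname), pos = res$pos,
                   mapq = res$mapq, stringsAsFactors = FALSE)
  df <- df[!is.na(df$mapq) & df$mapq >= config@min_mapq, , drop = FALSE]
  first <- .flag_bit(df$flag, 64L)
  m <- merge(df[first, c("qname", "rname", "pos")],
             df[!first, c("qname", "rname", "pos")],
             by = "qname", suffixes = c("1", "2"))
  if (!nrow(m)) return(empty)
  genes <- geneRanges(annotation)
  sym <- S4Vectors::mcols(genes)$symbol
  assign_gene <- function(chrom, pos) {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
    suppressWarnings(GenomeInfoDb::seqlevels(gr) <- union(
      GenomeInfoDb::seqlevels(gr), GenomeInfoDb::seqlevels(genes)))
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(gr, genes, select = "first"))
    sym[hits]
  }
  g1 <- assign_gene(m$rname1, m$pos1)
  g2 <- assign_gene(m$rname2, m$pos2)
  ok <- !is.na(g1) & !is.na(g2) & g1 != g2
  if (!any(ok)) return(empty)
  a <- pmin(g1[ok], g2[ok]); b <- pmax(g1[ok], g2[ok])
  tab <- table(paste(a, b, sep = "\r"))
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(
    gene_a = vapply(parts, `[`, character(1), 1L),
    gene_b = vapply(parts, `[`, character(1), 2L),
    n = as.integer(tab), stringsAsFactors = FALSE)
  out <- out[order(-out$n, out$gene_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Shannon-Wiener diversity of a count distribution
#'
#' H = -sum p_i ln p_i in natural-log units; 0 <= H <= ln(k).
#'
#' @param counts non-negative counts (e.g. discordant pairs per gene
#'   pair); their sum must be positive.
#' @return H as a double.
#' @export
shannonDiversity <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total == 0) stop("counts sum to zero")
  p <- counts[counts > 0] / total
  -sum(p * log(p))
}

#' Summarize a validation run
#'
#' Either pass the per-fusion results of [validateFusions()], or the two
#' cohort counts directly. The breakpoint percentage is
#' `100 * n_with_breakpoint / n_validated`, rounded to the nearest
#' integer for display, and 0 when nothing validated.
#'
#' @param results data.frame from [validateFusions()], or the number of
#'   validated fusions as a single integer.
#' @param n_with_breakpoint number of validated fusions with at least one
#'   breakpoint (counts mode only).
#' @return List: `n_validated`, `n_with_breakpoint`,
#'   `percent_with_breakpoint`, and (results mode) `per_sample` means.
#' @export
summarizeValidation <- function(results, n_with_breakpoint = NULL) {
  if (is.numeric(results) && length(results) == 1L) {
    nv <- as.integer(results)
    nb <- as.integer(n_with_breakpoint)
    per_sample <- NULL
  } else {
    v <- results$status != "not_validated"
    nv <- sum(v)
    nb <- sum(results$status == "validated_with_breakpoint")
    per_sample <- do.call(rbind, lapply(
      split(results, results$sample_id), function(s)
        data.frame(sample_id = s$sample_id[1L],
                   n_calls = nrow(s),
                   n_validated = sum(s$status != "not_validated"),
                   mean_discordant = mean(s$n_discordant),
                   stringsAsFactors = FALSE)))
  }
  pct <- if (nv > 0L) round(100 * nb / nv) else 0L
  list(n_validated = nv, n_with_breakpoint = nb,
       percent_with_breakpoint = as.integer(pct), per_sample = per_sample)
}

#' Crosstab pipeline validation against an external label set
#'
#' Joins on (sample, unordered partner pair) over the fusions present in
#' the external set and tabulates pipeline status against the external
#' validated flag. The headline percentage is the share of
#' pipeline-validated fusions that the external source also labels
#' validated.
#'
#' @param results data.frame from [validateFusions()] (needs sample_id,
#'   gene5, gene3, status).
#' @param external data.frame with `sample_id`, `gene5`, `gene3` and a
#'   logical `validated` column.
#' @return List: `table` (2x2 matrix, pipeline x external) and `percent`
#'   (integer).
#' @export
crosstabWithExternal <- function(results, external) {
  key <- function(df) paste(df$sample_id,
                            pmin(df$gene5, df$gene3),
                            pmax(df$gene5, df$gene3))
  rk <- key(results)
  ek <- key(external)
  common <- intersect(rk, ek)
  ri <- match(common, rk); ei <- match(common, ek)
  pipe_v <- results$status[ri] != "not_validated"
  ext_v <- as.logical(external$validated)[ei]
  tab <- matrix(c(sum(pipe_v & ext_v), sum(pipe_v & !ext_v),
                  sum(!pipe_v & ext_v), sum(!pipe_v & !ext_v)),
                nrow = 2, byrow = TRUE,
                dimnames = list(pipeline = c("validated", "not_validated"),
                                external = c("validated", "not_validated")))
  denom <- tab[1, 1] + tab[1, 2]
  pct <- if (denom > 0) round(100 * tab[1, 1] / denom) else 0L
  list(table = tab, percent = as.integer(pct))
}
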