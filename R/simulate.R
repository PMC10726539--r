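# Deterministic synthetic-data generator: toy genome and gene models,
# planted fusions with configurable junction microhomology and segmental
# amplification, paired-end WGS reads written as SAM, and caller-style
# call tables with decoy false positives. Reads are emitted pre-aligned
# (SAM coordinates computed analytically from the planted junctions) so
# the test loop stays hermetic and deterministic.

.BASES <- c("A", "C", "G", "T")

.random_dna <- function(n) {
  paste(sample(.BASES, n, replace = TRUE), collapse = "")
}

#' Simulate a toy reference: genome, gene models, repeat track
#'
#' Chromosomes are random DNA; genes are placed on a slot grid (one gene
#' per slot) so that neighboring genes are separated by well more than the
#' fragment-size range, each with 3-8 non-overlapping exons and
#' approximate CDS bounds. A handful of intervals per chromosome form the
#' repeat track. Everything is deterministic given `config@seed`.
#'
#' @param config a [SimulationConfig-class].
#' @return A [FusionSimulation-class] with an empty truth table (see
#'   [plantFusions()]).
#' @export
simulateReference <- function(config = simulationConfig()) {
  methods::validObject(config)
  set.seed(config@seed)
  n_chrom <- config@n_chromosomes
  L <- config@chrom_length
  chrom_names <- paste0("chr", seq_len(n_chrom))
  genome <- Biostrings::DNAStringSet(vapply(seq_len(n_chrom),
                                            function(i) .random_dna(L),
                                            character(1)))
  names(genome) <- chrom_names

  gpc <- rep(config@n_genes %/% n_chrom, n_chrom)
  extra <- config@n_genes %% n_chrom
  if (extra > 0) gpc[seq_len(extra)] <- gpc[seq_len(extra)] + 1L
  slot_w <- floor(L / max(gpc))
  if (slot_w < 4000)
    stop("n_genes too large for chrom_length: genes do not fit")

  gene_rows <- list()
  exon_list <- list()
  gid <- 0L
  for (ci in seq_len(n_chrom)) {
    for (si in seq_len(gpc[ci])) {
      gid <- gid + 1L
      slot_start <- (si - 1L) * slot_w + 1L
      glen <- min(max(round(0.3 * slot_w), 4000L), 14000L)
      offset <- sample(seq_len(max(1L, slot_w - glen - 200L)), 1L)
      gstart <- slot_start + offset
      gend <- gstart + glen - 1L
      strand <- sample(c("+", "-"), 1L)
      k <- sample(seq(config@exons_per_gene[1], config@exons_per_gene[2]),
                  1L)
      repeat {
        elens <- sample(150:500, k, replace = TRUE)
        if (sum(elens) + (k - 1L) * 80L <= glen || k == 1L) break
        k <- k - 1L
      }
      intron_total <- glen - sum(elens)
      if (k > 1L) {
        ilens <- as.integer(stats::rmultinom(
          1L, intron_total - (k - 1L), rep(1 / (k - 1L), k - 1L))) + 1L
      } else ilens <- integer(0)
      starts <- integer(k); ends <- integer(k)
      pos <- gstart
      for (e in seq_len(k)) {
        starts[e] <- pos
        ends[e] <- pos + elens[e] - 1L
        if (e < k) pos <- ends[e] + ilens[e] + 1L
      }
      ends[k] <- gend  # last exon absorbs rounding
      sym <- sprintf("G%03d", gid)
      gene_rows[[gid]] <- data.frame(
        chrom = chrom_names[ci], start = gstart, end = gend,
        strand = strand, symbol = sym,
        gene_id = sprintf("SIMG%04d", gid),
        cds_start = starts[1L] + floor((ends[1L] - starts[1L]) / 2),
        cds_end = ends[k] - floor((ends[k] - starts[k]) / 2),
        stringsAsFactors = FALSE)
      exon_list[[sym]] <- GenomicRanges::GRanges(
        chrom_names[ci], IRanges::IRanges(starts, ends), strand = strand)
    }
  }
  gdf <- do.call(rbind, gene_rows)
  flags <- function(p) stats::runif(nrow(gdf)) < p
  genes <- GenomicRanges::GRanges(
    gdf$chrom, IRanges::IRanges(gdf$start, gdf$end), strand = gdf$strand,
    gene_id = gdf$gene_id, symbol = gdf$symbol,
    biotype = "protein_coding",
    cds_start = gdf$cds_start, cds_end = gdf$cds_end,
    is_mirna_host = flags(0.15), is_snorna_host = flags(0.10),
    in_cosmic = flags(0.20), is_kinase = flags(0.20))
  sl <- stats::setNames(rep(L, n_chrom), chrom_names)
  GenomeInfoDb::seqlengths(genes) <- sl
  ann <- new("GeneAnnotation", genes = genes,
             exons = GenomicRanges::GRangesList(exon_list))

  rep_rows <- do.call(rbind, lapply(chrom_names, function(cn) {
    nrep <- 15L
    w <- sample(300:3000, nrep, replace = TRUE)
    s <- sample(seq_len(L - max(w) - 1L), nrep)
    data.frame(chrom = cn, start = s, end = s + w - 1L,
               class = sample(c("LINE/L1", "LINE/L2", "SINE/Alu",
                                "LTR/ERV"), nrep, replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  repeats <- GenomicRanges::GRanges(
    rep_rows$chrom, IRanges::IRanges(rep_rows$start, rep_rows$end),
    repeat_class = rep_rows$class)
  GenomeInfoDb::seqlengths(repeats) <- sl

  new("FusionSimulation", genome = genome, annotation = ann,
      repeats = repeats, truth = data.frame(),
      derivatives = Biostrings::DNAStringSet(), config = config)
}

#' Plant fusions: pick partners, write microhomology into the genome,
#' build derivative contigs
#'
#' For each planted fusion a derivative contig concatenates the retained
#' 5' segment (ending at the 5' breakpoint) with the retained 3' segment
#' (starting at the 3' breakpoint). The requested junction microhomology
#' is physically written into the reference: the bases immediately lost
#' upstream of the 3' breakpoint are set equal to the retained 5' tail,
#' and the next base is forced to mismatch so the homology length is
#' exact. Intrachromosomal partners are drawn left-to-right with enough
#' separation that junction-straddling pairs are discordant.
#'
#' @param sim a [FusionSimulation-class] from [simulateReference()].
#' @return The simulation with `truth` and `derivatives` filled in and the
#'   genome edited.
#' @export
plantFusions <- function(sim) {
  config <- sim@config
  set.seed(config@seed + 1L)
  n <- config@n_true_fusions
  if (n == 0L) return(sim)
  genes <- geneRanges(sim@annotation)
  gdf <- data.frame(
    symbol = S4Vectors::mcols(genes)$symbol,
    chrom = as.character(GenomicRanges::seqnames(genes)),
    start = GenomicRanges::start(genes), end = GenomicRanges::end(genes),
    stringsAsFactors = FALSE)
  n_intra <- round(config@fraction_intrachromosomal * n)
  flank <- config@derivative_flank
  min_sep <- as.integer(2L * flank + 6L * config@insert_mean)

  used <- character(0)
  pick_pair <- function(intra) {
    for (try in seq_len(500L)) {
      avail <- gdf[!gdf$symbol %in% used, ]
      if (intra) {
        tab <- table(avail$chrom)
        chroms <- names(tab)[tab >= 2L]
        if (!length(chroms)) break
        # draw from the best-stocked chromosome so that later
        # interchromosomal fusions still find partners on both sides
        cn <- sample(names(tab)[tab == max(tab)], 1L)
        cand <- avail[avail$chrom == cn, ]
        two <- cand[sample(nrow(cand), 2L), ]
        two <- two[order(two$start), ]
        if (two$start[2L] - two$end[1L] < min_sep) next
        return(two)
      } else {
        chroms <- unique(avail$chrom)
        if (length(chroms) < 2L) break
        cn <- sample(chroms, 2L)
        g5 <- avail[avail$chrom == cn[1L], ]
        g3 <- avail[avail$chrom == cn[2L], ]
        return(rbind(g5[sample(nrow(g5), 1L), ], g3[sample(nrow(g3), 1L), ]))
      }
    }
    stop("could not place the requested fusions; too few genes")
  }

  genome_chr <- lapply(as.character(sim@genome), charToRaw)
  hlens <- rep_len(config@microhomology_range, n)
  afac <- rep_len(config@amplification_factors, max(n_intra, 1L))
  truth <- list(); ders <- list()
  intra_i <- 0L
  for (i in seq_len(n)) {
    intra <- i <= n_intra
    pr <- pick_pair(intra)
    used <- c(used, pr$symbol)
    margin5 <- max(600L, min(1000L, floor((pr$end[1] - pr$start[1]) / 4)))
    margin3 <- max(600L, min(1000L, floor((pr$end[2] - pr$start[2]) / 4)))
    bp5 <- as.integer(sample(seq(pr$start[1] + margin5,
                                 pr$end[1] - margin5), 1L))
    bp3 <- as.integer(sample(seq(pr$start[2] + margin3,
                                 pr$end[2] - margin3), 1L))
    h <- hlens[i]
    c5 <- pr$chrom[1]; c3 <- pr$chrom[2]
    raw5 <- genome_chr[[c5]]; raw3 <- genome_chr[[c3]]
    # write the homology into the lost tail upstream of bp3
    if (h > 0L)
      genome_chr[[c3]][(bp3 - h):(bp3 - 1L)] <- raw5[(bp5 - h + 1L):bp5]
    # force a mismatch one base further out so recovered h is exact
    if (genome_chr[[c3]][bp3 - h - 1L] == raw5[bp5 - h]) {
      alt <- setdiff(.BASES, rawToChar(raw5[bp5 - h]))
      genome_chr[[c3]][bp3 - h - 1L] <- charToRaw(sample(alt, 1L))
    }
    f <- if (intra) { intra_i <- intra_i + 1L; afac[intra_i] } else 1L
    lenA <- as.integer(min(flank, bp5))
    a_start <- bp5 - lenA + 1L
    b_end <- as.integer(min(config@chrom_length, bp3 + flank - 1L))
    truth[[i]] <- data.frame(
      fusion_id = sprintf("fus%02d", i),
      gene5 = pr$symbol[1], gene3 = pr$symbol[2],
      chrom5 = c5, bp5 = bp5, strand5 = "+",
      chrom3 = c3, bp3 = bp3, strand3 = "+",
      intrachromosomal = intra, microhomology_len = h,
      amplification_factor = f,
      derivative = sprintf("der%02d", i),
      a_start = a_start, b_end = b_end, junction_offset = lenA,
      stringsAsFactors = FALSE)
    ders[[sprintf("der%02d", i)]] <- paste0(
      rawToChar(genome_chr[[c5]][a_start:bp5]),
      rawToChar(genome_chr[[c3]][bp3:b_end]))
  }
  genome <- Biostrings::DNAStringSet(vapply(genome_chr, rawToChar,
                                            character(1)))
  names(genome) <- names(sim@genome)
  sim@genome <- genome
  sim@truth <- do.call(rbind, truth)
  sim@derivatives <- Biostrings::DNAStringSet(unlist(ders))
  sim
}

# analytic mapping of one derivative read interval [x, x+rl-1] back to
# reference coordinates; J = junction offset (last 5'-side base)
.map_derivative_read <- function(x, rl, tr) {
  J <- tr$junction_offset
  if (x + rl - 1L <= J) {
    list(chrom = tr$chrom5, pos = tr$a_start + x - 1L,
         cigar = sprintf("%dM", rl), side = "A", clip = 0L)
  } else if (x > J) {
    list(chrom = tr$chrom3, pos = tr$bp3 + (x - J) - 1L,
         cigar = sprintf("%dM", rl), side = "B", clip = 0L)
  } else {
    l5 <- J - x + 1L; l3 <- rl - l5
    if (l5 >= l3)
      list(chrom = tr$chrom5, pos = tr$a_start + x - 1L,
           cigar = sprintf("%dM%dS", l5, l3), side = "A", clip = l3)
    else
      list(chrom = tr$chrom3, pos = tr$bp3,
           cigar = sprintf("%dS%dM", l5, l3), side = "B", clip = l5)
  }
}

#' Simulate paired-end WGS reads and write a coordinate-sorted SAM/BAM
#'
#' Concordant pairs are drawn uniformly along every chromosome at the
#' configured base depth. Each derivative contig is additionally sequenced
#' at `max(amplification_factor - 1, 1) x` base depth; its reads are
#' mapped back to reference coordinates analytically, so junction-
#' straddling pairs come out as discordant pairs between the two partner
#' loci and junction-crossing reads come out soft-clipped with the clipped
#' sequence matching the partner locus.
#'
#' @param sim a planted [FusionSimulation-class].
#' @param out_sam output SAM path.
#' @param make_bam also produce a coordinate-sorted, indexed BAM
#'   (default TRUE).
#' @return List: `sam`, `bam` (or NA), `stats` (per-fusion counts of
#'   emitted junction-straddling discordant pairs and soft-clipped
#'   junction reads), `discordant_reads` (per-fusion read names).
#' @export
simulateWgsReads <- function(sim, out_sam, make_bam = TRUE) {
  config <- sim@config
  set.seed(config@seed + 2L)
  rl <- config@read_length
  chrom_names <- names(sim@genome)
  L <- config@chrom_length
  qual <- strrep(rawToChar(as.raw(33L + config@base_quality)), rl)

  recs <- list(); ri <- 0L
  emit <- function(df) { ri <<- ri + 1L; recs[[ri]] <<- df }

  draw_inserts <- function(n) {
    ins <- round(stats::rnorm(n, config@insert_mean, config@insert_sd))
    as.integer(pmin(pmax(ins, 2L * rl + 10L),
                    as.integer(config@insert_mean * 3)))
  }

  # background concordant coverage
  for (ci in seq_along(chrom_names)) {
    cn <- chrom_names[ci]
    seqstr <- as.character(sim@genome[[cn]])
    n_pairs <- round(L * config@base_depth / (2 * rl))
    ins <- draw_inserts(n_pairs)
    s <- floor(stats::runif(n_pairs, 1, L - ins)) ;  s <- as.integer(s)
    p1 <- s; p2 <- s + ins - rl
    qn <- sprintf("bg%s_%06d", cn, seq_len(n_pairs))
    emit(data.frame(
      qname = c(qn, qn), flag = c(rep(99L, n_pairs), rep(147L, n_pairs)),
      rname = cn, pos = c(p1, p2), mapq = config@mapq,
      cigar = sprintf("%dM", rl), rnext = "=", pnext = c(p2, p1),
      tlen = c(ins, -ins),
      seq = c(substring(seqstr, p1, p1 + rl - 1L),
              substring(seqstr, p2, p2 + rl - 1L)),
      stringsAsFactors = FALSE))
  }

  # derivative coverage
  stats_rows <- list(); disc_reads <- list()
  if (nrow(sim@truth)) {
    for (i in seq_len(nrow(sim@truth))) {
      tr <- sim@truth[i, ]
      der <- as.character(sim@derivatives[[tr$derivative]])
      Ld <- nchar(der)
      cov <- max(tr$amplification_factor - 1L, 1L) * config@base_depth
      n_pairs <- round(Ld * cov / (2 * rl))
      ins <- draw_inserts(n_pairs)
      s <- as.integer(floor(stats::runif(n_pairs, 1, Ld - ins)))
      x1 <- s; x2 <- s + ins - rl
      qn <- sprintf("%s_%05d", tr$derivative, seq_len(n_pairs))
      m1 <- lapply(x1, .map_derivative_read, rl = rl, tr = tr)
      m2 <- lapply(x2, .map_derivative_read, rl = rl, tr = tr)
      side1 <- vapply(m1, `[[`, character(1), "side")
      side2 <- vapply(m2, `[[`, character(1), "side")
      chr1 <- vapply(m1, `[[`, character(1), "chrom")
      chr2 <- vapply(m2, `[[`, character(1), "chrom")
      pos1 <- vapply(m1, `[[`, integer(1), "pos")
      pos2 <- vapply(m2, `[[`, integer(1), "pos")
      cig1 <- vapply(m1, `[[`, character(1), "cigar")
      cig2 <- vapply(m2, `[[`, character(1), "cigar")
      clip1 <- vapply(m1, `[[`, integer(1), "clip")
      clip2 <- vapply(m2, `[[`, integer(1), "clip")
      straddle <- side1 != side2
      proper <- !straddle & clip1 == 0L & clip2 == 0L
      f1 <- ifelse(proper, 99L, 97L)
      f2 <- ifelse(proper, 147L, 145L)
      rnext1 <- ifelse(chr1 == chr2, "=", chr2)
      rnext2 <- ifelse(chr1 == chr2, "=", chr1)
      tl <- ifelse(proper, ins, 0L)
      seq1 <- substring(der, x1, x1 + rl - 1L)
      seq2 <- substring(der, x2, x2 + rl - 1L)
      emit(data.frame(
        qname = c(qn, qn), flag = c(f1, f2),
        rname = c(chr1, chr2), pos = c(pos1, pos2), mapq = config@mapq,
        cigar = c(cig1, cig2), rnext = c(rnext1, rnext2),
        pnext = c(pos2, pos1), tlen = c(tl, -tl),
        seq = c(seq1, seq2),
        stringsAsFactors = FALSE))
      # junction-crossing reads additionally get a supplementary record
      # for the clipped remainder on the partner locus, as a split-read
      # aligner would emit (and as depth counting then sees)
      supp_one <- function(x, clip, side, flag_primary, seqs, mate_pos,
                           mate_chr) {
        keep <- which(clip >= 12L)
        if (!length(keep)) return(NULL)
        l5 <- tr$junction_offset - x[keep] + 1L  # 5'-side portion length
        l3 <- rl - l5
        on_a <- side[keep] == "B"  # primary on B => supplement on A
        data.frame(
          qname = qn[keep], flag = flag_primary + 2048L,
          rname = ifelse(on_a, tr$chrom5, tr$chrom3),
          pos = ifelse(on_a, tr$bp5 - l5 + 1L, tr$bp3),
          mapq = config@mapq,
          cigar = ifelse(on_a, sprintf("%dM%dS", l5, l3),
                         sprintf("%dS%dM", l5, l3)),
          rnext = mate_chr[keep], pnext = mate_pos[keep], tlen = 0L,
          seq = seqs[keep], stringsAsFactors = FALSE)
      }
      s1 <- supp_one(x1, clip1, side1, 97L, seq1, pos2, chr2)
      s2 <- supp_one(x2, clip2, side2, 145L, seq2, pos1, chr1)
      if (!is.null(s1)) emit(s1)
      if (!is.null(s2)) emit(s2)
      min_part <- pmin(pmax(clip1, clip2), rl - pmax(clip1, clip2))
      stats_rows[[i]] <- data.frame(
        fusion_id = tr$fusion_id,
        n_discordant = sum(straddle),
        n_softclip = sum((clip1 >= 12L | clip2 >= 12L) &
                           (rl - pmax(clip1, clip2)) >= 12L),
        stringsAsFactors = FALSE)
      disc_reads[[tr$fusion_id]] <- qn[straddle]
    }
  }

  all <- do.call(rbind, recs)
  all <- all[order(match(all$rname, chrom_names), all$pos), ]
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", chrom_names, L))
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                   all$qname, all$flag, all$rname, all$pos, all$mapq,
                   all$cigar, all$rnext, all$pnext, all$tlen, all$seq, qual)
  con <- file(out_sam, "w")
  writeLines(header, con)
  writeLines(lines, con)
  close(con)
  bam <- NA_character_
  if (make_bam) {
    bam <- Rsamtools::asBam(out_sam,
                            destination = sub("\\.sam$", "", out_sam),
                            overwrite = TRUE, indexDestination = TRUE)
  }
  list(sam = out_sam, bam = bam,
       stats = if (length(stats_rows)) do.call(rbind, stats_rows)
               else data.frame(),
       discordant_reads = disc_reads)
}

#' Simulate caller-style output tables with decoy false positives
#'
#' True rows carry the planted junction coordinates and are drawn with
#' stochastically larger spanning-pair counts and anchor lengths; decoy
#' rows are random unrearranged gene pairs drawn from background
#' distributions (shifted-geometric support, short anchors, a mostly
#' interchromosomal geometry), a third of them carrying banned tags and a
#' tenth carrying common-mapping reads. An FPKM expression matrix is
#' generated alongside, with fusion genes expressed lower on average.
#'
#' @param sim a planted [FusionSimulation-class].
#' @param sample_id sample identifier for all rows.
#' @param n_samples expression-matrix columns to simulate (default 4; the
#'   first is `sample_id`).
#' @return List: `fusioncatcher` and `arriba` ([FusionCallSet-class]),
#'   `labels` (data.frame sample_id/gene5/gene3/label), `expression`
#'   (FPKM matrix, genes x samples).
#' @export
simulateCallerOutput <- function(sim, sample_id = "sim1", n_samples = 4L) {
  config <- sim@config
  set.seed(config@seed + 3L)
  truth <- sim@truth
  genes <- geneRanges(sim@annotation)
  gdf <- data.frame(
    symbol = S4Vectors::mcols(genes)$symbol,
    chrom = as.character(GenomicRanges::seqnames(genes)),
    start = GenomicRanges::start(genes), end = GenomicRanges::end(genes),
    stringsAsFactors = FALSE)
  n_true <- nrow(truth)

  true_rows <- if (n_true) data.frame(
    sample_id = sample_id,
    gene5 = truth$gene5, gene3 = truth$gene3,
    chrom5 = truth$chrom5, pos5 = truth$bp5, strand5 = truth$strand5,
    chrom3 = truth$chrom3, pos3 = truth$bp3, strand3 = truth$strand3,
    spanning_pairs = 5L + stats::rnbinom(n_true, size = 4, mu = 10),
    longest_anchor = sample(20:60, n_true, replace = TRUE),
    common_mapping_reads = 0L,
    predicted_effect = sample(c("in-frame", "out-of-frame", "UTR/intronic"),
                              n_true, replace = TRUE,
                              prob = c(0.4, 0.4, 0.2)),
    confidence = sample(c("high", "medium", "low"), n_true, replace = TRUE,
                        prob = c(0.6, 0.3, 0.1)),
    stringsAsFactors = FALSE) else NULL
  if (n_true) {
    true_rows$spanning_unique_reads <-
      pmax(1L, round(0.6 * true_rows$spanning_pairs))
    true_rows$tags <- replicate(n_true, character(0), simplify = FALSE)
  }

  nd <- config@n_decoy_calls
  true_keys <- if (n_true) paste(pmin(truth$gene5, truth$gene3),
                                 pmax(truth$gene5, truth$gene3)) else
    character(0)
  decoys <- list(); di <- 0L
  while (di < nd) {
    intra <- stats::runif(1) < 0.12
    if (intra) {
      cn <- sample(unique(gdf$chrom), 1L)
      cand <- gdf[gdf$chrom == cn, ]
      if (nrow(cand) < 2L) next
      pr <- cand[sample(nrow(cand), 2L), ]
    } else {
      pr <- gdf[sample(nrow(gdf), 2L), ]
      if (pr$chrom[1] == pr$chrom[2]) next
    }
    if (paste(min(pr$symbol), max(pr$symbol)) %in% true_keys) next
    di <- di + 1L
    decoys[[di]] <- data.frame(
      sample_id = sample_id, gene5 = pr$symbol[1], gene3 = pr$symbol[2],
      chrom5 = pr$chrom[1],
      pos5 = sample(seq(pr$start[1] + 200L, pr$end[1] - 200L), 1L),
      strand5 = sample(c("+", "-"), 1L),
      chrom3 = pr$chrom[2],
      pos3 = sample(seq(pr$start[2] + 200L, pr$end[2] - 200L), 1L),
      strand3 = sample(c("+", "-"), 1L),
      spanning_pairs = 2L + stats::rgeom(1L, 0.55),
      longest_anchor = sample(13:25, 1L),
      common_mapping_reads = 0L,
      predicted_effect = sample(c("unknown", "out-of-frame", "in-frame"),
                                1L, prob = c(0.5, 0.3, 0.2)),
      confidence = sample(c("low", "medium", "high"), 1L,
                          prob = c(0.6, 0.3, 0.1)),
      stringsAsFactors = FALSE)
  }
  decoy_df <- do.call(rbind, decoys)
  if (!is.null(decoy_df)) {
    decoy_df$spanning_unique_reads <-
      pmax(0L, round(0.5 * decoy_df$spanning_pairs))
    banned_pick <- stats::runif(nd) < 0.35
    common_pick <- !banned_pick & stats::runif(nd) < 0.10
    decoy_df$tags <- lapply(seq_len(nd), function(i)
      if (banned_pick[i]) sample(bannedTags(), 1L) else character(0))
    decoy_df$common_mapping_reads[common_pick] <-
      sample(1:5, sum(common_pick), replace = TRUE)
  }
  calls <- if (is.null(decoy_df)) true_rows
           else rbind(if (n_true) true_rows[, names(decoy_df)] else NULL,
                      decoy_df)
  labels <- data.frame(
    sample_id = calls$sample_id, gene5 = calls$gene5, gene3 = calls$gene3,
    label = c(rep(TRUE, n_true), rep(FALSE, nrow(calls) - n_true)),
    stringsAsFactors = FALSE)

  fc <- calls; fc$confidence <- "none"
  fusioncatcher <- FusionCallSet(fc, caller = "fusioncatcher-like")
  arriba <- FusionCallSet(calls, caller = "arriba-like")

  fusion_genes <- unique(c(truth$gene5, truth$gene3))
  base <- stats::rlnorm(nrow(gdf), meanlog = 2, sdlog = 1)
  base[gdf$symbol %in% fusion_genes] <-
    base[gdf$symbol %in% fusion_genes] * 0.5
  expr <- vapply(seq_len(n_samples), function(s)
    base * stats::rlnorm(nrow(gdf), 0, 0.2), numeric(nrow(gdf)))
  rownames(expr) <- gdf$symbol
  colnames(expr) <- c(sample_id,
                      sprintf("%s_rep%d", sample_id,
                              seq_len(n_samples - 1L)))[seq_len(n_samples)]
  list(fusioncatcher = fusioncatcher, arriba = arriba, labels = labels,
       expression = expr)
}

#' Simulate an assembled, labeled feature table
#'
#' Directly generates the feature table a cohort-scale run would produce:
#' true rows stochastically dominate decoys in spanning-pair support and
#' anchor length and show the intrachromosomal excess, decoys follow
#' background distributions, groups emulate cancer-type strata. Used for
#' classifier training experiments at sizes where simulating reads would
#' be wasteful.
#'
#' @param n rows (default 5000).
#' @param pos_fraction fraction of true positives (default 0.01).
#' @param n_groups number of groups / cancer types (default 3).
#' @param seed RNG seed.
#' @return data.frame with feature columns plus `label` (logical),
#'   `group`, `sample_id`.
#' @export
simulateFeatureTable <- function(n = 5000L, pos_fraction = 0.01,
                                 n_groups = 3L, seed = 1L) {
  set.seed(seed)
  n_pos <- max(1L, round(n * pos_fraction))
  lab <- c(rep(TRUE, n_pos), rep(FALSE, n - n_pos))
  pick <- function(pos_draw, neg_draw)
    c(pos_draw(n_pos), neg_draw(n - n_pos))
  df <- data.frame(
    spanning_pairs = pick(
      function(k) 4L + stats::rnbinom(k, size = 5, mu = 14),
      function(k) 2L + stats::rgeom(k, 0.5)),
    spanning_unique_reads = NA_integer_,
    longest_anchor = pick(
      function(k) sample(20:60, k, replace = TRUE),
      function(k) sample(13:25, k, replace = TRUE)),
    same_chromosome = pick(
      function(k) stats::runif(k) < 0.71,
      function(k) stats::runif(k) < 0.12),
    log_expr_ratio = pick(
      function(k) stats::rnorm(k, 0, 1),
      function(k) stats::rnorm(k, 0.6, 1.2)),
    fpkm5 = pick(function(k) stats::rlnorm(k, 1.1, 0.8),
                 function(k) stats::rlnorm(k, 2, 1)),
    fpkm3 = pick(function(k) stats::rlnorm(k, 1.1, 0.8),
                 function(k) stats::rlnorm(k, 2, 1)),
    gene_length5 = stats::rlnorm(n, 9, 0.5),
    gene_length3 = stats::rlnorm(n, 9, 0.5),
    in_cosmic5 = pick(function(k) stats::runif(k) < 0.2,
                      function(k) stats::runif(k) < 0.05),
    is_mirna_host5 = stats::runif(n) < 0.12,
    predicted_effect = pick(
      function(k) sample(c("in-frame", "out-of-frame", "UTR/intronic"),
                         k, replace = TRUE, prob = c(0.5, 0.3, 0.2)),
      function(k) sample(c("in-frame", "out-of-frame", "UTR/intronic",
                           "unknown"), k, replace = TRUE,
                         prob = c(0.15, 0.35, 0.3, 0.2))),
    confidence = pick(
      function(k) sample(c("high", "medium", "low"), k, replace = TRUE,
                         prob = c(0.55, 0.3, 0.15)),
      function(k) sample(c("high", "medium", "low"), k, replace = TRUE,
                         prob = c(0.15, 0.35, 0.5))),
    label = lab, stringsAsFactors = FALSE)
  df$spanning_unique_reads <- pmax(0L, round(df$spanning_pairs *
                                               stats::runif(n, 0.4, 0.8)))
  df$group <- sample(sprintf("grp%d", seq_len(n_groups)), n, replace = TRUE)
  df$sample_id <- sprintf("s%04d", sample.int(max(50L, n %/% 20L), n,
                                              replace = TRUE))
  ord <- sample.int(n)
  df[ord, , drop = FALSE]
}

#' Write a simulation to disk as standard formats
#'
#' Writes `genome.fa` (+ `.fai`), `genes.gtf`, `repeats.bed` and
#' `truth.tsv` into `dir`.
#'
#' @param sim a [FusionSimulation-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(sim@genome, fa)
  Rsamtools::indexFa(fa)
  genes <- geneRanges(sim@annotation)
  mc <- S4Vectors::mcols(genes)
  gtf_lines <- character(0)
  for (i in seq_along(genes)) {
    cn <- as.character(GenomicRanges::seqnames(genes))[i]
    st <- as.character(GenomicRanges::strand(genes))[i]
    attr0 <- sprintf('gene_id "%s"; gene_name "%s"; gene_biotype "%s";',
                     mc$gene_id[i], mc$symbol[i], mc$biotype[i])
    gtf_lines <- c(gtf_lines, sprintf(
      "%s\tsim\tgene\t%d\t%d\t.\t%s\t.\t%s", cn,
      GenomicRanges::start(genes)[i], GenomicRanges::end(genes)[i], st,
      attr0))
    ex <- sim@annotation@exons[[mc$symbol[i]]]
    gtf_lines <- c(gtf_lines, sprintf(
      "%s\tsim\texon\t%d\t%d\t.\t%s\t.\t%s", cn,
      GenomicRanges::start(ex), GenomicRanges::end(ex), st, attr0))
    gtf_lines <- c(gtf_lines, sprintf(
      "%s\tsim\tCDS\t%d\t%d\t.\t%s\t0\t%s", cn,
      mc$cds_start[i], mc$cds_end[i], st, attr0))
  }
  writeLines(gtf_lines, file.path(dir, "genes.gtf"))
  bed <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(sim@repeats)),
    start = GenomicRanges::start(sim@repeats) - 1L,
    end = GenomicRanges::end(sim@repeats),
    name = S4Vectors::mcols(sim@repeats)$repeat_class)
  write.table(bed, file.path(dir, "repeats.bed"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (nrow(sim@truth))
    write.table(sim@truth, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' One-call simulator: reference, fusions, reads, caller output
#'
#' Convenience wrapper running [simulateReference()], [plantFusions()],
#' [simulateWgsReads()] and [simulateCallerOutput()].
#'
#' @param config a [SimulationConfig-class].
#' @param dir working directory for the SAM/BAM (tempdir subdirectory by
#'   default).
#' @return List: `sim`, `bam`, `sam`, `reads` (read-simulation stats),
#'   `calls` (caller-output list).
#' @export
simulateFusionDataset <- function(config = simulationConfig(),
                                  dir = tempfile("fusionsim")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- plantFusions(simulateReference(config))
  reads <- simulateWgsReads(sim, file.path(dir, "reads.sam"))
  calls <- simulateCallerOutput(sim)
  list(sim = sim, bam = reads$bam, sam = reads$sam, reads = reads,
       calls = calls)
}
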