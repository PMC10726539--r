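# Shared simulated datasets, built once per test run and cached.

.fwgs_cache <- new.env(parent = emptyenv())

# compact dataset: 2 x 150 kb genome, 4 planted fusions, 20x
small_sim_config <- function(seed = 7L, ...) {
  simulationConfig(chrom_length = 150000L, n_genes = 12L,
                   n_true_fusions = 4L, base_depth = 20,
                   n_decoy_calls = 20L, derivative_flank = 3000L,
                   seed = seed, ...)
}

small_sim_dataset <- function() {
  if (is.null(.fwgs_cache$small))
    .fwgs_cache$small <- simulateFusionDataset(
      small_sim_config(), dir = file.path(tempdir(), "fwgs_small"))
  .fwgs_cache$small
}

# the full default-scale dataset (2 x 1 Mb, 10 fusions, 30x, 90 decoys)
default_sim_dataset <- function() {
  if (is.null(.fwgs_cache$full))
    .fwgs_cache$full <- simulateFusionDataset(
      simulationConfig(seed = 1L), dir = file.path(tempdir(), "fwgs_full"))
  .fwgs_cache$full
}

truth_calls <- function(ds) {
  truth <- ds$sim@truth
  FusionCallSet(data.frame(
    sample_id = "sim1", gene5 = truth$gene5, gene3 = truth$gene3,
    chrom5 = truth$chrom5, pos5 = truth$bp5, strand5 = truth$strand5,
    chrom3 = truth$chrom3, pos3 = truth$bp3, strand3 = truth$strand3,
    stringsAsFactors = FALSE))
}

# random call table for prefilter property tests
random_calls <- function(n, seed) {
  set.seed(seed)
  tag_pool <- c(bannedTags()[1:10], "exon-exon", "known", "", "mt-like")
  df <- data.frame(
    sample_id = "s", gene5 = sprintf("A%03d", seq_len(n)),
    gene3 = sprintf("B%03d", seq_len(n)),
    chrom5 = "chr1", pos5 = sample.int(1e6, n), strand5 = "+",
    chrom3 = "chr2", pos3 = sample.int(1e6, n), strand3 = "+",
    spanning_pairs = sample(0:20, n, TRUE),
    common_mapping_reads = sample(0:3, n, TRUE,
                                  prob = c(0.7, 0.1, 0.1, 0.1)),
    stringsAsFactors = FALSE)
  df$tags <- lapply(seq_len(n), function(i) {
    t <- sample(tag_pool, sample(0:3, 1), replace = FALSE)
    t[nzchar(t)]
  })
  FusionCallSet(df)
}

# hand-written mini SAM: two toy chromosomes, 5 planted cross-region
# discordant pairs plus confounders (low MAPQ, proper, duplicate,
# secondary, intra-gene)
mini_sam <- function(path = tempfile(fileext = ".sam")) {
  rl <- 50L
  seqs <- strrep("ACGT", 2500)  # 10 kb each
  rec <- function(qname, flag, rname, pos, mapq, rnext, pnext,
                  cigar = sprintf("%dM", rl)) {
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t0\t%s\t%s",
            qname, flag, rname, pos, mapq, cigar, rnext, pnext,
            substr(strrep("ACGT", 20), 1, rl), strrep("I", rl))
  }
  pair <- function(qname, r1, p1, r2, p2, mapq = 60L, flag1 = 97L,
                   flag2 = 145L) {
    c(rec(qname, flag1, r1, p1, mapq, r2, p2),
      rec(qname, flag2, r2, p2, mapq, r1, p1))
  }
  lines <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chrT1\tLN:10000",
    "@SQ\tSN:chrT2\tLN:10000",
    pair("disc1", "chrT1", 1200, "chrT2", 3100),
    pair("disc2", "chrT1", 1300, "chrT2", 3200),
    pair("disc3", "chrT1", 1400, "chrT2", 3300),
    pair("disc4", "chrT1", 1500, "chrT2", 3400),
    pair("disc5", "chrT1", 1600, "chrT2", 3500),
    pair("lowq1", "chrT1", 1250, "chrT2", 3150, mapq = 5L),
    # proper pair inside region 1 (concordant insert)
    pair("prop1", "chrT1", 1100, "chrT1", 1350, flag1 = 99L, flag2 = 147L),
    # duplicate-flagged cross-region pair
    pair("dup1", "chrT1", 1700, "chrT2", 3600, flag1 = 97L + 1024L,
         flag2 = 145L + 1024L),
    # secondary cross-region pair
    pair("sec1", "chrT1", 1800, "chrT2", 3700, flag1 = 97L + 256L,
         flag2 = 145L + 256L),
    # both mates inside region 1
    pair("intra1", "chrT1", 1150, "chrT1", 1850))
  # coordinate order within each chromosome
  body <- lines[-(1:3)]
  rn <- sub("^\\S+\t\\d+\t(\\S+)\t.*", "\\1", body)
  ps <- as.integer(sub("^\\S+\t\\d+\t\\S+\t(\\d+)\t.*", "\\1", body))
  writeLines(c(lines[1:3], body[order(match(rn, c("chrT1", "chrT2")), ps)]),
             path)
  bam <- Rsamtools::asBam(path, destination = sub("\\.sam$", "", path),
                          overwrite = TRUE, indexDestination = TRUE)
  list(sam = path, bam = bam,
       regions = stats::setNames(GenomicRanges::GRanges(
         c("chrT1", "chrT2"),
         IRanges::IRanges(c(1000, 3000), c(2000, 4000))),
         c("region5", "region3")))
}

# tiny hand-built annotation: one gene per call, explicit exons/CDS
toy_annotation <- function() {
  genes <- GenomicRanges::GRanges(
    c("chr1", "chr1", "chr2"),
    IRanges::IRanges(c(1000, 20000, 5000), c(9000, 29000, 14000)),
    strand = c("+", "-", "+"),
    gene_id = c("g1", "g2", "g3"), symbol = c("GA", "GB", "GC"),
    biotype = "protein_coding",
    cds_start = c(2500, 21500, 6500), cds_end = c(7500, 27500, 12500),
    is_mirna_host = c(TRUE, FALSE, FALSE),
    is_snorna_host = FALSE,
    in_cosmic = c(FALSE, TRUE, FALSE),
    is_kinase = c(FALSE, FALSE, TRUE))
  GenomeInfoDb::seqlengths(genes) <- c(chr1 = 50000L, chr2 = 50000L)
  exons <- GenomicRanges::GRangesList(
    GA = GenomicRanges::GRanges("chr1", IRanges::IRanges(
      c(1000, 4000, 8000), c(2999, 4999, 9000)), strand = "+"),
    GB = GenomicRanges::GRanges("chr1", IRanges::IRanges(
      c(20000, 24000, 28000), c(21999, 24999, 29000)), strand = "-"),
    GC = GenomicRanges::GRanges("chr2", IRanges::IRanges(
      c(5000, 9000, 13000), c(6999, 9999, 14000)), strand = "+"))
  new("GeneAnnotation", genes = genes, exons = exons)
}
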