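random_genome <- function(lens, seed) {
  set.seed(seed)
  g <- Biostrings::DNAStringSet(vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = ""),
    character(1)))
  names(g) <- names(lens)
  g
}

# write h bases of junction homology into a genome, mismatch-terminated
plant_homology <- function(genome, bp5, bp3, h) {
  c5 <- strsplit(as.character(genome[["chrA"]]), "")[[1]]
  c3 <- strsplit(as.character(genome[["chrB"]]), "")[[1]]
  if (h > 0) c3[(bp3 - h):(bp3 - 1)] <- c5[(bp5 - h + 1):bp5]
  if (c3[bp3 - h - 1] == c5[bp5 - h])
    c3[bp3 - h - 1] <- setdiff(c("A", "C", "G", "T"), c5[bp5 - h])[1]
  genome[["chrB"]] <- Biostrings::DNAString(paste(c3, collapse = ""))
  genome
}

test_that("microhomology is the exact common prefix of the junction flanks", {
  genome <- random_genome(c(chrA = 5000L, chrB = 5000L), seed = 51)
  for (h in 0:8) {
    g <- plant_homology(genome, 2500L, 3000L, h)
    mh <- microhomologyAtBreakpoint(g, "chrA", 2500, "+", "chrB", 3000, "+")
    expect_equal(mh$homology_len, h)
    expect_equal(mh$label,
                 if (h == 0) "none" else if (h <= 5) "microhomologous"
                 else "homologous")
  }
  # longer than 5 nt flips the label to homologous
  g8 <- plant_homology(genome, 2500L, 3000L, 8L)
  expect_equal(
    microhomologyAtBreakpoint(g8, "chrA", 2500, "+", "chrB", 3000,
                              "+")$label, "homologous")
  # max_checked caps the reported length
  expect_equal(
    microhomologyAtBreakpoint(g8, "chrA", 2500, "+", "chrB", 3000, "+",
                              max_checked = 3)$homology_len, 3L)
})

test_that("reference-orientation homology equals a naive character oracle", {
  genome <- random_genome(c(chrA = 20000L, chrB = 20000L), seed = 53)
  a <- strsplit(as.character(genome[["chrA"]]), "")[[1]]
  b <- strsplit(as.character(genome[["chrB"]]), "")[[1]]
  set.seed(54)
  for (i in 1:200) {
    p5 <- sample(100:19900, 1); p3 <- sample(100:19900, 1)
    mh <- microhomologyAtBreakpoint(genome, "chrA", p5, "+", "chrB", p3,
                                    "+", max_checked = 20,
                                    orientation = "reference")$homology_len
    oracle <- 0L
    while (oracle < 20L && a[p5 - oracle] == b[p3 - 1L - oracle])
      oracle <- oracle + 1L
    expect_equal(mh, oracle)
  }
})

test_that("homology is invariant under simultaneous reverse complement", {
  genome <- random_genome(c(chrA = 4000L, chrB = 4000L), seed = 57)
  g <- plant_homology(genome, 1500L, 2500L, 4L)
  rc <- Biostrings::DNAStringSet(list(
    chrA = Biostrings::reverseComplement(g[["chrA"]]),
    chrB = Biostrings::reverseComplement(g[["chrB"]])))
  set.seed(58)
  for (p in list(c(1500L, 2500L), c(2000L, 1000L), c(123L, 3877L))) {
    fwd <- microhomologyAtBreakpoint(g, "chrA", p[1], "+", "chrB", p[2],
                                     "+")$homology_len
    rev <- microhomologyAtBreakpoint(
      rc, "chrA", 4000L - p[1] + 1L, "-", "chrB", 4000L - p[2] + 1L,
      "-")$homology_len
    expect_equal(rev, fwd)
  }
})

test_that("control breakpoints are seeded, bounded and never the observed", {
  c1 <- simulateControlBreakpoints("chrA", 5000, "chrB", 7000,
                                   20000, 20000, window = 1000,
                                   n_controls = 100, seed = 9)
  c2 <- simulateControlBreakpoints("chrA", 5000, "chrB", 7000,
                                   20000, 20000, window = 1000,
                                   n_controls = 100, seed = 9)
  expect_identical(c1, c2)
  expect_true(all(abs(c1$pos5 - 5000) <= 1000))
  expect_true(all(abs(c1$pos3 - 7000) <= 1000))
  expect_false(any(c1$pos5 == 5000 & c1$pos3 == 7000))
  # near a chromosome end the draw window is clipped, not out of range
  ce <- simulateControlBreakpoints("chrA", 30, "chrB", 19990,
                                   20000, 20000, window = 1000,
                                   n_controls = 50, seed = 10)
  expect_true(all(ce$pos5 >= 2 & ce$pos3 <= 19999))
  expect_error(simulateControlBreakpoints("a", 5, "b", 5, 10, 10,
                                          window = 0), "window")
  # uniformity of the shifts
  big <- simulateControlBreakpoints("chrA", 5000, "chrB", 7000,
                                    20000, 20000, window = 1000,
                                    n_controls = 10000, seed = 11)
  ks <- suppressWarnings(stats::ks.test(big$pos5, "punif", 4000, 6000))
  expect_gt(ks$p.value, 0.001)
})

test_that("the rank-sum homology test behaves at its boundary cases", {
  expect_lt(microhomologyTest(rep(5, 50), rep(0, 50)), 1e-10)
  set.seed(61)
  x <- sample(0:5, 40, TRUE)
  expect_equal(microhomologyTest(x, x), 0.5, tolerance = 0.05)
  expect_equal(microhomologyTest(rep(2, 30), rep(2, 30)), 1)
  expect_error(microhomologyTest(numeric(0), 1:3), "non-empty")
  # agrees with the exact null enumeration at small n (no ties)
  set.seed(62)
  obs <- sample(seq(0.1, 0.9, 0.1), 6)
  ctl <- sample(seq(1.05, 1.85, 0.1), 6) - 1
  p_norm <- microhomologyTest(obs, ctl)
  p_exact <- stats::wilcox.test(obs, ctl, alternative = "greater",
                                exact = TRUE)$p.value
  expect_equal(p_norm, p_exact, tolerance = 0.05)
})

test_that("depth profiles flip the retained side and track amplification", {
  ds <- small_sim_dataset()
  gd <- globalDepth(ds$bam)
  truth <- ds$sim@truth
  tr <- truth[truth$amplification_factor == 3, ][1, ]
  dp5 <- depthProfile(ds$bam, tr$chrom5, tr$bp5, retained = "left",
                      global_depth = gd)
  expect_equal(nrow(dp5), 201L)
  expect_equal(range(dp5$offset), c(-100L, 100L))
  # amplified retained side sits well above the lost side
  expect_gt(mean(dp5$ratio[dp5$offset < 0]), 2)
  expect_lt(mean(dp5$ratio[dp5$offset > 0]), 1.5)
  # the 3' partner is retained on the genomic right: flipping makes its
  # amplified side negative too
  dp3 <- depthProfile(ds$bam, tr$chrom3, tr$bp3, retained = "right",
                      global_depth = gd)
  expect_gt(mean(dp3$ratio[dp3$offset < 0]),
            mean(dp3$ratio[dp3$offset > 0]))
  # unamplified background: ratio about 1 (averaged over windows, since a
  # single 200 bp window carries sizeable autocorrelated Poisson noise)
  quiet <- vapply(c(30000L, 50000L, 70000L, 100000L, 130000L),
                  function(p) mean(depthProfile(
                    ds$bam, "chr1", p, retained = "left",
                    global_depth = gd)$ratio), numeric(1))
  expect_equal(mean(quiet), 1, tolerance = 0.25)
  # zero coverage gives ratio 0; a profile at the chromosome edge is
  # truncated and flagged
  empty_sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate", "@SQ\tSN:chrT1\tLN:1000"),
             empty_sam)
  empty_bam <- Rsamtools::asBam(empty_sam,
                                destination = sub("\\.sam$", "", empty_sam),
                                overwrite = TRUE, indexDestination = TRUE)
  dp0 <- depthProfile(empty_bam, "chrT1", 500, "left", global_depth = 10)
  expect_true(all(dp0$ratio == 0))
  dp_edge <- depthProfile(empty_bam, "chrT1", 30, "left", global_depth = 10)
  expect_true(attr(dp_edge, "truncated"))
  expect_lt(nrow(dp_edge), 201L)
  expect_error(depthProfile(empty_bam, "chrT1", 500, "left",
                            global_depth = 0), "positive")
})

test_that("breakpoint context classes follow the CDS > UTR > intron rule", {
  ann <- toy_annotation()
  bp <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
    pos = c(3500, 4500, 1500, 8500, 45000))
  # GA: exons 1000-2999 / 4000-4999 / 8000-9000, CDS 2500-7500; 4500 is
  # exonic inside the CDS, 3500 intronic, 1500 and 8500 exonic UTR
  ctx <- annotateBreakpointContext(bp, ann)
  expect_equal(ctx$region_class,
               c("intron", "CDS", "UTR", "UTR", "intergenic"))
  expect_equal(ctx$gene[2], "GA")
  expect_true(is.na(ctx$gene[5]))
  # repeat overlap annotation rides along
  repeats <- GenomicRanges::GRanges("chr1", IRanges::IRanges(4400, 4600),
                                    repeat_class = "LINE/L2")
  ctx2 <- annotateBreakpointContext(bp, ann, repeats)
  expect_equal(ctx2$repeat_class[2], "LINE/L2")
  expect_true(is.na(ctx2$repeat_class[1]))
})

test_that("the context chi-square is calibrated under a uniform null", {
  ds <- small_sim_dataset()
  ann <- ds$sim@annotation
  genes <- geneRanges(ann)
  syms <- S4Vectors::mcols(genes)$symbol
  set.seed(63)
  ps <- replicate(40, {
    idx <- sample(length(genes), 150, TRUE)
    pos <- GenomicRanges::start(genes)[idx] +
      vapply(GenomicRanges::width(genes)[idx], function(w)
        sample.int(w, 1L), integer(1)) - 1L
    ctx <- annotateBreakpointContext(
      data.frame(chrom = as.character(
        GenomicRanges::seqnames(genes))[idx], pos = pos), ann)
    suppressWarnings(contextChisq(ctx, ann, genes = syms)$p.value)
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.001)
  # and a grossly non-uniform draw (all CDS) is detected
  mc <- S4Vectors::mcols(genes)
  cds_bp <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(genes)),
    pos = pmin(mc$cds_start + 10L, GenomicRanges::end(genes)))
  ctx_cds <- annotateBreakpointContext(cds_bp, ann)
  keep <- ctx_cds$region_class != "intergenic"
  p_alt <- suppressWarnings(contextChisq(ctx_cds, ann,
                                         genes = syms)$p.value)
  expect_lt(p_alt, 0.01)
})

test_that("exon-expression contrasts recover planted fold changes", {
  ann <- toy_annotation()
  # GC (+ strand, exons 5000-6999/9000-9999/13000-14000), 3' junction at
  # 8000 keeps the last two exons
  fus <- data.frame(gene5 = "GA", gene3 = "GC", pos5 = 5000, pos3 = 8000)
  ee <- rbind(
    data.frame(gene = "GA", exon_start = c(1000, 4000, 8000),
               exon_end = c(2999, 4999, 9000), expr = c(10, 10, 2)),
    data.frame(gene = "GC", exon_start = c(5000, 9000, 13000),
               exon_end = c(6999, 9999, 14000), expr = c(2, 10, 10)))
  res <- exonExpressionContrast(fus, ann, ee)
  # GA on +, junction 5000: first two exons retained -> 10/2 = 5
  expect_equal(res$per_gene$fold[res$per_gene$side == "5"], 5)
  expect_equal(res$per_gene$fold[res$per_gene$side == "3"], 5)
  # flat expression: fold 1, p = 1
  ee_flat <- ee; ee_flat$expr <- 4
  fus2 <- rbind(fus, data.frame(gene5 = "GB", gene3 = "GC",
                                pos5 = 25000, pos3 = 8000))
  ee_flat <- rbind(ee_flat,
                   data.frame(gene = "GB", exon_start = c(20000, 24000,
                                                          28000),
                              exon_end = c(21999, 24999, 29000), expr = 4))
  res_flat <- exonExpressionContrast(fus2, ann, ee_flat)
  expect_true(all(res_flat$per_gene$fold == 1))
  expect_equal(res_flat$p5, 1)
  # planted 5x upregulation of 3'-retained exons with noise is recovered
  set.seed(64)
  ds <- small_sim_dataset()
  truth <- ds$sim@truth
  anns <- ds$sim@annotation
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    g3 <- truth$gene3[i]
    ex <- exonsBySymbol(anns)[[g3]]
    strand <- as.character(GenomicRanges::strand(
      lookupGene(anns, g3)))
    upstream <- GenomicRanges::start(ex) <= truth$bp3[i]
    retained <- if (strand == "+") !upstream else upstream
    retained <- retained | (GenomicRanges::start(ex) <= truth$bp3[i] &
                              GenomicRanges::end(ex) >= truth$bp3[i])
    base <- rlnorm(length(ex), 1, 0.2)
    rows[[i]] <- data.frame(
      gene = g3, exon_start = GenomicRanges::start(ex),
      exon_end = GenomicRanges::end(ex),
      expr = base * ifelse(retained, 5, 1))
  }
  ee_sim <- do.call(rbind, rows)
  fus_sim <- data.frame(gene5 = truth$gene5, gene3 = truth$gene3,
                        pos5 = truth$bp5, pos3 = truth$bp3)
  res_sim <- exonExpressionContrast(fus_sim, anns, ee_sim)
  expect_equal(res_sim$mean_fold3, 5, tolerance = 0.2)
  expect_lt(res_sim$p3, 0.01)
  expect_error(exonExpressionContrast(fus[0, ], ann, ee), "eligible")
})

test_that("kinase fusions are classed as in-frame or promoter swaps", {
  ann <- toy_annotation()  # GC is the kinase (chr2, +, CDS 6500-12500)
  mk <- function(gene3, pos3, effect) data.frame(
    gene5 = "GA", gene3 = gene3, pos5 = 5000L, pos3 = pos3,
    predicted_effect = effect, stringsAsFactors = FALSE)
  expect_equal(classifyKinaseFusion(mk("GC", 9000L, "in-frame"), ann),
               "in_frame_kinase")
  # out-of-frame with junction upstream of the kinase CDS start
  expect_equal(classifyKinaseFusion(mk("GC", 5500L, "out-of-frame"), ann),
               "promoter_swap_kinase")
  # junction inside the CDS disrupts the kinase: not a promoter swap
  expect_equal(classifyKinaseFusion(mk("GC", 9000L, "out-of-frame"), ann),
               "none")
  # no kinase partner
  expect_equal(classifyKinaseFusion(mk("GB", 25000L, "in-frame"), ann),
               "none")
  # in-frame with the kinase as 5' partner also counts
  swap <- data.frame(gene5 = "GC", gene3 = "GA", pos5 = 9000L,
                     pos3 = 5000L, predicted_effect = "in-frame",
                     stringsAsFactors = FALSE)
  expect_equal(classifyKinaseFusion(swap, ann), "in_frame_kinase")
  # unknown partner warns and returns none
  expect_warning(
    out <- classifyKinaseFusion(mk("ZZ", 100L, "out-of-frame"), ann),
    "missing")
  expect_equal(out, "none")
})
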