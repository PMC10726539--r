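test_that("search regions follow the retained-side rule", {
  ann <- toy_annotation()
  cfg <- validationConfig(region_padding = 1000)
  # 5' partner on +: from gene start to junction + padding
  call <- list(gene5 = "GA", chrom5 = "chr1", pos5 = 5000, strand5 = "+",
               gene3 = "GC", chrom3 = "chr2", pos3 = 10000, strand3 = "+")
  r <- defineSearchRegions(call, ann, cfg)
  expect_equal(GenomicRanges::start(r["region5"]), 1000)
  expect_equal(GenomicRanges::end(r["region5"]), 6000)
  # 3' partner on +: from junction - padding to gene end
  expect_equal(GenomicRanges::start(r["region3"]), 9000)
  expect_equal(GenomicRanges::end(r["region3"]), 14000)
  # minus-strand 5' partner: retained side is downstream in genome coords
  call2 <- list(gene5 = "GB", chrom5 = "chr1", pos5 = 25000, strand5 = "-",
                gene3 = "GC", chrom3 = "chr2", pos3 = 10000, strand3 = "+")
  r2 <- defineSearchRegions(call2, ann, cfg)
  expect_equal(GenomicRanges::start(r2["region5"]), 24000)
  expect_equal(GenomicRanges::end(r2["region5"]), 29000)
  # junction near the chromosome start clips at 1
  call3 <- list(gene5 = "GA", chrom5 = "chr1", pos5 = 1001, strand5 = "-",
                gene3 = "GC", chrom3 = "chr2", pos3 = 10000, strand3 = "+")
  r3 <- defineSearchRegions(call3, ann, cfg)
  expect_equal(GenomicRanges::start(r3["region5"]), 1)
  # unknown symbol errors; junction far outside the gene warns and centers
  call4 <- list(gene5 = "NOPE", chrom5 = "chr1", pos5 = 5, strand5 = "+",
                gene3 = "GC", chrom3 = "chr2", pos3 = 10000, strand3 = "+")
  expect_error(defineSearchRegions(call4, ann, cfg), "not found")
  call5 <- list(gene5 = "GA", chrom5 = "chr1", pos5 = 30000, strand5 = "+",
                gene3 = "GC", chrom3 = "chr2", pos3 = 10000, strand3 = "+")
  expect_warning(r5 <- defineSearchRegions(call5, ann, cfg), "centering")
  expect_equal(GenomicRanges::start(r5["region5"]), 29000)
  expect_equal(GenomicRanges::end(r5["region5"]), 31000)
})

test_that("discordant-pair extraction keeps exactly the planted pairs", {
  ms <- mini_sam()
  pairs <- extractDiscordantPairs(ms$bam, ms$regions)
  expect_setequal(pairs$read_name, paste0("disc", 1:5))
  expect_true(all(pairs$mapq5 == 60L & pairs$mapq3 == 60L))
  # raising min_mapq above the written quality empties the result
  expect_equal(nrow(extractDiscordantPairs(
    ms$bam, ms$regions, validationConfig(min_mapq = 70))), 0L)
  # a low-mapq pair never qualifies even at min_mapq 20
  expect_false("lowq1" %in% pairs$read_name)
  # proper pairs spanning two overlapping regions are excluded
  overlapping <- stats::setNames(GenomicRanges::GRanges(
    c("chrT1", "chrT1"), IRanges::IRanges(c(1000, 1300), c(1500, 2000))),
    c("region5", "region3"))
  p2 <- extractDiscordantPairs(ms$bam, overlapping)
  expect_false("prop1" %in% p2$read_name)
})

test_that("extraction on the simulator agrees with the read-level truth", {
  ds <- small_sim_dataset()
  truth <- ds$sim@truth
  for (i in c(1L, nrow(truth))) {
    tr <- truth[i, ]
    call <- list(gene5 = tr$gene5, chrom5 = tr$chrom5, pos5 = tr$bp5,
                 strand5 = "+", gene3 = tr$gene3, chrom3 = tr$chrom3,
                 pos3 = tr$bp3, strand3 = "+")
    regions <- defineSearchRegions(call, ds$sim@annotation)
    pairs <- extractDiscordantPairs(ds$bam, regions)
    planted <- ds$reads$discordant_reads[[tr$fusion_id]]
    # every extracted pair was planted for this fusion; most are recovered
    expect_true(all(pairs$read_name %in% planted))
    expect_gte(nrow(pairs), 5L)
  }
})

test_that("breakpoints are localized exactly from soft-clipped reads", {
  ds <- small_sim_dataset()
  truth <- ds$sim@truth
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    call <- list(gene5 = tr$gene5, chrom5 = tr$chrom5, pos5 = tr$bp5,
                 strand5 = "+", gene3 = tr$gene3, chrom3 = tr$chrom3,
                 pos3 = tr$bp3, strand3 = "+")
    res <- validateFusion(call, ds$bam, ds$sim@genome, ds$sim@annotation)
    expect_identical(res$status, "validated_with_breakpoint")
    expect_equal(res$breakpoints$bp5[1], tr$bp5)
    expect_equal(res$breakpoints$bp3[1], tr$bp3)
    expect_gte(res$breakpoints$support[1], 2L)
  }
})

test_that("no soft-clips means validated without breakpoints", {
  ms <- mini_sam()
  pairs <- extractDiscordantPairs(ms$bam, ms$regions)
  set.seed(1)
  ref <- Biostrings::DNAStringSet(c(
    chrT1 = paste(sample(c("A", "C", "G", "T"), 10000, TRUE),
                  collapse = ""),
    chrT2 = paste(sample(c("A", "C", "G", "T"), 10000, TRUE),
                  collapse = "")))
  bps <- findBreakpoints(ms$bam, pairs, ms$regions, ref)
  expect_equal(nrow(bps), 0L)
  # and with no discordant pairs at all, breakpoints are not even sought
  expect_equal(nrow(findBreakpoints(ms$bam, pairs[0, ], ms$regions, ref)),
               0L)
})

test_that("random clipped sequence is rejected by the identity filter", {
  ds <- small_sim_dataset()
  tr <- ds$sim@truth[1, ]
  call <- list(gene5 = tr$gene5, chrom5 = tr$chrom5, pos5 = tr$bp5,
               strand5 = "+", gene3 = tr$gene3, chrom3 = tr$chrom3,
               pos3 = tr$bp3, strand3 = "+")
  regions <- defineSearchRegions(call, ds$sim@annotation)
  pairs <- extractDiscordantPairs(ds$bam, regions)
  # scramble the reference of the 3' region: clips no longer align there
  set.seed(2)
  scrambled <- ds$sim@genome
  scrambled[[tr$chrom3]] <- Biostrings::DNAString(
    paste(sample(c("A", "C", "G", "T"), ds$sim@config@chrom_length, TRUE),
          collapse = ""))
  bps <- findBreakpoints(ds$bam, pairs, regions, scrambled)
  # candidates can only come from the intact 5' side, pointing elsewhere
  expect_false(any(!is.na(bps$bp3) & bps$bp3 == tr$bp3 &
                     bps$support >= 2))
})

test_that("QC thresholds act monotonically on validation counts", {
  ds <- small_sim_dataset()
  calls <- truth_calls(ds)
  base <- validateFusions(calls, ds$bam, ds$sim@genome, ds$sim@annotation)
  n_base <- sum(base$status != "not_validated")
  for (cfg in list(validationConfig(min_mapq = 70),
                   validationConfig(min_discordant_pairs = 1000))) {
    strict <- validateFusions(calls, ds$bam, ds$sim@genome,
                              ds$sim@annotation, cfg)
    expect_lte(sum(strict$status != "not_validated"), n_base)
  }
})

test_that("global depth handles strides and empty files", {
  ds <- small_sim_dataset()
  cfg <- ds$sim@config
  gd <- globalDepth(ds$bam, stride = 100)
  expect_lt(abs(gd - cfg@base_depth) / cfg@base_depth, 0.12)
  # stride equal to chromosome length samples one position per chromosome
  gd1 <- globalDepth(ds$bam, stride = cfg@chrom_length)
  expect_length(gd1, 1L)
  expect_true(gd1 >= 0)
  # header-only SAM: depth 0 with a warning
  empty_sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate", "@SQ\tSN:chrT1\tLN:1000"),
             empty_sam)
  empty_bam <- Rsamtools::asBam(empty_sam,
                                destination = sub("\\.sam$", "", empty_sam),
                                overwrite = TRUE, indexDestination = TRUE)
  expect_warning(gd0 <- globalDepth(empty_bam), "no aligned reads")
  expect_equal(gd0, 0)
})

test_that("subsampling is seeded, nested and complete at fraction 1", {
  ds <- small_sim_dataset()
  calls <- truth_calls(ds)
  rt <- subsampleValidate(calls, ds$bam, ds$sim@genome, ds$sim@annotation,
                          fractions = c(0.5, 1.0))
  expect_equal(rt$retention[rt$fraction == 1], 1.0)
  # deterministic given the seed
  rt2 <- subsampleValidate(calls, ds$bam, ds$sim@genome, ds$sim@annotation,
                           fractions = c(0.5, 1.0))
  expect_identical(rt, rt2)
  # retention non-decreasing in fraction (nested subsamples)
  expect_true(all(diff(rt$retention[order(rt$fraction)]) >= 0))
  expect_error(subsampleValidate(calls, ds$bam, ds$sim@genome,
                                 ds$sim@annotation, fractions = c(0, 0.5)),
               "fractions")
})

test_that("the unbiased scan counts only cross-gene discordant pairs", {
  ds <- small_sim_dataset()
  sc <- unbiasedDiscordantScan(ds$bam, ds$sim@annotation)
  truth <- ds$sim@truth
  truth_keys <- paste(pmin(truth$gene5, truth$gene3),
                      pmax(truth$gene5, truth$gene3))
  scan_keys <- paste(pmin(sc$gene_a, sc$gene_b),
                     pmax(sc$gene_a, sc$gene_b))
  # every planted pair is found, and dominates the counts
  expect_true(all(truth_keys %in% scan_keys))
  expect_true(all(sc$n[scan_keys %in% truth_keys] >= 5))
  expect_true(all(sc$n[!scan_keys %in% truth_keys] <= 2))
  # a proper-pair-only alignment yields no counts, and an intra-gene
  # discordant pair is ignored
  ms <- mini_sam()
  ann <- new("GeneAnnotation",
             genes = {
               g <- GenomicRanges::GRanges(
                 "chrT1", IRanges::IRanges(c(1000, 1500), c(1400, 2000)),
                 gene_id = c("t1", "t2"), symbol = c("T1", "T2"),
                 biotype = "protein_coding",
                 cds_start = c(1100, 1600), cds_end = c(1300, 1900),
                 is_mirna_host = FALSE, is_snorna_host = FALSE,
                 in_cosmic = FALSE, is_kinase = FALSE)
               GenomeInfoDb::seqlengths(g) <- c(chrT1 = 10000L)
               g
             },
             exons = GenomicRanges::GRangesList(
               T1 = GenomicRanges::GRanges("chrT1",
                                           IRanges::IRanges(1000, 1400)),
               T2 = GenomicRanges::GRanges("chrT1",
                                           IRanges::IRanges(1500, 2000))))
  sc2 <- unbiasedDiscordantScan(ms$bam, ann)
  # disc* pairs have mates on chrT2 (ungened); intra1 lands in T1+T2
  expect_true(nrow(sc2) <= 1)
  if (nrow(sc2) == 1) expect_setequal(c(sc2$gene_a, sc2$gene_b),
                                      c("T1", "T2"))
})

test_that("Shannon diversity matches its closed form", {
  expect_equal(shannonDiversity(c(10)), 0)
  expect_equal(shannonDiversity(rep(7, 10)), log(10))
  set.seed(13)
  counts <- rpois(25, 40) + 1
  p <- counts / sum(counts)
  expect_equal(shannonDiversity(counts), -sum(p * log(p)))
  expect_error(shannonDiversity(c(0, 0)), "zero")
  expect_error(shannonDiversity(c(-1, 2)), "non-negative")
  # validated fusion pairs are more diverse than a scan dominated by one
  # recurrent artifact pair
  expect_gt(shannonDiversity(rep(5, 12)),
            shannonDiversity(c(200, rep(1, 11))))
})

test_that("validation summaries reproduce printed cohort arithmetic", {
  s <- summarizeValidation(4237, 3049)
  expect_equal(s$percent_with_breakpoint, 72L)
  expect_equal(summarizeValidation(0, 0)$percent_with_breakpoint, 0L)
  expect_equal(summarizeValidation(10, 10)$percent_with_breakpoint, 100L)
  # results-mode path
  res <- data.frame(
    sample_id = c("a", "a", "b"), gene5 = c("X", "Y", "Z"),
    gene3 = c("U", "V", "W"), n_discordant = c(5L, 2L, 0L),
    status = c("validated_with_breakpoint", "validated", "not_validated"))
  s2 <- summarizeValidation(res)
  expect_equal(s2$n_validated, 2L)
  expect_equal(s2$n_with_breakpoint, 1L)
  expect_equal(s2$percent_with_breakpoint, 50L)
  expect_equal(nrow(s2$per_sample), 2L)
})

test_that("the external crosstab joins on unordered pairs", {
  mk_labels <- function(n, prefix, validated) data.frame(
    sample_id = sprintf("%s%04d", prefix, seq_len(n)),
    gene5 = "A", gene3 = "B", validated = validated,
    stringsAsFactors = FALSE)
  ext <- rbind(mk_labels(161, "pv_ev", TRUE), mk_labels(244, "pv_en", FALSE),
               mk_labels(22, "pn_ev", TRUE), mk_labels(158, "pn_en", FALSE))
  res <- ext
  res$status <- ifelse(grepl("^pv", res$sample_id), "validated",
                       "not_validated")
  ct <- crosstabWithExternal(res, ext)
  expect_equal(as.vector(ct$table), c(161L, 22L, 244L, 158L))
  expect_equal(ct$percent, 40L)
  # reciprocal partner order still joins
  res_swapped <- res
  res_swapped$gene5 <- "B"; res_swapped$gene3 <- "A"
  expect_equal(crosstabWithExternal(res_swapped, ext)$percent, 40L)
  # empty external set
  ct0 <- crosstabWithExternal(res, ext[0, ])
  expect_equal(sum(ct0$table), 0L)
  # identical labelings have empty off-diagonal
  ext2 <- ext; ext2$validated <- res$status == "validated"
  ct2 <- crosstabWithExternal(res, ext2)
  expect_equal(ct2$table[1, 2] + ct2$table[2, 1], 0L)
})
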