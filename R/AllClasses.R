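#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

.PREDICTED_EFFECTS <- c("in-frame", "out-of-frame", "UTR/intronic", "unknown")
.CONFIDENCE_LEVELS <- c("high", "medium", "low", "none")
.CALLERS <- c("fusioncatcher-like", "arriba-like")

#' Columns every fusion-call table carries
#'
#' Internal column manifest of the normalized fusion-call representation.
#' All coordinates are 1-based inclusive; `tags` is a list column of
#' character vectors.
#' @keywords internal
.FUSION_CALL_COLUMNS <- c(
  "sample_id", "gene5", "gene3",
  "chrom5", "pos5", "strand5",
  "chrom3", "pos3", "strand3",
  "spanning_pairs", "spanning_unique_reads", "longest_anchor",
  "tags", "common_mapping_reads", "predicted_effect", "confidence"
)

#' FusionCallSet: a set of fusion-transcript predictions from one caller
#'
#' Normalized container for fusion calls parsed from a FusionCatcher-style
#' or Arriba-style table. One row per predicted fusion transcript; partner
#' junctions are stored as (chromosome, 1-based position, strand).
#'
#' @slot calls data.frame with the columns in the internal manifest
#'   (sample/partner identifiers, junction coordinates, read support,
#'   tags, predicted effect, confidence).
#' @slot caller character, `"fusioncatcher-like"` or `"arriba-like"`.
#' @export
setClass("FusionCallSet",
  representation(calls = "data.frame", caller = "character"),
  prototype(calls = data.frame(), caller = "fusioncatcher-like")
)

setValidity("FusionCallSet", function(object) {
  msgs <- character()
  if (!object@caller %in% .CALLERS)
    msgs <- c(msgs, sprintf("caller must be one of: %s",
                            paste(.CALLERS, collapse = ", ")))
  df <- object@calls
  if (nrow(df) > 0L) {
    missing_cols <- setdiff(.FUSION_CALL_COLUMNS, names(df))
    if (length(missing_cols))
      msgs <- c(msgs, sprintf("missing call columns: %s",
                              paste(missing_cols, collapse = ", ")))
    if (!length(missing_cols)) {
      if (any(df$pos5 < 1L) || any(df$pos3 < 1L))
        msgs <- c(msgs, "junction positions must be >= 1")
      if (any(df$spanning_pairs < 0L) || any(df$spanning_unique_reads < 0L) ||
          any(df$common_mapping_reads < 0L))
        msgs <- c(msgs, "read counts must be >= 0")
      if (!all(df$predicted_effect %in% .PREDICTED_EFFECTS))
        msgs <- c(msgs, "invalid predicted_effect value")
      if (!all(df$confidence %in% .CONFIDENCE_LEVELS))
        msgs <- c(msgs, "invalid confidence value")
      if (object@caller == "fusioncatcher-like" &&
          !all(df$confidence == "none"))
        msgs <- c(msgs, "fusioncatcher-like calls must have confidence 'none'")
      if (!is.list(df$tags))
        msgs <- c(msgs, "tags must be a list column")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a FusionCallSet
#'
#' @param calls data.frame of normalized calls (see [fusionCalls()] for the
#'   column set). Missing columns are filled with neutral defaults.
#' @param caller caller dialect the calls came from.
#' @return A [FusionCallSet-class] object.
#' @export
FusionCallSet <- function(calls = data.frame(), caller = "fusioncatcher-like") {
  if (nrow(calls) > 0L) {
    defaults <- list(
      spanning_pairs = 0L, spanning_unique_reads = 0L,
      longest_anchor = NA_integer_, common_mapping_reads = 0L,
      predicted_effect = "unknown",
      confidence = if (caller == "fusioncatcher-like") "none" else "low",
      strand5 = "+", strand3 = "+"
    )
    for (nm in names(defaults))
      if (is.null(calls[[nm]])) calls[[nm]] <- defaults[[nm]]
    if (is.null(calls$tags)) calls$tags <- replicate(nrow(calls), character(0),
                                                     simplify = FALSE)
    calls <- calls[, .FUSION_CALL_COLUMNS]
  }
  new("FusionCallSet", calls = calls, caller = caller)
}

#' GeneAnnotation: gene models with interval and symbol lookup
#'
#' Gene models parsed from GTF, carrying per-gene boolean flags (COSMIC
#' membership, miRNA/snoRNA host status, kinase status) and approximate CDS
#' bounds used for breakpoint-context and promoter-swap classification.
#'
#' @slot genes GRanges, one range per gene; mcols hold gene_id, symbol,
#'   biotype, cds_start, cds_end and the boolean flags.
#' @slot exons GRangesList keyed by gene symbol.
#' @export
setClass("GeneAnnotation",
  representation(genes = "GRanges", exons = "GRangesList"))

setValidity("GeneAnnotation", function(object) {
  msgs <- character()
  need <- c("gene_id", "symbol", "biotype", "cds_start", "cds_end",
            "is_mirna_host", "is_snorna_host", "in_cosmic", "is_kinase")
  missing_cols <- setdiff(need, names(S4Vectors::mcols(object@genes)))
  if (length(missing_cols))
    msgs <- c(msgs, sprintf("genes mcols missing: %s",
                            paste(missing_cols, collapse = ", ")))
  if (!length(missing_cols) && length(object@genes)) {
    sym <- S4Vectors::mcols(object@genes)$symbol
    if (anyDuplicated(sym))
      msgs <- c(msgs, "duplicated gene symbols")
    if (!all(sym %in% names(object@exons)))
      msgs <- c(msgs, "every gene needs an exon set")
    # exons must lie inside their gene
    for (i in seq_along(object@genes)) {
      ex <- object@exons[[sym[i]]]
      g <- object@genes[i]
      if (length(ex) == 0L) { msgs <- c(msgs, "gene without exons"); break }
      if (any(GenomicRanges::start(ex) < GenomicRanges::start(g)) ||
          any(GenomicRanges::end(ex) > GenomicRanges::end(g))) {
        msgs <- c(msgs, sprintf("exons outside gene bounds for %s", sym[i]))
        break
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' ValidationConfig: thresholds for the WGS validation pipeline
#'
#' Quality and search parameters for discordant-pair extraction and
#' soft-clip breakpoint localization. Defaults are conventional
#' SV-calling values; every threshold is exposed so alternative pipelines
#' can be mirrored.
#'
#' @slot min_mapq minimum mapping quality required of both mates (default 20).
#' @slot min_discordant_pairs minimum discordant pairs to call a fusion
#'   validated (default 1).
#' @slot min_clip_len minimum soft-clip length in nt considered as breakpoint
#'   evidence (default 12).
#' @slot min_clip_baseq minimum mean base quality over the clipped segment
#'   (default 20).
#' @slot clip_search_window bp around discordant-mate positions searched for
#'   clipped reads (default 1000).
#' @slot min_align_identity minimum identity of the local alignment of a
#'   clipped segment against the partner region (default 0.9).
#' @slot min_align_len minimum aligned length of that alignment (default 12).
#' @slot breakpoint_cluster_radius bp radius for merging candidate
#'   breakpoints (default 5).
#' @slot region_padding bp added past the junction when defining search
#'   regions (default 1000).
#' @slot depth_stride stride in bp for global depth sampling (default 100).
#' @slot subsample_fractions read fractions for the subsampling harness
#'   (default 0.25, 0.50, 0.75).
#' @slot subsample_seed seed used for read-name subsampling (default 123).
#' @export
setClass("ValidationConfig",
  representation(
    min_mapq = "integer", min_discordant_pairs = "integer",
    min_clip_len = "integer", min_clip_baseq = "numeric",
    clip_search_window = "integer", min_align_identity = "numeric",
    min_align_len = "integer", breakpoint_cluster_radius = "integer",
    region_padding = "integer", depth_stride = "integer",
    subsample_fractions = "numeric", subsample_seed = "integer"),
  prototype(
    min_mapq = 20L, min_discordant_pairs = 1L,
    min_clip_len = 12L, min_clip_baseq = 20,
    clip_search_window = 1000L, min_align_identity = 0.9,
    min_align_len = 12L, breakpoint_cluster_radius = 5L,
    region_padding = 1000L, depth_stride = 100L,
    subsample_fractions = c(0.25, 0.5, 0.75), subsample_seed = 123L)
)

setValidity("ValidationConfig", function(object) {
  msgs <- character()
  pos <- c(min_mapq = object@min_mapq >= 0,
           min_discordant_pairs = object@min_discordant_pairs >= 1,
           min_clip_len = object@min_clip_len >= 1,
           clip_search_window = object@clip_search_window >= 1,
           min_align_len = object@min_align_len >= 1,
           breakpoint_cluster_radius = object@breakpoint_cluster_radius >= 0,
           region_padding = object@region_padding >= 0,
           depth_stride = object@depth_stride >= 1)
  if (!all(pos))
    msgs <- c(msgs, sprintf("non-positive parameter: %s",
                            paste(names(pos)[!pos], collapse = ", ")))
  if (object@min_align_identity <= 0 || object@min_align_identity > 1)
    msgs <- c(msgs, "min_align_identity must be in (0, 1]")
  if (length(object@subsample_fractions) &&
      (any(object@subsample_fractions <= 0) ||
       any(object@subsample_fractions > 1)))
    msgs <- c(msgs, "subsample_fractions must be in (0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' @rdname ValidationConfig-class
#' @param ... slot overrides, e.g. `min_mapq = 30`.
#' @return A `ValidationConfig` object.
#' @export
validationConfig <- function(...) {
  args <- list(...)
  ints <- c("min_mapq", "min_discordant_pairs", "min_clip_len",
            "clip_search_window", "min_align_len",
            "breakpoint_cluster_radius", "region_padding", "depth_stride",
            "subsample_seed")
  for (nm in intersect(names(args), ints)) args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c(list("ValidationConfig"), args))
}

#' SimulationConfig: conditions for the synthetic fusion dataset
#'
#' Parameters of the deterministic simulator: a small multi-chromosome
#' genome with exon/intron gene models, planted intra- and interchromosomal
#' fusions with configurable junction microhomology and segmental
#' amplification, paired-end WGS reads written as SAM, and caller-style
#' call tables with decoy false positives. The default intrachromosomal
#' fraction (0.7) mirrors the observed excess of intrachromosomal events
#' among DNA-validated fusions.
#'
#' @slot n_chromosomes number of chromosomes (default 2).
#' @slot chrom_length length of each chromosome in bp (default 1e6).
#' @slot n_genes total number of genes (default 40).
#' @slot exons_per_gene range of exon counts per gene (default 3..8).
#' @slot n_true_fusions planted fusions (default 10).
#' @slot fraction_intrachromosomal fraction of planted fusions with both
#'   partners on one chromosome (default 0.7).
#' @slot microhomology_range candidate junction-microhomology lengths in nt,
#'   cycled over the planted fusions (default 0..8).
#' @slot amplification_factors candidate copy-ratio targets for
#'   intrachromosomal fusions (default 1,2,3); interchromosomal fusions get 1.
#' @slot base_depth haploid sequencing depth of the background genome
#'   (default 30).
#' @slot read_length read length in nt (default 100).
#' @slot insert_mean,insert_sd fragment-size model (default 350 / 50).
#' @slot n_decoy_calls decoy (false-positive) caller rows (default 90).
#' @slot derivative_flank bp of sequence retained on each side of the
#'   junction in the derivative contig (default 3000).
#' @slot mapq mapping quality written for simulated reads (default 60).
#' @slot base_quality constant Phred base quality of simulated reads
#'   (default 35).
#' @slot seed master seed; every simulator stage derives from it.
#' @export
setClass("SimulationConfig",
  representation(
    n_chromosomes = "integer", chrom_length = "integer", n_genes = "integer",
    exons_per_gene = "integer", n_true_fusions = "integer",
    fraction_intrachromosomal = "numeric", microhomology_range = "integer",
    amplification_factors = "integer", base_depth = "numeric",
    read_length = "integer", insert_mean = "numeric", insert_sd = "numeric",
    n_decoy_calls = "integer", derivative_flank = "integer",
    mapq = "integer", base_quality = "integer", seed = "integer"),
  prototype(
    n_chromosomes = 2L, chrom_length = 1000000L, n_genes = 40L,
    exons_per_gene = c(3L, 8L), n_true_fusions = 10L,
    fraction_intrachromosomal = 0.7, microhomology_range = 0:8,
    amplification_factors = c(1L, 2L, 3L), base_depth = 30,
    read_length = 100L, insert_mean = 350, insert_sd = 50,
    n_decoy_calls = 90L, derivative_flank = 3000L,
    mapq = 60L, base_quality = 35L, seed = 1L)
)

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  if (object@n_chromosomes < 1 || object@chrom_length < 10000 ||
      object@n_genes < 2 || object@n_true_fusions < 0 ||
      object@base_depth <= 0 || object@read_length < 20 ||
      object@insert_mean <= 2 * object@read_length + 10)
    msgs <- c(msgs, "degenerate simulation geometry")
  if (object@fraction_intrachromosomal < 0 ||
      object@fraction_intrachromosomal > 1)
    msgs <- c(msgs, "fraction_intrachromosomal must be in [0, 1]")
  if (any(object@microhomology_range < 0))
    msgs <- c(msgs, "microhomology lengths must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' @rdname SimulationConfig-class
#' @param ... slot overrides, e.g. `chrom_length = 2e5`.
#' @return A `SimulationConfig` object.
#' @export
simulationConfig <- function(...) {
  args <- list(...)
  ints <- c("n_chromosomes", "chrom_length", "n_genes", "exons_per_gene",
            "n_true_fusions", "microhomology_range", "amplification_factors",
            "read_length", "n_decoy_calls", "derivative_flank", "mapq",
            "base_quality", "seed")
  for (nm in intersect(names(args), ints)) args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c(list("SimulationConfig"), args))
}

#' FusionSimulation: a fully specified synthetic dataset
#'
#' Produced by [simulateReference()] and enriched by [plantFusions()]:
#' holds the (possibly edited) genome, the annotation, the repeat track,
#' the fusion truth table and the derivative contig sequences.
#'
#' @slot genome DNAStringSet of chromosome sequences.
#' @slot annotation GeneAnnotation of the simulated gene models.
#' @slot repeats GRanges of simulated repeat intervals (mcols: repeat_class).
#' @slot truth data.frame of planted fusions (one row per fusion:
#'   partners, breakpoints, microhomology length, amplification factor).
#' @slot derivatives DNAStringSet of derivative (fused) contigs.
#' @slot config SimulationConfig the dataset was generated under.
#' @export
setClass("FusionSimulation",
  representation(genome = "DNAStringSet", annotation = "GeneAnnotation",
                 repeats = "GRanges", truth = "data.frame",
                 derivatives = "DNAStringSet", config = "SimulationConfig"))

#' TrainingConfig: protocol for classifier training and tuning
#'
#' @slot n_tuning_candidates hyperparameter candidates drawn from the
#'   seeded space-filling design (default 100).
#' @slot nrounds boosting rounds per model (default 100).
#' @slot early_stopping_rounds early-stopping patience (default 10).
#' @slot cv_scheme `"leave-one-group-out"` (default) or `"k-fold"`.
#' @slot k folds when `cv_scheme = "k-fold"` (default 10).
#' @slot holdout_fraction fraction held out before training when a simple
#'   train/test split is requested (default 0.25); 0 disables the split.
#' @slot classification_threshold probability threshold for the binary call
#'   (default 0.2).
#' @slot seed seed controlling the candidate design, fold assignment and
#'   the booster.
#' @export
setClass("TrainingConfig",
  representation(
    n_tuning_candidates = "integer", nrounds = "integer",
    early_stopping_rounds = "integer", cv_scheme = "character",
    k = "integer", holdout_fraction = "numeric",
    classification_threshold = "numeric", seed = "integer"),
  prototype(
    n_tuning_candidates = 100L, nrounds = 100L,
    early_stopping_rounds = 10L, cv_scheme = "leave-one-group-out",
    k = 10L, holdout_fraction = 0.25, classification_threshold = 0.2,
    seed = 1L)
)

setValidity("TrainingConfig", function(object) {
  msgs <- character()
  if (!object@cv_scheme %in% c("leave-one-group-out", "k-fold"))
    msgs <- c(msgs, "cv_scheme must be leave-one-group-out or k-fold")
  if (object@nrounds < 1 || object@n_tuning_candidates < 1)
    msgs <- c(msgs, "rounds and candidate counts must be positive")
  if (object@holdout_fraction < 0 || object@holdout_fraction >= 1)
    msgs <- c(msgs, "holdout_fraction must be in [0, 1)")
  if (object@classification_threshold < 0 ||
      object@classification_threshold > 1)
    msgs <- c(msgs, "classification_threshold must be in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' @rdname TrainingConfig-class
#' @param ... slot overrides, e.g. `n_tuning_candidates = 20`.
#' @return A `TrainingConfig` object.
#' @export
trainingConfig <- function(...) {
  args <- list(...)
  ints <- c("n_tuning_candidates", "nrounds", "early_stopping_rounds",
            "k", "seed")
  for (nm in intersect(names(args), ints)) args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c(list("TrainingConfig"), args))
}

#' ModelBundle: a trained fusion classifier with its manifest
#'
#' @slot model fitted xgboost booster.
#' @slot feature_names encoded feature-column manifest; prediction refuses
#'   tables whose encoded columns differ.
#' @slot threshold classification threshold associated with the model.
#' @slot tuning data.frame tuning trace (one row per candidate, CV scores).
#' @slot params winning hyperparameter set.
#' @slot config TrainingConfig used.
#' @export
setClass("ModelBundle",
  representation(model = "ANY", feature_names = "character",
                 threshold = "numeric", tuning = "data.frame",
                 params = "list", config = "TrainingConfig"))

#' MetricsReport: binary-classification performance metrics
#'
#' Threshold metrics (precision, recall, specificity, accuracy, f1,
#' Cohen's kappa) are always computed; probability metrics (log loss,
#' ROC AUC, PR AUC, Brier score) are `NA` with `has_probabilities = FALSE`
#' when no probabilities were supplied, mirroring how rule-based filters
#' produce no scores.
#'
#' @slot tp,fn,fp,tn confusion counts.
#' @slot precision,recall,specificity,accuracy,f1,kappa threshold metrics.
#' @slot log_loss,roc_auc,pr_auc,brier probability metrics (NA when absent).
#' @slot has_probabilities logical flag.
#' @slot degenerate character vector naming metrics that were defined-0
#'   because their denominator was empty.
#' @export
setClass("MetricsReport",
  representation(
    tp = "integer", fn = "integer", fp = "integer", tn = "integer",
    precision = "numeric", recall = "numeric", specificity = "numeric",
    accuracy = "numeric", f1 = "numeric", kappa = "numeric",
    log_loss = "numeric", roc_auc = "numeric", pr_auc = "numeric",
    brier = "numeric", has_probabilities = "logical",
    degenerate = "character"))
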