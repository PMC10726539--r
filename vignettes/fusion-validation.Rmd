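---
title: "Validating fusion transcripts in matched WGS data: models, parameters and design"
author: "fusionWGS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating fusion transcripts in matched WGS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusionWGS)
```

# The validation model

A fusion transcript called from RNA-Seq asserts that exonic sequence of
a 5′ partner gene is joined to a 3′ partner. If the underlying genomic
rearrangement is real, a matched WGS library must contain read pairs
whose two mates map near the two junctions with a geometry incompatible
with the reference (discordant pairs), and usually reads that cross the
genomic breakpoint itself, which aligners report with soft-clipped
ends. `fusionWGS` treats the presence of quality-filtered discordant
pairs as validation and a localized soft-clip breakpoint as the
stronger tier of evidence:

1. **Search regions** (`defineSearchRegions`). For each partner the
   region runs from the gene boundary on the transcribed (retained)
   side of the junction to the junction plus `region_padding`
   (default 1000 bp) past it, clipped at chromosome ends. The retained
   side is decided by the call's junction strand. The padding absorbs
   both imprecision in the RNA junction (intronic genomic breakpoints
   are invisible to spliced reads) and the fragment-size spread of the
   WGS library, which is why it should stay above the library's insert
   range.

2. **Discordant pairs** (`extractDiscordantPairs`). A pair qualifies
   when one mate maps in each region, both mates have
   MAPQ ≥ `min_mapq` (20), and no record is a duplicate, secondary,
   supplementary or unmapped alignment. Proper-pair-flagged reads are
   excluded: a concordant insert is what the aligner says a normal
   fragment looks like, so it cannot witness a rearrangement. Each read
   name counts once even when the regions overlap. Pair orientation is
   deliberately not constrained by default — real rearrangements
   produce every orientation class — but all thresholds sit in
   `ValidationConfig` for stricter reproductions.

3. **Breakpoints** (`findBreakpoints`). Reads with a soft clip of at
   least `min_clip_len` (12 nt) and mean clipped base quality ≥ 20,
   lying within `clip_search_window` (1000 bp) of any discordant mate,
   are candidate junction-crossing reads. The clipped segment is
   locally aligned (Smith–Waterman via `pairwiseAlignment`; match +1,
   mismatch −4, gap open 6, gap extend 1) against the *opposite*
   partner's region sequence in both orientations; an alignment with
   identity ≥ 0.9 over ≥ 12 nt turns the clip boundary into a
   breakpoint candidate on its own partner and the junction-facing end
   of the alignment into the candidate on the other. Candidates within
   `breakpoint_cluster_radius` (5 bp) on both coordinates merge; the
   reported position is the support-weighted mode with ties broken
   toward the smaller coordinate. The scoring penalties are
   conventional SV-calling values: with a −4 mismatch, a 12-nt
   alignment tolerates at most one error before falling under the
   identity floor, which is what keeps random clips out (the test suite
   checks exactly this rejection).

A fusion with fewer than `min_discordant_pairs` (default 1) pairs is
`not_validated`. One pair is deliberately permissive: the decoy
specificity of the pipeline comes from requiring *both* mates to land
in the two specific partner regions at MAPQ ≥ 20, which background
read pairs essentially never do, rather than from a count threshold.
Raising either threshold can only shrink the validated set
(monotonicity is a tested invariant).

# Depth, subsampling and the unbiased scan

Global depth is the mean of per-base depth sampled every
`depth_stride` = 100 bp, pooled over chromosomes. Depth counting
includes supplementary (split-read) alignments, matching the default
filter of `samtools depth`; breakpoint-crossing reads therefore
contribute their full length to coverage. Subsampling
(`subsampleValidate`) assigns each read name one uniform draw under
`subsample_seed` (123) and keeps it at fraction *f* iff the draw is
below *f* — both mates survive or drop together, smaller fractions are
nested inside larger ones (making retention monotone by construction),
and subsampling happens before any filtering. The unbiased scan
(`unbiasedDiscordantScan`) applies the same pair-level QC genome-wide
and counts pairs whose mates fall in two different annotated genes;
`shannonDiversity` (H = −Σ pᵢ ln pᵢ) summarizes how concentrated those
counts are — recurrent artifact pairs give H near 0, genuine fusion
sets give H near ln k.

# The classifier

`trainClassifier` fits a gradient-boosted decision-tree ensemble
(xgboost, binary logistic objective) on RNA-only features, with the WGS
validation verdict as the label. Design choices that matter:

* **Hyperparameter search**: `n_tuning_candidates` (100) points from a
  seeded Latin-hypercube design over tree depth (3–8), learning rate
  (10⁻²–10⁻⁰·⁵, log scale), minimum child weight (1–20), row and
  column subsampling (0.5–1), gamma (0–2) and the positive-class
  weight (1 up to the class ratio — the realistic regime is ~1%
  positives). A space-filling design covers the space at any budget,
  unlike a factorial grid.
* **Cross-validation**: leave-one-group-out over cancer-type-like
  groups by default, because validation rates differ sharply between
  groups and a random split would leak group identity; k-fold (k = 10)
  is available for single-cohort models. Each candidate trains up to
  100 rounds with early stopping after 10 stagnant rounds on the
  held-out fold.
* **Objective**: candidates are ranked by mean CV PR-AUC and by mean CV
  F1 (at the classification threshold, default 0.2); the winner
  minimizes the rank sum with PR-AUC dominant on ties. Under heavy
  class imbalance PR-AUC is the informative curve; F1 anchors the
  operating point.
* **Threshold**: fixed 0.2 by default; `selectThresholdYouden` derives
  a data-driven threshold maximizing sensitivity + specificity − 1
  when an evaluation split is available. Probabilities are reported
  uncalibrated.
* **Determinism**: the candidate design, fold assignment and booster
  all derive from `TrainingConfig@seed`, and training is single-thread,
  so a seed fully reproduces the tuning trace and predictions.

`computeMetrics` reports the full panel (precision, recall,
specificity, accuracy, F1, Cohen's kappa, log loss, ROC AUC as the
tie-aware rank statistic, PR AUC as average precision, Brier score).
Probability metrics are flagged absent for rule-based filters, which
produce no scores; empty-denominator metrics are defined 0 and named in
the report rather than erroring.

# Microhomology

The breakpoint junction is compared outward: the retained 5′ tail
(ending at the 5′ breakpoint) against the just-lost tail immediately
upstream of the 3′ breakpoint, both in transcript orientation, and the
homology is their exact common-prefix length. If it equals h, the same
derivative chromosome is explained by placing the junction anywhere in
that h-base window — the ambiguity characteristic of
microhomology-mediated end-joining. 1–5 nt is labeled microhomologous,
longer homologous, capped at `max_checked` (20 nt). A
reference-orientation mode ignores strands for pipelines that compare
raw reference flanks; transcript orientation is the default because the
junction is defined by the transcript. Controls are drawn uniformly
within 1 kb of each observed breakpoint (both partners shifted
independently, the observed pair excluded, chromosome ends clipped),
and the cohort comparison is a one-sided Mann–Whitney U (observed
greater), tie-corrected by the normal approximation — homology lengths
are small integers, so exact enumeration is unavailable anyway; two
identical constant samples return p = 1 by convention.

# The simulator

The generator is first-class, tested code, and its defaults are the
conditions every cohort-level check runs under: 2 chromosomes × 1 Mb,
40 genes with 3–8 exons placed on a slot grid (neighbors separated by
far more than the insert range, so intrachromosomal junction pairs are
discordant), 10 planted fusions of which 70% are intrachromosomal
(mirroring the observed excess of intrachromosomal events among
DNA-validated fusions), microhomology lengths cycling 0–8 nt,
amplification factors cycling 1/2/3 on intrachromosomal fusions, 30×
base depth, 100-nt reads with 350 ± 50 fragment size, and 90 decoy
calls. Reads are emitted pre-aligned — SAM coordinates computed
analytically from the planted junction — which keeps the loop hermetic
and lets tests assert exact read-name-level truth.

Modeling choices worth knowing:

* Microhomology is *physically written into the reference* (the lost
  tail upstream of the 3′ breakpoint is set equal to the retained 5′
  tail, and the next base outward is forced to mismatch), so recovery
  is exact by sequence, not by bookkeeping.
* A derivative at amplification factor f is sequenced at
  max(f − 1, 1) × base depth; with the diploid background this makes
  the retained side read out at f × the genome average while the lost
  side stays at 1. Factor-1 fusions still carry one extra copy — a
  derivative present at zero copies would leave no junction evidence
  at all.
* Junction-crossing reads are written as a soft-clipped primary on the
  side holding the longer piece plus a supplementary record for the
  clipped remainder (≥ 12 nt), as split-read aligners emit them. Depth
  operations count supplementary records; pair-level operations
  exclude them.
* Decoy caller rows follow background distributions (shifted-geometric
  spanning pairs, 13–25-nt anchors, ~12% intrachromosomal, a third
  carrying banned tags, a tenth carrying common-mapping reads), while
  true rows are drawn with larger support, longer anchors and lower
  partner expression — the qualitative contrasts observed between
  validated and non-validated fusions. `simulateFeatureTable` produces
  the same contrasts directly at cohort scale (5000 rows, 1%
  positives) for classifier experiments where read-level simulation
  would be wasteful.

What the simulator does **not** emulate: sequencing errors and base-
quality decay, PCR duplicates, repetitive or low-complexity genomes
(chromosomes are i.i.d. random DNA), multi-mapping ambiguity,
read-through chimeras and other RNA-side artifact mechanisms, and real
aligner behavior at breakpoints. Passing tests therefore demonstrate
the pipeline's logic — region arithmetic, pair bookkeeping, clip
re-alignment, clustering, recovery of planted signals — not its
robustness to the full messiness of patient WGS.

# Numerical and degenerate-input conventions

* Coordinates are 1-based inclusive throughout; BED input is converted
  on ingest. Sequence is uppercased; minus strand means reverse
  complement.
* The expression log-ratio uses a 0.01 pseudo-count
  (log₂((FPKM₅+ε)/(FPKM₃+ε))), bounding the ratio at zero expression.
  The exon-expression fold change divides by ε only when the untagged
  mean is exactly zero, so finite contrasts are unperturbed.
* Missing information stays `NA` (never silently 0): absent expression,
  interchromosomal genomic distance, unresolvable partners (rows
  flagged `incomplete`). Zero-variance feature columns are dropped with
  their names logged; a constant column with NAs is kept, since the
  missingness pattern itself is informative.
* Breakpoint clustering ties break toward the smaller coordinate;
  clip-alignment orientation ties fall to plus; Youden threshold ties
  take the smallest cut.
* The binomial enrichment is exactly `pbinom(k−1, n, p, lower = FALSE)`
  with p the unweighted universe share of the set (multiplicity counts
  in the list, not in the universe — the natural reading of sampling
  with replacement); k = 0 and p = 1 both give p-value 1. The
  95th-percentile expression universe uses linear interpolation
  (`quantile` type 7).
* The context χ² takes expected proportions from class lengths within
  the fused genes only, because observed breakpoints are confined to
  search regions, not the whole genome.

# Problem sizes used by the test and acceptance runs

The unit suites run on a compact dataset (2 × 150 kb, 12 genes, 4
fusions, 20×) chosen so each property is exercised with sub-minute
feedback; the cohort-level checks run on the default simulation above
and a 5000-row feature table. Classifier leakage is checked by
averaging pooled leave-one-group-out ROC AUC over three independent
label permutations, which tightens the chance-level estimate without
touching the data conditions.

# Known limitations

Multiple distinct breakpoint pairs per fusion are all retained but
summaries report only the top-supported one. The CDS bounds derived
from GTFs without explicit CDS features are midpoint approximations,
adequate for context classes and promoter-swap calls on toy models but
not for real annotation, where CDS features should be present. The
classifier's feature schema is extensible (any extra column in the
table is encoded and carried through the manifest), but prediction
refuses tables whose encoded columns differ from training rather than
imputing. Orientation consistency of discordant pairs with the
predicted fusion strands is not enforced; the hook exists in the
config should a stricter reproduction need it.
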