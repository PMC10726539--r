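# Gradient-boosted classification of true-positive fusions from RNA-only
# features, with seeded space-filling hyperparameter tuning under grouped
# cross-validation, the full metrics panel, and the classical-filter
# benchmark.

#' Encode a feature table for the booster
#'
#' Characters/factors are one-hot encoded, logicals become 0/1, numerics
#' pass through; NA is preserved (the booster handles missingness
#' natively). Identifier and label columns are excluded.
#'
#' @param table data.frame (feature table).
#' @param feature_names optional manifest to conform to; encoding then
#'   errors if the encoded columns differ.
#' @return Numeric matrix with a `feature_names` attribute.
#' @export
encodeFeatures <- function(table, feature_names = NULL) {
  drop_cols <- c("label", "group", "sample_id", "gene5", "gene3")
  df <- table[, setdiff(names(table), drop_cols), drop = FALSE]
  cols <- list()
  for (nm in names(df)) {
    col <- df[[nm]]
    if (is.logical(col)) {
      cols[[nm]] <- as.numeric(col)
    } else if (is.character(col) || is.factor(col)) {
      col <- as.character(col)
      for (lev in sort(unique(col[!is.na(col)]))) {
        key <- paste0(nm, "=", lev)
        v <- as.numeric(col == lev)
        v[is.na(col)] <- NA
        cols[[key]] <- v
      }
    } else {
      cols[[nm]] <- as.numeric(col)
    }
  }
  m <- do.call(cbind, cols)
  if (!is.null(feature_names)) {
    missing <- setdiff(feature_names, colnames(m))
    extra <- setdiff(colnames(m), feature_names)
    if (length(missing) || length(extra))
      stop(sprintf(
        "feature columns do not match the model manifest (missing: %s | unexpected: %s)",
        paste(missing, collapse = ","), paste(extra, collapse = ",")))
    m <- m[, feature_names, drop = FALSE]
  }
  attr(m, "feature_names") <- colnames(m)
  m
}

# seeded space-filling (Latin hypercube) hyperparameter candidates
.tuning_candidates <- function(n, pos_weight_max, seed) {
  set.seed(seed)
  u <- lhs::randomLHS(n, 7L)
  data.frame(
    max_depth = 3L + as.integer(floor(u[, 1] * 6)),          # 3..8
    eta = 10^(-2 + u[, 2] * 1.5),                            # 0.01..~0.3
    min_child_weight = 1 + u[, 3] * 19,                      # 1..20
    subsample = 0.5 + u[, 4] * 0.5,
    colsample_bytree = 0.5 + u[, 5] * 0.5,
    gamma = u[, 6] * 2,
    scale_pos_weight = 1 + u[, 7] * (pos_weight_max - 1))
}

.xgb_params <- function(cand) {
  list(objective = "binary:logistic", eval_metric = "aucpr",
       max_depth = cand$max_depth, eta = cand$eta,
       min_child_weight = cand$min_child_weight,
       subsample = cand$subsample,
       colsample_bytree = cand$colsample_bytree, gamma = cand$gamma,
       scale_pos_weight = cand$scale_pos_weight, nthread = 1)
}

#' Train the gradient-boosted true-positive-fusion classifier
#'
#' Hyperparameter candidates are drawn from a seeded Latin-hypercube
#' design over tree depth, learning rate, minimum child weight,
#' row/column subsampling, gamma and the positive-class weight (the data
#' are typically ~1% positives). Each candidate is scored by grouped
#' cross-validation -- leave-one-group-out by default, k-fold
#' alternatively -- with early stopping on the held-out fold. The winner
#' optimizes the joint PR-AUC + f1 objective (rank-sum of the two CV
#' means, PR-AUC dominant on ties) and is refit on all training rows.
#' Fully deterministic given `config@seed`.
#'
#' @param table labeled feature table from [assembleFeatureTable()] (or
#'   [simulateFeatureTable()]): columns `label` (logical), `group`, plus
#'   features.
#' @param config a [TrainingConfig-class].
#' @return A [ModelBundle-class].
#' @export
trainClassifier <- function(table, config = trainingConfig()) {
  if (!all(c("label", "group") %in% names(table)))
    stop("table needs label and group columns")
  y <- as.numeric(table$label)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  groups <- as.character(table$group)
  X <- encodeFeatures(table)
  if (config@cv_scheme == "leave-one-group-out") {
    if (length(unique(groups)) < 2L)
      stop("leave-one-group-out needs at least 2 groups")
    fold <- match(groups, sort(unique(groups)))
  } else {
    set.seed(config@seed)
    fold <- sample(rep_len(seq_len(config@k), nrow(X)))
  }
  nfold <- max(fold)
  pos_weight_max <- max(2, sum(y == 0) / max(1, sum(y == 1)))
  cands <- .tuning_candidates(config@n_tuning_candidates, pos_weight_max,
                              config@seed)
  thr <- config@classification_threshold

  trace <- lapply(seq_len(nrow(cands)), function(ci) {
    params <- .xgb_params(cands[ci, ])
    prs <- f1s <- iters <- numeric(nfold)
    for (f in seq_len(nfold)) {
      tr <- fold != f; te <- !tr
      if (length(unique(y[tr])) < 2L || !any(te)) {
        prs[f] <- NA; f1s[f] <- NA; iters[f] <- NA; next
      }
      dtr <- xgboost::xgb.DMatrix(X[tr, , drop = FALSE], label = y[tr])
      dte <- xgboost::xgb.DMatrix(X[te, , drop = FALSE], label = y[te])
      fit <- xgboost::xgb.train(
        params = c(params, seed = config@seed), data = dtr,
        nrounds = config@nrounds, evals = list(val = dte),
        early_stopping_rounds = config@early_stopping_rounds, verbose = 0)
      p <- predict(fit, dte)
      prs[f] <- prAUC(y[te] == 1, p)
      f1s[f] <- .f1_at(y[te] == 1, p >= thr)
      iters[f] <- if (!is.null(attributes(fit)$best_iteration))
        attributes(fit)$best_iteration else config@nrounds
    }
    data.frame(candidate = ci, cv_pr_auc = mean(prs, na.rm = TRUE),
               cv_f1 = mean(f1s, na.rm = TRUE),
               best_iter = stats::median(iters, na.rm = TRUE))
  })
  trace <- do.call(rbind, trace)
  # joint objective: rank-sum of PR-AUC and f1, PR-AUC dominant on ties
  rank_pr <- rank(-trace$cv_pr_auc, ties.method = "min")
  rank_f1 <- rank(-trace$cv_f1, ties.method = "min")
  score <- rank_pr + rank_f1
  winner <- order(score, rank_pr, trace$candidate)[1L]
  params <- .xgb_params(cands[winner, ])
  nrounds <- max(1L, as.integer(round(trace$best_iter[winner])))
  dall <- xgboost::xgb.DMatrix(X, label = y)
  final <- xgboost::xgb.train(params = c(params, seed = config@seed),
                              data = dall, nrounds = nrounds, verbose = 0)
  new("ModelBundle", model = final,
      feature_names = attr(X, "feature_names"),
      threshold = thr,
      tuning = cbind(cands, trace[, c("cv_pr_auc", "cv_f1", "best_iter")]),
      params = params, config = config)
}

#' Score a feature table with a trained model
#'
#' @param model a [ModelBundle-class].
#' @param table feature table whose encoded columns must match the
#'   model's manifest (a schema error lists any differences).
#' @param threshold classification threshold; probability >= threshold
#'   calls a fusion true (default: the bundle's threshold).
#' @return data.frame: `probability`, `call` (logical).
#' @export
predictFusions <- function(model, table, threshold = model@threshold) {
  X <- encodeFeatures(table, feature_names = model@feature_names)
  p <- predict(model@model, xgboost::xgb.DMatrix(X))
  data.frame(probability = p, call = p >= threshold)
}

#' Pick the classification threshold maximizing Youden's J
#'
#' Scans every observed probability as a cut-point and returns the one
#' maximizing sensitivity + specificity - 1; ties break toward the
#' smallest threshold.
#'
#' @param probabilities numeric scores in [0, 1].
#' @param labels logical truth of the same length (both classes
#'   required).
#' @return The selected threshold.
#' @export
selectThresholdYouden <- function(probabilities, labels) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present to pick a threshold")
  cuts <- sort(unique(probabilities))
  npos <- sum(labels); nneg <- sum(!labels)
  j <- vapply(cuts, function(t) {
    call <- probabilities >= t
    sum(call & labels) / npos + sum(!call & !labels) / nneg - 1
  }, numeric(1))
  cuts[which.max(j)]  # which.max returns the first (smallest) maximizer
}

.f1_at <- function(labels, calls) {
  tp <- sum(calls & labels); fp <- sum(calls & !labels)
  fn <- sum(!calls & labels)
  if (tp == 0) return(0)
  prec <- tp / (tp + fp); rec <- tp / (tp + fn)
  2 * prec * rec / (prec + rec)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) estimator, tie-aware.
#' @param labels logical truth.
#' @param scores numeric scores.
#' @return AUC in [0, 1].
#' @export
rocAUC <- function(labels, scores) {
  labels <- as.logical(labels)
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0 || nneg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Area under the precision-recall curve
#'
#' Average-precision estimator: sum over positives of precision at each
#' recall step, descending the score ordering (ties processed as one
#' block).
#' @inheritParams rocAUC
#' @return PR-AUC in [0, 1].
#' @export
prAUC <- function(labels, scores) {
  labels <- as.logical(labels)
  npos <- sum(labels)
  if (npos == 0 || all(labels)) return(NA_real_)
  ord <- order(-scores)
  lab <- labels[ord]; sc <- scores[ord]
  # collapse tied scores into blocks
  blocks <- rle(sc)
  tp <- 0; fp <- 0; ap <- 0
  i <- 1L
  for (b in seq_along(blocks$lengths)) {
    len <- blocks$lengths[b]
    seg <- lab[i:(i + len - 1L)]
    dtp <- sum(seg); dfp <- len - dtp
    if (dtp > 0) {
      prec_end <- (tp + dtp) / (tp + dtp + fp + dfp)
      ap <- ap + dtp / npos * prec_end
    }
    tp <- tp + dtp; fp <- fp + dfp
    i <- i + len
  }
  ap
}

#' Compute the full binary-classification metrics panel
#'
#' Threshold metrics follow the standard confusion-matrix formulas;
#' Cohen's kappa is (p_o - p_e) / (1 - p_e). Probability metrics (log
#' loss, ROC AUC, PR AUC, Brier score) are computed only when
#' probabilities are supplied and are NA otherwise, with
#' `has_probabilities = FALSE` -- rule-based filters yield no scores.
#' Metrics with an empty denominator are defined 0 and listed in the
#' report's `degenerate` slot.
#'
#' @param labels logical truth.
#' @param calls logical predictions of the same length.
#' @param probabilities optional numeric scores in [0, 1].
#' @return A [MetricsReport-class].
#' @export
computeMetrics <- function(labels, calls, probabilities = NULL) {
  labels <- as.logical(labels); calls <- as.logical(calls)
  n <- length(labels)
  if (n == 0L || length(calls) != n)
    stop("labels and calls must be non-empty and of equal length")
  tp <- sum(calls & labels); fn <- sum(!calls & labels)
  fp <- sum(calls & !labels); tn <- sum(!calls & !labels)
  degenerate <- character(0)
  safe_div <- function(num, den, name) {
    if (den == 0) { degenerate <<- c(degenerate, name); 0 }
    else num / den
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  specificity <- safe_div(tn, tn + fp, "specificity")
  accuracy <- (tp + tn) / n
  f1 <- if (precision + recall == 0) {
    degenerate <- c(degenerate, "f1"); 0
  } else 2 * precision * recall / (precision + recall)
  po <- accuracy
  pe <- ((tp + fn) / n) * ((tp + fp) / n) +
    ((fp + tn) / n) * ((fn + tn) / n)
  kappa <- if (pe == 1) { degenerate <- c(degenerate, "kappa"); 0 }
           else (po - pe) / (1 - pe)
  if (!is.null(probabilities)) {
    if (length(probabilities) != n)
      stop("probabilities must match labels in length")
    eps <- 1e-15
    p <- pmin(pmax(probabilities, eps), 1 - eps)
    log_loss <- -mean(ifelse(labels, log(p), log(1 - p)))
    brier <- mean((probabilities - as.numeric(labels))^2)
    roc_auc <- rocAUC(labels, probabilities)
    pr_auc <- prAUC(labels, probabilities)
    has_p <- TRUE
  } else {
    log_loss <- roc_auc <- pr_auc <- brier <- NA_real_
    has_p <- FALSE
  }
  new("MetricsReport", tp = as.integer(tp), fn = as.integer(fn),
      fp = as.integer(fp), tn = as.integer(tn),
      precision = precision, recall = recall, specificity = specificity,
      accuracy = accuracy, f1 = f1, kappa = kappa, log_loss = log_loss,
      roc_auc = roc_auc, pr_auc = pr_auc, brier = brier,
      has_probabilities = has_p, degenerate = degenerate)
}

.CLASSICAL_RULES <- c("high_conf", "high_med_conf", "min_discordant_3",
                      "high_med_and_min3", "in_frame_only")

#' Apply a classical filtering rule
#'
#' The benchmark rules: keep high-confidence calls; keep high+medium
#' confidence; keep calls with 3 or more supporting discordant mates
#' (`spanning_pairs >= 3`); the conjunction of the last two; keep only
#' in-frame fusions.
#'
#' @param x a [FusionCallSet-class] or a data.frame carrying the columns
#'   the rule needs (`confidence`, `spanning_pairs`,
#'   `predicted_effect`).
#' @param rule one of `"high_conf"`, `"high_med_conf"`,
#'   `"min_discordant_3"`, `"high_med_and_min3"`, `"in_frame_only"`.
#' @return Logical vector, TRUE = kept.
#' @export
classicalFilter <- function(x, rule = .CLASSICAL_RULES) {
  rule <- match.arg(rule, .CLASSICAL_RULES)
  df <- if (methods::is(x, "FusionCallSet")) fusionCalls(x) else x
  needs_conf <- rule %in% c("high_conf", "high_med_conf",
                            "high_med_and_min3")
  if (needs_conf) {
    conf <- df$confidence
    if (is.null(conf) || all(is.na(conf)) || all(conf == "none"))
      stop(sprintf(
        "rule '%s' needs confidence labels, which this caller does not provide",
        rule))
  }
  switch(rule,
    high_conf = df$confidence == "high",
    high_med_conf = df$confidence %in% c("high", "medium"),
    min_discordant_3 = df$spanning_pairs >= 3L,
    high_med_and_min3 = df$confidence %in% c("high", "medium") &
      df$spanning_pairs >= 3L,
    in_frame_only = df$predicted_effect == "in-frame")
}

#' Benchmark the classifier against the classical filters
#'
#' One [computeMetrics()] row per method, on the same labels. The
#' classifier row includes the probability metrics; filter rows omit
#' them.
#'
#' @param table feature table (columns must satisfy the rules and the
#'   model manifest).
#' @param labels logical truth.
#' @param model a [ModelBundle-class] or NULL to benchmark filters only.
#' @param rules character vector of classical rules to include.
#' @param threshold classifier threshold (default: model's).
#' @return data.frame, one row per method (`method` column first).
#' @export
compareFilters <- function(table, labels, model = NULL,
                           rules = .CLASSICAL_RULES,
                           threshold = NULL) {
  rows <- list()
  if (!is.null(model)) {
    thr <- if (is.null(threshold)) model@threshold else threshold
    pred <- predictFusions(model, table, threshold = thr)
    m <- computeMetrics(labels, pred$call, pred$probability)
    rows[["classifier"]] <- cbind(data.frame(method = "classifier"),
                                  as.data.frame(m))
  }
  for (r in rules) {
    keep <- classicalFilter(table, r)
    m <- computeMetrics(labels, keep)
    rows[[r]] <- cbind(data.frame(method = r), as.data.frame(m))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
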