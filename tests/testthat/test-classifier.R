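test_that("the printed test-cohort confusion matrix yields the printed metrics", {
  labels <- c(rep(TRUE, 864 + 350), rep(FALSE, 308 + 26072))
  calls <- c(rep(TRUE, 864), rep(FALSE, 350), rep(TRUE, 308),
             rep(FALSE, 26072))
  m <- computeMetrics(labels, calls)
  expect_equal(round(m@precision, 2), 0.74)
  expect_equal(round(m@recall, 2), 0.71)
  expect_equal(round(m@kappa, 2), 0.71)
  expect_equal(m@tp, 864L); expect_equal(m@fn, 350L)
  expect_equal(m@fp, 308L); expect_equal(m@tn, 26072L)
  expect_false(m@has_probabilities)
  expect_true(is.na(m@roc_auc))
})

test_that("metrics match independent formula oracles on random data", {
  set.seed(17)
  n <- 500
  labels <- runif(n) < 0.3
  probs <- pmin(pmax(runif(n) * 0.6 + labels * 0.3, 0.001), 0.999)
  calls <- probs >= 0.5
  m <- computeMetrics(labels, calls, probs)
  tp <- sum(calls & labels); fp <- sum(calls & !labels)
  fn <- sum(!calls & labels); tn <- sum(!calls & !labels)
  expect_equal(m@precision, tp / (tp + fp))
  expect_equal(m@recall, tp / (tp + fn))
  expect_equal(m@specificity, tn / (tn + fp))
  expect_equal(m@accuracy, (tp + tn) / n)
  expect_equal(m@f1, 2 * tp / (2 * tp + fp + fn))
  po <- (tp + tn) / n
  pe <- ((tp + fn) * (tp + fp) + (fp + tn) * (fn + tn)) / n^2
  expect_equal(m@kappa, (po - pe) / (1 - pe))
  expect_equal(m@log_loss,
               -mean(ifelse(labels, log(probs), log(1 - probs))))
  expect_equal(m@brier, mean((probs - as.numeric(labels))^2))
  # rank-based ROC AUC against the pairwise-comparison oracle
  pos <- probs[labels]; neg <- probs[!labels]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(m@roc_auc, mean(cmp))
  skip_if_not_installed("pROC")
  expect_equal(m@roc_auc,
               as.numeric(pROC::auc(pROC::roc(labels, probs,
                                              quiet = TRUE,
                                              direction = "<"))))
  # average-precision PR AUC against a direct scan oracle
  ord <- order(-probs)
  lab_o <- labels[ord]
  prec_at <- cumsum(lab_o) / seq_len(n)
  expect_equal(m@pr_auc, sum(prec_at[lab_o]) / sum(labels))
})

test_that("degenerate predictions are defined-0 and flagged, not errors", {
  m <- computeMetrics(c(TRUE, FALSE), c(FALSE, FALSE))
  expect_equal(m@precision, 0)
  expect_true("precision" %in% m@degenerate)
  perf <- computeMetrics(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE))
  expect_equal(perf@precision, 1); expect_equal(perf@recall, 1)
  expect_equal(perf@f1, 1); expect_equal(perf@kappa, 1)
  expect_error(computeMetrics(logical(0), logical(0)), "non-empty")
  # independent calls give kappa 0
  lab <- rep(c(TRUE, FALSE), each = 50)
  expect_equal(computeMetrics(lab, rep(c(TRUE, FALSE), 50))@kappa, 0)
})

test_that("Youden threshold selection equals the exhaustive scan", {
  set.seed(23)
  labels <- runif(200) < 0.4
  probs <- round(runif(200, 0, 1), 2)  # force ties among cut-points
  t_pkg <- selectThresholdYouden(probs, labels)
  cuts <- sort(unique(probs))
  j <- vapply(cuts, function(t) {
    call <- probs >= t
    sum(call & labels) / sum(labels) +
      sum(!call & !labels) / sum(!labels) - 1
  }, numeric(1))
  expect_equal(t_pkg, cuts[which.max(j)])
  # perfectly separated: J = 1 at the positive block's smallest score
  sep_p <- c(rep(0.9, 5), rep(0.1, 5))
  sep_l <- c(rep(TRUE, 5), rep(FALSE, 5))
  expect_equal(selectThresholdYouden(sep_p, sep_l), 0.9)
  # all-equal probabilities: J = 0, threshold is that value
  expect_equal(selectThresholdYouden(rep(0.5, 10), sep_l), 0.5)
  expect_error(selectThresholdYouden(runif(5), rep(TRUE, 5)),
               "both classes")
})

test_that("prediction applies the >= threshold convention", {
  tab <- simulateFeatureTable(300, 0.1, 2, seed = 41)
  fit <- trainClassifier(tab, trainingConfig(n_tuning_candidates = 4,
                                             seed = 41))
  pred <- predictFusions(fit, tab, threshold = 0)
  expect_true(all(pred$call))  # probability >= 0 always
  pred1 <- predictFusions(fit, tab, threshold = 1)
  expect_equal(pred1$call, pred1$probability >= 1)
  p <- c(0.1, 0.25)
  expect_equal(p >= 0.2, c(FALSE, TRUE))  # the documented rule
  # schema enforcement: dropping a column is a hard error naming it
  broken <- tab[, setdiff(names(tab), "longest_anchor")]
  expect_error(predictFusions(fit, broken), "longest_anchor")
})

test_that("training is seeded-deterministic and validates its inputs", {
  tab <- simulateFeatureTable(400, 0.1, 3, seed = 43)
  cfg <- trainingConfig(n_tuning_candidates = 5, seed = 43)
  f1 <- trainClassifier(tab, cfg)
  f2 <- trainClassifier(tab, cfg)
  expect_identical(f1@tuning, f2@tuning)
  expect_identical(predictFusions(f1, tab)$probability,
                   predictFusions(f2, tab)$probability)
  one_group <- tab; one_group$group <- "only"
  expect_error(trainClassifier(one_group, cfg), "2 groups")
  one_class <- tab; one_class$label <- TRUE
  expect_error(trainClassifier(one_class, cfg), "both classes")
  # k-fold alternative runs
  f3 <- trainClassifier(tab, trainingConfig(n_tuning_candidates = 3,
                                            cv_scheme = "k-fold", k = 4,
                                            seed = 43))
  expect_s4_class(f3, "ModelBundle")
  expect_equal(nrow(f3@tuning), 3L)
})

test_that("classical filters implement the benchmark rules", {
  df <- data.frame(
    confidence = c("high", "medium", "low"),
    spanning_pairs = c(2L, 3L, 10L),
    predicted_effect = c("in-frame", "out-of-frame", "in-frame"),
    stringsAsFactors = FALSE)
  expect_equal(classicalFilter(df, "high_conf"), c(TRUE, FALSE, FALSE))
  expect_equal(classicalFilter(df, "high_med_conf"), c(TRUE, TRUE, FALSE))
  expect_equal(classicalFilter(df, "min_discordant_3"),
               c(FALSE, TRUE, TRUE))
  expect_equal(classicalFilter(df, "high_med_and_min3"),
               c(FALSE, TRUE, FALSE))
  expect_equal(classicalFilter(df, "in_frame_only"), c(TRUE, FALSE, TRUE))
  # a fusioncatcher-like set has no confidence labels to filter on
  ds <- small_sim_dataset()
  expect_error(classicalFilter(ds$calls$fusioncatcher, "high_conf"),
               "confidence")
  expect_silent(classicalFilter(ds$calls$fusioncatcher,
                                "min_discordant_3"))
})

test_that("the filter benchmark reuses the same metrics path per method", {
  tab <- simulateFeatureTable(600, 0.08, 2, seed = 47)
  fit <- trainClassifier(tab, trainingConfig(n_tuning_candidates = 4,
                                             seed = 47))
  cmp <- compareFilters(tab, tab$label, fit)
  expect_equal(nrow(cmp), 6L)
  expect_equal(cmp$method[1], "classifier")
  # classifier row carries probability metrics; filter rows do not
  expect_false(is.na(cmp$pr_auc[1]))
  expect_true(all(is.na(cmp$pr_auc[-1])))
  # each row equals computeMetrics applied manually to that method
  for (r in c("high_conf", "in_frame_only")) {
    keep <- classicalFilter(tab, r)
    m <- as.data.frame(computeMetrics(tab$label, keep))
    expect_equal(cmp[cmp$method == r, names(m)], m,
                 ignore_attr = TRUE)
  }
  # a filter keeping nothing is reported defined-0, not an error
  none <- tab; none$predicted_effect <- "unknown"
  cmp0 <- compareFilters(none, none$label, model = NULL,
                         rules = "in_frame_only")
  expect_equal(cmp0$precision, 0)
})
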