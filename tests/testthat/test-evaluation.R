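# Metrics: confusion-based, ranking-based (with independent oracles),
# calibration, per-protein macro averaging and run aggregation.

counts <- function(TP, FP, TN, FN) {
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN, threshold = 0.5),
            class = "confusion_counts")
}

test_that("confusion counts enumerate the four outcomes", {
  ct <- confusion(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0), threshold = 0.5)
  expect_identical(ct[c("TP", "FN", "FP", "TN")],
                   list(TP = 1L, FN = 1L, FP = 1L, TN = 1L))
  perfect <- confusion(c(1, 1, 0), c(1, 1, 0))
  expect_identical(perfect$FP + perfect$FN, 0L)
  allpos <- confusion(rep(1, 10), c(rep(1, 3), rep(0, 7)))
  expect_identical(c(allpos$TP, allpos$FP), c(3L, 7L))
  expect_error(confusion(c(0.1), c(1, 0)), "equal length")
})

test_that("MCC, F1 and DICE match their closed formulas", {
  ct <- counts(8L, 2L, 88L, 2L)
  expect_equal(mcc(ct), 700 / 900, tolerance = 1e-12)
  expect_equal(f1(ct), 0.8)
  expect_equal(dice(ct), 0.8)
  expect_equal(mcc(counts(5L, 0L, 5L, 0L)), 1)
  expect_equal(f1(counts(5L, 0L, 5L, 0L)), 1)
  # degenerate marginals: MCC 0 by convention
  expect_equal(mcc(counts(0L, 0L, 7L, 3L)), 0)
  expect_equal(mcc(counts(3L, 7L, 0L, 0L)), 0)
  expect_equal(accuracy(ct), 96 / 100)
  expect_equal(precision(ct), 0.8)
  expect_equal(recall(ct), 0.8)
})

test_that("DICE equals F1 on every confusion table with margins up to 20", {
  for (P in 0:20) for (Np in 0:20) {
    if (P + Np == 0) next
    TP <- if (P > 0) sample(0:P, 1) else 0L
    FP <- if (Np > 0) sample(0:Np, 1) else 0L
    ct <- counts(TP, FP, Np - FP, P - TP)
    expect_identical(dice(ct), f1(ct))
  }
})

# O(n^2) concordant-pair oracle with half credit for ties.
auroc_oracle <- function(p, y) {
  pos <- which(y == 1); neg <- which(y == 0)
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (p[i] > p[j]) + 0.5 * (p[i] == p[j])
  }
  tot / (length(pos) * length(neg))
}

test_that("AUROC equals exhaustive pair counting, including ties", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_true(is.na(auroc(c(0.1, 0.9), c(1, 1))))
  set.seed(202)
  for (rep in 1:10) {
    n <- 60L
    p <- round(runif(n), 1)                  # coarse grid forces ties
    y <- rbinom(n, 1, 0.3)
    if (sum(y) %in% c(0L, n)) next
    expect_equal(auroc(p, y), auroc_oracle(p, y), tolerance = 1e-12)
  }
})

test_that("AUROC and AUPRC agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  p <- runif(150); y <- rbinom(150, 1, 0.25)
  ours <- auroc(p, y)
  theirs <- suppressMessages(as.numeric(pROC::auc(y, p)))
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("AUPRC integrates the precision-recall steps", {
  # perfect ranking: area 1
  expect_equal(auprc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  # hand-computed 4-point case: scores 0.9(1), 0.7(0), 0.5(1), 0.3(0)
  # thresholds: R jumps at ranks 1 and 3 with precisions 1 and 2/3
  expect_equal(auprc(c(0.9, 0.7, 0.5, 0.3), c(1, 0, 1, 0)),
               0.5 * 1 + 0.5 * (2 / 3), tolerance = 1e-12)
  expect_true(is.na(auprc(c(0.2, 0.8), c(0, 0))))
  # all-tied scores: single block, precision = prevalence
  expect_equal(auprc(rep(0.4, 8), c(1, 1, 0, 0, 0, 0, 0, 0)), 0.25)
})

test_that("Brier score matches its closed forms", {
  expect_equal(brier(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(brier(rep(0.5, 20), rbinom(20, 1, 0.5)), 0.25)
  expect_equal(brier(c(0.8, 0.3), c(1, 0)), (0.04 + 0.09) / 2)
  # constant-p predictor on labels with positive rate q
  set.seed(8)
  y <- rbinom(400, 1, 0.3); q <- mean(y); p0 <- 0.2
  expect_equal(brier(rep(p0, 400), y), q * (1 - p0)^2 + (1 - q) * p0^2,
               tolerance = 1e-12)
  expect_error(brier(c(1.2), c(1)), "\\[0,1\\]")
})

test_that("reliability bins cover [0,1], conserve counts and match hand binning", {
  rb <- reliability_bins(rep(0.55, 7), rep(1, 7), n_bins = 10)
  expect_identical(rb$count[6], 7L)
  expect_identical(sum(rb$count), 7L)
  p <- c(0.05, 0.15, 0.18, 0.55, 0.95, 1.0)
  y <- c(0, 0, 1, 1, 1, 1)
  rb2 <- reliability_bins(p, y, n_bins = 10)
  expect_identical(sum(rb2$count), length(p))
  expect_identical(rb2$count[1], 1L)
  expect_identical(rb2$count[2], 2L)
  expect_equal(rb2$mean_predicted[2], mean(c(0.15, 0.18)))
  expect_equal(rb2$observed_frequency[2], 0.5)
  expect_identical(rb2$count[10], 2L)     # right edge inclusive in last bin
  expect_identical(rb2$count[3], 0L)      # empty bins reported
  expect_error(reliability_bins(p, y, n_bins = 1), "at least 2")
})

test_that("per-protein macro metrics average only where defined", {
  labels <- list(
    a = label_track("a", c(1, 1, 0, 0)),
    b = label_track("b", c(1, 0, 0, 0)),
    c = label_track("c", c(0, 0, 0, 0)))   # no positives
  # protein a predicted perfectly, b inverted, c confidently negative
  preds <- rbind(
    prediction_table("a", 1:4, "A", c(0.9, 0.9, 0.1, 0.1)),
    prediction_table("b", 1:4, "A", c(0.1, 0.9, 0.1, 0.1)),
    prediction_table("c", 1:4, "A", c(0.1, 0.1, 0.1, 0.1)))
  pp <- per_protein_metrics(preds, labels)
  expect_identical(nrow(pp$per_protein), 3L)
  mcc_a <- pp$per_protein$MCC[pp$per_protein$protein_id == "a"]
  expect_equal(mcc_a, 1)
  expect_identical(unname(pp$n_excluded["recall"]), 1L)
  # macro over {1, mcc_b, 0}: protein c has MCC 0 (degenerate marginal)
  mcc_b <- pp$per_protein$MCC[pp$per_protein$protein_id == "b"]
  expect_equal(pp$macro$MCC, mean(c(1, mcc_b, 0)))
  # single protein: macro equals its own metrics
  solo <- per_protein_metrics(preds[preds$protein_id == "a", ], labels["a"])
  expect_equal(solo$macro$MCC, 1)
  # identical prediction sets: strict win rate is zero
  expect_equal(mcc_win_rate(preds, preds, labels), 0)
})

test_that("run aggregation reports mean and sample SD", {
  r1 <- list(MCC = 0.7); r2 <- list(MCC = 0.8)
  agg <- aggregate_runs(list(r1, r2))
  row <- agg[agg$metric == "MCC", ]
  expect_equal(row$mean, 0.75)
  expect_equal(row$sd, sd(c(0.7, 0.8)))
  expect_equal(row$sd, 0.0707, tolerance = 1e-3)
  same <- aggregate_runs(list(r1, r1, r1))
  expect_equal(same[same$metric == "MCC", "sd"], 0)
  single <- aggregate_runs(list(r1))
  expect_true(is.na(single[single$metric == "MCC", "sd"]))
})
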