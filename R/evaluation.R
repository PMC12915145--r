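# Residue-level and protein-level evaluation: threshold metrics, ranking
# metrics with explicit tie handling, calibration, and run aggregation.
# All formulas are implemented directly (and cross-checked against
# independent oracles in the tests) because their exact conventions —
# tie handling, degenerate denominators, masking — are part of the
# package's contract.

#' Confusion counts at a threshold
#'
#' @param probabilities Predicted probabilities.
#' @param labels 0/1 labels, aligned.
#' @param threshold Call threshold; `probability >= threshold` is positive.
#' @return List of class `confusion_counts` with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(probabilities, labels, threshold = 0.5) {
  if (length(probabilities) != length(labels)) {
    stop("probabilities and labels must have equal length", call. = FALSE)
  }
  call_pos <- probabilities >= threshold
  y <- labels == 1L
  structure(list(TP = sum(call_pos & y), FP = sum(call_pos & !y),
                 TN = sum(!call_pos & !y), FN = sum(!call_pos & y),
                 threshold = threshold),
            class = "confusion_counts")
}

#' Threshold metrics from confusion counts
#'
#' `mcc` returns 0 by convention when any marginal is zero (degenerate
#' denominator). `dice` is `2TP / (2TP + FP + FN)`, identical to `f1` on
#' the same counts.
#'
#' @param counts A `confusion_counts` object.
#' @return A single numeric value.
#' @export
mcc <- function(counts) {
  with(counts, {
    denom <- as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
    if (denom == 0) return(0)
    (as.numeric(TP) * TN - as.numeric(FP) * FN) / sqrt(denom)
  })
}

#' @rdname mcc
#' @export
f1 <- function(counts) {
  with(counts, {
    if (2 * TP + FP + FN == 0) return(NA_real_)
    2 * TP / (2 * TP + FP + FN)
  })
}

#' @rdname mcc
#' @export
dice <- function(counts) f1(counts)

#' @rdname mcc
#' @export
accuracy <- function(counts) {
  with(counts, (TP + TN) / (TP + TN + FP + FN))
}

#' @rdname mcc
#' @export
precision <- function(counts) {
  with(counts, if (TP + FP == 0) NA_real_ else TP / (TP + FP))
}

#' @rdname mcc
#' @export
recall <- function(counts) {
  with(counts, if (TP + FN == 0) NA_real_ else TP / (TP + FN))
}

#' Area under the ROC curve
#'
#' Rank-statistic implementation (equivalent to the Mann-Whitney U): ties
#' between a positive and a negative score contribute 1/2. Undefined when
#' only one class is present (`NA`).
#'
#' @param probabilities Scores (any monotone scale).
#' @param labels 0/1 labels.
#' @return AUROC in `[0,1]`, or `NA` if a class is absent.
#' @export
auroc <- function(probabilities, labels) {
  pos <- labels == 1L
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(probabilities, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (as.numeric(n1) * n0)
}

#' Area under the precision-recall curve
#'
#' Step integration of the precision-recall curve over distinct score
#' thresholds (descending), i.e. average precision:
#' `sum_k (R_k - R_{k-1}) * P_k`. Tied scores enter as one block.
#' Undefined (`NA`) without positives.
#'
#' @inheritParams auroc
#' @return AUPRC in `[0,1]`, or `NA` if no positive labels.
#' @export
auprc <- function(probabilities, labels) {
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L || all(labels == 1L)) return(NA_real_)
  ord <- order(probabilities, decreasing = TRUE)
  s <- probabilities[ord]; y <- labels[ord]
  # block boundaries at distinct scores
  ends <- which(c(s[-1L] != s[-length(s)], TRUE))
  tp <- cumsum(y)[ends]
  n <- ends
  prec <- tp / n
  rec <- tp / n_pos
  sum((rec - c(0, rec[-length(rec)])) * prec)
}

#' Brier score
#'
#' Mean squared difference between predicted probability and the binary
#' outcome; 0 for a perfect confident predictor, 0.25 for the constant-0.5
#' predictor.
#'
#' @inheritParams auroc
#' @return Brier score in `[0,1]`.
#' @export
brier <- function(probabilities, labels) {
  if (any(probabilities < 0 | probabilities > 1)) {
    stop("probabilities must lie in [0,1]", call. = FALSE)
  }
  mean((probabilities - labels)^2)
}

#' Reliability (calibration) bins
#'
#' Equal-width probability bins on `[0,1]`; the last bin includes its right
#' edge. Empty bins are reported with count 0, so counts always sum to the
#' input size.
#'
#' @inheritParams auroc
#' @param n_bins Number of bins (>= 2).
#' @return A `data.frame` with `bin`, `lower`, `upper`, `count`,
#'   `mean_predicted`, `observed_frequency`.
#' @export
reliability_bins <- function(probabilities, labels, n_bins = 10L) {
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be at least 2", call. = FALSE)
  edges <- seq(0, 1, length.out = n_bins + 1L)
  idx <- pmin(findInterval(probabilities, edges, rightmost.closed = TRUE),
              n_bins)
  out <- data.frame(bin = seq_len(n_bins), lower = edges[-length(edges)],
                    upper = edges[-1L], count = 0L,
                    mean_predicted = NA_real_, observed_frequency = NA_real_)
  for (b in seq_len(n_bins)) {
    sel <- idx == b
    out$count[b] <- sum(sel)
    if (any(sel)) {
      out$mean_predicted[b] <- mean(probabilities[sel])
      out$observed_frequency[b] <- mean(labels[sel])
    }
  }
  out
}

#' Full metric report for one prediction set
#'
#' @inheritParams auroc
#' @param threshold Call threshold for the confusion-based metrics.
#' @return Named list: `ACC`, `precision`, `recall`, `AUROC`, `AUPRC`,
#'   `F1`, `MCC`, `DICE`, `Brier`, `n` (metrics undefined on the input are
#'   `NA`).
#' @export
metric_report <- function(probabilities, labels, threshold = 0.5) {
  cts <- confusion(probabilities, labels, threshold)
  list(ACC = accuracy(cts), precision = precision(cts), recall = recall(cts),
       AUROC = auroc(probabilities, labels),
       AUPRC = auprc(probabilities, labels),
       F1 = f1(cts), MCC = mcc(cts), DICE = dice(cts),
       Brier = brier(probabilities, labels), n = length(labels))
}

# Align a prediction table with label tracks; masked-in residues only.
align_predictions <- function(predictions, labels) {
  out <- lapply(names(labels), function(id) {
    tr <- labels[[id]]
    sub <- predictions[predictions$protein_id == id, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    keep <- tr$mask[sub$position] == 1L
    sub <- sub[keep, , drop = FALSE]
    data.frame(protein_id = id, probability = sub$probability,
               label = tr$labels[sub$position], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Pooled residue-level metrics over a protein set
#'
#' All masked-in residues of all proteins enter one pool — the default
#' reporting convention for protein, peptide, small-molecule and
#' nucleic-acid partners.
#'
#' @param predictions A prediction table covering the proteins.
#' @param labels Named list of label tracks.
#' @param threshold Call threshold.
#' @return A [metric_report()] list.
#' @export
pooled_metrics <- function(predictions, labels, threshold = 0.5) {
  al <- align_predictions(predictions, labels)
  if (is.null(al) || !nrow(al)) stop("no overlapping residues", call. = FALSE)
  metric_report(al$probability, al$label, threshold)
}

#' Per-protein metrics with macro averaging
#'
#' Metrics are computed per protein and then averaged across proteins (the
#' carbohydrate-task reporting convention). Proteins without any true
#' positive residue are excluded from the recall/DICE/F1 macro averages,
#' and single-class proteins from the AUROC/AUPRC averages; exclusion
#' counts are reported.
#'
#' @inheritParams pooled_metrics
#' @return List with `per_protein` (data.frame, one row per protein),
#'   `macro` (named means over defined values), and `n_excluded` (per
#'   metric).
#' @export
per_protein_metrics <- function(predictions, labels, threshold = 0.5) {
  al <- align_predictions(predictions, labels)
  if (is.null(al) || !nrow(al)) stop("no overlapping residues", call. = FALSE)
  per <- do.call(rbind, lapply(split(al, al$protein_id), function(d) {
    rep_ <- metric_report(d$probability, d$label, threshold)
    data.frame(protein_id = d$protein_id[1L],
               ACC = rep_$ACC, precision = rep_$precision,
               recall = rep_$recall, AUROC = rep_$AUROC, AUPRC = rep_$AUPRC,
               F1 = rep_$F1, MCC = rep_$MCC, DICE = rep_$DICE,
               Brier = rep_$Brier, n = rep_$n,
               has_positive = any(d$label == 1L), stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  metric_cols <- c("ACC", "precision", "recall", "AUROC", "AUPRC", "F1",
                   "MCC", "DICE", "Brier")
  macro <- vapply(metric_cols, function(mcol) {
    vals <- per[[mcol]]
    if (mcol %in% c("recall", "DICE", "F1")) vals <- vals[per$has_positive]
    mean(vals, na.rm = TRUE)
  }, numeric(1L))
  n_excluded <- c(recall = sum(!per$has_positive),
                  auc = sum(is.na(per$AUROC)))
  list(per_protein = per, macro = as.list(macro), n_excluded = n_excluded)
}

#' Per-protein MCC win rate between two prediction sets
#'
#' Fraction of proteins on which set A achieves strictly higher MCC than
#' set B (ties do not count as wins).
#'
#' @param predictions_a,predictions_b Two prediction tables over the same
#'   proteins.
#' @param labels Named list of label tracks.
#' @param threshold Call threshold.
#' @return Win-rate fraction in `[0,1]`.
#' @export
mcc_win_rate <- function(predictions_a, predictions_b, labels,
                         threshold = 0.5) {
  pa <- per_protein_metrics(predictions_a, labels, threshold)$per_protein
  pb <- per_protein_metrics(predictions_b, labels, threshold)$per_protein
  common <- intersect(pa$protein_id, pb$protein_id)
  if (!length(common)) stop("no common proteins", call. = FALSE)
  a <- pa$MCC[match(common, pa$protein_id)]
  b <- pb$MCC[match(common, pb$protein_id)]
  mean(a > b)
}

#' Aggregate metric reports over independent runs
#'
#' Mean and sample (n-1) standard deviation per metric, the reporting
#' convention for repeated-split training.
#'
#' @param reports List of [metric_report()] results (homogeneous scope).
#' @return A `data.frame` with `metric`, `mean`, `sd` (`NA` when n < 2)
#'   and `n_runs`.
#' @export
aggregate_runs <- function(reports) {
  if (!length(reports)) stop("no reports to aggregate", call. = FALSE)
  metric_cols <- c("ACC", "precision", "recall", "AUROC", "AUPRC", "F1",
                   "MCC", "DICE", "Brier")
  rows <- lapply(metric_cols, function(mcol) {
    vals <- vapply(reports, function(r) {
      v <- r[[mcol]]
      if (is.null(v)) NA_real_ else as.numeric(v)
    }, numeric(1L))
    vals <- vals[!is.na(vals)]
    data.frame(metric = mcol,
               mean = if (length(vals)) mean(vals) else NA_real_,
               sd = if (length(vals) >= 2L) stats::sd(vals) else NA_real_,
               n_runs = length(vals))
  })
  do.call(rbind, rows)
}
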