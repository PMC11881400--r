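## Evaluation scores: BCE, Brier score and its binned reliability /
## resolution / uncertainty decomposition, binned calibration errors in
## fixed-width (ECE) and equal-count (ACE) flavours, AUC, accuracy, and the
## paired/unpaired t-test machinery for comparing model repeats.

.check_probs_labels <- function(probs, y) {
  if (!length(probs)) stop("empty input")
  if (length(probs) != length(y)) stop("probs and labels differ in length")
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1")
  invisible(NULL)
}

#' Brier score
#'
#' Mean squared error between predicted probabilities and binary labels.
#'
#' @param probs predicted probabilities.
#' @param y 0/1 labels.
#' @return the Brier score in `[0, 1]`.
#' @export
brier_score <- function(probs, y) {
  .check_probs_labels(probs, y)
  mean((probs - y)^2)
}

#' Binary cross-entropy (log loss)
#'
#' Natural-log cross-entropy; probabilities are clipped to keep it finite.
#'
#' @inheritParams brier_score
#' @return mean negative log-likelihood.
#' @export
bce_loss <- function(probs, y) {
  .check_probs_labels(probs, y)
  p <- clip_probs(probs)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

## internal: bin membership under either scheme.
## fixed_width: half-open edges [k/B, (k+1)/B), last bin closed.
## equal_count: stable sort of predictions cut into B contiguous groups
## whose sizes differ by at most one (the first N %% B groups are larger);
## tied predictions stay together in the bin of their first occurrence, so
## constant predictions fall into a single bin.
.bin_assign <- function(probs, n_bins, scheme) {
  n <- length(probs)
  if (scheme == "fixed_width") {
    pmin(floor(probs * n_bins), n_bins - 1L) + 1L
  } else {
    ord <- order(probs)                  # stable for numeric input
    base <- n %/% n_bins; extra <- n %% n_bins
    sizes <- base + (seq_len(n_bins) <= extra)
    b_sorted <- rep(seq_len(n_bins), times = sizes)
    ps <- probs[ord]
    new_run <- c(TRUE, diff(ps) != 0)
    b_sorted <- b_sorted[which(new_run)[cumsum(new_run)]]
    bin <- integer(n)
    bin[ord] <- b_sorted
    bin
  }
}

## internal: per-bin stats table shared by binned_ce and the decomposition
.bin_stats <- function(probs, y, n_bins, scheme) {
  bin <- .bin_assign(probs, n_bins, scheme)
  n_b <- tabulate(bin, nbins = n_bins)
  conf <- acc <- lo <- hi <- rep(NA_real_, n_bins)
  occ <- which(n_b > 0)
  conf[occ] <- vapply(occ, function(b) mean(probs[bin == b]), numeric(1))
  acc[occ] <- vapply(occ, function(b) mean(y[bin == b]), numeric(1))
  if (scheme == "fixed_width") {
    lo <- (seq_len(n_bins) - 1) / n_bins
    hi <- seq_len(n_bins) / n_bins
  } else {
    lo[occ] <- vapply(occ, function(b) min(probs[bin == b]), numeric(1))
    hi[occ] <- vapply(occ, function(b) max(probs[bin == b]), numeric(1))
  }
  data.frame(bin = seq_len(n_bins), n = n_b, conf = conf, acc = acc,
             lo = lo, hi = hi)
}

#' Binned calibration error (ECE / ACE)
#'
#' The weighted absolute gap between per-bin accuracy (empirical positive
#' fraction) and per-bin confidence (mean predicted probability):
#' `CE = (1/N) * sum_b n_b * |acc(b) - conf(b)|`. With `scheme =
#' "fixed_width"` this is the expected calibration error (equally spaced
#' bins); with `"equal_count"` the adaptive calibration error (quantile
#' bins holding the same number of predictions, sizes differing by at most
#' one; tied predictions share the bin of their first member, so a constant
#' prediction occupies a single bin). Empty bins contribute zero.
#'
#' @inheritParams brier_score
#' @param n_bins number of bins (default 10).
#' @param scheme binning scheme.
#' @return list with `ce` and the per-bin table `bins`
#'   (`bin`, `n`, `conf`, `acc`, `lo`, `hi`).
#' @export
binned_ce <- function(probs, y, n_bins = 10L,
                      scheme = c("fixed_width", "equal_count")) {
  scheme <- match.arg(scheme)
  .check_probs_labels(probs, y)
  n_bins <- .check_count(n_bins, "n_bins")
  bs <- .bin_stats(probs, y, n_bins, scheme)
  gap <- abs(bs$acc - bs$conf)
  ce <- sum(bs$n * ifelse(bs$n > 0, gap, 0)) / length(probs)
  list(ce = ce, bins = bs)
}

#' Expected calibration error (fixed-width bins)
#' @inheritParams binned_ce
#' @return the ECE value.
#' @export
ece <- function(probs, y, n_bins = 10L)
  binned_ce(probs, y, n_bins, "fixed_width")$ce

#' Adaptive calibration error (equal-count bins)
#' @inheritParams binned_ce
#' @return the ACE value.
#' @export
ace <- function(probs, y, n_bins = 10L)
  binned_ce(probs, y, n_bins, "equal_count")$ce

#' Binned Brier score decomposition
#'
#' The classical reliability / resolution / uncertainty decomposition over a
#' binning of the predictions: `REL = (1/N) sum_b n_b (conf(b) - acc(b))^2`,
#' `RES = (1/N) sum_b n_b (acc(b) - ybar)^2`, `UNC = ybar (1 - ybar)` with
#' `ybar` the empirical base rate. When predictions are constant within each
#' bin, `REL - RES + UNC` equals the Brier score exactly.
#'
#' @inheritParams binned_ce
#' @return list with `reliability`, `resolution`, `uncertainty`, `bins`.
#' @export
brier_decomposition <- function(probs, y, n_bins = 10L,
                                scheme = c("fixed_width", "equal_count")) {
  scheme <- match.arg(scheme)
  .check_probs_labels(probs, y)
  n_bins <- .check_count(n_bins, "n_bins")
  bs <- .bin_stats(probs, y, n_bins, scheme)
  ybar <- mean(y)
  occ <- bs$n > 0
  rel <- sum(bs$n[occ] * (bs$conf[occ] - bs$acc[occ])^2) / length(probs)
  res <- sum(bs$n[occ] * (bs$acc[occ] - ybar)^2) / length(probs)
  list(reliability = rel, resolution = res, uncertainty = ybar * (1 - ybar),
       bins = bs)
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive is
#' scored above a random negative, ties counting one half.
#'
#' @inheritParams brier_score
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(probs, y) {
  .check_probs_labels(probs, y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: only one class present")
  r <- rank(probs, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification accuracy at a probability threshold
#'
#' @inheritParams brier_score
#' @param threshold decision threshold (default 0.5; `prob >= threshold`
#'   predicts active).
#' @return fraction of correct predictions.
#' @export
accuracy_score <- function(probs, y, threshold = 0.5) {
  .check_probs_labels(probs, y)
  mean((probs >= threshold) == (y == 1))
}

#' Compare repeated metric values of two models by t-test
#'
#' Two-sided Student t-test at the caller's chosen level; paired when model B
#' is a modification of model A sharing its repeat seeds, Welch unpaired
#' otherwise.
#'
#' @param metric_repeats_a,metric_repeats_b metric values across repeats.
#' @param paired use a paired test (requires equal lengths).
#' @return list with `t_statistic`, `p_value`, `df`, `paired`.
#' @export
compare_models <- function(metric_repeats_a, metric_repeats_b, paired = FALSE) {
  a <- as.numeric(metric_repeats_a); b <- as.numeric(metric_repeats_b)
  if (length(a) < 2 || length(b) < 2) stop("need at least two repeats per model")
  if (paired) {
    if (length(a) != length(b)) stop("paired test requires equal lengths")
    if (sd(a - b) == 0)
      stop("degenerate paired test: differences have zero variance")
    tt <- t.test(a, b, paired = TRUE)
  } else {
    tt <- t.test(a, b, var.equal = FALSE)
  }
  list(t_statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), paired = paired)
}

#' Full calibration report for one set of test predictions
#'
#' Bundles every evaluation score with the per-bin statistics of both
#' calibration-error variants and the fixed-width Brier decomposition. If
#' only one class is present, AUC is recorded as `NA` with a warning and the
#' remaining metrics are computed.
#'
#' @inheritParams brier_score
#' @param n_bins bins shared by ECE, ACE and the decomposition.
#' @return object of class `calibration_report`.
#' @export
evaluate_model <- function(probs, y, n_bins = 10L) {
  .check_probs_labels(probs, y)
  e <- binned_ce(probs, y, n_bins, "fixed_width")
  a <- binned_ce(probs, y, n_bins, "equal_count")
  dec <- brier_decomposition(probs, y, n_bins, "fixed_width")
  auc_val <- if (length(unique(y)) < 2) {
    warning("single-class test set: AUC undefined, recorded as NA")
    NA_real_
  } else auc_score(probs, y)
  structure(
    list(bce = bce_loss(probs, y), brier = brier_score(probs, y),
         ece = e$ce, ace = a$ce, auc = auc_val,
         accuracy = accuracy_score(probs, y),
         reliability = dec$reliability, resolution = dec$resolution,
         uncertainty = dec$uncertainty,
         bins_fixed_width = e$bins, bins_equal_count = a$bins,
         n_bins = as.integer(n_bins), n_test = length(probs)),
    class = "calibration_report")
}

#' @exportS3Method base::print
print.calibration_report <- function(x, ...) {
  cat(sprintf(
    "<calibration_report> n = %d\n  BCE %.4f | Brier %.4f | ECE %.4f | ACE %.4f | AUC %s | ACC %.4f\n",
    x$n_test, x$bce, x$brier, x$ece, x$ace,
    if (is.na(x$auc)) "NA" else sprintf("%.4f", x$auc), x$accuracy))
  invisible(x)
}

#' Flatten a calibration report to a one-row data frame
#' @param report a `calibration_report`.
#' @return data.frame of the scalar metrics.
#' @export
report_row <- function(report) {
  data.frame(bce = report$bce, brier = report$brier, ece = report$ece,
             ace = report$ace, auc = report$auc, accuracy = report$accuracy,
             reliability = report$reliability, resolution = report$resolution,
             uncertainty = report$uncertainty, n_test = report$n_test)
}
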