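## Post hoc Platt scaling: a two-parameter logistic fit on held-out logits,
## applicable to baseline logits directly and to averaged-probability models
## (ensembles, Bayesian last layer) through the logit transform.

#' Fit a Platt scaler
#'
#' Maximum-likelihood fit of `sigmoid(a * logit + b)` against binary labels
#' (an unregularized logistic regression of the labels on the logits, fitted
#' by IRLS). With `smooth = TRUE`, the classic smoothed targets
#' `(N+ + 1)/(N+ + 2)` for positives and `1/(N- + 2)` for negatives are used
#' instead, and the BCE objective is minimized by BFGS.
#'
#' @param logits uncalibrated logit scores from the calibration set.
#' @param y 0/1 labels of the calibration set.
#' @param smooth use Platt's smoothed targets (default off).
#' @return object of class `platt_scaler` with fields `a` (slope) and `b`
#'   (intercept). A non-positive slope triggers a warning but not an error.
#' @export
fit_platt <- function(logits, y, smooth = FALSE) {
  logits <- as.numeric(logits)
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1")
  if (length(logits) != length(y)) stop("logits and labels differ in length")
  if (length(unique(y)) < 2) stop("calibration labels contain a single class")
  if (!smooth) {
    fit <- suppressWarnings(
      glm.fit(cbind(1, logits), y, family = binomial()))
    b <- unname(fit$coefficients[1]); a <- unname(fit$coefficients[2])
  } else {
    n1 <- sum(y == 1); n0 <- sum(y == 0)
    t <- ifelse(y == 1, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
    obj <- function(par) {
      p <- clip_probs(sigmoid(par[1] * logits + par[2]))
      -mean(t * log(p) + (1 - t) * log(1 - p))
    }
    grad <- function(par) {
      p <- sigmoid(par[1] * logits + par[2])
      d <- p - t
      c(mean(d * logits), mean(d))
    }
    opt <- optim(c(1, 0), obj, grad, method = "BFGS",
                 control = list(reltol = 1e-12, maxit = 500))
    a <- opt$par[1]; b <- opt$par[2]
  }
  if (!is.finite(a) || !is.finite(b)) stop("Platt fit produced non-finite parameters")
  if (a <= 0) warning("Platt slope is non-positive; the classifier ranks worse than chance")
  structure(list(a = a, b = b, smooth = smooth), class = "platt_scaler")
}

#' @exportS3Method base::print
print.platt_scaler <- function(x, ...) {
  cat(sprintf("<platt_scaler> p = sigmoid(%.4f * logit + %.4f)\n", x$a, x$b))
  invisible(x)
}

#' Apply a Platt scaler to logits
#'
#' @param scaler a `platt_scaler`.
#' @param logits logit scores.
#' @return calibrated probabilities, clipped; strictly monotone in the
#'   logits whenever the slope is positive (so AUC is unchanged).
#' @export
apply_platt <- function(scaler, logits) {
  clip_probs(sigmoid(scaler$a * as.numeric(logits) + scaler$b))
}

#' Logit transform of clipped probabilities
#'
#' `log(p / (1 - p))` after clipping — the inverse of the sigmoid on the
#' clipped range, and the access point to an "ensemble logit" for
#' averaged-probability models.
#'
#' @param probs probability vector.
#' @return logit vector.
#' @export
probs_to_logits <- function(probs) qlogis(clip_probs(probs))

#' Stack Platt scaling on an averaged-probability model
#'
#' Fits the scaler on the logit-transformed validation probabilities of an
#' uncertainty-quantification model (ensemble or Bayesian last layer) and
#' applies it to the logit-transformed test probabilities.
#'
#' @param uq_probs_valid validation-set probabilities of the UQ model.
#' @param y_valid validation labels.
#' @param uq_probs_test test-set probabilities of the UQ model.
#' @param smooth passed to [fit_platt()].
#' @return calibrated test probabilities with the fitted scaler attached as
#'   attribute `"scaler"`.
#' @export
stack_platt <- function(uq_probs_valid, y_valid, uq_probs_test,
                        smooth = FALSE) {
  scaler <- fit_platt(probs_to_logits(uq_probs_valid), y_valid, smooth = smooth)
  out <- apply_platt(scaler, probs_to_logits(uq_probs_test))
  attr(out, "scaler") <- scaler
  out
}
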