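# Metric stack: MCC, AUC, concordance index, ROC enrichment, MSE/MAE.
# Tie and degenerate-case conventions are explicit and documented, so
# results are reproducible on small folds.

#' Matthews correlation coefficient
#'
#' Closed form on the 2x2 contingency table; equals the Pearson correlation
#' of the two binary vectors. Convention: any zero marginal (all-one-class
#' labels or predictions) returns 0, avoiding 0/0 on degenerate folds.
#'
#' @param labels,predicted_labels binary vectors (0/1) of equal length.
#' @return scalar in `[-1, 1]`.
#' @export
mcc <- function(labels, predicted_labels) {
  assert_that(length(labels) > 0, "empty input")
  assert_that(length(labels) == length(predicted_labels),
              "label vectors must have equal length")
  assert_that(is_binary_vector(labels) && is_binary_vector(predicted_labels),
              "mcc requires binary {0,1} vectors")
  tp <- as.double(sum(labels == 1 & predicted_labels == 1))
  tn <- as.double(sum(labels == 0 & predicted_labels == 0))
  fp <- as.double(sum(labels == 0 & predicted_labels == 1))
  fn <- as.double(sum(labels == 1 & predicted_labels == 0))
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom2 == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom2)
}

#' Area under the ROC curve
#'
#' Tie-corrected Mann-Whitney rank statistic: the probability that a random
#' active outranks a random inactive, ties counted one half.
#'
#' @param labels binary vector (both classes must be present).
#' @param scores numeric score vector (higher = more active).
#' @return scalar in `[0, 1]`.
#' @export
auc <- function(labels, scores) {
  assert_that(length(labels) == length(scores), "inputs must have equal length")
  assert_that(is_binary_vector(labels), "auc requires binary labels")
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    validation_error("auc undefined: only one class present")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Concordance index
#'
#' Fraction of pairs with distinct true values whose predicted scores
#' preserve the ordering: over all ordered pairs with `delta_i > delta_j`,
#' the step function of `b_i - b_j` (1 if positive, 1/2 if zero, 0 if
#' negative) is averaged; the normalization constant Z is the number of such
#' comparable pairs. Ties in the true values are excluded from Z.
#'
#' @param true_values numeric vector delta (e.g. measured affinities).
#' @param scores numeric predicted values b.
#' @return scalar in `[0, 1]`.
#' @export
concordance_index <- function(true_values, scores) {
  assert_that(length(true_values) == length(scores) && length(scores) > 1,
              "need at least two paired values")
  d_gt <- outer(true_values, true_values, `>`)
  Z <- sum(d_gt)
  if (Z == 0) {
    validation_error("concordance index undefined: no comparable pair (all true values equal)")
  }
  b_diff <- outer(scores, scores, `-`)
  step <- (b_diff > 0) + 0.5 * (b_diff == 0)
  sum(step[d_gt]) / Z
}

#' ROC enrichment at a fixed false-positive-rate threshold
#'
#' Early-recognition metric for virtual screening: the true-positive rate at
#' the score cutoff where the false-positive rate first reaches
#' `fpr_threshold`, divided by that threshold. A random scorer is ~1; a
#' perfect ranker attains the ceiling `1/fpr_threshold` (20 at 5%). No
#' interpolation: the cutoff is the smallest score cutoff with
#' FPR >= threshold, so small-n results are reproducible integer counts.
#'
#' @param labels binary vector (both classes must be present).
#' @param scores numeric score vector (higher = more active).
#' @param fpr_threshold value in (0, 1); conventionally 0.005, 0.01, 0.02,
#'   0.05.
#' @return scalar `>= 0`.
#' @export
roc_enrichment <- function(labels, scores, fpr_threshold = 0.05) {
  assert_that(length(labels) == length(scores), "inputs must have equal length")
  assert_that(is_binary_vector(labels), "roc_enrichment requires binary labels")
  assert_that(fpr_threshold > 0 && fpr_threshold < 1,
              "fpr_threshold must be in (0, 1)")
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    validation_error("roc_enrichment undefined: only one class present")
  }
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  # candidate cutoffs: last position of each distinct score value
  last_of_value <- which(c(sc[-1] != sc[-length(sc)], TRUE))
  fp <- cumsum(lab == 0)[last_of_value]
  tp <- cumsum(lab == 1)[last_of_value]
  k <- which(fp / n_neg >= fpr_threshold)[1]
  if (is.na(k)) k <- length(last_of_value)
  (tp[k] / n_pos) / fpr_threshold
}

#' Mean squared and mean absolute error
#' @param true_values,predictions numeric vectors of equal positive length.
#' @return named numeric vector `c(mse = ..., mae = ...)`.
#' @export
mse_mae <- function(true_values, predictions) {
  assert_that(length(true_values) > 0, "empty input")
  assert_that(length(true_values) == length(predictions),
              "inputs must have equal length")
  r <- predictions - true_values
  c(mse = mean(r^2), mae = mean(abs(r)))
}

#' Bundle of prediction-set metrics
#'
#' Computes the requested metrics on a prediction set, applying the
#' evaluation conventions: regression models are scored on continuous
#' outputs for `mse`/`mae`/`ci`, and on thresholded labels plus raw scores
#' for `mcc`/`auc`/`re*`. The degenerate guards are those of the individual
#' metrics (`ci` -> `NA` with a note when all true values are equal; `mcc`
#' zero-marginal -> 0).
#'
#' @param true_values numeric truth (continuous or 0/1).
#' @param scores numeric predictions.
#' @param metrics character subset of `mcc, auc, ci, mse, mae, re0.5, re1,
#'   re2, re5`.
#' @param threshold activity threshold used to binarize continuous truth for
#'   classification metrics (and scores for `mcc`).
#' @return named list of metric values plus `n`.
#' @export
compute_metrics <- function(true_values, scores,
                            metrics = c("mcc", "auc", "ci", "mse", "mae"),
                            threshold = NULL) {
  binary_truth <- is_binary_vector(true_values)
  lab <- NULL
  if (binary_truth) {
    lab <- true_values
  } else if (!is.null(threshold)) {
    lab <- as.numeric(true_values >= threshold)
  }
  pred_lab <- if (binary_truth) {
    as.numeric(scores >= if (!is.null(threshold)) threshold else 0.5)
  } else if (!is.null(threshold)) {
    as.numeric(scores >= threshold)
  } else NULL
  out <- list()
  for (m in metrics) {
    out[[m]] <- switch(
      m,
      mse = unname(mse_mae(true_values, scores)["mse"]),
      mae = unname(mse_mae(true_values, scores)["mae"]),
      ci = tryCatch(concordance_index(true_values, scores),
                    hpcm_error = function(e) NA_real_),
      mcc = {
        if (is.null(lab) || is.null(pred_lab)) {
          validation_error("mcc needs binary truth or a threshold")
        }
        mcc(lab, pred_lab)
      },
      auc = {
        if (is.null(lab)) validation_error("auc needs binary truth or a threshold")
        tryCatch(auc(lab, scores), hpcm_error = function(e) NA_real_)
      },
      re0.5 = , re1 = , re2 = , re5 = {
        if (is.null(lab)) {
          validation_error("roc enrichment needs binary truth or a threshold")
        }
        q <- c(re0.5 = 0.005, re1 = 0.01, re2 = 0.02, re5 = 0.05)[[m]]
        tryCatch(roc_enrichment(lab, scores, q),
                 hpcm_error = function(e) NA_real_)
      },
      validation_error(sprintf("unknown metric '%s'", m)))
  }
  out$n <- length(true_values)
  out
}
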