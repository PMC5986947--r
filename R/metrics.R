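#' Confusion counts for a binary classification
#'
#' Summarizes binary predictions with the four counts the performance
#' metrics are defined over: `Np` observed positives, `Nn` observed
#' negatives, `Npn` negatives misclassified as positive, and `Nnp`
#' positives misclassified as negative.
#'
#' @param truth Observed labels.
#' @param pred Predicted labels, same length.
#' @param positive The label counted as positive.
#' @return A `confusion_counts` object (list with `Np`, `Nn`, `Npn`,
#'   `Nnp`).
#' @export
#' @examples
#' confusion_counts(c("nif", "nif", "non", "non"),
#'                  c("nif", "non", "non", "nif"), positive = "nif")
confusion_counts <- function(truth, pred, positive) {
  if (length(truth) != length(pred))
    stop(sprintf("length mismatch: truth has %d, pred has %d",
                 length(truth), length(pred)))
  truth <- as.character(truth); pred <- as.character(pred)
  is_pos <- truth == positive
  out <- list(Np = sum(is_pos), Nn = sum(!is_pos),
              Npn = sum(!is_pos & pred == positive),
              Nnp = sum(is_pos & pred != positive))
  class(out) <- "confusion_counts"
  out
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion counts: Np = %d, Nn = %d, Npn = %d, Nnp = %d\n",
              x$Np, x$Nn, x$Npn, x$Nnp))
  invisible(x)
}

#' Performance metrics from confusion counts
#'
#' Computes sensitivity, specificity, accuracy, precision and Matthews
#' correlation coefficient in the intuitive miss-rate form:
#' \deqn{Sn = 1 - Nnp/Np, \quad Sp = 1 - Npn/Nn, \quad
#'       Ac = 1 - (Nnp + Npn)/(Np + Nn),}
#' \deqn{Pre = 1 - Npn/(Np - Nnp + Npn),}
#' \deqn{MCC = \frac{1 - (Nnp/Np + Npn/Nn)}
#'   {\sqrt{(1 + (Npn - Nnp)/Np)(1 + (Nnp - Npn)/Nn)}}.}
#' These are algebraically identical to the classical TP/FP/TN/FN
#' formulas with TP = Np - Nnp, FN = Nnp, FP = Npn, TN = Nn - Npn.
#' A metric whose denominator is zero is returned as `NA` (explicitly
#' undefined), never silently as 0; the others are still computed.
#'
#' @param counts A [confusion_counts()] object.
#' @return A named numeric vector with elements `Sn`, `Sp`, `Ac`, `Pre`,
#'   `MCC` (class `metric_set`).
#' @export
#' @examples
#' metrics_from_counts(confusion_counts(rep(c("a", "b"), c(4, 4)),
#'                                      rep(c("a", "b"), c(4, 4)), "a"))
metrics_from_counts <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  Np <- counts$Np; Nn <- counts$Nn; Npn <- counts$Npn; Nnp <- counts$Nnp
  stopifnot(Nnp <= Np, Npn <= Nn, Np >= 0, Nn >= 0)
  sn <- if (Np > 0) 1 - Nnp / Np else NA_real_
  sp <- if (Nn > 0) 1 - Npn / Nn else NA_real_
  ac <- if (Np + Nn > 0) 1 - (Nnp + Npn) / (Np + Nn) else NA_real_
  pre <- if (Np - Nnp + Npn > 0) 1 - Npn / (Np - Nnp + Npn) else NA_real_
  mcc <- if (Np > 0 && Nn > 0) {
    d1 <- 1 + (Npn - Nnp) / Np
    d2 <- 1 + (Nnp - Npn) / Nn
    if (d1 > 0 && d2 > 0)
      (1 - (Nnp / Np + Npn / Nn)) / sqrt(d1 * d2)
    else NA_real_
  } else NA_real_
  out <- c(Sn = sn, Sp = sp, Ac = ac, Pre = pre, MCC = mcc)
  class(out) <- "metric_set"
  out
}

#' @export
print.metric_set <- function(x, ...) {
  v <- unclass(x)
  cat(paste(sprintf("%s = %s", names(v),
                    ifelse(is.na(v), "undefined", sprintf("%.4f", v))),
            collapse = ", "), "\n")
  invisible(x)
}

#' Area under the ROC curve
#'
#' Rank-based (equivalently, trapezoid) AUC of positive-class scores
#' against binary truth; tied scores are handled by midranks, so the
#' result equals the probability that a random positive outscores a
#' random negative, counting ties as one half.
#'
#' @param scores Numeric positive-class scores or probabilities.
#' @param truth Binary labels, same length.
#' @param positive Label counted as positive.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, truth, positive) {
  stopifnot(length(scores) == length(truth))
  is_pos <- as.character(truth) == positive
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to compute AUC")
  r <- rank(scores)  # midranks for ties
  (sum(r[is_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
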