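# Agreement statistics for the reader study: confusion-matrix metrics,
# Cohen's / weighted / Fleiss kappa, and ROC analysis of ordinal confidence
# ratings.

#' ConfusionCounts: a 2x2 contingency of calls against ground truth
#'
#' @slot TP,FP,TN,FN nonnegative integer counts; positives = "presence"
#' @seealso [confusionCounts()], [classificationMetrics()], [cohensKappa()]
#' @export
setClass("ConfusionCounts",
  representation(TP = "integer", FP = "integer", TN = "integer", FN = "integer"))

setValidity("ConfusionCounts", function(object) {
  v <- c(object@TP, object@FP, object@TN, object@FN)
  if (length(v) != 4L || any(is.na(v)) || any(v < 0L))
    return("TP, FP, TN, FN must be single nonnegative integers")
  if (sum(v) == 0L) return("total count must be positive")
  TRUE
})

#' Create ConfusionCounts
#'
#' @param TP,FP,TN,FN nonnegative counts
#' @return a [ConfusionCounts-class]
#' @examples
#' cc <- confusionCounts(TP = 4377, FP = 257, TN = 13671, FN = 1631)
#' classificationMetrics(cc)
#' @export
confusionCounts <- function(TP, FP, TN, FN) {
  methods::new("ConfusionCounts", TP = as.integer(TP), FP = as.integer(FP),
               TN = as.integer(TN), FN = as.integer(FN))
}

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP=%d FP=%d TN=%d FN=%d (n=%d)\n", object@TP,
              object@FP, object@TN, object@FN,
              object@TP + object@FP + object@TN + object@FN))
})

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), accuracy =
#' (TP+TN)/(TP+FP+TN+FN).  A zero denominator yields NaN with a warning.
#'
#' @param cc a [ConfusionCounts-class]
#' @return named numeric vector (sensitivity, specificity, accuracy)
#' @export
classificationMetrics <- function(cc) {
  stopifnot(methods::is(cc, "ConfusionCounts"))
  tp <- cc@TP; fp <- cc@FP; tn <- cc@TN; fn <- cc@FN
  sens <- if (tp + fn > 0) tp / (tp + fn) else { warning("no positives: sensitivity undefined"); NaN }
  spec <- if (tn + fp > 0) tn / (tn + fp) else { warning("no negatives: specificity undefined"); NaN }
  acc <- (tp + tn) / (tp + fp + tn + fn)
  c(sensitivity = sens, specificity = spec, accuracy = acc)
}

.kappaFromTable <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < .Machine$double.eps * 8)
    return(if (abs(po - 1) < 1e-12) 1 else NaN)  # degenerate single-cell table
  (po - pe) / (1 - pe)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement, kappa = (p_o - p_e)/(1 - p_e) with expected
#' agreement from the row/column marginals.  Accepts either a
#' [ConfusionCounts-class] (agreement between an observer's binary calls and
#' the ground truth) or two paired categorical rating vectors.
#'
#' @param x a [ConfusionCounts-class], or a vector of ratings
#' @param y second rating vector when \code{x} is a vector
#' @param categories optional category levels shared by both vectors
#' @return the kappa coefficient
#' @examples
#' cohensKappa(confusionCounts(TP = 40, FP = 0, TN = 60, FN = 0))  # 1
#' @export
cohensKappa <- function(x, y = NULL, categories = NULL) {
  if (methods::is(x, "ConfusionCounts")) {
    tab <- matrix(c(x@TP, x@FN, x@FP, x@TN), 2, 2)
    return(.kappaFromTable(tab))
  }
  if (is.null(y)) stop("supply ConfusionCounts or two paired rating vectors")
  if (length(x) != length(y)) stop("paired ratings must have equal length")
  lev <- categories %||% sort(unique(c(x, y)))
  tab <- table(factor(x, levels = lev), factor(y, levels = lev))
  .kappaFromTable(tab)
}

#' Large-sample confidence interval for Cohen's kappa
#'
#' Asymptotic standard error sqrt(p_o (1 - p_o) / (n (1 - p_e)^2)).
#'
#' @inheritParams cohensKappa
#' @param conf confidence level (default 0.95)
#' @return named numeric (kappa, se, lower, upper)
#' @export
cohensKappaCI <- function(x, y = NULL, categories = NULL, conf = 0.95) {
  if (methods::is(x, "ConfusionCounts")) {
    tab <- matrix(c(x@TP, x@FN, x@FP, x@TN), 2, 2)
  } else {
    lev <- categories %||% sort(unique(c(x, y)))
    tab <- table(factor(x, levels = lev), factor(y, levels = lev))
  }
  tab <- as.matrix(tab)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  k <- (po - pe) / (1 - pe)
  se <- sqrt(po * (1 - po) / (n * (1 - pe)^2))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  c(kappa = k, se = se, lower = max(-1, k - z * se), upper = min(1, k + z * se))
}

#' Weighted kappa for ordinal ratings
#'
#' Standard weighted kappa with agreement weights
#' w_ij = 1 - (|i - j| / (k - 1))^q, q = 1 (linear) or q = 2 (quadratic).
#' On a binary scale both weightings reduce to Cohen's kappa.
#'
#' @param x,y paired ordinal rating vectors on the same scale
#' @param weights "quadratic" (default) or "linear"
#' @param categories category levels in scale order; default the sorted union
#' @return the weighted kappa coefficient
#' @export
weightedKappa <- function(x, y, weights = c("quadratic", "linear"),
                          categories = NULL) {
  weights <- match.arg(weights)
  q <- if (weights == "quadratic") 2 else 1
  if (length(x) != length(y)) stop("paired ratings must have equal length")
  lev <- categories %||% sort(unique(c(x, y)))
  k <- length(lev)
  if (k < 2L) return(1)
  tab <- table(factor(x, levels = lev), factor(y, levels = lev))
  n <- sum(tab)
  w <- 1 - (abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1))^q
  po <- sum(w * tab) / n
  pe <- sum(w * outer(rowSums(tab), colSums(tab))) / n^2
  if (abs(1 - pe) < .Machine$double.eps * 8)
    return(if (abs(po - 1) < 1e-12) 1 else NaN)
  (po - pe) / (1 - pe)
}

#' Fleiss kappa for a fixed number of raters
#'
#' Overall and per-category chance-corrected agreement for n items each rated
#' by exactly m raters into k categories.
#'
#' @param counts n x k matrix: counts of raters assigning each item (row) to
#'   each category (column); every row must sum to the same m >= 2
#' @return list with \code{overall}, \code{perCategory} (named by column) and
#'   \code{m}, \code{n}
#' @export
fleissKappa <- function(counts) {
  counts <- as.matrix(counts)
  m <- unique(rowSums(counts))
  if (length(m) != 1L)
    stop("every item must be rated by the same number of raters")
  m <- as.numeric(m)
  if (m < 2) stop("Fleiss kappa needs at least 2 raters per item")
  n <- nrow(counts)
  pj <- colSums(counts) / (n * m)
  Pi <- (rowSums(counts^2) - m) / (m * (m - 1))
  Pbar <- mean(Pi)
  Pe <- sum(pj^2)
  overall <- if (abs(1 - Pe) < 1e-15) {
    if (abs(Pbar - 1) < 1e-12) 1 else NaN
  } else (Pbar - Pe) / (1 - Pe)
  qj <- 1 - pj
  perCat <- vapply(seq_len(ncol(counts)), function(j) {
    x <- counts[, j]
    denom <- n * m * (m - 1) * pj[j] * qj[j]
    if (denom <= 0) return(NaN)
    1 - sum(x * (m - x)) / denom
  }, numeric(1))
  names(perCat) <- colnames(counts)
  list(overall = overall, perCategory = perCat, m = m, n = n)
}

#' ROC curve and AUC from five-point confidence ratings
#'
#' Empirical ROC over the 4 cutpoints of the 5-level ordinal scale (a rating
#' >= c is called positive, c = 2..5) plus the trivial endpoints; AUC by the
#' trapezoidal rule.  This equals the tie-corrected concordance probability
#' P(score_pos > score_neg) + 0.5 P(tie).
#'
#' @param scores integer ratings in 1..5 (or any ordinal scale)
#' @param labels binary ground truth (logical or 0/1), both classes present
#' @return list with \code{auc} and \code{points} (data.frame cutpoint, fpr, tpr)
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  if (!any(labels) || all(labels)) stop("ROC requires both classes in labels")
  lev <- sort(unique(scores))
  cuts <- lev[-1]
  nPos <- sum(labels); nNeg <- sum(!labels)
  tpr <- c(1, vapply(cuts, function(c) sum(scores >= c & labels) / nPos, numeric(1)), 0)
  fpr <- c(1, vapply(cuts, function(c) sum(scores >= c & !labels) / nNeg, numeric(1)), 0)
  ord <- order(fpr, tpr)
  fprS <- fpr[ord]; tprS <- tpr[ord]
  auc <- sum(diff(fprS) * (tprS[-1] + tprS[-length(tprS)]) / 2)
  pts <- data.frame(cutpoint = c(-Inf, cuts, Inf), fpr = fpr, tpr = tpr)
  list(auc = auc, points = pts)
}
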