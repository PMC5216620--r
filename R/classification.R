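#' ROC curve and AUC from decision scores
#'
#' AUC is the Mann-Whitney U statistic normalized by `n_pos * n_neg`, with
#' tied scores contributing 1/2 (so all-equal scores give AUC = 0.5).  The
#' ROC points are the tie-grouped (FPR, TPR) staircase from (0, 0) to
#' (1, 1); its trapezoidal integral equals the normalized U statistic.
#'
#' @param scores Numeric decision values (larger = more positive-like).
#' @param labels Class labels.
#' @param positive Label of the positive class (default `"older"`).
#' @return List with `auc` and `roc_points` (data frame `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, labels, positive = "older") {
  pos <- labels == positive
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0 || nn == 0) stop("undefined AUC: need both classes")
  rk <- rank(scores)   # midranks handle ties
  auc <- (sum(rk[pos]) - np * (np + 1) / 2) / (np * nn)
  o <- order(scores, decreasing = TRUE)
  sp <- pos[o]; ss <- scores[o]
  grp_last <- c(ss[-1] != ss[-length(ss)], TRUE)   # end of each tie group
  tpr <- cumsum(sp)[grp_last] / np
  fpr <- cumsum(!sp)[grp_last] / nn
  list(auc = auc,
       roc_points = data.frame(fpr = c(0, fpr), tpr = c(0, tpr)))
}

#' Leave-one-out linear SVM classification
#'
#' For every subject a linear soft-margin SVM (dual coordinate descent,
#' L2-regularized bias) is trained on the remaining subjects, with features
#' z-scored by training-fold statistics, and the held-out decision value is
#' recorded.  Accuracy, sensitivity (recall of the positive class) and
#' specificity come from the LOOCV predictions; ROC/AUC from the pooled
#' decision values.  An optional permutation test shuffles the labels and
#' re-runs the whole LOOCV.
#'
#' @param X S x F feature matrix.
#' @param labels Length-S class labels (two classes; see `positive`).
#' @param C SVM cost parameter.
#' @param positive Positive class for sensitivity/specificity bookkeeping.
#' @param n_perm Number of label permutations for the accuracy p-value
#'   (0 = skip).
#' @param rng_seed Seed for the permutations.
#' @return Object of class `classification_result`: `accuracy`,
#'   `sensitivity`, `specificity`, `auc`, `roc_points`,
#'   `per_subject_scores`, `predicted`, `p_perm`.
#' @export
svm_loocv_classify <- function(X, labels, C = 1.0, positive = "older",
                               n_perm = 0, rng_seed = NULL) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  stopifnot(nrow(X) == length(labels))
  if (nrow(X) < 6) stop("need at least 6 subjects")
  classes <- unique(labels)
  if (length(classes) != 2) stop("need exactly two classes")
  if (!positive %in% classes) stop("positive class not present")
  if (min(table(labels)) < 2)
    stop("class-size error: each class needs at least 2 members for LOOCV")
  ysign <- ifelse(labels == positive, 1, -1)
  run <- function(ys) cpp_svm_loocv(X, ys, C)
  dec <- run(ysign)
  predicted <- ifelse(dec > 0, positive, setdiff(classes, positive))
  acc <- mean(predicted == labels)
  sens <- mean(predicted[labels == positive] == positive)
  spec <- mean(predicted[labels != positive] != positive)
  roc <- roc_auc(dec, labels, positive)
  p <- NA_real_
  if (n_perm > 0) {
    if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))
    n_exceed <- 0L
    for (b in seq_len(n_perm)) {
      ys <- ysign[sample.int(length(ysign))]
      accp <- mean(ifelse(run(ys) > 0, 1, -1) == ys)
      if (accp >= acc) n_exceed <- n_exceed + 1L
    }
    p <- (n_exceed + 1) / (n_perm + 1)
  }
  structure(list(accuracy = acc, sensitivity = sens, specificity = spec,
                 auc = roc$auc, roc_points = roc$roc_points,
                 per_subject_scores = dec, predicted = predicted,
                 labels = labels, positive = positive, C = C,
                 p_perm = p, n_perm = as.integer(n_perm)),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf(paste0("<classification_result> accuracy = %.1f%%, ",
                     "sensitivity = %.1f%%, specificity = %.1f%%, ",
                     "AUC = %.1f%%\n"),
              100 * x$accuracy, 100 * x$sensitivity, 100 * x$specificity,
              100 * x$auc))
  if (!is.na(x$p_perm))
    cat(sprintf("  permutation p = %.4g (n_perm = %d)\n", x$p_perm, x$n_perm))
  invisible(x)
}

#' Linear SVM (single fit)
#'
#' Dual coordinate-descent solver for the linear soft-margin SVM with an
#' L2-regularized bias.  Exposed for testing; decision value is
#' `X %*% w + b`.
#'
#' @param X n x p matrix.
#' @param ysign Length-n labels coded +-1.
#' @param C Cost parameter.
#' @return List with `w`, `b` and dual coefficients `alpha`.
#' @export
svm_fit <- function(X, ysign, C = 1.0) {
  X <- as.matrix(X)
  stopifnot(all(ysign %in% c(-1, 1)), nrow(X) == length(ysign))
  cpp_svm_fit(X, as.numeric(ysign), C)
}
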