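#' Pearson correlation between predicted and observed values
#'
#' @param a,b Equal-length numeric vectors (length >= 3).
#' @return Correlation, or `NA` when either vector is constant.
#' @export
pearson_r <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)
}

#' Mean absolute error
#'
#' @param pred,obs Equal-length numeric vectors.
#' @return `mean(|pred - obs|)` in the units of the inputs (years here).
#' @export
mae <- function(pred, obs) {
  stopifnot(length(pred) == length(obs))
  mean(abs(pred - obs))
}

#' Rank features by absolute correlation with the target
#'
#' Descending `|Pearson r(feature, y)|`; constant features get `|r| = 0`;
#' ties are broken by ascending feature index (stable).
#'
#' @param X S x F feature matrix.
#' @param y Target vector (ages).
#' @return Integer vector of feature indices, best first.
#' @export
rank_features_by_corr <- function(X, y) {
  X <- as.matrix(X)
  stopifnot(ncol(X) >= 1, nrow(X) == length(y))
  absr <- vapply(seq_len(ncol(X)), function(j) {
    xj <- X[, j]
    if (sd(xj) == 0 || sd(y) == 0) 0 else abs(cor(xj, y))
  }, 0)
  order(-absr, seq_along(absr))
}

#' Consensus features across inner cross-validation folds
#'
#' Features selected in at least a fraction `theta` of the folds.  With an
#' empty consensus the supplied fallback (typically the single top-ranked
#' feature) is returned with a message.
#'
#' @param selections List of per-fold feature vectors (indices or labels).
#' @param theta Required selection fraction (0.5 default; 1 = unanimity).
#' @param fallback Value returned (with a message) when no feature reaches
#'   `theta`.
#' @return Vector of consensus features.
#' @export
consensus_features <- function(selections, theta = 0.5, fallback = NULL) {
  stopifnot(length(selections) > 0, theta > 0, theta <= 1)
  tab <- table(unlist(selections))
  keep <- names(tab)[as.numeric(tab) + 1e-9 >= theta * length(selections)]
  if (is.numeric(selections[[1]])) keep <- sort(as.numeric(keep))
  if (length(keep) == 0 && !is.null(fallback)) {
    message("empty consensus; falling back to top-ranked feature")
    return(fallback)
  }
  keep
}

new_prediction_result <- function(predicted, observed, p_perm = NA_real_,
                                  per_fold_features = NULL,
                                  consensus = NULL, n_perm = 0L,
                                  epsilon = NA_real_, C = NA_real_,
                                  theta = NA_real_, rng_seed = NULL,
                                  method = "uvpa", extra = list()) {
  res <- list(predicted_ages = predicted, observed_ages = observed,
              r_pred_obs = pearson_r(predicted, observed),
              p_perm = p_perm, mae = mae(predicted, observed),
              per_fold_features = per_fold_features,
              consensus_features = consensus, n_perm = as.integer(n_perm),
              epsilon = epsilon, C = C, theta = theta, rng_seed = rng_seed,
              method = method)
  structure(c(res, extra), class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction_result> %s: r(pred, obs) = %.3f, MAE = %.3f years",
              toupper(x$method), x$r_pred_obs, x$mae))
  if (!is.na(x$p_perm))
    cat(sprintf(", permutation p = %.4g (n_perm = %d)", x$p_perm, x$n_perm))
  cat("\n")
  if (length(x$consensus_features))
    cat("  consensus features:", paste(x$consensus_features, collapse = ", "),
        "\n")
  invisible(x)
}

#' Univariate pattern prediction (LOOCV linear regression)
#'
#' For every subject, an ordinary least-squares line `age ~ feature` is fit
#' on the remaining S - 1 subjects and used to predict the held-out subject.
#' A zero-variance training feature makes that fold predict the training
#' mean age.  Training folds are recomputed from scratch so the held-out
#' subject's age can never influence its own prediction.
#'
#' @param feature Length-S numeric vector (e.g. one altered-edge Fisher z).
#' @param ages Length-S chronological ages (years).
#' @param n_perm Number of label permutations for the significance test
#'   (0 = skip).
#' @param rng_seed Seed for the permutations.
#' @return A `prediction_result`.
#' @export
uvpa_loocv <- function(feature, ages, n_perm = 0, rng_seed = NULL) {
  stopifnot(length(feature) == length(ages), length(ages) >= 4)
  run <- function(y) {
    s <- length(y)
    pred <- numeric(s)
    for (i in seq_len(s)) {
      xt <- feature[-i]; yt <- y[-i]
      mx <- mean(xt); my <- mean(yt)
      sxx <- sum((xt - mx)^2)
      pred[i] <- if (sxx <= 0) my
                 else my + sum((xt - mx) * (yt - my)) / sxx * (feature[i] - mx)
    }
    pred
  }
  pred <- run(ages)
  p <- NA_real_
  if (n_perm > 0) {
    p <- permutation_pvalue(function(yp) pearson_r(run(yp), yp),
                            ages, n_perm = n_perm, rng_seed = rng_seed)
  }
  new_prediction_result(pred, ages, p_perm = p, n_perm = n_perm,
                        rng_seed = rng_seed, method = "uvpa")
}

#' Multivariate pattern prediction (nested LOOCV + linear eps-SVR)
#'
#' Outer leave-one-out loop for unbiased prediction; inner leave-one-out
#' loop, run on each outer training set, for feature selection: features are
#' ranked by `|corr(feature, age)|` on the inner-training data, a linear
#' eps-SVR is trained on the top-k standardized features for every k, and
#' the k maximizing the inner r(predicted, observed) is retained (ties go to
#' the smaller k).  The consensus of the per-inner-fold top-k sets (selected
#' in >= `theta` of folds; fallback: top-ranked feature) defines the outer
#' model, an eps-SVR trained on all S - 1 training subjects.  Features are
#' z-scored and ages centred with training-fold statistics only.
#'
#' @param X S x F feature matrix.
#' @param y Length-S chronological ages.
#' @param epsilon SVR tube half-width (years); LIBSVM's default 0.001.
#' @param C SVR cost parameter (unstated in the source framework; default 1).
#' @param theta Consensus fraction across inner folds.
#' @param n_perm Number of age permutations (each re-runs the entire nested
#'   pipeline); 0 = skip.
#' @param rng_seed Seed for the permutations.
#' @param feature_labels Labels used in the reported feature sets.
#' @param solver_tol Stopping tolerance of the dual coordinate-descent SVR
#'   solver (maximum projected-gradient violation, in years; 0.1 is also
#'   LIBLINEAR's default).  Inner model-selection fits use this value; the
#'   outer per-fold models are always solved to at least 1e-6.
#' @return A `prediction_result` with per-outer-fold and overall consensus
#'   feature sets.
#' @export
mvpa_nested_loocv <- function(X, y, epsilon = 0.001, C = 1.0, theta = 0.5,
                              n_perm = 0, rng_seed = NULL,
                              feature_labels = NULL, solver_tol = 0.1) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), ncol(X) >= 1)
  if (nrow(X) < 8) stop("need at least 8 subjects")
  if (all(apply(X, 2, sd) == 0))
    stop("uninformative features: all columns are constant")
  if (is.null(feature_labels))
    feature_labels <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  fit <- cpp_mvpa_nested(X, y, epsilon, C, theta, solver_tol)
  per_fold_idx <- lapply(fit$per_fold, as.integer)
  cons_idx <- consensus_overall(per_fold_idx, theta)
  p <- NA_real_
  if (n_perm > 0) {
    p <- permutation_pvalue(function(yp) {
      pearson_r(cpp_mvpa_nested(X, yp, epsilon, C, theta, solver_tol)$pred,
                yp)
    }, y, n_perm = n_perm, rng_seed = rng_seed)
  }
  new_prediction_result(
    fit$pred, y, p_perm = p,
    per_fold_features = lapply(per_fold_idx, function(ix) feature_labels[ix]),
    consensus = feature_labels[cons_idx], n_perm = n_perm,
    epsilon = epsilon, C = C, theta = theta, rng_seed = rng_seed,
    method = "mvpa",
    extra = list(kstar = as.integer(fit$kstar),
                 fallback_folds = as.logical(fit$fallback),
                 consensus_indices = cons_idx))
}

# The same theta rule applied across outer folds; fallback: most frequently
# selected feature (ties -> smallest index).
consensus_overall <- function(per_fold_idx, theta) {
  cnt <- table(factor(unlist(per_fold_idx),
                      levels = sort(unique(unlist(per_fold_idx)))))
  keep <- as.integer(names(cnt)[as.numeric(cnt) + 1e-9 >=
                                  theta * length(per_fold_idx)])
  if (length(keep) == 0)
    keep <- as.integer(names(cnt)[which.max(cnt)])
  sort(keep)
}

#' Permutation p-value for a prediction statistic
#'
#' The labels are permuted `n_perm` times, the full prediction pipeline is
#' re-run on each permutation (feature selection included, so selection
#' optimism is part of the null), and the +1-corrected exceedance
#' probability is returned:
#' `p = (#{r_perm >= r_obs} + 1) / (n_perm + 1)`.
#'
#' @param stat_fun Function taking a permuted label vector and returning the
#'   statistic (e.g. r(predicted, observed) from a full LOOCV run).
#' @param y Observed labels.
#' @param n_perm Number of permutations (>= 1).
#' @param rng_seed Seed making the permutation set reproducible.
#' @return p-value in `[1/(n_perm + 1), 1]`.
#' @export
permutation_pvalue <- function(stat_fun, y, n_perm = 1000, rng_seed = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  r_obs <- stat_fun(y)
  if (is.na(r_obs)) stop("observed statistic is undefined")
  if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))
  n_exceed <- 0L
  for (b in seq_len(n_perm)) {
    rp <- stat_fun(y[sample.int(length(y))])
    if (!is.na(rp) && rp >= r_obs) n_exceed <- n_exceed + 1L
  }
  (n_exceed + 1) / (n_perm + 1)
}

#' Linear epsilon-SVR (single fit)
#'
#' Dual coordinate-descent solver for the linear epsilon-insensitive support
#' vector regressor with an L2-regularized bias (bias folded into the kernel
#' as a +1 term).  Exposed mainly for testing and for custom pipelines; the
#' prediction frameworks call it internally with training-fold
#' standardization.
#'
#' @param X n x p numeric matrix.
#' @param y Length-n targets.
#' @param C Cost parameter.
#' @param epsilon Tube half-width.
#' @return List with `w` (length p), `b`, and the dual coefficients `beta`;
#'   predict with `X %*% w + b`.
#' @export
svr_fit <- function(X, y, C = 1.0, epsilon = 0.001) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  cpp_svr_fit(X, as.numeric(y), C, epsilon)
}
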