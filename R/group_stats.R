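#' One-sample t-test per node
#'
#' Two-sided test of mean zero at each column of a subjects x nodes z-value
#' matrix, df = S - 1.  Zero-variance nodes get sentinels: `t = +-Inf`,
#' `p = 0` when the mean is non-zero, `t = NA`, `p = NA` when the column is
#' identically zero.  `NA` entries are skipped per node.
#'
#' @param zmaps S x N numeric matrix.
#' @return Object of class `group_stat`: `t`, `p`, `df`, `direction`
#'   (`"increase"`, `"decrease"`, `"none"` per node).
#' @export
one_sample_t <- function(zmaps) {
  zmaps <- as.matrix(zmaps)
  if (nrow(zmaps) < 3) stop("need at least 3 subjects")
  n <- colSums(!is.na(zmaps))
  m <- colMeans(zmaps, na.rm = TRUE)
  s <- apply(zmaps, 2, sd, na.rm = TRUE)
  t <- m / (s / sqrt(n))
  t[s == 0 & m != 0] <- sign(m[s == 0 & m != 0]) * Inf
  t[s == 0 & m == 0] <- NA_real_
  t[n < 3] <- NA_real_
  p <- 2 * pt(-abs(t), n - 1)
  p[is.infinite(t)] <- 0
  group_stat(t, p, df = n - 1)
}

group_stat <- function(t, p, df, estimate = NULL) {
  t <- unname(t); p <- unname(p); df <- unname(df)
  if (!is.null(estimate)) estimate <- unname(estimate)
  direction <- rep("none", length(t))
  direction[!is.na(t) & t > 0] <- "increase"
  direction[!is.na(t) & t < 0] <- "decrease"
  structure(list(t = t, p = p, df = df, direction = direction,
                 estimate = estimate),
            class = "group_stat")
}

#' @export
print.group_stat <- function(x, ...) {
  cat(sprintf("<group_stat> %d nodes, %d with p < 0.05 (uncorrected)\n",
              length(x$t), sum(x$p < 0.05, na.rm = TRUE)))
  invisible(x)
}

#' Residualize nuisance covariates from z-maps
#'
#' Least-squares regression of every node column on an intercept plus the
#' covariates (e.g. whole-brain GMV, education years, gender coded 0/1),
#' with the column means added back so group means are preserved for the
#' subsequent between-group contrast.  Collinear covariates trigger a
#' warning and a pseudo-inverse fit.
#'
#' @param zmaps S x N matrix.
#' @param covariates S x K matrix or data frame (numeric; gender pre-coded).
#' @return S x N matrix of covariate-adjusted values.
#' @export
residualize_covariates <- function(zmaps, covariates) {
  zmaps <- as.matrix(zmaps)
  covariates <- as.matrix(covariates)
  if (nrow(covariates) != nrow(zmaps))
    stop("covariates must have one row per subject")
  if (ncol(covariates) >= nrow(zmaps))
    stop("need more subjects than covariates")
  x <- cbind(1, covariates)
  keep <- !is.na(colSums(zmaps))
  out <- zmaps
  if (any(keep)) {
    y <- zmaps[, keep, drop = FALSE]
    res <- lsq_residuals(y, x)
    out[, keep] <- sweep(res, 2, colMeans(y), `+`)
  }
  out
}

#' Two-sample t-test per node
#'
#' Pooled-variance (Student) two-sided t-test of group A minus group B at
#' every node, optionally restricted to a mask (nodes outside the mask get
#' `NA`).  `direction` is `"increase"` where A > B.  Set `var_equal = FALSE`
#' for the Welch variant.
#'
#' @param zA,zB S1 x N and S2 x N matrices (same N).
#' @param mask Optional logical length-N vector (e.g. the union of the two
#'   groups' significant one-sample results).
#' @param var_equal Pooled variance (default) or Welch.
#' @return A `group_stat` (see [one_sample_t()]); `estimate` holds the mean
#'   difference A - B.
#' @export
two_sample_t <- function(zA, zB, mask = NULL, var_equal = TRUE) {
  zA <- as.matrix(zA); zB <- as.matrix(zB)
  if (ncol(zA) != ncol(zB)) stop("groups must share the node dimension")
  if (nrow(zA) < 3 || nrow(zB) < 3) stop("need at least 3 subjects per group")
  n <- ncol(zA)
  if (is.null(mask)) mask <- rep(TRUE, n)
  if (!any(mask)) warning("empty mask: no nodes tested")
  t <- p <- df <- est <- rep(NA_real_, n)
  for (j in which(mask)) {
    a <- zA[, j][!is.na(zA[, j])]
    b <- zB[, j][!is.na(zB[, j])]
    if (length(a) < 3 || length(b) < 3) next
    n1 <- length(a); n2 <- length(b)
    d <- mean(a) - mean(b)
    est[j] <- d
    if (var_equal) {
      sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
      se <- sqrt(sp2 * (1 / n1 + 1 / n2))
      df[j] <- n1 + n2 - 2
    } else {
      v1 <- var(a) / n1; v2 <- var(b) / n2
      se <- sqrt(v1 + v2)
      df[j] <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
    }
    if (se == 0) {
      t[j] <- if (d == 0) NA_real_ else sign(d) * Inf
      p[j] <- if (d == 0) NA_real_ else 0
    } else {
      t[j] <- d / se
      p[j] <- 2 * pt(-abs(t[j]), df[j])
    }
  }
  group_stat(t, p, df, estimate = est)
}

#' Benjamini-Hochberg FDR mask
#'
#' Step-up procedure: reject the `k` smallest p-values where `k` is the
#' largest index with `p_(k) <= q * k / m` (`m` = number of non-missing
#' p-values).  `NA` p-values are never rejected.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param q FDR level.
#' @return Logical rejection mask.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  mask <- rep(FALSE, length(p_values))
  ok <- which(!is.na(p_values))
  m <- length(ok)
  if (m == 0) return(mask)
  o <- ok[order(p_values[ok])]
  ps <- p_values[o]
  below <- which(ps <= q * seq_len(m) / m)
  if (length(below)) mask[o[seq_len(max(below))]] <- TRUE
  mask
}

#' Cluster-extent filtering
#'
#' Keeps only connected components of the mask whose size strictly exceeds
#' `k`.  In ROI mode (no adjacency) every node is its own component, so use
#' `k = 0` there; in grid mode pass a symmetric logical/0-1 adjacency matrix
#' (e.g. face adjacency of a voxel grid).
#'
#' @param mask Logical vector.
#' @param adjacency Optional symmetric adjacency matrix.
#' @param k Minimum surviving component size (strict `> k`).
#' @return Filtered logical mask.
#' @export
cluster_filter <- function(mask, adjacency = NULL, k = 23) {
  mask <- as.logical(mask)
  mask[is.na(mask)] <- FALSE
  comps <- mask_components(mask, adjacency)
  out <- rep(FALSE, length(mask))
  for (comp in comps) if (length(comp) > k) out[comp] <- TRUE
  out
}

# Connected components of the masked node set.
mask_components <- function(mask, adjacency = NULL) {
  idx <- which(mask)
  if (length(idx) == 0) return(list())
  if (is.null(adjacency)) return(as.list(idx))
  adjacency <- adjacency != 0
  if (!isSymmetric(unname(adjacency))) stop("adjacency must be symmetric")
  comps <- list()
  seen <- rep(FALSE, length(mask))
  for (s in idx) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE; comp <- integer()
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      comp <- c(comp, v)
      nb <- which(adjacency[v, ] & mask & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}

#' Define altered-connectivity features from a group contrast
#'
#' One feature per surviving component (per node in ROI mode) and direction:
#' the set of target nodes whose group difference survived FDR and cluster
#' filtering for a given seed.
#'
#' @param stat A `group_stat` from [two_sample_t()].
#' @param seed_label Seed the contrast belongs to.
#' @param node_labels Node labels aligned with `stat`.
#' @param q FDR level.
#' @param adjacency,k Passed to [cluster_filter()]; defaults suit ROI mode.
#' @return List of feature definitions (`label`, `seed_label`,
#'   `target_nodes`, `direction`); empty list when nothing survives.
#' @export
define_features <- function(stat, seed_label, node_labels, q = 0.05,
                            adjacency = NULL, k = 0) {
  fmask <- fdr_bh(stat$p, q)
  cmask <- cluster_filter(fmask, adjacency, k)
  comps <- mask_components(cmask, adjacency)
  feats <- list()
  for (comp in comps) {
    if (length(comp) > 0 && !all(cmask[comp])) next
    dir <- stat$direction[comp[1]]
    nodes <- node_labels[comp]
    feats[[length(feats) + 1]] <- list(
      label = paste(paste(nodes, collapse = "+"), "and", seed_label),
      seed_label = seed_label, target_nodes = nodes, direction = dir)
  }
  feats
}

#' Extract the subjects x features table
#'
#' Feature value = mean Fisher z over the feature's target nodes in the
#' subject's connectivity map for the feature's seed.
#'
#' @param conn_maps Nested list: `conn_maps[[subject_id]][[seed_label]]` is
#'   an [rsfc_map()].
#' @param feature_defs List of feature definitions from [define_features()].
#' @return Object of class `feature_table`: `values` (S x F matrix),
#'   `subject_ids`, `feature_labels`, `directions`, `defs`.
#' @export
extract_feature_table <- function(conn_maps, feature_defs) {
  if (length(feature_defs) == 0)
    stop("empty feature set: no altered connectivity survived thresholding")
  subjects <- names(conn_maps)
  vals <- matrix(NA_real_, length(subjects), length(feature_defs))
  for (i in seq_along(subjects)) {
    for (j in seq_along(feature_defs)) {
      def <- feature_defs[[j]]
      map <- conn_maps[[i]][[def$seed_label]]
      if (is.null(map)) stop("missing map for seed ", def$seed_label)
      vals[i, j] <- mean(map$z[match(def$target_nodes, map$node_labels)])
    }
  }
  labels <- vapply(feature_defs, `[[`, "", "label")
  colnames(vals) <- labels
  rownames(vals) <- subjects
  structure(list(values = vals, subject_ids = subjects,
                 feature_labels = labels,
                 directions = vapply(feature_defs, `[[`, "", "direction"),
                 defs = feature_defs),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d subjects x %d features (%d decrease, %d increase)\n",
              nrow(x$values), ncol(x$values),
              sum(x$directions == "decrease"), sum(x$directions == "increase")))
  invisible(x)
}
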