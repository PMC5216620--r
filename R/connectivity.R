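#' Seed definition
#'
#' Either a set of node labels/indices (ROI mode, primary) or an MNI centre
#' with a radius in mm (volume mode).  Volume mode is resolved against a
#' node-coordinate table and reduces to ROI mode.
#'
#' @param label Seed name (e.g. `"M1.L"`).
#' @param nodes Node labels (character) or indices (integer) forming the
#'   seed, for ROI mode.
#' @param mni_center Numeric length-3 MNI coordinate (mm), for volume mode.
#' @param radius Sphere radius in mm, for volume mode.
#' @return Object of class `seed_def`.
#' @export
seed_def <- function(label, nodes = NULL, mni_center = NULL, radius = NULL) {
  if (is.null(nodes) && (is.null(mni_center) || is.null(radius)))
    stop("seed needs either nodes or mni_center + radius")
  if (!is.null(radius) && radius <= 0) stop("seed radius must be positive")
  structure(list(label = label, nodes = nodes,
                 mni_center = mni_center, radius = radius),
            class = "seed_def")
}

#' Resolve the node set of a seed
#'
#' @param seed A [seed_def()].
#' @param ts A [bold_ts()] providing the node labels.
#' @param node_coords Optional data frame (`label`, `x`, `y`, `z` in MNI mm)
#'   required for volume-mode seeds.
#' @return Integer column indices into `ts$values`.
#' @export
resolve_seed_nodes <- function(seed, ts, node_coords = NULL) {
  labels <- ts$node_labels
  if (!is.null(seed$nodes)) {
    idx <- if (is.character(seed$nodes)) match(seed$nodes, labels)
           else as.integer(seed$nodes)
    if (anyNA(idx) || any(idx < 1 | idx > length(labels)))
      stop("seed nodes not found in time series: ", seed$label)
  } else {
    if (is.null(node_coords))
      stop("volume-mode seed requires node_coords: ", seed$label)
    d <- sqrt((node_coords$x - seed$mni_center[1])^2 +
              (node_coords$y - seed$mni_center[2])^2 +
              (node_coords$z - seed$mni_center[3])^2)
    idx <- match(node_coords$label[d <= seed$radius], labels)
    idx <- idx[!is.na(idx)]
  }
  if (length(idx) == 0) stop("empty seed after masking: ", seed$label)
  idx
}

#' Mean seed time series
#'
#' Arithmetic mean across the seed's nodes at every time point.
#'
#' @inheritParams resolve_seed_nodes
#' @return Numeric length-T vector.
#' @export
seed_signal <- function(ts, seed, node_coords = NULL) {
  idx <- resolve_seed_nodes(seed, ts, node_coords)
  rowMeans(ts$values[, idx, drop = FALSE])
}

#' Fisher r-to-z transform
#'
#' `z = atanh(r)`, with `r` clipped to +-(1 - 1e-12) so perfect correlations
#' map to a large finite value.
#'
#' @param r Correlations in `[-1, 1]`.
#' @return z values.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    stop("fisher_z domain error: |r| > 1")
  atanh(pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12))
}

#' Seed-based connectivity map
#'
#' Pearson correlation of the seed's mean signal with every node, plus the
#' Fisher z transform.  The seed's own nodes and zero-variance nodes carry
#' `NA` sentinels (kept in place so vectors stay aligned; downstream
#' statistics skip them).
#'
#' @inheritParams resolve_seed_nodes
#' @param subject_id Identifier stored in the result.
#' @return Object of class `rsfc_map`: `node_labels`, `r`, `z`, `seed_label`,
#'   `seed_nodes`, `subject_id`.
#' @export
rsfc_map <- function(ts, seed, subject_id = NA_character_,
                     node_coords = NULL) {
  idx <- resolve_seed_nodes(seed, ts, node_coords)
  s <- rowMeans(ts$values[, idx, drop = FALSE])
  if (sd(s) == 0) stop("degenerate seed (zero variance): ", seed$label)
  x <- ts$values
  n <- nrow(x)
  if (n < 8) stop("need at least 8 time points")
  sc <- s - mean(s)
  xc <- sweep(x, 2, colMeans(x))
  sds <- sqrt(colSums(xc^2))
  r <- unname(as.numeric(crossprod(xc, sc)) / (sds * sqrt(sum(sc^2))))
  r[sds == 0] <- NA_real_
  r[idx] <- NA_real_
  z <- ifelse(is.na(r), NA_real_, fisher_z(r))
  structure(list(subject_id = subject_id, seed_label = seed$label,
                 node_labels = ts$node_labels, r = r, z = z,
                 seed_nodes = idx),
            class = "rsfc_map")
}

#' @export
print.rsfc_map <- function(x, ...) {
  cat(sprintf("<rsfc_map> seed %s, subject %s, %d nodes (%d sentinel)\n",
              x$seed_label, x$subject_id, length(x$r), sum(is.na(x$r))))
  invisible(x)
}

#' Default single-node seeds at bilateral M1 and S1
#'
#' @return List of four [seed_def()] objects.
#' @export
default_seeds <- function() {
  lapply(SEED_NODES, function(l) seed_def(l, nodes = l))
}
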