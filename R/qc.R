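#' Framewise displacement of a motion trace
#'
#' FD is the mean, over successive volume pairs, of the Euclidean norm of the
#' parameter differences: `FD = 1/(M-1) * sum_{i=2}^{M} sqrt(dx_i^2 + dy_i^2
#' + dz_i^2)`, computed separately for the translation triplet (mm) and the
#' rotation triplet (degrees, no radius conversion).
#'
#' @param trace M x 6 numeric matrix: columns 1-3 translations (mm),
#'   columns 4-6 rotations (degrees).
#' @return Named numeric vector `c(fd_translation, fd_rotation)`.
#' @export
compute_fd <- function(trace) {
  trace <- as.matrix(trace)
  if (nrow(trace) < 2) stop("insufficient data: motion trace needs M >= 2")
  if (ncol(trace) != 6) stop("motion trace must have 6 columns")
  if (!all(is.finite(trace))) stop("motion trace must be finite")
  d <- diff(trace)
  c(fd_translation = mean(sqrt(rowSums(d[, 1:3, drop = FALSE]^2))),
    fd_rotation   = mean(sqrt(rowSums(d[, 4:6, drop = FALSE]^2))))
}

#' Motion-based subject exclusion
#'
#' Subjects whose maximum absolute translation strictly exceeds
#' `threshold_trans` (mm) or whose maximum absolute rotation strictly
#' exceeds `threshold_rot` (degrees) are excluded.  A value exactly at the
#' threshold is kept.  Subjects without a motion trace are excluded with
#' reason `"missing-motion"`.
#'
#' @param records Data frame with a `subject_id` column.
#' @param traces Named list of M x 6 motion matrices, names matching
#'   `subject_id`.
#' @param threshold_trans,threshold_rot Exclusion thresholds (strict).
#' @return List with `kept` (subset of `records`) and `qc` (one row per
#'   subject: FD values, maxima, `excluded`, `reason`).
#' @export
apply_exclusion <- function(records, traces,
                            threshold_trans = 1.0, threshold_rot = 1.0) {
  stopifnot(is.data.frame(records), "subject_id" %in% names(records))
  qc <- lapply(records$subject_id, function(id) {
    tr <- traces[[id]]
    if (is.null(tr)) {
      return(data.frame(subject_id = id, fd_translation = NA_real_,
                        fd_rotation = NA_real_, max_abs_translation = NA_real_,
                        max_abs_rotation = NA_real_, excluded = TRUE,
                        reason = "missing-motion", stringsAsFactors = FALSE))
    }
    fd <- compute_fd(tr)
    mt <- max(abs(tr[, 1:3]))
    mr <- max(abs(tr[, 4:6]))
    exc <- (mt > threshold_trans) || (mr > threshold_rot)
    reason <- if (!exc) "" else if (mt > threshold_trans) "high-translation"
              else "high-rotation"
    data.frame(subject_id = id, fd_translation = fd[["fd_translation"]],
               fd_rotation = fd[["fd_rotation"]], max_abs_translation = mt,
               max_abs_rotation = mr, excluded = exc, reason = reason,
               stringsAsFactors = FALSE)
  })
  qc <- do.call(rbind, qc)
  list(kept = records[!qc$excluded, , drop = FALSE], qc = qc)
}

#' Band-pass filter node time series
#'
#' Ideal (rectangular) frequency-domain band-pass applied identically to each
#' column: Fourier components with frequency inside `[low, high]` Hz are
#' retained, all others (including DC, so the output is mean-centred) are
#' zeroed.
#'
#' @param ts A [bold_ts()].
#' @param low,high Band edges in Hz; `0 < low < high < 1/(2*tr)`.
#' @return Filtered [bold_ts()].
#' @export
bandpass <- function(ts, low = 0.01, high = 0.08) {
  stopifnot(inherits(ts, "bold_ts"))
  nyq <- 1 / (2 * ts$tr)
  if (!(low > 0 && low < high && high < nyq))
    stop("invalid band: need 0 < low < high < Nyquist = ", nyq, " Hz")
  x <- ts$values
  n <- nrow(x)
  f <- (seq_len(n) - 1) / (n * ts$tr)
  f_eff <- pmin(f, 1 / ts$tr - f)   # fold negative frequencies
  keep <- f_eff >= low & f_eff <= high
  xf <- mvfft(x)
  xf[!keep, ] <- 0
  out <- Re(mvfft(xf, inverse = TRUE)) / n
  bold_ts(out, ts$tr, ts$node_labels)
}

#' Nuisance regression
#'
#' Replaces each node signal by its least-squares residual on an intercept,
#' the supplied confound columns and (optionally) the global mean signal
#' across nodes.  Residuals are orthogonal to every design column.  A
#' rank-deficient design triggers a warning and a minimum-norm
#' (pseudo-inverse) solution.
#'
#' @param ts A [bold_ts()].
#' @param confounds T x K numeric matrix (e.g. the 6 motion parameters), or
#'   NULL for intercept (and global signal) only.
#' @param include_global Add the row mean across nodes as a regressor
#'   (global signal regression).
#' @return Residualized [bold_ts()].
#' @export
regress_nuisance <- function(ts, confounds = NULL, include_global = FALSE) {
  stopifnot(inherits(ts, "bold_ts"))
  y <- ts$values
  n <- nrow(y)
  x <- matrix(1, n, 1)
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != n) stop("confounds must have T rows")
    if (!all(is.finite(confounds))) stop("confounds must be finite")
    x <- cbind(x, confounds)
  }
  if (include_global) x <- cbind(x, rowMeans(y))
  res <- lsq_residuals(y, x)
  bold_ts(res, ts$tr, ts$node_labels)
}

# Least-squares residuals of each column of y on design x; pseudo-inverse
# fallback when x is rank deficient.
lsq_residuals <- function(y, x) {
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    warning("rank-deficient design; using pseudo-inverse solution")
    sv <- svd(x)
    pos <- sv$d > max(sv$d) * 1e-10
    coef <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])
    y - x %*% coef
  } else {
    qr.resid(qx, y)
  }
}

#' Read a 6-column motion-parameter file
#'
#' Whitespace- or tab-delimited text, one row per volume.  Files following
#' the radian convention for rotations are converted to degrees.
#'
#' @param path File path.
#' @param units Rotation units in the file, `"deg"` (default) or `"rad"`.
#' @return M x 6 numeric matrix (rotations in degrees).
#' @export
read_motion <- function(path, units = c("deg", "rad")) {
  units <- match.arg(units)
  m <- as.matrix(read.table(path, header = FALSE))
  if (ncol(m) != 6) stop("motion file must have 6 columns: ", path)
  if (units == "rad") m[, 4:6] <- m[, 4:6] * 180 / pi
  colnames(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  m
}
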