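# Shared fixtures: all synthetic, built in code at test time.

# A small, fast cohort configuration for pipeline-level tests.
small_config <- function(seed = 1L, ...) {
  args <- modifyList(list(n_older = 12, n_younger = 12, n_timepoints = 120,
                          high_motion_fraction = 0, rng_seed = seed),
                     list(...))
  do.call(sim_config, args)
}

# Tiny deterministic bold_ts from a matrix.
make_ts <- function(values, tr = 2) bold_ts(as.matrix(values), tr = tr)

# Brute-force Pearson correlation (independent oracle).
bf_cor <- function(a, b) {
  n <- length(a)
  ca <- a - sum(a) / n
  cb <- b - sum(b) / n
  sum(ca * cb) / sqrt(sum(ca^2) * sum(cb^2))
}

# Independent primal objective for the package's linear SVM / SVR
# formulation (L2-regularized bias): used to verify the dual solvers.
svr_primal_obj <- function(par, X, y, C, eps) {
  p <- ncol(X)
  w <- par[seq_len(p)]; b <- par[p + 1]
  0.5 * sum(par^2) + C * sum(pmax(0, abs(y - (X %*% w + b)) - eps))
}

svm_primal_obj <- function(par, X, ysign, C) {
  p <- ncol(X)
  w <- par[seq_len(p)]; b <- par[p + 1]
  0.5 * sum(par^2) + C * sum(pmax(0, 1 - ysign * (X %*% w + b)))
}

# Multi-start Nelder-Mead minimizer of a convex primal (oracle only; slow).
primal_oracle <- function(obj, p, ..., starts = 3) {
  best <- NULL
  for (s in seq_len(starts)) {
    set.seed(1000 + s)
    par <- rnorm(p + 1, 0, s - 1)
    o <- optim(par, obj, ..., method = "Nelder-Mead",
               control = list(maxit = 50000, reltol = 1e-14))
    for (k in 1:4)
      o <- optim(o$par, obj, ..., method = "Nelder-Mead",
                 control = list(maxit = 50000, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  best
}
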