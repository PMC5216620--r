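#' Default node labels for the synthetic sensorimotor cohort
#'
#' The sensorimotor set (bilateral M1, S1, SMA, mid-posterior insula,
#' rolandic operculum, superior parietal lobule) plus `n_null` "null" nodes
#' that carry no connectivity with any other node and act as negative
#' controls for the group statistics.
#'
#' @param n_null Number of null control nodes (at least 5).
#' @return Character vector of node labels.
#' @export
default_node_labels <- function(n_null = 5) {
  c(SM_NODES, paste0("Null.", seq_len(n_null)))
}

#' Simulation configuration for a synthetic two-group rsFC cohort
#'
#' Encodes the stated world the generator emulates: an older and a younger
#' group with fixed age ranges, T resting-state time points at a given TR,
#' a sensorimotor node set with a common within-network correlation, an
#' age-dependent decline of insula-to-M1/S1 connectivity inside the older
#' group, a group-level increase of M1/S1-to-superior-parietal connectivity,
#' and 6-parameter motion traces with a configurable fraction of high-motion
#' subjects.
#'
#' @param n_older,n_younger Group sizes (>= 3 each).
#' @param age_range_older,age_range_younger Age ranges in years, `c(min, max)`.
#' @param n_timepoints Number of usable volumes per subject.
#' @param tr Repetition time in seconds.
#' @param node_labels Node labels; must contain all sensorimotor nodes of
#'   [default_node_labels()] plus at least 5 other (null) nodes.
#' @param base_within_network_r Baseline correlation between sensorimotor
#'   nodes, in `[0, 1)`.
#' @param insula_decline_slope Change in insula-to-M1/S1 correlation per year
#'   of age within the older group (non-positive; r units per year).
#' @param parietal_increase_delta Additive shift of M1/S1-to-SPL correlation
#'   for every older subject (r units).
#' @param noise_sd Marginal standard deviation of the node signals.
#' @param high_motion_fraction Probability that a subject's motion trace
#'   contains an injected excursion exceeding the exclusion thresholds.
#' @param subject_jitter_sd Standard deviation of a per-subject shift of the
#'   within-network baseline correlation (inter-individual variability).
#' @param motion_step_sd Standard deviation of the motion random-walk steps
#'   (mm for translations, degrees for rotations).
#' @param ar1_phi Optional AR(1) coefficient for temporal autocorrelation of
#'   the node signals (0 = white).
#' @param confound_freq,confound_amp Optional sinusoidal confound (Hz,
#'   amplitude) added to every node, giving the band-pass stage structured
#'   signal to remove.
#' @param education_mean,education_sd,gmv_mean,gmv_sd,p_female Named
#'   per-group (`older`, `younger`) covariate distribution parameters.
#' @param rng_seed Integer seed; the whole cohort is a deterministic function
#'   of the configuration including this seed.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_older = 52, n_younger = 51,
                       age_range_older = c(51, 76),
                       age_range_younger = c(18, 26),
                       n_timepoints = 250, tr = 2,
                       node_labels = default_node_labels(),
                       base_within_network_r = 0.4,
                       insula_decline_slope = -0.012,
                       parietal_increase_delta = 0.08,
                       noise_sd = 1,
                       high_motion_fraction = 0.1,
                       subject_jitter_sd = 0.06,
                       motion_step_sd = 0.02,
                       ar1_phi = 0,
                       confound_freq = NULL, confound_amp = 0,
                       education_mean = c(older = 9.9, younger = 13.9),
                       education_sd = c(older = 3.2, younger = 1.2),
                       gmv_mean = c(older = 575, younger = 620),
                       gmv_sd = c(older = 50, younger = 50),
                       p_female = c(older = 30 / 52, younger = 26 / 51),
                       rng_seed = 1L) {
  cfg <- list(n_older = as.integer(n_older), n_younger = as.integer(n_younger),
              age_range_older = as.numeric(age_range_older),
              age_range_younger = as.numeric(age_range_younger),
              n_timepoints = as.integer(n_timepoints), tr = as.numeric(tr),
              node_labels = as.character(node_labels),
              base_within_network_r = base_within_network_r,
              insula_decline_slope = insula_decline_slope,
              parietal_increase_delta = parietal_increase_delta,
              noise_sd = noise_sd,
              high_motion_fraction = high_motion_fraction,
              subject_jitter_sd = subject_jitter_sd,
              motion_step_sd = motion_step_sd,
              ar1_phi = ar1_phi,
              confound_freq = confound_freq, confound_amp = confound_amp,
              education_mean = education_mean, education_sd = education_sd,
              gmv_mean = gmv_mean, gmv_sd = gmv_sd, p_female = p_female,
              rng_seed = as.integer(rng_seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_older < 3 || cfg$n_younger < 3)
    stop_config("group sizes must be >= 3")
  if (cfg$age_range_older[1] > cfg$age_range_older[2] ||
      cfg$age_range_younger[1] > cfg$age_range_younger[2])
    stop_config("age ranges must be ordered (min <= max)")
  if (cfg$n_timepoints < 8) stop_config("n_timepoints must be >= 8")
  if (cfg$tr <= 0) stop_config("tr must be positive")
  if (anyDuplicated(cfg$node_labels)) stop_config("node labels must be unique")
  if (!all(SM_NODES %in% cfg$node_labels))
    stop_config("node_labels must include the sensorimotor set: ",
                paste(SM_NODES, collapse = ", "))
  if (sum(!(cfg$node_labels %in% SM_NODES)) < 5)
    stop_config("node_labels must include at least 5 null nodes")
  if (cfg$base_within_network_r < 0 || cfg$base_within_network_r >= 1)
    stop_config("base_within_network_r must be in [0, 1)")
  if (cfg$insula_decline_slope > 0)
    stop_config("insula_decline_slope must be <= 0")
  if (cfg$high_motion_fraction < 0 || cfg$high_motion_fraction > 1)
    stop_config("high_motion_fraction must be in [0, 1]")
  if (cfg$noise_sd <= 0) stop_config("noise_sd must be positive")
  if (abs(cfg$ar1_phi) >= 1) stop_config("ar1_phi must be in (-1, 1)")
  for (f in c("education_mean", "education_sd", "gmv_mean", "gmv_sd",
              "p_female")) {
    if (!all(c("older", "younger") %in% names(cfg[[f]])))
      stop_config(f, " must be named with 'older' and 'younger'")
  }
  invisible(cfg)
}

#' Repair a symmetric matrix to the nearest positive-definite correlation
#'
#' Eigenvalues are clipped at `floor` and the result rescaled to unit
#' diagonal.  Matrices that are already comfortably positive definite are
#' returned unchanged, so prescribed edge values are preserved exactly
#' whenever possible.
#'
#' @param R Symmetric matrix with unit diagonal.
#' @param floor Eigenvalue floor.
#' @return A positive-definite correlation matrix.
#' @export
repair_correlation <- function(R, floor = 1e-6) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) > floor) return(R)
  v <- pmax(e$values, floor)
  M <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(M))
  M <- M / (d %o% d)
  M <- (M + t(M)) / 2
  diag(M) <- 1
  if (min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop_config("correlation matrix not repairable to positive definite")
  dimnames(M) <- dimnames(R)
  M
}

#' Target correlation matrix for one synthetic subject
#'
#' Within-network edges equal the baseline correlation (plus an optional
#' per-subject shift).  For older subjects, every insula-to-M1/S1 edge is
#' lowered linearly with age (`base + slope * (age - min_age)`) and every
#' M1/S1-to-SPL edge is raised by a constant, mirroring the direction of the
#' reported group effects (decreased insula coupling, increased parietal
#' coupling).  Null nodes are uncorrelated with everything.
#'
#' @param subject A one-row data frame or list with fields `group` and `age`.
#' @param config A [sim_config()].
#' @param base_shift Per-subject additive shift of the within-network
#'   baseline (used by [simulate_cohort()] for inter-individual variability).
#' @return N x N positive-definite correlation matrix with node dimnames.
#' @export
build_target_correlation <- function(subject, config, base_shift = 0) {
  labels <- config$node_labels
  n <- length(labels)
  base <- min(max(config$base_within_network_r + base_shift, 0.02), 0.9)
  sm <- labels %in% SM_NODES
  R <- diag(n)
  dimnames(R) <- list(labels, labels)
  R[sm, sm] <- base
  diag(R) <- 1
  if (identical(as.character(subject$group), "older")) {
    age0 <- config$age_range_older[1]
    ins_val <- base + config$insula_decline_slope * (subject$age - age0)
    spl_val <- base + config$parietal_increase_delta
    clip <- function(x) min(max(x, -0.95), 0.95)
    for (a in INSULA_NODES) for (b in SEED_NODES) {
      R[a, b] <- R[b, a] <- clip(ins_val)
    }
    for (a in SPL_NODES) for (b in SEED_NODES) {
      R[a, b] <- R[b, a] <- clip(spl_val)
    }
  }
  repair_correlation(R)
}

#' A T x N node time-series container
#'
#' @param values Numeric T x N matrix of node signals.
#' @param tr Repetition time in seconds.
#' @param node_labels Unique labels for the N columns.
#' @return Object of class `bold_ts`.
#' @export
bold_ts <- function(values, tr, node_labels = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(node_labels)) node_labels <- paste0("node", seq_len(ncol(values)))
  if (nrow(values) < 8) stop_config("time series must have at least 8 points")
  if (anyDuplicated(node_labels)) stop_config("node labels must be unique")
  if (length(node_labels) != ncol(values))
    stop_config("node_labels length must match columns")
  if (!all(is.finite(values))) stop_config("time series must be finite")
  colnames(values) <- node_labels
  structure(list(values = values, tr = as.numeric(tr),
                 node_labels = as.character(node_labels)),
            class = "bold_ts")
}

#' @export
print.bold_ts <- function(x, ...) {
  cat(sprintf("<bold_ts> %d time points x %d nodes, TR = %gs\n",
              nrow(x$values), ncol(x$values), x$tr))
  invisible(x)
}

#' Simulate a 6-parameter rigid-body motion trace
#'
#' A clipped Gaussian random walk (3 translations in mm, 3 rotations in
#' degrees).  With probability `high_motion_fraction` an excursion strictly
#' exceeding the 1 mm / 1 degree exclusion thresholds is injected.  The clip
#' at +-0.8 guarantees that non-excursion traces can never trip the strict
#' thresholds, so `high_motion_fraction` is exactly the flagging rate.
#'
#' Uses the current RNG stream; seed externally (or via [simulate_cohort()])
#' for reproducibility.
#'
#' @param config A [sim_config()].
#' @param subject Subject record (unused beyond documentation of provenance;
#'   the excursion draw is i.i.d. across subjects).
#' @return M x 6 matrix, columns `trans_x, trans_y, trans_z, rot_x, rot_y,
#'   rot_z`.
#' @export
simulate_motion <- function(config, subject = NULL) {
  m <- config$n_timepoints
  steps <- matrix(rnorm(m * 6L, 0, config$motion_step_sd), m, 6L)
  steps[1L, ] <- 0
  pos <- apply(steps, 2L, cumsum)
  pos <- pmin(pmax(pos, -0.8), 0.8)
  if (runif(1) < config$high_motion_fraction) {
    axis <- sample.int(6L, 1L)
    t0 <- sample.int(m - 1L, 1L) + 1L
    amp <- sample(c(-1, 1), 1L) * runif(1, 1.05, 2)
    pos[t0:min(m, t0 + 4L), axis] <- amp
  }
  colnames(pos) <- c("trans_x", "trans_y", "trans_z",
                     "rot_x", "rot_y", "rot_z")
  pos
}

ar1_noise <- function(n, phi) {
  if (phi == 0) return(rnorm(n))
  x <- stats::filter(rnorm(n), phi, method = "recursive")
  as.numeric(x) * sqrt(1 - phi^2)
}

#' Simulate a complete two-group cohort
#'
#' Draws demographics, per-subject target correlation matrices, node time
#' series (Cholesky-mixed noise so the empirical correlations converge to
#' the targets as T grows) and motion traces.  Deterministic given the
#' configuration, including its `rng_seed`.
#'
#' @param config A [sim_config()].
#' @return A list of class `sm_cohort` with elements `cohort` (data frame:
#'   subject_id, group, age, gender, education_years, gmv), `series` (named
#'   list of [bold_ts()]), `motion` (named list of motion matrices) and
#'   `truth` (ground-truth edge lists, per-subject target matrices and
#'   jitters).
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$rng_seed)
  groups <- list(older = config$n_older, younger = config$n_younger)
  rec_list <- list()
  for (g in names(groups)) {
    n <- groups[[g]]
    rng <- if (g == "older") config$age_range_older else config$age_range_younger
    rec_list[[g]] <- data.frame(
      subject_id = sprintf("%s_%03d", g, seq_len(n)),
      group = g,
      age = runif(n, rng[1], rng[2]),
      gender = ifelse(runif(n) < config$p_female[[g]], "F", "M"),
      education_years = pmin(pmax(
        rnorm(n, config$education_mean[[g]], config$education_sd[[g]]), 0), 25),
      gmv = pmax(rnorm(n, config$gmv_mean[[g]], config$gmv_sd[[g]]), 1),
      stringsAsFactors = FALSE)
  }
  cohort <- rbind(rec_list$older, rec_list$younger)
  rownames(cohort) <- NULL
  s_all <- nrow(cohort)
  jitter <- rnorm(s_all, 0, config$subject_jitter_sd)
  # keep the shifted baseline inside a sane correlation range
  jitter <- pmin(pmax(jitter, 0.02 - config$base_within_network_r),
                 0.9 - config$base_within_network_r)

  labels <- config$node_labels
  n_nodes <- length(labels)
  tt <- config$n_timepoints
  series <- vector("list", s_all)
  motion <- vector("list", s_all)
  targets <- vector("list", s_all)
  conf_sig <- if (!is.null(config$confound_freq) && config$confound_amp > 0) {
    config$confound_amp *
      sin(2 * pi * config$confound_freq * config$tr * seq_len(tt))
  } else NULL
  for (i in seq_len(s_all)) {
    rec <- cohort[i, ]
    tgt <- build_target_correlation(rec, config, base_shift = jitter[i])
    targets[[i]] <- tgt
    u <- chol(tgt)
    z <- matrix(0, tt, n_nodes)
    for (j in seq_len(n_nodes)) z[, j] <- ar1_noise(tt, config$ar1_phi)
    x <- (z %*% u) * config$noise_sd
    if (!is.null(conf_sig)) x <- x + conf_sig
    series[[i]] <- bold_ts(x, config$tr, labels)
    motion[[i]] <- simulate_motion(config, rec)
  }
  names(series) <- names(motion) <- names(targets) <- cohort$subject_id

  age_edges <- expand.grid(node_a = INSULA_NODES, node_b = SEED_NODES,
                           stringsAsFactors = FALSE)
  age_edges$direction <- "decrease"
  grp_edges <- expand.grid(node_a = SPL_NODES, node_b = SEED_NODES,
                           stringsAsFactors = FALSE)
  grp_edges$direction <- "increase"
  truth <- list(age_coupled_edges = age_edges,
                group_shifted_edges = grp_edges,
                insula_decline_slope = config$insula_decline_slope,
                parietal_increase_delta = config$parietal_increase_delta,
                base_within_network_r = config$base_within_network_r,
                jitter = setNames(jitter, cohort$subject_id),
                targets = targets)
  structure(list(cohort = cohort, series = series, motion = motion,
                 truth = truth, config = config),
            class = "sm_cohort")
}

#' @export
print.sm_cohort <- function(x, ...) {
  cat(sprintf("<sm_cohort> %d older + %d younger subjects, T = %d, %d nodes\n",
              sum(x$cohort$group == "older"),
              sum(x$cohort$group == "younger"),
              x$config$n_timepoints, length(x$config$node_labels)))
  invisible(x)
}

#' Simulate an older-adult feature table with one planted age signal
#'
#' Builds an S x (1 + n_null) feature matrix in which the first column has a
#' prescribed population correlation with age and the remaining columns are
#' independent noise.  Used to study recovery of an informative connectivity
#' feature by the prediction frameworks.
#'
#' @param n Number of subjects.
#' @param n_null Number of uninformative features.
#' @param r_planted Population correlation of the planted feature with age
#'   (e.g. -0.6 for an age-related connectivity decline).
#' @param age_range Age range (years), sampled uniformly.
#' @param rng_seed Integer seed.
#' @return List with `X` (feature matrix; planted feature first, labelled
#'   `planted`), `age`, and `planted` (the planted column index, 1).
#' @export
simulate_feature_table <- function(n = 52, n_null = 49, r_planted = -0.6,
                                   age_range = c(51, 76), rng_seed = 1L) {
  stopifnot(abs(r_planted) < 1, n >= 5)
  set.seed(as.integer(rng_seed))
  age <- runif(n, age_range[1], age_range[2])
  zage <- (age - mean(age)) / sd(age)
  planted <- r_planted * zage + sqrt(1 - r_planted^2) * rnorm(n)
  X <- cbind(planted, matrix(rnorm(n * n_null), n, n_null))
  colnames(X) <- c("planted", paste0("null_", seq_len(n_null)))
  list(X = X, age = age, planted = 1L)
}
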