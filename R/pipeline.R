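#' Default pipeline configuration
#'
#' A single list drives the full pipeline; every stage reads its parameters
#' from its own section.  CLI flags and user lists are merged over these
#' defaults with [modifyList()].
#'
#' @param out_dir Output directory.
#' @param seed Master seed; stage-specific seeds are derived from it.
#' @param gsr Include global signal regression in the nuisance stage.
#' @param stages Character vector of stages to run, in order, from
#'   `simulate`, `qc`, `connect`, `stats`, `predict`, `classify`, `report`.
#' @param ... Overrides for the stage sections (`sim`, `qc`, `stats`,
#'   `predict`, `classify`), each a list.
#' @return Config list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("connage_run_"), seed = 1L,
                       gsr = TRUE,
                       stages = c("simulate", "qc", "connect", "stats",
                                  "predict", "classify", "report"), ...) {
  base <- list(
    out_dir = out_dir, seed = as.integer(seed), gsr = gsr, stages = stages,
    input_dir = NULL, plots = FALSE,
    sim = list(),
    qc = list(threshold_trans = 1.0, threshold_rot = 1.0,
              low = 0.01, high = 0.08),
    stats = list(q = 0.05, k = 0),
    predict = list(epsilon = 0.001, C = 1.0, theta = 0.5, n_perm = 1000,
                   uvpa = TRUE),
    classify = list(C = 1.0, n_perm = 0))
  cfg <- modifyList(base, list(...))
  unknown <- setdiff(cfg$stages, c("simulate", "qc", "connect", "stats",
                                   "predict", "classify", "report"))
  if (length(unknown)) stop_config("unknown stages: ",
                                   paste(unknown, collapse = ", "))
  structure(cfg, class = "run_config")
}

stage_error <- function(stage, e) {
  stop(structure(class = c("connage_stage_error", "error", "condition"),
                 list(message = sprintf("stage '%s' failed: %s", stage,
                                        conditionMessage(e)),
                      call = NULL, stage = stage)))
}

write_manifest <- function(dir, stage, params, files) {
  files <- files[file.exists(files)]
  manifest <- list(stage = stage, params = params,
                   outputs = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest,
                       file.path(dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes the enabled stages in order: simulate (or load) a cohort ->
#' motion QC, band-pass and nuisance regression -> seed-based connectivity
#' maps -> covariate-adjusted group statistics defining altered-edge
#' features -> age prediction in the older group (MVPA and per-feature
#' UVPA) -> older-vs-younger SVM classification on increased vs decreased
#' edge sets -> demographics report.  Every stage writes its outputs and a
#' manifest (parameters + output md5 sums) under `config$out_dir`; rerunning
#' with an identical config reproduces identical outputs.
#'
#' @param config A [run_config()].
#' @return List of in-memory stage results (class `run_report`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stop_config("need a run_config")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list(config = config)
  st <- function(name) name %in% config$stages

  if (st("simulate")) {
    res$sim <- tryCatch({
      cfg <- do.call(sim_config, modifyList(config$sim,
                                            list(rng_seed = config$seed)))
      sim <- simulate_cohort(cfg)
      write_cohort(sim, config$out_dir)
      write_manifest(config$out_dir, "simulate", unclass(cfg),
                     file.path(config$out_dir,
                               c("cohort.tsv", "truth.json")))
      sim
    }, error = function(e) stage_error("simulate", e))
  } else if (!is.null(config$input_dir)) {
    loaded <- read_cohort(config$input_dir,
                          tr = config$sim$tr %||% 2)
    res$sim <- structure(list(cohort = loaded$cohort, series = loaded$series,
                              motion = loaded$motion, truth = NULL,
                              config = NULL),
                         class = "sm_cohort")
  }

  if (st("qc")) {
    res$qc <- tryCatch({
      sim <- res$sim
      if (is.null(sim)) stop("no cohort available (simulate or input_dir)")
      exc <- apply_exclusion(sim$cohort, sim$motion,
                             config$qc$threshold_trans,
                             config$qc$threshold_rot)
      write.table(exc$qc, file.path(config$out_dir, "qc.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      clean <- list()
      for (id in exc$kept$subject_id) {
        ts <- bandpass(sim$series[[id]], config$qc$low, config$qc$high)
        clean[[id]] <- regress_nuisance(ts, confounds = sim$motion[[id]],
                                        include_global = config$gsr)
      }
      write_manifest(config$out_dir, "qc",
                     c(config$qc, list(gsr = config$gsr)),
                     file.path(config$out_dir, "qc.tsv"))
      list(kept = exc$kept, qc = exc$qc, clean = clean)
    }, error = function(e) stage_error("qc", e))
  }

  if (st("connect")) {
    res$conn <- tryCatch({
      seeds <- default_seeds()
      clean <- res$qc$clean
      maps <- lapply(names(clean), function(id) {
        m <- lapply(seeds, function(sd) rsfc_map(clean[[id]], sd, id))
        names(m) <- vapply(seeds, `[[`, "", "label")
        m
      })
      names(maps) <- names(clean)
      cdir <- file.path(config$out_dir, "connectivity")
      dir.create(cdir, showWarnings = FALSE)
      for (id in names(maps)) for (sl in names(maps[[id]]))
        write_rsfc_map(maps[[id]][[sl]],
                       file.path(cdir, sprintf("%s_%s.tsv", id, sl)))
      write_manifest(config$out_dir, "connect",
                     list(seeds = vapply(seeds, `[[`, "", "label")),
                     list.files(cdir, full.names = TRUE))
      maps
    }, error = function(e) stage_error("connect", e))
  }

  if (st("stats")) {
    res$stats <- tryCatch({
      maps <- res$conn
      kept <- res$qc$kept
      node_labels <- maps[[1]][[1]]$node_labels
      seeds <- names(maps[[1]])
      covars <- cbind(gmv = kept$gmv, education = kept$education_years,
                      gender = as.numeric(kept$gender == "F"))
      feature_defs <- list()
      stat_rows <- list()
      for (sl in seeds) {
        zmat <- t(vapply(kept$subject_id,
                         function(id) maps[[id]][[sl]]$z,
                         numeric(length(node_labels))))
        grp <- kept$group
        zr <- zmat
        for (g in unique(grp)) {
          idx <- grp == g
          zr[idx, ] <- residualize_covariates(zmat[idx, , drop = FALSE],
                                              covars[idx, , drop = FALSE])
        }
        onesA <- one_sample_t(zr[grp == "older", , drop = FALSE])
        onesB <- one_sample_t(zr[grp == "younger", , drop = FALSE])
        union_mask <- fdr_bh(onesA$p, config$stats$q) |
                      fdr_bh(onesB$p, config$stats$q)
        diff <- two_sample_t(zr[grp == "older", , drop = FALSE],
                             zr[grp == "younger", , drop = FALSE],
                             mask = union_mask)
        defs <- define_features(diff, sl, node_labels, q = config$stats$q,
                                k = config$stats$k)
        feature_defs <- c(feature_defs, defs)
        stat_rows[[sl]] <- data.frame(
          seed = sl, node = node_labels, t = diff$t, p = diff$p,
          fdr_flag = fdr_bh(diff$p, config$stats$q),
          direction = diff$direction, stringsAsFactors = FALSE)
      }
      stat_tab <- do.call(rbind, stat_rows)
      write.table(stat_tab, file.path(config$out_dir, "group_stats.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      ft <- extract_feature_table(maps, feature_defs)
      write_feature_table(ft, file.path(config$out_dir, "features.tsv"))
      write_manifest(config$out_dir, "stats", config$stats,
                     file.path(config$out_dir,
                               c("group_stats.tsv", "features.tsv")))
      list(feature_defs = feature_defs, feature_table = ft,
           table = stat_tab, kept = kept)
    }, error = function(e) stage_error("stats", e))
  }

  if (st("predict")) {
    res$predict <- tryCatch({
      ft <- res$stats$feature_table
      kept <- res$stats$kept
      older <- kept$group == "older"
      Xo <- ft$values[ft$subject_ids %in% kept$subject_id[older], ,
                      drop = FALSE]
      ages <- kept$age[match(rownames(Xo), kept$subject_id)]
      pcfg <- config$predict
      mv <- mvpa_nested_loocv(Xo, ages, epsilon = pcfg$epsilon, C = pcfg$C,
                              theta = pcfg$theta, n_perm = pcfg$n_perm,
                              rng_seed = config$seed + 1L,
                              feature_labels = ft$feature_labels)
      uv <- NULL
      if (isTRUE(pcfg$uvpa)) {
        uv <- lapply(seq_len(ncol(Xo)), function(j)
          uvpa_loocv(Xo[, j], ages, n_perm = pcfg$n_perm,
                     rng_seed = config$seed + 1L + j))
        names(uv) <- ft$feature_labels
      }
      out <- list(
        mvpa = list(r_pred_obs = mv$r_pred_obs, mae = mv$mae,
                    p_perm = mv$p_perm, n_perm = mv$n_perm,
                    consensus_features = mv$consensus_features),
        uvpa = lapply(uv, function(u)
          list(r_pred_obs = u$r_pred_obs, mae = u$mae, p_perm = u$p_perm)))
      jsonlite::write_json(out, file.path(config$out_dir, "prediction.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      write.table(data.frame(subject_id = rownames(Xo), observed_age = ages,
                             predicted_age = mv$predicted_ages),
                  file.path(config$out_dir, "predicted_ages.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      if (isTRUE(config$plots)) {
        grDevices::pdf(file.path(config$out_dir, "prediction_scatter.pdf"))
        graphics::plot(ages, mv$predicted_ages, xlab = "chronological age",
                       ylab = "estimated age",
                       main = sprintf("MVPA r = %.3f, MAE = %.2f",
                                      mv$r_pred_obs, mv$mae))
        graphics::abline(0, 1, lty = 2)
        grDevices::dev.off()
      }
      write_manifest(config$out_dir, "predict", pcfg,
                     file.path(config$out_dir,
                               c("prediction.json", "predicted_ages.tsv")))
      list(mvpa = mv, uvpa = uv)
    }, error = function(e) stage_error("predict", e))
  }

  if (st("classify")) {
    res$classify <- tryCatch({
      ft <- res$stats$feature_table
      kept <- res$stats$kept
      labels <- kept$group[match(ft$subject_ids, kept$subject_id)]
      out <- list()
      for (dir_ in c("decreased", "increased")) {
        cols <- which(ft$directions ==
                        if (dir_ == "decreased") "decrease" else "increase")
        if (length(cols) == 0) next
        out[[dir_]] <- svm_loocv_classify(
          ft$values[, cols, drop = FALSE], labels, C = config$classify$C,
          n_perm = config$classify$n_perm, rng_seed = config$seed + 5000L)
      }
      if (length(out) == 0) stop("no directional feature sets available")
      summ <- lapply(out, function(o)
        list(accuracy = o$accuracy, sensitivity = o$sensitivity,
             specificity = o$specificity, auc = o$auc, p_perm = o$p_perm))
      jsonlite::write_json(summ,
                           file.path(config$out_dir, "classification.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      for (dir_ in names(out))
        write.table(out[[dir_]]$roc_points,
                    file.path(config$out_dir,
                              sprintf("roc_%s.tsv", dir_)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      write_manifest(config$out_dir, "classify", config$classify,
                     file.path(config$out_dir,
                               c("classification.json", "roc_decreased.tsv",
                                 "roc_increased.tsv")))
      out
    }, error = function(e) stage_error("classify", e))
  }

  if (st("report")) {
    res$report <- tryCatch({
      rep <- demographics_report(res$qc$kept, res$qc$qc)
      write.table(rep, file.path(config$out_dir, "demographics.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write_manifest(config$out_dir, "report", list(),
                     file.path(config$out_dir, "demographics.tsv"))
      rep
    }, error = function(e) stage_error("report", e))
  }
  structure(res, class = "run_report")
}

#' Group demographics and motion homogeneity report
#'
#' Per-group mean and SD for age, education, GMV and (when QC results are
#' supplied) framewise displacement, with two-sample two-tailed t-tests for
#' the continuous variables and a chi-square test for gender.
#'
#' @param records Cohort data frame (after QC) with `group`, `age`, `gender`,
#'   `education_years`, `gmv`.
#' @param qc Optional QC table from [apply_exclusion()] (adds FD rows).
#' @return Data frame with one row per variable: group means/SDs, statistic,
#'   p-value.
#' @export
demographics_report <- function(records, qc = NULL) {
  stopifnot(all(table(records$group) >= 3))
  vars <- list(age = records$age, education_years = records$education_years,
               gmv = records$gmv)
  if (!is.null(qc)) {
    m <- qc[match(records$subject_id, qc$subject_id), ]
    vars$fd_translation <- m$fd_translation
    vars$fd_rotation <- m$fd_rotation
  }
  grp <- records$group
  rows <- lapply(names(vars), function(v) {
    x <- vars[[v]]
    a <- x[grp == "older"]; b <- x[grp == "younger"]
    tt <- t.test(a, b, var.equal = TRUE)
    data.frame(variable = v,
               older_mean = mean(a), older_sd = sd(a),
               younger_mean = mean(b), younger_sd = sd(b),
               statistic = unname(tt$statistic), p_value = tt$p.value,
               stringsAsFactors = FALSE)
  })
  tab <- table(grp, records$gender)
  chi <- suppressWarnings(chisq.test(tab))
  rows[[length(rows) + 1]] <- data.frame(
    variable = "gender_female_fraction",
    older_mean = mean(records$gender[grp == "older"] == "F"), older_sd = NA,
    younger_mean = mean(records$gender[grp == "younger"] == "F"),
    younger_sd = NA,
    statistic = unname(chi$statistic), p_value = chi$p.value,
    stringsAsFactors = FALSE)
  do.call(rbind, rows)
}
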