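#' Write a simulated cohort to a directory of delimited text files
#'
#' Layout: `cohort.tsv` (subject_id, group, age, gender, education_years,
#' gmv), `timeseries/<id>.tsv` (T rows x N labelled columns),
#' `motion/<id>.tsv` (M rows x 6 columns, no header) and `truth.json`.
#'
#' @param sim An `sm_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "sm_cohort"))
  dir.create(file.path(dir, "timeseries"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "motion"), showWarnings = FALSE)
  write.table(sim$cohort, file.path(dir, "cohort.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (id in sim$cohort$subject_id) {
    write.table(sim$series[[id]]$values,
                file.path(dir, "timeseries", paste0(id, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(sim$motion[[id]], file.path(dir, "motion", paste0(id, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  truth <- sim$truth
  truth$targets <- NULL   # matrices are re-derivable from the config
  truth$config <- unclass(sim$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing `cohort.tsv`, `timeseries/`, `motion/`.
#' @param tr Repetition time in seconds for the time series.
#' @param motion_units Rotation units of the motion files.
#' @return List with `cohort`, `series`, `motion` (as in [simulate_cohort()]).
#' @export
read_cohort <- function(dir, tr = 2, motion_units = c("deg", "rad")) {
  motion_units <- match.arg(motion_units)
  cohort <- read.delim(file.path(dir, "cohort.tsv"), stringsAsFactors = FALSE)
  series <- motion <- list()
  for (id in cohort$subject_id) {
    ts_path <- file.path(dir, "timeseries", paste0(id, ".tsv"))
    mo_path <- file.path(dir, "motion", paste0(id, ".tsv"))
    if (file.exists(ts_path)) {
      v <- as.matrix(read.delim(ts_path, check.names = FALSE))
      series[[id]] <- bold_ts(v, tr)
    }
    if (file.exists(mo_path)) motion[[id]] <- read_motion(mo_path, motion_units)
  }
  list(cohort = cohort, series = series, motion = motion)
}

#' Write a connectivity map as TSV (node_label, r, z)
#'
#' @param map An [rsfc_map()].
#' @param path Output file.
#' @export
write_rsfc_map <- function(map, path) {
  write.table(data.frame(node_label = map$node_labels, r = map$r, z = map$z),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a feature table TSV (subjects x features)
#'
#' @param ft A `feature_table` (write) or file path (read).
#' @param path Output file.
#' @export
write_feature_table <- function(ft, path) {
  df <- data.frame(subject_id = ft$subject_ids, ft$values,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$subject_id
  structure(list(values = vals, subject_ids = df$subject_id,
                 feature_labels = colnames(vals),
                 directions = rep(NA_character_, ncol(vals)), defs = NULL),
            class = "feature_table")
}
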