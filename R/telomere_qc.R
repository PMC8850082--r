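#' Run-level quality control for telomere qPCR assay runs
#'
#' An assay run (plate group) is excluded when its count of invalid control
#' wells reaches 8, or when more than 4 of its control DNA values fall
#' outside 2.5 standard deviations of the across-run control mean.
#'
#' @param run_wells Data frame with columns `run_id` and `invalid_wells`
#'   (non-negative counts), one row per run.
#' @param control_values Data frame with columns `run_id` and `value`
#'   (control DNA T/S values), long format; may be `NULL` if only the
#'   invalid-well rule is wanted.
#' @param all_run_mean,all_run_sd Mean and standard deviation of control DNA
#'   values across all assay runs; `all_run_sd` must be positive.
#' @param max_invalid_wells Invalid-well threshold (default 8; `>=` excludes).
#' @param max_outlying_controls Control-value threshold (default 4; strictly
#'   more than this count excludes).
#' @param n_sd Width of the control band in standard deviations (default 2.5).
#' @return Character vector of excluded run ids (possibly empty).
#' @export
flag_runs <- function(run_wells, control_values, all_run_mean, all_run_sd,
                      max_invalid_wells = 8, max_outlying_controls = 4,
                      n_sd = 2.5) {
  stopifnot(all(c("run_id", "invalid_wells") %in% names(run_wells)))
  if (any(run_wells$invalid_wells < 0)) stop("invalid_wells must be >= 0")
  if (!is.null(control_values) && (!is.finite(all_run_sd) || all_run_sd <= 0)) {
    stop("all_run_sd must be positive")
  }
  bad <- run_wells$run_id[run_wells$invalid_wells >= max_invalid_wells]
  if (!is.null(control_values)) {
    stopifnot(all(c("run_id", "value") %in% names(control_values)))
    out <- abs(control_values$value - all_run_mean) > n_sd * all_run_sd
    n_out <- tapply(out, control_values$run_id, sum)
    bad <- union(bad, names(n_out)[n_out > max_outlying_controls])
  }
  as.character(sort(unique(as.character(bad))))
}

#' Replicate-level quality control for one sample's T/S ratios
#'
#' Each sample is assayed in duplicate wells on three days, nominally six
#' T/S values.  The largest and smallest values are marked as potential
#' outliers; a trimmed mean `m` is computed excluding both; a potential
#' outlier `v` is excluded when `|log(m / v)|` exceeds `threshold`
#' (natural log by default).  Potential outliers that pass the test are
#' restored, and the final mean and SD are computed over retained values.
#'
#' @param values Positive T/S ratios, at least 3.
#' @param threshold Log-ratio bound (default 0.4).
#' @param log_base Base of the logarithm used for the ratio test (default
#'   `exp(1)`).
#' @param restore_passing Restore a potential outlier that passes the test
#'   (default `TRUE`); set `FALSE` to always drop the marked extremes.
#' @return List with `mean`, `sd`, `n_retained`, `retained` (values) and
#'   `excluded` (values, possibly empty).
#' @export
qc_replicates <- function(values, threshold = 0.4, log_base = exp(1),
                          restore_passing = TRUE) {
  if (anyNA(values) || any(values <= 0)) {
    stop("replicate T/S values must be positive and non-missing")
  }
  if (length(values) < 3L) {
    stop("insufficient replicates: at least 3 T/S values are required")
  }
  i_min <- which.min(values)
  i_max <- which.max(values)
  if (values[i_min] == values[i_max]) {
    # all replicates identical: no outlier candidates
    return(list(mean = values[1L], sd = stats::sd(values),
                n_retained = length(values), retained = values,
                excluded = numeric(0)))
  }
  core <- values[-c(i_min, i_max)]
  m <- mean(core)
  is_out <- function(v) abs(log(m / v, base = log_base)) > threshold
  drop_idx <- integer(0)
  for (i in unique(c(i_min, i_max))) {
    if (is_out(values[i]) || !restore_passing) drop_idx <- c(drop_idx, i)
  }
  retained <- if (length(drop_idx) > 0L) values[-drop_idx] else values
  list(mean = mean(retained), sd = stats::sd(retained),
       n_retained = length(retained), retained = retained,
       excluded = values[drop_idx])
}

#' Replicate QC over a long-format table of T/S measurements
#'
#' Applies [qc_replicates()] per sample after dropping measurements from
#' excluded assay runs.
#'
#' @param replicates Data frame with columns `sample_id`, `run_id`, `ts`.
#' @param excluded_runs Run ids to drop before per-sample QC (e.g. from
#'   [flag_runs()]).
#' @param ... Passed to [qc_replicates()].
#' @return Data frame with one row per sample: `sample_id`, `ts_mean`,
#'   `ts_sd`, `n_retained`, `n_excluded`.  Samples left with fewer than 3
#'   values after run exclusion are dropped with a warning.
#' @export
qc_replicate_table <- function(replicates, excluded_runs = character(0), ...) {
  stopifnot(all(c("sample_id", "run_id", "ts") %in% names(replicates)))
  keep <- !(as.character(replicates$run_id) %in% as.character(excluded_runs))
  replicates <- replicates[keep, , drop = FALSE]
  ids <- unique(replicates$sample_id)
  rows <- lapply(ids, function(id) {
    v <- replicates$ts[replicates$sample_id == id]
    if (length(v) < 3L) return(NULL)
    r <- qc_replicates(v, ...)
    data.frame(sample_id = id, ts_mean = r$mean, ts_sd = r$sd,
               n_retained = r$n_retained, n_excluded = length(r$excluded))
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0L) {
    warning(dropped, " sample(s) dropped: fewer than 3 replicates after ",
            "run exclusion")
  }
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}
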