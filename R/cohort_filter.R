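#' Required cohort columns
#'
#' Column names a cohort table must carry: identifiers and survey design
#' variables, the model covariates, exclusion flags, and one column per OBS
#' component.
#'
#' @param schema An `obs_schema` (defaults to [default_schema()]).
#' @return Named list with elements `design`, `covariates`, `flags`,
#'   `components`.
#' @export
cohort_columns <- function(schema = default_schema()) {
  list(design = c("id", "stratum", "psu", "weight"),
       covariates = c("sex", "age", "ethnicity", "education", "pir",
                      "energy", "crp", "ltl"),
       flags = c("pregnant", "recall_status"),
       components = schema$component)
}

#' Sex-specific plausible energy-intake bounds (kcal/d)
#'
#' Intakes strictly below the lower bound or strictly above the upper bound
#' are implausible; a value exactly on a bound is retained.
#'
#' @return Data frame with columns `sex`, `lower`, `upper`.
#' @export
energy_bounds <- function() {
  data.frame(sex = c("male", "female"),
             lower = c(800, 500), upper = c(4200, 3500))
}

#' Apply the cohort exclusion pipeline
#'
#' Sequentially excludes participants that (1) are missing any OBS component
#' or model covariate, (2) are outside the adult age range (under 20 or 85
#' and over; the oldest ages are top-coded at 85 in the source data),
#' (3) are pregnant, (4) have a dietary recall below the minimum criteria,
#' or (5) report an implausible energy intake (male: <800 or >4200 kcal/d,
#' female: <500 or >3500 kcal/d, bounds exclusive).  A participant violating
#' several criteria is counted once, at the first violated step, matching
#' the sequential semantics of an attrition flowchart.
#'
#' @param cohort Cohort data frame (see [cohort_columns()]).
#' @param schema An `obs_schema` determining the component columns checked
#'   for missingness.
#' @param required Character vector of columns whose missingness triggers
#'   step 1; defaults to the OBS components plus the model covariates.
#' @param age_range Inclusive retained age range (default `c(20, 84)`).
#' @return List with `cohort` (filtered rows, original column set) and
#'   `attrition`, a data frame with columns `step`, `removed`, `remaining`.
#' @export
apply_exclusions <- function(cohort, schema = default_schema(),
                             required = NULL, age_range = c(20, 84)) {
  cols <- cohort_columns(schema)
  need <- unique(c(cols$design, cols$covariates, cols$flags, cols$components))
  absent <- setdiff(need, names(cohort))
  if (length(absent) > 0L) {
    stop("cohort lacks required column(s): ", paste(absent, collapse = ", "))
  }
  if (is.null(required)) required <- c(cols$components, cols$covariates)

  keep <- rep(TRUE, nrow(cohort))
  steps <- c("missing_data", "age_out_of_range", "pregnant",
             "recall_below_minimum", "implausible_energy")
  removed <- integer(length(steps))
  names(removed) <- steps

  violates <- list(
    missing_data = function(d) {
      Reduce(`|`, lapply(required, function(cl) is.na(d[[cl]])))
    },
    age_out_of_range = function(d) {
      d$age < age_range[1] | d$age > age_range[2]
    },
    pregnant = function(d) d$pregnant %in% TRUE,
    recall_below_minimum = function(d) d$recall_status == "below_minimum",
    implausible_energy = function(d) {
      eb <- energy_bounds()
      lo <- eb$lower[match(d$sex, eb$sex)]
      hi <- eb$upper[match(d$sex, eb$sex)]
      d$energy < lo | d$energy > hi
    }
  )

  for (s in steps) {
    idx <- which(keep)
    bad <- violates[[s]](cohort[idx, , drop = FALSE])
    bad[is.na(bad)] <- FALSE
    removed[s] <- sum(bad)
    keep[idx[bad]] <- FALSE
  }

  attrition <- data.frame(step = steps, removed = unname(removed),
                          remaining = nrow(cohort) - cumsum(unname(removed)))
  list(cohort = cohort[keep, , drop = FALSE], attrition = attrition)
}

#' Write an attrition log to TSV
#'
#' @param attrition Attrition data frame from [apply_exclusions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_attrition <- function(attrition, path) {
  utils::write.table(attrition, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
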