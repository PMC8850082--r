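#' Default oxidative balance score component schema
#'
#' The oxidative balance score (OBS) sums 0/1/2 points over twenty dietary
#' and lifestyle components: sixteen nutrients from 24-hour dietary recall
#' and four lifestyle factors (leisure-time physical activity, alcohol
#' consumption, body mass index, serum cotinine).  Fifteen components are
#' antioxidants (points rise with the sex-specific tertile) and five are
#' prooxidants (points fall with the tertile); alcohol alone is scored by a
#' fixed sex-specific rule rather than tertiles.
#'
#' @return A data frame of class `obs_schema` with one row per component and
#'   columns `component`, `group` (`"dietary"`/`"lifestyle"`), `polarity`
#'   (`"antioxidant"`/`"prooxidant"`), `rule` (`"sex_tertile"`/
#'   `"fixed_alcohol"`) and `units`.
#' @seealso [default_cutpoints()], [validate_schema()]
#' @export
#' @examples
#' s <- default_schema()
#' table(s$group, s$polarity)
default_schema <- function() {
  path <- system.file("extdata", "obs_components.tsv", package = "oxbal",
                      mustWork = TRUE)
  read_schema(path)
}

#' Read an OBS component schema from a TSV file
#'
#' @param path Path to a tab-separated file with columns `component`,
#'   `group`, `polarity`, `rule`, `units`.
#' @return An `obs_schema` data frame.
#' @export
read_schema <- function(path) {
  sch <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("component", "group", "polarity", "rule", "units")
  missing <- setdiff(required, names(sch))
  if (length(missing) > 0L) {
    stop("schema file lacks column(s): ", paste(missing, collapse = ", "))
  }
  structure(sch, class = c("obs_schema", "data.frame"))
}

#' Default sex-specific tertile cutpoints for the OBS components
#'
#' Returns the packaged reference cutpoints (lower boundary `t1`, upper
#' boundary `t2`, each in the component's units) for every tertile-scored
#' component and both sexes.  Tertile groups are formed as `< t1`,
#' `[t1, t2)` and `>= t2`; for prooxidant components the same ascending
#' boundaries are used and the point order is reversed.  Alcohol is scored
#' by [alcohol_rule()] and has no cutpoint entry.
#'
#' @return A data frame of class `cutpoint_set` with columns `component`,
#'   `sex`, `t1`, `t2` and attribute `provenance = "packaged_table1"`.
#' @seealso [compute_cutpoints()] to recompute cutpoints from a cohort.
#' @export
default_cutpoints <- function() {
  path <- system.file("extdata", "obs_cutpoints_table1.tsv", package = "oxbal",
                      mustWork = TRUE)
  read_cutpoints(path, provenance = "packaged_table1")
}

#' Read a cutpoint set from a TSV file
#'
#' @param path Path to a tab-separated file with columns `component`, `sex`,
#'   `t1`, `t2`.
#' @param provenance Provenance tag stored on the result, one of
#'   `"packaged_table1"` or `"computed_from_data"`.
#' @return A `cutpoint_set` data frame.
#' @export
read_cutpoints <- function(path, provenance = "computed_from_data") {
  cp <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(component = "character",
                                         sex = "character",
                                         t1 = "numeric", t2 = "numeric"))
  new_cutpoint_set(cp, provenance)
}

new_cutpoint_set <- function(cp, provenance) {
  required <- c("component", "sex", "t1", "t2")
  missing <- setdiff(required, names(cp))
  if (length(missing) > 0L) {
    stop("cutpoint table lacks column(s): ", paste(missing, collapse = ", "))
  }
  structure(as.data.frame(cp), provenance = provenance,
            class = c("cutpoint_set", "data.frame"))
}

#' Write a cutpoint set to TSV
#'
#' The written file round-trips through [read_cutpoints()] with every value
#' preserved exactly.
#'
#' @param cutpoints A `cutpoint_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cutpoints <- function(cutpoints, path) {
  utils::write.table(as.data.frame(cutpoints), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export schema and cutpoints as one tabular configuration
#'
#' Writes a TSV with columns `component`, `group`, `polarity`, `rule`,
#' `units`, `sex`, `t1`, `t2`; components without tertile cutpoints
#' (alcohol) appear once with empty `sex`/`t1`/`t2`.
#'
#' @param schema An `obs_schema`.
#' @param cutpoints A `cutpoint_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_obs_config <- function(schema, cutpoints, path) {
  merged <- merge(as.data.frame(schema), as.data.frame(cutpoints),
                  by = "component", all.x = TRUE, sort = FALSE)
  merged <- merged[order(match(merged$component, schema$component),
                         merged$sex), ]
  utils::write.table(merged, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Sex-specific fixed scoring rule for alcohol consumption
#'
#' Nondrinkers (exactly 0 g/d) receive 2 points, nonheavy drinkers 1 point
#' and heavy drinkers 0 points, with heavy drinking defined as at least
#' 30 g/d for males and 15 g/d for females.
#'
#' @return A list with components `heavy_threshold` (named numeric, g/d per
#'   sex) and `nondrinker_value` (0).
#' @export
alcohol_rule <- function() {
  list(heavy_threshold = c(male = 30, female = 15), nondrinker_value = 0)
}

#' Look up tertile cutpoints for one component and sex
#'
#' @param cutpoints A `cutpoint_set`.
#' @param component Component name.
#' @param sex `"male"` or `"female"`.
#' @return Named numeric vector `c(t1, t2)`.
#' @export
lookup_cutpoints <- function(cutpoints, component, sex) {
  if (identical(component, "alcohol")) {
    stop("alcohol is scored by a fixed rule and has no tertile cutpoints")
  }
  hit <- cutpoints$component == component & cutpoints$sex == sex
  if (sum(hit) != 1L) {
    stop("no unique cutpoint entry for component '", component,
         "', sex '", sex, "'")
  }
  c(t1 = cutpoints$t1[hit], t2 = cutpoints$t2[hit])
}

#' Validate an OBS schema and cutpoint set
#'
#' Checks the structural invariants of the default scoring scheme: unique
#' component names, exactly one fixed-rule alcohol component (prooxidant,
#' lifestyle), strictly ordered cutpoints, and full cutpoint coverage of
#' every tertile-scored component for both sexes.  Violations are reported,
#' not thrown.
#'
#' @param schema An `obs_schema`.
#' @param cutpoints A `cutpoint_set`, or `NULL` to skip cutpoint checks.
#' @return Character vector of violation messages; empty when valid.
#' @export
validate_schema <- function(schema, cutpoints = NULL) {
  v <- character(0)
  if (anyDuplicated(schema$component)) {
    dup <- unique(schema$component[duplicated(schema$component)])
    v <- c(v, paste0("duplicated component name(s): ",
                     paste(dup, collapse = ", ")))
  }
  bad_group <- setdiff(unique(schema$group), c("dietary", "lifestyle"))
  if (length(bad_group) > 0L) {
    v <- c(v, paste0("unknown group(s): ", paste(bad_group, collapse = ", ")))
  }
  bad_pol <- setdiff(unique(schema$polarity), c("antioxidant", "prooxidant"))
  if (length(bad_pol) > 0L) {
    v <- c(v, paste0("unknown polarity: ", paste(bad_pol, collapse = ", ")))
  }
  fixed <- schema[schema$rule == "fixed_alcohol", , drop = FALSE]
  if (nrow(fixed) != 1L || fixed$component != "alcohol") {
    v <- c(v, "exactly one component (alcohol) must have rule=fixed_alcohol")
  } else if (fixed$polarity != "prooxidant" || fixed$group != "lifestyle") {
    v <- c(v, "alcohol must be a prooxidant lifestyle component")
  }
  bad_rule <- setdiff(unique(schema$rule), c("sex_tertile", "fixed_alcohol"))
  if (length(bad_rule) > 0L) {
    v <- c(v, paste0("unknown rule(s): ", paste(bad_rule, collapse = ", ")))
  }
  if (!is.null(cutpoints)) {
    bad <- !(cutpoints$t1 < cutpoints$t2)
    if (any(bad)) {
      v <- c(v, paste0("cutpoints not strictly ordered (t1 < t2) for: ",
                       paste(unique(paste(cutpoints$component[bad],
                                          cutpoints$sex[bad])),
                             collapse = "; ")))
    }
    tert <- schema$component[schema$rule == "sex_tertile"]
    need <- expand.grid(component = tert, sex = c("male", "female"),
                        stringsAsFactors = FALSE)
    have <- paste(cutpoints$component, cutpoints$sex)
    miss <- need[!(paste(need$component, need$sex) %in% have), , drop = FALSE]
    if (nrow(miss) > 0L) {
      v <- c(v, paste0("missing cutpoints for: ",
                       paste(paste(miss$component, miss$sex),
                             collapse = "; ")))
    }
    extra_dup <- have[duplicated(have)]
    if (length(extra_dup) > 0L) {
      v <- c(v, paste0("duplicated cutpoint entries for: ",
                       paste(unique(extra_dup), collapse = "; ")))
    }
  }
  v
}

#' @export
print.obs_schema <- function(x, ...) {
  cat("OBS component schema: ", nrow(x), " components (",
      sum(x$group == "dietary"), " dietary, ",
      sum(x$group == "lifestyle"), " lifestyle; ",
      sum(x$polarity == "antioxidant"), " antioxidant, ",
      sum(x$polarity == "prooxidant"), " prooxidant)\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' @export
print.cutpoint_set <- function(x, ...) {
  cat("OBS tertile cutpoints (", nrow(x), " entries, provenance: ",
      attr(x, "provenance"), ")\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}
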