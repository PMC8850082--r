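#' Sex-specific tertile cutpoints from observed values
#'
#' Computes the 33 1/3 and 66 2/3 percentiles of `values` with
#' [weighted_quantile()] (unweighted by default).  With weights, the
#' boundary is the smallest observed value whose cumulative normalized
#' weight reaches the target probability.
#'
#' @param values Numeric component values for one sex.
#' @param weights Optional survey weights.
#' @return Named numeric vector `c(t1, t2)`.
#' @export
compute_tertiles <- function(values, weights = NULL) {
  values <- values[!is.na(values)]
  if (length(unique(values)) < 3L) {
    stop("degenerate distribution: need at least 3 distinct values")
  }
  q <- weighted_quantile(values, c(1 / 3, 2 / 3), weights)
  t <- c(t1 = unname(q[1L]), t2 = unname(q[2L]))
  if (!(t[1L] < t[2L])) {
    stop("degenerate distribution: tertile boundaries coincide")
  }
  t
}

#' Recompute a full cutpoint set from a cohort
#'
#' Builds sex-specific tertile cutpoints for every tertile-scored schema
#' component from the cohort's observed values, e.g. for a synthetic cohort
#' or a reanalysis sample.
#'
#' @param cohort Cohort data frame with `sex` and one column per component.
#' @param schema An `obs_schema`.
#' @param weights Optional survey weights (length `nrow(cohort)`).
#' @return A `cutpoint_set` with provenance `"computed_from_data"`.
#' @export
compute_cutpoints <- function(cohort, schema = default_schema(),
                              weights = NULL) {
  comps <- schema$component[schema$rule == "sex_tertile"]
  rows <- list()
  for (comp in comps) {
    for (sx in c("male", "female")) {
      sel <- cohort$sex == sx & !is.na(cohort[[comp]])
      t <- compute_tertiles(cohort[[comp]][sel],
                            if (is.null(weights)) NULL else weights[sel])
      rows[[length(rows) + 1L]] <- data.frame(component = comp, sex = sx,
                                              t1 = t[1L], t2 = t[2L])
    }
  }
  new_cutpoint_set(do.call(rbind, rows), "computed_from_data")
}

tertile_group <- function(value, t1, t2) {
  # groups: 0 = [< t1], 1 = [t1, t2), 2 = [>= t2]
  ifelse(value >= t2, 2L, ifelse(value >= t1, 1L, 0L))
}

#' Assign OBS points for one component
#'
#' Tertile-scored components: the value is placed in `< t1`, `[t1, t2)` or
#' `>= t2`; antioxidants score 0/1/2 from the lowest to the highest group
#' and prooxidants score 2/1/0.  Alcohol uses the fixed sex-specific rule:
#' nondrinkers (0 g/d) 2 points, nonheavy drinkers 1, heavy drinkers
#' (>= 30 g/d male, >= 15 g/d female) 0.
#'
#' @param value Component value(s) in the component's units.
#' @param sex `"male"`/`"female"`, recycled to `length(value)`.
#' @param component Component name (single string).
#' @param schema An `obs_schema`.
#' @param cutpoints A `cutpoint_set` covering the component (ignored for
#'   alcohol).
#' @return Integer points in `{0, 1, 2}`, `NA` where `value` is `NA`.
#' @export
#' @examples
#' assign_component_points(45, "male", "alcohol")
#' assign_component_points(120, "female", "vitamin_c")
assign_component_points <- function(value, sex, component,
                                    schema = default_schema(),
                                    cutpoints = default_cutpoints()) {
  row <- schema[schema$component == component, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown component: ", component)
  sex <- rep_len(sex, length(value))
  if (!all(sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'")
  }
  pts <- rep(NA_integer_, length(value))
  ok <- !is.na(value)
  if (row$rule == "fixed_alcohol") {
    thr <- alcohol_rule()$heavy_threshold[sex]
    pts[ok] <- ifelse(value[ok] == 0, 2L,
                      ifelse(value[ok] >= thr[ok], 0L, 1L))
    return(pts)
  }
  for (sx in unique(sex[ok])) {
    t <- lookup_cutpoints(cutpoints, component, sx)
    sel <- ok & sex == sx
    grp <- tertile_group(value[sel], t["t1"], t["t2"])
    pts[sel] <- if (row$polarity == "antioxidant") grp else 2L - grp
  }
  pts
}

#' Compute per-participant oxidative balance scores
#'
#' Assigns points for every schema component and sums them into the total
#' OBS, the dietary OBS (16 nutrient components) and the lifestyle OBS
#' (physical activity, alcohol, BMI, cotinine).  Under the default schema
#' the total lies in `[0, 40]` = dietary `[0, 32]` + lifestyle `[0, 8]`.
#'
#' @param cohort Cohort data frame with `id`, `sex` and one column per
#'   component; rows should already have passed [apply_exclusions()].
#' @param schema An `obs_schema`.
#' @param cutpoints A `cutpoint_set`; `NULL` recomputes cutpoints from the
#'   cohort with [compute_cutpoints()].
#' @return Data frame with `id`, `sex`, one `points_<component>` column per
#'   component, and `obs_dietary`, `obs_lifestyle`, `obs_total`.
#' @export
compute_obs <- function(cohort, schema = default_schema(),
                        cutpoints = default_cutpoints()) {
  if (is.null(cutpoints)) cutpoints <- compute_cutpoints(cohort, schema)
  res <- data.frame(id = cohort$id, sex = cohort$sex)
  for (comp in schema$component) {
    res[[paste0("points_", comp)]] <-
      assign_component_points(cohort[[comp]], cohort$sex, comp,
                              schema, cutpoints)
  }
  pts <- function(comps) {
    m <- as.matrix(res[paste0("points_", comps)])
    as.integer(rowSums(m))
  }
  res$obs_dietary <- pts(schema$component[schema$group == "dietary"])
  res$obs_lifestyle <- pts(schema$component[schema$group == "lifestyle"])
  res$obs_total <- res$obs_dietary + res$obs_lifestyle
  res
}

#' Sex-specific quartile labels for a score
#'
#' Cuts the score at its sex-specific 25/50/75 percentiles (same quantile
#' definition as [compute_tertiles()]) into ordered labels Q1 (lowest) to
#' Q4; a value equal to a cut belongs to the upper group.
#'
#' @param score Numeric score values.
#' @param sex `"male"`/`"female"` per value.
#' @param weights Optional survey weights.
#' @return Ordered factor with levels Q1 < Q2 < Q3 < Q4.
#' @export
assign_quartiles <- function(score, sex, weights = NULL) {
  lab <- rep(NA_character_, length(score))
  for (sx in unique(sex)) {
    sel <- sex == sx & !is.na(score)
    v <- score[sel]
    if (length(unique(v)) < 4L) {
      stop("degenerate distribution: need at least 4 distinct score values",
           " for sex '", sx, "'")
    }
    q <- weighted_quantile(v, c(0.25, 0.5, 0.75),
                           if (is.null(weights)) NULL else weights[sel])
    grp <- 1L + (v >= q[1L]) + (v >= q[2L]) + (v >= q[3L])
    lab[sel] <- paste0("Q", grp)
  }
  factor(lab, levels = paste0("Q", 1:4), ordered = TRUE)
}

#' Write per-participant OBS results to TSV
#'
#' @param obs Result of [compute_obs()] (optionally with a quartile column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obs <- function(obs, path) {
  utils::write.table(obs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
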