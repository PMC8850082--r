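#' Covariate sets of the four adjustment models
#'
#' Model 1 is crude; Model 2 adjusts for age, ethnicity, education and the
#' poverty income ratio; Model 3 adds dietary energy intake; Model 4 adds
#' C-reactive protein.  The sets are strictly nested.
#'
#' @param model Integer 1–4.
#' @return Character vector of covariate names (empty for Model 1).
#' @export
model_covariates <- function(model) {
  base <- c("age", "ethnicity", "education", "pir")
  switch(as.character(model),
         "1" = character(0),
         "2" = base,
         "3" = c(base, "energy"),
         "4" = c(base, "energy", "crp"),
         stop("model must be 1, 2, 3 or 4"))
}

canonical_levels <- list(
  ethnicity = c("non_hispanic_white", "non_hispanic_black",
                "mexican_american", "other_hispanic", "other_race"),
  education = c("less_than_9th", "9_11th", "high_school", "some_college",
                "college_graduate"),
  pir = c("<=1.3", "1.3-3.5", ">3.5")
)

ensure_factors <- function(cohort) {
  for (cl in names(canonical_levels)) {
    if (!is.factor(cohort[[cl]])) {
      lev <- canonical_levels[[cl]]
      vals <- unique(as.character(cohort[[cl]]))
      if (all(vals %in% lev)) {
        cohort[[cl]] <- factor(cohort[[cl]], levels = lev)
      } else {
        cohort[[cl]] <- factor(cohort[[cl]])
      }
    } else {
      cohort[[cl]] <- droplevels(cohort[[cl]])
    }
  }
  cohort
}

covariate_matrix <- function(cohort, covariates) {
  if (length(covariates) == 0L) return(NULL)
  f <- stats::reformulate(covariates)
  d <- cohort[, covariates, drop = FALSE]
  d <- droplevels(d)  # a level absent from this stratum would give a zero column
  mm <- stats::model.matrix(f, data = d)
  mm[, -1, drop = FALSE]
}

fit_exposure_model <- function(y, exposure, cohort, design, model, ...) {
  X <- cbind(`(Intercept)` = 1, exposure)
  cov <- covariate_matrix(cohort, model_covariates(model))
  if (!is.null(cov)) X <- cbind(X, cov)
  survey_lm(y, X, design, ...)
}

extract_terms <- function(fit, terms, sex, model, exposure) {
  co <- fit$coefficients
  out <- co[co$term %in% terms, , drop = FALSE]
  cbind(data.frame(sex = sex, model = model, exposure = exposure),
        out, row.names = NULL)
}

#' Primary OBS–telomere association analysis
#'
#' For each sex separately, fits the four adjustment models with the total
#' OBS entered (a) as a continuous exposure, (b) as sex-specific quartiles
#' (Q1 reference, Q2–Q4 indicator terms) and (c) as an ordinal trend term,
#' against natural-log T/S ratio, using survey-weighted regression with
#' Taylor-linearization variance.
#'
#' @param cohort Filtered cohort data frame (see [apply_exclusions()]).
#' @param schema An `obs_schema`.
#' @param cutpoints A `cutpoint_set`, or `NULL` to recompute sex-specific
#'   tertiles from this cohort (the usual choice for a new sample).
#' @param models Integer vector of models to fit (default `1:4`).
#' @param trend_coding `"index"` or `"median"`, see [trend_test()].
#' @param ... Passed to [survey_lm()] (e.g. `lonely_psu`).
#' @return List with `results` (tidy data frame: `sex`, `model`, `exposure`
#'   in `{continuous, quartile, trend}`, `term`, `beta`, `se`, `ci_low`,
#'   `ci_high`, `statistic`, `p_value`, `df`), `obs` (per-participant
#'   scores with quartile labels) and `cutpoints`.
#' @export
run_primary_analysis <- function(cohort, schema = default_schema(),
                                 cutpoints = NULL, models = 1:4,
                                 trend_coding = "index", ...) {
  cohort <- ensure_factors(cohort)
  if (!all(c("male", "female") %in% cohort$sex)) {
    stop("both sexes must be present in the filtered cohort")
  }
  if (is.null(cutpoints)) cutpoints <- compute_cutpoints(cohort, schema)
  obs <- compute_obs(cohort, schema, cutpoints)
  obs$quartile <- assign_quartiles(obs$obs_total, obs$sex)

  rows <- list()
  for (sx in c("male", "female")) {
    sel <- cohort$sex == sx
    d <- cohort[sel, , drop = FALSE]
    o <- obs[sel, , drop = FALSE]
    design <- survey_design(d$stratum, d$psu, d$weight)
    y <- log(d$ltl)
    for (m in models) {
      fit_c <- fit_exposure_model(y, cbind(obs = o$obs_total), d, design,
                                  m, ...)
      rows[[length(rows) + 1L]] <-
        extract_terms(fit_c, "obs", sx, m, "continuous")
      qd <- cbind(Q2 = as.integer(o$quartile == "Q2"),
                  Q3 = as.integer(o$quartile == "Q3"),
                  Q4 = as.integer(o$quartile == "Q4"))
      fit_q <- fit_exposure_model(y, qd, d, design, m, ...)
      rows[[length(rows) + 1L]] <-
        extract_terms(fit_q, c("Q2", "Q3", "Q4"), sx, m, "quartile")
      fit_t <- trend_test(y, o$quartile,
                          covariate_matrix(d, model_covariates(m)), design,
                          coding = trend_coding, score = o$obs_total, ...)
      rows[[length(rows) + 1L]] <-
        extract_terms(fit_t, "trend", sx, m, "trend")
    }
  }
  list(results = do.call(rbind, rows), obs = obs, cutpoints = cutpoints)
}

#' Dietary and lifestyle sub-score analysis
#'
#' Fits the four adjustment models per sex with the dietary OBS (16
#' nutrient components) and the lifestyle OBS (physical activity, alcohol,
#' BMI, cotinine) as continuous exposures.
#'
#' @inheritParams run_primary_analysis
#' @return List with `results` (tidy data frame as in
#'   [run_primary_analysis()], `exposure` in `{dietary, lifestyle}`) and
#'   `obs`.
#' @export
run_subscore_analysis <- function(cohort, schema = default_schema(),
                                  cutpoints = NULL, models = 1:4, ...) {
  cohort <- ensure_factors(cohort)
  if (is.null(cutpoints)) cutpoints <- compute_cutpoints(cohort, schema)
  obs <- compute_obs(cohort, schema, cutpoints)
  rows <- list()
  for (sx in c("male", "female")) {
    sel <- cohort$sex == sx
    d <- cohort[sel, , drop = FALSE]
    o <- obs[sel, , drop = FALSE]
    design <- survey_design(d$stratum, d$psu, d$weight)
    y <- log(d$ltl)
    for (m in models) {
      for (sub in c("dietary", "lifestyle")) {
        ex <- cbind(obs = o[[paste0("obs_", sub)]])
        fit <- fit_exposure_model(y, ex, d, design, m, ...)
        rows[[length(rows) + 1L]] <- extract_terms(fit, "obs", sx, m, sub)
      }
    }
  }
  list(results = do.call(rbind, rows), obs = obs)
}

#' Leave-one-component-out sensitivity analysis
#'
#' For each schema component in turn, recomputes the total OBS without that
#' component (a 19-component score, range 0–38 under the default schema)
#' and refits the fully adjusted continuous-score model per sex.
#'
#' @inheritParams run_primary_analysis
#' @param model Adjustment model used for the refits (default 4).
#' @return Data frame with one row per component and sex: `component`,
#'   `sex`, `beta`, `se`, `ci_low`, `ci_high`, `statistic`, `p_value`,
#'   `df`.
#' @export
run_sensitivity <- function(cohort, schema = default_schema(),
                            cutpoints = NULL, model = 4, ...) {
  cohort <- ensure_factors(cohort)
  if (is.null(cutpoints)) cutpoints <- compute_cutpoints(cohort, schema)
  obs <- compute_obs(cohort, schema, cutpoints)
  rows <- list()
  for (comp in schema$component) {
    reduced <- obs$obs_total - obs[[paste0("points_", comp)]]
    for (sx in c("male", "female")) {
      sel <- cohort$sex == sx
      d <- cohort[sel, , drop = FALSE]
      design <- survey_design(d$stratum, d$psu, d$weight)
      fit <- fit_exposure_model(log(d$ltl), cbind(obs = reduced[sel]),
                                d, design, model, ...)
      co <- fit$coefficients
      co <- co[co$term == "obs", , drop = FALSE]
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(component = comp, sex = sx),
              co[, setdiff(names(co), "term"), drop = FALSE],
              row.names = NULL)
    }
  }
  do.call(rbind, rows)
}

#' Format a beta estimate with its confidence interval
#'
#' @param beta,ci_low,ci_high Numeric vectors.
#' @param digits Decimal places (default 4).
#' @return Character vector like `"0.0701 (0.0205–0.1197)"`.
#' @export
format_beta_ci <- function(beta, ci_low, ci_high, digits = 4) {
  fmt <- paste0("%.", digits, "f")
  sprintf(paste0(fmt, " (", fmt, "–", fmt, ")"), beta, ci_low, ci_high)
}

baseline_cell_stats <- function(d, design) {
  fmt_ms <- function(s, digits) sprintf(paste0("%.", digits, "f ± %.",
                                               digits, "f"),
                                        s["mean"], s["sd"])
  fmt_mq <- function(s, digits) sprintf(paste0("%.", digits, "f (%.", digits,
                                               "f, %.", digits, "f)"),
                                        s["median"], s["p25"], s["p75"])
  rows <- list()
  add <- function(characteristic, value) {
    rows[[length(rows) + 1L]] <<- data.frame(characteristic = characteristic,
                                             value = value)
  }
  if (nrow(d) == 0L) {
    add("n", "0")
    return(do.call(rbind, rows))
  }
  add("n", as.character(nrow(d)))
  add("age_years", fmt_ms(weighted_descriptives(d$age, design, "mean_sd"), 1))
  for (cl in c("ethnicity", "education", "pir")) {
    tab <- weighted_descriptives(d[[cl]], design, "category_pct")
    for (k in seq_len(nrow(tab))) {
      add(paste0(cl, ":", tab$level[k]),
          sprintf("%d (%.2f)", tab$n[k], tab$pct[k]))
    }
  }
  add("energy_kcal",
      fmt_ms(weighted_descriptives(d$energy, design, "mean_sd"), 0))
  add("crp_mg_dl",
      fmt_mq(weighted_descriptives(d$crp, design, "median_iqr"), 2))
  add("telomere_ts",
      fmt_mq(weighted_descriptives(d$ltl, design, "median_iqr"), 2))
  add("log_telomere_ts",
      fmt_ms(weighted_descriptives(log(d$ltl), design, "mean_sd"), 2))
  do.call(rbind, rows)
}

#' Baseline-characteristics table by OBS quartile for one sex
#'
#' Weighted descriptive statistics (no inferential p-values) in the layout
#' of a survey baseline table: one column for the whole sex stratum and one
#' per OBS quartile.  Continuous variables show weighted mean ± SD or
#' weighted median (P25, P75); categorical variables show unweighted counts
#' with weighted percentages.  An empty quartile renders with an explicit
#' zero count.
#'
#' @param cohort Filtered cohort rows for one sex.
#' @param quartile Quartile labels aligned with `cohort` rows.
#' @return Data frame with columns `characteristic`, `total`, `Q1`–`Q4`.
#' @export
baseline_table <- function(cohort, quartile) {
  cohort <- ensure_factors(cohort)
  make_col <- function(sel) {
    d <- cohort[sel, , drop = FALSE]
    if (nrow(d) == 0L) {
      return(data.frame(characteristic = "n", value = "0"))
    }
    baseline_cell_stats(d, survey_design(d$stratum, d$psu, d$weight))
  }
  cols <- c(list(total = make_col(rep(TRUE, nrow(cohort)))),
            stats::setNames(lapply(paste0("Q", 1:4),
                                   function(q) make_col(quartile == q)),
                            paste0("Q", 1:4)))
  out <- cols$total
  names(out)[2] <- "total"
  for (q in paste0("Q", 1:4)) {
    qc <- cols[[q]]
    out[[q]] <- qc$value[match(out$characteristic, qc$characteristic)]
    out[[q]][is.na(out[[q]])] <- "0"
  }
  out
}

#' Assemble the report bundle
#'
#' Builds the study's output tables from fitted results: per-sex baseline
#' characteristics by OBS quartile, the quartile/trend/continuous
#' association table, the sub-score association table, the sensitivity
#' table and the attrition log.  Betas and confidence bounds are formatted
#' to 4 decimal places.
#'
#' @param cohort Filtered cohort.
#' @param primary Result of [run_primary_analysis()].
#' @param subscore Optional result of [run_subscore_analysis()].
#' @param sensitivity Optional result of [run_sensitivity()].
#' @param attrition Optional attrition log from [apply_exclusions()].
#' @return Named list of data frames: `baseline_male`, `baseline_female`,
#'   `associations`, and when supplied `subscores`, `sensitivity`,
#'   `attrition`.
#' @export
make_reports <- function(cohort, primary, subscore = NULL,
                         sensitivity = NULL, attrition = NULL) {
  cohort <- ensure_factors(cohort)
  obs <- primary$obs
  bundle <- list()
  for (sx in c("male", "female")) {
    sel <- cohort$sex == sx
    bundle[[paste0("baseline_", sx)]] <-
      baseline_table(cohort[sel, , drop = FALSE], obs$quartile[sel])
  }

  res <- primary$results
  assoc <- list()
  for (sx in c("male", "female")) {
    for (m in sort(unique(res$model))) {
      pick <- function(expo, term) {
        r <- res[res$sex == sx & res$model == m & res$exposure == expo &
                   res$term == term, , drop = FALSE]
        r
      }
      q <- lapply(c("Q2", "Q3", "Q4"), function(tt) pick("quartile", tt))
      tr <- pick("trend", "trend")
      cc <- pick("continuous", "obs")
      assoc[[length(assoc) + 1L]] <- data.frame(
        sex = sx, model = m, Q1 = "Ref",
        Q2 = format_beta_ci(q[[1]]$beta, q[[1]]$ci_low, q[[1]]$ci_high),
        Q3 = format_beta_ci(q[[2]]$beta, q[[2]]$ci_low, q[[2]]$ci_high),
        Q4 = format_beta_ci(q[[3]]$beta, q[[3]]$ci_low, q[[3]]$ci_high),
        p_trend = sprintf("%.2f", tr$p_value),
        continuous = format_beta_ci(cc$beta, cc$ci_low, cc$ci_high))
    }
  }
  bundle$associations <- do.call(rbind, assoc)

  if (!is.null(subscore)) {
    sres <- subscore$results
    sub <- list()
    for (expo in c("dietary", "lifestyle")) {
      for (m in sort(unique(sres$model))) {
        cell <- function(sx) {
          r <- sres[sres$sex == sx & sres$model == m &
                      sres$exposure == expo, , drop = FALSE]
          format_beta_ci(r$beta, r$ci_low, r$ci_high)
        }
        sub[[length(sub) + 1L]] <- data.frame(score = expo, model = m,
                                              male = cell("male"),
                                              female = cell("female"))
      }
    }
    bundle$subscores <- do.call(rbind, sub)
  }
  if (!is.null(sensitivity)) {
    sens <- sensitivity
    sens$beta_ci <- format_beta_ci(sens$beta, sens$ci_low, sens$ci_high)
    bundle$sensitivity <- sens
  }
  if (!is.null(attrition)) bundle$attrition <- attrition
  bundle
}

#' Write a report bundle as TSV files
#'
#' @param bundle List of data frames from [make_reports()].
#' @param dir Output directory (created if absent).
#' @return Character vector of written paths, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(bundle)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(bundle[[nm]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
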