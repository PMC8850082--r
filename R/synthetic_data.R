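#' Configuration for the synthetic survey-cohort generator
#'
#' Describes an NHANES-like stratified two-PSU-per-stratum cohort: sample
#' size and design geometry, sex-specific intake distributions tied to the
#' packaged component cutpoints, zero-inflated alcohol and cotinine, an
#' outcome model with a planted linear effect of the true OBS on the
#' natural-log telomere T/S ratio, and optional planted exclusion
#' violations.
#'
#' Tertile-scored intakes are log-normal per sex with parameters chosen so
#' the packaged cutpoints are the population tertiles
#' (`meanlog = (log t1 + log t2)/2`,
#' `sdlog = (log t2 - log t1)/(2 qnorm(2/3))`); nutrient intakes share a
#' latent log-energy factor with correlation `energy_corr`.  The outcome is
#' `log(T/S) = alpha_sex + beta_sex (OBS - 20) + gamma' (centred
#' covariates) + PSU effect + N(0, sigma)`.
#'
#' @param n Number of participants.
#' @param n_strata Number of design strata.
#' @param psus_per_stratum PSUs per stratum (default 2).
#' @param sex_ratio Proportion male.
#' @param beta Named numeric: planted effect per OBS point on log T/S for
#'   `male` and `female`.
#' @param alpha Named numeric intercepts of log T/S per sex.
#' @param gamma Named list of covariate coefficients (`age`, `energy`,
#'   `crp`) applied to centred covariates.
#' @param sigma Residual SD of log T/S (default 0.24).
#' @param psu_sd SD of a shared PSU-level intercept (default 0.02).
#' @param energy_corr Correlation of log nutrient intakes with log energy.
#' @param zero_prob Named numeric: point mass at zero for
#'   `alcohol_male`, `alcohol_female`, `cotinine`.
#' @param smoker_prob Probability of the high-cotinine mixture component.
#' @param violation_rates Named numeric rates in `[0, 1]` for planted
#'   exclusion violations: `missing`, `age`, `pregnant`, `recall`,
#'   `energy`; counts are `round(n * rate)` on disjoint rows.
#' @param seed Integer seed; the generator is reproducible given the seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n = 1600, n_strata = 14, psus_per_stratum = 2,
                       sex_ratio = 0.5,
                       beta = c(male = 0, female = 0.004),
                       alpha = c(male = 0.03, female = 0.05),
                       gamma = list(age = -0.002, energy = 2e-5, crp = -0.02),
                       sigma = 0.24, psu_sd = 0.02, energy_corr = 0.5,
                       zero_prob = c(alcohol_male = 0.35,
                                     alcohol_female = 0.55,
                                     cotinine = 0.05),
                       smoker_prob = 0.25,
                       violation_rates = c(missing = 0, age = 0, pregnant = 0,
                                           recall = 0, energy = 0),
                       seed = 1L) {
  cfg <- list(n = n, n_strata = n_strata,
              psus_per_stratum = psus_per_stratum, sex_ratio = sex_ratio,
              beta = beta, alpha = alpha, gamma = gamma, sigma = sigma,
              psu_sd = psu_sd, energy_corr = energy_corr,
              zero_prob = zero_prob, smoker_prob = smoker_prob,
              violation_rates = violation_rates, seed = as.integer(seed))
  if (!is.numeric(n) || n < 8 * n_strata) {
    stop("n must be at least 8 * n_strata")
  }
  if (sigma <= 0) stop("sigma must be positive")
  if (any(violation_rates < 0 | violation_rates > 1)) {
    stop("violation_rates must lie in [0, 1]")
  }
  if (!all(c("missing", "age", "pregnant", "recall", "energy") %in%
           names(violation_rates))) {
    stop("violation_rates must be named: missing, age, pregnant, recall,",
         " energy")
  }
  if (any(zero_prob < 0 | zero_prob > 1)) {
    stop("zero_prob entries must lie in [0, 1]")
  }
  if (sex_ratio <= 0 || sex_ratio >= 1) stop("sex_ratio must be in (0, 1)")
  if (!all(c("male", "female") %in% names(beta)) ||
      !all(c("male", "female") %in% names(alpha))) {
    stop("beta and alpha must be named for male and female")
  }
  structure(cfg, class = "sim_config")
}

lognormal_params_from_cutpoints <- function(t1, t2) {
  t1 <- unname(t1); t2 <- unname(t2)
  z <- stats::qnorm(2 / 3)
  c(meanlog = (log(t1) + log(t2)) / 2, sdlog = (log(t2) - log(t1)) / (2 * z))
}

moment_match_lognormal <- function(mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Generate a synthetic NHANES-like cohort with known ground truth
#'
#' Draws a stratified two-PSU-per-stratum cohort under `config`, computes
#' each participant's true OBS by scoring the generated intakes against
#' cutpoints recomputed from the generated sample, builds the log T/S
#' outcome with the planted sex-specific effect, and finally plants the
#' requested exclusion violations on disjoint rows.
#'
#' Survey weights are inverse inclusion probabilities that vary by stratum
#' and age band, so weighted and unweighted estimands genuinely differ.
#'
#' @param config A [sim_config()].
#' @return List with `cohort` (a cohort data frame accepted by
#'   [apply_exclusions()]) and `truth`: planted `beta`, `alpha`, `gamma`,
#'   `sigma`, the per-participant true OBS (`obs_true`), the cutpoints used,
#'   and `planted`, a list of row ids per violation type.
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n
  schema <- default_schema()
  ref_cp <- default_cutpoints()

  sex <- ifelse(stats::runif(n) < config$sex_ratio, "male", "female")
  age <- sample(20:84, n, replace = TRUE)
  stratum <- sample(seq_len(config$n_strata), n, replace = TRUE)
  psu <- sample(seq_len(config$psus_per_stratum), n, replace = TRUE)

  # inverse-probability weights varying by stratum and age band
  stratum_factor <- seq(0.6, 1.4, length.out = config$n_strata)
  age_factor <- ifelse(age < 40, 1.25, ifelse(age < 60, 1.0, 0.75))
  weight <- 1 / (stratum_factor[stratum] * age_factor)

  en_par <- list(male = moment_match_lognormal(2477, 781),
                 female = moment_match_lognormal(1818, 622))
  energy <- numeric(n)
  z_energy <- stats::rnorm(n)
  eb <- energy_bounds()
  for (sx in c("male", "female")) {
    p <- en_par[[sx]]
    sel <- which(sex == sx)
    energy[sel] <- exp(p["meanlog"] + p["sdlog"] * z_energy[sel])
    # truncate to the plausible envelope by redrawing the latent factor, so
    # only planted rows can violate the energy criterion
    lo <- eb$lower[eb$sex == sx] + 1; hi <- eb$upper[eb$sex == sx] - 1
    bad <- sel[energy[sel] < lo | energy[sel] > hi]
    while (length(bad) > 0L) {
      z_energy[bad] <- stats::rnorm(length(bad))
      energy[bad] <- exp(p["meanlog"] + p["sdlog"] * z_energy[bad])
      bad <- bad[energy[bad] < lo | energy[bad] > hi]
    }
  }

  cohort <- data.frame(id = seq_len(n), sex = sex, age = age,
                       stratum = stratum, psu = psu, weight = weight,
                       energy = energy)

  rho <- config$energy_corr
  tert_comps <- setdiff(schema$component[schema$rule == "sex_tertile"],
                        "cotinine")
  diet_comps <- schema$component[schema$group == "dietary"]
  for (comp in tert_comps) {
    r <- if (comp %in% diet_comps) rho else 0
    z <- r * z_energy + sqrt(1 - r^2) * stats::rnorm(n)
    v <- numeric(n)
    for (sx in c("male", "female")) {
      t <- lookup_cutpoints(ref_cp, comp, sx)
      p <- lognormal_params_from_cutpoints(t["t1"], t["t2"])
      sel <- sex == sx
      v[sel] <- exp(p["meanlog"] + p["sdlog"] * z[sel])
    }
    cohort[[comp]] <- v
  }

  # zero-inflated alcohol; cotinine as nonsmoker/smoker mixture with a
  # below-detection point mass
  p0_alc <- ifelse(sex == "male", config$zero_prob["alcohol_male"],
                   config$zero_prob["alcohol_female"])
  alc_pos <- exp(stats::rnorm(n, ifelse(sex == "male", log(10), log(6)), 1))
  cohort$alcohol <- ifelse(stats::runif(n) < p0_alc, 0, alc_pos)
  smoker <- stats::runif(n) < config$smoker_prob
  cot <- exp(stats::rnorm(n, ifelse(smoker, log(80), log(0.05)),
                          ifelse(smoker, 1, 1.2)))
  cohort$cotinine <- ifelse(stats::runif(n) < config$zero_prob["cotinine"],
                            0, cot)

  eth_lev <- c("non_hispanic_white", "non_hispanic_black",
               "mexican_american", "other_hispanic", "other_race")
  cohort$ethnicity <- factor(sample(eth_lev, n, replace = TRUE,
                                    prob = c(0.60, 0.13, 0.20, 0.045, 0.025)),
                             levels = eth_lev)
  edu_lev <- c("less_than_9th", "9_11th", "high_school", "some_college",
               "college_graduate")
  cohort$education <- factor(sample(edu_lev, n, replace = TRUE,
                                    prob = c(0.08, 0.14, 0.23, 0.27, 0.28)),
                             levels = edu_lev)
  pir_lev <- c("<=1.3", "1.3-3.5", ">3.5")
  cohort$pir <- factor(sample(pir_lev, n, replace = TRUE,
                              prob = c(0.18, 0.35, 0.47)), levels = pir_lev)
  crp_med <- ifelse(sex == "male", 0.14, 0.22)
  cohort$crp <- exp(stats::rnorm(n, log(crp_med), 1.2))
  cohort$pregnant <- FALSE
  cohort$recall_status <- "ok"

  # true OBS: generated intakes scored against cutpoints recomputed from
  # this generated sample
  cp <- compute_cutpoints(cohort, schema)
  obs <- compute_obs(cohort, schema, cp)

  psu_key <- paste(stratum, psu, sep = "::")
  psu_eff <- stats::rnorm(length(unique(psu_key)), 0, config$psu_sd)
  names(psu_eff) <- unique(psu_key)
  g <- config$gamma
  ln_ltl <- config$alpha[sex] +
    config$beta[sex] * (obs$obs_total - 20) +
    g$age * (age - 45) + g$energy * (energy - 2100) +
    g$crp * (cohort$crp - 0.3) +
    psu_eff[psu_key] +
    stats::rnorm(n, 0, config$sigma)
  cohort$ltl <- exp(as.numeric(ln_ltl))

  # planted exclusion violations on disjoint rows
  counts <- round(n * config$violation_rates)
  planted <- list(missing = integer(0), age = integer(0),
                  pregnant = integer(0), recall = integer(0),
                  energy = integer(0))
  pool <- seq_len(n)
  take <- function(k, from = pool) {
    k <- min(k, length(from))
    ids <- if (k > 0) from[sample.int(length(from), k)] else integer(0)
    pool <<- setdiff(pool, ids)
    ids
  }
  if (counts["missing"] > 0) {
    ids <- take(counts["missing"])
    comp_pick <- sample(schema$component, length(ids), replace = TRUE)
    for (k in seq_along(ids)) cohort[ids[k], comp_pick[k]] <- NA
    planted$missing <- ids
  }
  if (counts["age"] > 0) {
    ids <- take(counts["age"])
    cohort$age[ids] <- sample(85:95, length(ids), replace = TRUE)
    planted$age <- ids
  }
  if (counts["pregnant"] > 0) {
    ids <- take(counts["pregnant"], intersect(pool, which(sex == "female")))
    cohort$pregnant[ids] <- TRUE
    planted$pregnant <- ids
  }
  if (counts["recall"] > 0) {
    ids <- take(counts["recall"])
    cohort$recall_status[ids] <- "below_minimum"
    planted$recall <- ids
  }
  if (counts["energy"] > 0) {
    ids <- take(counts["energy"])
    eb <- energy_bounds()
    hi <- eb$upper[match(cohort$sex[ids], eb$sex)]
    cohort$energy[ids] <- hi * stats::runif(length(ids), 1.2, 1.6)
    planted$energy <- ids
  }

  truth <- list(beta = config$beta, alpha = config$alpha,
                gamma = config$gamma, sigma = config$sigma,
                obs_true = obs, cutpoints = cp, planted = planted,
                config = config)
  list(cohort = cohort, truth = truth)
}

#' Generate telomere replicate sets with planted outliers
#'
#' Each sample receives `n_per_sample` T/S values (duplicate wells over
#' three runs) as multiplicative log-normal noise around a sample-level
#' T/S; a known fraction of samples get one replicate multiplied by
#' `outlier_factor`, so an outlier is detectable by the replicate QC
#' whenever `|log(outlier_factor)|` exceeds the QC threshold.
#'
#' @param n_samples Number of samples.
#' @param n_per_sample Replicates per sample (default 6).
#' @param noise_sd SD of log replicate noise (default 0.05).
#' @param outlier_fraction Fraction of samples with one planted outlier.
#' @param outlier_factor Multiplicative factor applied to the planted
#'   replicate.
#' @param seed Integer seed.
#' @return List with `replicates` (long data frame: `sample_id`, `run_id`,
#'   `ts`) and `truth` (`outlier_samples`: sample ids with a planted
#'   outlier).
#' @export
generate_replicate_sets <- function(n_samples = 50, n_per_sample = 6,
                                    noise_sd = 0.05, outlier_fraction = 0.1,
                                    outlier_factor = 2.0, seed = 1L) {
  set.seed(as.integer(seed))
  base <- exp(stats::rnorm(n_samples, log(1.03), 0.2))
  run <- rep_len(rep(1:3, each = 2), n_per_sample)
  reps <- lapply(seq_len(n_samples), function(i) {
    data.frame(sample_id = i, run_id = run,
               ts = base[i] * exp(stats::rnorm(n_per_sample, 0, noise_sd)))
  })
  reps <- do.call(rbind, reps)
  n_out <- round(n_samples * outlier_fraction)
  out_ids <- if (n_out > 0) sort(sample(seq_len(n_samples), n_out)) else
    integer(0)
  for (i in out_ids) {
    rows <- which(reps$sample_id == i)
    j <- sample(rows, 1L)
    reps$ts[j] <- reps$ts[j] * outlier_factor
  }
  list(replicates = reps, truth = list(outlier_samples = out_ids))
}
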