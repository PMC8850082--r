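#' Survey design for a stratified multistage sample
#'
#' Bundles the design variables used by the Taylor-linearization variance
#' estimator: stratum id, primary sampling unit (PSU) id nested within
#' stratum, and a positive analysis weight per observation.
#'
#' @param stratum Stratum ids.
#' @param psu PSU ids (interpreted within stratum).
#' @param weight Positive finite analysis weights.
#' @return A list of class `survey_design` with elements `stratum`, `psu`,
#'   `weight`, `n`.
#' @export
survey_design <- function(stratum, psu, weight) {
  n <- length(weight)
  if (length(stratum) != n || length(psu) != n) {
    stop("stratum, psu and weight must have equal length")
  }
  if (any(!is.finite(weight)) || any(weight <= 0)) {
    stop("weights must be positive and finite")
  }
  structure(list(stratum = as.character(stratum),
                 psu = paste(stratum, psu, sep = "::"),
                 weight = as.numeric(weight), n = n),
            class = "survey_design")
}

#' @export
print.survey_design <- function(x, ...) {
  cat("Survey design: ", x$n, " observations, ",
      length(unique(x$stratum)), " strata, ",
      length(unique(x$psu)), " PSUs\n", sep = "")
  invisible(x)
}

design_subset <- function(design, idx) {
  survey_design(design$stratum[idx], design$psu[idx], design$weight[idx])
}

#' Survey-weighted descriptive statistics
#'
#' Weighted mean and standard deviation, weighted median and quartiles
#' (same quantile definition as the scoring functions), or, for categorical
#' variables, unweighted counts with weighted percentages.
#'
#' @param x Values (numeric, or factor/character for `"category_pct"`).
#' @param design A `survey_design` aligned with `x`.
#' @param kind One of `"mean_sd"`, `"median_iqr"`, `"category_pct"`.
#' @return For `"mean_sd"`: named numeric `c(mean, sd)` (the SD is the
#'   weighted population SD).  For `"median_iqr"`: named numeric
#'   `c(p25, median, p75)`.  For `"category_pct"`: data frame with columns
#'   `level`, `n` (unweighted) and `pct` (weighted, summing to 100).
#' @export
weighted_descriptives <- function(x, design, kind = c("mean_sd", "median_iqr",
                                                      "category_pct")) {
  kind <- match.arg(kind)
  w <- design$weight
  if (length(x) != design$n) stop("x and design lengths differ")
  keep <- !is.na(x)
  x <- x[keep]; w <- w[keep]
  if (sum(w) <= 0) stop("total weight must be positive")
  if (kind == "mean_sd") {
    m <- sum(w * x) / sum(w)
    v <- sum(w * (x - m)^2) / sum(w)
    c(mean = m, sd = sqrt(v))
  } else if (kind == "median_iqr") {
    q <- weighted_quantile(x, c(0.25, 0.5, 0.75), w)
    c(p25 = unname(q[1L]), median = unname(q[2L]), p75 = unname(q[3L]))
  } else {
    lev <- if (is.factor(x)) levels(x) else sort(unique(as.character(x)))
    xf <- factor(as.character(x), levels = lev)
    n <- as.integer(table(xf))
    wt <- tapply(w, xf, sum, default = 0)
    data.frame(level = lev, n = n, pct = 100 * as.numeric(wt) / sum(w))
  }
}

#' Survey-weighted linear regression with Taylor-linearization variance
#'
#' Point estimates are weighted least squares with the analysis weights.
#' The covariance matrix is the stratified ultimate-cluster linearization
#' estimator: with per-PSU totals of weighted score contributions
#' \eqn{z_{hj} = \sum_{i \in PSU\,hj} w_i x_i e_i}, the middle matrix is
#' \eqn{G = \sum_h \frac{n_h}{n_h - 1} \sum_j (z_{hj} - \bar z_h)
#' (z_{hj} - \bar z_h)'} and \eqn{V = (X'WX)^{-1} G (X'WX)^{-1}}.
#' Design degrees of freedom are (number of PSUs) minus (number of strata);
#' confidence intervals and p-values are t-based on these df.
#'
#' @param y Numeric outcome vector.
#' @param X Design matrix including the intercept column.
#' @param design A `survey_design`.
#' @param lonely_psu `"fail"` (default) errors when a stratum has a single
#'   PSU; `"adjust"` centres such strata at the grand mean of PSU totals.
#' @param conf_level Confidence level for the intervals (default 0.95).
#' @return A list of class `svy_lm` with `coefficients` (data frame: `term`,
#'   `beta`, `se`, `ci_low`, `ci_high`, `statistic`, `p_value`, `df`),
#'   `vcov`, `df`, `n`, `residuals`, `fitted`.
#' @export
survey_lm <- function(y, X, design, lonely_psu = c("fail", "adjust"),
                      conf_level = 0.95) {
  lonely_psu <- match.arg(lonely_psu)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)) - 1L)
  n <- length(y)
  if (nrow(X) != n || design$n != n) stop("y, X and design lengths differ")
  w <- design$weight
  XtWX <- crossprod(X, w * X)
  qrA <- qr(XtWX)
  if (qrA$rank < ncol(X)) {
    stop("collinearity: weighted cross-product matrix X'WX is singular")
  }
  beta <- solve(qrA, crossprod(X, w * y))
  e <- as.numeric(y - X %*% beta)

  # per-PSU totals of weighted score contributions
  U <- (w * e) * X
  psu <- design$psu
  stratum_of_psu <- tapply(design$stratum, psu, `[`, 1L)
  Z <- rowsum(U, group = psu)
  strat <- stratum_of_psu[rownames(Z)]

  n_h <- table(strat)
  if (any(n_h < 2L) && lonely_psu == "fail") {
    stop("lonely PSU: stratum ", paste(names(n_h)[n_h < 2L], collapse = ", "),
         " has a single PSU; variance is undefined (see lonely_psu)")
  }
  p <- ncol(X)
  G <- matrix(0, p, p)
  grand <- colMeans(Z)
  for (h in names(n_h)) {
    Zh <- Z[strat == h, , drop = FALSE]
    nh <- nrow(Zh)
    if (nh >= 2L) {
      zbar <- colMeans(Zh)
      D <- sweep(Zh, 2L, zbar)
      G <- G + (nh / (nh - 1)) * crossprod(D)
    } else {
      d <- Zh[1L, ] - grand
      G <- G + tcrossprod(d)
    }
  }
  Ainv <- solve(qrA, diag(p))
  V <- Ainv %*% G %*% Ainv
  dimnames(V) <- list(colnames(X), colnames(X))

  df <- length(unique(psu)) - length(unique(design$stratum))
  if (df <= 0) stop("non-positive design degrees of freedom")
  se <- sqrt(diag(V))
  b <- as.numeric(beta)
  tstat <- b / se
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df)
  coef <- data.frame(term = colnames(X), beta = b, se = se,
                     ci_low = b - tcrit * se, ci_high = b + tcrit * se,
                     statistic = tstat,
                     p_value = 2 * stats::pt(-abs(tstat), df),
                     df = df, row.names = NULL)
  structure(list(coefficients = coef, vcov = V, df = df, n = n,
                 residuals = e, fitted = as.numeric(X %*% beta)),
            class = "svy_lm")
}

#' @export
print.svy_lm <- function(x, ...) {
  cat("Survey-weighted linear model (n = ", x$n, ", design df = ", x$df,
      ")\n", sep = "")
  print(x$coefficients, digits = 4, ...)
  invisible(x)
}

#' Trend test across ordered exposure categories
#'
#' Enters the ordinal category index (1, 2, ...) — or, with
#' `coding = "median"`, the within-category median of `score` — as a single
#' continuous term in a survey-weighted linear model alongside the supplied
#' covariate columns, and returns the fitted model.  The p-value of the
#' trend term is the p for trend.
#'
#' @param y Outcome vector.
#' @param categories Ordered factor of exposure categories (e.g. OBS
#'   quartiles from [assign_quartiles()]).
#' @param covariates Numeric design matrix of adjustment columns (no
#'   intercept), or `NULL` for a crude model.
#' @param design A `survey_design`.
#' @param coding `"index"` (default) or `"median"`.
#' @param score Raw score values, required for `coding = "median"`.
#' @param ... Passed to [survey_lm()].
#' @return A `svy_lm`; the trend term is named `"trend"`.
#' @export
trend_test <- function(y, categories, covariates = NULL, design,
                       coding = c("index", "median"), score = NULL, ...) {
  coding <- match.arg(coding)
  idx <- as.integer(categories)
  if (coding == "median") {
    if (is.null(score)) stop("score is required for median coding")
    med <- tapply(score, categories, stats::median)
    trend <- as.numeric(med[idx])
  } else {
    trend <- as.numeric(idx)
  }
  X <- cbind(`(Intercept)` = 1, trend = trend)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  survey_lm(y, X, design, ...)
}
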