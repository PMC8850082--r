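# Fixtures built in code: a small hand-checkable cohort and shared helpers.

# A complete, violation-free participant row; fields overridable.
toy_row <- function(id, sex = "female", ...) {
  base <- list(
    id = id, sex = sex, age = 45,
    ethnicity = "non_hispanic_white", education = "high_school",
    pir = "1.3-3.5", energy = if (sex == "male") 2400 else 1800,
    crp = 0.2, ltl = 1.05, pregnant = FALSE, recall_status = "ok",
    stratum = 1 + id %% 2, psu = 1 + id %% 2, weight = 1,
    fiber = 15, carotene = 200, riboflavin = 1.6, niacin = 20,
    vitamin_b6 = 1.5, folate = 350, vitamin_b12 = 4, vitamin_c = 80,
    vitamin_e = 6, calcium = 800, magnesium = 250, zinc = 9, copper = 1.1,
    selenium = 90, total_fat = 70, iron = 12, physical_activity = 600,
    alcohol = 5, bmi = 26, cotinine = 0.1)
  mods <- list(...)
  base[names(mods)] <- mods
  as.data.frame(base)
}

toy_cohort <- function(n = 10, ...) {
  do.call(rbind, lapply(seq_len(n), toy_row, ...))
}

# Brute-force oracle for the step-type weighted quantile: walk the sorted
# values accumulating weight until the target share is reached.
oracle_quantile <- function(x, p, w = rep(1, length(x))) {
  o <- order(x)
  acc <- 0
  total <- sum(w)
  for (i in o) {
    acc <- acc + w[i]
    if (acc / total >= p) return(x[i])
  }
  x[o[length(o)]]
}

# Independent loop-based Taylor-linearization oracle, written as explicit
# sums over strata/PSUs/observations (no matrix shortcuts shared with the
# implementation under test).
oracle_linearization <- function(y, X, w, stratum, psu) {
  X <- as.matrix(X)
  p <- ncol(X)
  A <- matrix(0, p, p)
  b <- numeric(p)
  for (i in seq_along(y)) {
    A <- A + w[i] * X[i, ] %*% t(X[i, ])
    b <- b + w[i] * X[i, ] * y[i]
  }
  beta <- solve(A, b)
  e <- numeric(length(y))
  for (i in seq_along(y)) e[i] <- y[i] - sum(X[i, ] * beta)
  G <- matrix(0, p, p)
  for (h in unique(stratum)) {
    psus <- unique(psu[stratum == h])
    nh <- length(psus)
    zs <- matrix(0, nh, p)
    for (j in seq_along(psus)) {
      idx <- which(stratum == h & psu == psus[j])
      for (i in idx) zs[j, ] <- zs[j, ] + w[i] * X[i, ] * e[i]
    }
    zbar <- colSums(zs) / nh
    for (j in seq_len(nh)) {
      d <- zs[j, ] - zbar
      G <- G + (nh / (nh - 1)) * d %*% t(d)
    }
  }
  V <- solve(A) %*% G %*% solve(A)
  list(beta = as.numeric(beta), V = V)
}

# Fixed n = 12 dataset: 2 strata x 2 PSUs x 3 observations, fixed weights.
fixed_svy_data <- function() {
  set.seed(42)
  d <- data.frame(
    stratum = rep(1:2, each = 6),
    psu = rep(rep(1:2, each = 3), 2),
    w = c(1.2, 0.8, 1.5, 1.0, 2.0, 0.6, 1.1, 0.9, 1.3, 0.7, 1.4, 1.6),
    x = c(0.5, 1.2, -0.3, 2.1, 0.8, 1.5, -1.0, 0.2, 1.8, 0.9, -0.4, 1.1))
  d$y <- 1 + 0.5 * d$x + stats::rnorm(12, 0, 0.3)
  d
}
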