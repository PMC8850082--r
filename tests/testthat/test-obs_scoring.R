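test_that("tertile boundaries match the brute-force cumulative-weight oracle", {
  # frozen case: 1..9 equally weighted
  expect_equal(compute_tertiles(1:9), c(t1 = 3, t2 = 6))
  expect_equal(oracle_quantile(1:9, 1 / 3), 3)
  expect_equal(oracle_quantile(1:9, 2 / 3), 6)

  set.seed(21)
  for (i in 1:30) {
    x <- sample(round(runif(25, 0, 50), 1))
    w <- runif(25, 0.2, 3)
    t <- compute_tertiles(x, w)
    expect_equal(unname(t["t1"]), oracle_quantile(x, 1 / 3, w))
    expect_equal(unname(t["t2"]), oracle_quantile(x, 2 / 3, w))
  }
})

test_that("unweighted tertiles equal equally-weighted tertiles", {
  x <- c(4, 8, 15, 16, 23, 42, 7, 1)
  expect_equal(compute_tertiles(x), compute_tertiles(x, rep(2.5, length(x))))
})

test_that("degenerate distributions are rejected", {
  expect_error(compute_tertiles(rep(5, 10)), "degenerate")
  expect_error(compute_tertiles(c(1, 2)), "degenerate")
  # nearly all weight on one value collapses the boundaries
  expect_error(compute_tertiles(c(1, 2, 3, 4), c(100, 1e-9, 1e-9, 1e-9)),
               "degenerate")
})

test_that("tertile point assignment follows polarity and interval convention", {
  cp <- default_cutpoints()
  # antioxidant: 0/1/2 from lowest to highest tertile
  expect_equal(assign_component_points(120, "female", "vitamin_c"), 2L)
  expect_equal(assign_component_points(50, "female", "vitamin_c"), 1L)
  expect_equal(assign_component_points(10, "female", "vitamin_c"), 0L)
  # boundary values: exactly t1 -> middle group, exactly t2 -> top group
  expect_equal(assign_component_points(38.01, "female", "vitamin_c"), 1L)
  expect_equal(assign_component_points(98.49, "female", "vitamin_c"), 2L)
  # prooxidant: reversed, 0 points in the highest tertile
  expect_equal(assign_component_points(25, "male", "iron"), 0L)
  expect_equal(assign_component_points(15, "male", "iron"), 1L)
  expect_equal(assign_component_points(5, "male", "iron"), 2L)
  expect_equal(assign_component_points(12.88, "male", "iron"), 1L)
})

test_that("alcohol points use the fixed sex-specific rule", {
  expect_equal(assign_component_points(45, "male", "alcohol"), 0L)
  expect_equal(assign_component_points(0, "female", "alcohol"), 2L)
  expect_equal(assign_component_points(10, "male", "alcohol"), 1L)
  # thresholds are inclusive for heavy drinking
  expect_equal(assign_component_points(30, "male", "alcohol"), 0L)
  expect_equal(assign_component_points(29.9, "male", "alcohol"), 1L)
  expect_equal(assign_component_points(15, "female", "alcohol"), 0L)
  expect_equal(assign_component_points(14.9, "female", "alcohol"), 1L)
})

test_that("a missing cutpoint entry is a configuration error", {
  cp <- default_cutpoints()
  cp_miss <- cp[!(cp$component == "zinc" & cp$sex == "female"), ]
  expect_error(assign_component_points(8, "female", "zinc",
                                       cutpoints = cp_miss),
               "no unique cutpoint")
  expect_error(assign_component_points(8, "female", "not_a_nutrient"),
               "unknown component")
})

test_that("a hand-scored female record sums to the manual table lookup", {
  cohort <- toy_row(1, sex = "female",
                    fiber = 17, carotene = 50, riboflavin = 1.5, niacin = 25,
                    vitamin_b6 = 1.0, folate = 400, vitamin_b12 = 5,
                    vitamin_c = 120, vitamin_e = 5, calcium = 900,
                    magnesium = 200, zinc = 8, copper = 1.0, selenium = 70,
                    total_fat = 60, iron = 10, physical_activity = 900,
                    alcohol = 0, bmi = 22, cotinine = 0.5)
  obs <- compute_obs(cohort)
  # manual row-by-row lookup against the packaged cutpoints:
  # dietary 2+0+1+2+0+2+2+2+1+2+1+1+1+1+1+1 = 20
  # lifestyle: activity 2, alcohol 2, BMI 2, cotinine 0 = 6
  expect_equal(obs$obs_dietary, 20L)
  expect_equal(obs$obs_lifestyle, 6L)
  expect_equal(obs$obs_total, 26L)
})

test_that("all-minimum and all-maximum participants hit the score bounds", {
  lo <- toy_row(1, sex = "male",
                fiber = 1, carotene = 1, riboflavin = 0.1, niacin = 1,
                vitamin_b6 = 0.1, folate = 10, vitamin_b12 = 0.1,
                vitamin_c = 1, vitamin_e = 0.5, calcium = 50, magnesium = 20,
                zinc = 1, copper = 0.1, selenium = 5,
                total_fat = 500, iron = 100, physical_activity = 0,
                alcohol = 50, bmi = 45, cotinine = 500)
  o <- compute_obs(lo)
  expect_equal(c(o$obs_total, o$obs_dietary, o$obs_lifestyle), c(0L, 0L, 0L))

  hi <- toy_row(2, sex = "male",
                fiber = 50, carotene = 1000, riboflavin = 10, niacin = 60,
                vitamin_b6 = 8, folate = 900, vitamin_b12 = 20,
                vitamin_c = 400, vitamin_e = 30, calcium = 2000,
                magnesium = 700, zinc = 30, copper = 4, selenium = 300,
                total_fat = 10, iron = 2, physical_activity = 4000,
                alcohol = 0, bmi = 19, cotinine = 0.001)
  o <- compute_obs(hi)
  expect_equal(c(o$obs_total, o$obs_dietary, o$obs_lifestyle),
               c(40L, 32L, 8L))
})

test_that("flipping a component's polarity maps points p to 2 - p", {
  g <- generate_cohort(sim_config(n = 160, n_strata = 4, seed = 3))
  schema <- default_schema()
  flipped <- schema
  flipped$polarity[flipped$component == "zinc"] <- "prooxidant"
  cp <- compute_cutpoints(g$cohort, schema)
  p0 <- assign_component_points(g$cohort$zinc, g$cohort$sex, "zinc",
                                schema, cp)
  p1 <- assign_component_points(g$cohort$zinc, g$cohort$sex, "zinc",
                                flipped, cp)
  expect_equal(p1, 2L - p0)
})

test_that("score decomposition and leave-one-out algebra hold on random cohorts", {
  g <- generate_cohort(sim_config(n = 240, n_strata = 4, seed = 5))
  schema <- default_schema()
  obs <- compute_obs(g$cohort, schema, compute_cutpoints(g$cohort, schema))
  expect_equal(obs$obs_total, obs$obs_dietary + obs$obs_lifestyle)
  expect_true(all(obs$obs_total >= 0 & obs$obs_total <= 40))
  expect_true(all(obs$obs_dietary <= 32 & obs$obs_lifestyle <= 8))

  # removing one component lowers each total by exactly that component's
  # points, with a new maximum of 38
  reduced_schema <- schema[schema$component != "copper", ]
  obs_red <- compute_obs(g$cohort, reduced_schema,
                         compute_cutpoints(g$cohort, reduced_schema))
  expect_equal(obs_red$obs_total, obs$obs_total - obs$points_copper)
  expect_true(all(obs_red$obs_total <= 38))
})

test_that("quartile labels are sex-specific, monotone, and oracle-sized", {
  # scores 1..8 in one sex: cuts at the smallest values whose cumulative
  # share reaches 1/4, 1/2, 3/4 are 2, 4, 6, giving groups {1},{2,3},{4,5},
  # {6,7,8} (hand-walked cumulative-count oracle)
  q <- assign_quartiles(1:8, rep("male", 8))
  expect_equal(oracle_quantile(1:8, 0.25), 2)
  expect_equal(oracle_quantile(1:8, 0.75), 6)
  expect_equal(as.vector(table(q)), c(1L, 2L, 2L, 3L))
  expect_true(all(diff(as.integer(q)[order(1:8)]) >= 0))

  set.seed(9)
  score <- sample(0:40, 100, replace = TRUE)
  sex <- sample(c("male", "female"), 100, replace = TRUE)
  q <- assign_quartiles(score, sex)
  for (sx in c("male", "female")) {
    s <- score[sex == sx]; qq <- q[sex == sx]
    o <- order(s)
    expect_true(all(diff(as.integer(qq)[o]) >= 0))
  }

  expect_error(assign_quartiles(rep(7, 10), rep("male", 10)), "degenerate")
})
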