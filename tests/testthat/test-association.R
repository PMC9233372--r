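test_that("duration categories use inclusive 420/660 minute boundaries", {
  cats <- categorize_durations(c(420, 660, 540, 419, 661, NA))
  expect_equal(as.character(cats[1]), "extremely_short")
  expect_equal(as.character(cats[2]), "extremely_long")
  expect_equal(as.character(cats[3]), "non_extreme")
  expect_equal(as.character(cats[4]), "extremely_short")
  expect_equal(as.character(cats[5]), "extremely_long")
  expect_true(is.na(cats[6]))

  # exhaustive and mutually exclusive for any duration vector
  set.seed(3)
  x <- runif(500, 100, 900)
  cc <- categorize_durations(x)
  expect_false(any(is.na(cc)))
  expect_equal(sum(table(cc)), 500L)

  # percentile mode recomputes thresholds from the data
  cp <- categorize_durations(x, percentile_mode = TRUE)
  expect_equal(attr(cp, "short_max"), quantile(x, 0.05, names = FALSE))
  expect_equal(mean(cp == "extremely_short"), 0.05, tolerance = 0.01)
})

.mk_pheno <- function(n, sleep, age = NULL, sex = NULL) {
  if (is.null(age)) age <- sample(4:18, n, replace = TRUE)
  if (is.null(sex)) sex <- sample(c("male", "female"), n, replace = TRUE)
  data.frame(individual_id = sprintf("p%03d", 1:n),
             sleep_minutes = sleep, age_years = age, sex = sex,
             race = sample(c("white", "non_white"), n, replace = TRUE),
             iq = round(rnorm(n, 100, 15)), stringsAsFactors = FALSE)
}

test_that("noise-free linear fit recovers exact coefficients", {
  set.seed(10)
  n <- 50
  dbp <- runif(n)
  ph <- .mk_pheno(n, sleep = 2 * dbp + 3)
  res <- suppressWarnings(            # noise-free fit is deliberately exact
    fit_dbp_linear(ph, setNames(dbp, ph$individual_id),
                   covariates = character(0)))
  expect_equal(res$beta[res$term == "dbp"], 2, tolerance = 1e-10)
  expect_equal(res$beta[res$term == "(Intercept)"], 3, tolerance = 1e-10)
})

test_that("OLS matches the normal-equations oracle and row permutation", {
  fx <- fixtures()$reg6
  n <- length(fx$y)
  ph <- .mk_pheno(n, sleep = fx$y, age = fx$x1,
                  sex = ifelse(fx$x2 == 1, "male", "female"))
  dbp <- setNames(fx$x1, ph$individual_id)  # use x1 as the dbp column
  res <- fit_dbp_linear(ph, dbp, covariates = "sex")
  # oracle computed from (X'X)^{-1} X'y in the fixture
  expect_equal(res$beta[res$term == "(Intercept)"], fx$oracle_beta[1],
               tolerance = 1e-10)
  expect_equal(res$beta[res$term == "dbp"], fx$oracle_beta[2],
               tolerance = 1e-10)
  expect_equal(res$beta[res$term == "sexmale"], fx$oracle_beta[3],
               tolerance = 1e-10)

  perm <- sample(n)
  res2 <- fit_dbp_linear(ph[perm, ], dbp, covariates = "sex")
  expect_equal(res2$beta, res$beta, tolerance = 1e-12)
})

test_that("collinear designs are rejected with the offending term", {
  set.seed(12)
  n <- 40
  ph <- .mk_pheno(n, sleep = rnorm(n, 540, 60))
  ph$iq <- ph$age_years * 2          # exact collinearity after dbp? no: with age
  dbp <- setNames(runif(n), ph$individual_id)
  expect_error(fit_dbp_linear(ph, dbp, covariates = c("age_years", "iq")),
               "collinear")
})

test_that("category model separates a perfectly predictive score", {
  set.seed(13)
  n <- 120
  dbp <- runif(n)
  sleep <- ifelse(dbp > median(dbp), 700, 500)  # long sleepers iff high dbp
  ph <- .mk_pheno(n, sleep = sleep)
  res <- fit_dbp_category(ph, setNames(dbp, ph$individual_id),
                          "extremely_long", covariates = character(0))
  expect_gt(res$beta[res$term == "dbp"], 0)

  # constant indicator is fatal
  ph2 <- .mk_pheno(n, sleep = rep(500, n))
  expect_error(fit_dbp_category(ph2, setNames(dbp, ph2$individual_id),
                                "extremely_long",
                                covariates = character(0)),
               "constant")

  # logistic link returns a positive coefficient too
  resl <- suppressWarnings(           # perfect separation is the point here
    fit_dbp_category(ph, setNames(dbp, ph$individual_id),
                     "extremely_long", covariates = character(0),
                     link = "logistic"))
  expect_gt(resl$beta[resl$term == "dbp"], 0)
})

test_that("interaction model reports the product term, rejects constants", {
  set.seed(14)
  n <- 300
  dbp <- runif(n)
  age <- sample(4:18, n, replace = TRUE)
  sleep <- 600 + 5 * dbp * age + rnorm(n, 0, 5)
  ph <- .mk_pheno(n, sleep = sleep, age = age)
  res <- fit_dbp_interaction(ph, setNames(dbp, ph$individual_id),
                             "age_years", covariates = "age_years")
  row <- res[res$term == "dbp:age_years", ]
  expect_equal(row$beta, 5, tolerance = 0.5)
  expect_lt(row$p, 1e-6)

  ph$age_years <- 10
  expect_error(fit_dbp_interaction(ph, setNames(dbp, ph$individual_id),
                                   "age_years", covariates = "age_years"),
               "constant")
})

test_that("stratified fits skip empty strata and keep the others", {
  set.seed(15)
  n <- 200
  age <- sample(6:12, n, replace = TRUE)      # primary-school ages only
  dbp <- runif(n)
  ph <- .mk_pheno(n, sleep = 540 - 3 * age + 20 * dbp + rnorm(n, 0, 10),
                  age = age)
  out <- fit_dbp_stratified(ph, setNames(dbp, ph$individual_id))
  expect_true(is.character(out$preschool))    # skipped with a note
  expect_true(is.character(out$secondary))
  expect_s3_class(out$primary, "regression_result")
  expect_equal(attr(out$primary, "stratum"), "primary")
  expect_gt(out$primary$beta[out$primary$term == "dbp"], 0)
})
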