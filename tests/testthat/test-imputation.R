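test_that("predictor selection ranks by absolute correlation with ties fixed", {
  set.seed(2)
  n <- 300L
  d <- data.frame(
    age = rnorm(n),
    gender01 = sample(0:1, n, TRUE),
    medicaid01 = sample(0:1, n, TRUE),
    private01 = sample(0:1, n, TRUE),
    smoking = sample(0:2, n, TRUE),
    kde_h0.25 = rnorm(n)
  )
  d$target <- 2 * d$age + rnorm(n, 0, 0.1)   # nearly collinear with age
  got <- select_predictors(d, "target",
                           candidates = c("age", "gender01", "medicaid01",
                                          "private01", "smoking", "kde_h0.25"))
  expect_equal(got[1], "age")
  expect_length(got, 5L)
  # brute-force recomputation of the ranking (indicator expansion by hand)
  expand <- function(v) {
    if (identical(v, "smoking")) sapply(0:2, function(l) as.numeric(d[[v]] == l))
    else matrix(d[[v]], ncol = 1)
  }
  cands <- c("age", "gender01", "medicaid01", "private01", "smoking",
             "kde_h0.25")
  sc <- sapply(cands, function(v) {
    r <- suppressWarnings(cor(matrix(d$target, ncol = 1), expand(v),
                              use = "pairwise.complete.obs"))
    r[!is.finite(r)] <- 0
    max(abs(r))
  })
  expect_equal(got, cands[order(-sc)][1:5])
  # a constant candidate has correlation 0 and ranks last
  d$flat <- 1
  got2 <- select_predictors(d, "target", candidates = c(cands, "flat"), n = 7)
  expect_equal(got2[7], "flat")
  expect_warning(select_predictors(d, "target", candidates = c("age", "flat")),
                 "fewer than")
})

test_that("PMM hands each recipient the nearest donor's observed value", {
  # donors with predicted means exactly 1, 2, 4 (perfect linear fit y = x)
  x <- rep(c(1, 2, 4), each = 4)
  y <- x
  X <- cbind(1, c(x, 2.9, 4))
  yy <- c(y, NA, NA)
  set.seed(1)
  filled <- impute_pmm(yy, X, posterior = FALSE)
  # recipient at 2.9: (2.9-2)^2 < (2.9-4)^2, so donor value 2
  expect_equal(filled[13], 2)
  # exact zero-distance match returns that donor's value
  expect_equal(filled[14], 4)
  # brute-force donor search agrees
  mu_d <- X[1:12, ] %*% c(0, 1)
  expect_equal(filled[13], y[which.min((2.9 - mu_d)^2)])
  expect_error(impute_pmm(c(1, 2, NA), cbind(1, 1:3)), ">= 10 complete")
})

test_that("PMM imputes only observed values and responds to the posterior draw", {
  set.seed(7)
  n <- 400L
  X <- cbind(1, rnorm(n), rnorm(n))
  y <- drop(X %*% c(1, 2, -1)) + rnorm(n)
  y[sample(n, 80)] <- NA
  set.seed(42)
  filled <- impute_pmm(y, X)
  expect_false(anyNA(filled))
  expect_true(all(filled[is.na(y)] %in% y[!is.na(y)]))
  # the draw is seeded: same seed, same completion
  set.seed(42)
  expect_equal(as.vector(impute_pmm(y, X)), as.vector(filled))
})

test_that("logistic imputation draws at the fitted probability", {
  # intercept-only model with 30% positives: every missing case gets p = 0.3
  n_obs <- 10000L; n_mis <- 10000L
  y <- c(rep(c(1, 0), c(3000, 7000)), rep(NA, n_mis))
  X <- matrix(1, n_obs + n_mis, 1)
  set.seed(5)
  filled <- impute_logistic(y, X, posterior = FALSE)
  expect_equal(attr(filled, "p_mis"), rep(0.3, n_mis), tolerance = 1e-9)
  freq <- mean(filled[(n_obs + 1):(n_obs + n_mis)])
  expect_lt(abs(freq - 0.3), 3 * sqrt(0.3 * 0.7 / n_mis))
  # single observed class imputes the constant
  y1 <- c(rep(1, 20), NA, NA)
  expect_warning(f1 <- impute_logistic(y1, matrix(1, 22, 1)), "single-class")
  expect_equal(f1[21:22], c(1, 1))
})

test_that("two-category polytomous imputation equals logistic to 1e-10", {
  set.seed(9)
  n <- 500L
  X <- cbind(1, rnorm(n), sample(0:1, n, TRUE))
  y <- rbinom(n, 1, plogis(drop(X %*% c(-0.3, 0.8, -0.5))))
  y[sample(n, 100)] <- NA
  pl <- attr(impute_logistic(y, X, posterior = FALSE), "p_mis")
  pp <- attr(impute_polytomous(y, X, levels = 0:1, posterior = FALSE), "p_mis")
  expect_equal(unname(pp[, "1"]), unname(pl), tolerance = 1e-10)
})

test_that("polytomous probabilities normalize and draws stay in the levels", {
  set.seed(10)
  n <- 600L
  X <- cbind(1, rnorm(n))
  y <- sample(0:2, n, TRUE, prob = c(0.2, 0.3, 0.5))
  y[sample(n, 150)] <- NA
  filled <- impute_polytomous(y, X, levels = 0:2)
  P <- attr(filled, "p_mis")
  expect_equal(rowSums(P), rep(1, 150), tolerance = 1e-12)
  expect_true(all(filled[is.na(y)] %in% 0:2))
})

test_that("chained imputation preserves observed cells and is reproducible", {
  cfg <- small_synth_config(seed = 31, n = 500L)
  sim <- simulate_cohort(cfg)
  cd <- encode_covariates(sim$participants)
  cd <- attach_density(cd, sim$blocks, c(0.25, 0.5))
  plan <- imputation_plan(m = 3, n_cycles = 3, seed = 17)
  imp <- run_chained(cd, plan)
  vars <- c("gender01", "race_eth", "age", "smoking", "medicaid01",
            "private01", "education")
  for (d in imp$datasets) {
    for (v in vars) {
      obs <- !imp$mask[, v]
      expect_identical(d[[v]][obs], cd[[v]][obs])  # bit-exact preservation
      expect_false(anyNA(d[[v]]))
    }
    # outcomes never imputed in the default mode
    expect_identical(is.na(d$dentition), is.na(cd$dentition))
    expect_identical(is.na(d$sroh), is.na(cd$sroh))
  }
  # PMM plausibility: imputed ages appear among observed ages
  obs_ages <- cd$age[!is.na(cd$age)]
  for (d in imp$datasets)
    expect_true(all(d$age[imp$mask[, "age"]] %in% obs_ages))
  imp2 <- run_chained(cd, plan)
  expect_identical(imp$datasets, imp2$datasets)
  # different master seed gives different completions
  imp3 <- run_chained(cd, imputation_plan(m = 3, n_cycles = 3, seed = 18))
  expect_false(identical(imp$datasets, imp3$datasets))
})

test_that("chained imputation on complete data is the identity", {
  cd <- toy_coded(150, seed = 12)
  plan <- imputation_plan(m = 3, n_cycles = 2, seed = 1)
  imp <- run_chained(cd, plan)
  for (d in imp$datasets) expect_identical(d, cd)
  # one missing cell: m completions, observed untouched
  cd2 <- cd
  cd2$age[5] <- NA
  imp2 <- run_chained(cd2, plan)
  for (d in imp2$datasets) {
    expect_false(is.na(d$age[5]))
    expect_identical(d$age[-5], cd2$age[-5])
  }
})

test_that("imputed-data means track the truth under MCAR masking", {
  set.seed(20)
  n <- 5000L
  cd <- toy_coded(n, seed = 20)
  true_mean <- mean(cd$age)
  cd$age[sample(n, n / 5)] <- NA
  imp <- run_chained(cd, imputation_plan(m = 5, n_cycles = 3, seed = 33))
  means <- vapply(imp$datasets, function(d) mean(d$age), numeric(1))
  se <- sd(cd$age, na.rm = TRUE) / sqrt(n)
  expect_lt(abs(mean(means) - true_mean), 3 * se)
})

test_that("degenerate imputation inputs raise the documented errors", {
  cd <- toy_coded(60, seed = 2)
  cd$age <- NA_real_
  expect_error(run_chained(cd, imputation_plan(m = 2, n_cycles = 1)),
               "100% missing")
  expect_error(imputation_plan(m = 1), "m must be")
  expect_error(imputation_plan(n_cycles = 0), "n_cycles")
  # complete-case mode performs listwise deletion
  cd2 <- toy_coded(60, seed = 2)
  cd2$smoking[1:10] <- NA
  cc <- run_chained(cd2, imputation_plan(m = 2, n_cycles = 1),
                    mode = "complete_case")
  expect_length(cc$datasets, 1L)
  expect_equal(nrow(cc$datasets[[1]]), 50L)
})
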