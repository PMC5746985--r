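test_that("two-category adjacent-categories fit IS binary logistic regression", {
  set.seed(3)
  n <- 300L
  X <- cbind(`(Intercept)` = 1, x1 = rnorm(n), x2 = sample(0:1, n, TRUE))
  y <- rbinom(n, 1, plogis(drop(X %*% c(-0.5, 1, 0.7))))
  fg <- fit_gaclr(design = X, outcome = y)
  ref <- glm(y ~ X - 1, family = binomial(),
             control = list(epsilon = 1e-14))
  expect_equal(unname(coef(fg)), unname(coef(ref)), tolerance = 1e-8)
  fl <- fit_logit(design = X, outcome = y)
  expect_equal(unname(coef(fl)), unname(coef(fg)), tolerance = 1e-8)
})

test_that("saturated fit reproduces closed-form cross-product odds ratios", {
  # rows = dentition categories 0/1/2, cols = x = 0/1
  counts <- rbind(c(20, 10), c(15, 15), c(5, 10))
  y <- rep(rep(0:2, 2), times = as.vector(counts))
  x <- rep(rep(0:1, each = 3), times = as.vector(counts))
  fit <- fit_gaclr(design = cbind(`(Intercept)` = 1, x = x), outcome = y)
  or <- exp(coef(fit))
  expect_equal(unname(or[["panel0:x"]]), (15 * 20) / (10 * 15), tolerance = 1e-6)
  expect_equal(unname(or[["panel1:x"]]), (10 * 15) / (15 * 5), tolerance = 1e-6)
  # saturated intercepts are the baseline-column odds
  expect_equal(unname(or[["panel0:(Intercept)"]]), 15 / 20, tolerance = 1e-6)
  expect_equal(unname(or[["panel1:(Intercept)"]]), 5 / 15, tolerance = 1e-6)
})

test_that("Newton fit matches brute-force likelihood maximization", {
  for (seed in 1:6) {
    inst <- random_acl_instance(seed, n = sample(100:300, 1),
                                q = sample(2:4, 1))
    fit <- fit_gaclr(design = inst$X, outcome = inst$y)
    oracle <- oracle_fit_acl(inst$X, inst$y)
    expect_equal(unname(coef(fit)), oracle, tolerance = 1e-5,
                 info = paste("seed", seed))
  }
})

test_that("panel coefficients are successive differences of multinomial ones", {
  inst <- random_acl_instance(17, n = 250, q = 3)
  fit <- fit_gaclr(design = inst$X, outcome = inst$y)
  G <- oracle_fit_multinom(inst$X, inst$y)   # baseline-category fit
  p <- ncol(inst$X)
  expect_equal(unname(coef(fit)[1:p]), G[, 1], tolerance = 1e-5)
  expect_equal(unname(coef(fit)[(p + 1):(2 * p)]), G[, 2] - G[, 1],
               tolerance = 1e-5)
})

test_that("fitted category probabilities sum to one", {
  inst <- random_acl_instance(23, n = 200, q = 2)
  fit <- fit_gaclr(design = inst$X, outcome = inst$y)
  p <- ncol(inst$X)
  eta <- cbind(inst$X %*% coef(fit)[1:p], inst$X %*% coef(fit)[(p + 1):(2 * p)])
  P <- gaclr_probs(eta)
  expect_equal(rowSums(P), rep(1, 200), tolerance = 1e-12)
})

test_that("GACLR validity checks fire on degenerate outcomes", {
  X <- cbind(1, rnorm(50))
  expect_error(fit_gaclr(design = X, outcome = rep(0L, 50)),
               "fewer than 2")
  expect_error(fit_gaclr(design = X, outcome = rep(c(0L, 2L), 25)),
               "categor")
})

test_that("binary logit matches closed forms", {
  # intercept-only: log odds of the mean
  y <- rep(c(1, 0), c(30, 70))
  f0 <- fit_logit(design = matrix(1, 100, 1,
                                  dimnames = list(NULL, "(Intercept)")),
                  outcome = y)
  expect_equal(unname(coef(f0)), log(0.3 / 0.7), tolerance = 1e-8)
  # 2x2 table [[30,10],[20,40]]: OR = (30*40)/(10*20) = 6
  y2 <- c(rep(0, 40), rep(1, 60))
  x2 <- c(rep(0, 30), rep(1, 10), rep(0, 20), rep(1, 40))
  f2 <- fit_logit(design = cbind(`(Intercept)` = 1, x = x2), outcome = y2)
  expect_equal(unname(exp(coef(f2)[["x"]])), 6, tolerance = 1e-8)
  expect_error(fit_logit(design = matrix(1, 10, 1), outcome = rep(1, 10)),
               "single class")
})

test_that("McFadden's R2 is one minus the likelihood ratio of logs", {
  expect_equal(mcfadden_r2(-50, -50), 0)
  expect_equal(mcfadden_r2(-25, -50), 0.5)
  expect_error(mcfadden_r2(-10, 0), "undefined")
  # toy fit: recompute both log-likelihoods by direct summation
  set.seed(6)
  X <- cbind(1, rnorm(120))
  y <- rbinom(120, 1, plogis(drop(X %*% c(0.2, 1))))
  f <- fit_logit(design = X, outcome = y)
  eta <- drop(X %*% coef(f))
  ll <- sum(y * eta - log(1 + exp(eta)))
  ll0 <- sum(y * log(mean(y)) + (1 - y) * log(1 - mean(y)))
  expect_equal(f$r2, 1 - ll / ll0, tolerance = 1e-10)
})

test_that("Rubin pooling reproduces the hand-computed combination", {
  mk <- function(est, v) {
    structure(list(coefficients = c(b = est), vcov = matrix(v, 1, 1,
                   dimnames = list("b", "b")),
                   loglik = -1, loglik0 = -2, n = 100, k = 1, r2 = 0.5),
              class = "logit_fit")
  }
  pooled <- pool_rubin(list(mk(0, 1), mk(1, 1)))
  expect_equal(pooled$estimate, 0.5)
  expect_equal(pooled$W, 1)
  expect_equal(pooled$B, 0.5)
  expect_equal(pooled$se^2, 1 + (1 + 1 / 2) * 0.5)   # T = 1.75
  # identical fits: B = 0, pooled SE = sqrt(W)
  same <- pool_rubin(list(mk(0.3, 0.04), mk(0.3, 0.04), mk(0.3, 0.04)))
  expect_equal(same$B, 0)
  expect_equal(same$se, 0.2)
  # disagreement always widens the interval: T >= W
  expect_gte(pooled$se^2, pooled$W)
  bad <- mk(1, 1); names(bad$coefficients) <- "c"
  expect_error(pool_rubin(list(mk(0, 1), bad)), "mismatch")
  expect_error(pool_rubin(list(mk(0, 1))), "at least 2")
})

test_that("pooling across real per-imputation fits keeps parameter order", {
  cd <- toy_coded(400, seed = 44)
  fits <- lapply(1:3, function(k) {
    d <- cd
    set.seed(k)
    d$age <- d$age + rnorm(400, 0, 0.5)  # mimic imputation variability
    fit_gaclr(d, "kde_h0.25")
  })
  pooled <- pool_rubin(fits)
  expect_equal(pooled$term, names(coef(fits[[1]])))
  expect_true(all(pooled$se^2 >= pooled$W - 1e-12))
  expect_true(all(pooled$ci_lo < pooled$ci_hi))
  expect_true(all(pooled$or > 0))
})

test_that("significance stars follow the strict printed thresholds", {
  expect_equal(significance_stars(c(0.005, 0.04, 0.09, 0.5)),
               c("***", "**", "*", ""))
  # boundary values fall to the weaker code (strict inequality)
  expect_equal(significance_stars(c(0.01, 0.05, 0.10)), c("**", "*", ""))
  expect_error(significance_stars(1.5))
})
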