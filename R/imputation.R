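# Multiple imputation of explanatory variables by chained equations, using
# three conditional models chosen by variable type: predictive mean matching
# (continuous), Bayesian logistic regression (binary), and Bayesian
# polytomous (multinomial) regression (categorical). Each produces proper
# imputations by drawing model parameters from their (approximate) posterior
# before drawing the imputed value.

#' Imputation plan
#'
#' @param m number of imputed datasets (default 10).
#' @param n_cycles chained-equation sweeps per dataset (default 10).
#' @param n_predictors predictors per conditional model (default 5, the most
#'   highly correlated variables).
#' @param seed master RNG seed.
#' @return object of class `imputation_plan`.
#' @export
imputation_plan <- function(m = 10L, n_cycles = 10L, n_predictors = 5L,
                            seed = 1L) {
  if (m < 2L) stop("m must be >= 2", call. = FALSE)
  if (n_cycles < 1L) stop("n_cycles must be >= 1", call. = FALSE)
  if (n_predictors < 1L) stop("n_predictors must be >= 1", call. = FALSE)
  structure(list(m = as.integer(m), n_cycles = as.integer(n_cycles),
                 n_predictors = as.integer(n_predictors),
                 seed = as.integer(seed)),
            class = "imputation_plan")
}

# Variable dictionary for the coded analysis table: imputation method and
# category levels. kde_* columns are continuous and always complete.
.covariate_specs <- list(
  gender01   = list(method = "logistic",   levels = 0:1),
  race_eth   = list(method = "polytomous", levels = 0:3),
  age        = list(method = "pmm",        levels = NULL),
  smoking    = list(method = "polytomous", levels = 0:2),
  medicaid01 = list(method = "logistic",   levels = 0:1),
  private01  = list(method = "logistic",   levels = 0:1),
  education  = list(method = "polytomous", levels = 0:2)
)
.outcome_specs <- list(
  dentition = list(method = "polytomous", levels = 0:2),
  sroh      = list(method = "logistic",   levels = 0:1)
)

.imputable_vars <- function(mode) {
  # fixed sweep order: gender, race/ethnicity, age, smoking, Medicaid,
  # private insurance, education (then outcomes if they are imputed too)
  covs <- c("gender01", "race_eth", "age", "smoking", "medicaid01",
            "private01", "education")
  if (mode == "impute_all") c(covs, "dentition", "sroh") else covs
}

.spec_of <- function(v) {
  if (v %in% names(.covariate_specs)) return(.covariate_specs[[v]])
  if (v %in% names(.outcome_specs)) return(.outcome_specs[[v]])
  list(method = "pmm", levels = NULL)  # kde columns and other numerics
}

# expand a variable to the numeric column(s) used for correlation ranking:
# continuous/binary as one column, multi-category as one indicator per level
.indicator_cols <- function(x, spec) {
  if (is.null(spec$levels) || length(spec$levels) <= 2L)
    return(matrix(as.numeric(x), ncol = 1L))
  vapply(spec$levels, function(l) as.numeric(x == l), numeric(length(x)))
}

#' Select imputation predictors by correlation
#'
#' Ranks candidate variables by absolute pairwise Pearson correlation with
#' the target, computed on pairwise-complete numerically coded columns
#' (binary as 0/1, multi-category variables expanded to indicators; a
#' category variable scores the maximum over its indicator columns).
#' Undefined correlations (constant columns, no overlap) score 0. Ties are
#' broken by the fixed candidate order.
#'
#' @param data coded analysis data.frame (may contain missing values).
#' @param target target variable name.
#' @param candidates candidate variable names (default: all other covariates
#'   plus any `kde_h*` columns).
#' @param n number of predictors to return (default 5).
#' @return character vector of <= n predictor names, best first.
#' @export
select_predictors <- function(data, target, candidates = NULL, n = 5L) {
  if (is.null(candidates)) {
    candidates <- setdiff(c(.imputable_vars("covariates_only"),
                            grep("^kde_h", names(data), value = TRUE)),
                          target)
  }
  candidates <- candidates[candidates %in% names(data)]
  if (length(candidates) < n)
    warning("fewer than ", n, " candidate predictors; using all ",
            length(candidates), call. = FALSE)
  tcols <- .indicator_cols(data[[target]], .spec_of(target))
  score <- vapply(candidates, function(cv) {
    ccols <- .indicator_cols(data[[cv]], .spec_of(cv))
    r <- suppressWarnings(stats::cor(tcols, ccols,
                                     use = "pairwise.complete.obs"))
    r[!is.finite(r)] <- 0
    max(abs(r))
  }, numeric(1))
  candidates[order(-score)][seq_len(min(n, length(candidates)))]
}

# design matrix (with intercept) from predictor variables of a completed table
.design_for <- function(data, predictors) {
  cols <- list(`(Intercept)` = rep(1, nrow(data)))
  for (v in predictors) {
    spec <- .spec_of(v)
    if (is.null(spec$levels) || length(spec$levels) <= 2L) {
      cols[[v]] <- as.numeric(data[[v]])
    } else {
      for (l in spec$levels[-1L])
        cols[[paste0(v, "_", l)]] <- as.numeric(data[[v]] == l)
    }
  }
  do.call(cbind, cols)
}

# least-squares fit with rank check and ridge fallback
.lm_draw <- function(X, y) {
  k <- ncol(X)
  qrx <- qr(X)
  if (qrx$rank < k) {
    warning("rank-deficient imputation design; using ridge fallback",
            call. = FALSE)
    XtX <- crossprod(X) + diag(1e-6, k)
    beta <- solve(XtX, crossprod(X, y))
    res <- y - X %*% beta
    Rinv <- chol2inv(chol(XtX))
    list(beta = drop(beta), rss = sum(res^2), df = length(y) - qrx$rank,
         XtX_inv = Rinv)
  } else {
    beta <- qr.coef(qrx, y)
    res <- qr.resid(qrx, y)
    XtX_inv <- chol2inv(chol(crossprod(X)))
    list(beta = drop(beta), rss = sum(res^2), df = length(y) - k,
         XtX_inv = XtX_inv)
  }
}

#' Predictive mean matching imputation
#'
#' Fits the linear model `Y = b0 + b1 X1 + ... + b5 X5 + e` on complete
#' cases; draws the residual variance from its scaled inverse chi-squared
#' posterior and the coefficients from their conditional normal posterior
#' (noninformative prior); computes predicted means for donors (at the ML
#' estimate) and for recipients (at the posterior draw); each missing value
#' receives the observed value of the single donor whose predicted mean is
#' nearest in squared distance, ties broken uniformly at random.
#'
#' @param y numeric target with `NA`s to fill.
#' @param X design matrix (with intercept), complete.
#' @param posterior draw parameters from the posterior (`TRUE`, proper
#'   imputation) or use the ML estimate (`FALSE`, deterministic given data).
#' @return `y` with missing entries replaced by donor values; the donor
#'   predicted means are attached as attribute `mu_mis`.
#' @export
impute_pmm <- function(y, X, posterior = TRUE) {
  mis <- is.na(y)
  obs <- !mis
  if (sum(obs) < 10L)
    stop("PMM needs >= 10 complete cases; use a different method", call. = FALSE)
  fit <- .lm_draw(X[obs, , drop = FALSE], y[obs])
  if (posterior) {
    sigma2 <- fit$rss / stats::rchisq(1L, df = max(fit$df, 1L))
    L <- t(chol(fit$XtX_inv))
    beta_star <- fit$beta + sqrt(sigma2) * drop(L %*% stats::rnorm(ncol(X)))
  } else {
    beta_star <- fit$beta
  }
  mu_don <- drop(X[obs, , drop = FALSE] %*% fit$beta)      # donors at ML estimate
  mu_rec <- drop(X[mis, , drop = FALSE] %*% beta_star)     # recipients at draw
  ydon <- y[obs]
  filled <- vapply(mu_rec, function(mu) {
    d <- (mu - mu_don)^2
    cand <- which(d == min(d))
    if (length(cand) > 1L) cand <- cand[sample.int(length(cand), 1L)]
    ydon[cand]
  }, numeric(1))
  y[mis] <- filled
  attr(y, "mu_mis") <- mu_rec
  y
}

# logistic ML fit returning coefficients and covariance, with ridge
# stabilization under separation / non-convergence
.logit_fit_core <- function(X, y) {
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = list(epsilon = 1e-12, maxit = 100L)))
  beta <- fit$coefficients
  if (!fit$converged || anyNA(beta) || any(abs(beta) > 15)) {
    warning("separation in logistic imputation model; ridge-stabilized fit",
            call. = FALSE)
    rf <- .fit_multinomial(X, as.integer(y), baseline = 0L, ridge = 1e-3)
    return(list(beta = drop(rf$coef), V = rf$vcov))
  }
  piv <- fit$qr$pivot
  Vp <- chol2inv(qr.R(fit$qr))
  V <- matrix(0, length(beta), length(beta))
  V[piv, piv] <- Vp
  list(beta = beta, V = V)
}

#' Logistic regression imputation for a binary variable
#'
#' Fits logistic regression on complete cases, draws coefficients from the
#' asymptotic normal posterior `N(beta_hat, V_hat)`, computes
#' `p = exp(mu)/(1 + exp(mu))` for each missing case, and imputes a
#' Bernoulli draw. A single-class target imputes the constant class with a
#' warning.
#'
#' @param y binary (0/1) target with `NA`s.
#' @param X complete design matrix with intercept.
#' @param posterior use a posterior parameter draw (default) or the ML
#'   estimate.
#' @return filled vector; fitted probabilities of the missing cases attached
#'   as attribute `p_mis`.
#' @export
impute_logistic <- function(y, X, posterior = TRUE) {
  mis <- is.na(y)
  obs <- !mis
  yo <- y[obs]
  if (length(unique(yo)) < 2L) {
    warning("single-class binary target; imputing the constant class",
            call. = FALSE)
    y[mis] <- yo[1L]
    attr(y, "p_mis") <- rep(as.numeric(yo[1L]), sum(mis))
    return(y)
  }
  fit <- .logit_fit_core(X[obs, , drop = FALSE], yo)
  beta <- fit$beta
  if (posterior) {
    L <- t(chol(fit$V))
    beta <- beta + drop(L %*% stats::rnorm(length(beta)))
  }
  p <- stats::plogis(drop(X[mis, , drop = FALSE] %*% beta))
  y[mis] <- stats::rbinom(sum(mis), 1L, p)
  attr(y, "p_mis") <- p
  y
}

#' Polytomous regression imputation for a categorical variable
#'
#' Fits the multinomial logit with the last category as baseline on complete
#' cases, draws the coefficient vector from the asymptotic normal posterior,
#' computes the per-category probabilities for each missing case, and
#' imputes a categorical draw.
#'
#' @param y integer-coded categorical target with `NA`s.
#' @param X complete design matrix with intercept.
#' @param levels the category codes (e.g. `0:2`).
#' @param posterior use a posterior parameter draw (default) or the ML
#'   estimate.
#' @return filled vector; probability matrix of the missing cases attached
#'   as attribute `p_mis`.
#' @export
impute_polytomous <- function(y, X, levels = sort(unique(y[!is.na(y)])),
                              posterior = TRUE) {
  mis <- is.na(y)
  obs <- !mis
  yo <- y[obs]
  present <- sort(unique(yo))
  if (length(present) < 2L) {
    warning("single-class categorical target; imputing the constant class",
            call. = FALSE)
    y[mis] <- yo[1L]
    return(y)
  }
  base <- present[length(present)]
  fit <- .fit_multinomial(X[obs, , drop = FALSE], yo, baseline = base)
  Bv <- as.vector(fit$coef)
  if (posterior) {
    L <- t(chol((fit$vcov + t(fit$vcov)) / 2))
    Bv <- Bv + drop(L %*% stats::rnorm(length(Bv)))
  }
  B <- matrix(Bv, ncol(X), length(present) - 1L)
  Eta <- X[mis, , drop = FALSE] %*% B          # non-baseline categories
  M <- cbind(Eta, 0)                            # baseline (last) gets 0
  mx <- .row_max(M)
  E <- exp(M - mx)
  P <- E / rowSums(E)
  cats <- c(present[present != base], base)
  u <- stats::runif(nrow(P))
  cum <- .row_cumsum(P)
  pick <- rowSums(u > cum) + 1L
  y[mis] <- cats[pick]
  colnames(P) <- as.character(cats)
  attr(y, "p_mis") <- P
  y
}

#' Run chained-equations multiple imputation
#'
#' Produces m completed datasets. Each missing cell is initialized by a
#' random draw from its observed marginal; variables are then swept in fixed
#' order (gender, race/ethnicity, age, smoking, Medicaid, private insurance,
#' education) `n_cycles` times, re-imputing each from the current completed
#' values of its 5 most correlated predictors via the method matched to its
#' type. The m chains run independently with sub-seeds derived from the
#' master seed. In the default `covariates_only` mode the outcomes
#' (dentition, sroh) are never imputed; `impute_all` imputes them too;
#' `complete_case` performs listwise deletion instead of imputation.
#'
#' @param data coded analysis data.frame (with kde columns attached).
#' @param plan an [imputation_plan()].
#' @param mode `"covariates_only"` (default), `"impute_all"`, or
#'   `"complete_case"`.
#' @return object of class `imputed_set`: list with `datasets` (list of
#'   completed data.frames), `mask` (logical matrix of originally-missing
#'   cells), `plan`, `mode`, `predictors` (the selected predictor sets).
#' @export
run_chained <- function(data, plan = imputation_plan(),
                        mode = c("covariates_only", "impute_all",
                                 "complete_case")) {
  mode <- match.arg(mode)
  vars <- .imputable_vars(if (mode == "complete_case") "impute_all" else mode)
  if (mode == "complete_case") {
    keep <- stats::complete.cases(data[, vars])
    out <- list(datasets = list(data[keep, , drop = FALSE]),
                mask = NULL, plan = plan, mode = mode, predictors = NULL)
    class(out) <- "imputed_set"
    return(out)
  }
  mask <- vapply(vars, function(v) is.na(data[[v]]), logical(nrow(data)))
  all_missing <- colSums(!mask) == 0L
  if (any(all_missing))
    stop("variable(s) 100% missing, cannot impute: ",
         paste(vars[all_missing], collapse = ", "), call. = FALSE)
  to_impute <- vars[colSums(mask) > 0L]
  kde_cols <- grep("^kde_h", names(data), value = TRUE)
  cand_pool <- c(vars, kde_cols)
  predictors <- lapply(stats::setNames(to_impute, to_impute), function(v)
    select_predictors(data, v, candidates = setdiff(cand_pool, v),
                      n = plan$n_predictors))
  datasets <- vector("list", plan$m)
  for (kimp in seq_len(plan$m)) {
    set.seed(.sub_seed(plan$seed, 5L, kimp))
    cur <- data
    for (v in to_impute) {                     # marginal-draw initialization
      mis <- mask[, v]
      cur[[v]][mis] <- sample(data[[v]][!mis], sum(mis), replace = TRUE)
    }
    for (cyc in seq_len(plan$n_cycles)) {
      for (v in to_impute) {
        spec <- .spec_of(v)
        X <- .design_for(cur, predictors[[v]])
        yv <- cur[[v]]
        yv[mask[, v]] <- NA
        filled <- switch(spec$method,
          pmm        = impute_pmm(yv, X),
          logistic   = impute_logistic(yv, X),
          polytomous = impute_polytomous(yv, X, levels = spec$levels))
        cur[[v]] <- as.vector(filled)
      }
    }
    datasets[[kimp]] <- cur
  }
  out <- list(datasets = datasets, mask = mask, plan = plan, mode = mode,
              predictors = predictors)
  class(out) <- "imputed_set"
  out
}

#' @export
print.imputed_set <- function(x, ...) {
  cat("Multiply imputed set:", length(x$datasets), "dataset(s), mode =",
      x$mode, "\n")
  if (!is.null(x$mask))
    cat("missing cells per variable:\n")
  if (!is.null(x$mask)) print(colSums(x$mask))
  invisible(x)
}
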