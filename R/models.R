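# Maximum-likelihood fitting of the generalized adjacent-categories logistic
# regression (GACLR) for ordinal dentition status and of binary logistic
# regression for self-rated oral health, plus Rubin's-rules pooling across
# multiply imputed datasets.

.analysis_terms <- c("(Intercept)", "female", "nh_white", "nh_black",
                     "other_race", "age", "former_smoker", "never_smoker",
                     "medicaid", "private_ins", "edu_high_school",
                     "edu_college")

#' Build the analysis design matrix
#'
#' Expands a coded analysis table into the regression design used by all
#' models: intercept; female; race/ethnicity indicators (Hispanic reference);
#' age in years; smoking indicators (current-smoker reference); Medicaid and
#' private dental insurance; education indicators (primary-school reference);
#' and optionally one peer-density exposure column.
#'
#' @param data coded analysis data.frame (see [encode_covariates()]).
#' @param kde_column optional name of a `kde_h*` column to append.
#' @return numeric design matrix with named columns.
#' @export
analysis_design <- function(data, kde_column = NULL) {
  X <- cbind(
    `(Intercept)`   = 1,
    female          = data$gender01,
    nh_white        = as.numeric(data$race_eth == 1L),
    nh_black        = as.numeric(data$race_eth == 2L),
    other_race      = as.numeric(data$race_eth == 3L),
    age             = data$age,
    former_smoker   = as.numeric(data$smoking == 1L),
    never_smoker    = as.numeric(data$smoking == 2L),
    medicaid        = data$medicaid01,
    private_ins     = data$private01,
    edu_high_school = as.numeric(data$education == 1L),
    edu_college     = as.numeric(data$education == 2L)
  )
  if (!is.null(kde_column)) {
    if (!kde_column %in% names(data))
      stop("density column not found: ", kde_column, call. = FALSE)
    X <- cbind(X, data[[kde_column]])
    colnames(X)[ncol(X)] <- kde_column
  }
  X
}

# fast row-wise max / cumulative sum for matrices with few columns
.row_max <- function(M) {
  out <- M[, 1L]
  if (ncol(M) > 1L) for (j in 2:ncol(M)) out <- pmax(out, M[, j])
  out
}

.row_cumsum <- function(M) {
  if (ncol(M) > 1L) for (j in 2:ncol(M)) M[, j] <- M[, j] + M[, j - 1L]
  M
}

# Baseline-category multinomial logistic fit by damped Newton iterations.
# y takes values 0..(J-1); category `baseline` has linear predictor 0. The
# coefficient matrix has one column per non-baseline category, ordered by
# category. Convergence: gradient norm < tol; step-halving on likelihood
# decrease; optional ridge penalty stabilizes separated data.
.fit_multinomial <- function(X, y, baseline = 0L, tol = 1e-8, maxit = 100L,
                             ridge = 0) {
  # scale columns to unit max-magnitude so the gradient-norm stopping rule is
  # meaningful for covariates on very different scales (age in years, density
  # in persons per square mile); estimates are transformed back afterwards
  sc <- apply(X, 2L, function(cc) { m <- max(abs(cc)); if (m == 0) 1 else m })
  Xs <- sweep(X, 2L, sc, "/")
  res <- .fit_multinomial_core(Xs, y, baseline, tol, maxit, ridge)
  K <- ncol(res$coef)
  res$coef <- res$coef / sc
  Dinv <- diag(rep(1 / sc, K), ncol(X) * K)
  res$vcov <- Dinv %*% res$vcov %*% Dinv
  dimnames(res$coef) <- list(colnames(X), colnames(res$coef))
  res
}

.fit_multinomial_core <- function(X, y, baseline = 0L, tol = 1e-8,
                                  maxit = 100L, ridge = 0) {
  cats <- sort(unique(y))
  J <- length(cats)
  if (J < 2L) stop("outcome has a single category", call. = FALSE)
  if (!baseline %in% cats) stop("baseline category absent", call. = FALSE)
  other <- cats[cats != baseline]
  p <- ncol(X)
  n <- nrow(X)
  K <- J - 1L
  # indicator matrix for non-baseline categories
  Yind <- vapply(other, function(cc) as.numeric(y == cc), numeric(n))
  B <- matrix(0, p, K)
  loglik_at <- function(B) {
    Eta <- X %*% B
    M <- cbind(0, Eta)
    mx <- .row_max(M)
    lse <- mx + log(rowSums(exp(M - mx)))
    sum(rowSums(Yind * Eta)) - sum(lse) - 0.5 * ridge * sum(B^2)
  }
  ll <- loglik_at(B)
  for (it in seq_len(maxit)) {
    Eta <- X %*% B
    M <- cbind(0, Eta)
    mx <- .row_max(M)
    E <- exp(M - mx)
    P <- E[, -1L, drop = FALSE] / rowSums(E)   # probs of non-baseline cats
    G <- crossprod(X, Yind - P) - ridge * B    # p x K gradient
    gnorm <- sqrt(sum(G^2))
    if (gnorm < tol) break
    # observed information: K*K blocks of p x p
    H <- matrix(0, p * K, p * K)
    for (a in seq_len(K)) {
      for (b in a:K) {
        w <- P[, a] * ((a == b) - P[, b])
        blk <- crossprod(X, X * w)
        ia <- (a - 1L) * p + seq_len(p)
        ib <- (b - 1L) * p + seq_len(p)
        H[ia, ib] <- blk
        if (a != b) H[ib, ia] <- blk
      }
    }
    if (ridge > 0) H <- H + diag(ridge, p * K)
    step <- tryCatch(solve(H, as.vector(G)), error = function(e) NULL)
    if (is.null(step))
      stop("singular information matrix: design may be rank deficient",
           call. = FALSE)
    lambda <- 1
    repeat {
      Bnew <- B + lambda * matrix(step, p, K)
      llnew <- loglik_at(Bnew)
      if (is.finite(llnew) && llnew >= ll - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10)
        stop("GACLR/multinomial fit failed to improve the likelihood ",
             "(iteration ", it, ", gradient norm ", signif(gnorm, 3), ")",
             call. = FALSE)
    }
    B <- Bnew
    ll <- llnew
    if (it == maxit)
      stop("multinomial fit did not converge in ", maxit,
           " iterations (gradient norm ", signif(gnorm, 3), ")", call. = FALSE)
  }
  # covariance at the optimum
  Eta <- X %*% B
  M <- cbind(0, Eta)
  mx <- .row_max(M)
  E <- exp(M - mx)
  P <- E[, -1L, drop = FALSE] / rowSums(E)
  H <- matrix(0, p * K, p * K)
  for (a in seq_len(K)) {
    for (b in a:K) {
      w <- P[, a] * ((a == b) - P[, b])
      blk <- crossprod(X, X * w)
      ia <- (a - 1L) * p + seq_len(p)
      ib <- (b - 1L) * p + seq_len(p)
      H[ia, ib] <- blk
      if (a != b) H[ib, ia] <- blk
    }
  }
  if (ridge > 0) H <- H + diag(ridge, p * K)
  V <- solve(H)
  dimnames(B) <- list(colnames(X), paste0("cat", other))
  list(coef = B, vcov = V, loglik = ll, categories = cats,
       baseline = baseline, n = n, p = p)
}

# Intercept-only multinomial log-likelihood (closed form: category frequencies).
.loglik_null_multinomial <- function(y) {
  tab <- table(y)
  sum(tab * log(tab / sum(tab)))
}

#' Fit the generalized adjacent-categories logistic regression
#'
#' Ordinal model for three-level dentition status with category-specific
#' (non-proportional-odds) coefficients: for adjacent categories j and j+1,
#' `ln[P(Y = j+1) / P(Y = j)] = b_0j + b_1j X_1 + ... + b_qj X_q`.
#' The fit reparametrizes to a baseline-category multinomial logit (category
#' 0 baseline; cumulative sums of the panel linear predictors give the
#' multinomial predictors), maximizes by damped Newton iterations, and
#' recovers panel coefficients as successive differences with the covariance
#' transformed through the (linear) reparametrization.
#'
#' @param data coded analysis data.frame with a complete `dentition` column
#'   (rows with missing outcome are dropped).
#' @param kde_column name of the density exposure column to include, or NULL.
#' @param design optional pre-built design matrix (overrides `data`
#'   covariates); must then be paired with `outcome`.
#' @param outcome optional integer outcome vector 0..2 paired with `design`.
#' @return object of class `gaclr_fit`: named coefficient vector
#'   (`panelJ:term`), covariance, log-likelihoods, n, McFadden's R2.
#' @export
fit_gaclr <- function(data = NULL, kde_column = NULL, design = NULL,
                      outcome = NULL) {
  if (is.null(design)) {
    keep <- !is.na(data$dentition)
    data <- data[keep, , drop = FALSE]
    X <- analysis_design(data, kde_column)
    y <- data$dentition
  } else {
    X <- design
    y <- outcome
  }
  if (anyNA(X)) stop("design matrix contains missing values", call. = FALSE)
  cats <- sort(unique(y))
  J <- length(cats)
  if (J < 2L)
    stop("dentition outcome has fewer than 2 categories present", call. = FALSE)
  if (!identical(cats, seq_len(J) - 1) && !identical(cats, as.integer(seq_len(J) - 1L)))
    stop("outcome categories must be 0..J-1 with every category present; ",
         "collapse empty categories first", call. = FALSE)
  mfit <- .fit_multinomial(X, y, baseline = 0L)
  p <- ncol(X)
  K <- J - 1L
  # adjacent-category panels: theta_1 = gamma_1, theta_j = gamma_j - gamma_{j-1}
  A <- diag(K) ; if (K > 1L) for (j in 2:K) A[j, j - 1L] <- -1
  Afull <- kronecker(A, diag(p))
  theta <- as.vector(mfit$coef %*% t(A))
  V <- Afull %*% mfit$vcov %*% t(Afull)
  panels <- paste0("panel", seq_len(K) - 1L)
  nms <- as.vector(outer(colnames(X), panels, function(t, pn) paste0(pn, ":", t)))
  names(theta) <- nms
  dimnames(V) <- list(nms, nms)
  ll0 <- .loglik_null_multinomial(y)
  structure(list(
    coefficients = theta, vcov = V,
    loglik = mfit$loglik, loglik0 = ll0,
    n = mfit$n, k = length(theta),
    r2 = mcfadden_r2(mfit$loglik, ll0),
    panels = panels, terms = colnames(X)
  ), class = "gaclr_fit")
}

#' Fit the binary logistic regression for self-rated oral health
#'
#' Standard ML logistic regression (iteratively reweighted least squares via
#' `stats::glm.fit`) of the binary poor vs fair-or-better outcome on the same
#' covariate set as the ordinal model. If the fit fails to converge or shows
#' signs of separation (|coefficient| > 15 on the logit scale), it is re-fit
#' with a small ridge penalty and a warning.
#'
#' @param data coded analysis data.frame with a `sroh` column (rows with
#'   missing outcome dropped).
#' @param kde_column density exposure column name, or NULL.
#' @param design,outcome optional explicit design/outcome pair.
#' @return object of class `logit_fit` with the same fields as `gaclr_fit`.
#' @export
fit_logit <- function(data = NULL, kde_column = NULL, design = NULL,
                      outcome = NULL) {
  if (is.null(design)) {
    keep <- !is.na(data$sroh)
    data <- data[keep, , drop = FALSE]
    X <- analysis_design(data, kde_column)
    y <- data$sroh
  } else {
    X <- design
    y <- outcome
  }
  if (anyNA(X)) stop("design matrix contains missing values", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("binary outcome has a single class", call. = FALSE)
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = list(epsilon = 1e-12, maxit = 100L))
  )
  beta <- fit$coefficients
  if (!fit$converged || any(abs(beta) > 15)) {
    warning("possible separation in logistic fit; applying ridge stabilization",
            call. = FALSE)
    rfit <- .fit_multinomial(X, as.integer(y), baseline = 0L, ridge = 1e-4)
    beta <- drop(rfit$coef)
    V <- rfit$vcov
  } else {
    R <- qr.R(fit$qr)
    piv <- fit$qr$pivot
    Vp <- chol2inv(R)
    V <- matrix(NA_real_, length(beta), length(beta))
    V[piv, piv] <- Vp
  }
  eta <- drop(X %*% beta)
  ll <- sum(y * eta - log1p(exp(eta)))
  pbar <- mean(y)
  ll0 <- sum(y) * log(pbar) + sum(1 - y) * log(1 - pbar)
  names(beta) <- colnames(X)
  dimnames(V) <- list(colnames(X), colnames(X))
  structure(list(
    coefficients = beta, vcov = V,
    loglik = ll, loglik0 = ll0,
    n = length(y), k = length(beta),
    r2 = mcfadden_r2(ll, ll0),
    terms = colnames(X)
  ), class = "logit_fit")
}

#' McFadden's pseudo R-squared
#'
#' `1 - loglik / loglik0` against the intercept-only null; lies in `[0, 1)`
#' for a nested null with `loglik0 < 0`.
#'
#' @param loglik fitted-model log-likelihood.
#' @param loglik0 intercept-only log-likelihood (must be < 0).
#' @return numeric scalar.
#' @export
mcfadden_r2 <- function(loglik, loglik0) {
  if (!is.finite(loglik0) || loglik0 == 0)
    stop("McFadden's R2 undefined: null log-likelihood is 0", call. = FALSE)
  1 - loglik / loglik0
}

#' Significance stars
#'
#' Strict-inequality thresholds: `***` p < 0.01, `**` p < 0.05, `*` p < 0.10.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return character vector of star codes.
#' @export
significance_stars <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  ifelse(is.na(p), "",
         ifelse(p < 0.01, "***", ifelse(p < 0.05, "**",
                ifelse(p < 0.10, "*", ""))))
}

#' Pool per-imputation fits by Rubin's rules
#'
#' Combines m fits of the same model (identical parameterization) on m
#' imputed datasets: pooled estimate = mean of estimates; within-imputation
#' variance W = mean of squared SEs; between-imputation variance B = sample
#' variance of estimates; total variance `T = W + (1 + 1/m) B`. Degrees of
#' freedom follow the Barnard-Rubin small-sample formula with complete-data
#' df `n - k`; intervals and p-values use the t reference on the log-OR
#' scale, exponentiated to the OR scale.
#'
#' @param fits list of >= 2 `gaclr_fit` or `logit_fit` objects.
#' @param level confidence level (default 0.95).
#' @return data.frame of class `pooled_fit`: term, estimate (log-OR), se, df,
#'   statistic, p, or, ci_lo, ci_hi, stars; attributes m, W, B, r2 (mean
#'   McFadden's R2 across imputations), n, k.
#' @export
pool_rubin <- function(fits, level = 0.95) {
  m <- length(fits)
  if (m < 2L) stop("pooling needs at least 2 fits", call. = FALSE)
  nms <- names(stats::coef(fits[[1L]]))
  for (f in fits)
    if (!identical(names(stats::coef(f)), nms))
      stop("fits have mismatched parameterizations", call. = FALSE)
  Q <- matrix(vapply(fits, stats::coef, numeric(length(nms))),
              nrow = length(nms))
  U <- matrix(vapply(fits, function(f) diag(f$vcov), numeric(length(nms))),
              nrow = length(nms))
  qbar <- rowMeans(Q)
  W <- rowMeans(U)
  B <- apply(Q, 1L, stats::var)
  Tv <- W + (1 + 1 / m) * B
  n <- mean(vapply(fits, function(f) f$n, numeric(1)))
  k <- fits[[1L]]$k
  nu_com <- max(n - k, 1)
  lambda <- ifelse(Tv > 0, (1 + 1 / m) * B / Tv, 0)
  nu_old <- ifelse(lambda > 0, (m - 1) / lambda^2, Inf)
  nu_obs <- (nu_com + 1) / (nu_com + 3) * nu_com * (1 - lambda)
  df <- 1 / (1 / nu_old + 1 / nu_obs)
  se <- sqrt(Tv)
  stat <- qbar / se
  p <- 2 * stats::pt(-abs(stat), df)
  tq <- stats::qt(1 - (1 - level) / 2, df)
  out <- data.frame(
    term = nms, estimate = qbar, se = se, W = W, B = B, df = df,
    statistic = stat, p = p,
    or = exp(qbar), ci_lo = exp(qbar - tq * se), ci_hi = exp(qbar + tq * se),
    stars = significance_stars(p),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "m") <- m
  attr(out, "n") <- n
  attr(out, "k") <- k
  attr(out, "r2") <- mean(vapply(fits, function(f) f$r2, numeric(1)))
  class(out) <- c("pooled_fit", "data.frame")
  out
}

#' @export
coef.gaclr_fit <- function(object, ...) object$coefficients

#' @export
coef.logit_fit <- function(object, ...) object$coefficients

#' @export
vcov.gaclr_fit <- function(object, ...) object$vcov

#' @export
vcov.logit_fit <- function(object, ...) object$vcov

#' @export
logLik.gaclr_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
logLik.logit_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n, class = "logLik")
}

.fit_table <- function(x) {
  se <- sqrt(diag(x$vcov))
  z <- x$coefficients / se
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(term = names(x$coefficients), estimate = x$coefficients, se = se,
             or = exp(x$coefficients), p = p, stars = significance_stars(p),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.gaclr_fit <- function(x, ...) {
  cat("Generalized adjacent-categories logistic regression\n")
  cat("n =", x$n, " logLik =", format(x$loglik, digits = 6),
      " McFadden's R2 =", format(x$r2, digits = 4), "\n\n")
  print(.fit_table(x), digits = 4)
  invisible(x)
}

#' @export
print.logit_fit <- function(x, ...) {
  cat("Binary logistic regression\n")
  cat("n =", x$n, " logLik =", format(x$loglik, digits = 6),
      " McFadden's R2 =", format(x$r2, digits = 4), "\n\n")
  print(.fit_table(x), digits = 4)
  invisible(x)
}

#' @export
print.pooled_fit <- function(x, ...) {
  if (is.null(attr(x, "m"))) {   # subsetted table: plain printing
    print(as.data.frame(x), digits = 4)
    return(invisible(x))
  }
  cat("Rubin's-rules pooled estimates (m =", attr(x, "m"), "imputations)\n")
  cat("n =", attr(x, "n"), " mean McFadden's R2 =",
      format(attr(x, "r2"), digits = 4), "\n\n")
  print(as.data.frame(x), digits = 4)
  cat("---\n*** p < 0.01; ** p < 0.05; * p < 0.10\n")
  invisible(x)
}
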