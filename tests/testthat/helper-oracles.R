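# Independent oracles used across tests. These deliberately avoid the
# package's fitting code paths: the adjacent-categories likelihood is written
# directly in its panel parametrization and maximized with a generic
# quasi-Newton optimizer.

# log-likelihood of the adjacent-categories model, panel parametrization:
# par = c(theta_panel0, theta_panel1, ...), each of length ncol(X)
acl_loglik <- function(par, X, y, K) {
  p <- ncol(X)
  Theta <- matrix(par, p, K)
  eta <- X %*% Theta
  cum <- cbind(0, t(apply(eta, 1L, cumsum)))
  if (K == 1L) cum <- cbind(0, eta)
  mx <- apply(cum, 1L, max)
  lse <- mx + log(rowSums(exp(cum - mx)))
  sum(cum[cbind(seq_along(y), y + 1L)]) - sum(lse)
}

acl_grad <- function(par, X, y, K) {
  p <- ncol(X)
  Theta <- matrix(par, p, K)
  eta <- X %*% Theta
  cum <- cbind(0, t(apply(eta, 1L, cumsum)))
  if (K == 1L) cum <- cbind(0, eta)
  mx <- apply(cum, 1L, max)
  E <- exp(cum - mx)
  P <- E / rowSums(E)                     # n x (K+1) category probabilities
  g <- vapply(seq_len(K), function(l) {
    resid <- as.numeric(y >= l) - rowSums(P[, (l + 1L):(K + 1L), drop = FALSE])
    crossprod(X, resid)
  }, numeric(p))
  as.vector(g)
}

# brute-force maximization of the adjacent-categories likelihood
oracle_fit_acl <- function(X, y, K = 2L) {
  opt <- stats::optim(rep(0, ncol(X) * K), fn = acl_loglik, gr = acl_grad,
                      X = X, y = y, K = K, method = "BFGS",
                      control = list(fnscale = -1, maxit = 2000,
                                     reltol = 1e-15))
  opt$par
}

# brute-force maximization of the baseline-category multinomial likelihood
# (category 0 baseline), used for the reparametrization identity
oracle_fit_multinom <- function(X, y, K = 2L) {
  nll <- function(par) {
    G <- matrix(par, ncol(X), K)
    M <- cbind(0, X %*% G)
    mx <- apply(M, 1L, max)
    lse <- mx + log(rowSums(exp(M - mx)))
    -(sum(M[cbind(seq_along(y), y + 1L)]) - sum(lse))
  }
  opt <- stats::optim(rep(0, ncol(X) * K), nll, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-15))
  matrix(opt$par, ncol(X), K)
}

# naive double-loop kernel density sum (both normalization modes)
oracle_density <- function(px, py, blocks, h, mode) {
  n <- length(px)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (b in seq_len(nrow(blocks))) {
      d <- sqrt((px[i] - blocks$x_mi[b])^2 + (py[i] - blocks$y_mi[b])^2)
      if (d <= h) {
        if (mode == "planar2d") {
          acc <- acc + blocks$count[b] * (2 / (pi * h^2)) * (1 - d^2 / h^2)
        } else {
          acc <- acc + blocks$count[b] * 0.75 * (1 - (d / h)^2)
        }
      }
    }
    out[i] <- if (mode == "planar2d") acc else acc / (sum(blocks$count) * h)
  }
  out
}

# random small GACLR instance with well-scaled covariates
random_acl_instance <- function(seed, n = 250L, q = 3L) {
  set.seed(seed)
  X <- cbind(1, matrix(rnorm(n * q), n, q))
  colnames(X) <- c("(Intercept)", paste0("x", seq_len(q)))
  Theta <- matrix(runif(2 * (q + 1), -0.8, 0.8), q + 1, 2)
  eta <- X %*% Theta
  P <- peerdensity::gaclr_probs(eta)
  u <- runif(n)
  y <- as.integer((u > P[, 1]) + (u > P[, 1] + P[, 2]))
  if (length(unique(y)) < 3L) return(random_acl_instance(seed + 1000L, n, q))
  list(X = X, y = y)
}
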