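# Synthetic cohort generator: clustered census blocks, participants with
# categorical covariates drawn from study-sample marginals, outcomes generated
# from known adjacent-categories and logistic coefficients, and a
# missing-at-random masking mechanism. Every downstream stage of the pipeline
# is testable against the known truth without any external data.

.default_gaclr_truth <- function() {
  terms <- c(.analysis_terms, "kde")
  # Log odds-ratio scale. Covariate effects follow the magnitudes reported for
  # the most local (0.25-mile) spatial model of the study sample; intercepts
  # are set so the three dentition categories have realistic prevalence at the
  # covariate means; the per-unit density effect is chosen so one SD of
  # synthetic density corresponds to an OR of roughly 0.85-0.88.
  panel0 <- c(-1.90, 0.189, -1.139, 0.086, -0.523, 0.0372, -0.130, -0.571,
              0.372, -0.135, 0.062, -0.102, -1.27e-05)
  panel1 <- c(-2.40, -0.120, -0.067, 0.019, -0.625, 0.0261, -0.092, -0.207,
              0.400, 0.358, -0.363, -0.732, -1.0e-06)
  m <- rbind(panel0 = panel0, panel1 = panel1)
  colnames(m) <- terms
  m
}

.default_logit_truth <- function() {
  stats::setNames(
    c(0.75, -0.097, 0.071, -0.546, -0.323, 0.0034, 0.130, 0.166,
      0.297, 0.416, 0.021, -0.245, 9.5e-06),
    c(.analysis_terms, "kde"))
}

#' Configuration for the synthetic cohort
#'
#' Bundles every knob of the generator. Defaults emulate the study sample:
#' covariate marginals and per-variable missingness rates follow the cohort
#' description table (72.7% female, 57.2% Hispanic, age mean 73.48 / SD 10.07
#' truncated to 50-105, smoking missing for 24.8% of records, and so on);
#' blocks are laid out on a jittered grid with cluster-concentrated counts so
#' the density surface shows the strong local variation of an urban block
#' grid.
#'
#' @param seed master RNG seed.
#' @param n_blocks number of census blocks.
#' @param n_participants cohort size (default 1822, the study sample size).
#' @param extent_mi side of the square study region in miles (must exceed
#'   twice the largest bandwidth).
#' @param n_clusters number of population clusters (0 = spatially homogeneous).
#' @param cluster_sd_mi spatial spread of each cluster (miles).
#' @param total_pop expected total 50+ population across blocks.
#' @param background_share share of population spread uniformly rather than
#'   in clusters.
#' @param jitter_sd_mi SD of residential jitter around the home block centroid.
#' @param marginals named list of covariate category probabilities.
#' @param age_mean,age_sd,age_range truncated-normal age model.
#' @param miss_rates named missingness rates per maskable variable.
#' @param gaclr_coefs 2 x 13 true coefficient matrix (panels x terms,
#'   final term = per-unit density effect).
#' @param logit_coefs length-13 true coefficient vector for the binary model.
#' @param coef_bandwidth bandwidth (miles) whose density column the true
#'   coefficients reference.
#' @param bandwidths bandwidths at which exposures are attached.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_blocks = 900L,
                         n_participants = 1822L,
                         extent_mi = 6,
                         n_clusters = 6L,
                         cluster_sd_mi = 0.6,
                         total_pop = 360000,
                         background_share = 0.15,
                         jitter_sd_mi = 0.02,
                         marginals = list(
                           gender    = c(male = 0.273, female = 0.727),
                           race_eth  = c(Hispanic = 0.572, `NH-White` = 0.112,
                                         `NH-Black` = 0.282, Other = 0.0346),
                           smoking   = c(current = 0.116, former = 0.303,
                                         never = 0.581),
                           medicaid  = c(no = 0.483, yes = 0.517),
                           private   = c(no = 0.933, yes = 0.0674),
                           education = c(primary = 0.378,
                                         `high school` = 0.350,
                                         college = 0.269)
                         ),
                         age_mean = 73.48, age_sd = 10.07,
                         age_range = c(50, 105),
                         miss_rates = c(gender = 0.00933, race_eth = 0.0483,
                                        age = 0.0214, smoking = 0.248,
                                        medicaid = 0.138, private = 0.137,
                                        education = 0.115,
                                        dentition = 0.182, sroh = 0.154),
                         gaclr_coefs = .default_gaclr_truth(),
                         logit_coefs = .default_logit_truth(),
                         coef_bandwidth = 0.25,
                         bandwidths = c(0.25, 0.5, 1, 1.5)) {
  cfg <- list(seed = as.integer(seed), n_blocks = as.integer(n_blocks),
              n_participants = as.integer(n_participants),
              extent_mi = extent_mi, n_clusters = as.integer(n_clusters),
              cluster_sd_mi = cluster_sd_mi, total_pop = total_pop,
              background_share = background_share, jitter_sd_mi = jitter_sd_mi,
              marginals = marginals, age_mean = age_mean, age_sd = age_sd,
              age_range = age_range, miss_rates = miss_rates,
              gaclr_coefs = gaclr_coefs, logit_coefs = logit_coefs,
              coef_bandwidth = coef_bandwidth, bandwidths = bandwidths)
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  stopifnot(cfg$n_blocks > 0, cfg$n_participants >= 0, cfg$total_pop > 0)
  if (cfg$extent_mi <= 2 * max(cfg$bandwidths))
    stop("extent must exceed twice the largest bandwidth", call. = FALSE)
  if (any(cfg$miss_rates < 0 | cfg$miss_rates > 1))
    stop("missingness rates must lie in [0, 1]", call. = FALSE)
  for (mg in cfg$marginals)
    if (any(mg < 0)) stop("marginal probabilities must be >= 0", call. = FALSE)
  if (!all(dim(cfg$gaclr_coefs) == c(2L, 13L)))
    stop("gaclr_coefs must be a 2 x 13 matrix (2 panels x 13 terms)",
         call. = FALSE)
  if (length(cfg$logit_coefs) != 13L)
    stop("logit_coefs must have 13 terms", call. = FALSE)
  invisible(cfg)
}

# deterministic sub-seed derivation from the master seed, kept below 2^31
.sub_seed <- function(seed, stage, k = 0L) {
  as.integer((as.double(seed) * 48271 + stage * 100003 + k * 7919) %% 2147483629)
}

#' Generate census-block centroids with clustered population counts
#'
#' Blocks sit on a jittered square grid over the study region. Expected
#' counts mix a uniform background with Gaussian population clusters
#' (emulating the strong block-to-block variation of an urban 50+
#' population); realized counts are Poisson draws. Deterministic given the
#' config seed.
#'
#' @param config a [synth_config()].
#' @return data.frame `x_mi, y_mi, count`.
#' @export
generate_blocks <- function(config) {
  validate_synth_config(config)
  set.seed(.sub_seed(config$seed, 1L))
  g <- ceiling(sqrt(config$n_blocks))
  sp <- config$extent_mi / g
  centers <- expand.grid(ix = seq_len(g) - 0.5, iy = seq_len(g) - 0.5)
  centers <- centers[seq_len(config$n_blocks), , drop = FALSE]
  x <- centers$ix * sp + stats::rnorm(config$n_blocks, 0, sp / 6)
  y <- centers$iy * sp + stats::rnorm(config$n_blocks, 0, sp / 6)
  w <- rep(1 / config$extent_mi^2, config$n_blocks)  # uniform background
  if (config$n_clusters > 0L) {
    cx <- stats::runif(config$n_clusters, 0.15, 0.85) * config$extent_mi
    cy <- stats::runif(config$n_clusters, 0.15, 0.85) * config$extent_mi
    clw <- rep(0, config$n_blocks)
    for (cc in seq_len(config$n_clusters)) {
      d2 <- (x - cx[cc])^2 + (y - cy[cc])^2
      clw <- clw + exp(-d2 / (2 * config$cluster_sd_mi^2))
    }
    w <- config$background_share * w / sum(w) +
      (1 - config$background_share) * clw / sum(clw)
  } else {
    w <- w / sum(w)
  }
  lambda <- config$total_pop * w
  data.frame(x_mi = x, y_mi = y, count = stats::rpois(config$n_blocks, lambda))
}

#' Generate raw participants (covariates complete, outcomes absent)
#'
#' Residences are sampled at block centroids with probability proportional to
#' the block's 50+ count, plus small positional jitter; covariates are drawn
#' independently from the configured marginals; age is truncated-normal.
#'
#' @param config a [synth_config()].
#' @param blocks block table from [generate_blocks()].
#' @return raw participant data.frame (standard participant columns;
#'   `missing_teeth` and `sroh4` are `NA`).
#' @export
generate_participants <- function(config, blocks) {
  validate_blocks(blocks)
  set.seed(.sub_seed(config$seed, 2L))
  n <- config$n_participants
  if (n == 0L) {
    out <- data.frame(id = character(0), x_mi = numeric(0), y_mi = numeric(0),
                      age = numeric(0), gender = character(0),
                      race_eth = character(0), smoking = character(0),
                      medicaid = character(0), private_ins = character(0),
                      education = character(0), missing_teeth = numeric(0),
                      sroh4 = character(0), stringsAsFactors = FALSE)
    return(out)
  }
  idx <- sample.int(nrow(blocks), n, replace = TRUE, prob = blocks$count)
  draw <- function(mg) sample(names(mg), n, replace = TRUE, prob = mg / sum(mg))
  # truncated normal age by rejection
  age <- numeric(0)
  while (length(age) < n) {
    cand <- stats::rnorm(2L * n, config$age_mean, config$age_sd)
    age <- c(age, cand[cand >= config$age_range[1] & cand <= config$age_range[2]])
  }
  data.frame(
    id = sprintf("P%05d", seq_len(n)),
    x_mi = blocks$x_mi[idx] + stats::rnorm(n, 0, config$jitter_sd_mi),
    y_mi = blocks$y_mi[idx] + stats::rnorm(n, 0, config$jitter_sd_mi),
    age = round(age[seq_len(n)], 1),
    gender = draw(config$marginals$gender),
    race_eth = draw(config$marginals$race_eth),
    smoking = draw(config$marginals$smoking),
    medicaid = draw(config$marginals$medicaid),
    private_ins = draw(config$marginals$private),
    education = draw(config$marginals$education),
    missing_teeth = NA_real_,
    sroh4 = NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Category probabilities of the adjacent-categories model
#'
#' Inverts the adjacent-categories form: with panel linear predictors
#' `eta_j` (j = 0 .. J-2), `P(Y = j)` is proportional to
#' `exp(sum_{k < j} eta_k)` (an empty sum is 0). Exposed for testing and for
#' the outcome generator.
#'
#' @param eta matrix n x (J-1) of panel linear predictors.
#' @return n x J matrix of category probabilities (rows sum to 1).
#' @export
gaclr_probs <- function(eta) {
  eta <- as.matrix(eta)
  cum <- cbind(0, .row_cumsum(eta))
  mx <- .row_max(cum)
  E <- exp(cum - mx)
  E / rowSums(E)
}

#' Generate outcomes from known coefficients
#'
#' Draws the ordinal dentition category from the adjacent-categories model
#' and a missing-tooth count uniformly within the category's range (0-8 /
#' 9-27 / 28); draws the binary self-rated outcome from the logistic model
#' and expands it to the 4-level scale (poor if 0, else uniformly
#' fair/good/excellent).
#'
#' @param coded coded analysis data.frame with the density column attached at
#'   the bandwidth the true coefficients reference.
#' @param gaclr_coefs 2 x 13 panel coefficient matrix.
#' @param logit_coefs length-13 coefficient vector.
#' @param kde_column density column name.
#' @param seed RNG seed.
#' @return list `missing_teeth` (integer), `sroh4` (character),
#'   `dentition` and `sroh` (the generated codes).
#' @export
generate_outcomes <- function(coded, gaclr_coefs, logit_coefs, kde_column,
                              seed = 1L) {
  X <- analysis_design(coded, kde_column)
  if (ncol(X) != ncol(gaclr_coefs) || ncol(X) != length(logit_coefs))
    stop("coefficient dimension mismatch: design has ", ncol(X), " columns",
         call. = FALSE)
  set.seed(.sub_seed(seed, 3L))
  n <- nrow(X)
  eta <- X %*% t(gaclr_coefs)          # n x 2 panel predictors
  P <- gaclr_probs(eta)
  u <- stats::runif(n)
  dentition <- as.integer((u > P[, 1]) + (u > P[, 1] + P[, 2]))
  missing_teeth <- integer(n)
  missing_teeth[dentition == 0L] <- sample(0:8, sum(dentition == 0L), TRUE)
  missing_teeth[dentition == 1L] <- sample(9:27, sum(dentition == 1L), TRUE)
  missing_teeth[dentition == 2L] <- 28L
  p1 <- stats::plogis(drop(X %*% logit_coefs))
  sroh <- stats::rbinom(n, 1L, p1)
  sroh4 <- ifelse(sroh == 0L, "poor",
                  sample(c("fair", "good", "excellent"), n, TRUE))
  list(missing_teeth = missing_teeth, sroh4 = sroh4,
       dentition = dentition, sroh = as.integer(sroh))
}

#' Impose missing-at-random missingness
#'
#' For each maskable variable, the missingness indicator follows a logistic
#' model whose predictors are the always-observed age (by decile, centred)
#' and gender, with the intercept calibrated so the marginal missingness
#' rate matches the configured rate in expectation. Age and gender
#' themselves are masked completely at random. Returns the masked table and
#' the mask so recovery against the retained truth can be tested.
#'
#' @param raw complete raw participant table.
#' @param rates named missingness rates (names among gender, race_eth, age,
#'   smoking, medicaid, private, education, dentition, sroh).
#' @param seed RNG seed.
#' @return list `data` (masked raw table), `mask` (logical matrix, TRUE =
#'   masked).
#' @export
impose_missingness <- function(raw, rates, seed = 1L) {
  set.seed(.sub_seed(seed, 4L))
  n <- nrow(raw)
  col_of <- c(gender = "gender", race_eth = "race_eth", age = "age",
              smoking = "smoking", medicaid = "medicaid",
              private = "private_ins", education = "education",
              dentition = "missing_teeth", sroh = "sroh4")
  dec <- as.numeric(cut(raw$age, stats::quantile(raw$age, 0:10 / 10),
                        include.lowest = TRUE, labels = FALSE))
  score <- 0.3 * as.numeric(scale(ifelse(is.na(dec), mean(dec, na.rm = TRUE), dec))) +
           0.3 * (ifelse(is.na(raw$gender), mean(raw$gender == "female", na.rm = TRUE),
                         as.numeric(raw$gender == "female")) -
                  mean(raw$gender == "female", na.rm = TRUE))
  mask <- matrix(FALSE, n, length(col_of),
                 dimnames = list(NULL, names(col_of)))
  out <- raw
  for (v in names(rates)) {
    r <- rates[[v]]
    if (is.na(r) || r <= 0 || !v %in% names(col_of)) next
    s <- if (v %in% c("age", "gender")) rep(0, n) else score
    alpha <- stats::uniroot(function(a) mean(stats::plogis(a + s)) - r,
                            c(-30, 30))$root
    mk <- stats::rbinom(n, 1L, stats::plogis(alpha + s)) == 1L
    mask[, v] <- mk
    out[[col_of[[v]]]][mk] <- NA
  }
  list(data = out, mask = mask)
}

#' Simulate a complete synthetic cohort
#'
#' End-to-end generator: blocks, participants, density attachment at the
#' truth bandwidth, outcomes from the true coefficients, and MAR masking.
#'
#' @param config a [synth_config()].
#' @param kernel_mode kernel mode for exposure attachment.
#' @return list with `blocks`, `participants` (masked raw table),
#'   `truth` (complete raw table, true coefficients, mask, the coded complete
#'   table with all bandwidth exposures).
#' @export
simulate_cohort <- function(config = synth_config(), kernel_mode = "planar2d") {
  blocks <- generate_blocks(config)
  raw <- generate_participants(config, blocks)
  coded <- encode_covariates(raw)
  coded <- attach_density(coded, blocks, config$bandwidths, kernel_mode)
  kcol <- kde_col(config$coef_bandwidth)
  oc <- generate_outcomes(coded, config$gaclr_coefs, config$logit_coefs,
                          kcol, seed = config$seed)
  raw$missing_teeth <- oc$missing_teeth
  raw$sroh4 <- oc$sroh4
  coded$dentition <- oc$dentition
  coded$sroh <- oc$sroh
  masked <- impose_missingness(raw, config$miss_rates, seed = config$seed)
  list(
    blocks = blocks,
    participants = masked$data,
    truth = list(participants = raw, coded = coded,
                 gaclr_coefs = config$gaclr_coefs,
                 logit_coefs = config$logit_coefs,
                 mask = masked$mask, config = config)
  )
}
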