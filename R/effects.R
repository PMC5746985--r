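# Derived effect measures on fitted odds ratios: combined-panel products,
# per-standard-deviation and per-decade scaling, and percent-change reporting.

#' Combine adjacent-panel odds ratios
#'
#' For the adjacent-categories model, the odds ratio for the extreme contrast
#' (edentulous vs functional dentition) is the product of the two panel odds
#' ratios (limited-vs-functional times edentulous-vs-limited), because the
#' panel log-odds add.
#'
#' @param or_upper odds ratio for the lower panel contrast (category 1 vs 0).
#' @param or_lower odds ratio for the upper panel contrast (category 2 vs 1).
#' @return combined odds ratio (category 2 vs 0).
#' @export
combined_or <- function(or_upper, or_lower) {
  if (any(or_upper <= 0) || any(or_lower <= 0))
    stop("odds ratios must be positive", call. = FALSE)
  or_upper * or_lower
}

#' Rescale a per-unit odds ratio to a different increment
#'
#' A per-unit OR raised to the power `delta` gives the OR for a
#' `delta`-unit change (log-odds are linear in the covariate):
#' `scaled = or^delta = exp(delta * log(or))`. Used to express the density
#' effect per standard deviation and the age effect per decade.
#'
#' @param or_per_unit per-unit odds ratio, > 0.
#' @param delta change in covariate units (e.g. one SD of density, 10 years).
#' @return scaled odds ratio.
#' @export
scaled_or <- function(or_per_unit, delta) {
  if (any(or_per_unit <= 0)) stop("odds ratio must be positive", call. = FALSE)
  exp(delta * log(or_per_unit))
}

#' Percent change implied by an odds ratio
#'
#' Signed integer percent, `round(100 * (or - 1))`, rounding halves away
#' from zero. Note that `percent_change(1/x)` is not `-percent_change(x)` in
#' general; the asymmetry is inherent to the ratio scale.
#'
#' @param or odds ratio, > 0.
#' @return signed integer percent.
#' @export
percent_change <- function(or) {
  if (any(or <= 0)) stop("odds ratio must be positive", call. = FALSE)
  x <- 100 * (or - 1)
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Confidence interval for a rescaled odds ratio
#'
#' The increment acts linearly on the log scale, so the scaled interval is
#' `exp(delta * log_or +/- z * delta * se)`.
#'
#' @param log_or per-unit log odds ratio.
#' @param se standard error of `log_or`, >= 0.
#' @param delta covariate increment.
#' @param level confidence level (default 0.95).
#' @return named vector `or, lo, hi` on the scaled OR scale.
#' @export
scaled_ci <- function(log_or, se, delta, level = 0.95) {
  if (se < 0) stop("se must be >= 0", call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(or = exp(delta * log_or),
    lo = exp(delta * log_or - z * abs(delta) * se),
    hi = exp(delta * log_or + z * abs(delta) * se))
}

#' Format an odds ratio the way near-unity density effects are reported
#'
#' Density ORs per person/sq-mile sit very close to 1 and are reported to 7
#' decimal places; all other ORs to 4.
#'
#' @param or odds ratio vector.
#' @return character vector.
#' @export
format_or <- function(or) {
  ifelse(abs(or - 1) < 0.01, sprintf("%.7f", or), sprintf("%.4f", or))
}

#' Effect summary table for a pooled fit
#'
#' Builds per-unit, per-SD (density) and per-decade (age) effect rows from a
#' pooled coefficient table, reporting scaled ORs and integer percent
#' changes.
#'
#' @param pooled a `pooled_fit` data.frame.
#' @param density_sd sample SD of the density exposure used for per-SD
#'   scaling.
#' @param density_term name of the density term (e.g. `"kde_h0.25"`).
#' @return data.frame `term, scale, delta, or, percent, ci_lo, ci_hi`.
#' @export
effect_table <- function(pooled, density_sd = NULL, density_term = NULL) {
  rows <- list()
  for (i in seq_len(nrow(pooled))) {
    tm <- pooled$term[i]
    est <- pooled$estimate[i]
    se <- pooled$se[i]
    base <- grepl(":", tm, fixed = TRUE)
    nm <- sub("^panel[0-9]+:", "", tm)
    delta <- 1
    scale <- "per_unit"
    if (!is.null(density_term) && nm == density_term && !is.null(density_sd)) {
      delta <- density_sd
      scale <- "per_sd"
    } else if (nm == "age") {
      delta <- 10
      scale <- "per_decade"
    }
    ci <- scaled_ci(est, se, delta)
    rows[[i]] <- data.frame(term = tm, scale = scale, delta = delta,
                            or = ci[["or"]], percent = percent_change(ci[["or"]]),
                            ci_lo = ci[["lo"]], ci_hi = ci[["hi"]],
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
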