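# Small fixture builders shared across test files.

toy_raw_participants <- function() {
  data.frame(
    id = c("A1", "A2", "A3", "A4"),
    x_mi = c(0.1, 0.2, 0.3, 0.4),
    y_mi = c(0.1, 0.2, 0.3, 0.4),
    age = c(65, 72, NA, 80),
    gender = c("female", "male", "female", "female"),
    race_eth = c("Hispanic", "NH-White", "NH-Black", "Other"),
    smoking = c("current", "former", "never", NA),
    medicaid = c("yes", "no", "yes", "no"),
    private_ins = c("no", "no", "yes", "no"),
    education = c("primary", "high school", "college", NA),
    missing_teeth = c(3, 12, 28, NA),
    sroh4 = c("poor", "fair", "excellent", "good"),
    stringsAsFactors = FALSE
  )
}

toy_blocks <- function() {
  data.frame(x_mi = c(0, 1, 0.5), y_mi = c(0, 0, 1), count = c(100L, 50L, 200L))
}

# coded analysis table with n rows, complete, plus a density column
toy_coded <- function(n = 200L, seed = 1L) {
  set.seed(seed)
  data.frame(
    id = sprintf("T%04d", seq_len(n)),
    x_mi = runif(n), y_mi = runif(n),
    dentition = sample(0:2, n, TRUE),
    sroh = sample(0:1, n, TRUE),
    gender01 = sample(0:1, n, TRUE, prob = c(0.3, 0.7)),
    race_eth = sample(0:3, n, TRUE),
    age = round(runif(n, 50, 100), 1),
    smoking = sample(0:2, n, TRUE),
    medicaid01 = sample(0:1, n, TRUE),
    private01 = sample(0:1, n, TRUE, prob = c(0.9, 0.1)),
    education = sample(0:2, n, TRUE),
    kde_h0.25 = runif(n, 1000, 40000),
    stringsAsFactors = FALSE
  )
}

small_synth_config <- function(seed = 1L, n = 400L) {
  peerdensity::synth_config(seed = seed, n_participants = n, n_blocks = 250L,
                            extent_mi = 4, n_clusters = 4L, total_pop = 160000)
}
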