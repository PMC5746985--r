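# Cohort data model: raw participant ingestion, outcome derivation, and
# covariate coding for the oral-health regression models.

# Category labels and their integer codes. The first level of each set is the
# reference category used throughout the regression models.
.gender_levels   <- c("male", "female")
.race_levels     <- c("Hispanic", "NH-White", "NH-Black", "Other")
.smoking_levels  <- c("current", "former", "never")
.yesno_levels    <- c("no", "yes")
.edu_levels      <- c("primary", "high school", "college")
.sroh_levels     <- c("poor", "fair", "good", "excellent")

.participant_header <- c("id", "x_mi", "y_mi", "age", "gender", "race_eth",
                         "smoking", "medicaid", "private_ins", "education",
                         "missing_teeth", "sroh4")
.block_header <- c("x_mi", "y_mi", "count")

#' Classify dentition status from a missing-tooth count
#'
#' Maps a count of missing teeth (out of a complete dentition of 28, third
#' molars excluded) to the three-level ordinal dentition status used as the
#' primary outcome: 0 = functional dentition (0-8 missing), 1 = limited
#' functional capacity (9-27 missing), 2 = edentulous (all 28 missing).
#'
#' @param missing_teeth integer vector of missing-tooth counts in 0..28.
#'   `NA` entries pass through as `NA`.
#' @param id optional identifiers used in error messages.
#' @return integer vector of dentition codes in \{0, 1, 2\}.
#' @export
classify_dentition <- function(missing_teeth, id = NULL) {
  x <- missing_teeth
  ok <- is.na(x) | (is.finite(x) & x == round(x) & x >= 0 & x <= 28)
  if (!all(ok)) {
    bad <- which(!ok)
    lab <- if (is.null(id)) bad else id[bad]
    stop("invalid missing_teeth count (must be an integer in 0..28) for record(s): ",
         paste(utils::head(lab, 5L), collapse = ", "), call. = FALSE)
  }
  out <- ifelse(is.na(x), NA_integer_,
                ifelse(x <= 8L, 0L, ifelse(x <= 27L, 1L, 2L)))
  as.integer(out)
}

#' Binarize self-rated oral health
#'
#' Collapses the four-level self-rating to the binary outcome analysed in the
#' logistic models: 0 = poor, 1 = at least fair (fair/good/excellent).
#'
#' @param rating character vector with levels poor/fair/good/excellent;
#'   `NA` passes through.
#' @return integer vector in \{0, 1\}.
#' @export
binarize_sroh <- function(rating) {
  known <- is.na(rating) | rating %in% .sroh_levels
  if (!all(known)) {
    stop("unknown self-rated oral health level(s): ",
         paste(unique(rating[!known]), collapse = ", "), call. = FALSE)
  }
  as.integer(ifelse(is.na(rating), NA_integer_,
                    ifelse(rating == "poor", 0L, 1L)))
}

.code_factor <- function(x, levels, what) {
  known <- is.na(x) | x %in% levels
  if (!all(known)) {
    stop("unmapped ", what, " label(s): ",
         paste(unique(x[!known]), collapse = ", "), call. = FALSE)
  }
  as.integer(match(x, levels) - 1L)
}

#' Encode raw participant records into the coded analysis table
#'
#' Applies the covariate coding scheme: binary gender (reference male),
#' race/ethnicity 0-3 (reference Hispanic), continuous age, smoking 0-2
#' (reference current smoker), binary Medicaid and private dental insurance
#' (reference no coverage), education 0-2 (reference primary school), and
#' derives the two outcomes (ordinal dentition status from the missing-tooth
#' count; binarized self-rated oral health). Missing cells remain `NA`.
#'
#' @param raw data.frame with the raw participant columns
#'   (`id, x_mi, y_mi, age, gender, race_eth, smoking, medicaid, private_ins,
#'   education, missing_teeth, sroh4`).
#' @return data.frame with columns `id, x_mi, y_mi, dentition, sroh, gender01,
#'   race_eth, age, smoking, medicaid01, private01, education`.
#' @export
encode_covariates <- function(raw) {
  need <- .participant_header
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0L)
    stop("participant table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  age <- as.numeric(raw$age)
  bad_age <- !is.na(age) & (age < 18 | age > 120)
  if (any(bad_age))
    stop("implausible age outside [18, 120] for record(s): ",
         paste(utils::head(raw$id[bad_age], 5L), collapse = ", "), call. = FALSE)
  data.frame(
    id         = raw$id,
    x_mi       = as.numeric(raw$x_mi),
    y_mi       = as.numeric(raw$y_mi),
    dentition  = classify_dentition(as.numeric(raw$missing_teeth), id = raw$id),
    sroh       = binarize_sroh(as.character(raw$sroh4)),
    gender01   = .code_factor(raw$gender, .gender_levels, "gender"),
    race_eth   = .code_factor(raw$race_eth, .race_levels, "race/ethnicity"),
    age        = age,
    smoking    = .code_factor(raw$smoking, .smoking_levels, "smoking"),
    medicaid01 = .code_factor(raw$medicaid, .yesno_levels, "medicaid"),
    private01  = .code_factor(raw$private_ins, .yesno_levels, "private insurance"),
    education  = .code_factor(raw$education, .edu_levels, "education"),
    stringsAsFactors = FALSE
  )
}

#' Decode a coded analysis table back to category labels
#'
#' Inverse of [encode_covariates()] on the covariate columns (outcome columns
#' are derived, not invertible, and are omitted). Used for round-trip checks.
#'
#' @param coded data.frame as returned by [encode_covariates()].
#' @return data.frame with labelled covariate columns.
#' @export
decode_covariates <- function(coded) {
  lab <- function(x, levels) ifelse(is.na(x), NA_character_, levels[x + 1L])
  data.frame(
    id          = coded$id,
    age         = coded$age,
    gender      = lab(coded$gender01, .gender_levels),
    race_eth    = lab(coded$race_eth, .race_levels),
    smoking     = lab(coded$smoking, .smoking_levels),
    medicaid    = lab(coded$medicaid01, .yesno_levels),
    private_ins = lab(coded$private01, .yesno_levels),
    education   = lab(coded$education, .edu_levels),
    stringsAsFactors = FALSE
  )
}

#' Read a participant CSV
#'
#' Expects the exact header
#' `id,x_mi,y_mi,age,gender,race_eth,smoking,medicaid,private_ins,education,missing_teeth,sroh4`.
#' Empty cells and the literal string `NA` parse as missing.
#'
#' @param path file path.
#' @return raw participant data.frame.
#' @export
read_participants <- function(path) {
  hdr <- names(utils::read.csv(path, nrows = 1L, check.names = FALSE))
  if (!identical(hdr, .participant_header))
    stop("participant CSV header must be exactly: ",
         paste(.participant_header, collapse = ","), call. = FALSE)
  utils::read.csv(path, na.strings = c("", "NA"), stringsAsFactors = FALSE,
                  check.names = FALSE)
}

#' Read a census-block centroid CSV
#'
#' Expects the exact header `x_mi,y_mi,count`: planar centroid coordinates in
#' miles and the non-negative integer count of residents aged 50+.
#'
#' @param path file path.
#' @return block data.frame.
#' @export
read_blocks <- function(path) {
  hdr <- names(utils::read.csv(path, nrows = 1L, check.names = FALSE))
  if (!identical(hdr, .block_header))
    stop("block CSV header must be exactly: ",
         paste(.block_header, collapse = ","), call. = FALSE)
  blocks <- utils::read.csv(path, na.strings = c("", "NA"),
                            stringsAsFactors = FALSE, check.names = FALSE)
  validate_blocks(blocks)
  blocks
}

validate_blocks <- function(blocks) {
  if (!all(c("x_mi", "y_mi", "count") %in% names(blocks)))
    stop("block table needs columns x_mi, y_mi, count", call. = FALSE)
  if (nrow(blocks) == 0L) stop("block table is empty", call. = FALSE)
  if (!all(is.finite(blocks$x_mi)) || !all(is.finite(blocks$y_mi)))
    stop("block coordinates must be finite", call. = FALSE)
  cnt <- blocks$count
  if (any(is.na(cnt)) || any(cnt < 0) || any(cnt != round(cnt)))
    stop("block counts must be non-negative integers", call. = FALSE)
  invisible(blocks)
}

#' Write the coded analysis table to CSV
#'
#' Emits the coded columns (plus any attached `kde_h*` exposure columns) with
#' empty cells for missing values.
#'
#' @param coded coded analysis data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_analysis_table <- function(coded, path) {
  utils::write.csv(coded, path, row.names = FALSE, na = "")
  invisible(path)
}
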