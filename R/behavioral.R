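## Regression-based demographic correction of PASAT scores and
## extreme-tertile group construction.
##
## Raw PASAT scores (0..60 correct sums) correlate with age, education
## and gender; scores are corrected by regressing raw score on the
## three covariates in a reference sample and standardizing the
## residual by the fit's residual SD.

#' Read a behavioral table
#'
#' TSV with header columns id, group, pasat_raw, age, education_years,
#' gender.  Raw scores outside 0..60 are rejected.
#'
#' @param path file path
#' @return data frame
#' @export
read_behavioral <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("id", "group", "pasat_raw", "age", "education_years", "gender")
  if (!all(need %in% names(tab)))
    stop("behavioral table must have columns: ", paste(need, collapse = ", "))
  bad <- !is.na(tab$pasat_raw) & (tab$pasat_raw < 0 | tab$pasat_raw > 60)
  if (any(bad)) stop("pasat_raw outside 0..60 for id(s): ",
                     paste(tab$id[bad], collapse = ", "))
  tab
}

#' Write a behavioral table
#' @param table data frame (typically with a `pasat_z` column added)
#' @param path file path
#' @export
write_behavioral <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

## gender as a numeric binary code regardless of input representation
gender_code <- function(g) {
  if (is.numeric(g)) return(g)
  as.numeric(factor(g)) - 1
}

#' Fit demographic norms for PASAT
#'
#' Ordinary least squares of raw score on age, years of education and
#' gender over a reference sample; the residual SD of the fit is the
#' standardization denominator of [z_correct()].  Externally supplied
#' normative coefficients can be used instead by constructing the same
#' structure by hand.
#'
#' @param table behavioral data frame (the reference sample; rows with
#'   missing covariates are an error here)
#' @return object of class `pasat_norms`: `coefficients` (intercept,
#'   age, education_years, gender), `residual_sd`, `n`
#' @export
fit_norms <- function(table) {
  need <- c("pasat_raw", "age", "education_years", "gender")
  stopifnot(all(need %in% names(table)))
  if (nrow(table) < 10) stop("need at least 10 reference subjects")
  if (anyNA(table[, need])) stop("reference sample has missing values")
  df <- data.frame(pasat_raw = table$pasat_raw, age = table$age,
                   education_years = table$education_years,
                   gender = gender_code(table$gender))
  for (v in c("age", "education_years", "gender"))
    if (stats::sd(df[[v]]) == 0) stop("covariate '", v, "' is constant")
  fit <- stats::lm(pasat_raw ~ age + education_years + gender, data = df)
  if (anyNA(stats::coef(fit))) stop("collinear covariates")
  rsd <- summary(fit)$sigma
  structure(list(coefficients = stats::coef(fit), residual_sd = rsd,
                 n = nrow(df)), class = "pasat_norms")
}

#' @export
print.pasat_norms <- function(x, ...) {
  cat(sprintf("PASAT norms (n = %d): residual SD %.2f\n", x$n, x$residual_sd))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Demographically corrected PASAT Z-scores
#'
#' Z = (raw - predicted) / residual SD under the fitted norms.
#' Subjects with a missing covariate or raw score are excluded from
#' scoring (Z set to NA) and reported.
#'
#' @param table behavioral data frame
#' @param norms a `pasat_norms`
#' @return the table with a `pasat_z` column; attribute `excluded`
#'   lists ids that could not be scored
#' @export
z_correct <- function(table, norms) {
  stopifnot(inherits(norms, "pasat_norms"))
  co <- norms$coefficients
  g <- gender_code(table$gender)
  pred <- co[1] + co[2] * table$age + co[3] * table$education_years + co[4] * g
  z <- (table$pasat_raw - pred) / norms$residual_sd
  excluded <- table$id[!is.finite(z)]
  if (length(excluded))
    message("z_correct: excluded (missing information): ",
            paste(excluded, collapse = ", "))
  table$pasat_z <- ifelse(is.finite(z), z, NA_real_)
  attr(table, "excluded") <- excluded
  table
}

#' Extreme-group construction by corrected Z-score
#'
#' Splits the scored subjects into a low-Z and a high-Z extreme group
#' of size `ceiling(n_scored * fraction)` each (the tertile rule that
#' turns 53 scored patients into two groups of 18).  Ties are broken by
#' subject id; the groups are disjoint by construction and an error is
#' raised if they would overlap.
#'
#' @param table behavioral data frame with `pasat_z` (NA rows are
#'   ignored)
#' @param fraction extreme fraction; default 1/3
#' @return list with `low` and `high` id vectors
#' @export
extreme_groups <- function(table, fraction = 1 / 3) {
  scored <- table[!is.na(table$pasat_z), ]
  n <- nrow(scored)
  if (n < 3) stop("need at least 3 scored subjects")
  size <- ceiling(n * fraction)
  if (2 * size > n) stop("extreme groups of size ", size,
                         " would overlap with only ", n, " scored subjects")
  ord <- order(scored$pasat_z, scored$id)
  list(low = scored$id[ord[seq_len(size)]],
       high = scored$id[rev(ord)[seq_len(size)]])
}
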