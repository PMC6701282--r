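#' Assign depressive-symptom group from a MADRS-SIGMA total score
#'
#' Subjects scoring strictly greater than 8 on the Montgomery-Asberg
#' Depression Rating Scale (structured-interview form; total 0-60) are
#' classified as "high" depressive-symptom, all others as "low".  The
#' boundary score of exactly 8 is "low": the cut-off is a strict
#' inequality.
#'
#' @param madrs_total Integer vector of MADRS-SIGMA total scores, each in
#'   0-60.
#' @param subject_id Optional character vector of subject identifiers,
#'   used to name the offending subject in validation errors.
#' @return Character vector of `"low"` / `"high"` labels.
#' @examples
#' assign_group(c(0, 8, 9, 25))
#' @export
assign_group <- function(madrs_total, subject_id = NULL) {
  if (length(madrs_total) == 0L) return(character(0))
  bad <- !is.finite(madrs_total) | madrs_total < 0 | madrs_total > 60 |
    madrs_total != round(madrs_total)
  if (any(bad)) {
    who <- if (is.null(subject_id)) paste0("element ", which(bad)[1L]) else
      subject_id[which(bad)[1L]]
    stop("madrs_total must be an integer in [0, 60]; offending subject: ",
         who, " (value ", madrs_total[which(bad)[1L]], ")")
  }
  ifelse(madrs_total > 8, "high", "low")
}

.cohort_required_cols <- c("subject_id", "age", "sex", "nihss",
                           "madrs_total", "history_depression",
                           "antidepressant")
.cohort_optional_cols <- c("reported_sadness", "reported_discouragement",
                           "reported_loss_of_interest")

.as_flag <- function(x, col) {
  if (is.logical(x)) return(x)
  xx <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(xx))
  out[xx %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[xx %in% c("false", "f", "0", "no", "n")] <- FALSE
  out[xx %in% c("", "na")] <- NA
  if (any(is.na(out) & !(xx %in% c("", "na"))))
    stop("column '", col, "' contains values not interpretable as yes/no: ",
         paste(unique(xx[is.na(out) & !(xx %in% c("", "na"))]), collapse = ", "))
  out
}

#' Validate a cohort data frame and derive the symptom group
#'
#' Checks column presence and types, uniqueness of subject ids, score and
#' age ranges, and the controlled sex vocabulary, then (re)derives the
#' `group` column from `madrs_total` -- a group column present in the
#' input is never trusted.
#'
#' @param df A data frame with at least the required columns
#'   `subject_id`, `age`, `sex`, `nihss`, `madrs_total`,
#'   `history_depression`, `antidepressant`.  Optional yes/no columns
#'   `reported_sadness`, `reported_discouragement`,
#'   `reported_loss_of_interest` are kept when present (they feed only the
#'   demographic report, never the imaging model).
#' @return The validated data frame with a derived `group` column, of
#'   class `cohort_table`.
#' @export
as_cohort <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(.cohort_required_cols, names(df))
  if (length(missing_cols))
    stop("cohort table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) stop("cohort table has no rows")
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id: ",
         df$subject_id[duplicated(df$subject_id)][1L])
  for (col in c("age", "nihss", "madrs_total")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (any(is.na(v)))
      stop("column '", col, "' is not numeric for subject ",
           df$subject_id[which(is.na(v))[1L]])
    df[[col]] <- v
  }
  if (any(df$age <= 0))
    stop("age must be positive; offending subject: ",
         df$subject_id[which(df$age <= 0)[1L]])
  if (any(df$nihss < 0 | df$nihss != round(df$nihss)))
    stop("nihss must be a non-negative integer; offending subject: ",
         df$subject_id[which(df$nihss < 0 | df$nihss != round(df$nihss))[1L]])
  df$sex <- tolower(trimws(as.character(df$sex)))
  if (!all(df$sex %in% c("female", "male")))
    stop("sex must be 'female' or 'male'; offending subject: ",
         df$subject_id[which(!df$sex %in% c("female", "male"))[1L]])
  for (col in c("history_depression", "antidepressant",
                intersect(.cohort_optional_cols, names(df))))
    df[[col]] <- .as_flag(df[[col]], col)
  df$group <- assign_group(df$madrs_total, df$subject_id)
  keep <- c(.cohort_required_cols,
            intersect(.cohort_optional_cols, names(df)), "group")
  df <- df[, keep]
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Load a cohort table from CSV
#'
#' Reads a UTF-8, comma-separated, headered cohort table, validates it
#' with [as_cohort()] and logs a per-group summary (n, mean/SD of age,
#' MADRS-SIGMA and NIHSS).
#'
#' @param path Path to the CSV file.
#' @param quiet Suppress the summary message.
#' @return A `cohort_table` data frame.
#' @export
load_cohort <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cohort <- as_cohort(df)
  if (!quiet) message(.cohort_summary_line(cohort))
  cohort
}

#' Write a cohort table to CSV
#'
#' @param cohort A `cohort_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

.cohort_summary_line <- function(cohort) {
  msd <- function(x) sprintf("%.2f (%.2f)", mean(x), stats::sd(x))
  parts <- vapply(c("low", "high"), function(g) {
    s <- cohort[cohort$group == g, ]
    sprintf("%s: n=%d, age %s, MADRS %s, NIHSS %s", g, nrow(s),
            msd(s$age), msd(s$madrs_total), msd(s$nihss))
  }, character(1))
  paste0("cohort loaded -- ", paste(parts, collapse = "; "))
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(.cohort_summary_line(x), "\n\n")
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Per-group subject counts
#'
#' @param cohort A `cohort_table`.
#' @return Named integer vector with elements `low` and `high`.
#' @export
group_counts <- function(cohort) {
  c(low = sum(cohort$group == "low"), high = sum(cohort$group == "high"))
}
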