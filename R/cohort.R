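# Patient cohort data model and I/O.
#
# A cohort is one row per patient: demographics, an open vocabulary of
# findings (columns prefixed "f_"), one or two reference ("true")
# diagnoses or a sentinel, and optional observed management. The unit of
# analysis downstream is the *case*: a patient with two reference
# diagnoses contributes two cases.

#' @name sentinels
#' @title Diagnosis sentinels
#' @description `NO_DIAGNOSIS` marks a patient for whom no final diagnosis
#'   was made; `RARE_DIAGNOSIS` marks a diagnosis outside the scope of the
#'   algorithms under study. Sentinel cases are excluded from the
#'   restricted sensitivity denominator but enlarge the inclusive one.
#' @export
NO_DIAGNOSIS <- "NO_DIAGNOSIS"

#' @rdname sentinels
#' @export
RARE_DIAGNOSIS <- "RARE_DIAGNOSIS"

SENTINELS <- c("NO_DIAGNOSIS", "RARE_DIAGNOSIS")

COHORT_FIXED_COLS <- c("patient_id", "age", "sex", "dx1", "dx2", "outcome",
                       "observed_delay_days", "observed_tests",
                       "observed_treatment")

#' Check whether a diagnosis label is a sentinel
#' @param dx character vector of diagnosis labels.
#' @return logical vector.
#' @export
is_sentinel <- function(dx) dx %in% SENTINELS

# Infer a finding column's type from its character values.
.type_finding <- function(x) {
  x[!nzchar(trimws(x))] <- NA
  nn <- x[!is.na(x)]
  if (length(nn) == 0L) return(as.logical(x))
  if (all(toupper(nn) %in% c("TRUE", "FALSE"))) return(as.logical(x))
  num <- suppressWarnings(as.numeric(nn))
  if (!anyNA(num)) return(suppressWarnings(as.numeric(x)))
  x
}

.validate_cohort <- function(df, source = "cohort") {
  bad <- which(is.na(df$age) | df$age <= 15)
  if (length(bad) > 0L)
    stop(source, " row ", bad[1L], " (patient '", df$patient_id[bad[1L]],
         "'): age must be > 15 years (study inclusion)", call. = FALSE)
  bad <- which(!df$sex %in% c("male", "female"))
  if (length(bad) > 0L)
    stop(source, " row ", bad[1L], ": unknown sex code '",
         df$sex[bad[1L]], "'", call. = FALSE)
  bad <- which(is.na(df$dx1) | !nzchar(df$dx1))
  if (length(bad) > 0L)
    stop(source, " row ", bad[1L],
         ": dx1 must name a diagnosis or a sentinel", call. = FALSE)
  bad <- which(is_sentinel(df$dx1) & !is.na(df$dx2))
  if (length(bad) > 0L)
    stop(source, " row ", bad[1L],
         ": sentinel patients cannot carry a second diagnosis",
         call. = FALSE)
  if (anyDuplicated(df$patient_id))
    stop(source, ": duplicate patient_id '",
         df$patient_id[duplicated(df$patient_id)][1L], "'", call. = FALSE)
  odd <- which(!is.na(df$observed_delay_days) & df$observed_delay_days < 0)
  if (length(odd) > 0L)
    stop(source, " row ", odd[1L], ": observed_delay_days must be >= 0",
         call. = FALSE)
  invisible(df)
}

#' Read a patient cohort file
#'
#' Cohort CSV dialect: fixed columns
#' `patient_id,age,sex,dx1,dx2,outcome,observed_delay_days,observed_tests,observed_treatment`,
#' findings as additional columns prefixed `f_`, unknown values as empty
#' cells, and observed test sequences `|`-separated. Finding column types
#' are inferred (logical, numeric, else category).
#'
#' @param path CSV file path.
#' @return a data frame of class `patient_cohort`; finding columns keep
#'   their `f_` prefix.
#' @export
load_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing_cols <- setdiff(COHORT_FIXED_COLS, names(df))
  if (length(missing_cols) > 0L)
    stop("cohort file ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (col in setdiff(names(df), COHORT_FIXED_COLS)) {
    if (!startsWith(col, "f_"))
      stop("cohort file ", path, ": unexpected column '", col,
           "' (findings must be prefixed f_)", call. = FALSE)
  }
  blank_to_na <- function(x) { x[!nzchar(trimws(x))] <- NA; x }
  df[] <- lapply(df, blank_to_na)
  df$age <- suppressWarnings(as.numeric(df$age))
  df$observed_delay_days <- suppressWarnings(as.numeric(df$observed_delay_days))
  for (col in grep("^f_", names(df), value = TRUE))
    df[[col]] <- .type_finding(df[[col]])
  df$outcome[is.na(df$outcome)] <- "unknown"
  .validate_cohort(df, source = basename(path))
  class(df) <- c("patient_cohort", "data.frame")
  df
}

#' Write a patient cohort file
#'
#' Inverse of [load_cohort()]: unknown findings become empty cells.
#'
#' @param cohort a `patient_cohort` data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Extract one patient's findings map
#'
#' @param cohort a `patient_cohort`.
#' @param patient_id patient identifier.
#' @return named list of finding values (names without the `f_` prefix);
#'   unknown findings are `NA`.
#' @export
patient_findings <- function(cohort, patient_id) {
  i <- match(patient_id, cohort$patient_id)
  if (is.na(i)) stop("unknown patient_id '", patient_id, "'", call. = FALSE)
  fcols <- grep("^f_", names(cohort), value = TRUE)
  f <- lapply(fcols, function(col) cohort[[col]][i])
  names(f) <- sub("^f_", "", fcols)
  f
}

#' Expand patients into cases
#'
#' One case per reference diagnosis: a patient with two diagnoses expands
#' into two cases; sentinel patients yield one sentinel case. Order is
#' preserved (dx1 before dx2 within a patient).
#'
#' @param cohort a `patient_cohort`.
#' @return data frame with columns `patient_id`, `true_diagnosis`.
#' @export
expand_cases <- function(cohort) {
  pid <- character(0); dx <- character(0)
  for (i in seq_len(nrow(cohort))) {
    pid <- c(pid, cohort$patient_id[i]); dx <- c(dx, cohort$dx1[i])
    if (!is.na(cohort$dx2[i])) {
      pid <- c(pid, cohort$patient_id[i]); dx <- c(dx, cohort$dx2[i])
    }
  }
  data.frame(patient_id = pid, true_diagnosis = dx,
             stringsAsFactors = FALSE)
}

#' Split cases into in-scope and excluded
#'
#' Excluded cases are the sentinels (no diagnosis, rare diagnosis) and any
#' diagnosis outside the covered set. The restricted sensitivity
#' denominator is the in-scope cases; the inclusive one is all enrolled
#' patients.
#'
#' @param cases case data frame from [expand_cases()].
#' @param covered character vector of in-scope diagnosis identifiers.
#' @return list with elements `in_scope` and `excluded`.
#' @export
filter_in_scope <- function(cases, covered) {
  keep <- !is_sentinel(cases$true_diagnosis) &
    cases$true_diagnosis %in% covered
  list(in_scope = cases[keep, , drop = FALSE],
       excluded = cases[!keep, , drop = FALSE])
}

#' Read a harm-weight table
#'
#' One row per diagnosis with the clinician-elicited harm of missing it
#' (`w_omission`, false negative) and of wrongly assigning it
#' (`w_commission`, false positive), both on a 0-10 scale relative to
#' natural death.
#'
#' @param path CSV with columns `diagnosis,w_omission,w_commission`.
#' @return data frame of class `harm_weights`.
#' @export
load_harm_weights <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("diagnosis", "w_omission", "w_commission")
  if (!all(need %in% names(df)))
    stop("harm table ", path, ": needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  for (col in c("w_omission", "w_commission")) {
    bad <- which(is.na(df[[col]]) | df[[col]] < 0 | df[[col]] > 10)
    if (length(bad) > 0L)
      stop("harm table ", path, " row ", bad[1L], " (",
           df$diagnosis[bad[1L]], "): ", col,
           " outside the 0-10 scale", call. = FALSE)
  }
  if (anyDuplicated(df$diagnosis))
    stop("harm table ", path, ": duplicate diagnosis", call. = FALSE)
  class(df) <- c("harm_weights", "data.frame")
  df
}
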