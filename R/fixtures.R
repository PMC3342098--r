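# Packaged study fixtures.
#
# The study's quantitative inputs are shipped as plain-text fixtures:
# per-algorithm confusion counts, per-diagnosis serial delays, the
# clinician-elicited harm weights, and a test catalog. The three
# flowchart encodings and the patient-level cohort are best-effort
# synthetic reconstructions (the published figures and raw data are not
# machine-readable) and are labelled `_synthetic` accordingly: their
# marginals are study-shaped, but box-level content is the package's own.

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "algopath")
  if (!nzchar(path))
    stop("packaged fixture '", file, "' not found", call. = FALSE)
  path
}

#' Packaged flowchart encodings
#'
#' Loads one of the three packaged algorithm reconstructions: `"chuk"`
#' (locally tailored, X-ray first, with re-testing loops), `"msf"`
#' (sputum smears first) or `"who"` (simplest, several diagnoses not
#' covered). These are synthetic reconstructions of the published
#' flowcharts, not transcriptions.
#'
#' @param which `"chuk"`, `"msf"` or `"who"`.
#' @return a [clinical_algorithm].
#' @export
study_algorithm <- function(which = c("chuk", "msf", "who")) {
  which <- match.arg(which)
  parse_algorithm(.extdata(paste0(which, "_synthetic.json")))
}

#' Packaged per-algorithm confusion counts
#'
#' The published per-diagnosis accuracy table: for each of the three
#' algorithms and each of the 12 in-scope diagnoses, the case count `n`
#' and the `fp`, `tp`, `fn`, `tn`, `fit` counters over the 184 cases.
#'
#' @param algorithm optional filter (`"chuk"`, `"msf"`, `"who"`); when
#'   given, returns that algorithm's rows as a `confusion_table`.
#' @return data frame (all rows), or a `confusion_table` for one
#'   algorithm.
#' @export
study_counts <- function(algorithm = NULL) {
  df <- utils::read.csv(.extdata("table2_counts.csv"),
                        stringsAsFactors = FALSE)
  if (is.null(algorithm)) return(df)
  algorithm <- match.arg(algorithm, c("chuk", "msf", "who"))
  out <- df[df$algorithm == algorithm,
            c("diagnosis", "n", "fp", "tp", "fn", "tn", "fit")]
  row.names(out) <- NULL
  attr(out, "n_cases") <- sum(out$tp) + sum(out$fn)
  class(out) <- c("confusion_table", "data.frame")
  out
}

#' Packaged per-diagnosis serial delays
#'
#' Theoretical delay in days to appropriate management under strictly
#' serial testing, per diagnosis, for the two computable algorithms, plus
#' the observed ward delay and the hypothetical minimal delay.
#'
#' @return data frame with columns `diagnosis`, `delay_chuk`,
#'   `delay_msf`, `actual_delay_chuk`, `minimal_delay`.
#' @export
study_delays <- function() {
  utils::read.csv(.extdata("table3_delays.csv"), stringsAsFactors = FALSE)
}

#' Packaged harm weights
#'
#' The clinician-elicited 0-10 harm weights per diagnosis: omission
#' (missing the diagnosis) and commission (wrongly assigning it).
#'
#' @return a `harm_weights` data frame.
#' @export
study_harm <- function() {
  load_harm_weights(.extdata("table4_harm.csv"))
}

#' Packaged synthetic study cohort
#'
#' A 201-patient cohort whose marginals match the study population (age
#' bands, 82/119 male/female, per-diagnosis case counts, one
#' dual-diagnosis patient, 9 undiagnosed and 9 rare-diagnosis patients)
#' with findings set to the CHUK reconstruction's noise-free archetypes.
#' Patient-level study data were never published; this is a synthetic
#' stand-in.
#'
#' @return a `patient_cohort`.
#' @export
study_cohort <- function() {
  load_cohort(.extdata("table1_cohort_synthetic.csv"))
}

#' Packaged test catalog
#'
#' @return data frame `test_id`, `turnaround_days`.
#' @export
study_test_catalog <- function() {
  utils::read.csv(.extdata("tests_catalog.csv"), stringsAsFactors = FALSE)
}

#' Build the synthetic study cohort from scratch
#'
#' Deterministically constructs the 201-patient cohort shipped as
#' `table1_cohort_synthetic.csv`: exact per-diagnosis counts, exact sex
#' and age-band composition (a fixed internal seed shuffles assignments so
#' the marginals are not confounded with patient order), one patient with
#' two diagnoses, and findings from [calibrate_profiles()] on the CHUK
#' reconstruction.
#'
#' @param alg flowchart whose calibrated archetypes supply the findings;
#'   defaults to the packaged CHUK reconstruction.
#' @return a `patient_cohort`.
#' @export
build_study_cohort <- function(alg = study_algorithm("chuk")) {
  counts <- study_diagnosis_counts()
  profiles <- calibrate_profiles(alg)

  # one dual-diagnosis patient: a smear-positive TB case also carrying
  # Kaposi's sarcoma, so both printed counts include it
  dx1 <- c(rep(names(counts)[1:12], counts[1:12] -
                 c(0, 0, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0)),
           rep("RARE_DIAGNOSIS", counts[["RARE_DIAGNOSIS"]]),
           rep("NO_DIAGNOSIS", counts[["NO_DIAGNOSIS"]]))
  n <- length(dx1)
  stopifnot(n == 201L)
  dx2 <- rep(NA_character_, n)
  dx2[match("tb_smear_pos", dx1)] <- "kaposi"

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(20020L)  # fixed: the fixture is one specific cohort
  sex <- sample(c(rep("female", 119L), rep("male", 82L)))
  band_counts <- c("15-24" = 22L, "25-34" = 72L, "35-44" = 69L,
                   "45-54" = 29L, "55-64" = 8L, "65-74" = 1L)
  bands <- sample(rep(names(band_counts), band_counts))
  lo <- pmax(as.numeric(sub("-.*", "", bands)), 16)
  hi <- as.numeric(sub(".*-", "", bands))
  age <- floor(stats::runif(n, lo, hi + 1))
  outcome <- sample(c(rep("died", 78L), rep("survived", 123L)))

  finding_ids <- sort(unique(unlist(lapply(profiles, names))))
  pool <- lapply(finding_ids, function(f) {
    v <- lapply(profiles, function(pr) pr[[f]])
    v[!vapply(v, is.null, logical(1))]
  })
  names(pool) <- finding_ids
  background <- lapply(pool, .background_value)

  df <- data.frame(patient_id = sprintf("P%03d", seq_len(n)), age = age,
                   sex = sex, dx1 = dx1, dx2 = dx2, outcome = outcome,
                   observed_delay_days = NA_real_,
                   observed_tests = NA_character_,
                   observed_treatment = NA_character_,
                   stringsAsFactors = FALSE)
  for (f in finding_ids) {
    col <- lapply(seq_len(n), function(i) {
      v <- profiles[[dx1[i]]][[f]]
      if (is.null(v) && !is.na(dx2[i])) v <- profiles[[dx2[i]]][[f]]
      if (is.null(v)) v <- background[[f]]
      v
    })
    df[[paste0("f_", f)]] <- unlist(col)
  }
  class(df) <- c("patient_cohort", "data.frame")
  df
}
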