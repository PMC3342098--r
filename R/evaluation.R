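# Confusion accounting, sensitivity, delay summaries and harm scoring.
#
# The accounting rule is asymmetric by design. Reaching the true diagnosis
# is a true positive for it. Reaching a *different* diagnosis is both a
# false negative for the true condition (it was missed) and a false
# positive for the condition wrongly assigned. Failing to fit, or ending
# at a non-diagnostic action, is a false negative only — no wrong
# diagnosis was committed. Sentinel cases (no diagnosis, rare diagnosis)
# can only contribute false positives, and only when a diagnosis was
# wrongly reached.

#' Score one case against its traversal
#'
#' @param true_diagnosis the case's reference diagnosis, or a sentinel
#'   (`NO_DIAGNOSIS` / `RARE_DIAGNOSIS`).
#' @param result a `traversal_result` from [traverse()], or a list with
#'   `status` and `terminal_diagnosis`.
#' @param covered character vector of the algorithm's covered diagnoses.
#' @return data frame of counter increments with columns `diagnosis`,
#'   `counter` (`tp`/`fp`/`fn`); zero rows when nothing is scored.
#' @export
score_case <- function(true_diagnosis, result, covered) {
  predicted <- if (identical(result$status, "FIT"))
    result$terminal_diagnosis else NA_character_
  if (!is.na(predicted) && !predicted %in% covered)
    stop("predicted diagnosis '", predicted,
         "' outside the covered set", call. = FALSE)
  inc <- function(diagnosis, counter)
    data.frame(diagnosis = diagnosis, counter = counter,
               stringsAsFactors = FALSE)
  empty <- inc(character(0), character(0))
  if (is_sentinel(true_diagnosis)) {
    if (!is.na(predicted)) return(inc(predicted, "fp"))
    return(empty)
  }
  if (is.na(predicted)) return(inc(true_diagnosis, "fn"))
  if (predicted == true_diagnosis) return(inc(true_diagnosis, "tp"))
  rbind(inc(true_diagnosis, "fn"), inc(predicted, "fp"))
}

#' Tabulate per-diagnosis confusion cells
#'
#' Aggregates [score_case()] increments over a case stream into one row
#' per covered diagnosis: `n` (cases with that reference diagnosis), `fp`,
#' `tp`, `fn`, `tn` and `fit`. True negatives are derived by conservation,
#' `tn = N - tp - fp - fn` with `N` the number of cases scored, so every
#' row sums to the case total.
#'
#' @param cases case data frame (columns `patient_id`, `true_diagnosis`).
#' @param results a `traversal_set` from [traverse_cohort()], or any data
#'   frame with one row per case carrying `status` and
#'   `terminal_diagnosis`.
#' @param covered character vector of covered diagnoses.
#' @return data frame of class `confusion_table`; attribute `n_cases`
#'   holds the case total.
#' @export
tabulate_confusion <- function(cases, results, covered) {
  if (nrow(cases) != nrow(results))
    stop("cases and results differ in length (", nrow(cases), " vs ",
         nrow(results), ")", call. = FALSE)
  counters <- c("tp", "fp", "fn")
  tab <- matrix(0L, nrow = length(covered), ncol = length(counters),
                dimnames = list(covered, counters))
  fit <- stats::setNames(integer(length(covered)), covered)
  n_dx <- stats::setNames(integer(length(covered)), covered)
  for (i in seq_len(nrow(cases))) {
    truth <- cases$true_diagnosis[i]
    res <- list(status = results$status[i],
                terminal_diagnosis = results$terminal_diagnosis[i])
    for (j in seq_len(nrow(sc <- score_case(truth, res, covered))))
      tab[sc$diagnosis[j], sc$counter[j]] <-
        tab[sc$diagnosis[j], sc$counter[j]] + 1L
    if (truth %in% covered) {
      n_dx[truth] <- n_dx[truth] + 1L
      if (identical(res$status, "FIT")) fit[truth] <- fit[truth] + 1L
    }
  }
  n_cases <- nrow(cases)
  out <- data.frame(diagnosis = covered, n = as.integer(n_dx),
                    fp = as.integer(tab[, "fp"]),
                    tp = as.integer(tab[, "tp"]),
                    fn = as.integer(tab[, "fn"]),
                    tn = as.integer(n_cases - tab[, "tp"] - tab[, "fp"] -
                                      tab[, "fn"]),
                    fit = as.integer(fit),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_cases") <- n_cases
  class(out) <- c("confusion_table", "data.frame")
  out
}

#' Overall algorithm sensitivity
#'
#' The proportion of correct diagnoses. `restricted` divides total true
#' positives by the in-scope case total (TP + FN); `inclusive` divides by
#' all enrolled patients, counting the undiagnosed and rare-diagnosis
#' patients in the denominator.
#'
#' @param cells a `confusion_table` (or data frame with `tp`, `fn`).
#' @param mode `"restricted"` or `"inclusive"`.
#' @param n_enrolled enrolled patient count; required for `inclusive`.
#' @return sensitivity in percent (unrounded; report to 1 decimal).
#' @export
sensitivity <- function(cells, mode = c("restricted", "inclusive"),
                        n_enrolled = NULL) {
  mode <- match.arg(mode)
  tp <- sum(cells$tp)
  denom <- if (mode == "restricted") tp + sum(cells$fn) else n_enrolled
  if (is.null(denom) || !is.numeric(denom) || denom <= 0)
    stop("sensitivity: empty or invalid denominator", call. = FALSE)
  100 * tp / denom
}

#' Average delay to appropriate management
#'
#' Summarises per-diagnosis serial delays into one number. The case-count
#' weighted mean (`weighted = TRUE`, the reported form) is
#' `sum(delay_d * n_d) / sum(n_d)`; the unweighted form averages the
#' per-diagnosis delays directly.
#'
#' @param delays named numeric vector, days per diagnosis.
#' @param counts named integer vector, cases per diagnosis (same names).
#' @param weighted logical.
#' @return mean delay in days (unrounded; report to 2 decimals).
#' @export
mean_delay <- function(delays, counts = NULL, weighted = TRUE) {
  if (length(delays) == 0L) stop("mean_delay: empty input", call. = FALSE)
  if (!weighted) return(mean(delays))
  if (is.null(counts)) stop("mean_delay: counts required when weighted",
                            call. = FALSE)
  if (!setequal(names(delays), names(counts)))
    stop("mean_delay: delays and counts must cover the same diagnoses",
         call. = FALSE)
  counts <- counts[names(delays)]
  sum(delays * counts) / sum(counts)
}

#' Harm-weighted error score
#'
#' Multiplies each diagnosis's false positives by its commission weight
#' and its false negatives by its omission weight, and sums. Total harm is
#' the sum of the two components.
#'
#' @param cells a `confusion_table`.
#' @param weights a `harm_weights` table ([load_harm_weights()]).
#' @return list with `commission`, `omission`, `total`.
#' @export
harm <- function(cells, weights) {
  idx <- match(cells$diagnosis, weights$diagnosis)
  need <- cells$fp > 0 | cells$fn > 0
  if (any(need & is.na(idx)))
    stop("missing harm weight for diagnosis '",
         cells$diagnosis[need & is.na(idx)][1L], "'", call. = FALSE)
  w_com <- ifelse(is.na(idx), 0, weights$w_commission[idx])
  w_om <- ifelse(is.na(idx), 0, weights$w_omission[idx])
  commission <- sum(cells$fp * w_com)
  omission <- sum(cells$fn * w_om)
  list(commission = commission, omission = omission,
       total = commission + omission)
}

#' Concordance of simulated and observed management
#'
#' Compares the management an algorithm prescribes for a patient with the
#' management actually observed, on the three-level scale: identical
#' (score 10, same ordered test sequence and same terminal decision),
#' similar (score 8, same tests and decision in a different order),
#' different (score 0, a different terminal decision).
#'
#' @param result a `traversal_result`.
#' @param observed_tests character vector of observed test ids in order
#'   (or a `|`-separated string).
#' @param observed_treatment observed terminal treatment/diagnosis label.
#' @return integer score: 10, 8 or 0.
#' @export
concordance <- function(result, observed_tests, observed_treatment) {
  if (length(observed_tests) == 1L && is.character(observed_tests) &&
      grepl("|", observed_tests, fixed = TRUE))
    observed_tests <- strsplit(observed_tests, "|", fixed = TRUE)[[1]]
  if (length(observed_tests) == 1L && (is.na(observed_tests) ||
                                       !nzchar(observed_tests)))
    observed_tests <- character(0)
  decision <- if (identical(result$status, "FIT"))
    result$terminal_diagnosis else NA_character_
  same_decision <- !is.na(decision) && !is.na(observed_treatment) &&
    decision == observed_treatment
  if (!same_decision) return(0L)
  if (identical(as.character(result$tests), as.character(observed_tests)))
    return(10L)
  if (setequal(result$tests, observed_tests)) return(8L)
  0L
}

#' Evaluate an algorithm on a cohort
#'
#' The full pipeline: expand patients into cases, split off the sentinel
#' and out-of-scope cases, route the in-scope cases through the flowchart,
#' tabulate the confusion cells, and compute sensitivity (both
#' denominators), fit, mean serial delay, and (when weights are supplied)
#' harm.
#'
#' @param alg a [clinical_algorithm].
#' @param cohort a `patient_cohort`.
#' @param weights optional `harm_weights`.
#' @param covered diagnoses considered in scope; defaults to the
#'   algorithm's own covered set, but a wider study scope may be imposed
#'   (cases whose diagnosis the algorithm cannot reach then count as
#'   false negatives rather than being excluded).
#' @param max_loop_iterations passed to [traverse()].
#' @return object of class `algorithm_evaluation`: `algorithm_id`, `cells`
#'   (confusion table), `results` (traversal set), `n_enrolled`,
#'   `n_cases`, `fit_count`, `fit_rate`, `sensitivity_restricted`,
#'   `sensitivity_inclusive`, `mean_delay_weighted`,
#'   `mean_delay_unweighted`, and `harm_*` components (NA without
#'   weights).
#' @export
evaluate_algorithm <- function(alg, cohort, weights = NULL,
                               covered = alg$diagnoses_covered,
                               max_loop_iterations = 3L) {
  covered <- union(covered, alg$diagnoses_covered)
  cases <- expand_cases(cohort)
  split <- filter_in_scope(cases, covered)
  in_scope <- split$in_scope
  results <- traverse_cohort(alg, in_scope, cohort, max_loop_iterations)
  cells <- tabulate_confusion(in_scope, results, covered)
  n_cases <- nrow(in_scope)
  fit_count <- sum(results$status == "FIT")
  sens_r <- if (n_cases > 0) sensitivity(cells, "restricted") else NA_real_
  sens_i <- if (nrow(cohort) > 0)
    sensitivity(cells, "inclusive", n_enrolled = nrow(cohort)) else NA_real_
  per_dx <- cells$diagnosis[cells$n > 0]
  if (length(per_dx) > 0) {
    dly <- vapply(per_dx, function(d)
      mean(results$delay_days[in_scope$true_diagnosis == d]), numeric(1))
    cnt <- stats::setNames(cells$n[cells$n > 0], per_dx)
    md_w <- mean_delay(dly, cnt, weighted = TRUE)
    md_u <- mean_delay(dly, weighted = FALSE)
  } else {
    md_w <- md_u <- NA_real_
  }
  h <- if (!is.null(weights)) harm(cells, weights) else
    list(commission = NA_real_, omission = NA_real_, total = NA_real_)
  structure(list(algorithm_id = alg$algorithm_id, cells = cells,
                 results = results, n_enrolled = nrow(cohort),
                 n_cases = n_cases, n_excluded = nrow(split$excluded),
                 fit_count = fit_count,
                 fit_rate = if (n_cases > 0) 100 * fit_count / n_cases
                            else NA_real_,
                 sensitivity_restricted = sens_r,
                 sensitivity_inclusive = sens_i,
                 mean_delay_weighted = md_w, mean_delay_unweighted = md_u,
                 harm_commission = h$commission, harm_omission = h$omission,
                 harm_total = h$total),
            class = "algorithm_evaluation")
}

#' @export
print.algorithm_evaluation <- function(x, ...) {
  cat("Evaluation of algorithm '", x$algorithm_id, "'\n", sep = "")
  cat("  cases: ", x$n_cases, " in scope (", x$n_excluded,
      " excluded) of ", x$n_enrolled, " enrolled patients\n", sep = "")
  cat("  fit: ", x$fit_count, " (", .fmt(x$fit_rate, 1), "%)\n", sep = "")
  cat("  sensitivity: ", .fmt(x$sensitivity_restricted, 1),
      "% restricted, ", .fmt(x$sensitivity_inclusive, 1),
      "% inclusive\n", sep = "")
  cat("  mean serial delay: ", .fmt(x$mean_delay_weighted, 2),
      " days (case-weighted), ", .fmt(x$mean_delay_unweighted, 2),
      " (unweighted)\n", sep = "")
  if (!is.na(x$harm_total))
    cat("  harm: ", .fmt(x$harm_commission, 2), " commission + ",
        .fmt(x$harm_omission, 2), " omission = ", .fmt(x$harm_total, 2),
        "\n", sep = "")
  invisible(x)
}

#' @export
summary.algorithm_evaluation <- function(object, ...) {
  print(object)
  cat("\nPer-diagnosis confusion cells:\n")
  print(as.data.frame(object$cells))
  invisible(object)
}

.fmt <- function(x, digits) {
  if (is.na(x)) "NA" else formatC(round(x, digits), format = "f",
                                  digits = digits)
}
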