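# Study replication and multi-algorithm comparison.

#' Recompute the study's headline metrics from the packaged tables
#'
#' Runs the whole scoring machinery on the packaged fixtures — the
#' per-algorithm confusion counts, the per-diagnosis serial delays and the
#' harm weights — and compares every recomputed value with the published
#' one at its printed precision. No traversal is involved: this is the
#' replication path, scoring the printed counts directly.
#'
#' @param counts data frame in the shape of [study_counts()]; override to
#'   probe the sensitivity of the checks.
#' @param delays data frame in the shape of [study_delays()].
#' @param weights a `harm_weights` table.
#' @param n_enrolled enrolled patient count (inclusive-sensitivity
#'   denominator).
#' @return data frame of class `study_replication` with columns `target`,
#'   `value` (recomputed, unrounded), `printed`, `digits`, `pass`.
#' @export
replicate_study <- function(counts = study_counts(),
                            delays = study_delays(),
                            weights = study_harm(),
                            n_enrolled = 201L) {
  cells_of <- function(a) {
    out <- counts[counts$algorithm == a,
                  c("diagnosis", "n", "fp", "tp", "fn", "tn", "fit")]
    class(out) <- c("confusion_table", "data.frame")
    out
  }
  chuk <- cells_of("chuk"); msf <- cells_of("msf"); who <- cells_of("who")

  targets <- list()
  add <- function(target, value, printed, digits) {
    targets[[length(targets) + 1L]] <<-
      data.frame(target = target, value = value, printed = printed,
                 digits = digits, stringsAsFactors = FALSE)
  }

  add("sensitivity_restricted_chuk", sensitivity(chuk, "restricted"), 95.7, 1)
  add("sensitivity_restricted_msf", sensitivity(msf, "restricted"), 88.0, 1)
  add("sensitivity_restricted_who", sensitivity(who, "restricted"), 70.1, 1)
  add("sensitivity_inclusive_who",
      sensitivity(who, "inclusive", n_enrolled = n_enrolled), 64.2, 1)
  add("fit_count_who", sum(who$fit), 171, 0)

  h_chuk <- harm(chuk, weights)
  h_msf <- harm(msf, weights)
  h_who <- harm(who, weights)
  add("harm_commission_chuk", h_chuk$commission, 27, 0)
  add("harm_omission_chuk", h_chuk$omission, 63, 0)
  add("harm_commission_msf", h_msf$commission, 64, 0)
  add("harm_omission_msf", h_msf$omission, 176, 0)
  add("harm_total_msf", h_msf$total, 240, 0)
  add("harm_total_who", h_who$total, 487.5, 1)

  add("mean_commission_weight", mean(weights$w_commission), 4.5, 1)

  dly <- stats::setNames(delays$delay_chuk, delays$diagnosis)
  cnt <- stats::setNames(chuk$n, chuk$diagnosis)
  add("mean_delay_weighted_chuk", mean_delay(dly, cnt, weighted = TRUE),
      1.86, 2)

  out <- do.call(rbind, targets)
  out$pass <- round(out$value, out$digits) == out$printed
  class(out) <- c("study_replication", "data.frame")
  out
}

#' @export
print.study_replication <- function(x, ...) {
  cat("Study replication from packaged tables:",
      sum(x$pass), "of", nrow(x), "targets reproduced\n\n")
  disp <- data.frame(target = x$target,
                     computed = mapply(function(v, d) round(v, d),
                                       x$value, x$digits),
                     printed = x$printed,
                     pass = ifelse(x$pass, "ok", "FAIL"))
  print(disp, row.names = FALSE)
  invisible(x)
}

#' Compare algorithms end to end on one cohort
#'
#' Evaluates each algorithm on the cohort (fit, sensitivity, delay, harm),
#' scores its structural complexity, and runs the pairwise CAPA
#' comparison, returning one consolidated ranking table. All randomness,
#' if the cohort was generated, is upstream in the cohort spec; the
#' comparison itself is deterministic.
#'
#' @param algorithms named list of [clinical_algorithm] objects.
#' @param cohort a `patient_cohort`.
#' @param weights optional `harm_weights`.
#' @param loop_rule CASA loop-parameter rule, see [casa_score()].
#' @param max_loop_iterations passed to [traverse()].
#' @return object of class `algorithm_comparison`: `table` (one row per
#'   algorithm: sensitivity, fit, delay, harm, CASA score, ranked by
#'   restricted sensitivity), `evaluations`, `casa`, `capa` (pairwise
#'   list).
#' @export
compare_algorithms <- function(algorithms, cohort, weights = NULL,
                               loop_rule = "unit",
                               max_loop_iterations = 3L) {
  stopifnot(is.list(algorithms), length(algorithms) > 0L)
  ids <- vapply(algorithms, `[[`, character(1), "algorithm_id")
  evals <- lapply(algorithms, evaluate_algorithm, cohort = cohort,
                  weights = weights,
                  max_loop_iterations = max_loop_iterations)
  casa <- lapply(algorithms, casa_score, loop_rule = loop_rule)
  cases <- expand_cases(cohort)
  capa <- list()
  if (length(algorithms) > 1L) {
    for (i in seq_len(length(algorithms) - 1L)) {
      for (j in seq(i + 1L, length(algorithms))) {
        capa[[paste(ids[i], ids[j], sep = ":")]] <-
          capa_compare(algorithms[[i]], algorithms[[j]], cases, cohort,
                       max_loop_iterations)
      }
    }
  }
  tab <- data.frame(
    algorithm = ids,
    sensitivity_restricted = vapply(evals, `[[`, numeric(1),
                                    "sensitivity_restricted"),
    sensitivity_inclusive = vapply(evals, `[[`, numeric(1),
                                   "sensitivity_inclusive"),
    fit_rate = vapply(evals, `[[`, numeric(1), "fit_rate"),
    mean_delay = vapply(evals, `[[`, numeric(1), "mean_delay_weighted"),
    harm_total = vapply(evals, `[[`, numeric(1), "harm_total"),
    casa = vapply(casa, `[[`, numeric(1), "score"),
    stringsAsFactors = FALSE)
  ord <- order(-tab$sensitivity_restricted)
  tab <- tab[ord, , drop = FALSE]
  row.names(tab) <- NULL
  structure(list(table = tab, evaluations = stats::setNames(evals, ids),
                 casa = stats::setNames(casa, ids), capa = capa),
            class = "algorithm_comparison")
}

#' @export
print.algorithm_comparison <- function(x, ...) {
  cat("Algorithm comparison (ranked by restricted sensitivity):\n")
  tab <- x$table
  tab$sensitivity_restricted <- round(tab$sensitivity_restricted, 1)
  tab$sensitivity_inclusive <- round(tab$sensitivity_inclusive, 1)
  tab$fit_rate <- round(tab$fit_rate, 1)
  tab$mean_delay <- round(tab$mean_delay, 2)
  print(tab, row.names = FALSE)
  if (length(x$capa) > 0) {
    cat("\nPairwise CAPA aggregates:\n")
    for (nm in names(x$capa))
      cat("  ", nm, ": ", x$capa[[nm]]$aggregate, "\n", sep = "")
  }
  invisible(x)
}
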