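# Traversal engine: virtual application of a flowchart to a patient.
#
# Simulates the step-by-step management a clinician would deliver by
# following the algorithm literally: start at the entry state, answer each
# dichotomous question from the patient's findings, accrue each box's
# serial delay on entry (again on re-entry through a loop), and stop at a
# terminal action box. A patient "fits" when a terminal box is reached;
# the failure modes — an unknown finding at a decision box, exceeding the
# loop allowance, or a malformed dead end — are statuses, not errors.

TRAVERSAL_STATUSES <- c("FIT", "NO_FIT_MISSING_FINDING",
                        "NO_FIT_LOOP_LIMIT", "NO_FIT_DEAD_END")

#' Route one patient through a clinical algorithm
#'
#' @param alg a [clinical_algorithm].
#' @param findings named list of finding values (see [patient_findings()]),
#'   or a `patient_cohort` row's findings.
#' @param patient_id identifier copied into the result.
#' @param max_loop_iterations backward-edge traversals allowed before the
#'   traversal is abandoned as `NO_FIT_LOOP_LIMIT`.
#' @return an object of class `traversal_result`: `status`,
#'   `terminal_diagnosis` (`NA` unless a diagnostic box was reached),
#'   `path` (node ids in visit order), `tests` (test ids in visit order),
#'   `delay_days`, `loop_iterations`.
#' @export
traverse <- function(alg, findings, patient_id = NA_character_,
                     max_loop_iterations = 3L) {
  stopifnot(inherits(alg, "clinical_algorithm"))
  cur <- alg$entry
  path <- character(0)
  tests <- character(0)
  delay <- 0
  loops <- 0L
  status <- NA_character_
  diagnosis <- NA_character_
  max_steps <- length(alg$nodes) * (max_loop_iterations + 1L) + 1L

  repeat {
    node <- alg$nodes[[cur]]
    path <- c(path, cur)
    delay <- delay + node$delay_days
    if (!is.null(node$test)) tests <- c(tests, node$test)
    out <- alg$adj[[cur]]

    if (length(out) == 0L) {
      status <- "FIT"
      if (node$kind == "diagnostic_action") diagnosis <- node$diagnosis
      break
    }
    if (node$kind == "decision") {
      ans <- eval_predicate(node$predicate, findings)
      if (is.na(ans)) { status <- "NO_FIT_MISSING_FINDING"; break }
      edge <- out[[if (ans) "yes" else "no"]]
    } else {
      edge <- out[["next"]]
    }
    if (is.null(edge)) { status <- "NO_FIT_DEAD_END"; break }
    if (edge$backward) {
      loops <- loops + 1L
      if (loops > max_loop_iterations) { status <- "NO_FIT_LOOP_LIMIT"; break }
    }
    cur <- edge$to
    if (length(path) >= max_steps) { status <- "NO_FIT_DEAD_END"; break }
  }

  structure(list(patient_id = patient_id, algorithm_id = alg$algorithm_id,
                 status = status, terminal_diagnosis = diagnosis,
                 path = path, tests = tests, delay_days = delay,
                 loop_iterations = loops),
            class = "traversal_result")
}

#' @export
print.traversal_result <- function(x, ...) {
  cat("Traversal of ", x$algorithm_id,
      if (!is.na(x$patient_id)) paste0(" for patient ", x$patient_id),
      ": ", x$status, "\n", sep = "")
  if (!is.na(x$terminal_diagnosis))
    cat("  diagnosis: ", x$terminal_diagnosis, "\n", sep = "")
  cat("  path: ", paste(x$path, collapse = " > "), "\n", sep = "")
  cat("  serial delay: ", x$delay_days, " days; loops: ",
      x$loop_iterations, "\n", sep = "")
  invisible(x)
}

#' Route a case list through an algorithm
#'
#' Applies [traverse()] once per case (patients with two diagnoses are
#' traversed once per case; traversals are independent, so the repeat is
#' identical). Order is preserved.
#'
#' @param alg a [clinical_algorithm].
#' @param cases case data frame from [expand_cases()].
#' @param cohort the `patient_cohort` the cases refer to.
#' @param max_loop_iterations passed to [traverse()].
#' @return data frame of class `traversal_set`, one row per case:
#'   `patient_id`, `true_diagnosis`, `algorithm_id`, `status`,
#'   `terminal_diagnosis`, `delay_days`, `loop_iterations`, `path` and
#'   `tests` (both `|`-separated).
#' @export
traverse_cohort <- function(alg, cases, cohort, max_loop_iterations = 3L) {
  n <- nrow(cases)
  res <- data.frame(patient_id = cases$patient_id,
                    true_diagnosis = cases$true_diagnosis,
                    algorithm_id = rep(alg$algorithm_id, n),
                    status = character(n),
                    terminal_diagnosis = rep(NA_character_, n),
                    delay_days = numeric(n),
                    loop_iterations = integer(n),
                    path = character(n), tests = character(n),
                    stringsAsFactors = FALSE)
  fcache <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    pid <- cases$patient_id[i]
    f <- get0(pid, envir = fcache)
    if (is.null(f)) {
      f <- patient_findings(cohort, pid)
      assign(pid, f, envir = fcache)
    }
    tr <- traverse(alg, f, pid, max_loop_iterations)
    res$status[i] <- tr$status
    res$terminal_diagnosis[i] <- tr$terminal_diagnosis
    res$delay_days[i] <- tr$delay_days
    res$loop_iterations[i] <- tr$loop_iterations
    res$path[i] <- paste(tr$path, collapse = "|")
    res$tests[i] <- paste(tr$tests, collapse = "|")
  }
  class(res) <- c("traversal_set", "data.frame")
  res
}

#' Serial delay accrued along a traversal path
#'
#' Recomputes the theoretical serial delay of a traversal from the node
#' delays along its path: every visited box contributes its turnaround,
#' re-entered boxes once per entry. Defined for non-fitting traversals too
#' (delay accrued up to the stop).
#'
#' @param alg the [clinical_algorithm] that produced the result.
#' @param result a `traversal_result`, or a character vector of node ids.
#' @return delay in days.
#' @export
path_delay <- function(alg, result) {
  stopifnot(inherits(alg, "clinical_algorithm"))
  path <- if (inherits(result, "traversal_result")) result$path else result
  unknown <- setdiff(path, names(alg$nodes))
  if (length(unknown) > 0L)
    stop("path references unknown node '", unknown[1L], "'", call. = FALSE)
  sum(vapply(alg$nodes[path], `[[`, numeric(1), "delay_days"))
}
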