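# Clinical Algorithm Nosology: structural complexity (CASA) and pairwise
# patient-abstraction similarity (CAPA).

#' CASA structural complexity score
#'
#' Content-independent complexity of a flowchart:
#' `2 * n_diagnostic + 1 * n_other + sum(loop parameters)`, where
#' diagnostic boxes are those assigning a diagnosis, every other box
#' weighs 1, and each backward (loop) edge contributes a loop parameter.
#' The source methodology does not pin down the loop-parameter valuation,
#' so it is pluggable: `"unit"` values every loop at 1; `"enclosed"`
#' values a loop by the number of boxes it spans in the canonical
#' depth-first ordering (loop target through loop source, inclusive).
#'
#' @param alg a [clinical_algorithm].
#' @param loop_rule `"unit"` or `"enclosed"`.
#' @return object of class `casa_result`: `algorithm_id`, `n1_dx`,
#'   `n2_d0`, `loop_params` (one value per backward edge), `loop_rule`,
#'   `score`.
#' @export
casa_score <- function(alg, loop_rule = c("unit", "enclosed")) {
  loop_rule <- match.arg(loop_rule)
  cen <- census(alg)
  loops <- cen$backward_edges
  lp <- if (nrow(loops) == 0L) numeric(0)
  else if (loop_rule == "unit") rep(1, nrow(loops))
  else {
    pos <- match(loops$from, alg$dfs_order)
    tpos <- match(loops$to, alg$dfs_order)
    abs(pos - tpos) + 1
  }
  structure(list(algorithm_id = alg$algorithm_id,
                 n1_dx = cen$n_diagnostic, n2_d0 = cen$n_other,
                 loop_params = lp, loop_rule = loop_rule,
                 score = 2 * cen$n_diagnostic + cen$n_other + sum(lp)),
            class = "casa_result")
}

#' @export
print.casa_result <- function(x, ...) {
  cat("CASA complexity of '", x$algorithm_id, "': ", x$score,
      "  (2x", x$n1_dx, " diagnostic + ", x$n2_d0, " other + ",
      sum(x$loop_params), " loop, rule=", x$loop_rule, ")\n", sep = "")
  invisible(x)
}

# Abstract one traversal to the pair (ordered tests, terminal decision).
# The decision is the terminal diagnosis when one was assigned, else the
# terminal action box's label.
.abstract <- function(alg, tr) {
  decision <- tr$terminal_diagnosis
  if (is.na(decision)) {
    last <- tr$path[length(tr$path)]
    decision <- alg$nodes[[last]]$label
  }
  list(tests = tr$tests, decision = decision)
}

.capa_case_score <- function(a, b) {
  if (!identical(a$decision, b$decision)) return(0L)
  if (identical(as.character(a$tests), as.character(b$tests))) return(10L)
  if (setequal(a$tests, b$tests)) return(8L)
  0L
}

#' CAPA pairwise algorithm comparison
#'
#' Routes every case through both algorithms, abstracts each management to
#' its ordered test sequence and terminal decision, and scores each case
#' on the three-level scale: identical (10, same tests in the same order
#' and same decision), similar (8, same tests in a different order, same
#' decision), different (0, a different decision — or a different set of
#' steps). Cases that fit neither or only one algorithm are excluded from
#' the distribution and reported as a count. The aggregate is the modal
#' per-case category score, ties broken toward the lower score.
#'
#' @param alg_a,alg_b [clinical_algorithm] objects.
#' @param cases case data frame ([expand_cases()]).
#' @param cohort the `patient_cohort` the cases refer to.
#' @param max_loop_iterations passed to [traverse()].
#' @return object of class `capa_result`: `pair`, `per_case_scores`,
#'   `distribution` (proportions over identical/similar/different),
#'   `n_scored`, `n_excluded`, `aggregate`.
#' @export
capa_compare <- function(alg_a, alg_b, cases, cohort,
                         max_loop_iterations = 3L) {
  scores <- integer(0)
  n_excluded <- 0L
  for (i in seq_len(nrow(cases))) {
    f <- patient_findings(cohort, cases$patient_id[i])
    ta <- traverse(alg_a, f, cases$patient_id[i], max_loop_iterations)
    tb <- traverse(alg_b, f, cases$patient_id[i], max_loop_iterations)
    if (!identical(ta$status, "FIT") || !identical(tb$status, "FIT")) {
      n_excluded <- n_excluded + 1L
      next
    }
    scores <- c(scores, .capa_case_score(.abstract(alg_a, ta),
                                         .abstract(alg_b, tb)))
  }
  levels <- c(identical = 10L, similar = 8L, different = 0L)
  counts <- vapply(levels, function(s) sum(scores == s), integer(1))
  dist <- if (length(scores) > 0) counts / length(scores) else
    stats::setNames(rep(NA_real_, 3L), names(levels))
  aggregate <- if (length(scores) > 0) {
    # modal category; ties resolved toward the lower score
    best <- names(counts)[counts == max(counts)]
    min(levels[best])
  } else NA_integer_
  structure(list(pair = c(alg_a$algorithm_id, alg_b$algorithm_id),
                 per_case_scores = scores, distribution = dist,
                 n_scored = length(scores), n_excluded = n_excluded,
                 aggregate = aggregate),
            class = "capa_result")
}

#' @export
print.capa_result <- function(x, ...) {
  cat("CAPA comparison ", x$pair[1], " vs ", x$pair[2], ": aggregate ",
      x$aggregate, "\n", sep = "")
  if (x$n_scored > 0) {
    d <- round(100 * x$distribution, 1)
    cat("  identical ", d[["identical"]], "% / similar ", d[["similar"]],
        "% / different ", d[["different"]], "%  (", x$n_scored,
        " cases scored, ", x$n_excluded, " excluded)\n", sep = "")
  } else {
    cat("  no case fit both algorithms (", x$n_excluded, " excluded)\n",
        sep = "")
  }
  invisible(x)
}
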