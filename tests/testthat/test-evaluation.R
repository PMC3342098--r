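# Confusion accounting, sensitivity, delay and harm operations.

fit_result <- function(dx) list(status = "FIT", terminal_diagnosis = dx)
nofit_result <- list(status = "NO_FIT_MISSING_FINDING",
                     terminal_diagnosis = NA_character_)

test_that("the per-case accounting rule covers all outcomes", {
  covered <- c("A", "B")
  # correct diagnosis
  inc <- score_case("A", fit_result("A"), covered)
  expect_equal(inc$diagnosis, "A"); expect_equal(inc$counter, "tp")
  # wrong diagnosis: FN for the truth AND FP for the wrong condition
  inc <- score_case("A", fit_result("B"), covered)
  expect_equal(inc$counter[inc$diagnosis == "A"], "fn")
  expect_equal(inc$counter[inc$diagnosis == "B"], "fp")
  # no fit: FN only, no FP anywhere
  inc <- score_case("A", nofit_result, covered)
  expect_equal(inc, data.frame(diagnosis = "A", counter = "fn"))
  # fit at a non-diagnostic terminal: also FN only
  inc <- score_case("A", fit_result(NA_character_), covered)
  expect_equal(inc, data.frame(diagnosis = "A", counter = "fn"))
  # sentinel truth: FP only when a diagnosis was wrongly reached
  inc <- score_case("NO_DIAGNOSIS", fit_result("B"), covered)
  expect_equal(inc, data.frame(diagnosis = "B", counter = "fp"))
  expect_equal(nrow(score_case("RARE_DIAGNOSIS", nofit_result, covered)), 0L)
  expect_error(score_case("A", fit_result("C"), covered), "outside")
})

test_that("a replayed study count matrix tabulates back to itself", {
  for (a in c("chuk", "msf", "who")) {
    cells <- study_counts(a)
    stream <- stream_from_counts(cells)
    tab <- tabulate_confusion(stream$cases, stream$results,
                              cells$diagnosis)
    expect_equal(tab$fp, cells$fp, label = paste(a, "fp"))
    expect_equal(tab$tp, cells$tp, label = paste(a, "tp"))
    expect_equal(tab$fn, cells$fn, label = paste(a, "fn"))
    expect_equal(tab$tn, cells$tn, label = paste(a, "tn"))
    expect_equal(tab$fit, cells$fit, label = paste(a, "fit"))
    expect_equal(tab$n, cells$n, label = paste(a, "n"))
  }
  # spotlight: the smear-positive TB row of the locally tailored chart
  cells <- study_counts("chuk")
  stream <- stream_from_counts(cells)
  tab <- tabulate_confusion(stream$cases, stream$results, cells$diagnosis)
  row <- tab[tab$diagnosis == "tb_smear_pos", ]
  expect_equal(c(row$fp, row$tp, row$fn, row$tn), c(1, 42, 1, 140))
})

test_that("single-case tabulation and length checking behave", {
  cases <- data.frame(patient_id = "P1", true_diagnosis = "A")
  res <- data.frame(status = "FIT", terminal_diagnosis = "A")
  tab <- tabulate_confusion(cases, res, "A")
  expect_equal(c(tab$tp, tab$fp, tab$fn, tab$tn), c(1, 0, 0, 0))
  expect_error(tabulate_confusion(cases, res[0, ], "A"), "differ in length")
})

test_that("confusion counts are conserved on random case streams", {
  set.seed(2718)
  covered <- LETTERS[1:6]
  for (k in 1:50) {
    n <- sample(10:60, 1)
    truth <- sample(c(covered, "NO_DIAGNOSIS"), n, replace = TRUE,
                    prob = c(rep(1, 6), 0.5))
    status <- sample(c("FIT", "NO_FIT_MISSING_FINDING"), n, TRUE,
                     prob = c(0.8, 0.2))
    pred <- ifelse(status == "FIT",
                   sample(c(covered, NA), n, TRUE), NA)
    cases <- data.frame(patient_id = sprintf("P%d", 1:n),
                        true_diagnosis = truth)
    results <- data.frame(status = status, terminal_diagnosis = pred)
    tab <- tabulate_confusion(cases, results, covered)
    # conservation: every row sums to the case total
    expect_true(all(tab$tp + tab$fp + tab$fn + tab$tn == n))
    # independent replay: counters re-derived per case, one at a time
    fp2 <- tp2 <- fn2 <- stats::setNames(integer(6), covered)
    for (i in 1:n) {
      t <- truth[i]; p <- pred[i]
      if (t %in% covered) {
        if (!is.na(p) && p == t) tp2[t] <- tp2[t] + 1L
        else fn2[t] <- fn2[t] + 1L
      }
      if (!is.na(p) && (!t %in% covered || p != t))
        fp2[p] <- fp2[p] + 1L
    }
    expect_equal(tab$tp, unname(tp2))
    expect_equal(tab$fp, unname(fp2))
    expect_equal(tab$fn, unname(fn2))
    # in-scope cases split exactly into TP + FN
    expect_equal(sum(tab$tp) + sum(tab$fn), sum(truth %in% covered))
  }
})

test_that("sensitivity uses the two published denominators", {
  cells <- data.frame(diagnosis = c("A", "B"), tp = c(100, 76),
                      fn = c(5, 3))
  expect_equal(round(sensitivity(cells, "restricted"), 1), 95.7)  # 176/184
  expect_equal(round(sensitivity(cells, "inclusive", n_enrolled = 201), 1),
               87.6)
  all_tp <- data.frame(diagnosis = "A", tp = 10, fn = 0)
  expect_equal(sensitivity(all_tp, "restricted"), 100)
  expect_error(sensitivity(data.frame(tp = 0, fn = 0), "restricted"),
               "denominator")
  expect_error(sensitivity(all_tp, "inclusive"), "denominator")
})

test_that("mean delay supports both weightings", {
  d <- c(A = 1, B = 3); n <- c(A = 3, B = 1)
  expect_equal(mean_delay(d, n, weighted = TRUE), 1.5)
  expect_equal(mean_delay(d, weighted = FALSE), 2.0)
  same <- c(A = 2.5, B = 2.5)
  expect_equal(mean_delay(same, c(A = 7, B = 2), TRUE), 2.5)
  expect_equal(mean_delay(same, weighted = FALSE), 2.5)
  expect_error(mean_delay(numeric(0)), "empty")
  expect_error(mean_delay(d, c(A = 1, C = 1), TRUE), "same diagnoses")
})

test_that("harm multiplies errors by their weights and splits cleanly", {
  w <- study_harm()
  for (a in c("chuk", "msf", "who")) {
    h <- harm(study_counts(a), w)
    expect_equal(h$total, h$commission + h$omission)
    expect_gte(h$commission, 0)
  }
  h <- harm(study_counts("msf"), w)
  expect_equal(h$commission, 64)
  expect_equal(h$omission, 176)
  zero <- data.frame(diagnosis = "tb_smear_pos", fp = 0, fn = 0)
  expect_equal(harm(zero, w), list(commission = 0, omission = 0, total = 0))
  # harm strictly increases in any error with positive weight
  base <- study_counts("chuk")
  bump <- base; bump$fp[1] <- bump$fp[1] + 1L
  expect_gt(harm(bump, w)$total, harm(base, w)$total)
  expect_error(harm(data.frame(diagnosis = "unknown_dx", fp = 1, fn = 0), w),
               "missing harm weight")
})

test_that("concordance scores identical, similar and different management", {
  tr <- list(status = "FIT", terminal_diagnosis = "TB",
             tests = c("cxr", "smear"))
  expect_equal(concordance(tr, c("cxr", "smear"), "TB"), 10L)
  expect_equal(concordance(tr, c("smear", "cxr"), "TB"), 8L)
  expect_equal(concordance(tr, c("cxr", "smear"), "PCP"), 0L)
  expect_equal(concordance(tr, "cxr|smear", "TB"), 10L)   # dialect string
  expect_equal(concordance(tr, c("cxr"), "TB"), 0L)        # different steps
  nofit <- list(status = "NO_FIT_MISSING_FINDING",
                terminal_diagnosis = NA_character_, tests = "cxr")
  expect_equal(concordance(nofit, "cxr", "TB"), 0L)
})

test_that("end-to-end evaluation on a noise-free calibrated cohort is perfect", {
  chuk <- study_algorithm("chuk")
  prof <- calibrate_profiles(chuk)
  spec <- cohort_spec(n_patients = 120, finding_profiles = prof,
                      noise_rate = 0, multi_dx_rate = 0, seed = 99)
  coh <- generate_cohort(spec)
  ev <- evaluate_algorithm(chuk, coh, weights = study_harm())
  expect_equal(ev$sensitivity_restricted, 100)
  expect_equal(ev$fit_rate, 100)
  expect_equal(ev$harm_total, 0)
  expect_equal(sum(ev$cells$fp), 0)
})
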