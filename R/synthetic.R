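# Synthetic cohort generation.
#
# Stands in for the study's raw patient data, which were never deposited:
# a cohort is drawn with a configurable disease spectrum (defaulting to
# the study's printed case mix), per-diagnosis finding archetypes, a
# misrouting noise rate, an occasional second diagnosis, and the study's
# age/sex distribution. Findings are conditionally independent given the
# diagnosis; noise replaces a finding with unknown (half the time) or a
# wrong value (the other half), producing the two observed failure modes:
# no-fit and misroute.

#' Default disease spectrum of the packaged study cohort
#'
#' Per-diagnosis case counts of the study population (201 enrolled
#' patients; the counts sum to 202 because one patient carried two
#' diagnoses), including the two sentinel categories.
#'
#' @return named integer vector of counts.
#' @export
study_diagnosis_counts <- function() {
  c(tb_smear_pos = 43L, pcp = 39L, pleural_tb = 25L,
    lobar_pneumonia = 21L, miliary_tb = 18L, atypical_pneumonia = 18L,
    kaposi = 7L, empyema = 3L, lung_abscess = 3L,
    mediastinal_adp_tb = 3L, cavitary_tb = 2L, pericardial_tb = 2L,
    RARE_DIAGNOSIS = 9L, NO_DIAGNOSIS = 9L)
}

.study_age_bands <- function() {
  c("15-24" = 22, "25-34" = 72, "35-44" = 69, "45-54" = 29,
    "55-64" = 8, "65-74" = 1) / 201
}

#' Specify a synthetic cohort
#'
#' Defaults reproduce the study population: prevalence proportional to the
#' printed per-diagnosis counts (e.g. smear-positive TB 43 of 201 enrolled
#' patients), 119/201 female, the printed age-band distribution, one
#' second diagnosis per 183 patients, and a 39% death rate (sampled but
#' not used in scoring).
#'
#' @param n_patients cohort size.
#' @param prevalence named probability vector over diagnoses and the
#'   sentinels `RARE_DIAGNOSIS`/`NO_DIAGNOSIS`; must sum to 1. Counts are
#'   accepted and normalised.
#' @param finding_profiles named list: diagnosis -> named list of finding
#'   archetype values (see [calibrate_profiles()]). May be `NULL` at spec
#'   time but is required by [generate_cohort()].
#' @param noise_rate probability that any one finding is corrupted: with
#'   `noise_rate/2` it becomes unknown, with `noise_rate/2` it is replaced
#'   by a wrong value.
#' @param multi_dx_rate probability a non-sentinel patient carries a
#'   second, distinct diagnosis.
#' @param age_band_probs named probabilities over age bands `"lo-hi"`.
#' @param p_female probability of female sex.
#' @param p_death marginal death rate for the `outcome` column.
#' @param seed integer seed; generation is a pure function of the spec.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 201L,
                        prevalence = study_diagnosis_counts(),
                        finding_profiles = NULL,
                        noise_rate = 0.05,
                        multi_dx_rate = 1 / 183,
                        age_band_probs = .study_age_bands(),
                        p_female = 119 / 201,
                        p_death = 0.39,
                        seed = 1L) {
  if (length(prevalence) == 0L || is.null(names(prevalence)))
    stop("prevalence must be a non-empty named vector", call. = FALSE)
  if (any(prevalence < 0))
    stop("prevalence entries must be non-negative", call. = FALSE)
  prevalence <- prevalence / sum(prevalence)
  for (p in list(noise_rate = noise_rate, multi_dx_rate = multi_dx_rate,
                 p_female = p_female, p_death = p_death)) {
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
      stop("probabilities must be single values in [0, 1]", call. = FALSE)
  }
  if (abs(sum(age_band_probs) - 1) > 1e-9)
    stop("age_band_probs must sum to 1", call. = FALSE)
  if (n_patients < 0) stop("n_patients must be >= 0", call. = FALSE)
  structure(list(n_patients = as.integer(n_patients),
                 prevalence = prevalence,
                 finding_profiles = finding_profiles,
                 noise_rate = noise_rate, multi_dx_rate = multi_dx_rate,
                 age_band_probs = age_band_probs, p_female = p_female,
                 p_death = p_death, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Background value for a finding: what a patient without any relevant
# disease shows. Typed off the pooled archetype values.
.background_value <- function(values) {
  if (all(vapply(values, is.logical, logical(1)))) return(FALSE)
  if (all(vapply(values, is.numeric, logical(1)))) return(0)
  "none"
}

.perturb_value <- function(v, pool) {
  alt <- pool[!vapply(pool, identical, logical(1), v)]
  if (length(alt) > 0) return(alt[[sample.int(length(alt), 1L)]])
  if (is.logical(v)) return(!v)
  if (is.numeric(v)) return(v + 1)
  "noise"
}

.empty_cohort <- function(finding_ids) {
  df <- data.frame(patient_id = character(0), age = numeric(0),
                   sex = character(0), dx1 = character(0),
                   dx2 = character(0), outcome = character(0),
                   observed_delay_days = numeric(0),
                   observed_tests = character(0),
                   observed_treatment = character(0),
                   stringsAsFactors = FALSE)
  for (f in finding_ids) df[[paste0("f_", f)]] <- logical(0)
  class(df) <- c("patient_cohort", "data.frame")
  df
}

#' Generate a synthetic patient cohort
#'
#' Draws `n_patients` records reproducibly from the spec: diagnosis from
#' the prevalence vector, sex and age band from their distributions (ages
#' uniform within a band, all > 15), findings from the diagnosis's
#' archetype (background-negative for unconstrained findings and for
#' sentinel patients), then each finding independently corrupted at the
#' noise rate. The global RNG state is saved and restored, so generation
#' has no side effects.
#'
#' @param spec a [cohort_spec()]; `finding_profiles` must be set.
#' @return a `patient_cohort` data frame.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  profiles <- spec$finding_profiles
  if (is.null(profiles))
    stop("cohort_spec has no finding_profiles; see calibrate_profiles()",
         call. = FALSE)
  finding_ids <- sort(unique(unlist(lapply(profiles, names))))
  if (spec$n_patients == 0L) return(.empty_cohort(finding_ids))

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(spec$seed)

  n <- spec$n_patients
  pool <- lapply(finding_ids, function(f) {
    vals <- lapply(profiles, function(pr) pr[[f]])
    vals <- vals[!vapply(vals, is.null, logical(1))]
    unique(c(vals, list(.background_value(vals))))
  })
  names(pool) <- finding_ids
  background <- lapply(pool, function(p) .background_value(p))

  dx_names <- names(spec$prevalence)
  non_sentinel <- setdiff(dx_names, SENTINELS)
  dx1 <- sample(dx_names, n, replace = TRUE, prob = spec$prevalence)
  dx2 <- rep(NA_character_, n)
  sex <- ifelse(stats::runif(n) < spec$p_female, "female", "male")
  bands <- sample(names(spec$age_band_probs), n, replace = TRUE,
                  prob = spec$age_band_probs)
  lo <- as.numeric(sub("-.*", "", bands))
  hi <- as.numeric(sub(".*-", "", bands))
  lo <- pmax(lo, 16)  # inclusion criterion: age > 15
  age <- floor(stats::runif(n, lo, hi + 1))
  outcome <- ifelse(stats::runif(n) < spec$p_death, "died", "survived")

  fmat <- vector("list", length(finding_ids))
  names(fmat) <- finding_ids
  for (f in finding_ids) fmat[[f]] <- rep(list(background[[f]]), n)

  for (i in seq_len(n)) {
    if (!is_sentinel(dx1[i]) && length(non_sentinel) > 1L &&
        stats::runif(1) < spec$multi_dx_rate) {
      others <- setdiff(non_sentinel, dx1[i])
      dx2[i] <- sample(others, 1L)
    }
    vals <- profiles[[dx1[i]]]
    if (!is.na(dx2[i])) {
      extra <- profiles[[dx2[i]]]
      vals <- c(vals, extra[setdiff(names(extra), names(vals))])
    }
    for (f in names(vals)) fmat[[f]][[i]] <- vals[[f]]
    if (spec$noise_rate > 0) {
      u <- stats::runif(length(finding_ids))
      for (k in seq_along(finding_ids)) {
        f <- finding_ids[k]
        if (u[k] < spec$noise_rate / 2) {
          fmat[[f]][[i]] <- NA
        } else if (u[k] < spec$noise_rate) {
          fmat[[f]][[i]] <- .perturb_value(fmat[[f]][[i]], pool[[f]])
        }
      }
    }
  }

  df <- data.frame(patient_id = sprintf("S%04d", seq_len(n)), age = age,
                   sex = sex, dx1 = dx1, dx2 = dx2, outcome = outcome,
                   observed_delay_days = NA_real_,
                   observed_tests = NA_character_,
                   observed_treatment = NA_character_,
                   stringsAsFactors = FALSE)
  for (f in finding_ids) {
    col <- fmat[[f]]
    col[vapply(col, function(v) length(v) != 1L || is.na(v), logical(1))] <-
      list(NA)
    tryu <- unlist(col)
    df[[paste0("f_", f)]] <- if (length(tryu) == nrow(df)) tryu else
      vapply(col, function(v) as.character(v), character(1))
  }
  class(df) <- c("patient_cohort", "data.frame")
  df
}

# ---- profile calibration ---------------------------------------------------

# Shortest forward path (ignoring backward edges) from the entry to a
# node satisfying `is_target`; returns the node-id vector or NULL.
.bfs_path <- function(alg, is_target) {
  fwd <- alg$edges[!alg$edges$backward, , drop = FALSE]
  prev <- stats::setNames(rep(NA_character_, length(alg$nodes)),
                          names(alg$nodes))
  seen <- alg$entry
  queue <- alg$entry
  while (length(queue) > 0L) {
    cur <- queue[[1L]]
    queue <- queue[-1L]
    if (is_target(alg$nodes[[cur]])) {
      path <- cur
      while (!is.na(prev[[cur]])) { cur <- prev[[cur]]; path <- c(cur, path) }
      return(path)
    }
    nxt <- fwd$to[fwd$from == cur]
    for (t in nxt) {
      if (!t %in% seen) {
        seen <- c(seen, t)
        prev[[t]] <- cur
        queue <- c(queue, t)
      }
    }
  }
  NULL
}

# Solve the conjunction of (predicate, required outcome) constraints on a
# single finding; returns a satisfying value or signals a contradiction.
.solve_finding <- function(finding, cons, dx) {
  fail <- function() stop("contradictory predicates on the path to '", dx,
                          "' for finding '", finding, "'", call. = FALSE)
  flag_req <- NULL
  pin <- NULL
  allow <- NULL
  excl <- list()
  lo <- -Inf; hi <- Inf
  numeric_mode <- FALSE
  step <- function(x) if (abs(x - round(x)) < 1e-9) 1 else
    max(abs(x) * 1e-6, 1e-6)
  for (c in cons) {
    op <- c$op; val <- c$value; want <- c$outcome
    if (op == "absent") { op <- "present"; want <- !want }
    if (op == "present") {
      if (!is.null(flag_req) && flag_req != want) fail()
      flag_req <- want
    } else if (op == "equals") {
      if (is.numeric(val)) numeric_mode <- TRUE
      if (want) {
        if (!is.null(pin) && !identical(pin, val)) fail()
        pin <- val
      } else excl <- c(excl, list(val))
    } else if (op == "in_set") {
      if (want) {
        allow <- if (is.null(allow)) val else intersect(allow, val)
        if (length(allow) == 0L) fail()
      } else excl <- c(excl, as.list(val))
    } else if (op == "at_least") {
      numeric_mode <- TRUE
      if (want) lo <- max(lo, val) else hi <- min(hi, val - step(val))
    } else if (op == "at_most") {
      numeric_mode <- TRUE
      if (want) hi <- min(hi, val) else lo <- max(lo, val + step(val))
    }
  }
  excluded <- function(v) any(vapply(excl, identical, logical(1), v))
  if (!is.null(flag_req)) {
    if (numeric_mode || !is.null(allow)) fail()
    if (!is.null(pin) && !identical(isTRUE(.as_flag(pin)), flag_req)) fail()
    if (excluded(flag_req)) fail()
    return(flag_req)
  }
  if (numeric_mode) {
    if (lo > hi + 1e-12) fail()
    v <- if (!is.null(pin)) pin else if (is.finite(lo)) lo else
      if (is.finite(hi)) hi else 1
    if (!is.null(pin) && (pin < lo - 1e-12 || pin > hi + 1e-12)) fail()
    tries <- 0L
    while (excluded(v)) {
      v <- v + 1
      tries <- tries + 1L
      if (v > hi + 1e-12 || tries > 1000L) fail()
    }
    return(v)
  }
  if (!is.null(pin)) {
    if (!is.null(allow) && !pin %in% allow) fail()
    if (excluded(pin)) fail()
    return(pin)
  }
  cands <- c(allow, "other", paste0("other_", seq_len(length(excl) + 1L)))
  for (v in cands) if (!excluded(v)) return(v)
  fail()
}

#' Derive per-diagnosis finding archetypes from a flowchart
#'
#' For each diagnosis the flowchart covers, back-propagates the path
#' constraints from the entry box to that diagnostic box: the archetype is
#' any findings map satisfying the conjunction of predicate outcomes along
#' the (shortest forward) path, so a noise-free patient with the archetype
#' traverses the flowchart to exactly that diagnosis.
#'
#' @param alg a [clinical_algorithm].
#' @return named list: diagnosis -> named list of finding values, suitable
#'   as `finding_profiles` for [cohort_spec()].
#' @export
calibrate_profiles <- function(alg) {
  stopifnot(inherits(alg, "clinical_algorithm"))
  profiles <- list()
  for (dx in alg$diagnoses_covered) {
    path <- .bfs_path(alg, function(n)
      n$kind == "diagnostic_action" && identical(n$diagnosis, dx))
    if (is.null(path))
      stop("diagnosis '", dx, "' unreachable by forward edges",
           call. = FALSE)
    cons <- list()
    for (i in seq_len(length(path) - 1L)) {
      node <- alg$nodes[[path[i]]]
      if (node$kind != "decision") next
      e <- alg$edges[alg$edges$from == path[i] &
                       alg$edges$to == path[i + 1L] &
                       !alg$edges$backward, , drop = FALSE]
      outcome <- e$branch[1L] == "yes"
      p <- node$predicate
      cons[[length(cons) + 1L]] <-
        list(finding = p$finding, op = p$op, value = p$value,
             outcome = outcome)
    }
    fnd <- unique(vapply(cons, `[[`, character(1), "finding"))
    prof <- lapply(fnd, function(f)
      .solve_finding(f, Filter(function(c) c$finding == f, cons), dx))
    names(prof) <- fnd
    profiles[[dx]] <- prof
  }
  profiles
}
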