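# Shared builders for the test suite. Everything is constructed in code;
# no binary fixtures.

edge_df <- function(from, to, branch = "next", backward = NA) {
  data.frame(from = from, to = to, branch = branch, backward = backward)
}

# Smallest legal flowchart: entry state -> one diagnostic box.
minimal_algorithm <- function(diagnosis = "TB", delay = 0) {
  clinical_algorithm(
    "minimal", "minimal", entry = "entry",
    nodes = list(
      flow_node("entry", "clinical_state", "patient presents"),
      flow_node("dx", "diagnostic_action", "treat", diagnosis = diagnosis,
                delay_days = delay)),
    edges = edge_df("entry", "dx"))
}

# One decision: smear positive -> TB, else PCP.
smear_algorithm <- function() {
  clinical_algorithm(
    "smear1", "one-decision", entry = "entry",
    nodes = list(
      flow_node("entry", "clinical_state", "cough"),
      flow_node("d1", "decision", "smear positive?",
                flow_predicate("smear", "equals", "positive")),
      flow_node("dx_tb", "diagnostic_action", "treat TB",
                diagnosis = "TB"),
      flow_node("dx_pcp", "diagnostic_action", "treat PCP",
                diagnosis = "PCP")),
    edges = rbind(edge_df("entry", "d1"),
                  edge_df("d1", "dx_tb", "yes"),
                  edge_df("d1", "dx_pcp", "no")))
}

# Three boolean decisions a, b, c; eight boolean patients enumerate the
# full truth table of terminal diagnoses.
toy3_algorithm <- function() {
  clinical_algorithm(
    "toy3", "three-decision toy", entry = "entry",
    nodes = list(
      flow_node("entry", "clinical_state", "start"),
      flow_node("da", "decision", "a?", flow_predicate("a", "present")),
      flow_node("db", "decision", "b?", flow_predicate("b", "present")),
      flow_node("dc", "decision", "c?", flow_predicate("c", "present")),
      flow_node("dx1", "diagnostic_action", "D1", diagnosis = "D1"),
      flow_node("dx2", "diagnostic_action", "D2", diagnosis = "D2"),
      flow_node("dx3", "diagnostic_action", "D3", diagnosis = "D3"),
      flow_node("dx4", "diagnostic_action", "D4", diagnosis = "D4")),
    edges = rbind(edge_df("entry", "da"),
                  edge_df("da", "db", "yes"), edge_df("da", "dc", "no"),
                  edge_df("db", "dx1", "yes"), edge_df("db", "dx2", "no"),
                  edge_df("dc", "dx3", "yes"), edge_df("dc", "dx4", "no")))
}

# Random valid flowchart: a random binary decision tree over boolean
# findings, optionally with loop edges spliced in (each splice replaces a
# random edge a->b with a -> new decision -> {yes: b, no: backward to an
# ancestor of a}).
random_algorithm <- function(n_decisions = 5, n_loops = 0,
                             id = "rand", p_diagnostic = 0.7) {
  counter <- new.env(parent = emptyenv())
  counter$node <- 0L; counter$dx <- 0L; counter$finding <- 0L
  nid <- function(prefix) {
    counter$node <- counter$node + 1L
    sprintf("%s%03d", prefix, counter$node)
  }
  nodes <- list(flow_node("entry", "clinical_state", "start"))
  edges <- NULL
  budget <- new.env(parent = emptyenv())
  budget$left <- n_decisions

  build <- function(parent, branch, ancestors) {
    if (budget$left > 0 && stats::runif(1) < 0.7) {
      budget$left <- budget$left - 1L
      counter$finding <- counter$finding + 1L
      id <- nid("d")
      nodes[[length(nodes) + 1L]] <<- flow_node(
        id, "decision", paste0("q", counter$finding),
        flow_predicate(paste0("f", counter$finding), "present"),
        delay_days = sample(0:2, 1))
      edges <<- rbind(edges, edge_df(parent, id, branch))
      build(id, "yes", c(ancestors, id))
      build(id, "no", c(ancestors, id))
    } else if (stats::runif(1) < p_diagnostic) {
      counter$dx <- counter$dx + 1L
      id <- nid("x")
      nodes[[length(nodes) + 1L]] <<- flow_node(
        id, "diagnostic_action", paste0("treat DX", counter$dx),
        diagnosis = paste0("DX", counter$dx),
        delay_days = sample(0:2, 1))
      edges <<- rbind(edges, edge_df(parent, id, branch))
    } else {
      id <- nid("a")
      nodes[[length(nodes) + 1L]] <<- flow_node(
        id, "other_action", "stop", delay_days = sample(0:2, 1))
      edges <<- rbind(edges, edge_df(parent, id, branch))
    }
  }
  build("entry", "next", "entry")

  for (l in seq_len(n_loops)) {
    i <- sample.int(nrow(edges), 1L)
    a <- edges$from[i]; b <- edges$to[i]; br <- edges$branch[i]
    # ancestors of a along tree edges
    anc <- a
    cur <- a
    repeat {
      # walk tree edges only; spliced loop edges carry backward = TRUE
      up <- edges$from[edges$to == cur & is.na(edges$backward)][1]
      if (length(up) == 0L || is.na(up)) break
      anc <- c(anc, up); cur <- up
      if (cur == "entry") break
    }
    target <- sample(anc, 1L)
    counter$finding <- counter$finding + 1L
    id <- nid("l")
    nodes[[length(nodes) + 1L]] <- flow_node(
      id, "decision", paste0("retry q", counter$finding),
      flow_predicate(paste0("f", counter$finding), "present"))
    edges <- edges[-i, , drop = FALSE]
    edges <- rbind(edges,
                   edge_df(a, id, br),
                   edge_df(id, b, "yes"),
                   edge_df(id, target, "no", backward = TRUE))
  }
  clinical_algorithm(id, id, entry = "entry", nodes = nodes, edges = edges)
}

# Random boolean findings covering every finding an algorithm queries.
random_findings <- function(alg, p_unknown = 0) {
  fnd <- unique(unlist(lapply(alg$nodes, function(n)
    if (!is.null(n$predicate)) n$predicate$finding)))
  vals <- lapply(fnd, function(f) {
    u <- stats::runif(1)
    if (u < p_unknown) NA else u < (1 + p_unknown) / 2
  })
  stats::setNames(vals, fnd)
}

# Rename every node of an algorithm (topology-preserving relabeling).
relabel_algorithm <- function(alg, prefix = "z") {
  map <- stats::setNames(paste0(prefix, seq_along(alg$nodes)),
                         names(alg$nodes))
  nodes <- lapply(alg$nodes, function(n) { n$id <- map[[n$id]]; n })
  names(nodes) <- NULL
  edges <- alg$edges
  edges$from <- unname(map[edges$from])
  edges$to <- unname(map[edges$to])
  clinical_algorithm(alg$algorithm_id, alg$name, map[[alg$entry]],
                     nodes, edges)
}

# Replay a per-algorithm count matrix (Table-2 shape: diagnosis, n, fp,
# tp, fn, tn, fit) as a per-case event stream, and independently as the
# (cases, results) pair tabulate_confusion() consumes. Misrouted false
# negatives are matched to false-positive slots of a *different*
# diagnosis (max-against-max greedy); fit cases in excess of TP +
# misroutes end at a non-diagnostic terminal; remaining false negatives
# are no-fits.
stream_from_counts <- function(cells) {
  dx <- cells$diagnosis
  fp_slots <- stats::setNames(cells$fp, dx)
  cap <- stats::setNames(pmin(cells$fn, cells$fit - cells$tp), dx)
  misroute <- matrix(0L, length(dx), length(dx), dimnames = list(dx, dx))
  pick <- function(primary, secondary, exclude = NULL) {
    cand <- names(primary)[primary > 0]
    cand <- setdiff(cand, exclude)
    if (length(cand) == 0L) return(NA_character_)
    cand[order(-primary[cand], -secondary[cand])][1L]
  }
  while (sum(fp_slots) > 0L) {
    s <- pick(fp_slots, cap)      # consume a trapped slot early
    t <- pick(cap, fp_slots, exclude = s)
    if (is.na(t)) stop("count matrix not replayable as a case stream")
    misroute[t, s] <- misroute[t, s] + 1L
    fp_slots[s] <- fp_slots[s] - 1L
    cap[t] <- cap[t] - 1L
  }
  true <- character(0); status <- character(0); pred <- character(0)
  push <- function(t, st, p) {
    true <<- c(true, t); status <<- c(status, st); pred <<- c(pred, p)
  }
  for (d in dx) {
    row <- cells[cells$diagnosis == d, ]
    mis <- sum(misroute[d, ])
    fit_nodx <- row$fit - row$tp - mis
    nofit <- row$fn - mis - fit_nodx
    stopifnot(fit_nodx >= 0, nofit >= 0)
    for (k in seq_len(row$tp)) push(d, "FIT", d)
    for (s in dx) for (k in seq_len(misroute[d, s])) push(d, "FIT", s)
    for (k in seq_len(fit_nodx)) push(d, "FIT", NA_character_)
    for (k in seq_len(nofit)) push(d, "NO_FIT_MISSING_FINDING",
                                   NA_character_)
  }
  list(cases = data.frame(patient_id = sprintf("C%03d", seq_along(true)),
                          true_diagnosis = true,
                          stringsAsFactors = FALSE),
       results = data.frame(status = status, terminal_diagnosis = pred,
                            stringsAsFactors = FALSE))
}
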