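# Flowchart data model: serial, dichotomous clinical algorithms.
#
# A clinical algorithm is a directed graph of typed boxes. Four kinds are
# distinguished: the entry clinical-state box, yes/no decision boxes,
# diagnostic action boxes (the only boxes that assign a diagnosis) and all
# other action boxes (tests, referrals, treatments without a diagnosis
# label). Transition is strictly dichotomous out of decision boxes and
# serial everywhere else; backward ("loop") edges return the clinician to
# an earlier point in the chart.

NODE_KINDS <- c("clinical_state", "decision", "diagnostic_action", "other_action")
PREDICATE_OPS <- c("present", "absent", "equals", "at_least", "at_most", "in_set")
BRANCHES <- c("yes", "no", "next")

#' Build a decision predicate
#'
#' A predicate asks one dichotomous question of a patient's findings map.
#' `present`/`absent` test a flag-valued finding; `equals`, `at_least`,
#' `at_most` and `in_set` compare against a reference value. Evaluation is
#' three-valued: `TRUE`, `FALSE`, or `NA` when the finding is unknown.
#'
#' @param finding finding identifier queried in the patient findings map.
#' @param op comparator, one of `r paste0('\x60', PREDICATE_OPS, '\x60', collapse = ", ")`.
#' @param value reference value (scalar, or vector for `in_set`). Must be
#'   omitted for `present`/`absent` and supplied otherwise.
#' @return an object of class `flow_predicate`.
#' @export
flow_predicate <- function(finding, op, value = NULL) {
  stopifnot(is.character(finding), length(finding) == 1L, nzchar(finding))
  op <- match.arg(op, PREDICATE_OPS)
  if (op %in% c("present", "absent")) {
    if (!is.null(value)) {
      stop("predicate on '", finding, "': comparator '", op,
           "' carries no reference value", call. = FALSE)
    }
  } else {
    if (is.null(value) || length(value) < 1L) {
      stop("predicate on '", finding, "': comparator '", op,
           "' requires a reference value", call. = FALSE)
    }
    if (op != "in_set" && length(value) != 1L) {
      stop("predicate on '", finding, "': comparator '", op,
           "' takes a scalar reference value", call. = FALSE)
    }
    if (op %in% c("at_least", "at_most") && !is.numeric(value)) {
      stop("predicate on '", finding, "': comparator '", op,
           "' requires a numeric reference value", call. = FALSE)
    }
  }
  structure(list(finding = finding, op = op, value = value),
            class = "flow_predicate")
}

# Coerce assorted truthy encodings to a logical flag; NA when not flag-like.
.as_flag <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  if (is.character(x)) {
    lx <- tolower(x)
    if (lx %in% c("true", "yes", "1", "present", "positive")) return(TRUE)
    if (lx %in% c("false", "no", "0", "absent", "negative")) return(FALSE)
  }
  NA
}

#' Evaluate a predicate against a findings map
#'
#' @param pred a [flow_predicate].
#' @param findings named list or vector of finding values; missing entries
#'   and `NA` values are treated as unknown.
#' @return `TRUE`, `FALSE`, or `NA` (finding unknown / not comparable).
#' @export
eval_predicate <- function(pred, findings) {
  stopifnot(inherits(pred, "flow_predicate"))
  v <- findings[[pred$finding]]
  if (is.null(v) || length(v) != 1L || is.na(v)) return(NA)
  switch(pred$op,
    present  = .as_flag(v),
    absent   = !.as_flag(v),
    equals   = isTRUE(v == pred$value),
    at_least = if (is.numeric(v)) v >= pred$value else NA,
    at_most  = if (is.numeric(v)) v <= pred$value else NA,
    in_set   = v %in% pred$value
  )
}

#' Build a flowchart node
#'
#' @param id node identifier, unique within the algorithm.
#' @param kind one of `clinical_state`, `decision`, `diagnostic_action`,
#'   `other_action`.
#' @param label human-readable box text.
#' @param predicate a [flow_predicate]; required for (and only allowed on)
#'   `decision` nodes.
#' @param diagnosis diagnosis identifier; only allowed on
#'   `diagnostic_action` nodes.
#' @param test optional test identifier performed at this box.
#' @param delay_days non-negative days consumed when this box is entered
#'   (test turnaround under serial management).
#' @return an object of class `flow_node`.
#' @export
flow_node <- function(id, kind, label = id, predicate = NULL,
                      diagnosis = NULL, test = NULL, delay_days = 0) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  kind <- match.arg(kind, NODE_KINDS)
  if (kind == "decision") {
    if (is.null(predicate))
      stop("decision node '", id, "' requires a predicate", call. = FALSE)
  } else if (!is.null(predicate)) {
    stop("node '", id, "' (", kind, ") must not carry a predicate",
         call. = FALSE)
  }
  if (!is.null(diagnosis) && kind != "diagnostic_action") {
    stop("node '", id, "' (", kind, ") must not carry a diagnosis label",
         call. = FALSE)
  }
  if (kind == "diagnostic_action" && is.null(diagnosis)) {
    stop("diagnostic action node '", id, "' requires a diagnosis label",
         call. = FALSE)
  }
  if (!is.numeric(delay_days) || length(delay_days) != 1L ||
      is.na(delay_days) || delay_days < 0) {
    stop("node '", id, "': delay_days must be a non-negative number",
         call. = FALSE)
  }
  structure(list(id = id, kind = kind, label = label, predicate = predicate,
                 diagnosis = diagnosis, test = test,
                 delay_days = as.numeric(delay_days)),
            class = "flow_node")
}

#' Construct and validate a clinical algorithm
#'
#' Assembles nodes and edges into a validated flowchart. Validation
#' enforces the serial-dichotomous discipline: the entry box is a clinical
#' state, every decision box has exactly one yes- and one no-edge, every
#' other non-terminal box exactly one next-edge, every box is reachable
#' from the entry, and every terminal box is an action (diagnostic or
#' other). Backward edges are detected from the entry-rooted depth-first
#' ordering; an explicit `backward` flag on an edge overrides detection.
#'
#' @param algorithm_id short identifier.
#' @param name display name.
#' @param entry id of the entry node.
#' @param nodes list of [flow_node] objects.
#' @param edges data frame with columns `from`, `to`, `branch`
#'   (yes/no/next) and optionally `backward` (logical; `NA` = detect).
#' @return an object of class `clinical_algorithm` with components
#'   `algorithm_id`, `name`, `entry`, `nodes` (named list), `edges`
#'   (data frame with resolved `backward` flags), `dfs_order` (canonical
#'   node ordering) and `diagnoses_covered`.
#' @export
clinical_algorithm <- function(algorithm_id, name, entry, nodes, edges) {
  stopifnot(is.list(nodes), length(nodes) > 0L, is.data.frame(edges))
  if (!all(vapply(nodes, inherits, logical(1), "flow_node")))
    stop("all nodes must be flow_node objects", call. = FALSE)
  ids <- vapply(nodes, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate node id: ", ids[duplicated(ids)][1L], call. = FALSE)
  names(nodes) <- ids

  if (nrow(edges) > 0L) {
    need <- c("from", "to", "branch")
    if (!all(need %in% names(edges)))
      stop("edges must have columns from, to, branch", call. = FALSE)
    if (is.null(edges$backward)) edges$backward <- NA
    edges <- edges[, c("from", "to", "branch", "backward")]
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
    edges$branch <- as.character(edges$branch)
    edges$backward <- as.logical(edges$backward)
  } else {
    edges <- data.frame(from = character(), to = character(),
                        branch = character(), backward = logical())
  }

  for (i in seq_len(nrow(edges))) {
    e <- edges[i, ]
    if (!e$from %in% ids || !e$to %in% ids)
      stop("dangling edge ", e$from, " -> ", e$to,
           ": unknown node id", call. = FALSE)
    if (!e$branch %in% BRANCHES)
      stop("edge ", e$from, " -> ", e$to, ": invalid branch '",
           e$branch, "'", call. = FALSE)
  }

  if (!entry %in% ids)
    stop("entry node '", entry, "' not found", call. = FALSE)
  if (nodes[[entry]]$kind != "clinical_state")
    stop("entry node '", entry, "' must have kind clinical_state",
         call. = FALSE)

  kinds <- vapply(nodes, `[[`, character(1), "kind")
  for (id in ids) {
    out <- edges[edges$from == id, , drop = FALSE]
    if (kinds[[id]] == "decision") {
      if (sum(out$branch == "yes") != 1L || sum(out$branch == "no") != 1L ||
          nrow(out) != 2L)
        stop("decision node '", id,
             "' must have exactly one yes-edge and one no-edge",
             call. = FALSE)
    } else if (nrow(out) > 0L) {
      if (nrow(out) != 1L || out$branch != "next")
        stop("node '", id,
             "' must have a single next-edge or be terminal", call. = FALSE)
    } else {
      if (!kinds[[id]] %in% c("diagnostic_action", "other_action"))
        stop("terminal node '", id,
             "' must be a diagnostic or other action box", call. = FALSE)
    }
  }

  ord <- .dfs_order(entry, ids, edges)
  unreachable <- setdiff(ids, ord)
  if (length(unreachable) > 0L)
    stop("unreachable node: ", unreachable[1L], call. = FALSE)

  pos <- match(edges$from, ord)  # detect loops from DFS discovery order
  tpos <- match(edges$to, ord)
  detected <- tpos <= pos
  edges$backward <- ifelse(is.na(edges$backward), detected, edges$backward)

  dx <- unlist(lapply(nodes, function(n)
    if (n$kind == "diagnostic_action") n$diagnosis else NULL))

  # adjacency cache for O(1) traversal steps
  adj <- lapply(ids, function(id) {
    out <- edges[edges$from == id, , drop = FALSE]
    stats::setNames(
      lapply(out$branch, function(b) {
        e <- out[out$branch == b, , drop = FALSE]
        list(to = e$to[1L], backward = isTRUE(e$backward[1L]))
      }),
      out$branch)
  })
  names(adj) <- ids

  structure(list(algorithm_id = algorithm_id, name = name,
                 entry = entry, nodes = nodes, edges = edges,
                 dfs_order = ord, adj = adj,
                 diagnoses_covered = sort(unique(unname(dx)))),
            class = "clinical_algorithm")
}

# Entry-rooted iterative depth-first discovery order. Out-edges are
# explored yes, no, next; ties (never produced by the validator, but
# tolerated) break by target node id.
.dfs_order <- function(entry, ids, edges) {
  seen <- character()
  stack <- entry
  while (length(stack) > 0L) {
    cur <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (cur %in% seen) next
    seen <- c(seen, cur)
    out <- edges[edges$from == cur, , drop = FALSE]
    if (nrow(out) > 0L) {
      out <- out[order(match(out$branch, BRANCHES), out$to), , drop = FALSE]
      # push in reverse so the first branch is explored first
      stack <- c(stack, rev(out$to))
    }
  }
  seen
}

#' @export
print.clinical_algorithm <- function(x, ...) {
  cen <- census(x)
  cat("Clinical algorithm: ", x$name, " [", x$algorithm_id, "]\n", sep = "")
  cat("  nodes: ", length(x$nodes),
      " (", cen$n_diagnostic, " diagnostic, ", cen$n_other, " other)\n",
      sep = "")
  cat("  edges: ", nrow(x$edges),
      " (", nrow(cen$backward_edges), " backward)\n", sep = "")
  cat("  diagnoses covered: ",
      paste(x$diagnoses_covered, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Count diagnostic and other boxes and list loop edges
#'
#' The box census underlying the CASA complexity score: diagnostic boxes
#' are those assigning a diagnosis; every other box (entry state,
#' decisions, tests, non-diagnostic actions) counts as "other".
#'
#' @param alg a [clinical_algorithm].
#' @return list with `n_diagnostic`, `n_other` and `backward_edges` (a data
#'   frame, possibly empty, of the loop edges).
#' @export
census <- function(alg) {
  stopifnot(inherits(alg, "clinical_algorithm"))
  kinds <- vapply(alg$nodes, `[[`, character(1), "kind")
  list(n_diagnostic = sum(kinds == "diagnostic_action"),
       n_other = sum(kinds != "diagnostic_action"),
       backward_edges = alg$edges[alg$edges$backward, , drop = FALSE])
}

# ---- document I/O ----------------------------------------------------------

.node_from_doc <- function(nd) {
  pred <- NULL
  if (!is.null(nd$predicate)) {
    p <- nd$predicate
    val <- if (is.null(p$value)) NULL else unlist(p$value)
    pred <- flow_predicate(p$finding, p$op, val)
  }
  flow_node(id = nd$id, kind = nd$kind,
            label = if (is.null(nd$label)) nd$id else nd$label,
            predicate = pred, diagnosis = nd$diagnosis, test = nd$test,
            delay_days = if (is.null(nd$delay_days)) 0 else nd$delay_days)
}

#' Parse a flowchart document
#'
#' Reads the declarative JSON flowchart dialect: top-level keys
#' `algorithm_id`, `name`, `entry`, `nodes` (list of
#' `{id, kind, label, predicate?, diagnosis?, test?, delay_days?}`) and
#' `edges` (list of `{from, to, branch, backward?}`); predicates are
#' `{finding, op, value?}`. The parsed structure is validated in full.
#'
#' @param document path to a JSON file, or a JSON string.
#' @return a validated [clinical_algorithm].
#' @export
parse_algorithm <- function(document) {
  doc <- jsonlite::fromJSON(document, simplifyVector = FALSE)
  for (k in c("algorithm_id", "entry", "nodes", "edges")) {
    if (is.null(doc[[k]]))
      stop("flowchart document missing key '", k, "'", call. = FALSE)
  }
  nodes <- lapply(doc$nodes, .node_from_doc)
  edges <- do.call(rbind, lapply(doc$edges, function(e) {
    data.frame(from = e$from, to = e$to, branch = e$branch,
               backward = if (is.null(e$backward)) NA else e$backward)
  }))
  if (is.null(edges))
    edges <- data.frame(from = character(), to = character(),
                        branch = character(), backward = logical())
  clinical_algorithm(algorithm_id = doc$algorithm_id,
                     name = if (is.null(doc$name)) doc$algorithm_id else doc$name,
                     entry = doc$entry, nodes = nodes, edges = edges)
}

#' Serialize a clinical algorithm to its document form
#'
#' Emits canonical JSON: nodes in entry-rooted depth-first order, edges
#' ordered by source position then branch. Two serializations of the same
#' algorithm are byte-identical, and `parse_algorithm()` of the output
#' reconstructs a structurally equal algorithm.
#'
#' @param alg a [clinical_algorithm].
#' @param path optional file path; when given the document is written there.
#' @return the JSON document as a character scalar (invisibly when `path`
#'   is given).
#' @export
serialize_algorithm <- function(alg, path = NULL) {
  stopifnot(inherits(alg, "clinical_algorithm"))
  ord <- alg$dfs_order
  nodes <- lapply(alg$nodes[ord], function(n) {
    out <- list(id = n$id, kind = n$kind, label = n$label)
    if (!is.null(n$predicate)) {
      p <- list(finding = n$predicate$finding, op = n$predicate$op)
      if (!is.null(n$predicate$value)) p$value <- I(n$predicate$value)
      out$predicate <- p
    }
    if (!is.null(n$diagnosis)) out$diagnosis <- n$diagnosis
    if (!is.null(n$test)) out$test <- n$test
    if (n$delay_days != 0) out$delay_days <- n$delay_days
    out
  })
  ed <- alg$edges
  ed <- ed[order(match(ed$from, ord), match(ed$branch, BRANCHES),
                 match(ed$to, ord)), , drop = FALSE]
  edges <- lapply(seq_len(nrow(ed)), function(i) {
    list(from = ed$from[i], to = ed$to[i], branch = ed$branch[i],
         backward = ed$backward[i])
  })
  doc <- list(algorithm_id = alg$algorithm_id, name = alg$name,
              entry = alg$entry, nodes = unname(nodes), edges = edges)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
  json <- as.character(json)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Test two algorithms for structural equality
#'
#' @param a,b [clinical_algorithm] objects.
#' @return `TRUE` when the canonical serializations agree.
#' @export
algorithm_equal <- function(a, b) {
  identical(serialize_algorithm(a), serialize_algorithm(b))
}
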