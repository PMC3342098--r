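# Flowchart model: construction, validation, document round trips, census.

test_that("minimal flowchart parses and reports its structure", {
  doc <- '{
    "algorithm_id": "mini", "name": "mini", "entry": "entry",
    "nodes": [
      {"id": "entry", "kind": "clinical_state", "label": "start"},
      {"id": "dx", "kind": "diagnostic_action", "label": "treat TB",
       "diagnosis": "TB"}
    ],
    "edges": [{"from": "entry", "to": "dx", "branch": "next"}]
  }'
  alg <- parse_algorithm(doc)
  expect_s3_class(alg, "clinical_algorithm")
  expect_length(alg$nodes, 2L)
  expect_equal(nrow(alg$edges), 1L)
  expect_equal(alg$diagnoses_covered, "TB")
  cen <- census(alg)
  expect_equal(cen$n_diagnostic, 1L)
  expect_equal(cen$n_other, 1L)
  expect_equal(nrow(cen$backward_edges), 0L)
})

test_that("validation names the offending node or edge", {
  # decision with only a yes-edge
  expect_error(
    clinical_algorithm(
      "bad", "bad", "entry",
      nodes = list(
        flow_node("entry", "clinical_state"),
        flow_node("d1", "decision", predicate = flow_predicate("x", "present")),
        flow_node("dx", "diagnostic_action", diagnosis = "A")),
      edges = rbind(edge_df("entry", "d1"), edge_df("d1", "dx", "yes"))),
    "d1")
  # dangling edge
  expect_error(
    clinical_algorithm(
      "bad", "bad", "entry",
      nodes = list(flow_node("entry", "clinical_state"),
                   flow_node("dx", "diagnostic_action", diagnosis = "A")),
      edges = rbind(edge_df("entry", "dx"), edge_df("dx", "ghost"))),
    "dangling|ghost")
  # unreachable node
  expect_error(
    clinical_algorithm(
      "bad", "bad", "entry",
      nodes = list(flow_node("entry", "clinical_state"),
                   flow_node("dx", "diagnostic_action", diagnosis = "A"),
                   flow_node("island", "other_action")),
      edges = edge_df("entry", "dx")),
    "unreachable")
  # terminal node of the wrong kind
  expect_error(
    clinical_algorithm(
      "bad", "bad", "entry",
      nodes = list(flow_node("entry", "clinical_state")),
      edges = data.frame(from = character(), to = character(),
                         branch = character())),
    "terminal")
  # entry of the wrong kind
  expect_error(
    clinical_algorithm(
      "bad", "bad", "dx",
      nodes = list(flow_node("dx", "diagnostic_action", diagnosis = "A")),
      edges = data.frame(from = character(), to = character(),
                         branch = character())),
    "clinical_state")
})

test_that("node and predicate invariants are enforced at construction", {
  expect_error(flow_node("n", "decision"), "predicate")
  expect_error(flow_node("n", "other_action",
                         predicate = flow_predicate("x", "present")),
               "predicate")
  expect_error(flow_node("n", "other_action", diagnosis = "A"), "diagnosis")
  expect_error(flow_node("n", "diagnostic_action"), "diagnosis")
  expect_error(flow_node("n", "other_action", delay_days = -1), "delay")
  expect_error(flow_predicate("x", "present", value = 1), "reference")
  expect_error(flow_predicate("x", "equals"), "requires")
  expect_error(flow_predicate("x", "at_least", "high"), "numeric")
})

test_that("predicate evaluation is three-valued", {
  f <- list(smear = "positive", days = 21, fever = TRUE, rash = FALSE)
  expect_true(eval_predicate(flow_predicate("smear", "equals", "positive"), f))
  expect_false(eval_predicate(flow_predicate("smear", "equals", "negative"), f))
  expect_true(eval_predicate(flow_predicate("days", "at_least", 21), f))
  expect_false(eval_predicate(flow_predicate("days", "at_most", 20), f))
  expect_true(eval_predicate(flow_predicate("fever", "present"), f))
  expect_true(eval_predicate(flow_predicate("rash", "absent"), f))
  expect_true(eval_predicate(flow_predicate("smear", "in_set",
                                            c("positive", "scanty")), f))
  # unknowns: absent from the map, or NA
  expect_true(is.na(eval_predicate(flow_predicate("cd4", "at_least", 200), f)))
  expect_true(is.na(eval_predicate(flow_predicate("x", "present"),
                                   list(x = NA))))
})

test_that("serialization is deterministic and round-trips structurally", {
  alg <- smear_algorithm()
  s1 <- serialize_algorithm(alg)
  s2 <- serialize_algorithm(alg)
  expect_identical(s1, s2)                       # byte-identical
  expect_true(algorithm_equal(parse_algorithm(s1), alg))

  set.seed(421)
  for (k in 1:50) {
    r <- random_algorithm(n_decisions = sample(1:8, 1),
                          n_loops = sample(0:2, 1),
                          id = paste0("rt", k))
    reparsed <- parse_algorithm(serialize_algorithm(r))
    expect_true(algorithm_equal(reparsed, r))
    expect_equal(length(reparsed$nodes), length(r$nodes))
    expect_equal(nrow(reparsed$edges), nrow(r$edges))
    # kinds, delays and predicates survive the round trip exactly
    expect_identical(
      lapply(reparsed$nodes[names(r$nodes)], `[`,
             c("kind", "delay_days", "predicate")),
      lapply(r$nodes, `[`, c("kind", "delay_days", "predicate")))
  }
})

test_that("packaged flowchart fixtures parse, validate and round-trip", {
  for (w in c("chuk", "msf", "who")) {
    alg <- study_algorithm(w)
    expect_s3_class(alg, "clinical_algorithm")
    expect_true(algorithm_equal(parse_algorithm(serialize_algorithm(alg)),
                                alg))
  }
  expect_setequal(study_algorithm("chuk")$diagnoses_covered,
                  names(study_diagnosis_counts())[1:12])
})

test_that("census agrees with brute-force enumeration on random charts", {
  set.seed(77)
  for (k in 1:100) {
    alg <- random_algorithm(n_decisions = sample(1:10, 1),
                            n_loops = sample(0:3, 1))
    cen <- census(alg)
    # independent enumeration straight off the node list
    kinds <- vapply(alg$nodes, function(n) n$kind, character(1))
    expect_identical(cen$n_diagnostic,
                     sum(kinds == "diagnostic_action"))
    expect_identical(cen$n_other, sum(kinds != "diagnostic_action"))
    expect_identical(cen$n_diagnostic + cen$n_other, length(alg$nodes))
    expect_identical(nrow(cen$backward_edges), sum(alg$edges$backward))
  }
})

test_that("backward-edge detection depends on topology only", {
  set.seed(99)
  for (k in 1:20) {
    alg <- random_algorithm(n_decisions = 6, n_loops = 2)
    rel <- relabel_algorithm(alg)
    expect_equal(sum(rel$edges$backward), sum(alg$edges$backward))
    expect_equal(census(rel)$n_diagnostic, census(alg)$n_diagnostic)
  }
})
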