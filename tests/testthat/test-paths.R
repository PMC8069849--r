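# Cyclic transition graphs: path probabilities, enumeration, circuits,
# multipath superposition and disturbance sequences.

triangle_graph <- function(p = 0.5) {
  # all six directed edges between three states
  e <- expand.grid(from = c("A", "B", "C"), to = c("A", "B", "C"),
                   stringsAsFactors = FALSE)
  e <- e[e$from != e$to, ]
  e$label <- paste0(e$from, e$to)
  e$p <- p
  transition_graph(c("A", "B", "C"), e)
}

test_that("path probabilities follow the product rule in both formulations", {
  g <- transition_graph(c("A", "B", "C"),
                        data.frame(from = c("A", "B"), to = c("B", "C"),
                                   label = c("x", "y"), p = c(0.5, 0.5),
                                   theta = c(1.2, 2.7)))
  path <- 1:2
  expect_equal(path_probability_classical(g, path, initial = 1), 0.25,
               tolerance = 1e-12)
  # per-leg squaring makes phases irrelevant: quantum equals classical
  expect_equal(path_probability_quantum(g, path, initial_amplitude = 1), 0.25,
               tolerance = 1e-12)
  # an initial amplitude sqrt(0.1) e^{i theta} contributes 0.1
  expect_equal(path_probability_quantum(g, 1, complex(modulus = sqrt(0.1),
                                                      argument = 0.8)),
               0.1 * 0.5, tolerance = 1e-12)
  # deterministic edges, certain start
  gd <- transition_graph(c("A", "B"),
                         data.frame(from = "A", to = "B", label = "z", p = 1))
  expect_equal(path_probability_classical(gd, 1, 1), 1)
  expect_error(path_probability_classical(g, c(2, 1)), "chain")

  # equivalence on random phased paths
  set.seed(21)
  g <- triangle_graph()
  g$edges$p <- runif(nrow(g$edges), 0.1, 1)
  g$edges$theta <- runif(nrow(g$edges), 0, 2 * pi)
  g <- transition_graph(g$states, g$edges[, c("from", "to", "label", "p", "theta")])
  for (i in 1:50) {
    paths <- enumerate_paths(g, sample(g$states, 1), sample(g$states, 1), 4)
    if (length(paths) == 0) next
    p <- paths[[sample(length(paths), 1)]]
    z0 <- complex(modulus = sqrt(runif(1)), argument = runif(1, 0, 2 * pi))
    expect_equal(path_probability_quantum(g, p, z0),
                 path_probability_classical(g, p, Mod(z0)^2),
                 tolerance = 1e-12)
  }
})

test_that("the boreal cycle yields exactly one three-step circuit", {
  g <- spruce_graph(p = 0.6)
  paths <- enumerate_paths(g, "black_spruce", "black_spruce", 3)
  expect_length(paths, 1)
  expect_equal(g$edges$label[paths[[1]]],
               c("thermokarst", "permafrost_peat_aggradation",
                 "aggradation_tree_regeneration"))
  expect_equal(path_probability_classical(g, paths[[1]], 1), 0.6^3,
               tolerance = 1e-12)
  circ <- find_intransitive_circuits(g, 3)
  expect_length(circ, 1)
  # max_len 0 finds nothing
  expect_length(enumerate_paths(g, "black_spruce", "black_spruce", 0), 0)
})

test_that("path enumeration matches the adjacency-power walk count", {
  g <- triangle_graph()
  # repeated edges allowed: walks of length <= L counted by powers of A
  for (L in 1:4) {
    for (s in g$states) for (t in g$states) {
      paths <- enumerate_paths(g, s, t, L, allow_repeated_edges = TRUE)
      expect_equal(length(paths), oracle_walk_count(g, s, t, L))
    }
  }
  # triangle, A -> A within 3 steps: 2 two-step + 2 three-step returns
  expect_length(enumerate_paths(g, "A", "A", 3), 4)
  # deterministic ordering by label sequence
  paths <- enumerate_paths(g, "A", "A", 3)
  keys <- vapply(paths, function(p) paste(g$edges$label[p], collapse = ">"),
                 character(1))
  expect_equal(keys, sort(keys))
  expect_error(enumerate_paths(g, "A", "nope", 2), "unknown state")
})

test_that("multipath superposition hits the constructive and destructive limits", {
  two_path <- function(theta2) {
    transition_graph(c("S", "M1", "M2", "E"),
                     data.frame(from = c("S", "M1", "S", "M2"),
                                to = c("M1", "E", "M2", "E"),
                                label = c("u1", "u2", "v1", "v2"),
                                p = 0.5,
                                theta = c(0, 0, theta2 / 2, theta2 / 2)))
  }
  # equal phases: coherent total is twice the classical total
  ens <- multipath_superposition(two_path(0), "S", "E", 2, mode = "coherent")
  expect_length(ens$paths, 2)
  expect_equal(ens$classical_total, 0.5, tolerance = 1e-12)
  expect_equal(ens$coherent_total, 1.0, tolerance = 1e-12)
  expect_equal(ens$coherent_total, 2 * ens$classical_total, tolerance = 1e-12)

  # paths pi apart: complete destructive interference
  ens <- multipath_superposition(two_path(pi), "S", "E", 2, mode = "coherent")
  expect_equal(ens$coherent_total, 0, tolerance = 1e-12)
  expect_gt(ens$classical_total, 0)

  # a single path cannot interfere
  ens <- multipath_superposition(spruce_graph(0.7), "black_spruce",
                                 "black_spruce", 3)
  expect_equal(ens$coherent_total, ens$classical_total, tolerance = 1e-12)

  # no path: empty ensemble, not an error
  dag <- transition_graph(c("A", "B"),
                          data.frame(from = "A", to = "B", label = "x", p = 1))
  ens <- multipath_superposition(dag, "B", "A", 5)
  expect_length(ens$paths, 0)
  expect_equal(ens$coherent_total, 0)

  # coherent total bounded by the squared sum of magnitudes
  set.seed(22)
  g <- triangle_graph()
  for (i in 1:10) {
    g2 <- g
    g2$edges$theta <- runif(nrow(g$edges), 0, 2 * pi)
    g2 <- transition_graph(g2$states,
                           g2$edges[, c("from", "to", "label", "p", "theta")])
    ens <- multipath_superposition(g2, "A", "B", 3, mode = "coherent")
    bound <- sum(Mod(ens$amplitudes))^2
    expect_lte(ens$coherent_total, bound + 1e-12)
    expect_gte(ens$coherent_total, 0)
  }
})

test_that("intransitive circuits are canonical and absent from DAGs", {
  rps <- roshambo_dominance_graph()
  circ <- find_intransitive_circuits(rps, 3)
  expect_length(circ, 1)
  # canonical start: lexicographically smallest state
  expect_equal(rps$edges$from[circ[[1]][1]], "paper")

  dag <- transition_graph(c("A", "B", "C"),
                          data.frame(from = c("A", "A", "B"),
                                     to = c("B", "C", "C"),
                                     label = c("x", "y", "z"), p = 1))
  expect_length(find_intransitive_circuits(dag, 5), 0)

  # triangle with all six edges: 6 two-cycles? no -- 3 two-cycles and 2
  # three-cycles, checked against an independent igraph count when available
  g <- triangle_graph()
  circ <- find_intransitive_circuits(g, 3)
  expect_length(circ, 5)
  if (requireNamespace("igraph", quietly = TRUE) &&
      "simple_cycles" %in% getNamespaceExports("igraph")) {
    ig <- igraph::graph_from_data_frame(g$edges[, c("from", "to")])
    ref <- igraph::simple_cycles(ig, max = 3)
    expect_length(circ, length(ref))
  }
})

test_that("disturbance sequences are order-sensitive state walks", {
  g <- spruce_graph()
  out <- apply_disturbance_sequence(g, "black_spruce",
                                    c("thermokarst",
                                      "permafrost_peat_aggradation",
                                      "aggradation_tree_regeneration"))
  expect_equal(unname(out$distribution[["black_spruce"]]), 1)
  expect_true(out$order_sensitive)

  # deterministic unique labels end in a single state
  expect_equal(sum(out$distribution > 0), 1)

  # hand-built 4-edge, 2-state graph where X then Y != Y then X:
  # X toggles the state, Y always resets to s1
  g2 <- transition_graph(c("s1", "s2"),
                         data.frame(from = c("s1", "s2", "s1", "s2"),
                                    to = c("s2", "s1", "s1", "s1"),
                                    label = c("X", "X", "Y", "Y"),
                                    p = 1))
  xy <- apply_disturbance_sequence(g2, "s1", c("X", "Y"))
  yx <- apply_disturbance_sequence(g2, "s1", c("Y", "X"))
  expect_equal(unname(xy$distribution[["s1"]]), 1)
  expect_equal(unname(yx$distribution[["s2"]]), 1)
  expect_true(xy$order_sensitive)
  expect_true(yx$order_sensitive)

  # mass splits over parallel labelled out-edges, renormalized among matches
  g3 <- transition_graph(c("a", "b", "c"),
                         data.frame(from = c("a", "a"), to = c("b", "c"),
                                    label = "burn", p = c(0.3, 0.1)))
  out <- apply_disturbance_sequence(g3, "a", "burn")
  expect_equal(unname(out$distribution[c("b", "c")]), c(0.75, 0.25),
               tolerance = 1e-12)

  # stranded label warns with the reachable prefix
  expect_warning(
    apply_disturbance_sequence(g3, "b", "burn"),
    "applies to no occupied state")
  expect_error(apply_disturbance_sequence(g3, "a", "flood"), "unknown disturbance")
})

test_that("out-edge masses renormalize to one per state", {
  set.seed(23)
  g <- triangle_graph()
  g$edges$p <- runif(nrow(g$edges), 0.05, 1)
  g <- transition_graph(g$states, g$edges[, c("from", "to", "label", "p", "theta")])
  for (s in g$states) {
    idx <- which(g$edges$from == s)
    w <- Mod(g$edges$amp[idx])^2
    expect_equal(sum(w / sum(w)), 1, tolerance = 1e-9)
  }
})
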