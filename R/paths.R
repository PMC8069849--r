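# Disturbance-labelled state-transition graphs. Unlike the acyclic networks
# in qbn(), these graphs may (and typically do) contain cycles: intransitive
# circuits such as the three-state boreal succession loop. Edge amplitudes
# form a possibility graph, not a stochastic matrix: out-edges of a state
# need not sum to 1 and are renormalized at use time.

#' Construct a disturbance-labelled state-transition graph
#'
#' @param states Character vector of unique ecosystem-state labels.
#' @param edges Data frame with columns `from`, `to`, `label` (disturbance
#'   name), `p` (classical transition probability, in `(0, 1]`) and optional
#'   `theta` (amplitude phase in radians, default 0). Parallel edges between
#'   the same pair of states must carry distinct labels.
#' @return An object of class `"transition_graph"`; edge amplitudes
#'   \eqn{\sqrt{p}\,e^{i\theta}} are stored in `edges$amp`.
#' @export
#' @examples
#' g <- spruce_graph()
#' find_intransitive_circuits(g, max_len = 3)
transition_graph <- function(states, edges) {
  states <- as.character(states)
  if (anyDuplicated(states)) stop("state labels must be unique", call. = FALSE)
  edges <- as.data.frame(edges)
  needed <- c("from", "to", "label", "p")
  missing <- setdiff(needed, names(edges))
  if (length(missing) > 0) {
    stop(sprintf("edge table lacks column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  if (!"theta" %in% names(edges)) edges$theta <- 0
  bad <- setdiff(c(edges$from, edges$to), states)
  if (length(bad) > 0) {
    stop(sprintf("edge endpoint(s) not in the state set: %s",
                 paste(unique(bad), collapse = ", ")), call. = FALSE)
  }
  if (any(edges$p <= 0 | edges$p > 1)) {
    stop("edge probabilities must lie in (0, 1]", call. = FALSE)
  }
  key <- paste(edges$from, edges$to, edges$label, sep = "\r")
  if (anyDuplicated(key)) {
    stop("parallel edges must carry distinct disturbance labels", call. = FALSE)
  }
  edges <- edges[order(edges$from, edges$to, edges$label), , drop = FALSE]
  rownames(edges) <- NULL
  edges$amp <- complex(modulus = sqrt(edges$p),
                       argument = canonical_phase(edges$theta))
  structure(list(states = states, edges = edges), class = "transition_graph")
}

#' @export
print.transition_graph <- function(x, ...) {
  cat(sprintf("<transition graph> %d states, %d edges\n",
              length(x$states), nrow(x$edges)))
  for (i in seq_len(nrow(x$edges))) {
    e <- x$edges[i, ]
    cat(sprintf("  %s -[%s, p=%.4g]-> %s\n", e$from, e$label, e$p, e$to))
  }
  invisible(x)
}

.path_edges <- function(g, path) {
  # path: integer vector of edge row indices; checks chaining
  if (length(path) < 1) stop("a path needs at least one edge", call. = FALSE)
  e <- g$edges[path, , drop = FALSE]
  if (nrow(e) > 1 && any(e$to[-nrow(e)] != e$from[-1])) {
    stop("broken path: consecutive edges do not chain", call. = FALSE)
  }
  e
}

#' Classical probability of a path trajectory
#'
#' The product rule \eqn{P(A \to B \to C) = P(A)\,P(B|A)\,P(C|B)}: the initial
#' state probability times the product of the squared edge-amplitude
#' magnitudes along the path.
#'
#' @param g A [transition_graph()].
#' @param path Integer vector of edge row indices (consecutive edges must
#'   chain), or a one-row-per-step data frame subset of `g$edges`.
#' @param initial Probability of the initial state (default 1).
#' @return Probability.
#' @export
path_probability_classical <- function(g, path, initial = 1) {
  if (initial < 0 || initial > 1) stop("initial probability must be in [0, 1]",
                                       call. = FALSE)
  e <- .path_edges(g, path)
  initial * prod(Mod(e$amp)^2)
}

#' Quantum path probability
#'
#' The per-leg Born form \eqn{P = |\psi_A|^2 |\psi_{B|A}|^2 |\psi_{C|B}|^2}:
#' each leg amplitude is squared before multiplying, so phases cancel leg by
#' leg and the value coincides with [path_probability_classical()] at
#' `initial = |initial_amplitude|^2`. Interference between trajectories
#' therefore arises only when whole paths are superposed -- see
#' [multipath_superposition()].
#'
#' @param g A [transition_graph()].
#' @param path As in [path_probability_classical()].
#' @param initial_amplitude Initial state amplitude (complex or [qamp()];
#'   default 1).
#' @return Probability.
#' @export
path_probability_quantum <- function(g, path, initial_amplitude = 1) {
  z <- .as_amp_complex(initial_amplitude)
  e <- .path_edges(g, path)
  Mod(z)^2 * prod(Mod(e$amp)^2)
}

.out_edges <- function(g, state) which(g$edges$from == state)

#' Enumerate all paths between two states
#'
#' Depth-first enumeration of every edge sequence from `start` to `end` of
#' length at most `max_len`. State revisits are allowed, but by default each
#' directed edge is used at most once per path, which bounds the number of
#' times any cycle can be traversed; set `allow_repeated_edges = TRUE` to
#' permit re-traversal (the length cap still applies). Paths are returned in
#' deterministic lexicographic order of their label sequences.
#'
#' @param g A [transition_graph()].
#' @param start,end State labels.
#' @param max_len Maximum number of edges per path.
#' @param allow_repeated_edges Allow one edge to occur twice in a path.
#' @return List of integer vectors of edge row indices (possibly empty).
#' @export
enumerate_paths <- function(g, start, end, max_len,
                            allow_repeated_edges = FALSE) {
  for (s in c(start, end)) {
    if (!s %in% g$states) stop(sprintf("unknown state '%s'", s), call. = FALSE)
  }
  if (max_len < 1) return(list())
  found <- list()
  walk <- function(current, path, used) {
    for (i in .out_edges(g, current)) {
      if (!allow_repeated_edges && used[i]) next
      nxt <- g$edges$to[i]
      p2 <- c(path, i)
      if (nxt == end) found[[length(found) + 1]] <<- p2
      if (length(p2) < max_len) {
        used2 <- used
        used2[i] <- TRUE
        walk(nxt, p2, used2)
      }
    }
  }
  walk(start, integer(0), rep(FALSE, nrow(g$edges)))
  if (length(found) > 1) {
    keys <- vapply(found, function(p) paste(g$edges$label[p], collapse = "\r"),
                   character(1))
    found <- found[order(keys)]
  }
  found
}

#' Superpose all trajectories between two states
#'
#' Gathers every path from `start` to `end` within `max_len` steps
#' (via [enumerate_paths()]) and combines them: per-path amplitudes are the
#' products of leg amplitudes; `classical_total` sums the per-path squared
#' magnitudes, while `coherent_total` squares the amplitude sum over all
#' paths simultaneously, so trajectories can interfere constructively (up to
#' twice the classical total for two equal in-phase paths) or destructively
#' (down to zero for two equal paths \eqn{\pi} apart).
#'
#' @param g A [transition_graph()].
#' @param start,end State labels.
#' @param max_len Maximum path length in edges.
#' @param mode `"classical"` or `"coherent"`: selects which total is reported
#'   as the headline `probability`; both totals are always computed.
#' @param initial_amplitude Amplitude of the start state (default 1).
#' @return An object of class `"path_ensemble"`: list with `paths` (edge-index
#'   vectors), `amplitudes` (complex per-path), `classical_total`,
#'   `coherent_total`, `interference_term`, `probability`, `mode`. An empty
#'   ensemble (no path) is returned, not an error.
#' @export
multipath_superposition <- function(g, start, end, max_len,
                                    mode = c("classical", "coherent"),
                                    initial_amplitude = 1) {
  mode <- match.arg(mode)
  paths <- enumerate_paths(g, start, end, max_len)
  z0 <- .as_amp_complex(initial_amplitude)
  amps <- vapply(paths, function(p) z0 * prod(g$edges$amp[p]), complex(1))
  classical <- sum(Mod(amps)^2)
  coherent <- if (length(amps)) Mod(sum(amps))^2 else 0
  structure(list(paths = paths, amplitudes = amps,
                 classical_total = classical, coherent_total = coherent,
                 interference_term = coherent - classical,
                 probability = if (mode == "classical") classical else coherent,
                 mode = mode, start = start, end = end, graph = g),
            class = "path_ensemble")
}

#' @export
print.path_ensemble <- function(x, digits = 4, ...) {
  cat(sprintf("<path ensemble> %s -> %s: %d path(s), %s mode\n",
              x$start, x$end, length(x$paths), x$mode))
  for (i in seq_along(x$paths)) {
    p <- x$paths[[i]]
    cat(sprintf("  [%s] p = %s\n",
                paste(x$graph$edges$label[p], collapse = " > "),
                format(Mod(x$amplitudes[i])^2, digits = digits)))
  }
  cat(sprintf("  classical total %s | coherent total %s | interference %+g\n",
              format(x$classical_total, digits = digits),
              format(x$coherent_total, digits = digits),
              signif(x$interference_term, digits)))
  invisible(x)
}

#' Find intransitive circuits (directed cycles)
#'
#' Enumerates every simple directed cycle of length at most `max_len`,
#' canonicalized to start at its lexicographically smallest state; parallel
#' edges with different disturbance labels yield distinct circuits. A DAG
#' returns an empty list. The three-state boreal succession loop and the
#' rock-beats-scissors-beats-paper dominance digraph each contain exactly one
#' such 3-cycle.
#'
#' @param g A [transition_graph()].
#' @param max_len Maximum cycle length in edges (self-loops count as
#'   length-1 cycles).
#' @return List of integer vectors of edge row indices, in deterministic
#'   order.
#' @export
find_intransitive_circuits <- function(g, max_len) {
  found <- list()
  ord <- sort(g$states)
  rank <- stats::setNames(seq_along(ord), ord)
  for (s in ord) {
    walk <- function(current, path, visited) {
      for (i in .out_edges(g, current)) {
        nxt <- g$edges$to[i]
        if (rank[[nxt]] < rank[[s]]) next  # canonical start = smallest state
        if (nxt == s) {
          found[[length(found) + 1]] <<- c(path, i)
        } else if (!visited[[nxt]] && length(path) + 1 < max_len) {
          v2 <- visited
          v2[[nxt]] <- TRUE
          walk(nxt, c(path, i), v2)
        }
      }
    }
    visited <- stats::setNames(as.list(rep(FALSE, length(g$states))), g$states)
    visited[[s]] <- TRUE
    if (max_len >= 1) walk(s, integer(0), visited)
  }
  if (length(found) > 1) {
    keys <- vapply(found, function(p) {
      paste(c(g$edges$from[p[1]], g$edges$label[p]), collapse = "\r")
    }, character(1))
    found <- found[order(keys)]
  }
  found
}

#' Drive the system through a sequence of disturbance events
#'
#' Starting from `start` with probability 1, applies each disturbance label in
#' order: from every currently occupied state, probability mass moves along
#' the out-edges carrying that label, weighted by their squared magnitudes
#' renormalized among the matching out-edges (the graph is a possibility
#' graph, not a stochastic matrix). A state with no matching out-edge keeps
#' its mass (the disturbance leaves it unchanged); if no occupied state can
#' respond to a label at all, a stranded-sequence warning reports the
#' reachable prefix. Because transitions depend on the current state, the
#' outcome generally depends on the order of the disturbances; the result
#' records whether permuting the sequence would change it.
#'
#' @param g A [transition_graph()].
#' @param start Starting state label.
#' @param labels Character vector of disturbance labels, applied in order.
#' @param check_order Compare against all permutations of `labels` (skipped
#'   beyond `order_cap` events) and flag order sensitivity.
#' @param order_cap Maximum sequence length for the permutation check.
#' @return An object of class `"disturbance_outcome"`: list with
#'   `distribution` (over end states), `order_sensitive` (logical or `NA` when
#'   unchecked), `stranded_at` (index of the first inapplicable label, or
#'   `NA`), `labels`, `start`.
#' @export
apply_disturbance_sequence <- function(g, start, labels, check_order = TRUE,
                                       order_cap = 5) {
  if (!start %in% g$states) stop(sprintf("unknown state '%s'", start), call. = FALSE)
  known <- unique(g$edges$label)
  bad <- setdiff(labels, known)
  if (length(bad) > 0) {
    stop(sprintf("unknown disturbance label(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  run <- function(seq_labels, warn = FALSE) {
    dist <- stats::setNames(rep(0, length(g$states)), g$states)
    dist[start] <- 1
    stranded <- NA_integer_
    for (step in seq_along(seq_labels)) {
      lab <- seq_labels[step]
      new <- stats::setNames(rep(0, length(g$states)), g$states)
      moved <- FALSE
      for (s in g$states[dist > 0]) {
        idx <- which(g$edges$from == s & g$edges$label == lab)
        if (length(idx) == 0) {
          new[s] <- new[s] + dist[s]
        } else {
          w <- Mod(g$edges$amp[idx])^2
          w <- w / sum(w)
          for (j in seq_along(idx)) {
            new[g$edges$to[idx[j]]] <- new[g$edges$to[idx[j]]] + dist[s] * w[j]
          }
          moved <- TRUE
        }
      }
      if (!moved) {
        if (is.na(stranded)) stranded <- step
        if (warn) {
          warning(sprintf(
            "disturbance '%s' (step %d) applies to no occupied state; reachable prefix: %s",
            lab, step,
            if (step > 1) paste(seq_labels[seq_len(step - 1)], collapse = ", ") else "<none>"),
            call. = FALSE)
        }
      }
      dist <- new
    }
    list(dist = dist, stranded = stranded)
  }
  main <- run(labels, warn = TRUE)
  order_sensitive <- NA
  if (check_order && length(labels) > 1 && length(labels) <= order_cap) {
    perms <- .permutations(length(labels))
    outcomes <- lapply(perms, function(p) suppressWarnings(run(labels[p]))$dist)
    order_sensitive <- any(vapply(outcomes, function(d) {
      max(abs(d - main$dist)) > 1e-12
    }, logical(1)))
  }
  structure(list(distribution = main$dist, order_sensitive = order_sensitive,
                 stranded_at = main$stranded, labels = labels, start = start),
            class = "disturbance_outcome")
}

.permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in .permutations(n - 1L)) {
      tail <- seq_len(n)[-i][rest]
      out[[length(out) + 1]] <- c(i, tail)
    }
  }
  out
}

#' @export
print.disturbance_outcome <- function(x, digits = 4, ...) {
  cat(sprintf("<disturbance sequence> from '%s' via [%s]\n", x$start,
              paste(x$labels, collapse = ", ")))
  print(round(x$distribution[x$distribution > 0], digits))
  if (!is.na(x$order_sensitive)) {
    cat(sprintf("  order sensitive: %s\n", x$order_sensitive))
  }
  if (!is.na(x$stranded_at)) {
    cat(sprintf("  stranded at step %d\n", x$stranded_at))
  }
  invisible(x)
}
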