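# Network structure: nodes with amplitude-valued conditional tables.
#
# A conditional amplitude table has one row per full parent-state
# configuration (first parent varying fastest, as in expand.grid) and one
# complex amplitude per node state; each row's squared magnitudes must sum
# to 1, so that squaring the table recovers an ordinary CPT.

.config_grid <- function(parent_states) {
  # parent_states: named list of state label vectors; returns data.frame of
  # configurations (zero-row grid with one empty config for root nodes)
  if (length(parent_states) == 0) {
    return(structure(data.frame(row.names = 1), names = character(0)))
  }
  expand.grid(parent_states, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

.config_keys <- function(grid) {
  if (ncol(grid) == 0) return("<root>")
  do.call(paste, c(lapply(names(grid), function(nm) paste0(nm, "=", grid[[nm]])),
                   sep = ";"))
}

#' Construct a network node with an amplitude-valued conditional table
#'
#' @param name Node name.
#' @param states Ordered character vector of at least two state labels.
#' @param parents Ordered character vector of parent node names (may be empty).
#' @param probs Numeric matrix of classical conditional probabilities with one
#'   row per parent configuration (first parent varying fastest, the
#'   [expand.grid()] convention) and one column per state; each row must sum
#'   to 1. A vector is accepted for root nodes.
#' @param phases Phase angles (radians) of the table entries: a matrix shaped
#'   like `probs`, or a scalar recycled everywhere (default 0, which makes the
#'   node classical).
#' @param amps Alternatively, a complex amplitude matrix (overrides
#'   `probs`/`phases`); each row must have unit L2 norm.
#' @param rotation Optional measurement-basis rotation angle in radians used
#'   by [sequential_condition()] for order-sensitive evidence; only binary
#'   nodes may rotate. Default 0 (ordinary projective evidence).
#' @return An object of class `"qnode"`.
#' @seealso [qbn()], [validate_network()]
#' @export
qnode <- function(name, states, parents = character(), probs = NULL,
                  phases = 0, amps = NULL, rotation = 0) {
  states <- as.character(states)
  if (length(states) < 2) stop("a node needs at least two states", call. = FALSE)
  if (anyDuplicated(states)) stop("state labels must be unique within a node", call. = FALSE)
  if (is.null(amps)) {
    if (is.null(probs)) stop("supply either probs or amps", call. = FALSE)
    probs <- rbind(probs)
    if (length(phases) == 1) {
      phases <- matrix(phases, nrow(probs), ncol(probs))
    }
    phases <- rbind(phases)
    if (!all(dim(probs) == dim(phases))) {
      stop("phases must have the same shape as probs", call. = FALSE)
    }
    if (any(probs < 0)) stop("conditional probabilities must be nonnegative", call. = FALSE)
    amps <- matrix(complex(modulus = sqrt(probs), argument = phases),
                   nrow(probs), ncol(probs))
  } else {
    amps <- rbind(amps)
    storage.mode(amps) <- "complex"
  }
  if (ncol(amps) != length(states)) {
    stop(sprintf("node '%s': table has %d columns but %d states",
                 name, ncol(amps), length(states)), call. = FALSE)
  }
  colnames(amps) <- states
  structure(list(name = as.character(name), states = states,
                 parents = as.character(parents), amps = amps,
                 rotation = canonical_phase(rotation)),
            class = "qnode")
}

#' Assemble a quantum-like Bayesian network
#'
#' Collects [qnode()] objects into a network, resolving parent references and
#' requiring the parent graph to be acyclic (cyclic state-transition systems
#' belong in [transition_graph()], not here). Conditional tables are checked
#' row-by-row for completeness and unit-norm rows; pass `validate = FALSE` to
#' build a deliberately broken network for inspection with
#' [validate_network()].
#'
#' @param ... [qnode()] objects (or a single list of them).
#' @param validate If `TRUE` (default), stop on any structural violation.
#' @return An object of class `"qbn"`.
#' @export
qbn <- function(..., validate = TRUE) {
  nodes <- list(...)
  if (length(nodes) == 1 && !inherits(nodes[[1]], "qnode")) nodes <- nodes[[1]]
  if (!all(vapply(nodes, inherits, logical(1), "qnode"))) {
    stop("all arguments must be qnode objects", call. = FALSE)
  }
  names(nodes) <- vapply(nodes, `[[`, character(1), "name")
  if (anyDuplicated(names(nodes))) stop("duplicate node names", call. = FALSE)
  net <- structure(list(nodes = nodes), class = "qbn")
  net$order <- .topo_order(net)   # NULL when cyclic
  if (validate) {
    report <- validate_network(net)
    if (nrow(report) > 0) {
      stop(paste0("invalid network:\n",
                  paste(sprintf("- [%s] %s: %s", report$type, report$node,
                                report$detail), collapse = "\n")),
           call. = FALSE)
    }
  }
  net
}

.topo_order <- function(net) {
  nms <- names(net$nodes)
  parents <- lapply(net$nodes, function(n) intersect(n$parents, nms))
  order <- character(0)
  remaining <- nms
  repeat {
    ready <- remaining[vapply(remaining, function(n) {
      all(parents[[n]] %in% order)
    }, logical(1))]
    if (length(ready) == 0) break
    order <- c(order, ready)
    remaining <- setdiff(remaining, ready)
  }
  if (length(remaining) > 0) return(NULL)
  order
}

#' Validate the structural invariants of a network
#'
#' Checks parent references, acyclicity, table completeness (one row per
#' parent configuration) and row normalization (squared magnitudes of each
#' row summing to 1). Returns a report rather than throwing: an empty report
#' means the network is valid.
#'
#' @param net A [qbn()] object (possibly built with `validate = FALSE`).
#' @param tol Row-normalization tolerance.
#' @return A data frame with columns `type`, `node`, `detail`; zero rows iff
#'   the network is valid.
#' @export
validate_network <- function(net, tol = 1e-9) {
  report <- list()
  add <- function(type, node, detail) {
    report[[length(report) + 1]] <<- data.frame(type = type, node = node,
                                                detail = detail)
  }
  nms <- names(net$nodes)
  for (node in net$nodes) {
    dangling <- setdiff(node$parents, nms)
    if (length(dangling) > 0) {
      add("dangling_parent", node$name,
          sprintf("unknown parent(s): %s", paste(dangling, collapse = ", ")))
    }
    resolved <- intersect(node$parents, nms)
    grid <- .config_grid(lapply(net$nodes[resolved], `[[`, "states"))
    names(grid) <- resolved
    expected <- nrow(grid)
    if (length(resolved) == length(node$parents) && nrow(node$amps) != expected) {
      add("missing_rows", node$name,
          sprintf("table has %d rows but %d parent configurations",
                  nrow(node$amps), expected))
    }
    norms <- rowSums(Mod(node$amps)^2)
    bad <- which(abs(norms - 1) > tol)
    if (length(bad) > 0) {
      keys <- .config_keys(grid)
      key <- if (bad[1] <= length(keys)) keys[bad[1]] else as.character(bad[1])
      add("unnormalized_row", node$name,
          sprintf("row %d (%s): squared magnitudes sum to %.6g, not 1",
                  bad[1], key, norms[bad[1]]))
    }
    if (node$rotation > tol && (2 * pi - node$rotation) > tol &&
        length(node$states) != 2) {
      add("rotation_arity", node$name,
          "measurement-basis rotation is only defined for binary nodes")
    }
  }
  if (is.null(net$order) && length(nms) > 0) {
    add("cycle", "<network>",
        paste("the parent graph contains a directed cycle; Bayesian networks",
              "must be acyclic -- model cyclic state-transition systems with",
              "transition_graph() and the path-trajectory tools instead"))
  }
  if (length(report) == 0) {
    return(data.frame(type = character(0), node = character(0),
                      detail = character(0)))
  }
  do.call(rbind, report)
}

.node_row_keys <- function(net, node) {
  grid <- .config_grid(lapply(net$nodes[node$parents], `[[`, "states"))
  names(grid) <- node$parents
  .config_keys(grid)
}

.assignment_cap <- function() {
  getOption("ecoqbn.max_assignments", 2^20)
}

#' Enumerate every full joint assignment of a network
#'
#' @param net A [qbn()] object.
#' @return Data frame with one character column per node (network order) and
#'   one row per joint assignment.
#' @export
all_assignments <- function(net) {
  sizes <- vapply(net$nodes, function(n) length(n$states), numeric(1))
  if (prod(sizes) > .assignment_cap()) {
    stop(sprintf(
      "network has %g joint assignments, above the exact-enumeration cap %g (option 'ecoqbn.max_assignments')",
      prod(sizes), .assignment_cap()), call. = FALSE)
  }
  expand.grid(lapply(net$nodes, `[[`, "states"),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

# complex joint amplitude for each row of an assignment data frame
.joint_amplitudes <- function(net, assignments) {
  amp <- rep(complex(real = 1, imaginary = 0), nrow(assignments))
  for (node in net$nodes) {
    keys <- if (length(node$parents) == 0) {
      rep("<root>", nrow(assignments))
    } else {
      do.call(paste, c(lapply(node$parents, function(p) {
        paste0(p, "=", assignments[[p]])
      }), sep = ";"))
    }
    row_idx <- match(keys, .node_row_keys(net, node))
    col_idx <- match(assignments[[node$name]], node$states)
    amp <- amp * node$amps[cbind(row_idx, col_idx)]
  }
  amp
}

.check_full_assignment <- function(net, assignment) {
  assignment <- unlist(assignment)
  missing <- setdiff(names(net$nodes), names(assignment))
  if (length(missing) > 0) {
    stop(sprintf("incomplete assignment: missing node(s) %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (nm in names(net$nodes)) {
    if (!assignment[[nm]] %in% net$nodes[[nm]]$states) {
      stop(sprintf("node '%s' has no state '%s'", nm, assignment[[nm]]),
           call. = FALSE)
    }
  }
  assignment[names(net$nodes)]
}

#' Classical joint probability of a full assignment
#'
#' The product-rule joint \eqn{\prod_i P(x_i \mid pa_i)} obtained from the
#' squared magnitudes of the table entries; over all assignments these sum
#' to 1.
#'
#' @param net A [qbn()] object.
#' @param assignment Named character vector covering every node.
#' @return Probability.
#' @export
classical_joint <- function(net, assignment) {
  assignment <- .check_full_assignment(net, assignment)
  df <- as.data.frame(as.list(assignment), stringsAsFactors = FALSE)
  names(df) <- names(net$nodes)
  Mod(.joint_amplitudes(net, df))^2
}

#' Complex joint amplitude of a full assignment
#'
#' The product of the complex table entries along the network's topological
#' order; magnitudes multiply and phases add (mod \eqn{2\pi}), so
#' `|joint_amplitude|^2` equals [classical_joint()].
#'
#' @inheritParams classical_joint
#' @return A [qamp()] object.
#' @export
joint_amplitude <- function(net, assignment) {
  assignment <- .check_full_assignment(net, assignment)
  df <- as.data.frame(as.list(assignment), stringsAsFactors = FALSE)
  names(df) <- names(net$nodes)
  z <- .joint_amplitudes(net, df)
  qamp(Mod(z), canonical_phase(Arg(z)))
}

#' @export
print.qbn <- function(x, ...) {
  cat(sprintf("<quantum-like Bayesian network> %d nodes\n", length(x$nodes)))
  for (n in x$nodes) {
    cat(sprintf("  %s (%s)%s%s\n", n$name, paste(n$states, collapse = "/"),
                if (length(n$parents)) paste0(" <- ", paste(n$parents, collapse = ", ")) else "",
                if (n$rotation != 0) sprintf(" [rotation %.4g rad]", n$rotation) else ""))
  }
  invisible(x)
}
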