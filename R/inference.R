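# Exact inference by enumeration, in two modes:
#   classical -- hidden assignments are marginalized by summing probabilities
#                (textbook Bayesian-network enumeration);
#   coherent  -- hidden assignments are marginalized by summing complex joint
#                amplitudes and squaring (a Feynman-style sum over histories),
#                so hidden configurations can interfere.
# The two agree exactly when every query state receives a single contributing
# history, or when the pairwise cross terms cancel (phase separations of
# pi/2); with equal phases the cross terms are maximally constructive.

#' Ordered evidence for a network
#'
#' Findings are `(node, state)` pairs whose order is preserved: order is
#' irrelevant for [posterior()] but significant for [sequential_condition()]
#' when measurement bases are rotated.
#'
#' @param ... Named character scalars, e.g. `evidence(riparian = "present")`.
#' @param rotations Optional named numeric vector of per-node basis rotation
#'   angles (radians) overriding the nodes' own `rotation` fields.
#' @return An object of class `"ordered_evidence"`.
#' @export
evidence <- function(..., rotations = NULL) {
  pairs <- list(...)
  if (length(pairs) == 1 && is.null(names(pairs)) && is.character(pairs[[1]]) &&
      !is.null(names(pairs[[1]]))) {
    pairs <- as.list(pairs[[1]])   # accept a named character vector
  }
  if (length(pairs) == 0) {
    out <- data.frame(node = character(0), state = character(0))
  } else {
    if (is.null(names(pairs)) || any(names(pairs) == "")) {
      stop("evidence findings must be named: evidence(node = \"state\")", call. = FALSE)
    }
    if (anyDuplicated(names(pairs))) {
      stop("a node may appear at most once in the evidence", call. = FALSE)
    }
    out <- data.frame(node = names(pairs),
                      state = vapply(pairs, as.character, character(1)))
  }
  structure(out, class = c("ordered_evidence", "data.frame"),
            rotations = rotations)
}

.as_evidence <- function(ev) {
  if (is.null(ev)) return(evidence())
  if (inherits(ev, "ordered_evidence")) return(ev)
  if (is.character(ev) && !is.null(names(ev))) {
    return(do.call(evidence, as.list(ev)))
  }
  stop("evidence must be an evidence() object or a named character vector",
       call. = FALSE)
}

.check_evidence <- function(net, ev) {
  for (i in seq_len(nrow(ev))) {
    nd <- net$nodes[[ev$node[i]]]
    if (is.null(nd)) stop(sprintf("unknown evidence node '%s'", ev$node[i]),
                          call. = FALSE)
    if (!ev$state[i] %in% nd$states) {
      stop(sprintf("node '%s' has no state '%s'", ev$node[i], ev$state[i]),
           call. = FALSE)
    }
  }
  invisible(ev)
}

#' Posterior distribution of a query node
#'
#' Exact enumeration over all joint assignments consistent with the evidence.
#' In `"classical"` mode hidden nodes are summed out in probability; in
#' `"coherent"` mode they are summed out in amplitude before Born's rule is
#' applied, so hidden configurations interfere, and the result is renormalized
#' over the query states. The per-state interference report compares the two
#' (unnormalized, evidence-restricted) masses; coherent masses may exceed 1
#' before normalization.
#'
#' @param net A [qbn()] object.
#' @param query Name of the query node (must not appear in the evidence).
#' @param ev Evidence: an [evidence()] object, a named character vector, or
#'   `NULL`.
#' @param mode `"classical"` or `"coherent"`.
#' @param tol Evidence with classical probability below `tol` is an error.
#' @return An object of class `"qbn_posterior"`: a list with `distribution`
#'   (named, sums to 1), `mode`, and `interference` (a data frame with one row
#'   per query state: `classical_sum`, `coherent_probability`,
#'   `interference_term`).
#' @export
#' @examples
#' net <- bat_network()
#' posterior(net, "habitat", evidence(riparian = "present"))
posterior <- function(net, query, ev = NULL, mode = c("classical", "coherent"),
                      tol = 1e-12) {
  mode <- match.arg(mode)
  ev <- .check_evidence(net, .as_evidence(ev))
  if (!query %in% names(net$nodes)) {
    stop(sprintf("unknown query node '%s'", query), call. = FALSE)
  }
  if (query %in% ev$node) {
    stop("the query node may not appear in the evidence", call. = FALSE)
  }
  asg <- all_assignments(net)
  amp <- .joint_amplitudes(net, asg)
  keep <- rep(TRUE, nrow(asg))
  for (i in seq_len(nrow(ev))) keep <- keep & (asg[[ev$node[i]]] == ev$state[i])
  if (sum(Mod(amp[keep])^2) <= tol) {
    stop("evidence has zero classical probability (impossible event)",
         call. = FALSE)
  }
  states <- net$nodes[[query]]$states
  qs <- factor(asg[[query]][keep], levels = states)
  z <- amp[keep]
  classical_mass <- vapply(split(Mod(z)^2, qs), sum, numeric(1))
  coherent_mass <- Mod(vapply(split(z, qs), sum, complex(1)))^2
  interference <- data.frame(state = states,
                             classical_sum = as.numeric(classical_mass),
                             coherent_probability = as.numeric(coherent_mass),
                             interference_term =
                               as.numeric(coherent_mass - classical_mass))
  mass <- if (mode == "classical") classical_mass else coherent_mass
  if (sum(mass) <= tol) {
    stop("total coherent mass vanishes (complete destructive interference); no posterior is defined",
         call. = FALSE)
  }
  dist <- as.numeric(mass) / sum(mass)
  names(dist) <- states
  structure(list(distribution = dist, mode = mode, query = query,
                 evidence = ev, interference = interference),
            class = "qbn_posterior")
}

#' @export
print.qbn_posterior <- function(x, digits = 4, ...) {
  cat(sprintf("<posterior> P(%s | %s), %s mode\n", x$query,
              if (nrow(x$evidence) == 0) "-" else
                paste(x$evidence$node, x$evidence$state, sep = "=", collapse = ", "),
              x$mode))
  print(round(x$distribution, digits))
  cat("interference (unnormalized masses):\n")
  print(cbind(x$interference[1], round(x$interference[-1], digits)),
        row.names = FALSE)
  invisible(x)
}

.rotation_for <- function(net, ev, node) {
  rot <- attr(ev, "rotations")
  if (!is.null(rot) && node %in% names(rot)) return(canonical_phase(rot[[node]]))
  net$nodes[[node]]$rotation
}

.assignment_labels <- function(asg) {
  do.call(paste, c(lapply(names(asg), function(nm) paste0(nm, "=", asg[[nm]])),
                   sep = "|"))
}

#' Condition the joint state vector on an ordered sequence of findings
#'
#' Starts from the joint wave function whose amplitude on each full assignment
#' is the [joint_amplitude()] product, then incorporates the findings one at a
#' time, in order:
#' \itemize{
#'   \item a finding on an unrotated node is ordinary projective conditioning
#'     (project onto the matching assignments and renormalize -- Born/Lüders
#'     collapse). Projective findings on distinct nodes commute, so any order
#'     gives the same final vector;
#'   \item a finding on a node with a measurement-basis rotation \eqn{\phi}
#'     is *uncertain* evidence: the observed outcome is the rotated
#'     superposition \eqn{u_k} of the node's basis states (columns of
#'     \eqn{[\cos\phi, -\sin\phi; \sin\phi, \cos\phi]}). It is applied by
#'     amplitude-space Jeffrey conditioning -- the node's marginal amplitude
#'     vector is revised to \eqn{u_k} while each conditional slice of the
#'     joint vector (renormalized by its L2 norm) is preserved. Jeffrey
#'     revision does not commute with other findings, which is what makes
#'     evidence order significant; at \eqn{\phi = 0} it reduces exactly to
#'     projective conditioning.
#' }
#'
#' @param net A [qbn()] object.
#' @param ev An [evidence()] object (order is significant).
#' @param tol Findings whose subspace carries squared mass below `tol` are
#'   impossible.
#' @return A [state_vector()] over the joint-assignment basis, with the
#'   assignment table attached as attribute `"assignments"`; use
#'   [marginal_distribution()] to read off node posteriors.
#' @export
sequential_condition <- function(net, ev, tol = 1e-12) {
  ev <- .check_evidence(net, .as_evidence(ev))
  asg <- all_assignments(net)
  psi <- .joint_amplitudes(net, asg)
  for (i in seq_len(nrow(ev))) {
    node <- ev$node[i]
    states <- net$nodes[[node]]$states
    k <- match(ev$state[i], states)
    phi <- .rotation_for(net, ev, node)
    unrotated <- phase_equal(phi, 0) ||
      min(phi, 2 * pi - phi) < 1e-12
    if (unrotated) {
      keep <- asg[[node]] == ev$state[i]
      p <- sum(Mod(psi[keep])^2)
      if (p <= tol) {
        stop(sprintf("finding %d (%s = %s) is impossible given the preceding evidence",
                     i, node, ev$state[i]), call. = FALSE)
      }
      psi[!keep] <- 0i
      psi <- psi / sqrt(p)
    } else {
      if (length(states) != 2) {
        stop(sprintf("node '%s': rotated measurement bases require a binary node",
                     node), call. = FALSE)
      }
      u <- if (k == 1) c(cos(phi), sin(phi)) else c(-sin(phi), cos(phi))
      new_psi <- rep(0i, length(psi))
      contributed <- FALSE
      for (j in 1:2) {
        if (abs(u[j]) < tol) next
        idx <- asg[[node]] == states[j]
        nrm <- sqrt(sum(Mod(psi[idx])^2))
        if (nrm <= tol) next
        new_psi[idx] <- u[j] * psi[idx] / nrm
        contributed <- TRUE
      }
      if (!contributed) {
        stop(sprintf("finding %d (%s = %s, rotated basis) is impossible given the preceding evidence",
                     i, node, ev$state[i]), call. = FALSE)
      }
      psi <- new_psi / sqrt(sum(Mod(new_psi)^2))
    }
  }
  out <- structure(list(basis = .assignment_labels(asg), amp = psi),
                   class = "state_vector")
  attr(out, "assignments") <- asg
  out
}

#' Marginal distribution of one node from a joint-basis state vector
#'
#' Sums the squared amplitude magnitudes of a joint state vector (as returned
#' by [sequential_condition()]) over the states of one node.
#'
#' @param psi A joint-basis [state_vector()] carrying an `"assignments"`
#'   attribute.
#' @param node Node name.
#' @return Named probability vector summing to 1.
#' @export
marginal_distribution <- function(psi, node) {
  asg <- attr(psi, "assignments")
  if (is.null(asg) || !node %in% names(asg)) {
    stop(sprintf("no assignment table for node '%s' on this state vector", node),
         call. = FALSE)
  }
  p <- tapply(Mod(psi$amp)^2, asg[[node]], sum)
  out <- as.numeric(p)
  names(out) <- names(p)
  out / sum(out)
}

#' Information gained about a query node from a single finding
#'
#' Kullback--Leibler divergence (nats) of the classical posterior after the
#' finding from the prior marginal of the query node. A value of 0 certifies
#' that the finding carries no information about the query -- the
#' "solution-incomplete" signature of intransitive networks such as
#' rock-paper-scissors, where one player's move alone says nothing about the
#' outcome.
#'
#' @param net A [qbn()] object.
#' @param finding A single-finding [evidence()] object or named character
#'   scalar, on a node other than `query`.
#' @param query Query node name.
#' @return Nonnegative real (possibly `Inf` when the finding rules states in
#'   that had prior probability 0 -- cannot happen for valid tables -- or
#'   shrinks the support).
#' @export
information_gain <- function(net, finding, query) {
  finding <- .as_evidence(finding)
  if (nrow(finding) != 1) stop("information_gain() takes exactly one finding",
                               call. = FALSE)
  if (finding$node == query) stop("finding node must differ from the query node",
                                  call. = FALSE)
  prior <- posterior(net, query, NULL, mode = "classical")$distribution
  post <- posterior(net, query, finding, mode = "classical")$distribution
  terms <- ifelse(post == 0, 0, post * log(post / prior))
  sum(terms)
}

#' Generate a random quantum-like network (for simulation and testing)
#'
#' Builds a random directed acyclic network on `n_nodes` nodes: each pair
#' `(i, j)` with `i < j` is linked with probability `p_edge`, and conditional
#' table rows are drawn flat on the probability simplex. Phases are all zero
#' (`phase = "zero"`, a classical network expressed in amplitudes) or drawn
#' uniformly on `[0, 2*pi)` (`phase = "random"`). Uses the current RNG state;
#' call `set.seed()` for reproducibility.
#'
#' @param n_nodes Number of nodes.
#' @param n_states States per node (default 2).
#' @param p_edge Probability of each forward edge.
#' @param phase `"zero"` or `"random"`.
#' @return A [qbn()] object with nodes named `n1, n2, ...`.
#' @export
random_network <- function(n_nodes, n_states = 2, p_edge = 0.5,
                           phase = c("zero", "random")) {
  phase <- match.arg(phase)
  nms <- paste0("n", seq_len(n_nodes))
  states <- paste0("s", seq_len(n_states))
  nodes <- vector("list", n_nodes)
  for (j in seq_len(n_nodes)) {
    parents <- if (j > 1) nms[seq_len(j - 1)][stats::runif(j - 1) < p_edge] else character(0)
    n_rows <- n_states^length(parents)
    probs <- matrix(stats::rexp(n_rows * n_states), n_rows, n_states)
    probs <- probs / rowSums(probs)
    phases <- if (phase == "random") {
      matrix(stats::runif(n_rows * n_states, 0, 2 * pi), n_rows, n_states)
    } else 0
    nodes[[j]] <- qnode(nms[j], states, parents, probs, phases)
  }
  qbn(nodes)
}
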