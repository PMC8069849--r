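# Independent oracles used across the suite. These deliberately avoid the
# package's enumeration code paths: joint amplitudes are assembled by
# mixed-radix row arithmetic on the raw tables, and walk counts come from
# adjacency-matrix powers.

# Brute-force joint amplitude of one full assignment (named character vector).
oracle_joint_amp <- function(net, assignment) {
  z <- complex(real = 1)
  for (nd in net$nodes) {
    row <- 1L
    stride <- 1L
    for (p in nd$parents) {
      i <- match(assignment[[p]], net$nodes[[p]]$states)
      row <- row + (i - 1L) * stride
      stride <- stride * length(net$nodes[[p]]$states)
    }
    col <- match(assignment[[nd$name]], nd$states)
    z <- z * nd$amps[row, col]
  }
  z
}

# All full assignments as a list of named character vectors.
oracle_assignments <- function(net) {
  grids <- lapply(net$nodes, `[[`, "states")
  df <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) unlist(df[i, , drop = FALSE]))
}

# Posterior over the query node by direct summation over all assignments:
# probabilities in classical mode, complex amplitudes in coherent mode.
oracle_posterior <- function(net, query, ev = NULL, mode = "classical") {
  states <- net$nodes[[query]]$states
  mass <- if (mode == "coherent") {
    stats::setNames(rep(complex(real = 0), length(states)), states)
  } else {
    stats::setNames(rep(0, length(states)), states)
  }
  for (a in oracle_assignments(net)) {
    if (!is.null(ev) && any(a[names(ev)] != ev)) next
    z <- oracle_joint_amp(net, a)
    q <- a[[query]]
    mass[q] <- mass[q] + (if (mode == "coherent") z else Mod(z)^2)
  }
  out <- if (mode == "coherent") Mod(mass)^2 else mass
  out / sum(out)
}

# Number of start -> end walks of length <= max_len, counting parallel edges,
# with edge re-use allowed: sum of adjacency-matrix powers.
oracle_walk_count <- function(g, start, end, max_len) {
  n <- length(g$states)
  A <- matrix(0, n, n, dimnames = list(g$states, g$states))
  for (i in seq_len(nrow(g$edges))) {
    A[g$edges$from[i], g$edges$to[i]] <- A[g$edges$from[i], g$edges$to[i]] + 1
  }
  total <- 0
  P <- diag(n)
  dimnames(P) <- dimnames(A)
  for (l in seq_len(max_len)) {
    P <- P %*% A
    total <- total + P[start, end]
  }
  total
}

# A small two-node chain used by several inference tests.
chain_net <- function(pa = c(0.3, 0.7), pb = rbind(c(0.9, 0.1), c(0.2, 0.8)),
                      phases_b = 0, rotation_b = 0) {
  qbn(
    qnode("A", c("a1", "a2"), probs = pa),
    qnode("B", c("b1", "b2"), parents = "A", probs = pb, phases = phases_b,
          rotation = rotation_b)
  )
}
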