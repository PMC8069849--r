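# File dialects.
#
# Network JSON:
#   {"nodes": [{"name": ..., "states": [...], "parents": [...],
#               "cpt": [{"given": {parent: state, ...},
#                        "amps": [{"p": ..., "theta": ...}, ...]}, ...],
#               "basis_rotation": radians}]}
# "theta" and "basis_rotation" may be omitted (0), so any classical BN file
# in this dialect is a valid network; amplitudes may equivalently be given
# in rectangular form {"re": ..., "im": ...}. The writer emits p/theta.
#
# Transition-graph JSON:
#   {"states": [...], "edges": [{"from","to","label","p","theta"}]}
# plus a CSV edge-list dialect with header from,to,label,p,theta.

.reject_unknown <- function(obj, allowed, where) {
  extra <- setdiff(names(obj), allowed)
  if (length(extra) > 0) {
    stop(sprintf("unknown key '%s' at %s", extra[1], where), call. = FALSE)
  }
}

.parse_amp <- function(a, where) {
  if (all(c("re", "im") %in% names(a))) {
    .reject_unknown(a, c("re", "im"), where)
    return(complex(real = a$re, imaginary = a$im))
  }
  .reject_unknown(a, c("p", "theta"), where)
  if (is.null(a$p)) stop(sprintf("amplitude at %s lacks 'p'", where), call. = FALSE)
  theta <- if (is.null(a$theta)) 0 else a$theta
  complex(modulus = sqrt(a$p), argument = theta)
}

#' Read a network from the JSON dialect
#'
#' Files without `theta` keys load with all phases 0, i.e. as classical
#' Bayesian networks; unknown keys and missing conditional-table rows are
#' rejected with the offending path.
#'
#' @param path Path to a network JSON file.
#' @return A [qbn()] object.
#' @export
read_network <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  .reject_unknown(doc, "nodes", "top level")
  if (is.null(doc$nodes)) stop("network file lacks 'nodes'", call. = FALSE)
  nodes <- lapply(seq_along(doc$nodes), function(i) {
    nd <- doc$nodes[[i]]
    where <- sprintf("nodes[%d]", i)
    .reject_unknown(nd, c("name", "states", "parents", "cpt", "basis_rotation"),
                    where)
    for (k in c("name", "states", "cpt")) {
      if (is.null(nd[[k]])) stop(sprintf("%s lacks '%s'", where, k), call. = FALSE)
    }
    states <- unlist(nd$states)
    parents <- if (is.null(nd$parents)) character(0) else unlist(nd$parents)
    rows <- lapply(seq_along(nd$cpt), function(j) {
      row <- nd$cpt[[j]]
      rw <- sprintf("%s.cpt[%d]", where, j)
      .reject_unknown(row, c("given", "amps"), rw)
      given <- if (is.null(row$given)) list() else row$given
      amps <- vapply(seq_along(row$amps), function(k) {
        .parse_amp(row$amps[[k]], sprintf("%s.amps[%d]", rw, k))
      }, complex(1))
      if (length(amps) != length(states)) {
        stop(sprintf("%s has %d amplitudes but node '%s' has %d states",
                     rw, length(amps), nd$name, length(states)), call. = FALSE)
      }
      list(given = given, amps = amps)
    })
    list(name = nd$name, states = states, parents = parents, rows = rows,
         rotation = if (is.null(nd$basis_rotation)) 0 else nd$basis_rotation)
  })
  # resolve parent state sets, then order rows to the canonical grid
  state_sets <- lapply(nodes, `[[`, "states")
  names(state_sets) <- vapply(nodes, `[[`, character(1), "name")
  qnodes <- lapply(nodes, function(nd) {
    unknown <- setdiff(nd$parents, names(state_sets))
    if (length(unknown) > 0) {
      stop(sprintf("node '%s' references unknown parent '%s'", nd$name,
                   unknown[1]), call. = FALSE)
    }
    grid <- .config_grid(state_sets[nd$parents])
    names(grid) <- nd$parents
    keys <- .config_keys(grid)
    row_keys <- vapply(nd$rows, function(row) {
      g <- row$given
      if (length(nd$parents) == 0) return("<root>")
      vals <- vapply(nd$parents, function(p) {
        if (is.null(g[[p]])) {
          stop(sprintf("node '%s': a cpt row lacks parent '%s' in 'given'",
                       nd$name, p), call. = FALSE)
        }
        as.character(g[[p]])
      }, character(1))
      paste(paste0(nd$parents, "=", vals), collapse = ";")
    }, character(1))
    idx <- match(keys, row_keys)
    if (anyNA(idx)) {
      stop(sprintf("node '%s': missing cpt row for configuration %s",
                   nd$name, keys[which(is.na(idx))[1]]), call. = FALSE)
    }
    amps <- do.call(rbind, lapply(nd$rows[idx], `[[`, "amps"))
    qnode(nd$name, nd$states, nd$parents, amps = amps, rotation = nd$rotation)
  })
  qbn(qnodes)
}

#' Write a network in the JSON dialect
#'
#' @param net A [qbn()] object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_network <- function(net, path) {
  nodes <- lapply(net$nodes, function(nd) {
    grid <- .config_grid(lapply(net$nodes[nd$parents], `[[`, "states"))
    names(grid) <- nd$parents
    cpt <- lapply(seq_len(nrow(nd$amps)), function(i) {
      given <- if (ncol(grid) == 0) {
        stats::setNames(list(), character(0))
      } else {
        as.list(grid[i, , drop = FALSE])
      }
      amps <- lapply(seq_len(ncol(nd$amps)), function(j) {
        z <- nd$amps[i, j]
        list(p = Mod(z)^2, theta = canonical_phase(Arg(z)))
      })
      list(given = given, amps = amps)
    })
    out <- list(name = nd$name, states = as.list(nd$states),
                parents = as.list(nd$parents), cpt = cpt)
    if (nd$rotation != 0) out$basis_rotation <- nd$rotation
    out
  })
  jsonlite::write_json(list(nodes = unname(nodes)), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a transition graph from the JSON dialect
#'
#' @param path Path to a graph JSON file.
#' @return A [transition_graph()].
#' @export
read_graph <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  .reject_unknown(doc, c("states", "edges"), "top level")
  if (is.null(doc$states) || is.null(doc$edges)) {
    stop("graph file needs 'states' and 'edges'", call. = FALSE)
  }
  edges <- do.call(rbind, lapply(seq_along(doc$edges), function(i) {
    e <- doc$edges[[i]]
    where <- sprintf("edges[%d]", i)
    .reject_unknown(e, c("from", "to", "label", "p", "theta"), where)
    for (k in c("from", "to", "label", "p")) {
      if (is.null(e[[k]])) stop(sprintf("%s lacks '%s'", where, k), call. = FALSE)
    }
    data.frame(from = e$from, to = e$to, label = e$label, p = e$p,
               theta = if (is.null(e$theta)) 0 else e$theta)
  }))
  transition_graph(unlist(doc$states), edges)
}

#' Write a transition graph in the JSON dialect
#'
#' @param g A [transition_graph()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_graph <- function(g, path) {
  edges <- lapply(seq_len(nrow(g$edges)), function(i) {
    e <- g$edges[i, ]
    list(from = e$from, to = e$to, label = e$label, p = e$p,
         theta = canonical_phase(e$theta))
  })
  jsonlite::write_json(list(states = as.list(g$states), edges = unname(edges)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a transition graph from a CSV edge list
#'
#' Expects the header `from,to,label,p,theta` (`theta` optional); the state
#' set is the union of endpoints unless supplied. Suits spreadsheet-authored
#' models.
#'
#' @param path CSV path.
#' @param states Optional explicit state set.
#' @return A [transition_graph()].
#' @export
read_edge_csv <- function(path, states = NULL) {
  edges <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("from", "to", "label", "p")
  missing <- setdiff(needed, names(edges))
  if (length(missing) > 0) {
    stop(sprintf("%s: CSV lacks column(s) %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (is.null(states)) states <- sort(unique(c(edges$from, edges$to)))
  transition_graph(states, edges)
}

#' Write a transition graph as a CSV edge list
#'
#' @param g A [transition_graph()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_edge_csv <- function(g, path) {
  out <- g$edges[, c("from", "to", "label", "p", "theta")]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
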