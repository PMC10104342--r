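#' Build and validate a simulation graph
#'
#' Assembles node declarations into a validated directed acyclic graph:
#' plates are expanded into i.i.d. replicates, parent references are
#' resolved, and acyclicity is verified so that every node can be sampled
#' after its parents. Declaration order is preserved and used to break
#' ties in the topological order, making all downstream output
#' deterministic.
#'
#' @param specs List of [node()] / [make_missing_node()] declarations.
#' @param name Graph name (used in rendering and file naming).
#' @return An object of class `dag_graph` with elements `name`, `nodes`
#'   (named list in declaration order, plates expanded), `edges`
#'   (two-column character matrix, parent then child) and `order`
#'   (topological order of node names).
#' @examples
#' g <- build_graph(list(
#'   node("A", func = rand_uniform),
#'   node("B", func = function(x) x + 1, args = list(x = node_ref("A")))
#' ), name = "chain")
#' topological_order(g)
#' @export
build_graph <- function(specs, name = "model") {
  if (inherits(specs, "dag_node")) specs <- list(specs)
  if (!is.list(specs) || length(specs) == 0L)
    sim_abort("simdag_domain_error", "specs must be a non-empty list of nodes")
  if (!all(vapply(specs, inherits, TRUE, "dag_node")))
    sim_abort("simdag_domain_error", "every element of specs must be a dag_node")

  specs <- expand_plates(specs)

  nm <- vapply(specs, `[[`, "", "name")
  if (anyDuplicated(nm))
    sim_abort("simdag_duplicate_name_error", sprintf(
      "duplicate node name '%s'", nm[duplicated(nm)][1L]))
  names(specs) <- nm

  n_sel <- sum(vapply(specs, function(n) n$kind == "selection", TRUE))
  n_str <- sum(vapply(specs, function(n) n$kind == "stratify", TRUE))
  if (n_sel > 1L)
    sim_abort("simdag_kind_error", "at most one selection node is allowed per graph")
  if (n_str > 1L)
    sim_abort("simdag_kind_error", "at most one stratify node is allowed per graph")

  # resolve references, derive edge set
  edges <- matrix(character(0), ncol = 2, dimnames = list(NULL, c("parent", "child")))
  for (nd in specs) {
    for (p in node_parents(nd)) {
      if (!p %in% nm)
        sim_abort("simdag_unresolved_reference_error", sprintf(
          "node '%s' references unknown node '%s'", nd$name, p))
      if (identical(p, nd$name))
        sim_abort("simdag_cycle_error", sprintf(
          "node '%s' may not be its own parent (cycle %s -> %s)", nd$name, nd$name, nd$name))
      edges <- rbind(edges, c(p, nd$name))
    }
    if (nd$kind == "missing") {
      for (role in c("underlying", "mask")) {
        ref <- nd$args[[role]]$name
        k <- specs[[ref]]$kind
        if (k != "standard")
          sim_abort("simdag_kind_error", sprintf(
            "%s of missing node '%s' must be a standard node, but '%s' has kind '%s'",
            role, nd$name, ref, k))
      }
    }
  }

  ord <- kahn_order(nm, edges)
  if (!is.null(attr(ord, "cycle")))
    sim_abort("simdag_cycle_error", sprintf(
      "graph contains a directed cycle: %s", paste(attr(ord, "cycle"), collapse = " -> ")))

  structure(list(name = name, nodes = specs, edges = edges, order = ord),
            class = "dag_graph")
}

# Flat plate expansion: a node tagged plate(id, k) becomes k replicates
# name_1..name_k. References between nodes sharing a plate id are rewired
# replicate-wise; references from an unplated node to a plated one are
# ambiguous and rejected.
expand_plates <- function(specs) {
  plated <- vapply(specs, function(n) !is.null(n$plate), TRUE)
  if (!any(plated)) return(specs)
  plate_ids <- vapply(specs[plated], function(n) n$plate$id, "")
  plate_names <- vapply(specs[plated], `[[`, "", "name")
  id_of <- stats::setNames(plate_ids, plate_names)

  out <- list()
  for (nd in specs) {
    if (is.null(nd$plate)) {
      bad <- intersect(node_parents(nd), plate_names)
      if (length(bad) > 0L)
        sim_abort("simdag_unresolved_reference_error", sprintf(
          "node '%s' references plate-tagged node '%s'; only nodes in the same plate may reference it",
          nd$name, bad[1L]))
      out[[length(out) + 1L]] <- nd
      next
    }
    same_plate <- names(id_of)[id_of == nd$plate$id]
    for (i in seq_len(nd$plate$k)) {
      rep_nd <- nd
      rep_nd$name <- sprintf("%s_%d", nd$name, i)
      rep_nd$plate <- NULL
      rep_nd$args <- lapply(nd$args, function(a) {
        if (is_node_ref(a) && a$name %in% same_plate)
          node_ref(sprintf("%s_%d", a$name, i))
        else a
      })
      out[[length(out) + 1L]] <- rep_nd
    }
  }
  out
}

# Kahn's algorithm; ties broken by declaration order (first eligible node
# in declaration order is emitted next). On a cycle, returns the partial
# order with attr "cycle" = one offending cycle as a name vector.
kahn_order <- function(nm, edges) {
  n <- length(nm)
  indeg <- stats::setNames(integer(n), nm)
  if (nrow(edges) > 0L) {
    tab <- table(edges[, "child"])
    indeg[names(tab)] <- as.integer(tab)
  }
  done <- stats::setNames(logical(n), nm)
  ord <- character(0)
  repeat {
    candidates <- nm[!done & indeg[nm] == 0L]
    if (length(candidates) == 0L) break
    u <- candidates[1L]
    done[u] <- TRUE
    ord <- c(ord, u)
    if (nrow(edges) > 0L) {
      ch <- edges[edges[, "parent"] == u, "child"]
      for (v in ch) indeg[v] <- indeg[v] - 1L
    }
  }
  if (length(ord) < n) {
    rem <- nm[!done]
    attr(ord, "cycle") <- find_cycle(rem, edges)
  }
  ord
}

# Walk parent pointers inside the leftover (cyclic) subgraph until a node
# repeats; report the cycle in edge direction, closed (A -> B -> A).
find_cycle <- function(rem, edges) {
  sub <- edges[edges[, "parent"] %in% rem & edges[, "child"] %in% rem, , drop = FALSE]
  path <- rem[1L]
  repeat {
    nxt <- sub[sub[, "child"] == path[length(path)], "parent"][1L]
    hit <- match(nxt, path)
    if (!is.na(hit)) {
      cyc <- rev(path[hit:length(path)])
      return(c(cyc, cyc[1L]))
    }
    path <- c(path, nxt)
  }
}

#' Topological order of a validated graph
#'
#' Returns the node names so that every parent precedes all of its
#' children; ties are broken by declaration order, so the result is
#' deterministic and matches the output column order.
#'
#' @param graph A `dag_graph` from [build_graph()].
#' @return Character vector of node names.
#' @export
topological_order <- function(graph) {
  stopifnot(inherits(graph, "dag_graph"))
  graph$order
}

#' Render a graph as DOT text
#'
#' Emits a Graphviz DOT description with one vertex per node and one arc
#' per edge. Node kinds are visually distinguished (standard: ellipse,
#' selection: diamond, missing: dashed box, stratify: octagon); hidden
#' nodes are greyed. Output is deterministic given the graph.
#'
#' @param graph A `dag_graph`.
#' @return A single string of DOT source.
#' @export
render_graph <- function(graph) {
  stopifnot(inherits(graph, "dag_graph"))
  shape <- c(standard = "ellipse", selection = "diamond",
             missing = "box", stratify = "octagon")
  lines <- c(sprintf("digraph \"%s\" {", graph$name))
  for (nd in graph$nodes) {
    attrs <- sprintf("shape=%s", shape[[nd$kind]])
    if (nd$kind == "missing") attrs <- paste0(attrs, ", style=dashed")
    if (!nd$observed && nd$kind == "standard")
      attrs <- paste0(attrs, ", style=dotted, color=grey")
    lines <- c(lines, sprintf("  \"%s\" [%s];", nd$name, attrs))
  }
  if (nrow(graph$edges) > 0L) {
    for (i in seq_len(nrow(graph$edges)))
      lines <- c(lines, sprintf("  \"%s\" -> \"%s\";",
                                graph$edges[i, "parent"], graph$edges[i, "child"]))
  }
  paste(c(lines, "}"), collapse = "\n")
}

#' @export
print.dag_graph <- function(x, ...) {
  kinds <- vapply(x$nodes, `[[`, "", "kind")
  cat(sprintf("<dag_graph '%s': %d nodes, %d edges>\n",
              x$name, length(x$nodes), nrow(x$edges)))
  cat("  order:", paste(x$order, collapse = " -> "), "\n")
  special <- kinds[kinds != "standard"]
  if (length(special) > 0L)
    cat("  special nodes:", paste(sprintf("%s (%s)", names(special), special),
                                  collapse = ", "), "\n")
  invisible(x)
}
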