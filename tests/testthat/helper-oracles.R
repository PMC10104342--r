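# Independent oracles and fixture builders, deliberately kept free of the
# package's graph machinery.

# Brute-force DFS cycle detection on an edge list over vertices 1..n.
dfs_has_cycle <- function(n, edges) {
  adj <- vector("list", n)
  if (nrow(edges) > 0L)
    for (i in seq_len(nrow(edges)))
      adj[[edges[i, 1L]]] <- c(adj[[edges[i, 1L]]], edges[i, 2L])
  state <- integer(n) # 0 unseen, 1 on stack, 2 done
  visit <- function(u) {
    state[u] <<- 1L
    for (v in adj[[u]]) {
      if (state[v] == 1L) return(TRUE)
      if (state[v] == 0L && visit(v)) return(TRUE)
    }
    state[u] <<- 2L
    FALSE
  }
  for (u in seq_len(n)) if (state[u] == 0L && visit(u)) return(TRUE)
  FALSE
}

# Exhaustive enumeration of all topological orders of a small digraph.
all_topological_orders <- function(names, edges) {
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  ok <- function(ord) {
    if (nrow(edges) == 0L) return(TRUE)
    pos <- match(names, ord)
    names(pos) <- names
    all(pos[edges[, 1L]] < pos[edges[, 2L]])
  }
  Filter(ok, perms(names))
}

# Build node specs for a pure-structure graph: every node returns a
# constant; parents wired per the edge list (character from/to).
structure_specs <- function(names, edges) {
  lapply(names, function(nm) {
    parents <- if (nrow(edges) > 0L) edges[edges[, 2L] == nm, 1L] else character(0)
    args <- stats::setNames(lapply(parents, node_ref), parents)
    node(nm, func = function(...) 0, args = args)
  })
}

# All ordered vertex pairs of a 4-vertex labelled digraph (no self-loops).
pairs4 <- local({
  p <- expand.grid(from = 1:4, to = 1:4)
  as.matrix(p[p$from != p$to, ])
})

const_true <- function() TRUE
const_false <- function() FALSE
const_value <- function(value) value
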