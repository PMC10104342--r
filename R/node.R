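#' Reference a parent node in an argument binding
#'
#' Wraps a node name so that, when a node is simulated, the argument receives
#' that parent's value for the current sample rather than the literal string.
#'
#' @param name Name of another node in the same graph.
#' @return An object of class `node_ref`.
#' @examples
#' node("B", func = function(x) x + 1, args = list(x = node_ref("A")))
#' @export
node_ref <- function(name) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    sim_abort("simdag_domain_error", "node_ref() needs a single non-empty node name")
  structure(list(name = name), class = "node_ref")
}

is_node_ref <- function(x) inherits(x, "node_ref")

#' The missing-value sentinel
#'
#' A dedicated sentinel marking masked entries produced by missing nodes.
#' It is distinct from `NA` and `NaN`, so missing strings and missing
#' arbitrary objects are representable. It is rendered as an empty field
#' in CSV output.
#'
#' @return `missing_value()` returns the sentinel; `is_missing_value(x)`
#'   tests for it.
#' @export
missing_value <- function() .missing_sentinel

.missing_sentinel <- structure(list(), class = "simdag_missing")

#' @rdname missing_value
#' @param x Any value.
#' @export
is_missing_value <- function(x) inherits(x, "simdag_missing")

#' @export
print.simdag_missing <- function(x, ...) {
  cat("<missing>\n")
  invisible(x)
}

node_kinds <- c("standard", "selection", "missing", "stratify")

#' Declare a node of a simulation graph
#'
#' A node is one variable of the model: a name, a generating function, and
#' argument bindings that are either literals or [node_ref()] references to
#' parent nodes. During simulation the function is called once per sample
#' with the bound arguments; its return value may be of any type (a scalar,
#' a string, a matrix, a set of sequences, ...) and is passed natively to
#' child nodes.
#'
#' @param name Unique node name (non-empty string).
#' @param func The generating function, or its (optionally
#'   `pkg::`-qualified) name as a string. Passing a string defers
#'   resolution to run time and keeps the node emittable to YAML.
#' @param args Named list of argument bindings. Values that are
#'   [node_ref()] objects are parent references; everything else is passed
#'   as a literal constant.
#' @param kind One of `"standard"`, `"selection"`, `"stratify"`. Selection
#'   nodes must return a single logical per sample and drive rejection
#'   sampling; stratify nodes must return a scalar label and drive output
#'   splitting. Missing nodes are built with [make_missing_node()].
#' @param observed Should this node's column be written to output?
#'   Selection and stratify nodes never produce a column regardless.
#' @param plate Optional plate tag: `list(id = <string>, k = <count>)` or a
#'   bare replicate count (the id then defaults to the node name). The node
#'   is expanded into `k` i.i.d. replicates `name_1 .. name_k` at build
#'   time; references between nodes sharing a plate id are rewired
#'   replicate-wise.
#' @return An object of class `dag_node`.
#' @examples
#' p <- node("p_heads", func = rand_uniform, args = list(min = 0, max = 1))
#' @export
node <- function(name, func, args = list(), kind = "standard",
                 observed = TRUE, plate = NULL) {
  func_sub <- substitute(func)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    sim_abort("simdag_domain_error", "node name must be a single non-empty string")
  if (!kind %in% setdiff(node_kinds, "missing"))
    sim_abort("simdag_domain_error", sprintf(
      "unknown node kind '%s' (missing nodes are built with make_missing_node())", kind))
  if (!is.list(args))
    sim_abort("simdag_domain_error", "args must be a list")
  if (length(args) > 0L) {
    nm <- names(args)
    if (is.null(nm) || any(!nzchar(nm)))
      sim_abort("simdag_domain_error", sprintf("all args of node '%s' must be named", name))
    if (anyDuplicated(nm))
      sim_abort("simdag_domain_error", sprintf(
        "duplicate argument name '%s' in node '%s'", nm[duplicated(nm)][1L], name))
  }

  func_name <- NA_character_
  if (is.character(func)) {
    func_name <- func
    func <- NULL
  } else if (is.function(func)) {
    # recover a qualified name when the caller passed a named function
    if (is.symbol(func_sub)) {
      func_name <- as.character(func_sub)
    } else if (is.call(func_sub) && identical(func_sub[[1L]], as.name("::"))) {
      func_name <- paste0(as.character(func_sub[[2L]]), "::", as.character(func_sub[[3L]]))
    }
  } else {
    sim_abort("simdag_domain_error", sprintf(
      "func of node '%s' must be a function or a function name", name))
  }

  plate <- normalize_plate(plate, name)

  structure(list(
    name = name, kind = kind, func = func, func_name = func_name,
    args = args, observed = isTRUE(observed), plate = plate
  ), class = "dag_node")
}

normalize_plate <- function(plate, name) {
  if (is.null(plate)) return(NULL)
  if (is.numeric(plate) && length(plate) == 1L)
    plate <- list(id = name, k = plate)
  if (!is.list(plate) || is.null(plate$k))
    sim_abort("simdag_domain_error", sprintf(
      "plate of node '%s' must be a replicate count or list(id =, k =)", name))
  if (is.null(plate$id)) plate$id <- name
  k <- plate$k
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1 || k != round(k))
    sim_abort("simdag_domain_error", sprintf(
      "plate replicate count of node '%s' must be an integer >= 1", name))
  list(id = as.character(plate$id), k = as.integer(k))
}

#' Declare a missing node
#'
#' A missing node masks the values of an underlying node according to a
#' mask node: per sample, its value is the underlying value where the mask
#' is `FALSE` and the missing sentinel ([missing_value()]) where the mask
#' is `TRUE`. MCAR, MAR and MNAR mechanisms are obtained by letting the
#' mask node depend on nothing, on other observed nodes, or on the
#' underlying value itself.
#'
#' @param name Name of the missing node.
#' @param underlying Name of the standard node whose values get masked.
#' @param mask Name of a standard node returning one logical per sample.
#' @param observed Should the masked column be written to output?
#' @return A `dag_node` of kind `"missing"`.
#' @export
make_missing_node <- function(name, underlying, mask, observed = TRUE) {
  if (is_node_ref(underlying)) underlying <- underlying$name
  if (is_node_ref(mask)) mask <- mask$name
  n <- node(name, func = ".missing", args = list(
    underlying = node_ref(underlying), mask = node_ref(mask)
  ), observed = observed)
  n$kind <- "missing"
  n$func_name <- NA_character_
  n$func <- NULL
  n
}

#' @export
print.dag_node <- function(x, ...) {
  extra <- ""
  if (!is.null(x$plate))
    extra <- sprintf(" [plate %s x%d]", x$plate$id, x$plate$k)
  parents <- vapply(x$args, function(a) if (is_node_ref(a)) a$name else NA_character_, "")
  parents <- parents[!is.na(parents)]
  cat(sprintf("<dag_node %s: kind=%s, parents={%s}%s>\n",
              x$name, x$kind, paste(parents, collapse = ", "), extra))
  invisible(x)
}

node_parents <- function(n) {
  out <- character(0)
  for (a in n$args) if (is_node_ref(a)) out <- c(out, a$name)
  unique(out)
}
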