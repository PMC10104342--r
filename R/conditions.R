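# Classed conditions so callers (and the CLI) can dispatch on failure category.

sim_abort <- function(class, msg, ..., call = NULL) {
  stop(structure(
    class = c(class, "simdag_error", "error", "condition"),
    list(message = msg, call = call, ...)
  ))
}

#' @rdname simdag-errors
#' @name simdag-errors
#' @title Condition classes signalled by simdag
#'
#' @description All errors raised by the package are classed conditions
#' inheriting from `simdag_error`, so they can be caught selectively with
#' `tryCatch()`. The classes are:
#'
#' * `simdag_duplicate_name_error` — two node specs share a name.
#' * `simdag_unresolved_reference_error` — a parent reference names no
#'   declared node.
#' * `simdag_cycle_error` — the graph has a directed cycle; the message
#'   lists one offending cycle.
#' * `simdag_kind_error` — a node of the wrong kind was used where a
#'   standard node is required (e.g. as the underlying/mask of a missing
#'   node), or a special node's function returned an unusable value.
#' * `simdag_domain_error` — an argument outside its documented domain.
#' * `simdag_config_error` — inconsistent run or generator settings.
#' * `simdag_schema_error` — a YAML document violates the schema; the
#'   message carries the offending path.
#' * `simdag_function_resolution_error` — a function name in a YAML
#'   document cannot be resolved to a callable.
#' * `simdag_unserializable_function_error` — a graph holding an anonymous
#'   function cannot be emitted to YAML.
#' * `simdag_function_evaluation_error` — a user node function failed;
#'   the message reports node name and sample index.
#' * `simdag_rejection_budget_error` — selection rejected too many
#'   candidates; the message reports the acceptance rate so far.
#' * `simdag_label_error` — a stratum label cannot be sanitised to a
#'   non-empty file-name-safe token.
NULL
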