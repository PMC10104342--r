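#' Run parameters for a simulation
#'
#' @param n_samples Number of retained samples (>= 1). With a selection
#'   node this is the post-selection count.
#' @param seed Optional integer master seed; when given, all randomness of
#'   the run derives from it and output is byte-reproducible.
#' @param output_dir Directory for CSV output (created on demand).
#' @param csv_name Base file name (without extension) for CSV output.
#' @param max_rejection_attempts Total candidate budget under selection;
#'   defaults to `10000 * n_samples`. Exhausting it raises a
#'   rejection-budget error reporting the acceptance rate so far.
#' @param serializers Optional named list mapping node names to cell
#'   serialisers for CSV output: `"json"`, `"fasta"`, `"matrix"`, or a
#'   function `value -> string`. See [write_sim_csv()].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_samples, seed = NULL, output_dir = ".",
                       csv_name = "simulation",
                       max_rejection_attempts = NULL,
                       serializers = list()) {
  if (!is.numeric(n_samples) || length(n_samples) != 1L || is.na(n_samples) ||
      n_samples < 1 || n_samples != round(n_samples))
    sim_abort("simdag_config_error", "n_samples must be an integer >= 1")
  n_samples <- as.integer(n_samples)
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
      sim_abort("simdag_config_error", "seed must be a single integer")
    seed <- as.integer(seed)
  }
  if (is.null(max_rejection_attempts))
    max_rejection_attempts <- 10000 * n_samples
  if (max_rejection_attempts < n_samples)
    sim_abort("simdag_config_error", "max_rejection_attempts must be >= n_samples")
  if (!is.character(csv_name) || length(csv_name) != 1L || !nzchar(csv_name))
    sim_abort("simdag_config_error", "csv_name must be a non-empty string")
  structure(list(n_samples = n_samples, seed = seed, output_dir = output_dir,
                 csv_name = csv_name,
                 max_rejection_attempts = as.double(max_rejection_attempts),
                 serializers = serializers),
            class = "sim_config")
}

#' Forward-sample a simulation graph
#'
#' Draws `n_samples` joint samples by evaluating each node's function in
#' topological order, passing literal bindings as-is and parent bindings
#' as the parent's value for the current sample. Values of any type are
#' carried natively between nodes without coercion.
#'
#' If the graph contains a selection node, candidate samples are drawn and
#' kept only when the selection function returns `TRUE`; drawing repeats
#' until `n_samples` candidates are retained or the rejection budget is
#' exhausted. Missing nodes substitute the missing sentinel where their
#' mask is `TRUE`; a stratify node's per-sample labels are recorded for
#' [stratify_rows()]. Selection and stratify nodes contribute no output
#' column.
#'
#' @param graph A `dag_graph` from [build_graph()].
#' @param config A [sim_config()]; alternatively pass `n_samples`/`seed`
#'   directly.
#' @param n_samples,seed Shorthand used when `config` is not given.
#' @return A `sample_table`: an ordered set of columns (one per observed
#'   node, in topological order), each a list of native per-sample values.
#'   Attributes carry the stratify labels (if any) and the selection
#'   acceptance rate.
#' @examples
#' g <- build_graph(list(
#'   node("A", func = rand_uniform),
#'   node("B", func = function(x) x + 1, args = list(x = node_ref("A")))
#' ))
#' tab <- simulate_graph(g, n_samples = 5, seed = 1)
#' as.data.frame(tab)
#' @export
simulate_graph <- function(graph, config = NULL, n_samples = NULL, seed = NULL) {
  stopifnot(inherits(graph, "dag_graph"))
  if (is.null(config)) {
    if (is.null(n_samples))
      sim_abort("simdag_config_error", "give either a sim_config or n_samples")
    config <- sim_config(n_samples, seed = seed)
  }
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)

  ord <- graph$order
  nodes <- graph$nodes
  funcs <- lapply(nodes, function(nd) {
    if (nd$kind == "missing") return(NULL)
    if (!is.null(nd$func)) nd$func else resolve_function(nd$func_name)
  })

  sel_name <- names(nodes)[vapply(nodes, function(n) n$kind == "selection", TRUE)]
  str_name <- names(nodes)[vapply(nodes, function(n) n$kind == "stratify", TRUE)]
  has_sel <- length(sel_name) == 1L

  n <- config$n_samples
  values <- lapply(nodes, function(nd) vector("list", n))
  labels <- if (length(str_name) == 1L) vector("list", n) else NULL

  kept <- 0L
  attempts <- 0
  while (kept < n) {
    if (has_sel && attempts >= config$max_rejection_attempts)
      sim_abort("simdag_rejection_budget_error", sprintf(
        "selection rejected too many candidates: %d retained of %s drawn (acceptance rate %.2g)",
        kept, format(attempts, big.mark = ","), kept / attempts))
    attempts <- attempts + 1
    env <- evaluate_candidate(nodes, funcs, ord, sample_index = kept + 1L,
                              sel_name = sel_name)
    if (has_sel && !isTRUE(env[[sel_name]])) next
    kept <- kept + 1L
    for (nm in ord) values[[nm]][[kept]] <- env[[nm]]
    if (!is.null(labels)) labels[[kept]] <- env[[str_name]]
  }

  observed <- vapply(nodes, function(nd)
    nd$observed && nd$kind %in% c("standard", "missing"), TRUE)
  cols <- values[ord[ord %in% names(nodes)[observed]]]

  if (!is.null(labels)) {
    labels <- vapply(labels, sanitize_label, "", node = str_name)
  }

  structure(list(columns = cols, n = n),
            class = "sample_table",
            strata_labels = labels,
            acceptance_rate = if (has_sel) kept / attempts else 1,
            graph_name = graph$name)
}

evaluate_candidate <- function(nodes, funcs, ord, sample_index, sel_name) {
  env <- list()
  for (nm in ord) {
    nd <- nodes[[nm]]
    if (nd$kind == "missing") {
      mask <- env[[nd$args$mask$name]]
      if (!is.logical(mask) || length(mask) != 1L || is.na(mask))
        sim_abort("simdag_kind_error", sprintf(
          "mask node '%s' of missing node '%s' must return TRUE or FALSE, got %s",
          nd$args$mask$name, nm, class(mask)[1L]))
      env[[nm]] <- if (mask) .missing_sentinel else env[[nd$args$underlying$name]]
      next
    }
    args <- lapply(nd$args, function(a) if (is_node_ref(a)) env[[a$name]] else a)
    val <- tryCatch(do.call(funcs[[nm]], args), error = function(e)
      sim_abort("simdag_function_evaluation_error", sprintf(
        "function of node '%s' failed at sample %d: %s", nm, sample_index,
        conditionMessage(e)), node = nm, sample_index = sample_index))
    if (nd$kind == "selection" &&
        (!is.logical(val) || length(val) != 1L || is.na(val)))
      sim_abort("simdag_kind_error", sprintf(
        "selection node '%s' must return TRUE or FALSE, got %s",
        nm, class(val)[1L]))
    env[[nm]] <- val
  }
  env
}

sanitize_label <- function(label, node) {
  if (is_missing_value(label) || length(label) != 1L || is.na(label))
    sim_abort("simdag_label_error", sprintf(
      "stratify node '%s' produced a label that is not a non-missing scalar", node))
  tok <- gsub("[^A-Za-z0-9._-]+", "_", as.character(label))
  tok <- gsub("^_+|_+$", "", tok)
  if (!nzchar(tok))
    sim_abort("simdag_label_error", sprintf(
      "stratify label '%s' cannot be sanitised to a non-empty file-name token",
      as.character(label)))
  tok
}

#' Split a sample table by its stratify labels
#'
#' Partitions the rows of a simulated table by the per-sample labels
#' computed by the graph's stratify node. Labels are sanitised to
#' file-name-safe tokens; strata are pairwise disjoint and their sizes sum
#' to the retained sample count.
#'
#' @param table A `sample_table` produced from a graph with a stratify node.
#' @param graph The graph it came from (used for error messages only).
#' @return A named list of `sample_table`s, one per stratum, of class
#'   `stratified_output`.
#' @export
stratify_rows <- function(table, graph = NULL) {
  stopifnot(inherits(table, "sample_table"))
  labels <- attr(table, "strata_labels")
  if (is.null(labels))
    sim_abort("simdag_config_error", "table was not simulated from a graph with a stratify node")
  out <- list()
  for (lab in unique(labels)) {
    idx <- which(labels == lab)
    cols <- lapply(table$columns, function(col) col[idx])
    out[[lab]] <- structure(list(columns = cols, n = length(idx)),
                            class = "sample_table",
                            graph_name = attr(table, "graph_name"))
  }
  structure(out, class = "stratified_output")
}

#' @export
print.sample_table <- function(x, ...) {
  cat(sprintf("<sample_table: %d samples x %d columns (%s)>\n",
              x$n, length(x$columns), paste(names(x$columns), collapse = ", ")))
  invisible(x)
}

#' @export
print.stratified_output <- function(x, ...) {
  sizes <- vapply(x, function(t) t$n, 1L)
  cat(sprintf("<stratified_output: %d strata (%s)>\n", length(x),
              paste(sprintf("%s: %d", names(sizes), sizes), collapse = ", ")))
  invisible(x)
}

#' @export
dim.sample_table <- function(x) c(x$n, length(x$columns))

#' Convert a sample table to a data frame
#'
#' Columns whose values are all length-1 atomic scalars are simplified to
#' plain vectors (missing sentinels become `NA`); other columns stay as
#' list columns.
#'
#' @param x A `sample_table`.
#' @param ... Unused.
#' @export
as.data.frame.sample_table <- function(x, ...) {
  cols <- lapply(x$columns, function(col) {
    scalar <- vapply(col, function(v)
      is_missing_value(v) || (is.atomic(v) && length(v) == 1L), TRUE)
    if (all(scalar)) {
      unlist(lapply(col, function(e) if (is_missing_value(e)) NA else e),
             use.names = FALSE)
    } else I(col)
  })
  as.data.frame(cols, stringsAsFactors = FALSE, optional = TRUE)
}

#' Column accessor for sample tables
#' @param x A `sample_table`.
#' @param name Column (node) name.
#' @export
`[[.sample_table` <- function(x, name) {
  if (name %in% c("columns", "n")) return(.subset2(x, name))
  .subset2(.subset2(x, "columns"), name)
}
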