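# Function registry: user-registered names take precedence over
# `pkg::name` lookup and the search path, so YAML examples run without
# packaging user code.
.registry <- new.env(parent = emptyenv())

#' Register a function under a name for YAML resolution
#'
#' Functions named in a YAML document are resolved first against this
#' registry, then as `pkg::name`, then on the search path. Registering is
#' the way to make ad-hoc user functions reachable from a document.
#'
#' @param name Name as it appears in the YAML `function:` field.
#' @param func The function.
#' @export
register_function <- function(name, func) {
  stopifnot(is.character(name), length(name) == 1L, is.function(func))
  assign(name, func, envir = .registry)
  invisible(name)
}

#' @rdname register_function
#' @export
clear_function_registry <- function() {
  rm(list = ls(.registry), envir = .registry)
  invisible(NULL)
}

resolve_function <- function(name) {
  if (is.na(name) || !nzchar(name))
    sim_abort("simdag_function_resolution_error",
              "node has no resolvable function name")
  if (exists(name, envir = .registry, inherits = FALSE))
    return(get(name, envir = .registry))
  if (grepl("::", name, fixed = TRUE)) {
    parts <- strsplit(name, "::", fixed = TRUE)[[1L]]
    f <- tryCatch(getExportedValue(parts[1L], parts[2L]), error = function(e) NULL)
    if (is.function(f)) return(f)
  } else {
    if (exists(name, envir = asNamespace("simdag"), inherits = FALSE)) {
      f <- get(name, envir = asNamespace("simdag"))
      if (is.function(f)) return(f)
    }
    f <- tryCatch(get(name, envir = globalenv()), error = function(e) NULL)
    if (is.function(f)) return(f)
  }
  sim_abort("simdag_function_resolution_error", sprintf(
    "cannot resolve '%s' to a function (registry, pkg::name, search path)", name))
}

node_keys <- c("function", "kwargs", "kind", "observed", "plate",
               "underlying", "mask")
instruction_keys <- c("n_samples", "seed", "output_dir", "csv_name",
                      "max_rejection_attempts")

#' Parse a YAML simulation document
#'
#' Reads the package's YAML dialect: a `graph:` section mapping node names
#' to their generating function and argument bindings, and an
#' `instructions:` section with the run parameters. Returns the validated
#' graph plus a run configuration.
#'
#' The schema is:
#' ```yaml
#' name: my_model            # optional
#' graph:
#'   <node>:
#'     function: pkg::fun    # or a registered / searchable name
#'     kwargs: {arg: value, parent_arg: <other node>}
#'     kind: standard        # optional: selection | stratify
#'     observed: true        # optional
#'     plate: {id: p, count: 3}   # optional flat plate
#'   <missing node>:
#'     kind: missing
#'     underlying: <node>
#'     mask: <node>
#' instructions:
#'   n_samples: 1000
#'   seed: 1                 # optional
#'   output_dir: out         # optional, default "."
#'   csv_name: my_model      # optional, default = model name
#' ```
#'
#' A `kwargs` string exactly matching a declared node name is a parent
#' reference; any other string is a literal. A leading `=` forces literal
#' interpretation of the remainder (`"=A"` is the string `"A"` even when a
#' node `A` exists).
#'
#' @param text A YAML string, or the path of a YAML file.
#' @param strict Reject unknown keys (default). With `strict = FALSE`
#'   unknown keys are tolerated with a warning.
#' @return A list with elements `graph` (a `dag_graph`) and `config`
#'   (a `sim_config`).
#' @export
parse_yaml <- function(text, strict = TRUE) {
  doc <- if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    yaml::read_yaml(text)
  else yaml::yaml.load(paste(text, collapse = "\n"))
  if (!is.list(doc)) sim_abort("simdag_schema_error", "document is not a YAML mapping")

  known_top <- c("name", "graph", "instructions")
  check_keys(names(doc), known_top, "document root", strict)
  if (is.null(doc$graph) || !is.list(doc$graph) || length(doc$graph) == 0L)
    sim_abort("simdag_schema_error", "missing or empty 'graph' section")
  if (is.null(doc$instructions) || is.null(doc$instructions$n_samples))
    sim_abort("simdag_schema_error", "'instructions' section must give n_samples")
  check_keys(names(doc$instructions), instruction_keys, "instructions", strict)

  model_name <- if (!is.null(doc$name)) doc$name else "model"
  declared <- names(doc$graph)
  if (is.null(declared) || any(!nzchar(declared)))
    sim_abort("simdag_schema_error", "every graph entry must be a named node")

  specs <- vector("list", length(declared))
  for (i in seq_along(declared)) {
    nm <- declared[i]
    entry <- doc$graph[[i]]
    if (!is.list(entry))
      sim_abort("simdag_schema_error", sprintf("graph/%s: entry must be a mapping", nm))
    check_keys(names(entry), node_keys, paste0("graph/", nm), strict)
    kind <- if (!is.null(entry$kind)) entry$kind else "standard"
    if (!kind %in% node_kinds)
      sim_abort("simdag_schema_error", sprintf("graph/%s: unknown kind '%s'", nm, kind))

    if (kind == "missing") {
      if (is.null(entry$underlying) || is.null(entry$mask))
        sim_abort("simdag_schema_error", sprintf(
          "graph/%s: a missing node needs 'underlying' and 'mask'", nm))
      specs[[i]] <- make_missing_node(nm, entry$underlying, entry$mask,
                                      observed = !isFALSE(entry$observed))
      next
    }
    if (is.null(entry[["function"]]))
      sim_abort("simdag_schema_error", sprintf("graph/%s: missing 'function'", nm))
    fname <- entry[["function"]]
    resolve_function(fname)  # fail early with the offending path
    kwargs <- entry$kwargs
    if (is.null(kwargs)) kwargs <- list()
    args <- lapply(kwargs, function(v) {
      if (is.character(v) && length(v) == 1L) {
        if (startsWith(v, "=")) return(substring(v, 2L))
        if (v %in% declared) return(node_ref(v))
      }
      v
    })
    plate <- NULL
    if (!is.null(entry$plate)) {
      if (!is.list(entry$plate) || is.null(entry$plate$count))
        sim_abort("simdag_schema_error", sprintf(
          "graph/%s: plate must be a mapping with 'count' (and optional 'id')", nm))
      plate <- list(id = if (!is.null(entry$plate$id)) entry$plate$id else nm,
                    k = entry$plate$count)
    }
    specs[[i]] <- node(nm, func = fname, args = args, kind = kind,
                       observed = !isFALSE(entry$observed), plate = plate)
  }

  graph <- build_graph(specs, name = model_name)
  ins <- doc$instructions
  config <- sim_config(
    n_samples = ins$n_samples,
    seed = ins$seed,
    output_dir = if (!is.null(ins$output_dir)) ins$output_dir else ".",
    csv_name = if (!is.null(ins$csv_name)) ins$csv_name else model_name,
    max_rejection_attempts = ins$max_rejection_attempts
  )
  list(graph = graph, config = config)
}

check_keys <- function(keys, allowed, where, strict) {
  unknown <- setdiff(keys, allowed)
  if (length(unknown) == 0L) return(invisible(NULL))
  msg <- sprintf("unknown key%s at %s: %s", if (length(unknown) > 1L) "s" else "",
                 where, paste(unknown, collapse = ", "))
  if (strict) sim_abort("simdag_schema_error", msg) else warning(msg, call. = FALSE)
  invisible(NULL)
}

#' Emit a graph and configuration as a YAML document
#'
#' Writes the package's YAML dialect such that [parse_yaml()] on the
#' result reconstructs an equivalent graph and configuration (round-trip
#' property). Every node's function must be name-recoverable: nodes built
#' from anonymous functions cannot be emitted.
#'
#' @param graph A `dag_graph`.
#' @param config A `sim_config`.
#' @return A YAML string.
#' @export
emit_yaml <- function(graph, config) {
  stopifnot(inherits(graph, "dag_graph"), inherits(config, "sim_config"))
  declared <- names(graph$nodes)
  gsec <- list()
  for (nd in graph$nodes) {
    if (nd$kind == "missing") {
      gsec[[nd$name]] <- list(kind = "missing",
                              underlying = nd$args$underlying$name,
                              mask = nd$args$mask$name,
                              observed = nd$observed)
      next
    }
    if (is.na(nd$func_name))
      sim_abort("simdag_unserializable_function_error", sprintf(
        "node '%s' holds an anonymous function; give it a named or registered function to emit YAML",
        nd$name))
    entry <- list("function" = nd$func_name)
    if (length(nd$args) > 0L)
      entry$kwargs <- lapply(nd$args, function(a) {
        if (is_node_ref(a)) return(a$name)
        if (is.character(a) && length(a) == 1L &&
            (a %in% declared || startsWith(a, "=")))
          return(paste0("=", a))
        a
      })
    if (nd$kind != "standard") entry$kind <- nd$kind
    if (!nd$observed) entry$observed <- FALSE
    gsec[[nd$name]] <- entry
  }
  ins <- list(n_samples = config$n_samples)
  if (!is.null(config$seed)) ins$seed <- config$seed
  ins$output_dir <- config$output_dir
  ins$csv_name <- config$csv_name
  yaml::as.yaml(list(name = graph$name, graph = gsec, instructions = ins))
}
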