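#' Write a sample table to CSV
#'
#' Writes an RFC-4180 CSV (UTF-8, header row of node names in column
#' order, fields quoted only when needed). Scalars are written canonically
#' and strings verbatim; the missing sentinel becomes an empty field.
#'
#' Non-scalar values cannot live in a CSV cell natively, so they are
#' serialised: modest-sized values (up to `sidecar_threshold` items) as a
#' quoted JSON literal in the cell, larger ones as per-sample sidecar
#' files whose relative path is written in the cell — tab-separated text
#' for numeric matrices/tensors, FASTA for sets of sequences. A per-node
#' entry in `config$serializers` overrides this default: `"json"`,
#' `"matrix"`, `"fasta"`, or a function mapping the value to a cell
#' string.
#'
#' @param table A `sample_table` (or `stratified_output`, in which case
#'   one file `<csv_name>_<stratum>.csv` is written per stratum).
#' @param config A [sim_config()] giving output directory and file name.
#' @param stratum_label Optional stratum token appended to the file name.
#' @param sidecar_threshold Item count above which a value goes to a
#'   sidecar file instead of an in-cell JSON literal.
#' @return The path(s) of the written file(s), invisibly.
#' @export
write_sim_csv <- function(table, config, stratum_label = NULL,
                          sidecar_threshold = 1024L) {
  if (inherits(table, "stratified_output")) {
    paths <- character(0)
    for (lab in names(table))
      paths <- c(paths, write_sim_csv(table[[lab]], config, stratum_label = lab,
                                      sidecar_threshold = sidecar_threshold))
    return(invisible(paths))
  }
  stopifnot(inherits(table, "sample_table"), inherits(config, "sim_config"))
  if (table$n == 0L || length(table$columns) == 0L)
    sim_abort("simdag_config_error", "refusing to write an empty table")

  base <- config$csv_name
  if (!is.null(stratum_label)) base <- paste0(base, "_", stratum_label)
  dir <- config$output_dir
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    sim_abort("simdag_io_error", sprintf("cannot create output directory '%s'", dir))
  path <- file.path(dir, paste0(base, ".csv"))

  col_names <- names(table$columns)
  cells <- matrix("", nrow = table$n, ncol = length(col_names))
  for (j in seq_along(col_names)) {
    nm <- col_names[j]
    ser <- config$serializers[[nm]]
    col <- table$columns[[nm]]
    for (i in seq_len(table$n)) {
      cells[i, j] <- serialize_cell(col[[i]], ser, sidecar_threshold,
                                    dir = dir, base = base, node = nm, row = i)
    }
  }

  lines <- c(paste(vapply(col_names, csv_quote, ""), collapse = ","),
             apply(cells, 1L, function(r)
               paste(vapply(r, csv_quote, ""), collapse = ",")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

csv_quote <- function(field) {
  if (grepl('[",\n\r]', field))
    paste0('"', gsub('"', '""', field), '"')
  else field
}

serialize_cell <- function(value, serializer, threshold, dir, base, node, row) {
  if (is_missing_value(value)) return("")
  if (is.function(serializer)) return(as.character(serializer(value)))

  if (inherits(value, "repertoire")) value <- value$sequences
  if (inherits(value, "shape_image")) value <- value$pixels

  if (identical(serializer, "fasta"))
    return(write_fasta_sidecar(value, dir, base, node, row))
  if (identical(serializer, "matrix"))
    return(write_matrix_sidecar(value, dir, base, node, row))
  if (identical(serializer, "json"))
    return(as.character(jsonlite::toJSON(value, auto_unbox = FALSE, digits = NA)))

  # default policy
  if (is.atomic(value) && length(value) == 1L && !is.array(value)) {
    if (is.na(value)) return("NA")
    if (is.character(value)) return(value)
    if (is.numeric(value)) return(format(value, digits = 15, trim = TRUE,
                                         scientific = FALSE))
    return(as.character(value))
  }
  if (length(value) > threshold) {
    if (is.character(value)) return(write_fasta_sidecar(value, dir, base, node, row))
    if (is.numeric(value)) return(write_matrix_sidecar(value, dir, base, node, row))
  }
  as.character(jsonlite::toJSON(value, auto_unbox = FALSE, digits = NA,
                                force = TRUE))
}

sidecar_dir <- function(dir, base) {
  sd <- file.path(dir, paste0(base, "_files"))
  if (!dir.exists(sd)) dir.create(sd, recursive = TRUE, showWarnings = FALSE)
  sd
}

write_fasta_sidecar <- function(seqs, dir, base, node, row) {
  sd <- sidecar_dir(dir, base)
  rel <- file.path(paste0(base, "_files"), sprintf("%s_%d.fasta", node, row))
  seqinr::write.fasta(as.list(seqs), names = paste0("seq", seq_along(seqs)),
                      file.out = file.path(dir, rel), as.string = TRUE)
  rel
}

write_matrix_sidecar <- function(x, dir, base, node, row) {
  sd <- sidecar_dir(dir, base)
  rel <- file.path(paste0(base, "_files"), sprintf("%s_%d.tsv", node, row))
  m <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  utils::write.table(m, file.path(dir, rel), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  rel
}
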