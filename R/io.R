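# Delimited-text readers/writers for the core containers, JSON checkpoints,
# and run manifests.  All writes go through a temp-file-plus-rename so a
# crashed run never leaves a truncated file behind.

write_atomic <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not move temp file onto ", path)
  invisible(path)
}

write_matrix_atomic <- function(m, path, col_names = NULL) {
  write_atomic(function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    if (!is.null(col_names)) writeLines(paste(col_names, collapse = "\t"), con)
    utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                       con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }, path)
}

write_json_atomic <- function(x, path) {
  write_atomic(function(tmp) {
    jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }, path)
}

parse_numeric_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty file: ", path)
  split_row <- function(l) strsplit(trimws(l), "[,\t ]+")[[1]]
  first <- split_row(lines[1])
  header <- suppressWarnings(any(is.na(as.numeric(first))))
  labels <- if (header) first else NULL
  body <- if (header) lines[-1] else lines
  if (length(body) == 0) stop("file has a header but no data rows: ", path)
  rows <- lapply(body, split_row)
  widths <- lengths(rows)
  if (length(unique(widths)) != 1) {
    stop("ragged rows in ", path, " (widths ",
         paste(unique(widths), collapse = ", "), ")")
  }
  m <- matrix(NA_real_, length(rows), widths[1])
  for (i in seq_along(rows)) {
    v <- suppressWarnings(as.numeric(rows[[i]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad)) {
      stop("non-numeric or non-finite cell at data row ", i, ", column ",
           bad[1], " of ", path)
    }
    m[i, ] <- v
  }
  list(matrix = m, labels = labels)
}

#' Read a regional time-series matrix
#'
#' Parses a whitespace- or comma-delimited `N x T` matrix (rows = regions),
#' with an optional first line of region labels.
#'
#' @param path file path.
#' @param tr_seconds sampling interval to attach.
#' @return a [graph_signal()].
#' @export
read_timeseries <- function(path, tr_seconds = 0.72) {
  if (!file.exists(path)) stop("no such file: ", path)
  p <- parse_numeric_matrix(path)
  labels <- p$labels
  m <- p$matrix
  if (!is.null(labels)) {
    # labels name the regions; for an N x T layout they arrive as a column,
    # so a label header line must match the row count
    if (length(labels) == nrow(m)) {
      # header line carried one label per region
    } else if (length(labels) == ncol(m)) {
      stop("header length matches timepoints, not regions; ",
           "expected one label per row")
    } else {
      stop("header has ", length(labels), " labels for ", nrow(m), " regions")
    }
  }
  graph_signal(m, tr_seconds, labels)
}

#' Write a regional time-series matrix
#'
#' @param x a [graph_signal()] or matrix.
#' @param path output path; written atomically. Region labels, when present,
#'   become a header line.
#' @export
write_timeseries <- function(x, path) {
  m <- if (inherits(x, "bc_signal")) x$data else as.matrix(x)
  labels <- if (inherits(x, "bc_signal")) x$region_labels else NULL
  write_matrix_atomic(m, path, col_names = labels)
}

#' Read a structural adjacency matrix
#'
#' Parses an `N x N` delimited matrix; an optional sidecar file `<path>.labels`
#' (one region label per line, ordered as the matrix rows) is attached when
#' present. Asymmetry beyond `1e-8` is an error; smaller asymmetries are
#' symmetrized with a warning.
#'
#' @param path file path.
#' @return a [graph()].
#' @export
read_adjacency <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  p <- parse_numeric_matrix(path)
  labels <- p$labels
  sidecar <- paste0(path, ".labels")
  if (is.null(labels) && file.exists(sidecar)) {
    labels <- trimws(readLines(sidecar))
    labels <- labels[nzchar(labels)]
  }
  graph(p$matrix, node_labels = labels)
}

#' Write a structural adjacency matrix
#'
#' @param g a [graph()] or matrix.
#' @param path output path; labels go to a `<path>.labels` sidecar.
#' @export
write_adjacency <- function(g, path) {
  m <- if (inherits(g, "bc_graph")) g$adjacency else as.matrix(g)
  labels <- if (inherits(g, "bc_graph")) g$node_labels else NULL
  write_matrix_atomic(m, path)
  if (!is.null(labels)) {
    write_atomic(function(tmp) writeLines(labels, tmp), paste0(path, ".labels"))
  }
  invisible(path)
}

#' Save a model checkpoint
#'
#' Serializes all parameter arrays plus an architecture manifest (hidden
#' size, walk order, layers, walk directions, format version) to a single
#' JSON file. Parameters are graph-size independent, so a checkpoint can be
#' restored against a different graph of the same architecture.
#'
#' @param model a [dcrnn()] or `bc_dcrnn_fit`.
#' @param path output path.
#' @export
save_checkpoint <- function(model, path) {
  if (inherits(model, "bc_dcrnn_fit")) model <- model$model
  stopifnot(inherits(model, "bc_dcrnn"))
  pack_cell <- function(cell) lapply(cell, function(a) {
    if (is.matrix(a)) list(dim = dim(a), data = as.vector(a))
    else list(dim = length(a), data = as.vector(a))
  })
  payload <- list(
    format = "boldcast-checkpoint-1",
    manifest = list(order = model$order, hidden_size = model$hidden_size,
                    n_layers = model$n_layers,
                    input_features = model$input_features,
                    include_reverse = model$include_reverse,
                    normalization = model$normalization),
    params = list(enc = lapply(model$params$enc, pack_cell),
                  dec = lapply(model$params$dec, pack_cell),
                  w = model$params$w, b = model$params$b))
  write_json_atomic(payload, path)
}

#' Restore a model checkpoint
#'
#' @param path checkpoint written by [save_checkpoint()].
#' @param transition the [transition_matrix()] of the graph to run on; its
#'   `include_reverse` flag must match the checkpoint.
#' @return a [dcrnn()] with the stored parameters.
#' @export
load_checkpoint <- function(path, transition) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  if (!identical(payload$format, "boldcast-checkpoint-1")) {
    stop("unrecognized checkpoint format: ", payload$format)
  }
  man <- payload$manifest
  if (!identical(as.logical(man$include_reverse), transition$include_reverse)) {
    stop("checkpoint was trained with include_reverse = ", man$include_reverse)
  }
  model <- dcrnn(transition, order = man$order, hidden_size = man$hidden_size,
                 n_layers = man$n_layers, input_features = man$input_features,
                 seed = 0)
  unpack_cell <- function(cell) {
    out <- lapply(cell, function(a) {
      if (length(a$dim) == 2) matrix(a$data, a$dim[1], a$dim[2]) else as.numeric(a$data)
    })
    out
  }
  model$params <- list(enc = lapply(payload$params$enc, unpack_cell),
                       dec = lapply(payload$params$dec, unpack_cell),
                       w = as.numeric(payload$params$w),
                       b = as.numeric(payload$params$b))
  model
}

#' Write a reproducibility manifest
#'
#' Records the invocation (config values, seed, package and R versions)
#' alongside any run output, so every numerical result can be regenerated
#' from its manifest; two runs with identical settings produce identical
#' manifests.
#'
#' @param config named list of run settings.
#' @param path output path.
#' @export
write_manifest <- function(config, path) {
  write_json_atomic(list(
    config = config,
    package = "boldcast",
    package_version = as.character(utils::packageVersion("boldcast")),
    r_version = as.character(getRversion())), path)
}
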