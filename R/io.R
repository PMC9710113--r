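delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

# strict delimited-table reader: rejects ragged rows and non-numeric cells
# with the offending location, which generic readers silently coerce
read_strict_table <- function(path, delim) {
  if (!file.exists(path)) stop_usage(paste0("File not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop_input(paste0(path, ": needs a header row and at least one data row."))
  cells <- strsplit(lines, delim, fixed = TRUE)
  header <- cells[[1]]
  n_col <- length(header)
  widths <- lengths(cells[-1])
  if (any(widths != n_col)) {
    bad <- which(widths != n_col)[1] + 1L
    stop_input(paste0(path, ": row ", bad, " has ", widths[bad - 1L],
                      " fields, expected ", n_col, "."))
  }
  body <- cells[-1]
  ids <- vapply(body, `[[`, character(1), 1L)
  vals <- matrix(NA_real_, length(body), n_col - 1L)
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]][-1]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      stop_input(paste0(path, ": non-numeric cell at row ", i + 1L,
                        " ('", ids[i], "'), column ", j + 1L, " ('",
                        header[j + 1L], "'): '", body[[i]][j + 1L], "'."))
    }
    vals[i, ] <- v
  }
  list(row_ids = ids, col_ids = header[-1], values = vals,
       corner = header[1])
}

#' Read an expression table from delimited text
#'
#' Reads a TSV/CSV (delimiter chosen by file extension) with a header row
#' and a leading identifier column and returns it oriented samples x genes.
#' The reader is strict: ragged rows and non-numeric cells are errors that
#' name the offending location, and duplicate gene identifiers are rejected.
#'
#' @param path file path (`.csv` is comma-separated, anything else
#'   tab-separated).
#' @param orientation `"samples_by_genes"` (rows are samples; default) or
#'   `"genes_by_samples"` (rows are genes, as scRNA-seq matrices commonly
#'   ship; the table is transposed on read).
#' @return Expression tibble: first column `cell`, one numeric column per
#'   gene.
#' @export
read_expression <- function(path,
                            orientation = c("samples_by_genes",
                                            "genes_by_samples")) {
  orientation <- match.arg(orientation)
  tab <- read_strict_table(path, delim_for(path))
  if (orientation == "genes_by_samples") {
    m <- t(tab$values)
    genes <- tab$row_ids
    samples <- tab$col_ids
  } else {
    m <- tab$values
    genes <- tab$col_ids
    samples <- tab$row_ids
  }
  if (anyDuplicated(genes)) {
    stop_input(paste0(path, ": duplicated gene identifiers: ",
                      paste(unique(genes[duplicated(genes)]),
                            collapse = ", ")))
  }
  colnames(m) <- genes
  dplyr::bind_cols(tibble(cell = samples), as_tibble(m))
}

#' Write an expression table as delimited text
#'
#' @param data expression tibble (leading identifier column) or matrix.
#' @param path output path; `.csv` writes comma-separated, else tabs.
#' @return `path`, invisibly.
#' @export
write_expression <- function(data, path) {
  m <- as_expression_matrix(data)
  write_labeled_matrix(m, path, corner = "cell")
}

write_labeled_matrix <- function(m, path, corner = "") {
  delim <- delim_for(path)
  rn <- rownames(m) %||% paste0("r", seq_len(nrow(m)))
  header <- paste(c(corner, colnames(m)), collapse = delim)
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rn[i], sprintf("%.17g", m[i, ])), collapse = delim)
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

# coerce expression input (tibble with leading id column, data frame, or
# numeric matrix) to a samples x genes matrix with gene column names
as_expression_matrix <- function(data) {
  if (is.matrix(data)) {
    if (!is.numeric(data)) stop_input("Expression matrix must be numeric.")
    if (is.null(colnames(data))) {
      stop_input("Expression matrix needs gene column names.")
    }
    if (!all(is.finite(data))) stop_input("Expression values must be finite.")
    return(data)
  }
  if (!is.data.frame(data)) {
    stop_input("Expression data must be a data frame or numeric matrix.")
  }
  first_is_id <- !is.numeric(data[[1]])
  ids <- if (first_is_id) as.character(data[[1]]) else
    paste0("s", seq_len(nrow(data)))
  num <- if (first_is_id) data[-1] else data
  not_num <- !vapply(num, is.numeric, logical(1))
  if (any(not_num)) {
    stop_input(paste0("Non-numeric expression column(s): ",
                      paste(names(num)[not_num], collapse = ", ")))
  }
  m <- as.matrix(num)
  if (!all(is.finite(m))) stop_input("Expression values must be finite.")
  rownames(m) <- ids
  m
}

#' Write / read a gene-gene score matrix
#'
#' Square delimited table with gene identifiers on both axes, written with
#' 17 significant digits so that write-then-read is an exact identity.
#' Reading is tolerant of score matrices produced by other tools: values
#' outside \[0, 1\] only raise a warning (and set the attribute
#' `"out_of_range"`); a non-square table or mismatched row/column labels is
#' an error.
#'
#' @param x a `"grn_fit"` or square numeric matrix with gene dimnames.
#' @param path file path (`.csv` comma-separated, else tab).
#' @return `write_score_matrix()` returns `path` invisibly;
#'   `read_score_matrix()` returns the square numeric matrix (targets on
#'   rows, regulators on columns).
#' @export
write_score_matrix <- function(x, path) {
  S <- if (inherits(x, "grn_fit")) x$scores else as.matrix(x)
  if (nrow(S) != ncol(S) || is.null(colnames(S))) {
    stop_input("A square score matrix with gene dimnames is required.")
  }
  rownames(S) <- colnames(S)
  write_labeled_matrix(S, path, corner = "gene")
}

#' @rdname write_score_matrix
#' @export
read_score_matrix <- function(path) {
  tab <- read_strict_table(path, delim_for(path))
  if (length(tab$row_ids) != length(tab$col_ids)) {
    stop_input(paste0(path, ": score matrix must be square (got ",
                      length(tab$row_ids), " rows x ",
                      length(tab$col_ids), " columns)."))
  }
  if (!identical(tab$row_ids, tab$col_ids)) {
    stop_input(paste0(path, ": row and column gene labels differ."))
  }
  S <- tab$values
  dimnames(S) <- list(target = tab$row_ids, regulator = tab$col_ids)
  if (any(S < 0 | S > 1)) {
    warn(paste0(path, ": scores outside [0, 1] found; keeping them (foreign score matrix?)."))
    attr(S, "out_of_range") <- TRUE
  }
  S
}

#' Write / read a directed edge list
#'
#' Plain delimited text, no header: `regulator, target[, weight]` per line
#' (the conventional gold-standard format). A third column is read when
#' present and ignored rows never are; self-loops are dropped on read.
#'
#' @param net a `"grn_network"` or edge data frame.
#' @param path file path (`.csv` comma-separated, else tab).
#' @return `write_edge_list()` returns `path` invisibly;
#'   `read_edge_list()` returns a `"grn_network"` tibble (with `weight`
#'   when a third column is present).
#' @export
write_edge_list <- function(net, path) {
  df <- as.data.frame(net)
  cols <- intersect(c("regulator", "target", "weight"), names(df))
  delim <- delim_for(path)
  lines <- do.call(paste, c(unname(df[cols]), list(sep = delim)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop_usage(paste0("File not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop_input(paste0(path, ": empty edge list."))
  cells <- strsplit(lines, delim_for(path), fixed = TRUE)
  widths <- lengths(cells)
  if (any(widths < 2L)) {
    stop_input(paste0(path, ": line ", which(widths < 2L)[1],
                      " has fewer than 2 fields."))
  }
  reg <- vapply(cells, `[[`, character(1), 1L)
  tgt <- vapply(cells, `[[`, character(1), 2L)
  w <- vapply(cells, function(x) {
    if (length(x) >= 3L) suppressWarnings(as.numeric(x[3])) else NA_real_
  }, numeric(1))
  df <- tibble(regulator = reg, target = tgt)
  if (!all(is.na(w))) df$weight <- w
  df <- df[df$regulator != df$target, , drop = FALSE]
  new_grn_network(df, union(df$regulator, df$target))
}

#' Read a transcription-factor list (one identifier per line)
#'
#' @param path file path.
#' @return Character vector of identifiers.
#' @export
read_tf_list <- function(path) {
  if (!file.exists(path)) stop_usage(paste0("File not found: ", path))
  out <- trimws(readLines(path, warn = FALSE))
  out <- out[nzchar(out)]
  if (length(out) == 0L) stop_input(paste0(path, ": empty TF list."))
  out
}

#' Write / read a run manifest
#'
#' The manifest records the fully-merged control record (including the
#' seed) plus input/output paths as structured key/value text, so a score
#' matrix can be reproduced bit-for-bit from the manifest alone.
#'
#' @param control a [grn_control()] record.
#' @param paths named list of file paths involved in the run.
#' @param path manifest file path.
#' @return `write_manifest()` returns `path` invisibly; `read_manifest()`
#'   returns a list with elements `control` (a `"grn_control"`) and
#'   `paths`.
#' @export
write_manifest <- function(control, paths, path) {
  yaml::write_yaml(list(tool = "splsnet",
                        version = as.character(utils::packageVersion("splsnet")),
                        control = unclass(control), paths = paths), path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_usage(paste0("File not found: ", path))
  raw <- yaml::read_yaml(path)
  list(control = do.call(grn_control, raw$control), paths = raw$paths)
}
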