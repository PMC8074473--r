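#' Construct an expression time-series object
#'
#' Bundles an `N`-by-`(T+1)` matrix of node values at equidistant time
#' points with the node names and, optionally, the column indices at which
#' independent experiments start.  Time series measured in several
#' experiments are commonly concatenated into one matrix; declaring the
#' experiment boundaries lets downstream lag-1 regression tasks drop the
#' lag pairs that would straddle two experiments.
#'
#' @param values Numeric matrix, rows = nodes (genes), columns = time
#'   points.  Row names are used as node names; unnamed rows are labelled
#'   `Z1, Z2, ...`.
#' @param boundaries Integer vector of column indices (strictly increasing,
#'   each in `2..ncol`) where a new independent experiment starts.  Empty by
#'   default (one uninterrupted series).
#'
#' @return An object of class `nhdbn_data`: a list with elements `values`,
#'   `node_names` and `boundaries`.
#' @examples
#' x <- matrix(rnorm(5 * 10), 5, 10, dimnames = list(paste0("G", 1:5), NULL))
#' d <- expression_data(x, boundaries = 6)
#' d
#' @export
expression_data <- function(values, boundaries = integer()) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("expression values must be numeric", call. = FALSE)
  }
  if (anyNA(values)) {
    stop("expression values must not contain missing values", call. = FALSE)
  }
  if (ncol(values) < 3L) {
    stop("need at least 3 time points (T+1 >= 3)", call. = FALSE)
  }
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("Z", seq_len(nrow(values)))
  }
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1L]
    stop("duplicate node name: ", dup, call. = FALSE)
  }
  boundaries <- as.integer(boundaries)
  if (length(boundaries)) {
    if (is.unsorted(boundaries, strictly = TRUE) ||
        any(boundaries < 2L) || any(boundaries > ncol(values))) {
      stop("boundaries must be strictly increasing column indices in 2..T+1",
           call. = FALSE)
    }
  }
  structure(
    list(values = values, node_names = rownames(values),
         boundaries = boundaries),
    class = "nhdbn_data"
  )
}

#' @export
print.nhdbn_data <- function(x, ...) {
  cat(sprintf("<nhdbn_data> %d nodes x %d time points\n",
              nrow(x$values), ncol(x$values)))
  cat("  nodes:", paste(head(x$node_names, 8L), collapse = ", "),
      if (length(x$node_names) > 8L) "..." else "", "\n")
  if (length(x$boundaries)) {
    cat("  experiment starts at columns:",
        paste(x$boundaries, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.nhdbn_data <- function(x) dim(x$values)

#' @importFrom tibble as_tibble
#' @export
as_tibble.nhdbn_data <- function(x, ...) {
  tibble::tibble(
    node = rep(x$node_names, times = ncol(x$values)),
    time = rep(seq_len(ncol(x$values)), each = nrow(x$values)),
    value = as.vector(x$values)
  )
}

#' Read an expression matrix from a TSV/CSV file
#'
#' Expected layout: one row per gene, first column the gene name, remaining
#' columns the time points.  A leading comment line of the form
#' `#boundaries: c1,c2` declares columns where independent experiments
#' start (counted among the time-point columns).  The field separator is
#' taken from the file extension (`.csv` = comma, otherwise tab).
#'
#' @param path Path to the file.
#' @param sep Field separator; defaults to `","` for `.csv` files and
#'   `"\t"` otherwise.
#' @return An [expression_data()] object.
#' @export
read_expression_matrix <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  lines <- readLines(path)
  boundaries <- integer()
  bnd <- grep("^#boundaries:", lines)
  if (length(bnd)) {
    spec <- sub("^#boundaries:\\s*", "", lines[bnd[1L]])
    boundaries <- as.integer(strsplit(spec, ",")[[1L]])
    if (anyNA(boundaries)) {
      stop("malformed #boundaries header in ", path, call. = FALSE)
    }
  }
  lines <- lines[!grepl("^#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, sep, fixed = TRUE)
  nf <- lengths(fields)
  if (length(unique(nf)) != 1L) {
    stop("ragged rows in ", path, ": rows have ",
         paste(unique(nf), collapse = ", "), " fields", call. = FALSE)
  }
  # tolerate an optional header row of non-numeric column labels
  first_vals <- suppressWarnings(as.numeric(fields[[1L]][-1L]))
  if (length(fields) > 1L && anyNA(first_vals)) {
    fields <- fields[-1L]
  }
  names_col <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(names_col)) {
    stop("duplicate gene name in ", path, ": ",
         names_col[duplicated(names_col)][1L], call. = FALSE)
  }
  vals <- t(vapply(fields, function(f) {
    v <- suppressWarnings(as.numeric(f[-1L]))
    if (anyNA(v)) {
      stop("non-numeric cell in row '", f[[1L]], "'", call. = FALSE)
    }
    v
  }, numeric(length(fields[[1L]]) - 1L)))
  rownames(vals) <- names_col
  expression_data(vals, boundaries = boundaries)
}

#' Write an expression matrix to a TSV/CSV file
#'
#' Inverse of [read_expression_matrix()]; experiment boundaries are stored
#' in a `#boundaries:` comment line.
#'
#' @param x An [expression_data()] object.
#' @param path Output path; `.csv` selects comma separation.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "nhdbn_data"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  con <- file(path, "w")
  on.exit(close(con))
  if (length(x$boundaries)) {
    writeLines(paste0("#boundaries: ", paste(x$boundaries, collapse = ",")),
               con)
  }
  writeLines(
    vapply(seq_len(nrow(x$values)), function(i) {
      paste(c(x$node_names[i],
              format(x$values[i, ], digits = 17, trim = TRUE)),
            collapse = sep)
    }, character(1)),
    con
  )
  invisible(path)
}
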