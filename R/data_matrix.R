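#' Two-group data matrix
#'
#' Container for an n x p numeric matrix \code{X} of \code{n} samples
#' (rows) on \code{p} continuous variables (columns), together with a
#' binary group-label vector \code{Y} with values in \{1, 2\}. This is the
#' universe over which variables are selected; \code{n} may be much
#' smaller than \code{p}.
#'
#' Arbitrary two-valued label vectors are accepted and mapped to \{1, 2\}
#' by the sorted order of the distinct values; the mapping is stored in
#' the \code{label_map} attribute.
#'
#' @param X numeric matrix, samples in rows.
#' @param Y vector of group labels with exactly two distinct values, each
#'   occurring at least twice (required downstream by leave-one-out
#'   cross-validation with LDA).
#' @param variable_names character vector of p unique variable names;
#'   defaults to column names or \code{V1..Vp}.
#' @param sample_ids character vector of n sample identifiers; defaults to
#'   row names or \code{S1..Sn}.
#' @param informative optional integer vector of ground-truth informative
#'   column indices (recorded by the synthetic generator).
#' @return an object of class \code{"data_matrix"} with elements \code{X},
#'   \code{Y}, \code{variable_names}, \code{sample_ids} and attributes
#'   \code{label_map} and (optionally) \code{informative}.
#' @export
data_matrix <- function(X, Y, variable_names = NULL, sample_ids = NULL,
                        informative = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  p <- ncol(X)
  if (n < 4L)
    stop("at least 4 samples are required, got ", n)
  if (p < 1L)
    stop("at least 1 variable is required")
  if (anyNA(X)) {
    bad <- which(is.na(X), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at row %d, column %d; missing values are not imputed",
                 bad[1L], bad[2L]))
  }
  if (length(Y) != n)
    stop("length of Y (", length(Y), ") does not match number of samples (", n, ")")
  lev <- sort(unique(as.character(Y)))
  if (length(lev) != 2L)
    stop("Y must contain exactly two distinct labels, got ",
         length(lev), ": ", paste(lev, collapse = ", "))
  y <- match(as.character(Y), lev)
  if (min(tabulate(y, 2L)) < 2L)
    stop("each of the two groups must contain at least two samples")
  if (is.null(variable_names)) {
    variable_names <- colnames(X)
    if (is.null(variable_names)) variable_names <- paste0("V", seq_len(p))
  }
  if (anyDuplicated(variable_names))
    stop("variable names must be unique")
  if (is.null(sample_ids)) {
    sample_ids <- rownames(X)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  }
  dimnames(X) <- list(sample_ids, variable_names)
  out <- list(X = X, Y = as.integer(y),
              variable_names = as.character(variable_names),
              sample_ids = as.character(sample_ids))
  attr(out, "label_map") <- stats::setNames(1:2, lev)
  if (!is.null(informative)) attr(out, "informative") <- as.integer(informative)
  class(out) <- "data_matrix"
  out
}

#' @export
print.data_matrix <- function(x, ...) {
  cat(sprintf("data_matrix: %d samples x %d variables, groups %d/%d\n",
              nrow(x$X), ncol(x$X), sum(x$Y == 1L), sum(x$Y == 2L)))
  lm <- attr(x, "label_map")
  cat("  label mapping:", paste(sprintf("%s -> %d", names(lm), lm), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.data_matrix <- function(x) dim(x$X)

#' Read a delimited data matrix with group labels
#'
#' Reads a header-bearing CSV/TSV file into a [data_matrix]. Labels come
#' either from a named column of the file or from a one-column companion
#' file with one label per sample. Samples are expected in rows; set
#' \code{samples_in_rows = FALSE} for files with variables in rows and
#' samples in columns (labels must then come from a companion file).
#'
#' Any cell that does not parse as a number is a hard error naming its row
#' and column; missing values are likewise rejected, never imputed.
#'
#' @param path path of the delimited file.
#' @param label_spec name of the label column in the file, or path of a
#'   companion file holding one label per sample.
#' @param delimiter field separator, default \code{","}.
#' @param samples_in_rows logical; \code{TRUE} (default) when rows are
#'   samples.
#' @return a [data_matrix].
#' @export
read_matrix <- function(path, label_spec, delimiter = ",",
                        samples_in_rows = TRUE) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", row.names = NULL)
  labels <- NULL
  if (samples_in_rows && label_spec %in% names(df)) {
    labels <- df[[label_spec]]
    df <- df[setdiff(names(df), label_spec)]
  } else if (file.exists(label_spec)) {
    labels <- utils::read.table(label_spec, header = FALSE,
                                stringsAsFactors = FALSE)[[1L]]
  } else {
    stop("label_spec '", label_spec,
         "' is neither a column of the input file nor an existing file")
  }
  first_col_names <- !samples_in_rows ||
    anyNA(suppressWarnings(as.numeric(df[[1L]])))
  row_ids <- NULL
  if (first_col_names && ncol(df) > 1L &&
      anyNA(suppressWarnings(as.numeric(df[[1L]])))) {
    row_ids <- df[[1L]]
    df <- df[-1L]
  }
  M <- matrix(suppressWarnings(as.numeric(as.matrix(df))),
              nrow = nrow(df), dimnames = list(row_ids, names(df)))
  if (anyNA(M)) {
    bad <- which(is.na(M), arr.ind = TRUE)[1L, ]
    stop(sprintf("unparseable or missing value at row %d, column %d of %s",
                 bad[1L], bad[2L], path))
  }
  if (!samples_in_rows) M <- t(M)
  dm <- data_matrix(M, labels)
  lm <- attr(dm, "label_map")
  message(sprintf("read_matrix: %d samples x %d variables from %s; labels %s",
                  nrow(dm$X), ncol(dm$X), path,
                  paste(sprintf("'%s' -> %d", names(lm), lm), collapse = ", ")))
  dm
}

#' Write a selection or cross-validation report
#'
#' Writes a [mrmr_forward] selection result (one row per selected
#' variable: rank, name, relevance, redundancy, score) or a
#' [gamma_search] report (one row per gamma: gamma, sensitivity,
#' specificity, accuracy) to disk. The \code{"tabular"} format is a TSV
#' with header; \code{"structured"} is nestable key-value JSON carrying
#' full diagnostics.
#'
#' @param result a \code{selection_result} or \code{cv_report}.
#' @param path output file path; the parent directory must exist.
#' @param format \code{"tabular"} (TSV) or \code{"structured"} (JSON).
#' @export
write_report <- function(result, path, format = c("tabular", "structured")) {
  format <- match.arg(format)
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  tab <- report_table(result)
  if (format == "tabular") {
    txt <- tab
    num <- vapply(txt, is.numeric, logical(1L))
    txt[num] <- lapply(txt[num], function(v) sprintf("%.15g", v))
    utils::write.table(txt, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(unclass(result), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
  }
  invisible(path)
}

report_table <- function(result) {
  if (inherits(result, "selection_result")) {
    data.frame(rank = seq_along(result$selected),
               variable = result$variable_names[result$selected],
               index = result$selected,
               relevance = result$steps$relevance,
               redundancy = result$steps$redundancy,
               score = result$steps$score)
  } else if (inherits(result, "cv_report")) {
    result$per_gamma[c("gamma", "sensitivity", "specificity", "accuracy")]
  } else {
    stop("write_report expects a selection_result or cv_report")
  }
}
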