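# Plain-text readers/writers for every interchange format: expression and
# signature matrices as TSV (genes in rows), Ct tables as CSV, labelled
# square matrices and long-format tables as CSV, embeddings as TSV. Parsing
# is strict: ragged rows, non-numeric cells and duplicate genes are rejected
# with the offending line number. CRLF and LF files parse identically.

.read_text_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- sub("\r$", "", readLines(path))
  while (length(lines) && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) < 2L) stop("file '", path, "' has no data rows")
  lines
}

# Numeric matrix, first column = gene names, header = c(<id>, colnames).
.read_numeric_table <- function(path, sep) {
  lines <- .read_text_lines(path)
  header <- strsplit(lines[[1]], sep, fixed = TRUE)[[1]]
  ncols <- length(header)
  if (ncols < 2L) stop(path, ": header must name at least one data column")
  n <- length(lines) - 1L
  genes <- character(n)
  values <- matrix(NA_real_, n, ncols - 1L)
  for (i in seq_len(n)) {
    f <- strsplit(lines[[i + 1L]], sep, fixed = TRUE)[[1]]
    if (length(f) != ncols) {
      stop(path, ": ragged row at line ", i + 1L, " (", length(f),
           " fields, expected ", ncols, ")")
    }
    num <- suppressWarnings(as.numeric(f[-1L]))
    if (anyNA(num)) {
      stop(path, ": non-numeric cell at line ", i + 1L)
    }
    genes[i] <- f[1L]
    values[i, ] <- num
  }
  dup <- which(duplicated(genes))
  if (length(dup)) {
    stop(path, ": duplicate gene '", genes[dup[1]], "' at line ", dup[1] + 1L)
  }
  dimnames(values) <- list(genes, header[-1L])
  values
}

.write_numeric_table <- function(values, path, sep, id = "gene") {
  lines <- c(paste(c(id, colnames(values)), collapse = sep),
             vapply(seq_len(nrow(values)), function(i) {
               paste(c(rownames(values)[i],
                       format(values[i, ], digits = 15, trim = TRUE,
                              scientific = FALSE)),
                     collapse = sep)
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' Expects genes in rows and a header row of sample names; the first column
#' holds gene names.
#'
#' @param path File path.
#' @param reference_samples,test_samples Character vectors assigning every
#'   sample column to a condition.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, reference_samples, test_samples) {
  values <- .read_numeric_table(path, "\t")
  samples <- colnames(values)
  assigned <- c(reference_samples, test_samples)
  if (!setequal(assigned, samples) || anyDuplicated(assigned)) {
    stop(path, ": reference/test assignment must cover each sample once")
  }
  condition <- stats::setNames(
    ifelse(samples %in% reference_samples, "reference", "test"), samples)
  expression_matrix(values, condition)
}

#' Write an expression matrix as TSV
#'
#' @param mat An [expression_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path) {
  stopifnot(inherits(mat, "expression_matrix"))
  .write_numeric_table(mat$values, path, "\t")
}

#' Read a signature collection from TSV
#'
#' Expects genes in rows and population names in the header; the stored
#' orientation (populations x genes) is transposed on read.
#'
#' @param path File path.
#' @return A [signature_set()].
#' @export
read_signature_set <- function(path) {
  signature_set(t(.read_numeric_table(path, "\t")))
}

#' Write a signature collection as TSV (genes in rows)
#'
#' @param sig A [signature_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature_set <- function(sig, path) {
  stopifnot(inherits(sig, "signature_set"))
  .write_numeric_table(t(sig$values), path, "\t")
}

#' Read a qPCR Ct table from CSV
#'
#' @param path CSV with columns `gene`, `group`, `animal`, `replicate`, `ct`.
#' @return Validated data frame.
#' @export
read_ct_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_ct_table(tab)
  tab
}

#' Write a qPCR Ct table as CSV
#'
#' @param table Ct data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(table, path) {
  .check_ct_table(table)
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a labelled square matrix (distance or correlation) as CSV
#'
#' @param m Labelled square numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labelled_matrix <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  .write_numeric_table(m, path, ",", id = "label")
}

#' Read a labelled square matrix from CSV
#'
#' @param path File path.
#' @return Labelled numeric matrix.
#' @export
read_labelled_matrix <- function(path) {
  .read_numeric_table(path, ",")
}

#' Long-format (heatmap-ready) export of a labelled matrix
#'
#' @param m Labelled square numeric matrix.
#' @return Data frame with columns `row`, `col`, `value`.
#' @export
matrix_long_format <- function(m) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  data.frame(row = rep(rownames(m), times = ncol(m)),
             col = rep(colnames(m), each = nrow(m)),
             value = as.vector(m),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read a differential-expression table written by the pipeline
#'
#' @param path TSV with the [deg_table()] columns.
#' @return Data frame.
#' @export
read_deg_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "log2fc", "fold", "p", "q")
  if (!all(need %in% names(tab))) {
    stop(path, ": expected columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(tab$gene)) stop(path, ": duplicate gene names")
  tab
}
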