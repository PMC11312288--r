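#' Construct an expression matrix with a two-group design
#'
#' Container for log2-scale expression values, genes in rows and samples in
#' columns, together with the sample-to-condition assignment used by the
#' differential-expression functions.
#'
#' @param values Numeric matrix (genes x samples) of log2 expression values,
#'   with gene row names and sample column names. All entries must be finite.
#' @param condition Named character vector mapping every sample name to
#'   `"reference"` or `"test"`. Each condition needs at least two samples.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values` (the matrix) and `condition` (a factor with levels
#'   `reference`, `test`, named by sample).
#' @examples
#' v <- matrix(rnorm(8), 2, 4,
#'   dimnames = list(c("Spp1", "Itgax"), c("WT_1", "WT_2", "KO_1", "KO_2")))
#' em <- expression_matrix(v, c(WT_1 = "reference", WT_2 = "reference",
#'                              KO_1 = "test", KO_2 = "test"))
#' @export
expression_matrix <- function(values, condition) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' must have gene row names and sample column names")
  }
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1L]
    stop("duplicate gene name: ", dup)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample names")
  }
  if (!all(is.finite(values))) {
    stop("expression values must all be finite")
  }
  if (is.null(names(condition)) ||
      !setequal(names(condition), colnames(values))) {
    stop("'condition' must be named by exactly the sample names")
  }
  condition <- condition[colnames(values)]
  if (!all(condition %in% c("reference", "test"))) {
    stop("condition values must be 'reference' or 'test'")
  }
  cond <- factor(as.character(condition), levels = c("reference", "test"))
  names(cond) <- colnames(values)
  if (any(table(cond) < 2L)) {
    stop("each condition needs at least 2 samples")
  }
  structure(list(values = values, condition = cond),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%d reference, %d test)\n",
              nrow(x$values), ncol(x$values),
              sum(x$condition == "reference"), sum(x$condition == "test")))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)
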