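# Population signature comparison: n expression profiles with n' gene
# attributes are compared through a Euclidean distance matrix D and an
# absolute-cosine cross-correlation matrix C, embedded by classical
# (Torgerson) multidimensional scaling, and clustered by average linkage.

#' Construct a signature set
#'
#' @param values Numeric matrix, populations in rows and gene attributes in
#'   columns, with unique row and column names and no missing values. At
#'   least two populations are required.
#' @return An object of class `signature_set` (list with element `values`).
#' @export
signature_set <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix (populations x genes)")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' must carry population row names and gene column names")
  }
  if (nrow(values) < 2L) stop("a signature set needs at least 2 populations")
  if (ncol(values) < 1L) stop("a signature set needs at least 1 gene")
  if (anyDuplicated(rownames(values))) stop("duplicate population names")
  if (anyDuplicated(colnames(values))) stop("duplicate gene names")
  if (!all(is.finite(values))) stop("signature values must all be finite")
  structure(list(values = values), class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("signature_set: %d populations x %d genes\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Build a population signature vector from a DE table
#'
#' The signature attribute for each panel gene is its log2 fold change versus
#' the study's own control, taken from a differential-expression table.
#'
#' @param deg Data frame with columns `gene` and `log2fc` ([deg_table()]).
#' @param panel Ordered character vector of gene names; every panel gene must
#'   be present in `deg`.
#' @return Named numeric vector of log2 fold changes, in panel order.
#' @export
build_signature <- function(deg, panel) {
  stopifnot(is.data.frame(deg), all(c("gene", "log2fc") %in% names(deg)),
            is.character(panel), length(panel) >= 1)
  missing <- setdiff(panel, deg$gene)
  if (length(missing)) {
    stop("panel genes absent from the DE table: ",
         paste(missing, collapse = ", "))
  }
  stats::setNames(deg$log2fc[match(panel, deg$gene)], panel)
}

#' Merge signature collections onto their common gene panel
#'
#' Gene symbols are matched case-insensitively; the merged panel is their
#' intersection in deterministic (case-folded alphabetical) order, displayed
#' with the first collection's casing. Populations are concatenated in input
#' order; name collisions across collections are disambiguated with
#' [make.unique()] (reported via a message).
#'
#' @param sets List of two or more [signature_set()] objects.
#' @return A merged `signature_set` restricted to the common panel.
#' @export
align_gene_panels <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2,
            all(vapply(sets, inherits, logical(1), "signature_set")))
  keys <- lapply(sets, function(s) tolower(colnames(s$values)))
  for (i in seq_along(keys)) {
    if (anyDuplicated(keys[[i]])) {
      stop("collection ", i, " has gene symbols that collide after ",
           "case-folding: ",
           paste(unique(keys[[i]][duplicated(keys[[i]])]), collapse = ", "))
    }
  }
  common <- Reduce(intersect, keys)
  if (!length(common)) stop("no genes shared across the signature collections")
  common <- sort(common)
  display <- colnames(sets[[1]]$values)[match(common, keys[[1]])]
  vals <- do.call(rbind, lapply(seq_along(sets), function(i) {
    sets[[i]]$values[, match(common, keys[[i]]), drop = FALSE]
  }))
  pops <- unlist(lapply(sets, function(s) rownames(s$values)))
  if (anyDuplicated(pops)) {
    message("duplicate population names across collections; suffixing with ",
            "make.unique()")
    pops <- make.unique(pops)
  }
  dimnames(vals) <- list(pops, display)
  signature_set(vals)
}

#' Euclidean distance matrix between population signatures
#'
#' Entry (i, j) is sqrt(sum_k (i_k - j_k)^2); the closer two populations,
#' the more similar their expression profiles.
#'
#' @param sig A [signature_set()].
#' @return Symmetric numeric matrix with zero diagonal, labelled by
#'   population.
#' @export
distance_matrix <- function(sig) {
  stopifnot(inherits(sig, "signature_set"))
  d <- as.matrix(stats::dist(sig$values, method = "euclidean"))
  dimnames(d) <- list(rownames(sig$values), rownames(sig$values))
  d
}

#' Absolute-cosine cross-correlation matrix
#'
#' Entry (i, j) is |i . j| / (||i|| ||j||), the magnitude of the cosine of
#' the angle between the two signature vectors: 0 means no relationship,
#' 1 means the profiles are equivalent up to scale. The modulus makes
#' anti-correlated profiles score as similar; set `signed = TRUE` for the
#' signed cosine as a sensitivity analysis.
#'
#' @param sig A [signature_set()]. Zero-magnitude population vectors are an
#'   error (no angle is defined for them).
#' @param signed Keep the cosine's sign (default `FALSE`, the modulus form).
#' @return Symmetric matrix with unit diagonal; entries in \[0, 1\]
#'   (or \[-1, 1\] when `signed`).
#' @export
correlation_matrix <- function(sig, signed = FALSE) {
  stopifnot(inherits(sig, "signature_set"))
  norms <- sqrt(rowSums(sig$values^2))
  if (any(norms == 0)) {
    stop("zero-magnitude signature vector(s): ",
         paste(rownames(sig$values)[norms == 0], collapse = ", "))
  }
  C <- tcrossprod(sig$values / norms)
  if (!signed) C <- abs(C)
  # clamp floating-point fuzz, then pin the diagonal
  C <- pmin(pmax(C, if (signed) -1 else 0), 1)
  diag(C) <- 1
  dimnames(C) <- list(rownames(sig$values), rownames(sig$values))
  C
}

.check_distance_matrix <- function(d, tol = 1e-8) {
  if (!is.matrix(d) || !is.numeric(d) || nrow(d) != ncol(d)) {
    stop("'d' must be a square numeric matrix")
  }
  if (is.null(rownames(d))) stop("'d' must be labelled")
  if (max(abs(d - t(d))) > tol) stop("'d' must be symmetric")
  if (max(abs(diag(d))) > tol) stop("'d' must have a zero diagonal")
  if (min(d) < -tol) stop("'d' must be non-negative")
  invisible(d)
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centres -d^2/2, eigendecomposes, and takes coordinates from the top
#' k non-negative eigenvalues. Eigenvector sign ambiguity is resolved by
#' forcing the largest-magnitude entry of each axis positive, so embeddings
#' are reproducible. Stress is sqrt(sum (d - dhat)^2 / sum d^2) over the
#' reconstructed pairwise distances dhat.
#'
#' @param d Labelled symmetric distance matrix (e.g. [distance_matrix()]).
#' @param k Embedding dimension, 1 <= k <= n - 1.
#' @return An object of class `mds_embedding`: list with `labels`,
#'   `coordinates` (n x k), `eigenvalues` (the k leading values,
#'   non-increasing) and `stress`.
#' @export
classical_mds <- function(d, k = 2) {
  .check_distance_matrix(d)
  n <- nrow(d)
  if (k < 1 || k > n - 1) stop("'k' must lie in 1..(n - 1)")
  J <- diag(n) - 1 / n
  B <- -0.5 * J %*% (d^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  lam <- e$values[seq_len(k)]
  X <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(lam, 0)), k, k)
  for (j in seq_len(k)) {
    i0 <- which.max(abs(X[, j]))
    if (X[i0, j] < 0) X[, j] <- -X[, j]
  }
  rownames(X) <- rownames(d)
  colnames(X) <- paste0("dim", seq_len(k))
  dhat <- as.matrix(stats::dist(X))
  denom <- sum(d^2)
  stress <- if (denom > 0) sqrt(sum((d - dhat)^2) / denom) else 0
  structure(list(labels = rownames(d), coordinates = X,
                 eigenvalues = lam, stress = stress),
            class = "mds_embedding")
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat(sprintf("mds_embedding: %d points in %d dimension(s), stress %.3g\n",
              length(x$labels), ncol(x$coordinates), x$stress))
  invisible(x)
}

#' Average-linkage hierarchical clustering of populations
#'
#' Agglomerates on the given distance matrix with average linkage. Labels are
#' sorted lexicographically before clustering so that merge order does not
#' depend on the input ordering (a deterministic tie-break).
#'
#' @param d Labelled symmetric distance matrix with at least two populations.
#' @return A standard [stats::hclust] object (merge order, heights, leaf
#'   order).
#' @export
hierarchical_cluster <- function(d) {
  .check_distance_matrix(d)
  if (nrow(d) < 2L) stop("clustering needs at least 2 populations")
  ord <- order(rownames(d))
  stats::hclust(stats::as.dist(d[ord, ord]), method = "average")
}

#' Export a dendrogram as Newick
#'
#' @param hc An [stats::hclust] object (e.g. from [hierarchical_cluster()]).
#' @param path Optional file path; when given the tree is written there.
#' @return The Newick string, invisibly when `path` is given.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  stopifnot(inherits(hc, "hclust"))
  phy <- ape::as.phylo(hc)
  if (is.null(path)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = path)
    invisible(ape::write.tree(phy))
  }
}
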