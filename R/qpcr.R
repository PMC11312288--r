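# Relative quantification by the comparative Ct method: technical replicates
# are averaged, each target is normalised to a reference gene (delta-Ct),
# referenced to the calibrator group's mean (delta-delta-Ct), and converted
# to a linear fold change as 2^-ddCt under perfect doubling efficiency.

.check_ct_table <- function(tab) {
  need <- c("gene", "group", "animal", "replicate", "ct")
  stopifnot(is.data.frame(tab))
  if (!all(need %in% names(tab))) {
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  }
  if (!is.numeric(tab$ct) || !all(is.finite(tab$ct))) {
    stop("Ct values must be finite numbers")
  }
  invisible(tab)
}

#' Average technical replicates
#'
#' Collapses a long Ct table to one arithmetic-mean Ct per (gene, group,
#' animal). Every animal must have been assayed for every gene.
#'
#' @param table Data frame with columns `gene`, `group`, `animal`,
#'   `replicate`, `ct` (e.g. from [simulate_qpcr_plate()] or
#'   [read_ct_table()]).
#' @return Data frame with columns `gene`, `group`, `animal`, `ct`.
#' @export
collapse_replicates <- function(table) {
  .check_ct_table(table)
  out <- stats::aggregate(ct ~ gene + group + animal, data = table,
                          FUN = mean)
  genes <- unique(table$gene)
  animals <- unique(table$animal)
  counts <- table(out$animal)[animals]
  if (any(counts != length(genes))) {
    bad <- animals[which(counts != length(genes))[1]]
    miss <- setdiff(genes, out$gene[out$animal == bad])
    stop("animal '", bad, "' is missing gene(s): ",
         paste(miss, collapse = ", "))
  }
  out[order(out$gene, out$group, out$animal), , drop = FALSE]
}

# Two-sided two-sample t with a convention for (numerically) constant input,
# as in the zero-noise limit: equal means give p = 1, unequal means the
# p = 0 limit.
.two_group_p <- function(x, y, var_equal = TRUE) {
  flat <- function() if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
  if (stats::var(x) == 0 && stats::var(y) == 0) return(flat())
  tryCatch(stats::t.test(x, y, var.equal = var_equal)$p.value,
           error = function(e) flat())
}

#' Delta-delta-Ct relative expression
#'
#' For every gene: per-animal delta-Ct = Ct_gene - Ct_reference;
#' delta-delta-Ct = delta-Ct - mean(delta-Ct over the calibrator group); the
#' reported fold change is 2^-mean(ddCt) over the non-calibrator group
#' (perfect doubling efficiency assumed). Significance is an unpaired
#' two-sided Student t-test on the per-animal delta-Ct values.
#'
#' @param mean_ct Per-animal mean Ct table from [collapse_replicates()].
#' @param reference_gene Name of the normalisation gene; must be present for
#'   every animal.
#' @param calibrator_group Group whose mean delta-Ct is the baseline
#'   (default `"WT"`). Exactly two groups are expected.
#' @return An object of class `relative_expression`: list with `results`
#'   (data frame: `gene`, `fold_change`, `log2_fold_change`, `p`,
#'   `n_calibrator`, `n_test`), `dct` (per-animal delta-Ct long table),
#'   `reference_gene` and `calibrator_group`. The calibrator group's
#'   geometric-mean fold is 1 by construction; the reference gene reports
#'   fold 1 exactly.
#' @export
ddct_fold_change <- function(mean_ct, reference_gene,
                             calibrator_group = "WT") {
  stopifnot(is.data.frame(mean_ct),
            all(c("gene", "group", "animal", "ct") %in% names(mean_ct)))
  groups <- unique(mean_ct$group)
  if (!calibrator_group %in% groups) {
    stop("calibrator group '", calibrator_group, "' has no animals")
  }
  if (length(groups) != 2L) {
    stop("expected exactly 2 groups, found: ", paste(groups, collapse = ", "))
  }
  test_group <- setdiff(groups, calibrator_group)
  ref <- mean_ct[mean_ct$gene == reference_gene, , drop = FALSE]
  if (!nrow(ref)) stop("reference gene '", reference_gene, "' not in table")
  animals <- unique(mean_ct$animal)
  if (!all(animals %in% ref$animal)) {
    stop("reference gene missing for animal(s): ",
         paste(setdiff(animals, ref$animal), collapse = ", "))
  }
  ref_ct <- stats::setNames(ref$ct, ref$animal)
  dct <- mean_ct
  dct$dct <- dct$ct - ref_ct[dct$animal]
  genes <- unique(mean_ct$gene)
  rows <- lapply(genes, function(g) {
    gd <- dct[dct$gene == g, , drop = FALSE]
    cal <- gd$dct[gd$group == calibrator_group]
    tst <- gd$dct[gd$group == test_group]
    ddct_test <- mean(tst) - mean(cal)
    data.frame(gene = g, fold_change = 2^(-ddct_test),
               log2_fold_change = -ddct_test,
               p = .two_group_p(tst, cal),
               n_calibrator = length(cal), n_test = length(tst),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  structure(list(results = do.call(rbind, rows),
                 dct = dct[, c("gene", "group", "animal", "dct")],
                 reference_gene = reference_gene,
                 calibrator_group = calibrator_group),
            class = "relative_expression")
}

#' @export
print.relative_expression <- function(x, ...) {
  cat(sprintf("relative_expression: %d gene(s), calibrator %s, reference %s\n",
              nrow(x$results), x$calibrator_group, x$reference_gene))
  print(x$results, ...)
  invisible(x)
}
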