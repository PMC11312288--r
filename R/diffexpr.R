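# Two-group differential expression: per-gene tests, BH adjustment, the
# q < 0.05 & |fold| > 1.5 significance filter, and the signed ranking metric
# that feeds gene-set enrichment.

#' Per-gene two-sample t-test
#'
#' Vectorised Welch (default) or pooled-variance t-test of test vs reference
#' for every gene. The statistic's sign equals the sign of
#' (test mean - reference mean). Genes with zero variance in both groups get
#' p = 1 when the group means are equal; when the means differ the statistic
#' is infinite and p = 0, and a message reports how many genes hit this
#' degenerate limit.
#'
#' @param mat An [expression_matrix()].
#' @param pooled Use the pooled-variance (classic Student) test instead of
#'   Welch's unequal-variance test.
#' @return A data frame with columns `gene`, `statistic`, `df`, `p`.
#' @examples
#' em <- simulate_expression_study(study_sim_config(100, seed = 1))
#' head(welch_t_per_gene(em))
#' @export
welch_t_per_gene <- function(mat, pooled = FALSE) {
  stopifnot(inherits(mat, "expression_matrix"))
  ref <- mat$values[, mat$condition == "reference", drop = FALSE]
  tst <- mat$values[, mat$condition == "test", drop = FALSE]
  n1 <- ncol(ref); n2 <- ncol(tst)
  m1 <- rowMeans(ref); m2 <- rowMeans(tst)
  v1 <- rowSums((ref - m1)^2) / (n1 - 1)
  v2 <- rowSums((tst - m2)^2) / (n2 - 1)
  if (pooled) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  diff <- m2 - m1
  statistic <- diff / se
  p <- 2 * stats::pt(-abs(statistic), df)
  zero_se <- se == 0
  if (any(zero_se)) {
    flat <- zero_se & diff == 0
    statistic[flat] <- 0
    p[flat] <- 1
    df[zero_se] <- NA_real_
    blown <- zero_se & diff != 0
    if (any(blown)) {
      statistic[blown] <- sign(diff[blown]) * Inf
      p[blown] <- 0
      message(sum(blown), " gene(s) with zero within-group variance and ",
              "unequal means: p set to the 0 limit")
    }
  }
  data.frame(gene = rownames(mat$values), statistic = statistic, df = df,
             p = p, row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values Numeric vector of p-values in \[0, 1\] (no missing values).
#' @return q-values of the same length, capped at 1, monotone non-decreasing
#'   in p-rank.
#' @examples
#' bh_adjust(c(0.005, 0.02, 0.03, 0.05))
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1)) {
    stop("p-values must be numeric, non-missing, and within [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

.signed_fold <- function(log2fc) {
  ifelse(log2fc >= 0, 2^log2fc, -(2^(-log2fc)))
}

#' Per-gene differential-expression table
#'
#' Fits the two-group comparison for every gene, adjusts p-values by
#' Benjamini-Hochberg, and applies the significance filter
#' (q < `q_threshold` and |signed fold| > `fc_threshold`, both strict).
#' The default engine is limma's moderated t (lmFit/eBayes), which borrows
#' variance information across genes — essential for power at three samples
#' per condition. `"welch"` and `"pooled"` select the per-gene tests of
#' [welch_t_per_gene()].
#'
#' The signed linear fold convention is `2^log2fc` for log2fc >= 0 and
#' `-2^(-log2fc)` otherwise, so a "fold change > 1.5" filter reads
#' |fold| > 1.5.
#'
#' @param mat An [expression_matrix()].
#' @param method `"moderated"` (default), `"welch"`, or `"pooled"`.
#' @param q_threshold,fc_threshold Strict thresholds for the significance
#'   filter (defaults 0.05 and 1.5).
#' @return A data frame (one row per gene) with columns `gene`, `log2fc`,
#'   `fold` (signed linear), `p`, `q`, `significant`, `direction`
#'   (`up`/`down`/`none`).
#' @examples
#' em <- simulate_expression_study(
#'   study_sim_config(200, planted_up = c(Spp1 = 600), seed = 1))
#' deg <- deg_table(em)
#' deg[deg$gene == "Spp1", ]
#' @export
deg_table <- function(mat, method = c("moderated", "welch", "pooled"),
                      q_threshold = 0.05, fc_threshold = 1.5) {
  stopifnot(inherits(mat, "expression_matrix"))
  method <- match.arg(method)
  if (method == "moderated") {
    design <- cbind(Intercept = 1, test = as.integer(mat$condition == "test"))
    fit <- limma::eBayes(limma::lmFit(mat$values, design))
    tab <- data.frame(gene = rownames(mat$values),
                      log2fc = unname(fit$coefficients[, "test"]),
                      p = unname(fit$p.value[, "test"]),
                      row.names = NULL, stringsAsFactors = FALSE)
  } else {
    tt <- welch_t_per_gene(mat, pooled = method == "pooled")
    ref <- rowMeans(mat$values[, mat$condition == "reference", drop = FALSE])
    tst <- rowMeans(mat$values[, mat$condition == "test", drop = FALSE])
    tab <- data.frame(gene = tt$gene, log2fc = tst - ref, p = tt$p,
                      row.names = NULL, stringsAsFactors = FALSE)
  }
  tab$fold <- .signed_fold(tab$log2fc)
  tab$q <- bh_adjust(tab$p)
  tab <- tab[, c("gene", "log2fc", "fold", "p", "q")]
  apply_deg_filter(tab, q_threshold, fc_threshold)$table
}

#' Apply the significance filter and summarise call counts
#'
#' Flags genes with q < `q_threshold` and |signed fold| > `fc_threshold`
#' (both inequalities strict) and assigns the call direction by the sign of
#' the fold.
#'
#' @param table A data frame with at least columns `gene`, `fold`, `q` (as
#'   produced by [deg_table()]).
#' @param q_threshold,fc_threshold Strict thresholds (defaults 0.05, 1.5).
#' @return A list with `table` (input plus `significant` and `direction`
#'   columns) and `summary` (list with `n_total`, `n_up`, `n_down`).
#' @export
apply_deg_filter <- function(table, q_threshold = 0.05, fc_threshold = 1.5) {
  stopifnot(is.data.frame(table),
            all(c("gene", "fold", "q") %in% names(table)),
            q_threshold > 0, fc_threshold > 0)
  sig <- table$q < q_threshold & abs(table$fold) > fc_threshold
  direction <- rep("none", nrow(table))
  direction[sig & table$fold > 0] <- "up"
  direction[sig & table$fold < 0] <- "down"
  table$significant <- sig
  table$direction <- direction
  list(table = table,
       summary = list(n_total = sum(sig),
                      n_up = sum(direction == "up"),
                      n_down = sum(direction == "down")))
}

#' Signed ranking metric for pre-ranked enrichment
#'
#' Scores each gene as sign(log2fc) * -log10(p), sorts in decreasing score
#' order, and breaks ties deterministically by gene name. Zero p-values are
#' clipped to `max_score` (reported via a message).
#'
#' @param table A data frame with columns `gene`, `log2fc`, `p`.
#' @param max_score Clip for -log10(p) when p underflows (default 300).
#' @return A data frame with columns `gene`, `score`, ordered by decreasing
#'   score.
#' @export
rank_metric <- function(table, max_score = 300) {
  stopifnot(is.data.frame(table),
            all(c("gene", "log2fc", "p") %in% names(table)),
            max_score > 0)
  nl <- -log10(table$p)
  clipped <- !is.finite(nl) | nl > max_score
  if (any(clipped)) {
    nl[clipped] <- max_score
    message(sum(clipped), " gene(s) with p ~ 0: score clipped to ", max_score)
  }
  score <- sign(table$log2fc) * nl
  ord <- order(-score, table$gene)
  data.frame(gene = table$gene[ord], score = score[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}
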