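# Pre-ranked gene-set enrichment: weighted running-sum enrichment score with
# a gene-set permutation null, sign-matched normalisation (NES), and a
# magnitude-based permutation p-value.

.check_ranked <- function(ranked) {
  stopifnot(is.data.frame(ranked),
            all(c("gene", "score") %in% names(ranked)))
  if (anyDuplicated(ranked$gene)) stop("ranked list has duplicate genes")
  if (anyNA(ranked$score) || !all(is.finite(ranked$score))) {
    stop("ranking scores must be finite")
  }
  invisible(ranked)
}

# Enrichment score from sorted hit positions only. The running sum moves
# linearly between hits, so its extrema occur at hit positions or just before
# them; this is what makes the permutation null cheap.
.es_from_hits <- function(idx, w, N) {
  Nh <- length(idx)
  Nm <- N - Nh
  if (Nm == 0L) return(0)
  s <- sum(w)
  w <- if (s > 0) w / s else rep(1 / Nh, Nh)
  cw <- cumsum(w)
  miss <- (idx - seq_len(Nh)) / Nm
  cand <- c(cw - miss, c(0, cw[-Nh]) - miss)
  cand[which.max(abs(cand))]
}

#' Weighted running-sum enrichment score
#'
#' Walks down the ranked list; at a gene in the set the sum increases by that
#' gene's |score|^`weight_exponent` (normalised so hit increments total 1),
#' at other genes it decreases by 1/(N - N_hit). The enrichment score is the
#' signed extremum of the walk. With `weight_exponent = 0` the walk is the
#' classic unweighted Kolmogorov-Smirnov-like statistic and ends at zero.
#'
#' When the set covers the whole ranked list the complement is empty and the
#' score is defined as 0.
#'
#' @param ranked Data frame with columns `gene`, `score`, already in ranking
#'   order (as from [rank_metric()]).
#' @param genes Character vector: the gene set. Must share at least one gene
#'   with the ranked list.
#' @param weight_exponent Exponent on |score| for hit increments (default 1;
#'   0 gives the unweighted walk).
#' @return A list with `es` (signed extremum) and `running_sum` (length-N
#'   numeric vector).
#' @export
enrichment_score <- function(ranked, genes, weight_exponent = 1) {
  .check_ranked(ranked)
  stopifnot(is.character(genes), length(genes) >= 1)
  hit <- ranked$gene %in% genes
  N <- nrow(ranked)
  Nh <- sum(hit)
  if (Nh == 0L) {
    stop("gene set shares no genes with the ranked list")
  }
  if (Nh == N) {
    return(list(es = 0, running_sum = numeric(N)))
  }
  w <- abs(ranked$score[hit])^weight_exponent
  s <- sum(w)
  incr <- if (s > 0) w / s else rep(1 / Nh, Nh)
  step <- rep(-1 / (N - Nh), N)
  step[hit] <- incr
  rs <- cumsum(step)
  list(es = rs[which.max(abs(rs))], running_sum = rs)
}

#' Permutation-normalised enrichment of one gene set
#'
#' Builds the null by resampling random gene sets of the same size from the
#' ranked universe. The normalised enrichment score (NES) divides the
#' observed score by the mean |null score| of matching sign; the permutation
#' p-value is two-sided on magnitude,
#' p = (1 + #\{|null es| >= |es|\}) / (1 + n_permutations), so its smallest
#' attainable value is 1/(n_permutations + 1). If fewer than 5 null draws
#' share the observed sign the NES is flagged unstable via a warning (and
#' `low_null = TRUE`).
#'
#' @param ranked Data frame with columns `gene`, `score` in ranking order.
#' @param genes Character vector: the gene set.
#' @param n_permutations Number of null draws (>= 10; default 999).
#' @param seed Integer seed; results are reproducible.
#' @param weight_exponent Passed to [enrichment_score()].
#' @param set_name Label carried into the result (default `"set"`).
#' @return A one-row data frame: `set_name`, `size` (genes in both set and
#'   universe), `es`, `nes`, `p_perm`, `n_permutations`, `seed`, `low_null`.
#' @export
permutation_nes <- function(ranked, genes, n_permutations = 999, seed = 1,
                            weight_exponent = 1, set_name = "set") {
  .check_ranked(ranked)
  if (n_permutations < 10) stop("'n_permutations' must be at least 10")
  obs <- enrichment_score(ranked, genes, weight_exponent)$es
  N <- nrow(ranked)
  Nh <- sum(ranked$gene %in% genes)
  scores <- abs(ranked$score)^weight_exponent
  null <- with_seed(substream_seed(seed, "permutation_nes"), {
    vapply(seq_len(n_permutations), function(b) {
      idx <- sort(sample.int(N, Nh))
      .es_from_hits(idx, scores[idx], N)
    }, numeric(1))
  })
  same <- null[sign(null) == sign(obs)]
  low_null <- length(same) < 5L
  if (obs == 0) {
    nes <- 0
  } else if (length(same) == 0L || mean(abs(same)) == 0) {
    nes <- NA_real_
  } else {
    nes <- obs / mean(abs(same))
  }
  if (low_null) {
    warning("fewer than 5 same-sign null enrichment scores; NES is unstable")
  }
  p_perm <- (1 + sum(abs(null) >= abs(obs))) / (1 + n_permutations)
  data.frame(set_name = set_name, size = Nh, es = obs, nes = nes,
             p_perm = p_perm, n_permutations = as.integer(n_permutations),
             seed = as.integer(seed), low_null = low_null,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Enrichment of a gene-set collection
#'
#' Runs [permutation_nes()] for every set in a collection and adds a
#' Benjamini-Hochberg q-value over the permutation p-values.
#'
#' @param ranked Data frame with columns `gene`, `score` in ranking order.
#' @param genesets Named list of character vectors (e.g. from [read_gmt()]).
#' @param ... Passed to [permutation_nes()].
#' @return Data frame with one row per set, ordered as given, plus column `q`.
#' @export
enrich_collection <- function(ranked, genesets, ...) {
  stopifnot(is.list(genesets), length(genesets) >= 1,
            !is.null(names(genesets)))
  res <- lapply(names(genesets), function(nm) {
    permutation_nes(ranked, genesets[[nm]], set_name = nm, ...)
  })
  res <- do.call(rbind, res)
  res$q <- bh_adjust(res$p_perm)
  res
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#'
#' @param path File path.
#' @return Named list of character gene vectors; descriptions are kept in
#'   attribute `description`.
#' @export
read_gmt <- function(path) {
  lines <- sub("\r$", "", readLines(path))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  sets <- list()
  desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stop("GMT line ", i, ": expected name, description and >= 1 gene")
    }
    genes <- f[-(1:2)]
    if (anyDuplicated(genes)) {
      stop("GMT line ", i, " (set '", f[1], "'): duplicate gene ",
           genes[duplicated(genes)][1])
    }
    if (f[1] %in% names(sets)) stop("GMT line ", i, ": duplicate set name ", f[1])
    sets[[f[1]]] <- genes
    desc[f[1]] <- f[2]
  }
  attr(sets, "description") <- desc
  sets
}

#' Write a GMT gene-set file
#'
#' @param genesets Named list of character gene vectors.
#' @param path Output file path.
#' @param descriptions Optional character vector of per-set descriptions
#'   (recycled `"na"` if missing).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(genesets, path, descriptions = NULL) {
  stopifnot(is.list(genesets), !is.null(names(genesets)))
  if (is.null(descriptions)) descriptions <- rep("na", length(genesets))
  lines <- vapply(seq_along(genesets), function(i) {
    paste(c(names(genesets)[i], descriptions[i], genesets[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
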