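# Synthetic-data generators. These emulate the study design the pipeline is
# built for: a two-condition (wild-type vs knockout) log2-intensity microarray
# study with a handful of strongly overexpressed microglial genes, a
# collection of microglial population signatures with planted block
# correlation, and comparative-Ct qPCR plates run in technical triplicate.

.check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x)) {
    stop("'", name, "' must be a single integer >= ", min)
  }
  as.integer(x)
}

.check_folds <- function(x, name, lower, upper) {
  if (is.null(x)) return(numeric(0))
  if (!is.numeric(x) || is.null(names(x)) || any(names(x) == "")) {
    stop("'", name, "' must be a named numeric vector of linear fold changes")
  }
  if (!all(is.finite(x)) || any(x <= lower) || any(x >= upper)) {
    stop("'", name, "' fold changes must lie in (", lower, ", ", upper, ")")
  }
  x
}

#' Configuration for a simulated two-condition expression study
#'
#' Defaults mirror the emulated design: three samples per condition (each
#' standing for a pool of biological replicates), additive Gaussian noise on
#' the log2 scale, and planted linear fold changes for named genes.
#'
#' @param n_genes Number of genes on the array.
#' @param n_samples_per_condition Samples per condition (default 3).
#' @param planted_up Named numeric vector of linear fold changes > 1; names
#'   become gene symbols in the output (e.g. `c(Spp1 = 600)`).
#' @param planted_down Named numeric vector of linear fold changes in (0, 1).
#' @param baseline_log2_mean Mean of per-gene baseline log2 intensities.
#' @param baseline_log2_sd Spread of per-gene baselines (default 1.5).
#' @param noise_sd_log2 Residual noise standard deviation on the log2 scale;
#'   zero is allowed for exact-limit checks.
#' @param seed Integer seed; generation is reproducible given the config.
#' @return An object of class `study_sim_config`.
#' @export
study_sim_config <- function(n_genes, n_samples_per_condition = 3,
                             planted_up = NULL, planted_down = NULL,
                             baseline_log2_mean = 7, baseline_log2_sd = 1.5,
                             noise_sd_log2 = 0.25, seed = 1) {
  n_genes <- .check_count(n_genes, "n_genes")
  n_samples_per_condition <- .check_count(n_samples_per_condition,
                                          "n_samples_per_condition", min = 2L)
  up <- .check_folds(planted_up, "planted_up", 1, Inf)
  down <- .check_folds(planted_down, "planted_down", 0, 1)
  roles <- c(names(up), names(down))
  if (anyDuplicated(roles)) {
    stop("planted gene roles must be unique: ",
         paste(unique(roles[duplicated(roles)]), collapse = ", "))
  }
  if (length(roles) > n_genes) {
    stop("more planted genes (", length(roles), ") than n_genes (", n_genes, ")")
  }
  if (!is.finite(noise_sd_log2) || noise_sd_log2 < 0) {
    stop("'noise_sd_log2' must be >= 0")
  }
  if (!is.finite(baseline_log2_sd) || baseline_log2_sd < 0) {
    stop("'baseline_log2_sd' must be >= 0")
  }
  structure(list(n_genes = n_genes,
                 n_samples_per_condition = n_samples_per_condition,
                 planted_up = up, planted_down = down,
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 noise_sd_log2 = noise_sd_log2,
                 seed = as.integer(seed)),
            class = "study_sim_config")
}

#' Simulate a two-condition expression study
#'
#' Draws per-gene baseline log2 intensities, plants the configured log2 fold
#' changes into the test condition, and adds independent Gaussian noise. For a
#' planted linear fold f the expected (test - reference) log2 difference is
#' exactly log2(f); non-planted genes have expected difference zero.
#'
#' @param cfg A [study_sim_config()].
#' @return An [expression_matrix()] with samples `WT_1..` (reference) and
#'   `KO_1..` (test). The true planted log2 effects are attached as attribute
#'   `planted_log2fc` (a named vector) for benchmarking.
#' @export
simulate_expression_study <- function(cfg) {
  stopifnot(inherits(cfg, "study_sim_config"))
  n <- cfg$n_samples_per_condition
  genes <- sprintf("g%05d", seq_len(cfg$n_genes))
  planted <- c(cfg$planted_up, cfg$planted_down)
  values <- with_seed(substream_seed(cfg$seed, "expression_study"), {
    pos <- if (length(planted)) sample.int(cfg$n_genes, length(planted)) else integer(0)
    genes[pos] <- names(planted)
    delta <- numeric(cfg$n_genes)
    delta[pos] <- log2(planted)
    baseline <- stats::rnorm(cfg$n_genes, cfg$baseline_log2_mean,
                             cfg$baseline_log2_sd)
    noise <- matrix(stats::rnorm(cfg$n_genes * 2L * n, 0, cfg$noise_sd_log2),
                    cfg$n_genes, 2L * n)
    baseline + outer(delta, c(rep(0, n), rep(1, n))) + noise
  })
  samples <- c(paste0("WT_", seq_len(n)), paste0("KO_", seq_len(n)))
  dimnames(values) <- list(genes, samples)
  condition <- stats::setNames(rep(c("reference", "test"), each = n), samples)
  em <- expression_matrix(values, condition)
  truth <- log2(planted)
  attr(em, "planted_log2fc") <- truth
  em
}

#' Configuration for a simulated signature collection
#'
#' Populations are organised in blocks (e.g. neurodevelopment-associated vs
#' disease-associated microglial subtypes). Block structure is realised by
#' mixing exactly orthonormal shared, block-level and population-level
#' component vectors so that, before measurement noise, the expected cosine is
#' `within_block_cosine` inside a block and `between_block_cosine` across
#' blocks.
#'
#' @param blocks Named list: block name -> character vector of population
#'   names. Population names must be unique across blocks.
#' @param n_genes Number of gene attributes per signature.
#' @param within_block_cosine Target cosine inside a block, in (0, 1].
#' @param between_block_cosine Target cosine across blocks, in [0, 1);
#'   must be strictly smaller than `within_block_cosine`.
#' @param noise_sd Per-gene Gaussian measurement noise (signature entries are
#'   generated with unit per-gene scale).
#' @param genes Optional character vector of gene names (length `n_genes`);
#'   defaults to synthetic symbols.
#' @param seed Integer seed.
#' @return An object of class `signature_sim_config`.
#' @export
signature_sim_config <- function(blocks, n_genes = 500,
                                 within_block_cosine = 0.9,
                                 between_block_cosine = 0.2,
                                 noise_sd = 0.1, genes = NULL, seed = 1) {
  if (!is.list(blocks) || is.null(names(blocks)) || !length(blocks)) {
    stop("'blocks' must be a named list of population name vectors")
  }
  pops <- unlist(blocks, use.names = FALSE)
  if (!length(pops) || anyDuplicated(pops)) {
    stop("population names must be non-empty and unique across blocks")
  }
  n_genes <- .check_count(n_genes, "n_genes")
  if (!(within_block_cosine > 0 && within_block_cosine <= 1)) {
    stop("'within_block_cosine' must be in (0, 1]")
  }
  if (!(between_block_cosine >= 0 && between_block_cosine < 1)) {
    stop("'between_block_cosine' must be in [0, 1)")
  }
  if (within_block_cosine <= between_block_cosine) {
    stop("'within_block_cosine' must exceed 'between_block_cosine'")
  }
  if (!is.finite(noise_sd) || noise_sd < 0) stop("'noise_sd' must be >= 0")
  need <- 1L + length(blocks) + length(pops)
  if (n_genes < need) {
    stop("n_genes must be at least ", need,
         " (one shared + one per block + one per population component)")
  }
  if (is.null(genes)) {
    genes <- sprintf("sg%05d", seq_len(n_genes))
  } else if (length(genes) != n_genes || anyDuplicated(genes)) {
    stop("'genes' must be ", n_genes, " unique names")
  }
  structure(list(blocks = blocks, n_genes = n_genes,
                 within_block_cosine = within_block_cosine,
                 between_block_cosine = between_block_cosine,
                 noise_sd = noise_sd, genes = genes,
                 seed = as.integer(seed)),
            class = "signature_sim_config")
}

#' Simulate a block-correlated signature collection
#'
#' @param cfg A [signature_sim_config()].
#' @return A [signature_set()] (populations x genes). The generating block of
#'   each population is attached as attribute `blocks` (named character
#'   vector) for benchmarking cluster recovery.
#' @export
simulate_signature_collection <- function(cfg) {
  stopifnot(inherits(cfg, "signature_sim_config"))
  pops <- unlist(cfg$blocks, use.names = FALSE)
  block_of <- rep(names(cfg$blocks), lengths(cfg$blocks))
  K <- length(cfg$blocks)
  P <- length(pops)
  a <- sqrt(cfg$between_block_cosine)
  b <- sqrt(cfg$within_block_cosine - cfg$between_block_cosine)
  cc <- sqrt(1 - cfg$within_block_cosine)
  values <- with_seed(substream_seed(cfg$seed, "signature_collection"), {
    # exactly orthonormal components: shared, per-block, per-population
    basis <- qr.Q(qr(matrix(stats::rnorm(cfg$n_genes * (1L + K + P)),
                            cfg$n_genes)))
    shared <- basis[, 1L]
    block_vec <- basis[, 1L + seq_len(K), drop = FALSE]
    pop_vec <- basis[, 1L + K + seq_len(P), drop = FALSE]
    v <- vapply(seq_len(P), function(p) {
      k <- match(block_of[p], names(cfg$blocks))
      a * shared + b * block_vec[, k] + cc * pop_vec[, p]
    }, numeric(cfg$n_genes))
    v <- t(v) * sqrt(cfg$n_genes)  # per-gene entries on an O(1) scale
    v + matrix(stats::rnorm(P * cfg$n_genes, 0, cfg$noise_sd), P, cfg$n_genes)
  })
  dimnames(values) <- list(pops, cfg$genes)
  sig <- signature_set(values)
  attr(sig, "blocks") <- stats::setNames(block_of, pops)
  sig
}

#' Configuration for a simulated qPCR plate
#'
#' @param genes Character vector of assayed genes, including the reference.
#' @param reference_gene Name of the normalisation gene (e.g. `"18S"`).
#' @param true_fold_changes Named numeric vector of planted linear fold
#'   changes (KO vs WT) for target genes; genes not listed get fold 1. The
#'   reference gene, if listed, must have fold 1.
#' @param n_animals_per_group Animals per group (default 6).
#' @param ct_noise_sd Technical noise on the Ct scale, in cycles; zero allowed.
#' @param n_technical_replicates Replicates per (gene, animal) (default 3).
#' @param animal_sd Per-animal global Ct shift (RNA loading), in cycles; it
#'   affects every gene of an animal equally and cancels in delta-Ct.
#' @param wt_target_ct Baseline WT Ct for target genes (default 25 cycles).
#' @param reference_ct Baseline Ct of the reference gene (default 10 cycles).
#' @param seed Integer seed.
#' @return An object of class `qpcr_sim_config`.
#' @export
qpcr_sim_config <- function(genes, reference_gene, true_fold_changes = NULL,
                            n_animals_per_group = 6, ct_noise_sd = 0.3,
                            n_technical_replicates = 3, animal_sd = 0.5,
                            wt_target_ct = 25, reference_ct = 10, seed = 1) {
  if (!is.character(genes) || !length(genes) || anyDuplicated(genes)) {
    stop("'genes' must be unique gene names")
  }
  if (!reference_gene %in% genes) {
    stop("reference gene '", reference_gene, "' must be among 'genes'")
  }
  folds <- .check_folds(true_fold_changes, "true_fold_changes", 0, Inf)
  if (!all(names(folds) %in% genes)) {
    stop("fold changes given for genes not on the plate: ",
         paste(setdiff(names(folds), genes), collapse = ", "))
  }
  if (reference_gene %in% names(folds) && folds[[reference_gene]] != 1) {
    stop("the reference gene must have fold change 1")
  }
  all_folds <- stats::setNames(rep(1, length(genes)), genes)
  all_folds[names(folds)] <- folds
  n_animals_per_group <- .check_count(n_animals_per_group,
                                      "n_animals_per_group", min = 2L)
  n_technical_replicates <- .check_count(n_technical_replicates,
                                         "n_technical_replicates")
  if (!is.finite(ct_noise_sd) || ct_noise_sd < 0) {
    stop("'ct_noise_sd' must be >= 0")
  }
  structure(list(genes = genes, reference_gene = reference_gene,
                 true_fold_changes = all_folds,
                 n_animals_per_group = n_animals_per_group,
                 ct_noise_sd = ct_noise_sd,
                 n_technical_replicates = n_technical_replicates,
                 animal_sd = animal_sd, wt_target_ct = wt_target_ct,
                 reference_ct = reference_ct, seed = as.integer(seed)),
            class = "qpcr_sim_config")
}

#' Simulate a qPCR Ct plate
#'
#' A planted linear fold f (KO vs WT) lowers the KO Ct of that gene by
#' log2(f) cycles, so the expected delta-delta-Ct is -log2(f) and the
#' comparative-Ct estimator recovers f. Per-animal loading shifts affect all
#' genes of an animal equally.
#'
#' @param cfg A [qpcr_sim_config()].
#' @return A data frame with columns `gene`, `group` (WT/KO), `animal`,
#'   `replicate`, `ct`; one row per technical replicate. All Ct values are
#'   checked to lie in (0, 40).
#' @export
simulate_qpcr_plate <- function(cfg) {
  stopifnot(inherits(cfg, "qpcr_sim_config"))
  groups <- c("WT", "KO")
  nA <- cfg$n_animals_per_group
  nR <- cfg$n_technical_replicates
  grid <- expand.grid(replicate = seq_len(nR), gene = cfg$genes,
                      animal_idx = seq_len(nA), group = groups,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  base <- ifelse(grid$gene == cfg$reference_gene, cfg$reference_ct,
                 cfg$wt_target_ct)
  shift <- ifelse(grid$group == "KO",
                  log2(cfg$true_fold_changes[grid$gene]), 0)
  animal <- paste0(grid$group, "_", grid$animal_idx)
  ct <- with_seed(substream_seed(cfg$seed, "qpcr_plate"), {
    eff <- stats::setNames(
      stats::rnorm(2L * nA, 0, cfg$animal_sd),
      paste0(rep(groups, each = nA), "_", rep(seq_len(nA), 2L)))
    base - shift + eff[animal] +
      stats::rnorm(nrow(grid), 0, cfg$ct_noise_sd)
  })
  if (!all(is.finite(ct)) || any(ct <= 0) || any(ct >= 40)) {
    stop("simulated Ct values fell outside (0, 40); ",
         "lower the noise or adjust the baseline cycles")
  }
  data.frame(gene = grid$gene, group = grid$group, animal = animal,
             replicate = grid$replicate, ct = as.numeric(ct),
             stringsAsFactors = FALSE)
}
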