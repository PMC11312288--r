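# Pipeline orchestration: a validated YAML configuration drives
# simulate -> differential expression -> enrichment -> signature comparison
# -> qPCR, writing plain-text artefacts and a JSON manifest with file hashes
# so that a rerun under the same seed is verifiably identical.

.schema <- list(
  top = c("schema_version", "seed", "stages", "de", "enrich", "compare",
          "qpcr", "simulate", "files"),
  stages = c("simulate", "de", "enrich", "compare", "qpcr"),
  de = c("reference_prefix", "test_prefix", "q_threshold", "fc_threshold",
         "method"),
  enrich = c("n_permutations", "weight_exponent"),
  compare = c("mds_k", "linkage", "n_clusters"),
  qpcr = c("reference_gene", "calibrator_group"),
  simulate = c("study", "signatures", "qpcr"),
  files = c("expression", "genesets", "signatures", "ct")
)

.check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    stop("unknown configuration key(s) in ", where, ": ",
         paste(unknown, collapse = ", "))
  }
  invisible(x)
}

#' Read and validate a pipeline configuration
#'
#' The configuration is YAML with a versioned schema (`schema_version: 1`).
#' Unknown keys anywhere are errors, not warnings.
#'
#' @param path Path to a YAML file.
#' @return Validated configuration list (class `analysis_config`).
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  validate_analysis_config(yaml::read_yaml(path))
}

#' Validate a pipeline configuration list
#'
#' @param cfg Configuration list (e.g. from [yaml::read_yaml()]).
#' @return The validated list, with defaults filled in.
#' @export
validate_analysis_config <- function(cfg) {
  stopifnot(is.list(cfg))
  .check_keys(cfg, .schema$top, "top level")
  if (is.null(cfg$schema_version) || cfg$schema_version != 1) {
    stop("config must declare schema_version: 1")
  }
  if (is.null(cfg$seed) || cfg$seed != round(cfg$seed)) {
    stop("config must declare an integer seed")
  }
  cfg$seed <- as.integer(cfg$seed)
  if (is.null(cfg$stages)) cfg$stages <- list()
  .check_keys(cfg$stages, .schema$stages, "stages")
  for (s in .schema$stages) {
    if (is.null(cfg$stages[[s]])) cfg$stages[[s]] <- FALSE
    stopifnot(is.logical(cfg$stages[[s]]))
  }
  for (sec in c("de", "enrich", "compare", "qpcr", "simulate", "files")) {
    if (!is.null(cfg[[sec]])) .check_keys(cfg[[sec]], .schema[[sec]], sec)
  }
  de_defaults <- list(reference_prefix = "WT", test_prefix = "KO",
                      q_threshold = 0.05, fc_threshold = 1.5,
                      method = "moderated")
  cfg$de <- utils::modifyList(de_defaults, as.list(cfg$de))
  if (cfg$de$q_threshold <= 0 || cfg$de$fc_threshold <= 0) {
    stop("DE thresholds must be positive")
  }
  cfg$enrich <- utils::modifyList(list(n_permutations = 999,
                                       weight_exponent = 1),
                                  as.list(cfg$enrich))
  cfg$compare <- utils::modifyList(list(mds_k = 2, linkage = "average",
                                        n_clusters = 2),
                                   as.list(cfg$compare))
  if (!identical(cfg$compare$linkage, "average")) {
    stop("only 'average' linkage is supported")
  }
  cfg$qpcr <- utils::modifyList(list(reference_gene = "18S",
                                     calibrator_group = "WT"),
                                as.list(cfg$qpcr))
  cfg$files <- utils::modifyList(list(expression = "expression.tsv",
                                      genesets = "genesets.gmt",
                                      signatures = "signatures.tsv",
                                      ct = "qpcr_ct.csv"),
                                 as.list(cfg$files))
  structure(cfg, class = c("analysis_config", "list"))
}

.resolve_path <- function(p, out_dir) {
  if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(out_dir, p)
}

.stage_fail <- function(stage, e) {
  stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
       call. = FALSE)
}

.run_stage <- function(stage, code) {
  tryCatch(code, error = function(e) .stage_fail(stage, e))
}

.sim_config_from_yaml <- function(section, constructor, seed) {
  args <- as.list(section)
  for (nm in c("planted_up", "planted_down", "true_fold_changes")) {
    if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
  }
  if (!is.null(args$blocks)) args$blocks <- lapply(args$blocks, unlist)
  if (!is.null(args$genes)) args$genes <- unlist(args$genes)
  if (is.null(args$seed)) args$seed <- seed
  do.call(constructor, args)
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in order: `simulate` (write fixtures),
#' `de` (differential expression), `enrich` (pre-ranked permutation
#' enrichment against the GMT collection), `compare` (distance and
#' cross-correlation matrices, MDS embedding, dendrogram), and `qpcr`
#' (delta-delta-Ct quantification). Each stage reads its inputs from files
#' under `out_dir` (or absolute paths in `files:`), so stages can also be run
#' against externally supplied data with `simulate` toggled off.
#'
#' A JSON manifest recording the package version, the configuration hash,
#' the seed and an MD5 hash of every output file is written to
#' `out_dir/manifest.json`; a rerun under the same configuration reproduces
#' identical hashes.
#'
#' @param config Path to a YAML config, or a configuration list.
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (is.character(config)) read_analysis_config(config)
         else validate_analysis_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  config_hash <- {
    tmp <- tempfile(fileext = ".yaml")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(yaml::as.yaml(unclass(cfg)), tmp)
    unname(tools::md5sum(tmp))
  }
  version <- as.character(utils::packageVersion("microsig"))
  message("microsig ", version, " | seed ", cfg$seed,
          " | config ", config_hash)
  manifest <- list(package = "microsig", version = version,
                   config_hash = config_hash, seed = cfg$seed,
                   stages = list())
  paths <- lapply(cfg$files, .resolve_path, out_dir = out_dir)

  add_stage <- function(name, files) {
    files <- unlist(files)
    manifest$stages[[name]] <<- list(
      files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                      basename(files))))
    message("stage ", name, ": ", length(files), " file(s)")
  }

  if (cfg$stages$simulate) {
    .run_stage("simulate", {
      if (is.null(cfg$simulate)) stop("no 'simulate' section in config")
      written <- character(0)
      if (!is.null(cfg$simulate$study)) {
        scfg <- .sim_config_from_yaml(cfg$simulate$study, study_sim_config,
                                      substream_seed(cfg$seed, "study"))
        em <- simulate_expression_study(scfg)
        write_expression_matrix(em, paths$expression)
        written <- c(written, paths$expression)
        # gene-set collection: the planted microglial set plus random decoys
        planted <- names(scfg$planted_up)
        sets <- list(MICROGLIAL_ACTIVATION = planted)
        decoys <- with_seed(substream_seed(cfg$seed, "genesets"), {
          lapply(1:3, function(i) sample(rownames(em$values), 50))
        })
        names(decoys) <- paste0("RANDOM_SET_", 1:3)
        write_gmt(c(sets, decoys), paths$genesets)
        written <- c(written, paths$genesets)
      }
      if (!is.null(cfg$simulate$signatures)) {
        gcfg <- .sim_config_from_yaml(cfg$simulate$signatures,
                                      signature_sim_config,
                                      substream_seed(cfg$seed, "signatures"))
        write_signature_set(simulate_signature_collection(gcfg),
                            paths$signatures)
        written <- c(written, paths$signatures)
      }
      if (!is.null(cfg$simulate$qpcr)) {
        qcfg <- .sim_config_from_yaml(cfg$simulate$qpcr, qpcr_sim_config,
                                      substream_seed(cfg$seed, "qpcr"))
        write_ct_table(simulate_qpcr_plate(qcfg), paths$ct)
        written <- c(written, paths$ct)
      }
      add_stage("simulate", written)
    })
  }

  deg_path <- file.path(out_dir, "deg_table.tsv")
  if (cfg$stages$de) {
    .run_stage("de", {
      samples <- colnames(.read_numeric_table(paths$expression, "\t"))
      em <- read_expression_matrix(
        paths$expression,
        reference_samples = samples[startsWith(samples,
                                               cfg$de$reference_prefix)],
        test_samples = samples[startsWith(samples, cfg$de$test_prefix)])
      deg <- deg_table(em, method = cfg$de$method,
                       q_threshold = cfg$de$q_threshold,
                       fc_threshold = cfg$de$fc_threshold)
      filt <- apply_deg_filter(deg, cfg$de$q_threshold, cfg$de$fc_threshold)
      utils::write.table(deg, deg_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      summary_path <- file.path(out_dir, "de_summary.json")
      jsonlite::write_json(filt$summary, summary_path, auto_unbox = TRUE,
                           pretty = TRUE)
      add_stage("de", c(deg_path, summary_path))
    })
  }

  if (cfg$stages$enrich) {
    .run_stage("enrich", {
      deg <- read_deg_table(deg_path)
      ranked <- rank_metric(deg)
      sets <- read_gmt(paths$genesets)
      res <- enrich_collection(
        ranked, sets, n_permutations = cfg$enrich$n_permutations,
        weight_exponent = cfg$enrich$weight_exponent,
        seed = substream_seed(cfg$seed, "enrich"))
      enr_path <- file.path(out_dir, "enrichment.tsv")
      utils::write.table(res, enr_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      add_stage("enrich", enr_path)
    })
  }

  if (cfg$stages$compare) {
    .run_stage("compare", {
      sig <- read_signature_set(paths$signatures)
      d <- distance_matrix(sig)
      C <- correlation_matrix(sig)
      files <- c(distance = file.path(out_dir, "distance.csv"),
                 correlation = file.path(out_dir, "correlation.csv"),
                 long = file.path(out_dir, "correlation_long.csv"),
                 mds = file.path(out_dir, "mds.tsv"),
                 tree = file.path(out_dir, "dendrogram.nwk"),
                 clusters = file.path(out_dir, "clusters.csv"))
      write_labelled_matrix(d, files["distance"])
      write_labelled_matrix(C, files["correlation"])
      utils::write.table(matrix_long_format(C), files["long"], sep = ",",
                         quote = FALSE, row.names = FALSE)
      emb <- classical_mds(d, k = cfg$compare$mds_k)
      .write_numeric_table(emb$coordinates, files["mds"], "\t",
                           id = "population")
      hc <- hierarchical_cluster(d)
      dendrogram_newick(hc, files["tree"])
      cl <- stats::cutree(hc, k = cfg$compare$n_clusters)
      utils::write.table(
        data.frame(population = names(cl), cluster = unname(cl)),
        files["clusters"], sep = ",", quote = FALSE, row.names = FALSE)
      add_stage("compare", files)
    })
  }

  if (cfg$stages$qpcr) {
    .run_stage("qpcr", {
      ct <- read_ct_table(paths$ct)
      rel <- ddct_fold_change(collapse_replicates(ct),
                              reference_gene = cfg$qpcr$reference_gene,
                              calibrator_group = cfg$qpcr$calibrator_group)
      qp_path <- file.path(out_dir, "qpcr_results.tsv")
      utils::write.table(rel$results, qp_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      add_stage("qpcr", qp_path)
    })
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Path to the packaged demo configuration
#'
#' A complete five-stage configuration emulating the study design: a
#' 4000-gene two-condition array study with planted microglial genes (Spp1 at
#' fold 600), an eleven-population two-block signature collection, and a
#' qPCR plate with Spp1 planted at fold 535.
#'
#' @return File path of the YAML config shipped with the package.
#' @export
demo_config_path <- function() {
  system.file("extdata", "demo_config.yaml", package = "microsig",
              mustWork = TRUE)
}
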