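## Pipeline orchestration: each run_* function wraps one stage, reads its
## inputs from a validated run config, writes outputs plus a provenance
## JSON (config hash, derived seed, stage counts) into the output
## directory, and is idempotent for a fixed config + seed.

#' Run configuration
#'
#' Loads (or builds) the single configuration object all pipeline stages
#' share: file paths, preprocessing thresholds, embedder choice, network
#' settings, open-set and evaluation settings, and one global seed from
#' which every stage derives its own seed (hash of the stage name), so
#' stages are individually reproducible.
#'
#' @param path YAML config file.
#' @param overrides Named list of keys to override (CLI flags map here).
#' @return A `run_config` list.
#' @export
read_run_config <- function(path, overrides = list()) {
  cfg <- yaml::read_yaml(path)
  cfg <- utils::modifyList(cfg, overrides)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param ... Config fields (see the package vignette for the schema).
#' @export
run_config <- function(...) {
  validate_run_config(list(...))
}

validate_run_config <- function(cfg) {
  defaults <- list(
    output_dir = "methtransfer_run",
    seed = 1L,
    preprocess = list(detection_threshold = 0.01, probe_max_missing = 0.30,
                      sample_max_missing = 0.20, harmonize_max_missing = 0.30,
                      select_k = 10000),
    embedder = list(kind = "mock", d0 = 640, d = 128, flank = 25),
    network = list(),
    openset = list(tail_size = 20, distance = "euclidean",
                   activation = "softmax"),
    evaluation = list(k_folds = 5),
    simulate = list()
  )
  cfg <- utils::modifyList(defaults, cfg)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

stage_seed <- function(cfg, stage) derive_seed(cfg$seed, stage)

stage_path <- function(cfg, ...) file.path(cfg$output_dir, ...)

write_provenance <- function(cfg, stage, counts = list()) {
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_plain <- unclass(cfg)
  payload <- list(
    stage = stage,
    seed = stage_seed(cfg, stage),
    global_seed = cfg$seed,
    config_hash = stable_hash(paste(deparse(cfg_plain), collapse = "")),
    package_version = as.character(utils::packageVersion("methtransfer")),
    counts = counts,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(payload, stage_path(cfg, paste0(stage, ".provenance.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(payload)
}

require_artifact <- function(cfg, path, producer) {
  if (!file.exists(path)) {
    abort_mt(sprintf("Missing artifact '%s'; run %s first.", path, producer),
             "missing_artifact_error")
  }
  path
}

#' Pipeline stages
#'
#' Each stage reads the shared [run_config()], performs one step of the
#' workflow, writes its outputs under `output_dir`, and records a
#' provenance JSON. Stage seeds derive from the global seed and the stage
#' name.
#'
#' * `run_simulate()` — generate a synthetic source/target domain pair plus
#'   toy genome and manifest, written in the same TSV/FASTA formats the
#'   real pipeline reads.
#' * `run_preprocess()` — QC, missingness filters, source-domain probe
#'   selection, harmonization, zero-fill; writes processed matrices and a
#'   run manifest.
#' * `run_embed()` — extract flank windows, embed, PCA-reduce to the PPE.
#' * `run_pretrain()` — train the network on the fused source domain.
#' * `run_finetune()` — fine-tune the pretrained checkpoint on the target.
#' * `run_evaluate()` — stratified k-fold cross-validation on the target.
#' * `run_openmax_eval()` — leave-one-class-out unknown-masking protocol.
#' * `run_interpret()` — gradient attribution + probe-to-gene mapping.
#'
#' @param cfg A [run_config()].
#' @return Each stage returns its main result invisibly.
#' @name pipeline_stages
NULL

#' @rdname pipeline_stages
#' @export
run_simulate <- function(cfg) {
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- cfg$simulate
  seed <- stage_seed(cfg, "simulate")
  src_spec <- do.call(synthetic_cohort_spec, utils::modifyList(
    list(n_classes = 6, samples_per_class = 40, n_probes = 200,
         effect_size = 0.3, seed = seed),
    sim$source %||% list()
  ))
  tgt_spec <- do.call(synthetic_cohort_spec, utils::modifyList(
    list(n_classes = 3, samples_per_class = 20, n_probes = 200,
         effect_size = 0.18, seed = seed + 1L),
    sim$target %||% list()
  ))
  pair <- generate_domain_pair(src_spec, tgt_spec,
                               sim$shared_informative_fraction %||% 0.8)
  toy <- generate_toy_genome_and_manifest(src_spec$n_probes,
                                          chrom_length = sim$chrom_length %||% 20000,
                                          seed = seed)
  write_cohort(pair$source$cohort, stage_path(cfg, "source_beta.tsv"),
               stage_path(cfg, "source_labels.tsv"))
  write_cohort(pair$target$cohort, stage_path(cfg, "target_beta.tsv"),
               stage_path(cfg, "target_labels.tsv"))
  write_probe_manifest(toy$manifest, stage_path(cfg, "manifest.tsv"))
  Biostrings::writeXStringSet(toy$genome, stage_path(cfg, "reference.fasta"))
  readr::write_tsv(pair$target$planted, stage_path(cfg, "planted_probes.tsv"))
  write_provenance(cfg, "simulate", list(
    source = dim(pair$source$cohort), target = dim(pair$target$cohort)
  ))
  invisible(pair)
}

#' @rdname pipeline_stages
#' @export
run_preprocess <- function(cfg) {
  pp <- cfg$preprocess
  src <- read_beta_matrix(
    require_artifact(cfg, stage_path(cfg, "source_beta.tsv"), "run_simulate (or provide source_beta.tsv)"),
    stage_path(cfg, "source_labels.tsv"), domain_tag = "source"
  )
  tgt <- read_beta_matrix(
    require_artifact(cfg, stage_path(cfg, "target_beta.tsv"), "run_simulate (or provide target_beta.tsv)"),
    stage_path(cfg, "target_labels.tsv"), domain_tag = "target"
  )
  seed <- stage_seed(cfg, "preprocess")
  src_clean <- zero_fill(filter_samples_by_missingness(
    filter_probes_by_class_missingness(src, pp$probe_max_missing),
    pp$sample_max_missing
  ))
  sel <- select_top_variable_probes(src_clean, k = min(pp$select_k, ncol(src_clean$beta)),
                                    seed = seed)
  res <- preprocess_cohort(tgt, selected = sel,
                           detection_threshold = pp$detection_threshold,
                           probe_max_missing = pp$probe_max_missing,
                           sample_max_missing = pp$sample_max_missing,
                           harmonize_max_missing = pp$harmonize_max_missing)
  harmonized <- probe_ids(res$cohort)
  src_final <- subset_cohort(src_clean, probes = harmonized)
  write_cohort(res$cohort, stage_path(cfg, "target_processed.tsv"),
               stage_path(cfg, "target_processed_labels.tsv"))
  write_cohort(src_final, stage_path(cfg, "source_processed.tsv"),
               stage_path(cfg, "source_processed_labels.tsv"))
  jsonlite::write_json(res$manifest, stage_path(cfg, "preprocess_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  write_provenance(cfg, "preprocess", list(
    harmonized_probes = length(harmonized),
    target = dim(res$cohort), source = dim(src_final)
  ))
  invisible(res)
}

#' @rdname pipeline_stages
#' @export
run_embed <- function(cfg) {
  emb <- cfg$embedder
  manifest <- read_probe_manifest(
    require_artifact(cfg, stage_path(cfg, "manifest.tsv"), "run_simulate (or provide manifest.tsv)")
  )
  genome <- Biostrings::readDNAStringSet(
    require_artifact(cfg, stage_path(cfg, "reference.fasta"), "run_simulate (or provide reference.fasta)")
  )
  names(genome) <- sub("\\s.*$", "", names(genome))
  tgt <- read_beta_matrix(
    require_artifact(cfg, stage_path(cfg, "target_processed.tsv"), "run_preprocess")
  )
  manifest <- manifest[match(probe_ids(tgt), manifest$probe_id), ]
  seqs <- extract_probe_windows(genome, manifest, flank = emb$flank)
  embedder <- switch(emb$kind,
    mock = mock_hash_embedder(emb$d0, stage_seed(cfg, "embed")),
    abort_mt(sprintf("Unknown embedder kind '%s'.", emb$kind), "config_error")
  )
  raw <- embed_sequences(embedder, seqs)
  ppe <- reduce_embeddings(raw, d = emb$d)
  write_matrix_tsv(ppe$matrix, stage_path(cfg, "ppe.tsv"))
  write_provenance(cfg, "embed", list(
    probes = nrow(ppe$matrix), d0 = emb$d0, d = emb$d
  ))
  invisible(ppe)
}

network_cfg_from <- function(cfg, x, labels, stage) {
  args <- utils::modifyList(
    list(input_shape = dim(x)[2:3], num_classes = length(unique(labels)),
         seed = stage_seed(cfg, stage)),
    cfg$network %||% list()
  )
  do.call(network_config, args)
}

load_fused <- function(cfg, which) {
  beta_path <- require_artifact(cfg, stage_path(cfg, paste0(which, "_processed.tsv")),
                                "run_preprocess")
  cohort <- read_beta_matrix(beta_path,
                             stage_path(cfg, paste0(which, "_processed_labels.tsv")))
  ppe <- read_matrix_tsv(require_artifact(cfg, stage_path(cfg, "ppe.tsv"), "run_embed"))
  list(x = fuse_cohort(cohort, ppe), labels = unname(cohort$labels))
}

#' @rdname pipeline_stages
#' @export
run_pretrain <- function(cfg) {
  fused <- load_fused(cfg, "source")
  ncfg <- network_cfg_from(cfg, fused$x, fused$labels, "pretrain")
  model <- build_network(ncfg, sort(unique(fused$labels)))
  model <- train_network(model, fused$x, fused$labels, ncfg)
  saveRDS(model, stage_path(cfg, "pretrained.rds"))
  write_provenance(cfg, "pretrain", list(
    epochs = nrow(model$training_log),
    classes = ncfg$num_classes
  ))
  invisible(model)
}

#' @rdname pipeline_stages
#' @export
run_finetune <- function(cfg) {
  pre <- readRDS(require_artifact(cfg, stage_path(cfg, "pretrained.rds"),
                                  "run_pretrain"))
  fused <- load_fused(cfg, "target")
  ncfg <- network_cfg_from(cfg, fused$x, fused$labels, "finetune")
  model <- fine_tune(pre, fused$x, fused$labels, ncfg)
  saveRDS(model, stage_path(cfg, "finetuned.rds"))
  write_provenance(cfg, "finetune", list(
    epochs = nrow(model$training_log),
    freeze_blocks = ncfg$freeze_blocks
  ))
  invisible(model)
}

#' @rdname pipeline_stages
#' @export
run_evaluate <- function(cfg) {
  fused <- load_fused(cfg, "target")
  ncfg <- network_cfg_from(cfg, fused$x, fused$labels, "evaluate")
  pre <- if (file.exists(stage_path(cfg, "pretrained.rds"))) {
    readRDS(stage_path(cfg, "pretrained.rds"))
  } else {
    NULL
  }
  cv <- cross_validate(fused$x, fused$labels, ncfg,
                       k = cfg$evaluation$k_folds,
                       seed = stage_seed(cfg, "evaluate"), pretrained = pre)
  readr::write_tsv(tidy(cv), stage_path(cfg, "cv_fold_metrics.tsv"))
  jsonlite::write_json(as.list(glance(cv)), stage_path(cfg, "cv_metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(cv$pooled$confusion, stage_path(cfg, "cv_confusion.tsv"),
                     sep = "\t", quote = FALSE)
  write_provenance(cfg, "evaluate", list(
    weighted_mcc = cv$pooled$weighted_mcc, k = cv$k
  ))
  invisible(cv)
}

#' @rdname pipeline_stages
#' @export
run_openmax_eval <- function(cfg) {
  fused <- load_fused(cfg, "target")
  ncfg <- network_cfg_from(cfg, fused$x, fused$labels, "openmax_eval")
  pre <- if (file.exists(stage_path(cfg, "pretrained.rds"))) {
    readRDS(stage_path(cfg, "pretrained.rds"))
  } else {
    NULL
  }
  os <- cfg$openset
  classes <- sort(unique(fused$labels))
  results <- purrr::map_dfr(classes, function(cl) {
    res <- unknown_masking_protocol(fused$x, fused$labels, cl, ncfg,
                                    tail_size = os$tail_size,
                                    distance = os$distance,
                                    activation = os$activation,
                                    pretrained = pre)
    tibble::tibble(class_masked = cl,
                   detection_accuracy = res$detection_accuracy)
  })
  readr::write_tsv(results, stage_path(cfg, "unknown_masking.tsv"))
  write_provenance(cfg, "openmax_eval", list(
    mean_detection = mean(results$detection_accuracy)
  ))
  invisible(results)
}

#' @rdname pipeline_stages
#' @param target_class Class to attribute in `run_interpret()` (defaults to
#'   the first class).
#' @export
run_interpret <- function(cfg, target_class = NULL) {
  model <- readRDS(require_artifact(cfg, stage_path(cfg, "finetuned.rds"),
                                    "run_finetune"))
  fused <- load_fused(cfg, "target")
  manifest <- read_probe_manifest(
    require_artifact(cfg, stage_path(cfg, "manifest.tsv"), "run_simulate (or provide manifest.tsv)")
  )
  target_class <- target_class %||% model$class_names[1]
  attr <- attribute_class_probes(model, fused$x, fused$labels, target_class,
                                 probe_names = dimnames(fused$x)[[2]])
  write_saliency_table(attr, stage_path(cfg, "saliency.tsv"), manifest)
  genes <- map_top_probes_to_genes(attr, manifest,
                                   top_k = min(100, nrow(attr$saliency)))
  writeLines(genes, stage_path(cfg, "top_genes.txt"))
  write_provenance(cfg, "interpret", list(
    target_class = target_class, n_genes = length(genes)
  ))
  invisible(attr)
}
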