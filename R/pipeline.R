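## Pipeline orchestration: a serializable configuration, staged execution in
## dependency order (preprocess -> reference modules/fingerprints -> MDTM ->
## network -> integration), structured logging, and a run manifest with
## checksums so identical config + inputs + seed give identical outputs.

#' Pipeline configuration
#'
#' All stage parameters in one serializable object. Inputs are either file
#' paths (`expression`, `detection`, `samples`, `traits`, `reference_gmt`)
#' or `simulate = TRUE`, in which case the bundled study-like simulation
#' ([example_config()]) is generated under the pipeline seed.
#'
#' @param inputs named list of input file paths (may be empty when
#'   simulating).
#' @param simulate generate the synthetic dataset instead of reading files.
#' @param stages named logical list of stage toggles: preprocess,
#'   reference_modules, fingerprint, mdtm, network, integration.
#' @param floor,detection_threshold,det_alpha preprocessing parameters.
#' @param det_group_by grouping for DET selection: "stimulus" or "group".
#' @param cluster_k,module_min_size,module_t_min reference-module
#'   extraction parameters (`module_t_min = NULL` for the ceiling(S/3)
#'   default). `cluster_k = NULL` picks k adaptively as
#'   clamp(n_probes / 100, 5, 30), keeping the expected transcripts per
#'   cluster well above typical module sizes so that a coherent program
#'   attracts a single k-means center (see the vignette).
#' @param module_input reference-module extraction input: "all" detected
#'   probes (default) or "dets" for the Welch-ANOVA-selected subset (useful
#'   at genome scale).
#' @param network a [network_config()] (stored as a plain list when
#'   serialized).
#' @param collapse_by replicate collapsing for network/integration.
#' @param hub_threshold joint GS/MM cutoff for hub genes.
#' @param min_overlap annotation floor in percent.
#' @param seed integer seed behind every randomized step.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(inputs = list(), simulate = FALSE,
                            stages = list(preprocess = TRUE,
                                          reference_modules = TRUE,
                                          fingerprint = TRUE, mdtm = TRUE,
                                          network = TRUE, integration = TRUE),
                            floor = 10, detection_threshold = 0.01,
                            det_alpha = 0.05, det_group_by = "stimulus",
                            cluster_k = NULL, module_min_size = 10,
                            module_t_min = NULL, module_input = "all",
                            network = network_config(),
                            collapse_by = "stimulus",
                            hub_threshold = 0.80, min_overlap = 10,
                            seed = 1L) {
  cfg <- list(inputs = inputs, simulate = isTRUE(simulate),
              stages = stages, floor = floor,
              detection_threshold = detection_threshold,
              det_alpha = det_alpha, det_group_by = det_group_by,
              cluster_k = cluster_k, module_min_size = module_min_size,
              module_t_min = module_t_min, module_input = module_input,
              network = unclass(network), collapse_by = collapse_by,
              hub_threshold = hub_threshold, min_overlap = min_overlap,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Save / load a pipeline configuration as YAML
#'
#' `load_config(save_config(cfg))` reproduces the configuration.
#'
#' @param cfg a [pipeline_config()].
#' @param path YAML file path.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$network <- do.call(network_config, raw$network)
  do.call(pipeline_config, raw)
}

.config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

.log_line <- function(con, stage, level, message) {
  line <- sprintf("%s\t%s\t%s", stage, level, message)
  if (!is.null(con)) writeLines(line, con)
  invisible(line)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order and writes every stage's
#' tables plus a run manifest (`manifest.json`, written last) recording the
#' package version, configuration hash, seed, input and output checksums,
#' per-stage dimensions and accumulated warnings. A disabled prerequisite
#' aborts with a dependency error (e.g. integration requires the network
#' stage).
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  st <- cfg$stages
  need <- function(stage, dep) {
    if (isTRUE(st[[stage]]) && !isTRUE(st[[dep]])) {
      .fail("stage '%s' requires stage '%s' to be enabled", stage, dep)
    }
  }
  need("reference_modules", "preprocess"); need("mdtm", "preprocess")
  need("network", "preprocess"); need("fingerprint", "reference_modules")
  need("integration", "network")

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(out_dir, "pipeline.log"), open = "wt")
  on.exit(close(log_con), add = TRUE)
  manifest <- list(package = "stimprint",
                   version = as.character(utils::packageVersion("stimprint")),
                   seed = cfg$seed, config_hash = .config_hash(cfg),
                   inputs = list(), stages = list(), outputs = list(),
                   warnings = character())
  outputs <- character()
  note <- function(stage, msg) .log_line(log_con, stage, "info", msg)
  warn <- function(stage, msg) {
    manifest$warnings <<- c(manifest$warnings, sprintf("%s: %s", stage, msg))
    .log_line(log_con, stage, "warning", msg)
  }
  emit <- function(path) outputs <<- c(outputs, path)

  ## ---- inputs ----
  traits <- NULL
  if (cfg$simulate) {
    ds <- generate_dataset(example_config(seed = cfg$seed))
    paths <- write_dataset(ds, file.path(out_dir, "simulated"))
    for (p in paths) emit(p)
    expr <- ds$expression; traits <- ds$traits
    reference_sets <- NULL
    note("simulate", sprintf("generated %d probes x %d samples",
                             nrow(expr$intensities), ncol(expr$intensities)))
  } else {
    for (nm_in in names(cfg$inputs)) {
      manifest$inputs[[nm_in]] <- unname(tools::md5sum(cfg$inputs[[nm_in]]))
    }
    intens <- read_expression_tsv(cfg$inputs$expression)
    samples <- read_sample_csv(cfg$inputs$samples)
    det <- if (!is.null(cfg$inputs$detection)) read_expression_tsv(cfg$inputs$detection)
    expr <- expression_matrix(intens, samples, detection_p = det)
    if (!is.null(cfg$inputs$traits)) traits <- read_trait_csv(cfg$inputs$traits)
    reference_sets <- if (!is.null(cfg$inputs$reference_gmt)) read_gmt(cfg$inputs$reference_gmt)
  }

  ## ---- preprocess ----
  nm <- NULL; dets <- NULL
  if (isTRUE(st$preprocess)) {
    expr <- floor_intensities(expr, cfg$floor)
    expr <- withCallingHandlers(
      detection_filter(expr, cfg$detection_threshold),
      warning = function(w) { warn("preprocess", conditionMessage(w)); invokeRestart("muffleWarning") })
    nm <- normalize_to_medium(expr)
    dets <- select_dets(nm, nm$samples$stimulus, alpha = cfg$det_alpha)
    utils::write.table(dets, file.path(out_dir, "dets.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    emit(file.path(out_dir, "dets.tsv"))
    manifest$stages$preprocess <- list(probes = nrow(nm$ratios),
                                       samples = ncol(nm$ratios),
                                       dets_kept = sum(dets$kept))
    note("preprocess", sprintf("%d probes, %d kept as DETs", nrow(nm$ratios), sum(dets$kept)))
  }

  ## ---- reference modules ----
  ref_modules <- NULL
  if (isTRUE(st$reference_modules)) {
    nm_det <- nm
    if (identical(cfg$module_input, "dets")) {
      kept_ids <- dets$probe_id[dets$kept]
      if (length(kept_ids) >= cfg$module_min_size) {
        nm_det$ratios <- nm$ratios[kept_ids, , drop = FALSE]
      } else {
        warn("reference_modules", "too few DETs; clustering all probes")
      }
    }
    k <- cfg$cluster_k %||% max(5L, min(30L, nrow(nm_det$ratios) %/% 100L))
    parts <- cluster_per_stimulus(nm_det, k = max(2L, min(k, nrow(nm_det$ratios) - 1L)),
                                  seed = cfg$seed)
    cc <- cocluster_scores(parts)
    ref_modules <- extract_modules(cc, min_size = cfg$module_min_size,
                                   t_min = cfg$module_t_min)
    write_gmt(unclass(ref_modules), file.path(out_dir, "reference_modules.gmt"))
    emit(file.path(out_dir, "reference_modules.gmt"))
    manifest$stages$reference_modules <- list(modules = length(ref_modules),
                                              unassigned = length(attr(ref_modules, "unassigned")))
    note("reference_modules", sprintf("%d modules extracted", length(ref_modules)))
  }
  if (is.null(reference_sets)) reference_sets <- ref_modules

  ## ---- fingerprint ----
  if (isTRUE(st$fingerprint) && length(ref_modules %||% list())) {
    fp <- fingerprint(ref_modules, nm)
    utils::write.table(fp, file.path(out_dir, "fingerprints.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    emit(file.path(out_dir, "fingerprints.tsv"))
    manifest$stages$fingerprint <- list(rows = nrow(fp))
  }

  ## ---- mdtm ----
  if (isTRUE(st$mdtm)) {
    md <- mdtm_samples(nm, subset = if (!is.null(dets)) dets$probe_id[dets$kept])
    utils::write.table(md, file.path(out_dir, "mdtm.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    emit(file.path(out_dir, "mdtm.tsv"))
    manifest$stages$mdtm <- list(samples = nrow(md))
  }

  ## ---- network ----
  net <- NULL
  if (isTRUE(st$network)) {
    net_cfg <- do.call(network_config, cfg$network)
    net <- network_modules(nm, net_cfg, collapse_by = cfg$collapse_by)
    lab_df <- data.frame(transcript_id = names(net$labels),
                         module_label = unname(net$labels))
    utils::write.table(lab_df, file.path(out_dir, "network_labels.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    emit(file.path(out_dir, "network_labels.tsv"))
    if (!is.null(net$eigengenes)) {
      eg_df <- data.frame(condition = rownames(net$eigengenes),
                          unclass(net$eigengenes), check.names = FALSE)
      utils::write.table(eg_df, file.path(out_dir, "eigengenes.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      emit(file.path(out_dir, "eigengenes.tsv"))
    }
    n_mod <- length(setdiff(unique(net$labels), "unassigned"))
    manifest$stages$network <- list(modules = n_mod, power = net$power,
                                    transcripts = length(net$labels))
    note("network", sprintf("%d network modules at power %d", n_mod, net$power))
  }

  ## ---- integration ----
  if (isTRUE(st$integration)) {
    if (is.null(traits) || !nrow(traits)) {
      warn("integration", "no trait table; integration skipped")
    } else if (is.null(net$eigengenes)) {
      warn("integration", "no network modules survived; integration skipped")
    } else {
      tr <- collapse_replicates(traits, by = "stimulus")
      mt <- module_trait_correlation(net$eigengenes, tr)
      mt_df <- data.frame(module = rownames(mt$r)[row(mt$r)],
                          trait = colnames(mt$r)[col(mt$r)],
                          r = as.vector(mt$r), p = as.vector(mt$p))
      utils::write.table(mt_df, file.path(out_dir, "module_trait.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      emit(file.path(out_dir, "module_trait.tsv"))
      gs <- gene_significance(net$expr, tr)
      mm <- module_membership(net$expr, net$eigengenes)
      hubs <- do.call(rbind, lapply(colnames(gs), function(trt) {
        hub_genes(gs, mm, net$labels, trt, cfg$hub_threshold)
      }))
      utils::write.table(hubs, file.path(out_dir, "hub_genes.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      emit(file.path(out_dir, "hub_genes.tsv"))
      manifest$stages$integration <- list(traits = ncol(tr), hubs = nrow(hubs))
      if (!is.null(reference_sets)) {
        assigned <- setdiff(unique(net$labels), "unassigned")
        net_sets <- lapply(assigned, function(m) names(net$labels)[net$labels == m])
        names(net_sets) <- assigned
        if (length(net_sets) && length(reference_sets)) {
          ann <- annotate_by_overlap(net_sets, reference_sets, cfg$min_overlap)
          utils::write.table(ann$assignments, file.path(out_dir, "module_annotation.tsv"),
                             sep = "\t", row.names = FALSE, quote = FALSE)
          emit(file.path(out_dir, "module_annotation.tsv"))
        }
      }
    }
  }

  manifest$outputs <- as.list(tools::md5sum(outputs))
  names(manifest$outputs) <- basename(names(manifest$outputs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
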