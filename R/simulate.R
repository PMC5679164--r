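## Synthetic stimulated-blood dataset generator.
##
## Emulates the structure of a whole-blood stimulation assay: each donor
## contributes one unstimulated ("medium") aliquot plus one aliquot per
## stimulus, probes carry a per-donor baseline, and stimulus-specific gene
## programs are induced (or repressed) on the log2 scale. Protein traits are
## coupled to planted program activity so the downstream eigengene-trait
## integration has a recoverable answer.

#' Define a planted gene program
#'
#' A program is a set of probes induced (or repressed) together whenever one
#' of its responsive stimuli is applied. Per-gene effect sizes are drawn once
#' per program from N(effect_log2, effect_sd_log2^2), mimicking gene-specific
#' induction magnitudes that are stable across donors.
#'
#' @param program_id character label.
#' @param gene_ids character vector of probe ids (must be part of the probe
#'   universe of the configuration using this program).
#' @param responsive_stimuli character vector of stimulus labels; must not
#'   include "medium".
#' @param effect_log2 mean induced log2 fold change (may be negative for
#'   repression programs).
#' @param effect_sd_log2 SD of per-gene effects around `effect_log2`.
#' @return an object of class `planted_program`.
#' @export
planted_program <- function(program_id, gene_ids, responsive_stimuli,
                            effect_log2 = 1, effect_sd_log2 = 0.25) {
  if (!is.character(program_id) || length(program_id) != 1L) {
    .fail("program_id must be a single string")
  }
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids)) .fail("duplicate gene ids in program '%s'", program_id)
  responsive_stimuli <- as.character(responsive_stimuli)
  if ("medium" %in% responsive_stimuli) {
    .fail("program '%s': responsive_stimuli must not include \"medium\"", program_id)
  }
  .assert_scalar_number(effect_log2, "effect_log2")
  .assert_scalar_number(effect_sd_log2, "effect_sd_log2", lower = 0)
  structure(list(program_id = program_id, gene_ids = gene_ids,
                 responsive_stimuli = responsive_stimuli,
                 effect_log2 = effect_log2, effect_sd_log2 = effect_sd_log2),
            class = "planted_program")
}

#' Configure a synthetic stimulation dataset
#'
#' @param n_donors number of donors; each yields one sample per condition.
#' @param stimuli condition labels; must contain "medium" exactly once.
#' @param n_probes probe universe size; probes are labelled P00001, P00002, ...
#' @param programs list of [planted_program()] objects. Gene ids must exist in
#'   the probe universe; programs may overlap.
#' @param trait_couplings data frame with columns `trait`, `kind`
#'   ("facs" or "luminex"), `program_id` (or NA for an uncoupled trait),
#'   `coupling_strength`, `noise_sd`. Each trait's log2 ratio in a condition
#'   is `coupling_strength * mean program activity + N(0, noise_sd^2)`.
#' @param baseline_mean_log2 mean log2 baseline intensity.
#' @param donor_sd_log2 SD of per-(probe, donor) baseline deviations.
#' @param residual_sd_log2 SD of per-measurement residual noise.
#' @param detection_fail_fraction expected fraction of probes that fail
#'   detection (p > 0.01) in every sample.
#' @param seed integer seed; identical seeds give bit-identical datasets.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_donors = 8,
                              stimuli = c("medium", sprintf("stim%02d", 1:15)),
                              n_probes = 2000,
                              programs = list(),
                              trait_couplings = NULL,
                              baseline_mean_log2 = 7,
                              donor_sd_log2 = 0.5,
                              residual_sd_log2 = 0.3,
                              detection_fail_fraction = 0,
                              seed = 1L) {
  stimuli <- as.character(stimuli)
  if (sum(stimuli == "medium") != 1L) {
    .fail("stimuli must contain \"medium\" exactly once")
  }
  if (anyDuplicated(stimuli)) .fail("duplicate stimulus labels")
  .assert_scalar_number(n_donors, "n_donors", lower = 1)
  .assert_scalar_number(n_probes, "n_probes", lower = 1)
  .assert_scalar_number(donor_sd_log2, "donor_sd_log2", lower = 0)
  .assert_scalar_number(residual_sd_log2, "residual_sd_log2", lower = 0)
  .assert_scalar_number(detection_fail_fraction, "detection_fail_fraction",
                        lower = 0, upper = 1)
  probe_ids <- sprintf("P%05d", seq_len(n_probes))
  for (pr in programs) {
    if (!inherits(pr, "planted_program")) .fail("programs must be planted_program objects")
    bad <- setdiff(pr$gene_ids, probe_ids)
    if (length(bad)) {
      .fail("program '%s' references probes outside the universe (e.g. %s)",
            pr$program_id, bad[1])
    }
    bad_stim <- setdiff(pr$responsive_stimuli, stimuli)
    if (length(bad_stim)) {
      .fail("program '%s' references unknown stimulus '%s'", pr$program_id, bad_stim[1])
    }
  }
  if (is.null(trait_couplings)) {
    trait_couplings <- data.frame(trait = character(), kind = character(),
                                  program_id = character(),
                                  coupling_strength = numeric(),
                                  noise_sd = numeric())
  }
  req <- c("trait", "kind", "program_id", "coupling_strength", "noise_sd")
  if (!all(req %in% names(trait_couplings))) {
    .fail("trait_couplings must have columns %s", paste(req, collapse = ", "))
  }
  known <- vapply(programs, function(p) p$program_id, character(1))
  bad <- setdiff(stats::na.omit(trait_couplings$program_id), known)
  if (length(bad)) .fail("trait coupling references unknown program '%s'", bad[1])
  structure(list(n_donors = as.integer(n_donors), stimuli = stimuli,
                 n_probes = as.integer(n_probes), probe_ids = probe_ids,
                 programs = programs, trait_couplings = trait_couplings,
                 baseline_mean_log2 = baseline_mean_log2,
                 donor_sd_log2 = donor_sd_log2,
                 residual_sd_log2 = residual_sd_log2,
                 detection_fail_fraction = detection_fail_fraction,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate a synthetic stimulation dataset
#'
#' Draws, in a fixed order from a single seeded stream: per-(probe, donor)
#' baseline deviations, per-gene program effects, per-measurement residuals,
#' detection failures, and trait noise. Linear intensities are
#' \eqn{2^{(baseline + donor + \sum program\ effects + residual)}}, floored
#' at 1. Detected probes receive detection p-values ~ U(0, 0.01) in every
#' sample; failed probes ~ U(0.02, 1) in every sample. Trait ratios are
#' \eqn{2^{(strength \times activity + noise)}} per non-medium condition, so
#' the stated linear coupling holds on the log2 scale and ratios stay
#' positive.
#'
#' @param config a [simulation_config()].
#' @return list with elements `expression` (an [expression_matrix()]),
#'   `traits` (data frame trait/kind/condition/value), and `truth` (list with
#'   `memberships`, per-sample `activity` matrix, `gene_effects`, and the
#'   `couplings` table).
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "simulation_config")) .fail("config must be a simulation_config")
  set.seed(config$seed)
  np <- config$n_probes; nd <- config$n_donors
  donors <- sprintf("D%02d", seq_len(nd))
  stimuli <- config$stimuli
  ## sample order: donor-major, stimulus order as configured
  samples <- data.frame(
    sample_id = paste(rep(donors, each = length(stimuli)),
                      rep(stimuli, times = nd), sep = "_"),
    donor_id = rep(donors, each = length(stimuli)),
    stimulus = rep(stimuli, times = nd),
    group = "healthy", stringsAsFactors = FALSE)
  ns <- nrow(samples)

  ## 1. per-(probe, donor) baseline deviations
  donor_eff <- matrix(stats::rnorm(np * nd, 0, config$donor_sd_log2), np, nd,
                      dimnames = list(config$probe_ids, donors))
  ## 2. per-gene program effects (stable across donors)
  gene_effects <- lapply(config$programs, function(pr) {
    e <- stats::rnorm(length(pr$gene_ids), pr$effect_log2, pr$effect_sd_log2)
    names(e) <- pr$gene_ids
    e
  })
  names(gene_effects) <- vapply(config$programs, `[[`, character(1), "program_id")
  ## 3. residuals
  resid <- matrix(stats::rnorm(np * ns, 0, config$residual_sd_log2), np, ns)

  ## binary program activity per sample
  activity <- matrix(0L, ns, length(config$programs),
                     dimnames = list(samples$sample_id, names(gene_effects)))
  for (j in seq_along(config$programs)) {
    activity[samples$stimulus %in% config$programs[[j]]$responsive_stimuli, j] <- 1L
  }

  lg <- matrix(config$baseline_mean_log2, np, ns,
               dimnames = list(config$probe_ids, samples$sample_id))
  lg <- lg + donor_eff[, match(samples$donor_id, donors)]
  for (j in seq_along(config$programs)) {
    genes <- config$programs[[j]]$gene_ids
    on <- activity[, j] == 1L
    if (any(on)) {
      lg[genes, on] <- lg[genes, on] + gene_effects[[j]][genes]
    }
  }
  lg <- lg + resid
  intens <- pmax(2^lg, 1)

  ## 4. detection failures (per probe), then per-cell p-values
  failed <- stats::runif(np) < config$detection_fail_fraction
  det <- matrix(NA_real_, np, ns, dimnames = dimnames(intens))
  det[failed, ] <- matrix(stats::runif(sum(failed) * ns, 0.02, 1), sum(failed), ns)
  det[!failed, ] <- matrix(stats::runif(sum(!failed) * ns, 0, 0.01), sum(!failed), ns)

  ## 5. trait values per non-medium condition
  conditions <- setdiff(stimuli, "medium")
  tc <- config$trait_couplings
  traits <- NULL
  if (nrow(tc)) {
    rows <- vector("list", nrow(tc))
    for (i in seq_len(nrow(tc))) {
      if (is.na(tc$program_id[i])) {
        act <- rep(0, length(conditions))
      } else {
        pr <- config$programs[[match(tc$program_id[i], names(gene_effects))]]
        act <- as.numeric(conditions %in% pr$responsive_stimuli)
      }
      val <- 2^(tc$coupling_strength[i] * act +
                  stats::rnorm(length(conditions), 0, tc$noise_sd[i]))
      rows[[i]] <- data.frame(trait = tc$trait[i], kind = tc$kind[i],
                              condition = conditions, value = val,
                              stringsAsFactors = FALSE)
    }
    traits <- do.call(rbind, rows)
    rownames(traits) <- NULL
  } else {
    traits <- data.frame(trait = character(), kind = character(),
                         condition = character(), value = numeric())
  }

  expr <- expression_matrix(intens, samples, detection_p = det)
  truth <- list(
    memberships = lapply(config$programs, `[[`, "gene_ids"),
    activity = activity,
    gene_effects = gene_effects,
    couplings = tc)
  names(truth$memberships) <- names(gene_effects)
  list(expression = expr, traits = traits, truth = truth)
}

#' Study-like default simulation configuration
#'
#' Encodes the structure of the assay the package models: 8 donors, 15
#' stimuli plus a medium control, 2,000 probes, two disjoint 50-gene induced
#' programs (mean log2 effect 2, per-gene SD 0.1) each responsive to five
#' distinct stimuli, residual noise SD 0.3, 5% detection failures, and three
#' protein traits: one FACS trait coupled to the first program, one Luminex
#' trait coupled to the second (both strength 1, noise SD 0.1), and one
#' uncoupled control trait.
#'
#' @param seed integer seed.
#' @param n_donors,n_probes,residual_sd_log2 overrides of the defaults above.
#'   Below 100 probes the two programs shrink to n_probes / 4 genes each so
#'   they still fit in the universe.
#' @return a [simulation_config()].
#' @export
example_config <- function(seed = 1L, n_donors = 8, n_probes = 2000,
                           residual_sd_log2 = 0.3) {
  probes <- sprintf("P%05d", seq_len(n_probes))
  ## two 50-gene programs, shrunk when the universe cannot hold them
  size <- if (n_probes >= 100L) 50L else max(2L, n_probes %/% 4L)
  progs <- list(
    planted_program("progA", probes[seq_len(size)], sprintf("stim%02d", 1:5),
                    effect_log2 = 2, effect_sd_log2 = 0.1),
    planted_program("progB", probes[size + seq_len(size)], sprintf("stim%02d", 6:10),
                    effect_log2 = 2, effect_sd_log2 = 0.1))
  couplings <- data.frame(
    trait = c("CD69_gMFI", "IL6_conc", "CD3_gMFI"),
    kind = c("facs", "luminex", "facs"),
    program_id = c("progA", "progB", NA),
    coupling_strength = c(1, 1, 0),
    noise_sd = c(0.1, 0.1, 0.1),
    stringsAsFactors = FALSE)
  simulation_config(n_donors = n_donors, n_probes = n_probes,
                    programs = progs, trait_couplings = couplings,
                    residual_sd_log2 = residual_sd_log2,
                    detection_fail_fraction = 0.05, seed = seed)
}

#' Write a generated dataset to disk
#'
#' Writes the expression matrix and detection p-values as TSV, the sample
#' sheet and trait table as CSV, program memberships as GMT, and the coupling
#' table as CSV.
#'
#' @param dataset result of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    detection = file.path(dir, "detection.tsv"),
    samples = file.path(dir, "samples.csv"),
    traits = file.path(dir, "traits.csv"),
    programs = file.path(dir, "programs.gmt"),
    couplings = file.path(dir, "couplings.csv"))
  write_expression_tsv(dataset$expression$intensities, paths["expression"])
  if (!is.null(dataset$expression$detection_p)) {
    write_expression_tsv(dataset$expression$detection_p, paths["detection"])
  }
  write_sample_csv(dataset$expression$samples, paths["samples"])
  write_trait_csv(dataset$traits, paths["traits"])
  write_gmt(dataset$truth$memberships, paths["programs"],
            descriptions = rep("planted program", length(dataset$truth$memberships)))
  utils::write.csv(dataset$truth$couplings, paths["couplings"], row.names = FALSE)
  invisible(paths)
}
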