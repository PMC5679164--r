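# stimprint

Modular transcriptional fingerprinting of stimulated whole blood.

## The problem

Immune competence is hard to read from resting blood. Stimulation assays
probe it directly: blood from each donor is split into aliquots, one kept as
an unstimulated **medium control** and the rest challenged with a panel of
stimuli (TLR agonists, whole pathogens, T-cell activators, cytokines).
Transcript abundance measured on every aliquot then carries two very
different signals -- stable inter-individual baseline differences, and the
**inducible** response of interest. `stimprint` implements an end-to-end
analysis for such multidimensional stimulation studies:

* **Donor-normalized inducible transcriptomics** -- intensity flooring,
  per-donor ratio-to-medium normalization, detection filtering, and
  differentially expressed transcript (DET) selection by Welch
  heteroscedastic ANOVA with Benjamini-Hochberg FDR control.
* **Reference coexpression modules** -- transcripts are clustered within
  each stimulus group; each transcript pair receives a **cocluster score**
  (0-15 with 15 stimuli) counting the partitions in which it shares a
  cluster; modules are maximal cliques of high-scoring pairs, scanned from
  perfectly conserved (score 15) down to score ceil(S/3).
* **Modular fingerprints** -- per module and condition, the percentage of
  transcripts >= 2-fold up and <= 2-fold down (signed fold change
  convention: 2-fold down is -2).
* **MDTM** (molecular distance to medium) -- a per-sample composite: the
  sum of |signed fold changes| that reach 2-fold over a transcript list.
* **Weighted coexpression network modules** -- soft-thresholded correlation
  adjacency, topological overlap (TOM) dissimilarity, average-linkage tree
  cut (min module size 30), eigengene merging at height 0.1, kME >= 0.7
  membership filter.
* **Trait integration** -- Pearson correlation of module eigengenes with
  FACS/Luminex protein traits; gene significance (GS) and module membership
  (MM/kME); hub genes at |GS| and |MM| > 0.80; annotation of network modules
  by percent overlap with the reference modules.
* **A seeded synthetic generator** -- planted stimulus-responsive gene
  programs and trait couplings with known ground truth, so every stage is
  testable end to end.

See `vignettes/stimulation-fingerprints.Rmd` for the model, the numerical
conventions, and the rationale behind every default.

## Worked example

```r
library(stimprint)

## a synthetic study: 8 donors x (medium + 15 stimuli), 2000 probes,
## two planted 50-gene programs and two coupled protein traits
ds <- generate_dataset(example_config(seed = 1))

## preprocess: floor, detection filter, ratio-to-medium, Welch+BH DETs
nm   <- normalize_to_medium(detection_filter(floor_intensities(ds$expression)))
dets <- select_dets(nm, nm$samples$stimulus)
sum(dets$kept)
#> [1] 94

## reference modules: per-stimulus k-means -> cocluster scores -> cliques
parts <- cluster_per_stimulus(nm, k = 19, seed = 2)
ms    <- extract_modules(cocluster_scores(parts), min_size = 10)
ms
#> module_set: 2 modules (sizes 45-49), 1808 unassigned transcripts

## fingerprint: % of each module responding 2-fold per condition
fp <- fingerprint(ms, nm)
head(fp[order(-fp$pct_up), ], 3)
#>  module_id condition pct_up pct_down n_genes
#>        M01    stim01    100        0      49
#>        M01    stim02    100        0      49
#>        M01    stim03    100        0      49

## molecular distance to medium per sample, over the DETs
md <- mdtm_samples(nm, subset = dets$probe_id[dets$kept])
head(md[order(-md$mdtm), c("sample_id", "stimulus", "mdtm")], 3)
#>   sample_id stimulus  mdtm
#>  D03_stim02   stim02 220.3
#>  D06_stim05   stim05 217.3
#>  D06_stim01   stim01 217.1

## network modules + trait integration
net <- network_modules(nm, network_config())
mt  <- module_trait_correlation(net$eigengenes, collapse_replicates(ds$traits))
round(mt$r, 3)
#>      CD69_gMFI IL6_conc CD3_gMFI
#> mod1     0.993   -0.514    0.076
#> mod2    -0.502    0.987   -0.185
```

The two recovered modules are the two planted programs; each correlates
near-perfectly with its coupled trait and weakly with the uncoupled control
trait (`CD3_gMFI`).

## Analysis workflow

The `analysis/` directory holds numbered drivers that run the same study as
a file-based workflow, writing tables under `results/` (not committed):

```sh
Rscript analysis/01_simulate.R          # synthetic study -> results/data/
Rscript analysis/02_preprocess.R        # DET table, power calculation
Rscript analysis/03_reference_modules.R # modules, fingerprints, MDTM
Rscript analysis/04_network.R           # network labels, eigengenes
Rscript analysis/05_integration.R       # module-trait, hubs, annotation
```

The same stages are also available as a single configurable entry point,
`run_pipeline(pipeline_config(...), out_dir)`, which writes a
`manifest.json` with checksums of every output.

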