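---
title: "Methods: modular fingerprinting of stimulated whole blood"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modular fingerprinting of stimulated whole blood}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stimprint)
```

## The assay and its statistical model

The pipeline targets stimulation studies of the following shape. Whole blood
from each of $D$ donors is split into aliquots; one aliquot per donor is left
unstimulated (the *medium control*) and the others each receive one of $S$
stimuli. Transcript abundance is measured on every aliquot, giving one sample
per donor x condition cell. Optionally, protein traits (flow-cytometry gMFI
values, secreted-protein concentrations) are measured on the same aliquots.

All inference happens on *ratios to medium*: each stimulated sample is divided,
probe by probe, by the same donor's medium control. This removes the dominant
nuisance axis -- stable inter-individual baseline differences -- and leaves
the *inducible* transcriptome. Statistics are computed on $\log_2$ ratios,
where donor baselines cancel additively and fold changes are symmetric.
Reported fold changes use the signed convention
$\mathrm{sfc}(v) = v$ for $v \ge 1$ and $-1/v$ otherwise, so 2-fold down is
$-2$, never $0.5$.

## Preprocessing defaults

* **Intensity floor 10** (`floor_intensities`): raw intensities below 10 are
  set to 10 before forming ratios, so near-background probes cannot create
  huge spurious ratios.
* **Detection filter at p = 0.01** (`detection_filter`): probes detected
  ($p \le 0.01$) in no sample are removed entirely.
* **DET selection** (`select_dets`): per-probe Welch heteroscedastic one-way
  ANOVA across stimulus groups on the $\log_2$ ratios, Benjamini--Hochberg
  adjusted, kept at FDR $\alpha = 0.05$. Welch's form is used because
  stimulus groups have visibly unequal variances; the statistic is computed
  in vectorized closed form and is oracle-tested against
  `stats::oneway.test` (identical to $10^{-10}$). Tukey post-hoc contrasts
  are available (`tukey = TRUE`) but only reported, never used for selection.
* **Power calculation** (`power_sample_size`): the closed-form two-sided
  normal-approximation sample size
  $n = \lceil 2(z_{1-\alpha/2}+z_{\mathrm{power}})^2 \sigma^2 / \Delta^2 \rceil$
  with $\sigma = 0.7$ ($\log_2$ ratio SD) and $\Delta = \log_2 2 = 1$ gives
  the 8 replicates per condition used throughout.

## Reference-module extraction

Reference modules are disjoint gene sets that co-behave *across* stimuli:

1. **Per-stimulus clustering** (`cluster_per_stimulus`): k-means on each
   stimulus group's $\log_2$ ratio profiles (genes x donors), giving $S$
   independent partitions. Profiles are deliberately **not** z-scored per
   gene (`scale = "none"`): under a categorical design a program's genes
   share an almost-constant induction profile across donors, and per-gene
   standardization divides that shared signal away, leaving only noise.
2. **Cocluster scoring** (`cocluster_scores`): every gene pair is scored by
   the number of partitions (0 to $S$; 15 in the reference design) in which
   it shares a cluster label.
3. **Clique selection** (`extract_modules`): a threshold $t$ scans from $S$
   down to $t_{\min} = \lceil S/3 \rceil$; at each $t$ the largest maximal
   clique (size $\ge$ `min_size`, default 10) of the graph with edges at
   score $\ge t$ is extracted and removed. Exact clique search
   (`igraph::largest_cliques`) is exponential in the worst case, so above
   `component_guard` (5000) nodes the method falls back to connected
   components.
4. **Consolidation** (`expand = TRUE`): the greedy scan can lock in a
   perfectly conserved core at $t = S$ and strand the rest of the same
   pattern. Two repairs, both preserving the invariant that a module is a
   clique in the $t_{\min}$ graph: module pairs whose union is still a
   $t_{\min}$-clique are merged, then modules grow by admitting unassigned
   genes whose score with *every* member is $\ge t_{\min}$. Spurious
   admissions are essentially impossible: a noise gene would need score
   $\ge t_{\min}$ with every one of tens of members simultaneously.

**Choosing k.** The pipeline default (`cluster_k = NULL`) is adaptive:
$k = \mathrm{clamp}(n/100,\ 5,\ 30)$ for $n$ transcripts. The governing
quantity is transcripts per center, $n/k$. If $n/k$ falls near the size of a
coherent program, k-means profitably splits the program's tight clump across
two centers in some stimuli, and its pair scores drop below $t_{\min}$.
Keeping $n/k \gtrsim 100$ (about twice a typical program) makes a clump
attract exactly one center, while chance co-clustering of unrelated genes
stays near $1/(k-1)$ per stimulus -- far too rare to accumulate to
$t_{\min}$ across 15 independent partitions. At transcriptome scale
($n \approx 10^4$) the clamp reproduces the conventional $k = 30$.
Average-linkage hierarchical clustering was evaluated as an alternative and
rejected: its highly uneven partitions (one giant cluster plus outlier
singletons) inflate chance co-clustering and flood the clique step with
spurious modules.

## Fingerprint and MDTM

The **modular fingerprint** (`fingerprint`) reduces each module x condition
cell to two percentages: the share of module transcripts whose
condition-level ratio (geometric mean over the stimulus's replicates) is
$\ge 2$-fold up, and the share $\le 2$-fold down (inclusive thresholds).
Module transcripts absent from a dataset stay in the denominator by default
so percentages remain comparable across datasets.

The **molecular distance to medium** (`mdtm`) is a per-sample composite:
the sum of $|\mathrm{sfc}|$ over transcripts with $|\mathrm{sfc}| \ge 2$,
conventionally over the DET list. It is zero exactly when no transcript
reaches 2-fold.

## Network modules

`network_modules` implements a weighted-coexpression workflow on
stimulus-collapsed $\log_2$ profiles of transcripts that reach 2-fold
induction somewhere (`prefilter_fold = 2`):

* **Adjacency and TOM**: $a_{ij} = |\mathrm{cor}(x_i, x_j)|^\beta$
  (signed variant available), with $\beta$ the smallest candidate whose
  degree distribution reaches scale-free fit $R^2 \ge 0.8$
  (`pick_soft_power`), falling back to 6. Topological overlap
  $\mathrm{TOM}_{ij} = (\sum_u a_{iu}a_{uj} + a_{ij}) /
  (\min(k_i,k_j) + 1 - a_{ij})$; clustering uses the dissimilarity
  $1 - \mathrm{TOM}$.
* **Tree cut**: average-linkage hierarchy cut by two explicit rules --
  a static cut at `cut_fraction` (0.99) of the maximum merge height, a
  size floor `min_module_size` (30), plus a core-scatter cohesion test
  (mean within-cluster dissimilarity $\le$ `max_core_scatter` (0.9) of the
  cut height). These documented rules replace adaptive branch-shape
  heuristics; they are deterministic and testable.
* **Eigengenes** (`module_eigengenes`): first principal component of the
  module's per-gene standardized profile matrix, unit norm, sign-aligned
  with the module's mean profile.
* **Merge and membership filter**: modules whose eigengenes are closer than
  `merge_cut_height` (0.1, i.e. $r > 0.9$) merge; genes with
  $|kME| <$ `min_kme` (0.7) to their own eigengene are unassigned, with one
  eigengene recomputation afterwards.

## Trait integration

Traits are collapsed to condition level as mean $\log_2$ ratios
(`collapse_replicates`), then:

* **Module--trait correlation** (`module_trait_correlation`): Pearson $r$
  and two-sided p-values between eigengenes and traits over shared
  conditions, pairwise-deleting missing values.
* **GS / MM** (`gene_significance`, `module_membership`): per-gene
  correlations with traits and with eigengenes.
* **Hub genes** (`hub_genes`): $|GS| > 0.80$ *and* $|MM| > 0.80$ (strict).
* **Annotation** (`annotate_by_overlap`): each network module is labeled by
  the reference module with the largest percent overlap
  ($100\,|W \cap R|/|W|$), "unannotated" below `min_overlap` (10%).

## The synthetic generator

`generate_dataset` emulates the assay's *structure*, not any particular
biology: intensities are
$2^{\,\mu + d_{pg} + \sum_k e_{pk} A_{ks} + \varepsilon}$ with baseline
$\mu = 7$, per-(probe, donor) effects $d \sim N(0, 0.5^2)$, per-gene program
effects $e \sim N(\text{effect},\ 0.1^2)$ switched by a binary
stimulus-activity matrix $A$, and residual $\varepsilon \sim N(0, 0.3^2)$,
floored at 1. Detection p-values are $U(0, 0.01)$ for detected probes and
$U(0.02, 1)$ for a planted fraction of always-failing probes. Trait values
are $2^{\,c \cdot \bar A_s + N(0, \sigma_t^2)}$, coupling the trait's
$\log_2$ ratio linearly to its program's activity while keeping measured
values positive. All draws come from one seeded stream in a fixed
documented order, so datasets are bit-reproducible. The generator makes no
attempt to emulate probe-level cross-correlation structure, batch effects,
or realistic trait distributions.

## Problem sizes and limitations

The defaults are tuned for desk scale: $\sim$2000 probes, 8 donors, 16
conditions run end to end in well under a minute; clique extraction falls
back to components beyond 5000 graph nodes. Known limitations:

* Reference-module recovery degrades with fewer than ~8 donors: with 4-donor
  (4-dimensional) per-stimulus profiles, k-means occasionally splits a true
  program irrecoverably.
* The static tree cut is simpler than adaptive branch-cutting; very
  close-sitting modules separated only by branch shape will merge.
* The exact clique step is worst-case exponential; the component fallback
  relaxes module cohesion above the guard size.
* Eigengene signs are canonical but arbitrary with respect to biology;
  interpret module--trait correlation signs together with the fingerprint.
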