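---
title: "Typing telomere maintenance mechanisms in single cells: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Typing telomere maintenance mechanisms in single cells: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scTMM)
```

# The problem

Cancer cells escape replicative senescence through a telomere maintenance
mechanism (TMM). Around 85% of tumors reactivate telomerase (TEL); most of
the rest use the recombination-based alternative lengthening of telomeres
(ALT). Bulk RNA-seq can type a *tumor*, but a tumor is a mixture: epithelial,
immune and stromal cells can each run a different mechanism, and some cells
show no detectable mechanism at all — the non-defined TMM (NDTMM) state,
which in gastric cancer marks a particularly aggressive population. scTMM
asks the question cell by cell: given a sparse single-cell count matrix and
TEL-/ALT-associated pathway signatures, which of the four states — `TEL`,
`ALT-like`, `TEL+ALT-like`, `NDTMM` — best describes each cell?

The "-like" in `ALT-like` matters: this is signature-level evidence of
pathway activity, not a direct telomere assay.

# The pipeline

1. **QC** (`compute_qc`, `filter_cells`). Cells are kept when they have at
   least `min_features = 200` detected genes and pass a mitochondrial
   percentage filter at `mito_pct_threshold = 5`%. The mitochondrial rule
   direction is exposed as `mito_rule` because the two readings genuinely
   circulate: the conventional direction (`keep_below`, our default) removes
   high-mito cells as damaged; the literal inverse (`keep_above`) is
   available for reproducing analyses that stated the criterion that way.
   We default to the convention because downstream cell-count bookkeeping in
   published gastric cohorts is only reachable with it.

2. **Normalization** (`lognormalize`). Library-size normalization,
   `x -> log(1 + 1e4 * x / total)`, sparsity-preserving.

3. **Imputation** (`build_markov`, `diffuse`). A MAGIC-style diffusion
   denoiser: Euclidean distances in the top `n_pcs = 20` principal
   components, adaptive Gaussian kernel with bandwidth at the `ka = 5`-th
   neighbor truncated at the `k = 15`-th, arithmetic-mean symmetrization,
   row normalization, and `t = 3` diffusion steps. All four defaults follow
   the published MAGIC recommendations; all are exposed because the output
   is genuinely parameter-sensitive, which is also why `run_pipeline`
   records every parameter in its manifest.

4. **Scoring** (`score_matrix`). The per-cell ssGSEA statistic: genes are
   ranked within each cell (high expression = high rank) and, for gene set
   $G$ of size $m$ in a universe of $N$ genes,
   $$ES = \sum_i \left[P_{in}(i) - P_{out}(i)\right]$$
   where the walk visits genes in decreasing rank order, $P_{in}$ is the
   $r^\alpha$-weighted cumulative fraction of set genes and $P_{out}$ the
   unweighted cumulative fraction of non-set genes. Because the gene with
   rank $r$ sits at walk position $N - r + 1$, the sum collapses to the
   closed form
   $$ES = \frac{\sum_{g \in G} r_g^{\alpha+1}}{\sum_{g \in G} r_g^{\alpha}}
   - \frac{N(N+1)/2 - \sum_{g \in G} r_g}{N - m},$$
   which is what the package evaluates (the test suite checks it against a
   literal running-sum implementation). We implement the ssGSEA statistic —
   per-cell independent, matching per-cell classification — rather than the
   GSVA kernel-density variant; $\alpha = 0.25$ is the published ssGSEA
   default. Scores are optionally normalized by the global max–min range.

5. **Significance and calling** (`permutation_pvalues`, `tmm_classify`).
   For each TMM signature set, `n_perm` same-size null gene sets are drawn
   and scored in every cell; $p = (1 + \#\{ES_{null} \ge ES_{obs}\}) /
   (n_{perm} + 1)$. p-values are BH-corrected across cells within each set;
   member-set q-values combine into TEL-group and ALT-group q-values
   (`group_rule = "any"` takes the minimum — the most permissive reading of
   "most prevalent type"; `majority` and `all` are available); a group is
   active below `fdr_threshold = 0.01`, and the four-way label follows the
   obvious truth table. `n_perm` defaults to 10,000 at desk scale and can be
   raised to the 10^7 scale of the original analyses by configuration.

6. **Characterization**. TMM frequency tables per cell type
   (`tmm_frequency`); Shannon entropy of each cell's expression distribution
   as a stemness proxy with k-means/PCA clustering and per-cluster
   composition (`cell_entropy`, `cluster_cells`, `entropy_by_cluster`);
   marker summaries with Wilcoxon tests (`marker_summary`, e.g. *MKI67* for
   proliferation, *PML* as a telomere-length proxy); and DESingle-style
   zero-inflated negative binomial differential expression (`de_two_group`).

# Two null-model decisions worth explaining

**Expression-matched null sets.** The textbook gene-resampling null draws
null sets uniformly from the universe. With realistic gene-to-gene mean
variation that null is miscalibrated for a *fixed* signature: the
signature's particular mean profile shifts every cell's observed score in
the same direction, so per-cell p-values for a null cohort are uniform only
on average over signatures, not for the one you actually test. scTMM
therefore defaults to expression-matched draws (`match_bins = 25`): genes
are binned by mean expression and each null gene is sampled from the bin of
the signature gene it replaces — the same device as the binned control genes
of standard single-cell signature scoring. `match_bins = 0` restores the
plain null.

**Cell-wise tie-breaking.** Sparse counts make the zero block one enormous
tie. Any tie order applied identically in every cell (such as
lexicographic gene-id order) hands each gene a *persistent* rank offset —
reproduced in every cell — which again no resampling null can absorb; in
calibration experiments it alone shifted mean null p-values by up to 0.1.
Matrix scoring therefore defaults to `tie_break = "cellwise"`: tied genes
are ordered by a pseudorandom permutation drawn deterministically from a
fixed internal seed plus the cell's row position. Tie placement becomes
per-cell noise, which the permutation null absorbs, and results remain
bit-identical across runs. The single-vector `rank_cell` keeps the
id-lexicographic rule, and `tie_break = "lexicographic"` restores it for
matrices.

A related caveat: calibration of the per-cell test is a statement about
independent cells. Diffusion imputation deliberately couples neighboring
cells, so the *across-cell* empirical distribution of p-values after
imputation is not expected to be uniform even though each cell's test is
valid. The package's calibration checks run on the normalized,
pre-imputation matrix; classification runs post-imputation, where the
denoising buys substantial sensitivity.

# The synthetic cohort generator

`simulate_cohort` emulates a droplet-based tumor cohort: per-gene log-means
from Normal(`baseline_log_mean = 0`, `gene_mean_sd = 1`) (so typical
expected counts near 1, spanning roughly 0.05–20 — shallow 10x-like depth
over a couple thousand expressed genes); negative binomial counts with size
`nb_dispersion = 1`; logistic dropout
`plogis(slope * (midpoint - log mu))` with `midpoint = log(0.5)`,
`slope = 1`, concentrating extra zeros on weak genes
(`midpoint = -Inf` disables dropout — the slope-zero corner of the logistic
is otherwise ill-defined); a mitochondrial block whose per-cell share is
drawn uniformly from `mito_fraction_range = c(0.01, 0.04)`; cell types with
strided marker blocks (`cell_type_lfc = 1`); and per-cell TMM activity —
each cell draws a TMM type, and every signature set of its active group(s)
has its genes' means multiplied by `2^signature_lfc`. Activity is planted
per cell, not per cell type, so within-cell-type TMM heterogeneity is part
of the ground truth. Functional gene blocks are strided evenly across the
gene-id range; a contiguous block would interact with any fixed tie order
(see above).

What the generator does **not** emulate: batch effects, doublets, ambient
RNA, UMI saturation, gene–gene correlation beyond the planted blocks, or
real TMM biology — the shipped six demo signature sets (three TEL-group,
three ALT-group, 30 genes each) are placeholders over the synthetic
universe, and real analyses must supply signature GMTs with TEL/ALT group
tags. Passing recovery tests therefore demonstrates that the statistical
machinery works under the stated generative assumptions, not that any
particular biological signature is valid.

# Numerical and testing choices

* ZINB fitting uses BFGS on $(\mathrm{logit}\,\pi, \log\mu, \log\theta)$
  from a deterministic moment start ($\mu_0$ = positive-part mean,
  $\theta_0$ = method of moments clamped to $[10^{-3}, 10^3]$, $\pi_0$ =
  excess-zero fraction), $\pi$ bounded in $[0, 1-10^{-6}]$; all-zero vectors
  return the $\pi = 1$ boundary with a flag. The two-group test shares
  $\theta$ across groups by default (stabilizes small-$n$ fits;
  `share_theta = FALSE` frees it), with likelihood-ratio tests at 2 df
  (overall), 1 df (zero part), 1 df (abundance); negative LRT statistics
  from optimizer noise are clamped to zero. DE classes follow the
  DESingle taxonomy (DEs / DEa / DEg) using the BH-corrected component
  tests at 0.05.
* k-means (10 restarts, seeded) on PCA scores replaces medoid clustering:
  deterministic, dependency-light, and cluster-level entropy comparison is
  the only stemness output the downstream summaries need — no lineage
  graph is inferred.
* Markov construction replaces a zero adaptive bandwidth (duplicate cells)
  by the smallest positive neighbor distance, with a warning.
* Reference problem sizes used throughout the test suite: recovery at 1,000
  cells x 2,000 genes with `n_perm = 1000`; calibration on ten 500-cell
  null cohorts; DE on 500 null genes plus 100-gene planted panels at 300
  cells per arm. The add-one permutation estimator bounds p at
  `1/(n_perm+1)`, so BH-corrected calls at FDR 0.01 need `n_perm` well
  above 100; 1,000 is the practical floor used in the tests.

# Known limitations

* The four-way call inherits the permutation resolution: with 50% of cells
  truly active, BH at 0.01 and `n_perm = 1000` the weakest detectable
  planted effect sits between `signature_lfc` 0.5 (near-chance recovery)
  and 1 (most cells recovered); real signatures with subtler shifts will
  need larger `n_perm` and deeper profiles.
* Group-level calls treat member sets as exchangeable evidence; `any` is
  deliberately permissive and will follow the single best member set.
* The ZINB model assumes counts are raw (not normalized) integers;
  normalized input is rejected rather than silently mis-fitted.
* Diffusion imputation shares information across neighbors: scores after
  imputation are not independent across cells, and any statistic that
  assumes independence should be computed pre-imputation.
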