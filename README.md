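# scTMM

Telomere maintenance mechanism (TMM) typing for single-cell RNA-seq.

Tumor cells become immortal by maintaining their telomeres — most through
telomerase (TEL), some through the recombination-based alternative
lengthening of telomeres (ALT), and an enigmatic remainder through no
detectable mechanism at all (non-defined TMM, NDTMM), a state linked to poor
prognosis in gastric cancer. Bulk RNA-seq types the mixture; scTMM types the
cells. Given a sparse count matrix and TEL-/ALT-associated pathway
signatures, it assigns every cell one of four labels — `TEL`, `ALT-like`,
`TEL+ALT-like`, `NDTMM` — and characterizes the resulting populations. It is
aimed at computational biologists analyzing tumor scRNA-seq who want
per-cell pathway calls with an honest null model.

## The statistic at the core

Each cell is scored against each signature set with the single-sample GSEA
(ssGSEA) statistic. With within-cell ranks $r_g$ (highest expression gets
rank $N$), set $G$ of size $m$, and weight $\alpha = 0.25$:

$$ES(G) \;=\; \frac{\sum_{g \in G} r_g^{\alpha+1}}{\sum_{g \in G} r_g^{\alpha}}
\;-\; \frac{N(N+1)/2 - \sum_{g \in G} r_g}{N - m},$$

the exact closed form of the usual running-sum definition. Significance per
(cell, set) comes from resampled null gene sets matched to the signature's
expression profile, $p = (1 + \#\{ES_{null} \ge ES_{obs}\})/(n_{perm}+1)$,
with Benjamini–Hochberg correction across cells. A cell's TEL and ALT
pathway groups are each called active below FDR 0.01, and the four-way label
follows: TEL only → `TEL`, ALT only → `ALT-like`, both → `TEL+ALT-like`,
neither → `NDTMM`.

Around the classifier: QC filtering (feature count, mitochondrial
percentage), library-size log-normalization, MAGIC-style Markov diffusion
imputation, TMM frequency tables, transcriptome entropy (StemID-style
stemness proxy) with PCA/k-means clustering, marker summaries (e.g. *MKI67*,
*PML*), and DESingle-style zero-inflated negative binomial differential
expression between TMM populations. A synthetic cohort generator with
planted per-cell signature activity makes the whole pipeline testable
without external data; see the methods vignette
(`vignettes/tmm-typing.Rmd`) for the model and every design decision.

## Worked example

Simulate a 400-cell cohort with four planted TMM types (signature log2
fold-change 1.5), run QC → normalize → impute → classify, and compare calls
with the planted truth:

```r
library(scTMM)

cfg  <- sim_config(n_cells = 400, n_genes = 1200, signature_lfc = 1.5, seed = 42)
sets <- demo_tmm_sets(cfg)          # 3 TEL-group + 3 ALT-group demo sets
sim  <- simulate_cohort(cfg, sets)

qc      <- compute_qc(sim$counts)
kept    <- filter_cells(qc, qc_thresholds(min_features = 100))
norm    <- lognormalize(sim$counts[kept, ])
imputed <- magic_impute(norm)
calls   <- tmm_classify(imputed, sets,
                        permutation_params(n_perm = 1000, seed = 43))
head(calls, 4)
#>     cell_id       tel_q       alt_q    label
#> 1 cell00001 1.000000000 0.002028428 ALT-like
#> 2 cell00002 1.000000000 1.000000000    NDTMM
#> 3 cell00003 1.000000000 0.106055082    NDTMM
#> 4 cell00004 0.002049233 0.627943485      TEL
```

`tel_q` and `alt_q` are the group-level q-values behind each call (smallest
member-set q under the default `group_rule = "any"`); a label is assigned
from whichever groups clear FDR 0.01. Frequencies per cell type:

```r
types <- setNames(sim$truth$cell_type, sim$truth$cell_id)
subset(tmm_frequency(calls, types[calls$cell_id]), cell_type == "epithelial")
#>    cell_type        label  n      pct
#> 1 epithelial          TEL 45 27.27273
#> 2 epithelial     ALT-like 35 21.21212
#> 3 epithelial TEL+ALT-like 48 29.09091
#> 4 epithelial        NDTMM 37 22.42424
```

Against the planted truth this run recovers the four labels with
macro-averaged accuracy 0.956. `run_pipeline()` wires the same stages
end-to-end from a YAML/list config and writes TSV artifacts plus a
checksummed JSON manifest.

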