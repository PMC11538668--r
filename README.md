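# zonatlas

Liver lobule zonation analysis for spatial transcriptomics.

## What this package is for

Hepatocytes divide labor along the portal–central (PN–CV) axis of the liver
lobule, and nutritional state (feeding, fasting, refeeding) reshapes that
division. Visium-style spatial transcriptomics measures a gene × spot count
matrix with array coordinates, but no annotation of where each spot sits on
the lobule axis. zonatlas is for researchers who want to go from Space
Ranger-style outputs (one sample per nutritional condition) to:

1. a per-spot **pseudotime coordinate** t ∈ [0, 1] on the PN–CV axis,
   reconstructed by a diffusion map on the expression k-NN structure,
   oriented with landmark genes (Alb/Cyp2f2 portal, Glul/Lgr5 central) so
   that t = 0 is periportal;
2. a **five-way zonation pattern** per gene per condition — periportal,
   pericentral, midzonal, bipolar, or non-zonated — from nonlinear fits of
   three models along t: a quadratic polynomial *a + bt + ct²*, a Gaussian
   peak *h·exp(−(t−μ)²/2σ²)*, and an inverted Gaussian
   *C − h·exp(−(t−μ)²/2σ²)*, selected by AIC. Zonation strength is the
   **normalized range** (max − min)/max of the fitted curve; genes below
   0.1 are non-zonated, and otherwise the peak location (with the 0.25/0.75
   pole boundaries) or an interior trough with elevated poles decides the
   label;
3. **pattern-transition tables** across conditions (Sankey-ready),
   **Wilcoxon rank-sum differential expression** with Benjamini–Hochberg
   FDR (default |log2FC| > 0.25, FDR < 0.05), and per-spot **ssGSEA**
   pathway scores along the axis.

Genes enter the classification when detected with more than 10 counts in at
least 200 spots. A lobule-structured synthetic data generator — hexagonal
lobules on a triangular spot lattice, five truth families, negative-binomial
counts at ~24 000 UMIs/spot, fasting mitochondrial boost, erythroid-
contaminated spots — provides ground truth for every recovery test; no
external data are needed.

## Worked example

Run the default three-condition study (simulation → QC → clustering →
diffusion pseudotime → classification → transitions → DE):

```r
library(zonatlas)
res <- run_pipeline(list(output_dir = "zonatlas-demo", seed = 1))
print(res$dataset)
#> spot_dataset: 600 genes x 3459 spots
#> conditions: ctrl, fasted, refed

table(res$labels$condition, res$labels$label)
#>          bipolar midzonal non_zonated pericentral periportal
#>   ctrl       120      135         120         102        120
#>   fasted     120      136         120         101        120
#>   refed      108      121         168          92        108
```

The simulated panel holds 120 genes per pattern; the classifier recovers
that composition in ctrl and fasted, while in the refed state the
non-zonated class grows by ~48 genes at the expense of the four zonated
classes — exactly the programmed refeeding behavior (10% of zonated genes,
Fasn/Thrsp-like, lose their zonation after refeeding). The transition table
pins those flows down per gene:

```r
tt <- transition_table(subset(res$labels, condition == "ctrl"),
                       subset(res$labels, condition == "refed"))
tt[, "non_zonated"]
#>  periportal pericentral    midzonal     bipolar non_zonated
#>          12          12          11          12         120
```

Twelve genes per zonated family land in the non-zonated column — the
programmed switch set (12 per family), recovered almost exactly; the gene
lists per cell sit in `attr(tt, "genes")`.

Differential expression between fasted and control spots surfaces the
simulated fasting signature — the mitochondrial boost tops the list:

```r
de <- res$de$fasted_vs_ctrl
head(de[order(de$fdr), c("gene", "avg_log2fc", "fdr", "passes")], 3)
#>       gene avg_log2fc           fdr passes
#> 481 mt-Nd1  0.5279526 3.455430e-114   TRUE
#> 488 mt-Nd4  0.4843549 1.860808e-101   TRUE
#> 485 mt-Co3  0.4966093 2.027828e-100   TRUE
```

Every artifact (QC table, cluster assignments, axis TSV, label table,
transition TSV/JSON, DE tables, run report with the fully resolved
configuration) is written under `output_dir`. Real data enter through
`read_visium()` bundles via the `input_dirs` config field instead of the
simulator block; `vignettes/zonation-analysis.Rmd` documents the model,
every tunable parameter, and the simulator's scope. A thin command-line
wrapper lives at `inst/cli/zonatlas.R`.

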