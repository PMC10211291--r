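# methylcell

Cell-type-resolved analysis of smoking-associated DNA methylation.

## The problem

Most epigenome-wide association studies (EWAS) of smoking measure whole
blood, a mixture of leukocyte types whose composition itself responds to
smoking. That confounds two questions: *which CpGs change within a cell
type*, and *which apparent changes are really shifts in cell-type (or
subtype) proportions*. `methylcell` implements, as a tested and reusable
pipeline, the analysis strategy of a cell-type-resolved smoking EWAS in
which six isolated leukocyte fractions (CD19+ B cells, CD15+ granulocytes,
CD14+ monocytes, CD56+ NK cells, CD4+ and CD8+ T cells) plus whole blood
are profiled in parallel:

1. **Deconvolution** — reference-based estimation of cell-type and
   12-subtype proportions by constrained projection: per sample, solve
   min ‖A·w − b‖² subject to w ≥ 0 and Σw ≤ 1, where A holds reference
   beta profiles over signature CpGs.
2. **EWAS per fraction** — per CpG, Huber robust regression (tuning
   constant 1.345, MAD scale) of the M-value, M = log₂(β/(1−β)), on
   smoking + age + sex + ancestry + BMI + estimated contaminant
   proportions; Bonferroni (0.05/420,000 ≈ 1.2×10⁻⁷ at array scale) and
   Benjamini–Hochberg FDR control; cell-type-specificity calls (significant
   in exactly one type; "highly specific" when the best p times 10⁴ still
   undercuts every other type) and directional concordance.
3. **Composite decomposition** — reconstruct the whole-blood effect as the
   proportion-weighted sum of per-type effects,
   ΔM_composite = ΔM_B·0.073 + ΔM_Gran·0.55 + ΔM_Mono·0.037 +
   ΔM_NK·0.060 + ΔM_CD4T·0.20 + ΔM_CD8T·0.087,
   and quantify agreement with the measured whole-blood ΔMeth.
4. **Subtype shift** — test the smoking-linked naive→memory B cell shift by
   OLS of estimated subtype percent on smoking, with and without covariate
   adjustment.
5. **Integration** — proxy smoking CpGs with cis-mQTL SNPs (p < 2×10⁻¹¹,
   distance < 10 kb, replicated in ≥ 2 studies), expand through complete LD
   (dosage r² > 0.95) to GWAS SNPs (p < 5×10⁻⁸, n > 1000), annotate with
   cis eQTM/eQTL evidence (p < 1×10⁻⁵, gene body ± 10 kb), and tally
   per-CpG multi-omics support.
6. **Enrichment** — Fisher exact (hypergeometric) overlap and a pre-ranked
   permutation-normalized enrichment score (NES) against curated EWAS
   catalog CpG sets.

Because the original cohort and consortium datasets are not redistributable,
the package ships a first-class **synthetic cohort generator** that emulates
the study's statistical structure (74 nonsmokers / 67 smokers, isolated
fractions with configurable purity, Dirichlet cell-type proportions,
injected beta-scale effects, LD-blocked genotypes with cis-QTL effects, toy
GWAS and EWAS catalogs) with full ground truth, so every stage is testable
offline.

## Worked example

```r
library(methylcell)

specs  <- wb_celltypes()
panel  <- make_reference_panel(600, specs, 20, seed = 1)
cohort <- make_cohort(74, 67, seed = 2)
eff    <- make_effects(panel, 74, seed = 3)
sim    <- simulate_methylomes(panel, cohort, specs, eff,
                              noise_sd = 0.1, purity = 1, seed = 4)

res <- lapply(sim$fractions, function(b)
  multiple_testing(fit_ewas(b, cohort), n_tests = 600))
delta <- sapply(res[specs$name], `[[`, "delta_meth")
rownames(delta) <- res$WB$cpg_id

comp <- composite_delta(delta)                       # printed weights
wb   <- setNames(res$WB$delta_meth, res$WB$cpg_id)
sig  <- res$WB$cpg_id[res$WB$bonferroni]
compare_to_wholeblood(comp, wb, sig)[c("r", "p", "n")]
```

```
$r
[1] 0.9993323

$p
[1] 1.049678e-82

$n
[1] 59
```

59 of the 600 simulated CpGs reach Bonferroni significance in whole blood;
at those CpGs the proportion-weighted composite of the six per-fraction
effect sizes correlates with the measured whole-blood effect at r = 0.999 —
whole-blood smoking effects are (here, by construction; in the study, by
measurement) the composite of cell-type-level effects.

The same cohort-scale experiments are packaged as `composite_benchmark()`
and `shift_benchmark()`; the latter recovers the injected 7.2
percentage-point reduction in naive B cells from the isolated B fraction by
12-subtype deconvolution (seed 1: 6.97 ± 0.10 pp over 20 replicates).

## Command-line pipeline

```sh
Rscript inst/exec/methylcell run-all --seed 1 --out outdir
# stages: simulate | deconvolve | ewas | composite | integrate | enrich
```

Configuration is JSON, one namespace per stage (`default_config()` lists
every knob); flags override the config. Outputs are plain-text TSV/CSV/BED/
GMT/JSON with stable names (`ewas_<fraction>.tsv`, `proportions.tsv`,
`links.tsv`, `enrichment.tsv`, `summary.json`).

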