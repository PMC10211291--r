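---
title: "Models and methods behind methylcell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind methylcell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylcell)
```

# Scope and data model

`methylcell` analyses smoking-associated DNA methylation with cell-type
resolution: six isolated leukocyte fractions (B cells, granulocytes,
monocytes, NK, CD4T, CD8T) and whole blood, each a CpG × sample matrix of
beta values (methylation proportions in [0, 1]). The pipeline begins at
normalized betas; probe chemistry, normalization and batch correction are
deliberately upstream of this package. All genomic coordinates are 0-based
half-open internally; the only conversion happens at the VCF boundary.
Missing covariates are refused rather than imputed, because silent
imputation in an EWAS design changes the estimand.

# Deconvolution by constrained projection

Cell-type proportions are estimated per sample by solving

$$\min_w \; \lVert A w - b \rVert^2 \quad \text{s.t. } w \ge 0,\;
\textstyle\sum_k w_k \le 1,$$

where $A$ is the reference profile matrix over signature CpGs and $b$ the
observed betas. The inequality constraint (rather than $\sum w = 1$) is the
classical choice for reference-based leukocyte deconvolution: it tolerates
cell content not represented in the panel. The equality variant is
available (`constraint = "sum_eq_1"`), and the two agree after
renormalization whenever the unconstrained sum saturates. The quadratic
program is solved exactly with `quadprog::solve.QP`; with a full-rank panel
and noise-free mixtures the recovery is exact to numerical precision, which
the tests assert at 1e-6.

Signature CpGs are chosen one-vs-rest: for each type, the `k` CpGs with the
largest |own mean − mean of others|, half from each sign where available,
ties broken lexicographically by CpG id so selection is deterministic.

The naive→memory B subtype shift is tested by OLS of estimated subtype
percent on smoking status, unadjusted and adjusted for age, sex, ancestry
and BMI. `p_adjusted_covariates` is deliberately named to make clear it is
a covariate-adjusted regression p, not a multiple-testing adjustment.
Whether the published subtype differences were computed on raw or
lineage-renormalized percentages is not stated in the source; both are
supported (`renormalize_to`), and raw percent is the default.

# Robust-regression EWAS

Betas are transformed to M-values, $M = \log_2 \beta/(1-\beta)$, after
clamping to $[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 10^{-6}$
(variance stabilization; regression residuals on the beta scale are
heteroscedastic near 0 and 1). Per CpG, M is regressed on smoking, age, sex,
one-hot ancestry (first level dropped), BMI, and the estimated contaminant
cell-type proportions — the fraction's own type dropped to avoid
collinearity with the intercept; for whole blood, the largest-mean
proportion is dropped instead. Contaminants estimated as exactly zero for
every sample carry no information and are likewise dropped rather than
allowed to make the design singular.

The fit is Huber M-estimation with the conventional defaults of the cited
robust-regression approach: tuning constant 1.345, scale by MAD, iterated
to convergence or 100 iterations (`MASS::rlm` with `acc = 1e-8`; MASS tests
relative change of the fit rather than of the coefficients, a difference
far below reporting precision). Two-sided p values use the t distribution
with $n - p$ degrees of freedom — conservative relative to the normal at
the study's n. A CpG whose least-squares fit is already exact (MAD of
residuals ~ 0) is reported as converged least squares, since the Huber
estimate coincides with least squares when no residual exceeds the
threshold; genuine non-convergence falls back to least squares and is
flagged in the `converged` column.

Effect sizes are reported two ways: the M-scale coefficient, and
`delta_meth`, the raw-beta group difference **smoker − nonsmoker**, always
computed from unwinsorized betas. The source text describes the difference
as "nonsmoker–smoker" yet reports smoking-induced *hypo*methylation as
negative values; this package resolves the contradiction by defining the
sign as smoker − nonsmoker so hypomethylation in smokers is negative.

Optional 90% winsorization clamps each CpG row at its 5% and 95% type-7
quantiles (per CpG, not global — the only reading under which a
"winsorized EWAS" of heterogeneous CpGs makes sense). Winsorized and raw
fits agree exactly on rows with no values outside the clamp quantiles.

Multiple testing: Bonferroni at $0.05/n$ (420,000 probes at array scale
gives the genome-wide threshold $1.2\times10^{-7}$) and Benjamini–Hochberg
FDR, computed within each cell-type EWAS separately, matching how
per-cell-type counts are reported. A CpG is *cell-type specific* when
significant in exactly one type; *highly specific* when the best p value
times $10^4$ is still no larger than the p in every other type — the
"$10^4$ p-value difference" is read as a ratio (equivalently ≥ 4 decades of
−log₁₀ p), the only interpretation under which the published examples are
coherent. Ties for the best p are never highly specific.

# Composite decomposition

The whole-blood effect is reconstructed per CpG as the weighted sum of
per-fraction effects with the printed average proportions (B 0.073,
Gran 0.55, Mono 0.037, NK 0.060, CD4T 0.20, CD8T 0.087). These weights sum
to 1.007 and are **not** renormalized by default: the package reproduces
the published arithmetic as stated, with an optional `renormalize` flag.
Subset composites (myeloid = Gran+Mono, lymphoid = rest) keep full-blood
weights so they add up to the all-types composite. Agreement is quantified
by Pearson r (p from the t transform, df = n − 2; the source does not state
its method) restricted to whole-blood Bonferroni-significant CpGs, with OLS
slopes reported in both orientations since the published figure's
orientation is ambiguous.

# Multi-omics integration

Every published threshold is applied as a **strict** inequality exactly as
printed, boundaries excluded: mQTL p < 2×10⁻¹¹ with SNP–CpG distance
< 10 kb and replication in ≥ 2 distinct studies (direction harmonization is
not required; the source is silent); GWAS p < 5×10⁻⁸ with population size
> 1000; complete LD as dosage r² > 0.95; eQTM/eQTL p < 1×10⁻⁵ with the CpG
inside the gene body ± 10 kb (half-open, strand-agnostic) and, for eQTLs,
the SNP within 10 kb of the anchoring CpG — distance measured CpG-to-SNP,
as written, not gene-to-SNP. The eQTM threshold is stated inconsistently in
the source (FDR < 0.05 in one place, p < 1×10⁻⁵ in another); the default
follows the p threshold, and the cutoff is a parameter. LD is computed as
squared Pearson correlation of dosages (composite LD), matching
genotype-based r² from standard tooling; haplotype-phase LD is not
attempted because phase is unavailable from dosage files. Multi-omics
support counts one flag per provided dataset (each mQTL study, each eQTM
study, each eQTL study, the GWAS linkage), with a default prioritization
cutoff of ≥ 4 datasets.

# Catalog enrichment

Overrepresentation of smoking CpGs in curated EWAS catalog sets is tested
two ways, reported side by side as in the source: a one-sided Fisher exact
test (hypergeometric upper tail over the tested-CpG universe, odds ratio
with Haldane correction for empty cells), and a pre-ranked running-sum
enrichment score — hits increment by $|s|^{p}$ normalized over hits,
misses decrement by $1/(N - n_{\text{set}})$, ES is the signed extremum —
normalized to an NES against set-size-matched random sets (set-membership
permutation, the pre-ranked flavor of permutation). The source does not
state the exponent or permutation count; the defaults are the conventional
exponent 1 and 1000 permutations. Its GSEA usage also inverts the usual
roles (the smoking CpGs as the "gene set"); the implementation is generic
in query and reference, so either orientation runs. Collection-level FDR q
follows the standard pooled-permutation construction, computed within each
NES sign.

# The synthetic world

The generator is a stated world, not a tuning dial; its defaults are the
study's stated conditions where given, and fixed calibration choices where
not:

* **Cohort**: 74 nonsmokers / 67 smokers; covariates age ~ N(40, 12²),
  sex ~ Bernoulli(0.5), ancestry ~ {EUR 0.6, AFR 0.3, OTH 0.1},
  BMI ~ N(27, 5²) — unremarkable adult-cohort values, chosen once.
* **Reference profiles**: two-component Beta mixture with modes near 0.1
  and 0.9, because array betas are bimodal; the source does not describe
  profiles. Signature CpGs are separated by ≥ 0.5 from all other types.
* **Proportions**: per subject Dirichlet centered at the printed average
  proportions, concentration 200 (tight around the means); configurable,
  `Inf` pins proportions exactly for degenerate-limit tests.
* **Isolated fractions**: purity × own profile + (1 − purity) × the
  subject's own whole-blood contaminant mix, with per-subject Beta purity
  jitter so contamination covariates are estimable. Default purities
  Gran 0.95, Mono 0.94, B 0.91, NK 0.90, CD4T/CD8T 0.93 (the published NK
  "49.4%" is a within-fraction subtype share, not an isolation purity).
* **Effects**: beta-scale deltas added to the affected cell type's smoker
  profile before mixing; signs point toward the interior of [0, 1] so the
  injected delta is realized without clamping (and matching the
  predominance of hypomethylation at highly methylated CpGs).
* **Subtype shift**: implemented purely as a proportion change — smokers'
  Dirichlet mean moves from 60.0% naive / 31.3% memory to 52.8% / 36.0%
  within the B fraction; no per-CpG delta is involved, so downstream
  methods must recover it through deconvolution.
* **Noise**: Gaussian on the M (logit) scale, then inverse-transformed and
  clamped to [1e-6, 1 − 1e-6]; downstream modeling is on M values, so this
  is where measurement error lives. Default SD 0.1.
* **Genetics**: LD blocks via a tag haplotype pair per block; each SNP
  copies each tag allele with probability $q = r_2^{1/4}$, which makes the
  expected pairwise dosage r² equal the target exactly (allele correlation
  is $q^2$ and r² its square); a shared within-block MAF keeps this
  identity exact. QTL summary tables are produced by re-simulating each
  study's molecular trait (injected slope × dosage + unit noise) and
  storing the regression p — injected pairs replicate across studies, null
  pairs do not. By default the CLI simulates external QTL studies at
  n = 1000 (consortium-scale power for the p < 2×10⁻¹¹ filter), while the
  programmatic default reuses the cohort's own subjects.

What the generator does **not** emulate: probe chemistry and
cross-hybridization, population structure and haplotype phase, correlated
neighborhoods of CpGs, LD leakage into QTL summary statistics (each
candidate pair is simulated independently), or realistic trait
architectures in the toy GWAS/EWAS catalogs. A green test therefore
establishes that the *methods* recover what was injected under the stated
noise model — not that the pipeline would reproduce any particular count
from real arrays.

# Numerical choices and degenerate inputs

Betas are clamped at 1e-6 before the logit; the QP adds a 1e-10 ridge only
if numerically singular; rank deficiency in the EWAS design is an error
naming the aliased columns; constant proportions in the shift test yield
p = 1 with a warning rather than NaN; zero-variance dosages make r²
undefined and are an error; ties in specificity ranking disqualify "highly
specific"; an exact tie in directional concordance reports sign "±".
Every generator requires an explicit integer seed and restores the
caller's RNG state, so identical seeds give byte-identical outputs.

# Known limitations

The robust-fit standard errors use the classical Huber correction as in
`summary.rlm(method = "XtX")`, not a sandwich estimator. The permutation
FDR for enrichment pools permuted NES across sets, which assumes roughly
exchangeable set sizes. The CLI's `run-all` exercises one fixed wiring of
the stages; programmatic use is more flexible. The toy catalogs are small
enough that enrichment q values are coarse at the default 200 CLI
permutations (1000 in the API default).
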