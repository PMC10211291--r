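# Synthetic cohort generator: reference panels and subject tables with known
# ground truth. Every generator takes an explicit seed and restores the
# caller's RNG state (withr::with_seed), so identical seeds give
# byte-identical output regardless of surrounding code.

#' Default whole-blood cell-type composition
#'
#' The six major leukocyte types with their average whole-blood proportions
#' (the same values used as composite weights; they sum to 1.007 as printed
#' and are renormalized only where a Dirichlet mean is needed) and the
#' default purity of the corresponding magnetically isolated fraction.
#'
#' @return data.frame with columns `name`, `mean_proportion`, `purity`.
#' @export
wb_celltypes <- function() {
  data.frame(
    name = c("Bcell", "Gran", "Mono", "NK", "CD4T", "CD8T"),
    mean_proportion = c(0.073, 0.55, 0.037, 0.060, 0.20, 0.087),
    purity = c(0.91, 0.95, 0.94, 0.90, 0.93, 0.93),
    stringsAsFactors = FALSE)
}

#' The 12 leukocyte subtype labels used for subtype deconvolution
#' @return character vector of subtype labels.
#' @export
leukocyte_subtypes <- function() {
  c("NaiveB", "MemB", "Neu", "Eos", "Bas", "Mono", "NaiveCD4T", "MemCD4T",
    "Treg", "NaiveCD8T", "MemCD8T", "NK")
}

#' Generate a synthetic reference methylation panel
#'
#' Per-cell-type mean beta profiles over `n_cpgs` CpGs on one synthetic
#' chromosome. Background CpGs are drawn from a two-component Beta mixture
#' (modes near 0.1 and 0.9, matching the bimodality of array betas) shared
#' across types; each type additionally receives `n_signature_per_type`
#' signature CpGs whose beta is separated by at least 0.5 from every other
#' type (half hypermethylated in the own type, half hypomethylated).
#'
#' @param n_cpgs total CpGs; must be at least `types * n_signature_per_type`.
#' @param types character vector of cell-type labels, or a data.frame with a
#'   `name` column (e.g. [wb_celltypes()]).
#' @param n_signature_per_type signature CpGs per type.
#' @param seed integer seed (required).
#' @param chrom synthetic chromosome name.
#' @return object of class `ref_panel`: list with `profiles` (CpG x type
#'   beta matrix), `signature` (named list of signature CpG ids per type)
#'   and `annot` (CpG annotation: `cpg_id`, `chrom`, `pos`, sorted unique
#'   0-based positions).
#' @export
make_reference_panel <- function(n_cpgs, types, n_signature_per_type,
                                 seed, chrom = "chrS") {
  seed <- check_seed(seed)
  if (is.data.frame(types)) types <- types$name
  types <- as.character(types)
  if (length(types) == 0) stop("at least one cell type required", call. = FALSE)
  if (anyDuplicated(types)) stop("duplicate cell-type names", call. = FALSE)
  k <- length(types)
  if (n_cpgs < k * n_signature_per_type) {
    stop("n_cpgs must be >= types * n_signature_per_type", call. = FALSE)
  }
  withr::with_seed(seed, {
    # bimodal background shared across types, plus small type-specific wobble
    base <- ifelse(stats::runif(n_cpgs) < 0.5,
                   stats::rbeta(n_cpgs, 2, 18), stats::rbeta(n_cpgs, 18, 2))
    profiles <- matrix(rep(base, k), ncol = k)
    wobble <- matrix(stats::rnorm(n_cpgs * k, 0, 0.15), ncol = k)
    profiles <- clamp_beta(ilogit2(logit2(clamp_beta(profiles)) + wobble),
                           0.02)
    colnames(profiles) <- types

    cpg_ids <- sprintf("cg%06d", seq_len(n_cpgs))
    rownames(profiles) <- cpg_ids
    pos <- sort(sample.int(n_cpgs * 500L, n_cpgs))

    # signature CpGs: own type on one side, all others on the opposite side,
    # guaranteeing >= 0.5 separation (0.85..0.97 vs 0.03..0.15)
    idx <- sample.int(n_cpgs, k * n_signature_per_type)
    signature <- vector("list", k)
    names(signature) <- types
    for (j in seq_len(k)) {
      own <- idx[((j - 1) * n_signature_per_type + 1):(j * n_signature_per_type)]
      hi <- stats::runif(length(own), 0.85, 0.97)
      lo <- matrix(stats::runif(length(own) * (k - 1), 0.03, 0.15),
                   ncol = k - 1)
      half <- seq_along(own) <= ceiling(length(own) / 2)
      profiles[own[half], j] <- hi[half]
      profiles[own[half], -j] <- lo[half, , drop = FALSE]
      profiles[own[!half], j] <- 1 - hi[!half]
      profiles[own[!half], -j] <- 1 - lo[!half, , drop = FALSE]
      signature[[j]] <- cpg_ids[sort(own)]
    }
    structure(list(
      profiles = profiles,
      signature = signature,
      annot = data.frame(cpg_id = cpg_ids, chrom = chrom, pos = pos,
                         stringsAsFactors = FALSE)),
      class = "ref_panel")
  })
}

#' @export
print.ref_panel <- function(x, ...) {
  cat(sprintf("ref_panel: %d CpGs x %d cell types (%d signature CpGs)\n",
              nrow(x$profiles), ncol(x$profiles),
              length(unlist(x$signature))))
  invisible(x)
}

#' Generate a synthetic subject table
#'
#' One row per subject with smoking status (0/1) and covariates drawn from
#' configurable distributions: age ~ Normal, sex ~ Bernoulli(F), ancestry ~
#' categorical, BMI ~ Normal.
#'
#' @param n_nonsmokers,n_smokers group sizes (both >= 2).
#' @param covariates list with `age_mean`, `age_sd`, `sex_p_female`,
#'   `ancestries` (named probability vector), `bmi_mean`, `bmi_sd`.
#' @param seed integer seed (required).
#' @return data.frame with `subject_id`, `smoking`, `age`, `sex`,
#'   `ancestry`, `bmi`.
#' @export
make_cohort <- function(n_nonsmokers, n_smokers,
                        covariates = list(), seed) {
  seed <- check_seed(seed)
  if (n_nonsmokers < 2 || n_smokers < 2) {
    stop("need at least 2 subjects per group", call. = FALSE)
  }
  cfg <- utils::modifyList(list(
    age_mean = 40, age_sd = 12, sex_p_female = 0.5,
    ancestries = c(EUR = 0.6, AFR = 0.3, OTH = 0.1),
    bmi_mean = 27, bmi_sd = 5), covariates)
  n <- n_nonsmokers + n_smokers
  withr::with_seed(seed, {
    data.frame(
      subject_id = sprintf("S%04d", seq_len(n)),
      smoking = rep(c(0L, 1L), c(n_nonsmokers, n_smokers)),
      age = round(stats::rnorm(n, cfg$age_mean, cfg$age_sd), 1),
      sex = ifelse(stats::runif(n) < cfg$sex_p_female, "F", "M"),
      ancestry = sample(names(cfg$ancestries), n, replace = TRUE,
                        prob = cfg$ancestries),
      bmi = round(stats::rnorm(n, cfg$bmi_mean, cfg$bmi_sd), 1),
      stringsAsFactors = FALSE)
  })
}

#' Draw a set of smoking effects to inject
#'
#' Each effect is a per-CpG beta-scale methylation difference
#' (smoker - nonsmoker) attributed either to a single cell type or to all
#' types ("all"). Effect signs point toward the interior of [0, 1] (a CpG
#' methylated above 0.5 loses methylation, and vice versa) so the injected
#' delta is realized without clamping; this matches the predominance of
#' smoking-associated hypomethylation at highly methylated CpGs.
#'
#' @param panel `ref_panel` to pick CpGs from.
#' @param n_effects number of affected CpGs (all distinct).
#' @param delta_range range of |delta| on the beta scale.
#' @param prop_all probability an effect is shared across all cell types.
#' @param cell_types types to draw from for non-shared effects.
#' @param seed integer seed (required).
#' @return data.frame with `cpg_id`, `cell_type` ("all" or a label),
#'   `delta`, `mechanism` ("direct").
#' @export
make_effects <- function(panel, n_effects, delta_range = c(0.02, 0.15),
                         prop_all = 0.4, cell_types = colnames(panel$profiles),
                         seed) {
  seed <- check_seed(seed)
  stopifnot(inherits(panel, "ref_panel"),
            n_effects <= nrow(panel$profiles))
  withr::with_seed(seed, {
    cpgs <- sample(rownames(panel$profiles), n_effects)
    ct <- ifelse(stats::runif(n_effects) < prop_all, "all",
                 sample(cell_types, n_effects, replace = TRUE))
    mag <- stats::runif(n_effects, delta_range[1], delta_range[2])
    mean_beta <- rowMeans(panel$profiles[cpgs, , drop = FALSE])
    data.frame(cpg_id = cpgs, cell_type = ct,
               delta = ifelse(mean_beta > 0.5, -mag, mag),
               mechanism = "direct", stringsAsFactors = FALSE)
  })
}
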