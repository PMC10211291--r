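# Paper-anchored simulation experiments. These wire the full pipeline
# together under the study's stated conditions (cohort of 74 nonsmokers and
# 67 smokers, logit noise SD 0.1, Dirichlet concentration 200) and are used
# by both the acceptance tests and scripts/acceptance.R.

#' Composite-decomposition benchmark
#'
#' Simulates the full cohort (74 nonsmokers + 67 smokers by default) with
#' whole blood generated as a Dirichlet(concentration 200) mixture of the
#' six cell types around the composite-equation weights, injects
#' `n_effects` smoking effects of mixed cell-type origin (|delta| in
#' `delta_range`), runs the robust-regression EWAS in every isolated
#' fraction and in whole blood, builds the proportion-weighted composite
#' effect with the printed weights, and correlates it with the measured
#' whole-blood effect at the whole-blood Bonferroni-significant CpGs.
#'
#' @param seed integer seed driving every random draw.
#' @param n_cpgs panel size.
#' @param n_nonsmokers,n_smokers cohort sizes.
#' @param n_effects number of injected smoking-affected CpGs.
#' @param delta_range injected |delta| range on the beta scale.
#' @param noise_sd logit-scale measurement noise SD.
#' @return list with `r`, `p`, `n_sig` (whole-blood Bonferroni CpGs used),
#'   `slope_composite_on_wb`, and the per-CpG `composite` / `wb_delta`
#'   vectors.
#' @export
composite_benchmark <- function(seed, n_cpgs = 600, n_nonsmokers = 74,
                                n_smokers = 67, n_effects = 74,
                                delta_range = c(0.02, 0.15),
                                noise_sd = 0.1) {
  seed <- check_seed(seed)
  specs <- wb_celltypes()
  panel <- make_reference_panel(n_cpgs, specs, 20, seed = seed)
  cohort <- make_cohort(n_nonsmokers, n_smokers, seed = seed + 1)
  effects <- make_effects(panel, n_effects, delta_range, seed = seed + 2)
  sim <- simulate_methylomes(panel, cohort, specs, effects,
                             noise_sd = noise_sd, dirichlet_conc = 200,
                             purity = 1, seed = seed + 3)
  results <- lapply(sim$fractions, function(beta) {
    multiple_testing(fit_ewas(beta, cohort), n_tests = n_cpgs)
  })
  delta_mat <- sapply(results[specs$name], `[[`, "delta_meth")
  rownames(delta_mat) <- results$WB$cpg_id
  comp <- composite_delta(delta_mat)
  wb_delta <- stats::setNames(results$WB$delta_meth, results$WB$cpg_id)
  sig <- results$WB$cpg_id[results$WB$bonferroni]
  cmp <- compare_to_wholeblood(comp, wb_delta, sig)
  list(r = cmp$r, p = cmp$p, n_sig = cmp$n,
       slope_composite_on_wb = cmp$slope_composite_on_wb,
       composite = comp, wb_delta = wb_delta, effects = effects)
}

#' Naive-to-memory B cell shift recovery benchmark
#'
#' Configures the generator with the published group means for naive and
#' memory B cells within the isolated B-cell fraction (nonsmokers 60.0% /
#' 31.3%, smokers 52.8% / 36.0%), simulates the B fraction for the cohort
#' over `n_seeds` replicates at logit noise SD 0.1, estimates subtype
#' proportions with a 12-subtype synthetic reference panel by constrained
#' projection, and measures the smoker-minus-nonsmoker difference in mean
#' estimated naive-B percent.
#'
#' @param seed integer master seed; replicate seeds are derived from it.
#' @param n_seeds number of Monte-Carlo replicates.
#' @param n_cpgs panel size.
#' @param n_nonsmokers,n_smokers cohort sizes.
#' @param naive_mean_ns,naive_mean_sm,memory_mean_ns,memory_mean_sm group
#'   mean subtype fractions within the B-cell fraction.
#' @param noise_sd logit-scale measurement noise SD.
#' @return list with `diff_mean` (mean smoker - nonsmoker difference in
#'   percentage points), `abs_diff` (its magnitude), `mc_se` (Monte-Carlo
#'   standard error of the mean), `injected` (the injected difference), and
#'   the per-seed `diffs`.
#' @export
shift_benchmark <- function(seed, n_seeds = 20, n_cpgs = 600,
                            n_nonsmokers = 74, n_smokers = 67,
                            naive_mean_ns = 0.600, naive_mean_sm = 0.528,
                            memory_mean_ns = 0.313, memory_mean_sm = 0.360,
                            noise_sd = 0.1) {
  seed <- check_seed(seed)
  specs <- wb_celltypes()
  panel <- make_reference_panel(n_cpgs, specs, 20, seed = seed)
  spanel <- make_subtype_panel(panel, n_signature_per_type = 15,
                               seed = seed + 1)
  sig_panel <- select_signature_cpgs(spanel, 15)
  b_config <- list(naive_mean_ns = naive_mean_ns,
                   naive_mean_sm = naive_mean_sm,
                   memory_mean_ns = memory_mean_ns,
                   memory_mean_sm = memory_mean_sm)
  diffs <- vapply(seq_len(n_seeds), function(i) {
    s <- seed + 7919L * i
    cohort <- make_cohort(n_nonsmokers, n_smokers, seed = s)
    sim <- simulate_methylomes(panel, cohort, specs,
                               noise_sd = noise_sd, dirichlet_conc = 200,
                               subtype_panel = spanel, b_config = b_config,
                               fractions = "Bcell", seed = s + 1)
    props <- estimate_proportions(sim$fractions$Bcell, sig_panel)
    sm <- cohort$smoking == 1
    100 * (mean(props$NaiveB[sm]) - mean(props$NaiveB[!sm]))
  }, 0)
  list(diff_mean = mean(diffs), abs_diff = abs(mean(diffs)),
       mc_se = stats::sd(diffs) / sqrt(n_seeds),
       injected = 100 * (naive_mean_sm - naive_mean_ns), diffs = diffs)
}
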