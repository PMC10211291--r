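# Whole-blood smoking effects reconstructed as proportion-weighted sums of
# per-cell-type effects, and agreement with the measured whole-blood EWAS.

#' Default composite weights (average cell-type proportions)
#'
#' B cell 0.073, granulocyte 0.55, monocyte 0.037, NK 0.060, CD4T 0.20,
#' CD8T 0.087. The weights sum to 1.007 and are deliberately not
#' renormalized by default, reproducing the published arithmetic as stated.
#'
#' @return named numeric vector of weights.
#' @export
composite_weights <- function() {
  c(Bcell = 0.073, Gran = 0.55, Mono = 0.037, NK = 0.060,
    CD4T = 0.20, CD8T = 0.087)
}

#' Myeloid / lymphoid grouping of the six cell types
#' @return named list with `myeloid` and `lymphoid` label vectors.
#' @export
lineage_groups <- function() {
  list(myeloid = c("Gran", "Mono"),
       lymphoid = c("Bcell", "NK", "CD4T", "CD8T"))
}

#' Proportion-weighted composite effect per CpG
#'
#' For each CpG, multiplies the per-cell-type effect size (delta methylation)
#' by the average cell-type proportion and sums over the requested subset.
#' Subset composites use the full-blood weights (not renormalized within the
#' subset), so myeloid + lymphoid composites sum to the all-types composite.
#'
#' @param delta_by_celltype CpG x cell-type matrix of effect sizes.
#' @param weights named weight vector (default [composite_weights()]).
#' @param subset "all", "myeloid" or "lymphoid".
#' @param renormalize if `TRUE`, weights are divided by their total sum
#'   before use (off by default).
#' @return named numeric vector of composite effects per CpG.
#' @export
composite_delta <- function(delta_by_celltype, weights = composite_weights(),
                            subset = c("all", "myeloid", "lymphoid"),
                            renormalize = FALSE) {
  subset <- match.arg(subset)
  if (renormalize) weights <- weights / sum(weights)
  keep <- switch(subset, all = names(weights),
                 myeloid = lineage_groups()$myeloid,
                 lymphoid = lineage_groups()$lymphoid)
  missing_ct <- setdiff(keep, colnames(delta_by_celltype))
  if (length(missing_ct) > 0) {
    stop("missing cell type(s) for subset '", subset, "': ",
         paste(missing_ct, collapse = ", "), call. = FALSE)
  }
  drop(delta_by_celltype[, keep, drop = FALSE] %*% weights[keep])
}

#' Compare composite effects with measured whole-blood effects
#'
#' Pearson correlation (two-sided p from the t transform with n - 2 df) and
#' ordinary least-squares slopes in both orientations, restricted to a CpG
#' set (typically the whole-blood Bonferroni-significant CpGs).
#'
#' @param composite named per-CpG composite effects.
#' @param wb_delta named per-CpG whole-blood effect sizes.
#' @param cpg_set CpG ids to compare on (>= 3).
#' @return list with `r`, `p`, `n`, `slope_composite_on_wb`,
#'   `slope_wb_on_composite`.
#' @export
compare_to_wholeblood <- function(composite, wb_delta, cpg_set) {
  cpg_set <- intersect(cpg_set, intersect(names(composite), names(wb_delta)))
  if (length(cpg_set) < 3) stop("need at least 3 CpGs in the set",
                                call. = FALSE)
  x <- wb_delta[cpg_set]
  y <- composite[cpg_set]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = length(cpg_set),
                slope_composite_on_wb = NA_real_,
                slope_wb_on_composite = NA_real_))
  }
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(cpg_set),
       slope_composite_on_wb = unname(stats::coef(stats::lm(y ~ x))[2]),
       slope_wb_on_composite = unname(stats::coef(stats::lm(x ~ y))[2]))
}
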