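#' Quality-control filtering of a beta matrix
#'
#' Drops samples whose fraction of detection failures exceeds
#' `sample_fail_frac` (default 5%), then drops blacklisted CpGs and any CpG
#' with a remaining detection failure. Mirrors the usual array QC order:
#' bad samples first, so a failure concentrated in one sample does not cost
#' the probe for everyone else.
#'
#' @param beta CpG x sample beta matrix.
#' @param detection_fail logical CpG x sample matrix of detection failures,
#'   aligned with `beta`; `NULL` means no failures.
#' @param blacklist character vector of CpG ids to remove (e.g.
#'   cross-reactive or SNP-overlapping probes).
#' @param sample_fail_frac samples with failure fraction strictly greater
#'   than this are dropped.
#' @return list with `beta` (filtered matrix) and `report` (data.frame of
#'   dropped ids with a `reason` column).
#' @export
apply_qc <- function(beta, detection_fail = NULL, blacklist = character(),
                     sample_fail_frac = 0.05) {
  check_beta_matrix(beta)
  if (is.null(detection_fail)) {
    detection_fail <- matrix(FALSE, nrow(beta), ncol(beta),
                             dimnames = dimnames(beta))
  }
  if (!identical(dim(detection_fail), dim(beta))) {
    stop("detection_fail must be aligned with beta", call. = FALSE)
  }
  report <- data.frame(id = character(), kind = character(),
                       reason = character(), stringsAsFactors = FALSE)

  fail_frac <- colMeans(detection_fail)
  bad_samples <- colnames(beta)[fail_frac > sample_fail_frac]
  if (length(bad_samples) == ncol(beta)) {
    stop("all samples failed QC", call. = FALSE)
  }
  if (length(bad_samples) > 0) {
    report <- rbind(report, data.frame(
      id = bad_samples, kind = "sample",
      reason = sprintf("failure fraction %.3f > %.3f",
                       fail_frac[bad_samples], sample_fail_frac),
      stringsAsFactors = FALSE))
    keep <- setdiff(colnames(beta), bad_samples)
    beta <- beta[, keep, drop = FALSE]
    detection_fail <- detection_fail[, keep, drop = FALSE]
  }

  bl <- intersect(rownames(beta), blacklist)
  failed_cpg <- rownames(beta)[rowSums(detection_fail) > 0]
  failed_cpg <- setdiff(failed_cpg, bl)
  if (length(bl) > 0) {
    report <- rbind(report, data.frame(id = bl, kind = "cpg",
                                       reason = "blacklisted",
                                       stringsAsFactors = FALSE))
  }
  if (length(failed_cpg) > 0) {
    report <- rbind(report, data.frame(id = failed_cpg, kind = "cpg",
                                       reason = "detection failure",
                                       stringsAsFactors = FALSE))
  }
  drop_cpg <- union(bl, failed_cpg)
  beta <- beta[setdiff(rownames(beta), drop_cpg), , drop = FALSE]
  list(beta = beta, report = report)
}
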