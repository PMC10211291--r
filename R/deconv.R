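# Reference-based cell-type deconvolution by constrained projection:
# per sample, nonnegative least squares of observed betas against the
# reference profiles, with the proportion sum constrained to <= 1 (the
# classical constraint, tolerating unmodeled cell content) or == 1.

#' Select signature CpGs for a reference panel
#'
#' One-vs-rest selection: for each cell type, keeps the `k_per_type` CpGs
#' with the largest absolute difference between the type's beta and the mean
#' of all other types, taking half from each sign where available. Ties are
#' broken by CpG id (lexicographic), so selection is deterministic.
#'
#' @param panel `ref_panel` (any CpG universe).
#' @param k_per_type CpGs to keep per type (>= 1).
#' @return `ref_panel` restricted to the union of selected CpGs; its
#'   `signature` lists the selection per type.
#' @export
select_signature_cpgs <- function(panel, k_per_type) {
  stopifnot(inherits(panel, "ref_panel"), k_per_type >= 1)
  prof <- panel$profiles
  k_types <- ncol(prof)
  ids <- rownames(prof)
  sel <- vector("list", k_types)
  names(sel) <- colnames(prof)
  for (j in seq_len(k_types)) {
    diff <- prof[, j] - rowMeans(prof[, -j, drop = FALSE])
    ord <- order(-abs(diff), ids)
    n_hi <- ceiling(k_per_type / 2)
    hi <- ord[diff[ord] > 0][seq_len(n_hi)]
    lo <- ord[diff[ord] < 0][seq_len(k_per_type - n_hi)]
    pick <- stats::na.omit(c(hi, lo))
    # not enough of one sign: fill from the overall ranking
    if (length(pick) < k_per_type) {
      pick <- union(pick, ord)[seq_len(min(k_per_type, length(ord)))]
    }
    sel[[j]] <- sort(ids[pick])
  }
  keep <- sort(unique(unlist(sel)))
  if (k_per_type > nrow(prof)) {
    warning("k_per_type exceeds available CpGs; keeping all")
  }
  structure(list(profiles = prof[keep, , drop = FALSE],
                 signature = sel,
                 annot = panel$annot[panel$annot$cpg_id %in% keep, ,
                                     drop = FALSE]),
            class = "ref_panel")
}

# quadratic program for one sample: min ||A w - b||^2 s.t. w >= 0 and
# sum(w) <= 1 (or == 1). Solved exactly with quadprog.
project_proportions <- function(A, b, constraint) {
  k <- ncol(A)
  Dmat <- crossprod(A)
  dvec <- crossprod(A, b)
  if (constraint == "sum_eq_1") {
    Amat <- cbind(rep(1, k), diag(k))
    bvec <- c(1, rep(0, k))
    meq <- 1L
  } else {
    Amat <- cbind(-rep(1, k), diag(k))
    bvec <- c(-1, rep(0, k))
    meq <- 0L
  }
  # ridge jitter only if the QP is numerically singular on this overlap
  sol <- tryCatch(
    quadprog::solve.QP(Dmat, dvec, Amat, bvec, meq = meq),
    error = function(e) quadprog::solve.QP(
      Dmat + diag(1e-10, k), dvec, Amat, bvec, meq = meq))
  w <- pmax(sol$solution, 0)
  names(w) <- colnames(A)
  w
}

#' Estimate cell-type proportions by constrained projection
#'
#' @param beta CpG x sample beta matrix (mixtures to decompose).
#' @param panel `ref_panel` of reference profiles; estimation uses the
#'   overlap of its CpGs with `beta` (warning below 50% overlap).
#' @param constraint "sum_le_1" (default; classical projection constraint)
#'   or "sum_eq_1".
#' @return data.frame with `sample_id`, one proportion column per panel cell
#'   type, and `residual` (Euclidean norm of the fit residual).
#' @export
estimate_proportions <- function(beta, panel,
                                 constraint = c("sum_le_1", "sum_eq_1")) {
  constraint <- match.arg(constraint)
  check_beta_matrix(beta)
  stopifnot(inherits(panel, "ref_panel"))
  common <- intersect(rownames(panel$profiles), rownames(beta))
  if (length(common) < 1) stop("no overlapping CpGs with panel", call. = FALSE)
  if (length(common) < 0.5 * nrow(panel$profiles)) {
    warning("fewer than 50% of panel CpGs found in the beta matrix")
  }
  A <- panel$profiles[common, , drop = FALSE]
  if (qr(A)$rank < ncol(A)) {
    stop("reference panel is rank-deficient on the overlapping CpGs",
         call. = FALSE)
  }
  B <- beta[common, , drop = FALSE]
  res <- t(vapply(seq_len(ncol(B)), function(i) {
    w <- project_proportions(A, B[, i], constraint)
    c(w, residual = sqrt(sum((B[, i] - A %*% w)^2)))
  }, numeric(ncol(A) + 1)))
  data.frame(sample_id = colnames(B), res,
             stringsAsFactors = FALSE, check.names = FALSE, row.names = NULL)
}

#' Test a smoking-associated subtype proportion shift
#'
#' Ordinary least squares of estimated subtype percent on smoking status,
#' reported both unadjusted and adjusted for covariates. `p_adjusted_covariates`
#' is the covariate-adjusted regression p value, not a multiple-testing
#' adjustment. Percentages are by default the raw estimated percent of the
#' fraction; pass `renormalize_to` (e.g. `c("NaiveB", "MemB")`) to express
#' the subtype as percent of that lineage total instead.
#'
#' @param props proportion table from [estimate_proportions()].
#' @param sheet subject/sample sheet with `smoking` and covariate columns;
#'   matched to `props$sample_id` via its `sample_id` or `subject_id`.
#' @param subtype subtype column of `props` to test.
#' @param adjust covariate column names for the adjusted model (default
#'   age, sex, ancestry, bmi).
#' @param renormalize_to optional character vector of subtype columns whose
#'   sum defines the denominator.
#' @return one-row data.frame: `subtype`, `mean_ns`, `se_ns`, `mean_sm`,
#'   `se_sm`, `diff` (smoker - nonsmoker, percentage points), `p`,
#'   `p_adjusted_covariates`.
#' @export
subtype_shift_test <- function(props, sheet, subtype,
                               adjust = c("age", "sex", "ancestry", "bmi"),
                               renormalize_to = NULL) {
  if (!subtype %in% names(props)) {
    stop("subtype '", subtype, "' not in proportion table", call. = FALSE)
  }
  key <- if ("sample_id" %in% names(sheet)) "sample_id" else "subject_id"
  idx <- match(props$sample_id, sheet[[key]])
  if (any(is.na(idx))) stop("proportion table has samples missing from sheet",
                            call. = FALSE)
  sheet <- sheet[idx, , drop = FALSE]
  y <- props[[subtype]]
  if (!is.null(renormalize_to)) {
    denom <- rowSums(props[, renormalize_to, drop = FALSE])
    y <- y / denom
  }
  y <- 100 * y
  smoking <- sheet$smoking
  if (min(table(smoking)) < 3) stop("need >= 3 samples per group",
                                    call. = FALSE)
  if (stats::var(y) == 0) {
    warning("constant proportions; p undefined, reported as 1")
    return(data.frame(subtype = subtype, mean_ns = mean(y), se_ns = 0,
                      mean_sm = mean(y), se_sm = 0, diff = 0, p = 1,
                      p_adjusted_covariates = 1, stringsAsFactors = FALSE))
  }
  fit0 <- stats::lm(y ~ smoking)
  s0 <- summary(fit0)$coefficients["smoking", ]
  df_adj <- data.frame(y = y, smoking = smoking, sheet[, adjust, drop = FALSE])
  fit1 <- stats::lm(y ~ ., data = df_adj)
  s1 <- summary(fit1)$coefficients["smoking", ]
  ns <- y[smoking == 0]
  sm <- y[smoking == 1]
  data.frame(subtype = subtype,
             mean_ns = mean(ns), se_ns = stats::sd(ns) / sqrt(length(ns)),
             mean_sm = mean(sm), se_sm = stats::sd(sm) / sqrt(length(sm)),
             diff = unname(s0["Estimate"]),
             p = unname(s0["Pr(>|t|)"]),
             p_adjusted_covariates = unname(s1["Pr(>|t|)"]),
             stringsAsFactors = FALSE)
}
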