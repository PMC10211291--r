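# Per-CpG smoking EWAS on M-values with Huber robust regression, per cell
# fraction, plus multiple-testing control, cell-type-specificity calls and
# directional concordance across fractions.

#' M-value transform
#'
#' `log2(beta / (1 - beta))` after clamping beta to `[eps, 1 - eps]`;
#' strictly monotone in beta and finite everywhere.
#'
#' @param beta beta matrix or vector.
#' @param eps clamp width in (0, 0.5).
#' @return object of the same shape on the M (log2-ratio) scale.
#' @export
mvalue_transform <- function(beta, eps = 1e-6) {
  stopifnot(eps > 0, eps < 0.5)
  logit2(clamp_beta(beta, eps))
}

#' Inverse M-value transform
#' @param m M-value matrix or vector.
#' @return beta values in (0, 1).
#' @export
mvalue_inverse <- function(m) ilogit2(m)

#' Winsorize each CpG row
#'
#' Per row, values below the `total_fraction/2` quantile are set to that
#' quantile and values above the `1 - total_fraction/2` quantile to that
#' quantile (type-7 quantiles). `total_fraction = 0.10` is the conventional
#' "90% winsorization".
#'
#' @param m numeric matrix (CpG x sample).
#' @param total_fraction total trimmed mass in `[0, 0.5)`.
#' @return winsorized matrix.
#' @export
winsorize_rows <- function(m, total_fraction = 0.10) {
  stopifnot(total_fraction >= 0, total_fraction < 0.5)
  if (total_fraction == 0) return(m)
  lo_q <- total_fraction / 2
  t(apply(m, 1, function(x) {
    q <- stats::quantile(x, c(lo_q, 1 - lo_q), type = 7, names = FALSE)
    pmin(pmax(x, q[1]), q[2])
  }))
}

# Build the EWAS design matrix: smoking + age + sex + ancestry (one-hot,
# first level dropped) + bmi + contaminant proportions. The fraction's own
# cell-type column is dropped to avoid collinearity with the intercept;
# with no own type (whole blood), the largest-mean proportion is dropped.
build_design <- function(sheet, contamination = NULL, own_type = NULL) {
  X <- cbind(`(Intercept)` = 1, smoking = sheet$smoking, age = sheet$age,
             sexM = as.integer(sheet$sex == "M"))
  anc <- sort(unique(sheet$ancestry))
  for (a in anc[-1]) {
    X <- cbind(X, as.integer(sheet$ancestry == a))
    colnames(X)[ncol(X)] <- paste0("ancestry", a)
  }
  X <- cbind(X, bmi = sheet$bmi)
  if (!is.null(contamination)) {
    pc <- contamination[match(sheet$subject_id %||% sheet$sample_id,
                              contamination$sample_id), , drop = FALSE]
    prop_cols <- setdiff(names(pc), c("sample_id", "residual"))
    drop <- if (!is.null(own_type) && own_type %in% prop_cols) {
      own_type
    } else {
      prop_cols[which.max(colMeans(pc[prop_cols]))]
    }
    for (ct in setdiff(prop_cols, drop)) {
      # contaminants estimated as (near-)zero for everyone carry no
      # information and would make the design singular
      if (stats::var(pc[[ct]]) < 1e-10) next
      X <- cbind(X, pc[[ct]])
      colnames(X)[ncol(X)] <- paste0("prop_", ct)
    }
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; aliased columns: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  X
}

#' Fit a per-CpG robust-regression EWAS for one fraction
#'
#' For each CpG, the M-value is regressed on smoking plus covariates (age,
#' sex, ancestry one-hot, BMI) and, when supplied, the estimated contaminant
#' cell-type proportions, using Huber M-estimation (tuning constant 1.345,
#' MAD scale, iterated to relative coefficient change < 1e-8 or 100
#' iterations). Two-sided p values come from the t distribution with
#' `n - parameters` degrees of freedom. `delta_meth` is always computed from
#' the raw (unwinsorized) betas as smoker mean minus nonsmoker mean.
#' Non-converging fits fall back to ordinary least squares and are flagged.
#'
#' @param beta CpG x sample beta matrix for the fraction.
#' @param sheet subject table aligned to `colnames(beta)` via `subject_id`
#'   (or `sample_id`).
#' @param contamination optional proportion table ([estimate_proportions()])
#'   used as covariates.
#' @param own_type fraction's own cell type, dropped from the contaminant
#'   covariates; `NULL` for whole blood.
#' @param winsorize if `TRUE`, M-values are 90% winsorized per CpG before
#'   fitting.
#' @param eps clamp for the M transform.
#' @return data.frame with `cpg_id`, `coefficient` (M-scale smoking effect),
#'   `se`, `p`, `q` (NA until [multiple_testing()]), `bonferroni`,
#'   `delta_meth`, `n_used`, `converged`.
#' @export
fit_ewas <- function(beta, sheet, contamination = NULL, own_type = NULL,
                     winsorize = FALSE, eps = 1e-6) {
  check_beta_matrix(beta)
  check_sample_sheet(sheet)
  key <- if (all(colnames(beta) %in% sheet$subject_id)) "subject_id"
         else "sample_id"
  idx <- match(colnames(beta), sheet[[key]])
  if (any(is.na(idx))) stop("beta columns missing from sample sheet",
                            call. = FALSE)
  sheet <- sheet[idx, , drop = FALSE]
  n <- ncol(beta)
  if (n < 10) stop("need at least 10 samples", call. = FALSE)
  X <- build_design(sheet, contamination, own_type)
  p_par <- ncol(X)
  m <- mvalue_transform(beta, eps)
  if (winsorize) m <- winsorize_rows(m)
  smoker <- sheet$smoking == 1L

  xtx_inv <- chol2inv(chol(crossprod(X)))
  i_smk <- match("smoking", colnames(X))

  fit_one <- function(y) {
    ls <- stats::lm.fit(X, y)
    # an (essentially) exact least-squares fit has MAD scale 0; the Huber
    # estimate coincides with least squares there, so report it as converged
    exact <- stats::mad(ls$residuals) < 1e-10
    # non-convergence is reported through the `converged` column, so
    # rlm's own warning would only add noise
    fit <- if (exact) NULL else tryCatch(
      withCallingHandlers(
        MASS::rlm(X, y, psi = MASS::psi.huber, k = 1.345,
                  scale.est = "MAD", maxit = 100, acc = 1e-8),
        warning = function(w) {
          if (grepl("failed to converge", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        }),
      error = function(e) NULL)
    converged <- exact || (!is.null(fit) && isTRUE(fit$converged))
    if (is.null(fit) || !isTRUE(fit$converged)) {
      sig2 <- sum(ls$residuals^2) / (n - p_par)
      b <- ls$coefficients["smoking"]
      se <- sqrt(sig2 * xtx_inv[i_smk, i_smk])
    } else {
      s <- summary(fit, method = "XtX")
      b <- s$coefficients["smoking", "Value"]
      se <- s$coefficients["smoking", "Std. Error"]
    }
    tval <- b / se
    c(b, se, 2 * stats::pt(-abs(tval), df = n - p_par), as.numeric(converged))
  }

  res <- t(apply(m, 1, fit_one))
  data.frame(cpg_id = rownames(beta),
             coefficient = res[, 1], se = res[, 2],
             p = pmin(pmax(res[, 3], .Machine$double.xmin), 1),
             q = NA_real_, bonferroni = NA,
             delta_meth = rowMeans(beta[, smoker, drop = FALSE]) -
               rowMeans(beta[, !smoker, drop = FALSE]),
             n_used = n, converged = res[, 4] == 1,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Genome-wide Bonferroni threshold
#' @param n_tests number of tests (CpG probes).
#' @param alpha family-wise error rate.
#' @return the threshold `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) alpha / n_tests

#' Multiple-testing annotation of an EWAS result
#'
#' Adds Benjamini-Hochberg q values (over `n_tests` tests) and the
#' Bonferroni significance flag at `alpha / n_tests`.
#'
#' @param results data.frame from [fit_ewas()].
#' @param n_tests number of tests; defaults to `nrow(results)` and may be
#'   overridden (e.g. 420000 to reproduce an array-scale threshold).
#' @param alpha family-wise / FDR level.
#' @return `results` with `q` and `bonferroni` filled in; the threshold is
#'   attached as attribute `bonferroni_threshold`.
#' @export
multiple_testing <- function(results, n_tests = nrow(results), alpha = 0.05) {
  stopifnot(n_tests >= nrow(results))
  results$q <- stats::p.adjust(results$p, method = "BH", n = n_tests)
  thr <- bonferroni_threshold(n_tests, alpha)
  results$bonferroni <- results$p < thr
  attr(results, "bonferroni_threshold") <- thr
  results
}

#' Classify cell-type specificity of CpGs across fractions
#'
#' A CpG is cell-type specific when it is significant (at the supplied
#' threshold) in exactly one cell type, and highly specific when its
#' best (minimum) p value times `ratio` is still no larger than the p value
#' in every other cell type, i.e. at least a `ratio`-fold p-value separation
#' (>= log10(ratio) difference in -log10 p). Ties for the best p value are
#' never highly specific.
#'
#' @param p_mat CpG x cell-type matrix of p values (NA = type missing, which
#'   excludes it from comparison for that CpG).
#' @param sig_mat logical matrix of the same shape: significance at the
#'   chosen threshold (Bonferroni or FDR 5%).
#' @param ratio required p-value ratio for high specificity.
#' @return data.frame: `cpg_id`, `significant_in` (comma list),
#'   `cell_type_specific`, `highly_specific`, `best_cell_type`.
#' @export
classify_specificity <- function(p_mat, sig_mat, ratio = 1e4) {
  stopifnot(identical(dim(p_mat), dim(sig_mat)), ncol(p_mat) >= 2)
  types <- colnames(p_mat)
  out <- lapply(seq_len(nrow(p_mat)), function(i) {
    p <- p_mat[i, ]
    sig <- sig_mat[i, ] & !is.na(p)
    avail <- which(!is.na(p))
    sig_in <- types[which(sig)]
    if (length(avail) == 0) {
      return(data.frame(cpg_id = rownames(p_mat)[i], significant_in = "",
                        cell_type_specific = FALSE, highly_specific = FALSE,
                        best_cell_type = NA_character_,
                        stringsAsFactors = FALSE))
    }
    best <- avail[which.min(p[avail])]
    tie <- sum(p[avail] == p[best]) > 1
    highly <- !tie && length(avail) >= 2 &&
      all(p[best] * ratio <= p[setdiff(avail, best)])
    data.frame(cpg_id = rownames(p_mat)[i],
               significant_in = paste(sig_in, collapse = ","),
               cell_type_specific = length(sig_in) == 1,
               highly_specific = highly,
               best_cell_type = if (tie) NA_character_ else types[best],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Directional concordance of effects across cell types
#'
#' Per CpG, counts the cell types sharing the majority sign of `delta_meth`;
#' zero deltas count as neither sign, exact ties report sign `"±"` with
#' the tied count.
#'
#' @param delta_mat CpG x cell-type matrix of beta-scale effect sizes.
#' @return data.frame: `cpg_id`, `concordant_n`, `majority_sign`
#'   ("+", "-", or "±").
#' @export
directional_concordance <- function(delta_mat) {
  stopifnot(ncol(delta_mat) >= 2)
  out <- t(apply(delta_mat, 1, function(d) {
    n_pos <- sum(d > 0, na.rm = TRUE)
    n_neg <- sum(d < 0, na.rm = TRUE)
    if (n_pos > n_neg) c(n_pos, "+")
    else if (n_neg > n_pos) c(n_neg, "-")
    else c(n_pos, "±")
  }))
  data.frame(cpg_id = rownames(delta_mat),
             concordant_n = as.integer(out[, 1]),
             majority_sign = out[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}
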