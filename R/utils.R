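# Internal helpers shared across modules.

#' Clamp methylation proportions away from 0 and 1
#'
#' @param x numeric vector or matrix of beta values.
#' @param eps clamp width; values are forced into `[eps, 1 - eps]`.
#' @return object of the same shape with values in `[eps, 1 - eps]`.
#' @keywords internal
clamp_beta <- function(x, eps = 1e-6) {
  stopifnot(is.numeric(eps), length(eps) == 1L, eps > 0, eps < 0.5)
  pmin(pmax(x, eps), 1 - eps)
}

logit2 <- function(b) log2(b / (1 - b))
ilogit2 <- function(m) {
  p <- 2^m
  p / (1 + p)
}

# All generators demand an explicit seed: silent reliance on the global RNG
# state makes synthetic cohorts irreproducible.
check_seed <- function(seed) {
  if (missing(seed) || is.null(seed) || length(seed) != 1L || is.na(seed) ||
      !is.numeric(seed) || seed != round(seed)) {
    stop("an explicit integer `seed` is required", call. = FALSE)
  }
  as.integer(seed)
}

# Dirichlet draws via normalized gammas; alpha is the concentration vector.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Validate a beta matrix: numeric, named dims, unique ids, values in [0,1].
check_beta_matrix <- function(beta, what = "beta") {
  if (!is.matrix(beta) || !is.numeric(beta)) {
    stop(what, " must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(beta)) || is.null(colnames(beta))) {
    stop(what, " must have CpG rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(beta))) stop("duplicate CpG ids", call. = FALSE)
  if (anyDuplicated(colnames(beta))) stop("duplicate sample ids", call. = FALSE)
  bad <- which(is.na(beta) | beta < 0 | beta > 1, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("beta out of range [0,1] at CpG '%s', sample '%s'",
                 rownames(beta)[bad[1, 1]], colnames(beta)[bad[1, 2]]),
         call. = FALSE)
  }
  invisible(beta)
}

check_sample_sheet <- function(sheet) {
  need <- c("subject_id", "smoking", "age", "sex", "ancestry", "bmi")
  miss <- setdiff(need, names(sheet))
  if (length(miss) > 0) {
    stop("sample sheet missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sheet$subject_id)) {
    stop("duplicate subject ids in sample sheet", call. = FALSE)
  }
  if (!all(sheet$smoking %in% c(0L, 1L))) {
    stop("smoking must be coded 0/1", call. = FALSE)
  }
  if (any(is.na(sheet[need]))) {
    stop("missing covariate values are not allowed; refusing to impute",
         call. = FALSE)
  }
  invisible(sheet)
}
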