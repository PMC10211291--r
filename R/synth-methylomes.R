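#' Simulate per-fraction methylomes and whole blood with known truth
#'
#' For every subject, true whole-blood cell-type proportions are drawn from
#' a Dirichlet distribution centered at the configured mean proportions
#' (concentration `dirichlet_conc`). Each isolated fraction is generated as
#' `purity x own profile + (1 - purity) x contaminant mix` (contaminants in
#' proportion to their whole-blood means); whole blood is the per-subject
#' proportion-weighted mixture of the cell-type profiles. Direct smoking
#' effects add their beta-scale delta to the affected cell-type profile
#' (or all profiles for `cell_type == "all"`) before mixing, for smokers
#' only. Measurement noise is Gaussian on the logit (M) scale, then
#' inverse-transformed; all betas are clamped to `[1e-6, 1 - 1e-6]`.
#'
#' When `subtype_panel` and `b_config` are supplied, the B-cell fraction is
#' instead composed from 12 leukocyte subtype profiles: per subject, subtype
#' shares are drawn from a Dirichlet centered at the smoking-group means
#' (naive/memory B means from `b_config`, remaining mass spread equally over
#' the other subtypes), which implements the smoking-linked naive-to-memory
#' shift as a proportion change, not a per-CpG delta.
#'
#' @param panel `ref_panel` over the cell types in `specs`.
#' @param cohort subject table from [make_cohort()].
#' @param specs cell-type composition (see [wb_celltypes()]).
#' @param effects data.frame from [make_effects()], or `NULL`.
#' @param noise_sd logit-scale Gaussian measurement noise SD.
#' @param dirichlet_conc concentration of the proportion Dirichlet; 200 keeps
#'   subjects tightly around the means.
#' @param purity optional named vector overriding `specs$purity` (e.g.
#'   `c(Bcell = 1)` or a single unnamed value for all types).
#' @param subtype_panel optional `ref_panel` over 12 subtypes sharing the
#'   CpG universe of `panel`.
#' @param b_config list with `naive`, `memory` (subtype labels),
#'   `naive_mean_ns`, `naive_mean_sm`, `memory_mean_ns`, `memory_mean_sm`
#'   (fractions of the B-cell fraction) and optionally `conc`.
#' @param fractions which matrices to generate (subset of the cell types
#'   plus "WB"); default all.
#' @param seed integer seed (required).
#' @return list with `fractions` (named list of CpG x subject beta matrices)
#'   and `truth` (`wb_proportions`, `b_subtype_shares`, `effects`).
#' @export
simulate_methylomes <- function(panel, cohort, specs = wb_celltypes(),
                                effects = NULL, noise_sd = 0.1,
                                dirichlet_conc = 200, purity = NULL,
                                subtype_panel = NULL, b_config = NULL,
                                fractions = NULL, seed) {
  seed <- check_seed(seed)
  stopifnot(inherits(panel, "ref_panel"), noise_sd >= 0)
  check_sample_sheet(cohort)
  types <- specs$name
  if (!all(types %in% colnames(panel$profiles))) {
    stop("panel is missing profiles for: ",
         paste(setdiff(types, colnames(panel$profiles)), collapse = ", "),
         call. = FALSE)
  }
  if (abs(sum(specs$mean_proportion) - 1) > 0.01) {
    stop("mean proportions must sum to 1 +/- 0.01", call. = FALSE)
  }
  pur <- specs$purity
  names(pur) <- types
  if (!is.null(purity)) {
    if (is.null(names(purity))) pur[] <- purity else pur[names(purity)] <- purity
  }
  if (!is.null(effects)) {
    bad <- !(effects$cpg_id %in% rownames(panel$profiles))
    if (any(bad)) stop("effect references unknown CpG: ",
                       effects$cpg_id[which(bad)[1]], call. = FALSE)
    bad <- !(effects$cell_type %in% c("all", types))
    if (any(bad)) stop("effect references unknown cell type: ",
                       effects$cell_type[which(bad)[1]], call. = FALSE)
  }
  fractions <- fractions %||% c(types, "WB")
  use_subtypes <- !is.null(subtype_panel)
  if (use_subtypes) {
    stopifnot(inherits(subtype_panel, "ref_panel"), !is.null(b_config))
    if (!identical(rownames(subtype_panel$profiles),
                   rownames(panel$profiles))) {
      stop("subtype_panel must share the CpG universe of panel",
           call. = FALSE)
    }
    b_config <- utils::modifyList(
      list(naive = "NaiveB", memory = "MemB", conc = dirichlet_conc),
      b_config)
  }

  n <- nrow(cohort)
  smoker <- cohort$smoking == 1L
  prof <- panel$profiles[, types, drop = FALSE]

  # group-specific profiles with direct effects applied to smokers
  prof_sm <- prof
  if (!is.null(effects)) {
    for (i in seq_len(nrow(effects))) {
      cols <- if (effects$cell_type[i] == "all") types else effects$cell_type[i]
      prof_sm[effects$cpg_id[i], cols] <-
        prof_sm[effects$cpg_id[i], cols] + effects$delta[i]
    }
    prof_sm <- clamp_beta(prof_sm)
  }

  withr::with_seed(seed, {
    mean_p <- specs$mean_proportion / sum(specs$mean_proportion)
    # infinite concentration = proportions fixed exactly at the means
    wb_props <- if (is.infinite(dirichlet_conc)) {
      matrix(mean_p, n, length(types), byrow = TRUE)
    } else {
      rdirichlet(n, dirichlet_conc * mean_p)
    }
    dimnames(wb_props) <- list(cohort$subject_id, types)

    b_shares <- NULL
    if (use_subtypes) {
      subtypes <- colnames(subtype_panel$profiles)
      mean_shares <- function(naive, memory) {
        rest <- setdiff(subtypes, c(b_config$naive, b_config$memory))
        m <- stats::setNames(rep((1 - naive - memory) / length(rest),
                                 length(subtypes)), subtypes)
        m[b_config$naive] <- naive
        m[b_config$memory] <- memory
        m
      }
      m_ns <- mean_shares(b_config$naive_mean_ns, b_config$memory_mean_ns)
      m_sm <- mean_shares(b_config$naive_mean_sm, b_config$memory_mean_sm)
      b_shares <- matrix(NA_real_, n, length(subtypes),
                         dimnames = list(cohort$subject_id, subtypes))
      if (any(!smoker)) {
        b_shares[!smoker, ] <- rdirichlet(sum(!smoker), b_config$conc * m_ns)
      }
      if (any(smoker)) {
        b_shares[smoker, ] <- rdirichlet(sum(smoker), b_config$conc * m_sm)
      }
    }

    add_noise <- function(mu) {
      mu <- clamp_beta(mu)
      if (noise_sd == 0) return(mu)
      clamp_beta(ilogit2(logit2(mu) +
        matrix(stats::rnorm(length(mu), 0, noise_sd), nrow(mu))))
    }

    out <- list()
    for (fr in fractions) {
      mu <- matrix(NA_real_, nrow(prof), n,
                   dimnames = list(rownames(prof), cohort$subject_id))
      if (fr == "WB") {
        p_ns <- prof
        p_sm <- prof_sm
        if (use_subtypes && "Bcell" %in% types) {
          # whole-blood B profile reflects the group-mean subtype mixture
          p_ns[, "Bcell"] <- subtype_panel$profiles %*% m_ns
          sub_sm <- clamp_beta(subtype_panel$profiles +
            direct_b_delta(effects, rownames(prof), types))
          p_sm[, "Bcell"] <- sub_sm %*% m_sm
        }
        mu[, !smoker] <- p_ns %*% t(wb_props[!smoker, , drop = FALSE])
        mu[, smoker] <- p_sm %*% t(wb_props[smoker, , drop = FALSE])
      } else if (fr == "Bcell" && use_subtypes) {
        sub_ns <- subtype_panel$profiles
        sub_sm <- clamp_beta(sub_ns +
          direct_b_delta(effects, rownames(prof), types))
        mu[, !smoker] <- sub_ns %*% t(b_shares[!smoker, , drop = FALSE])
        mu[, smoker] <- sub_sm %*% t(b_shares[smoker, , drop = FALSE])
      } else {
        if (!fr %in% types) stop("unknown fraction: ", fr, call. = FALSE)
        # per-subject purity (Beta around the nominal value) and contaminant
        # composition proportional to the subject's own whole-blood
        # proportions, so contamination covariates vary across subjects
        p0 <- pur[fr]
        pur_i <- if (p0 >= 1 || is.infinite(dirichlet_conc)) rep(p0, n) else {
          stats::rbeta(n, dirichlet_conc * p0, dirichlet_conc * (1 - p0))
        }
        others <- setdiff(types, fr)
        w_o <- wb_props[, others, drop = FALSE]
        w_o <- w_o / rowSums(w_o)
        mixW <- matrix(0, n, length(types), dimnames = list(NULL, types))
        mixW[, fr] <- pur_i
        mixW[, others] <- w_o * (1 - pur_i)
        mu[, !smoker] <- prof %*% t(mixW[!smoker, , drop = FALSE])
        mu[, smoker] <- prof_sm %*% t(mixW[smoker, , drop = FALSE])
      }
      out[[fr]] <- add_noise(mu)
    }
    list(fractions = out,
         truth = list(wb_proportions = wb_props,
                      b_subtype_shares = b_shares,
                      effects = effects))
  })
}

# beta-scale delta applied to every B subtype profile for smokers: effects
# attributed to Bcell or shared across all cell types.
direct_b_delta <- function(effects, cpg_ids, types) {
  d <- stats::setNames(numeric(length(cpg_ids)), cpg_ids)
  if (!is.null(effects)) {
    hit <- effects$cell_type %in% c("all", "Bcell")
    d[effects$cpg_id[hit]] <- effects$delta[hit]
  }
  d
}

#' Expand a subject table into a per-sample sheet for one fraction
#'
#' @param cohort subject table from [make_cohort()].
#' @param fraction fraction label (one of the cell types or "WB").
#' @return the cohort with `sample_id` (`<subject>_<fraction>`) and
#'   `fraction` columns prepended.
#' @export
as_sample_sheet <- function(cohort, fraction) {
  cbind(data.frame(sample_id = paste(cohort$subject_id, fraction, sep = "_"),
                   stringsAsFactors = FALSE),
        cohort, fraction = fraction)
}
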