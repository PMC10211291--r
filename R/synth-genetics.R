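# Synthetic genetics: LD-blocked dosages, cis-QTL summary tables from
# per-study re-simulation at the cohort size, and toy GWAS / EWAS-catalog
# extracts, all with recorded ground truth.
#
# LD mechanism: each block has one tag haplotype pair per subject drawn at
# the block's MAF; every SNP copies each tag allele with probability q and
# redraws it at the same MAF otherwise. Two SNPs then have allele (and
# dosage) correlation q^2, hence pairwise dosage r2 = q^4, so q is the
# fourth root of the target r2; r2 = 1 yields duplicated dosage columns.

cor_p <- function(x, y) {
  n <- length(x)
  r <- stats::cor(x, y)
  if (is.na(r) || abs(r) >= 1) return(list(r = r, p = .Machine$double.xmin))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = max(2 * stats::pt(-abs(t), n - 2), .Machine$double.xmin))
}

#' Simulate genotypes, QTL summary tables and toy catalogs
#'
#' Generates block-correlated dosages anchored at CpGs of `cpg_annot` (SNPs
#' within +/- 8 kb of the anchor, one gene span per block covering it), then
#' builds per-study mQTL / eQTL / eQTM summary tables by re-simulating each
#' study's molecular trait at the cohort size: injected pairs receive their
#' additive effect on the M (or expression) scale plus unit Gaussian noise,
#' all other candidate pairs are pure noise, and the stored p value is the
#' regression p. Injected effects therefore replicate across studies while
#' null pairs do not. A toy GWAS catalog places one passing hit on the last
#' SNP of each mQTL-carrying block (in LD with the proxy) plus deliberately
#' failing rows to exercise the filters, and a toy EWAS catalog embeds a
#' subset of `smcpg_ids` in its first set.
#'
#' @param cohort subject table from [make_cohort()].
#' @param cpg_annot CpG annotation (from a [make_reference_panel()]).
#' @param n_blocks,snps_per_block LD-block geometry.
#' @param maf_range minor-allele-frequency interval, within (0, 0.5].
#' @param within_block_r2 target expected pairwise dosage r2 within a block.
#' @param mqtl_specs data.frame(`snp_id`, `cpg_id`, `slope`) of injected
#'   mQTL effects, or "auto" (first SNP of every odd block -> its anchor
#'   CpG, slope 2), or `NULL` for none.
#' @param eqtl_specs data.frame(`snp_id`, `gene_id`, `slope`), "auto", or
#'   `NULL`.
#' @param eqtm_specs data.frame(`cpg_id`, `gene_id`, `slope`), "auto", or
#'   `NULL`.
#' @param mqtl_studies,eqtl_studies,eqtm_studies study labels for the
#'   summary tables.
#' @param qtl_study_n per-study sample size for the simulated summary
#'   statistics; `NULL` (default) reuses the cohort's subjects and dosages,
#'   a number draws fresh Hardy-Weinberg dosages of that size per study,
#'   emulating large external consortia.
#' @param smcpg_ids CpG ids to embed in the toy EWAS catalog (optional).
#' @param seed integer seed (required).
#' @return list with `genotypes` (SNP x subject dosage matrix), `snp_annot`,
#'   `expression` (gene x subject), `gene_annot`, `mqtl_records`,
#'   `eqtl_records`, `eqtm_records` (QTL tables), `gwas`,
#'   `trait_categories`, `catalog_assoc` (EWAS catalog associations),
#'   `truth` (injected effects and block structure).
#' @export
simulate_genetics <- function(cohort, cpg_annot, n_blocks = 10,
                              snps_per_block = 4, maf_range = c(0.1, 0.5),
                              within_block_r2 = 0.98,
                              mqtl_specs = "auto", eqtl_specs = "auto",
                              eqtm_specs = "auto",
                              mqtl_studies = c("BIOS", "FHS", "LBC_BSGS",
                                               "UKHLS"),
                              eqtl_studies = c("BIOS", "FHS", "CAGE",
                                               "eQTLGen"),
                              eqtm_studies = c("BIOS", "FHS"),
                              qtl_study_n = NULL, smcpg_ids = NULL, seed) {
  seed <- check_seed(seed)
  check_sample_sheet(cohort)
  stopifnot(maf_range[1] > 0, maf_range[2] <= 0.5,
            n_blocks <= nrow(cpg_annot))
  n <- nrow(cohort)
  n_q <- qtl_study_n %||% n
  q_copy <- within_block_r2^0.25

  withr::with_seed(seed, {
    anchors <- cpg_annot[sort(sample.int(nrow(cpg_annot), n_blocks)), ,
                         drop = FALSE]
    snp_rows <- list()
    geno <- list()
    gene_rows <- list()
    for (b in seq_len(n_blocks)) {
      maf <- stats::runif(1, maf_range[1], maf_range[2])
      offs <- sort(sample(setdiff(-8000:8000, 0), snps_per_block))
      tag1 <- stats::rbinom(n, 1, maf)
      tag2 <- stats::rbinom(n, 1, maf)
      for (j in seq_len(snps_per_block)) {
        if (within_block_r2 >= 1) {
          a1 <- tag1
          a2 <- tag2
        } else {
          keep1 <- stats::rbinom(n, 1, q_copy) == 1
          keep2 <- stats::rbinom(n, 1, q_copy) == 1
          a1 <- ifelse(keep1, tag1, stats::rbinom(n, 1, maf))
          a2 <- ifelse(keep2, tag2, stats::rbinom(n, 1, maf))
        }
        id <- sprintf("rs_b%02d_%02d", b, j)
        geno[[id]] <- as.integer(a1 + a2)
        snp_rows[[id]] <- data.frame(
          snp_id = id, chrom = anchors$chrom[b],
          pos = anchors$pos[b] + offs[j], block = b, maf = maf,
          anchor_cpg = anchors$cpg_id[b], stringsAsFactors = FALSE)
      }
      gene_rows[[b]] <- data.frame(
        gene_id = sprintf("gene_b%02d", b), chrom = anchors$chrom[b],
        start = max(0L, anchors$pos[b] - 2000L),
        end = anchors$pos[b] + 3000L, strand = "+",
        stringsAsFactors = FALSE)
    }
    genotypes <- do.call(rbind, geno)
    dimnames(genotypes) <- list(names(geno), cohort$subject_id)
    snp_annot <- do.call(rbind, snp_rows)
    rownames(snp_annot) <- NULL
    gene_annot <- do.call(rbind, gene_rows)

    auto_blocks <- seq(1, n_blocks, by = 2)
    first_snp <- function(b) sprintf("rs_b%02d_01", b)
    if (identical(mqtl_specs, "auto")) {
      mqtl_specs <- data.frame(snp_id = first_snp(auto_blocks),
                               cpg_id = anchors$cpg_id[auto_blocks],
                               slope = 2, stringsAsFactors = FALSE)
    }
    if (identical(eqtl_specs, "auto")) {
      eqtl_specs <- data.frame(snp_id = first_snp(auto_blocks),
                               gene_id = sprintf("gene_b%02d", auto_blocks),
                               slope = 1.5, stringsAsFactors = FALSE)
    }
    if (identical(eqtm_specs, "auto")) {
      eqtm_specs <- data.frame(cpg_id = anchors$cpg_id[auto_blocks],
                               gene_id = sprintf("gene_b%02d", auto_blocks),
                               slope = 0.8, stringsAsFactors = FALSE)
    }
    check_ref <- function(ids, pool, what) {
      bad <- setdiff(ids, pool)
      if (length(bad) > 0) stop("spec references unknown ", what, ": ",
                                bad[1], call. = FALSE)
    }
    if (!is.null(mqtl_specs)) {
      check_ref(mqtl_specs$snp_id, rownames(genotypes), "SNP")
      check_ref(mqtl_specs$cpg_id, cpg_annot$cpg_id, "CpG")
    }
    if (!is.null(eqtl_specs)) {
      check_ref(eqtl_specs$snp_id, rownames(genotypes), "SNP")
      check_ref(eqtl_specs$gene_id, gene_annot$gene_id, "gene")
    }
    if (!is.null(eqtm_specs)) {
      check_ref(eqtm_specs$cpg_id, cpg_annot$cpg_id, "CpG")
      check_ref(eqtm_specs$gene_id, gene_annot$gene_id, "gene")
    }

    spec_slope <- function(specs, a, b, cols) {
      if (is.null(specs)) return(0)
      hit <- specs[[cols[1]]] == a & specs[[cols[2]]] == b
      if (any(hit)) specs$slope[hit][1] else 0
    }

    # study-internal dosages: the cohort's own when qtl_study_n is NULL,
    # otherwise a fresh Hardy-Weinberg draw at the SNP's block MAF
    study_dosage <- function(sa) {
      if (is.null(qtl_study_n)) genotypes[sa$snp_id, ]
      else stats::rbinom(n_q, 2, sa$maf)
    }

    # mQTL tables: candidate pairs are every SNP x its block's anchor CpG
    mqtl_records <- do.call(rbind, lapply(mqtl_studies, function(st) {
      do.call(rbind, lapply(seq_len(nrow(snp_annot)), function(i) {
        sa <- snp_annot[i, ]
        slope <- spec_slope(mqtl_specs, sa$snp_id, sa$anchor_cpg,
                            c("snp_id", "cpg_id"))
        g_s <- study_dosage(sa)
        y <- slope * g_s + stats::rnorm(n_q)
        data.frame(study_id = st, snp_id = sa$snp_id, snp_chrom = sa$chrom,
                   snp_pos = sa$pos, target_id = sa$anchor_cpg,
                   target_type = "cpg", p = cor_p(g_s, y)$p,
                   stringsAsFactors = FALSE)
      }))
    }))

    # eQTL tables: every SNP x its block's gene
    eqtl_records <- do.call(rbind, lapply(eqtl_studies, function(st) {
      do.call(rbind, lapply(seq_len(nrow(snp_annot)), function(i) {
        sa <- snp_annot[i, ]
        gid <- sprintf("gene_b%02d", sa$block)
        slope <- spec_slope(eqtl_specs, sa$snp_id, gid,
                            c("snp_id", "gene_id"))
        g_s <- study_dosage(sa)
        y <- slope * g_s + stats::rnorm(n_q)
        data.frame(study_id = st, snp_id = sa$snp_id, snp_chrom = sa$chrom,
                   snp_pos = sa$pos, target_id = gid, target_type = "gene",
                   p = cor_p(g_s, y)$p, stringsAsFactors = FALSE)
      }))
    }))

    # eQTM tables: anchor CpG x block gene; the CpG occupies the variant
    # slot of the QTL table shape
    eqtm_records <- do.call(rbind, lapply(eqtm_studies, function(st) {
      do.call(rbind, lapply(seq_len(n_blocks), function(b) {
        cpg <- anchors$cpg_id[b]
        gid <- sprintf("gene_b%02d", b)
        slope <- spec_slope(eqtm_specs, cpg, gid, c("cpg_id", "gene_id"))
        mv <- stats::rnorm(n_q)
        ev <- slope * mv + stats::rnorm(n_q)
        data.frame(study_id = st, snp_id = cpg, snp_chrom = anchors$chrom[b],
                   snp_pos = anchors$pos[b], target_id = gid,
                   target_type = "gene", p = cor_p(mv, ev)$p,
                   stringsAsFactors = FALSE)
      }))
    }))

    # cohort-level expression matrix (genes x subjects)
    expression <- t(vapply(seq_len(n_blocks), function(b) {
      gid <- sprintf("gene_b%02d", b)
      e <- stats::rnorm(n)
      if (!is.null(eqtl_specs)) {
        for (i in which(eqtl_specs$gene_id == gid)) {
          e <- e + eqtl_specs$slope[i] * genotypes[eqtl_specs$snp_id[i], ]
        }
      }
      e
    }, numeric(n)))
    dimnames(expression) <- list(gene_annot$gene_id, cohort$subject_id)

    # toy GWAS catalog: the last SNP of every mQTL block is a passing hit
    trait_pool <- c("FEV1/FVC ratio" = "lung function",
                    "asthma" = "disease risk",
                    "Crohn's disease" = "disease risk",
                    "eosinophil count" = "blood traits",
                    "monocyte count" = "blood traits",
                    "educational attainment" = "other")
    gwas_rows <- list()
    if (!is.null(mqtl_specs)) {
      blocks_used <- unique(snp_annot$block[snp_annot$snp_id %in%
                                              mqtl_specs$snp_id])
      for (k in seq_along(blocks_used)) {
        b <- blocks_used[k]
        sid <- sprintf("rs_b%02d_%02d", b, snps_per_block)
        sa <- snp_annot[snp_annot$snp_id == sid, ]
        trait <- names(trait_pool)[(k - 1) %% length(trait_pool) + 1]
        gwas_rows[[length(gwas_rows) + 1]] <- data.frame(
          snp_id = sid, chrom = sa$chrom, pos = sa$pos, trait = trait,
          p = 10^-stats::runif(1, 9, 30),
          n = sample(2000:300000, 1), stringsAsFactors = FALSE)
      }
    }
    # deliberately failing rows: weak p, small n
    fail_snp <- snp_annot$snp_id[c(2, nrow(snp_annot) - 1)]
    gwas_rows[[length(gwas_rows) + 1]] <- data.frame(
      snp_id = fail_snp, chrom = "chrS", pos = 0L,
      trait = c("weak trait", "small study"), p = c(1e-6, 1e-12),
      n = c(50000L, 500L), stringsAsFactors = FALSE)
    gwas <- do.call(rbind, gwas_rows)
    rownames(gwas) <- NULL

    # toy EWAS catalog associations; first set embeds known smCpGs
    all_cpgs <- cpg_annot$cpg_id
    cat_rows <- list()
    set_defs <- list(
      list(set = "lung_function_ewas", trait = "lung function"),
      list(set = "bmi_ewas", trait = "body mass index"),
      list(set = "age_ewas", trait = "aging"))
    for (k in seq_along(set_defs)) {
      d <- set_defs[[k]]
      ids <- sample(all_cpgs, min(30, length(all_cpgs)))
      if (k == 1 && length(smcpg_ids) > 0) {
        ids <- unique(c(sample(smcpg_ids,
                               ceiling(length(smcpg_ids) * 0.6)), ids))
      }
      cat_rows[[k]] <- data.frame(
        set = d$set, trait = d$trait, cpg_id = ids,
        p = 10^-stats::runif(length(ids), 8, 40),
        array = sample(c("450k", "EPIC"), length(ids), replace = TRUE),
        n = sample(200:5000, length(ids), replace = TRUE),
        stringsAsFactors = FALSE)
    }
    catalog_assoc <- do.call(rbind, cat_rows)
    rownames(catalog_assoc) <- NULL

    list(genotypes = genotypes, snp_annot = snp_annot,
         expression = expression, gene_annot = gene_annot,
         mqtl_records = mqtl_records, eqtl_records = eqtl_records,
         eqtm_records = eqtm_records, gwas = gwas,
         trait_categories = trait_pool, catalog_assoc = catalog_assoc,
         truth = list(mqtl = mqtl_specs, eqtl = eqtl_specs,
                      eqtm = eqtm_specs,
                      gwas_snps = unique(gwas$snp_id[gwas$n > 1000 &
                                                       gwas$p < 5e-8]),
                      blocks = snp_annot))
  })
}
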