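# Multi-omics integration: proxy smoking-associated CpGs with filtered
# cis-mQTL SNPs, expand through complete LD to GWAS SNPs, annotate with cis
# eQTM/eQTL evidence, and tally per-CpG support across datasets.
#
# Every published filter threshold is applied as a strict inequality,
# exactly as printed; boundary values are excluded.

#' Filter mQTL records into smCpG proxy SNPs
#'
#' Keeps (SNP, CpG) pairs on the same chromosome with absolute SNP-CpG
#' distance strictly below `dist_max`, p strictly below `p_max`, and passing
#' in at least `min_studies` distinct studies.
#'
#' @param records QTL record data.frame (see [read_qtl()]) with
#'   `target_type == "cpg"`.
#' @param cpg_annot CpG annotation (`cpg_id`, `chrom`, `pos`); records whose
#'   CpG is absent are skipped and counted.
#' @param p_max,dist_max,min_studies filter thresholds.
#' @return data.frame of proxies: `cpg_id`, `snp_id`, `n_studies`, `min_p`;
#'   attribute `n_skipped` counts records with unannotated CpGs.
#' @export
filter_mqtls <- function(records, cpg_annot, p_max = 2e-11,
                         dist_max = 10000, min_studies = 2) {
  records <- records[records$target_type == "cpg", , drop = FALSE]
  idx <- match(records$target_id, cpg_annot$cpg_id)
  n_skipped <- sum(is.na(idx))
  keep <- !is.na(idx)
  records <- records[keep, , drop = FALSE]
  idx <- idx[keep]
  same_chrom <- records$snp_chrom == cpg_annot$chrom[idx]
  dist_ok <- abs(records$snp_pos - cpg_annot$pos[idx]) < dist_max
  pass <- records[same_chrom & dist_ok & records$p < p_max, , drop = FALSE]
  if (nrow(pass) == 0) {
    out <- data.frame(cpg_id = character(), snp_id = character(),
                      n_studies = integer(), min_p = numeric(),
                      stringsAsFactors = FALSE)
    attr(out, "n_skipped") <- n_skipped
    return(out)
  }
  key <- paste(pass$target_id, pass$snp_id, sep = "\r")
  n_stud <- tapply(pass$study_id, key, function(s) length(unique(s)))
  min_p <- tapply(pass$p, key, min)
  ok <- names(n_stud)[n_stud >= min_studies]
  parts <- strsplit(ok, "\r", fixed = TRUE)
  out <- data.frame(
    cpg_id = vapply(parts, `[`, "", 1),
    snp_id = vapply(parts, `[`, "", 2),
    n_studies = as.integer(n_stud[ok]),
    min_p = as.numeric(min_p[ok]),
    stringsAsFactors = FALSE)
  out <- out[order(out$cpg_id, out$snp_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Squared dosage correlation between two SNPs
#'
#' Composite (genotype-based) LD: the squared Pearson correlation of the two
#' dosage vectors, as computed by VCFtools-style genotype r2. Symmetric in
#' its arguments.
#'
#' @param genotypes SNP x sample dosage matrix.
#' @param snp_a,snp_b SNP ids (rows of `genotypes`).
#' @return r2 in `[0, 1]`.
#' @export
ld_r2 <- function(genotypes, snp_a, snp_b) {
  for (s in c(snp_a, snp_b)) {
    if (!s %in% rownames(genotypes)) stop("SNP not genotyped: ", s,
                                          call. = FALSE)
  }
  a <- genotypes[snp_a, ]
  b <- genotypes[snp_b, ]
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    stop("r2 undefined: zero dosage variance", call. = FALSE)
  }
  stats::cor(a, b)^2
}

#' Filter GWAS associations
#'
#' Keeps hits with p strictly below `p_max` and population size strictly
#' above `n_min`; duplicate (SNP, trait) rows are collapsed keeping the
#' minimum p.
#'
#' @param hits GWAS data.frame (see [read_gwas()]).
#' @param p_max,n_min thresholds (strict).
#' @return filtered, deduplicated data.frame.
#' @export
filter_gwas <- function(hits, p_max = 5e-8, n_min = 1000) {
  hits <- hits[hits$p < p_max & hits$n > n_min, , drop = FALSE]
  if (nrow(hits) == 0) return(hits)
  hits <- hits[order(hits$snp_id, hits$trait, hits$p), , drop = FALSE]
  hits <- hits[!duplicated(hits[c("snp_id", "trait")]), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Link proxy SNPs to GWAS SNPs through complete LD
#'
#' Emits a link when a proxy SNP is itself a GWAS SNP (r2 recorded as 1) or
#' its dosage r2 with a GWAS SNP is strictly above `r2_threshold`
#' ("complete LD"). Pairs with ungenotyped SNPs are skipped and counted.
#'
#' @param proxies proxy table from [filter_mqtls()].
#' @param gwas_hits filtered GWAS table from [filter_gwas()].
#' @param genotypes SNP x sample dosage matrix covering the SNPs.
#' @param r2_threshold complete-LD cutoff (strict >).
#' @param trait_categories optional named vector mapping trait to category
#'   (e.g. lung function / disease risk / blood traits / other); unmapped
#'   traits get "other".
#' @return data.frame of links: `cpg_id`, `proxy_snp`, `gwas_snp`, `r2`,
#'   `trait`, `gwas_p`, `category`; attribute `n_skipped`.
#' @export
link_gwas <- function(proxies, gwas_hits, genotypes, r2_threshold = 0.95,
                      trait_categories = NULL) {
  rows <- list()
  n_skipped <- 0L
  gwas_snps <- unique(gwas_hits$snp_id)
  for (i in seq_len(nrow(proxies))) {
    psnp <- proxies$snp_id[i]
    for (gsnp in gwas_snps) {
      if (psnp == gsnp) {
        r2 <- 1.0
      } else {
        if (!psnp %in% rownames(genotypes) ||
            !gsnp %in% rownames(genotypes)) {
          n_skipped <- n_skipped + 1L
          next
        }
        r2 <- ld_r2(genotypes, psnp, gsnp)
        if (r2 <= r2_threshold) next
      }
      gh <- gwas_hits[gwas_hits$snp_id == gsnp, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        cpg_id = proxies$cpg_id[i], proxy_snp = psnp, gwas_snp = gsnp,
        r2 = r2, trait = gh$trait, gwas_p = gh$p,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) == 0) {
    data.frame(cpg_id = character(), proxy_snp = character(),
               gwas_snp = character(), r2 = numeric(), trait = character(),
               gwas_p = numeric(), category = character(),
               stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
    out$category <- if (is.null(trait_categories)) "other" else {
      cat <- unname(trait_categories[out$trait])
      ifelse(is.na(cat), "other", cat)
    }
    out
  }
  out <- out[order(out$cpg_id, out$proxy_snp, out$gwas_snp, out$trait), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

# is a CpG position inside the gene span extended by `flank` on both sides?
# (0-based half-open: [start - flank, end + flank))
in_gene_window <- function(cpg_chrom, cpg_pos, gene, flank = 10000) {
  cpg_chrom == gene$chrom & cpg_pos >= gene$start - flank &
    cpg_pos < gene$end + flank
}

#' Filter eQTM records to cis CpG-gene pairs
#'
#' Keeps (CpG, gene) pairs with the CpG inside the gene span extended by
#' 10 kb on both sides (strand-agnostic, half-open) and p strictly below
#' `p_max`.
#'
#' @param records QTL records with `target_type == "gene"`, where `snp_id`
#'   carries the CpG id and `snp_chrom`/`snp_pos` its position (eQTM records
#'   reuse the QTL table shape with the CpG in the variant slot).
#' @param cpg_annot,gene_annot annotations.
#' @param p_max threshold (strict).
#' @param flank window extension in bp.
#' @return data.frame: `cpg_id`, `gene_id`, `study_id`, `p`.
#' @export
filter_eqtm <- function(records, cpg_annot, gene_annot, p_max = 1e-5,
                        flank = 10000) {
  records <- records[records$target_type == "gene", , drop = FALSE]
  gi <- match(records$target_id, gene_annot$gene_id)
  ci <- match(records$snp_id, cpg_annot$cpg_id)
  keep <- !is.na(gi) & !is.na(ci)
  records <- records[keep, , drop = FALSE]
  gi <- gi[keep]
  ci <- ci[keep]
  genes <- gene_annot[gi, , drop = FALSE]
  ok <- in_gene_window(cpg_annot$chrom[ci], cpg_annot$pos[ci], genes,
                       flank) & records$p < p_max
  out <- data.frame(cpg_id = records$snp_id[ok],
                    gene_id = records$target_id[ok],
                    study_id = records$study_id[ok],
                    p = records$p[ok], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Filter eQTL records to cis evidence anchored at proxy CpGs
#'
#' Keeps (SNP, gene) eQTL records whose SNP proxies a CpG (via `proxies`),
#' lies strictly within `dist_max` of that CpG, with the CpG inside the
#' gene's +/- 10 kb window, and p strictly below `p_max`. Evidence is
#' attached to the anchoring CpG.
#'
#' @param records QTL records with `target_type == "gene"` (SNP -> gene).
#' @param proxies proxy table from [filter_mqtls()] (cpg_id, snp_id).
#' @param cpg_annot,gene_annot annotations.
#' @param p_max,dist_max,flank thresholds.
#' @return data.frame: `cpg_id`, `snp_id`, `gene_id`, `study_id`, `p`.
#' @export
filter_eqtl <- function(records, proxies, cpg_annot, gene_annot,
                        p_max = 1e-5, dist_max = 10000, flank = 10000) {
  records <- records[records$target_type == "gene" & records$p < p_max, ,
                     drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(proxies))) {
    cpg <- proxies$cpg_id[i]
    ca <- cpg_annot[match(cpg, cpg_annot$cpg_id), , drop = FALSE]
    if (is.na(ca$cpg_id[1])) next
    rec <- records[records$snp_id == proxies$snp_id[i], , drop = FALSE]
    if (nrow(rec) == 0) next
    dist_ok <- rec$snp_chrom == ca$chrom &
      abs(rec$snp_pos - ca$pos) < dist_max
    rec <- rec[dist_ok, , drop = FALSE]
    if (nrow(rec) == 0) next
    gi <- match(rec$target_id, gene_annot$gene_id)
    ok <- !is.na(gi) &
      in_gene_window(ca$chrom, ca$pos, gene_annot[gi, , drop = FALSE], flank)
    rec <- rec[ok, , drop = FALSE]
    if (nrow(rec) > 0) {
      out[[length(out) + 1L]] <- data.frame(
        cpg_id = cpg, snp_id = rec$snp_id, gene_id = rec$target_id,
        study_id = rec$study_id, p = rec$p, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(cpg_id = character(), snp_id = character(),
                      gene_id = character(), study_id = character(),
                      p = numeric(), stringsAsFactors = FALSE))
  }
  res <- unique(do.call(rbind, out))
  rownames(res) <- NULL
  res
}

#' Tally multi-omics evidence per CpG
#'
#' Each provided dataset (each mQTL study, each eQTM study, each eQTL study,
#' the GWAS linkage) contributes one 0/1 flag per CpG; CpGs supported by at
#' least `min_layers` datasets are returned, sorted by descending support
#' then CpG id.
#'
#' @param evidence named list: one element per dataset, each a character
#'   vector of supported CpG ids.
#' @param min_layers minimum number of supporting datasets.
#' @return data.frame with `cpg_id`, one 0/1 column per dataset, and
#'   `n_omics_layers`; only rows meeting `min_layers`.
#' @export
multi_omics_tally <- function(evidence, min_layers = 4) {
  stopifnot(length(evidence) >= 1, !is.null(names(evidence)))
  if (min_layers > length(evidence)) {
    warning("min_layers exceeds the number of datasets; result is empty")
  }
  cpgs <- sort(unique(unlist(evidence)))
  flags <- vapply(evidence, function(e) as.integer(cpgs %in% e),
                  integer(length(cpgs)))
  if (is.null(dim(flags))) flags <- rbind(flags)  # single CpG
  dimnames(flags) <- list(NULL, names(evidence))
  out <- data.frame(cpg_id = cpgs, flags, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out$n_omics_layers <- rowSums(flags)
  out <- out[out$n_omics_layers >= min_layers, , drop = FALSE]
  out <- out[order(-out$n_omics_layers, out$cpg_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
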