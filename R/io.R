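# Plain-text readers and writers. One dialect per format, checked strictly:
# every writer produces files its reader accepts, and readers reject files
# that violate the dialect with messages naming the offending record.
#
# Genomic coordinates are 0-based half-open everywhere inside the package;
# the only conversion happens at the VCF boundary (VCF is 1-based).

read_tsv_strict <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  nf <- utils::count.fields(path, sep = sep, quote = "", comment.char = "")
  if (length(nf) == 0) stop("empty file: ", path, call. = FALSE)
  bad <- which(nf != nf[1])
  if (length(bad) > 0) {
    stop(sprintf("ragged row in %s at line %d (%d fields, expected %d)",
                 path, bad[1], nf[bad[1]], nf[1]), call. = FALSE)
  }
  utils::read.table(path, header = TRUE, sep = sep, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE, fileEncoding = "UTF-8")
}

#' Read and write beta-value matrices
#'
#' Tab-separated, UTF-8, '.' decimal; header row of sample ids; first column
#' `cpg_id`. Values must lie in `[0, 1]`. Round-trips are exact to at least
#' ten decimal places.
#'
#' @param path file path.
#' @return `read_beta`: numeric matrix (CpG x sample) with CpG rownames.
#' @export
read_beta <- function(path) {
  df <- read_tsv_strict(path)
  if (names(df)[1] != "cpg_id") {
    stop("beta TSV must have 'cpg_id' as its first column", call. = FALSE)
  }
  ids <- as.character(df$cpg_id)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (nrow(m) > 0) check_beta_matrix(m)
  m
}

#' @rdname read_beta
#' @param beta numeric CpG x sample matrix.
#' @export
write_beta <- function(beta, path) {
  if (nrow(beta) > 0) check_beta_matrix(beta)
  if (nrow(beta) == 0) {
    writeLines(paste(c("cpg_id", colnames(beta)), collapse = "\t"), path)
    return(invisible(path))
  }
  df <- data.frame(cpg_id = rownames(beta), beta, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write sample sheets
#'
#' Comma-separated subject table with columns `subject_id`, `smoking` (0/1),
#' `age`, `sex` (M/F), `ancestry`, `bmi`, and optionally `sample_id` and
#' `fraction`. Missing covariates are refused rather than imputed.
#'
#' @param path file path.
#' @return data.frame, one row per subject (or per sample when `sample_id`
#'   present).
#' @export
read_sample_sheet <- function(path) {
  df <- read_tsv_strict(path, sep = ",")
  df$smoking <- as.integer(df$smoking)
  check_sample_sheet(df)
  df
}

#' @rdname read_sample_sheet
#' @param sheet sample sheet data.frame.
#' @export
write_sample_sheet <- function(sheet, path) {
  check_sample_sheet(sheet)
  utils::write.table(sheet, path, sep = ",", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write CpG position annotation as BED
#'
#' BED3+name: chrom, 0-based start, end (= start + 1), CpG id. No header.
#'
#' @param path file path.
#' @return data.frame with `cpg_id`, `chrom`, `pos` (0-based).
#' @export
read_cpg_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "cpg_id"))
  if (any(df$end != df$start + 1L)) {
    stop("CpG BED intervals must be single bases (end = start + 1)",
         call. = FALSE)
  }
  out <- data.frame(cpg_id = df$cpg_id, chrom = df$chrom,
                    pos = as.integer(df$start), stringsAsFactors = FALSE)
  if (anyDuplicated(out$cpg_id)) stop("duplicate CpG ids in BED", call. = FALSE)
  if (anyDuplicated(out[c("chrom", "pos")])) {
    stop("duplicate CpG positions in BED", call. = FALSE)
  }
  out
}

#' @rdname read_cpg_bed
#' @param annot CpG annotation data.frame (`cpg_id`, `chrom`, `pos`).
#' @export
write_cpg_bed <- function(annot, path) {
  stopifnot(all(c("cpg_id", "chrom", "pos") %in% names(annot)))
  utils::write.table(
    data.frame(annot$chrom, annot$pos, annot$pos + 1L, annot$cpg_id),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write gene annotation
#'
#' TSV with columns `gene_id`, `chrom`, `start`, `end` (0-based half-open
#' gene span), `strand` (+/-).
#'
#' @param path file path.
#' @return data.frame of gene spans.
#' @export
read_gene_annot <- function(path) {
  df <- read_tsv_strict(path)
  need <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(df))) {
    stop("gene annotation needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$start >= df$end)) {
    stop("gene annotation requires start < end", call. = FALSE)
  }
  df
}

#' @rdname read_gene_annot
#' @param genes gene annotation data.frame.
#' @export
write_gene_annot <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write QTL summary tables
#'
#' TSV with columns `study_id`, `snp_id`, `snp_chrom`, `snp_pos` (0-based),
#' `target_id`, `target_type` (cpg/gene), `p`.
#'
#' @param path file path.
#' @return data.frame of QTL records.
#' @export
read_qtl <- function(path) {
  df <- read_tsv_strict(path)
  need <- c("study_id", "snp_id", "snp_chrom", "snp_pos", "target_id",
            "target_type", "p")
  if (!all(need %in% names(df))) {
    stop("QTL table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$p <= 0 | df$p > 1)) stop("QTL p must lie in (0,1]", call. = FALSE)
  if (!all(df$target_type %in% c("cpg", "gene"))) {
    stop("target_type must be 'cpg' or 'gene'", call. = FALSE)
  }
  df
}

#' @rdname read_qtl
#' @param qtl QTL record data.frame.
#' @export
write_qtl <- function(qtl, path) {
  utils::write.table(qtl, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write GWAS catalog extracts
#'
#' TSV with columns `snp_id`, `chrom`, `pos` (0-based), `trait`, `p`, `n`.
#'
#' @param path file path.
#' @return data.frame of GWAS associations.
#' @export
read_gwas <- function(path) {
  df <- read_tsv_strict(path)
  need <- c("snp_id", "chrom", "pos", "trait", "p", "n")
  if (!all(need %in% names(df))) {
    stop("GWAS table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' @rdname read_gwas
#' @param gwas GWAS association data.frame.
#' @export
write_gwas <- function(gwas, path) {
  utils::write.table(gwas, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write GMT set collections
#'
#' One set per line: name TAB description TAB id TAB id ... The description
#' field carries free-text metadata.
#'
#' @param path file path.
#' @return named list of sets, each `list(name, description, ids)`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("GMT line needs name, description and >= 1 id",
                            call. = FALSE)
    ids <- f[-(1:2)]
    if (anyDuplicated(ids)) {
      stop("duplicate ids within GMT set '", f[1], "'", call. = FALSE)
    }
    list(name = f[1], description = f[2], ids = ids)
  })
  names(sets) <- vapply(sets, `[[`, "", "name")
  sets
}

#' @rdname read_gmt
#' @param sets named list of sets (`name`, `description`, `ids`).
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, s$description, s$ids), collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read genotype dosages from TSV or minimal VCF
#'
#' TSV: first column `snp_id`, remaining columns one sample each, values in
#' \{0, 1, 2\}. VCF: v4.x with GT fields; phased and unphased calls accepted;
#' multi-allelic records are skipped with a warning; missing genotypes are an
#' error (no imputation). VCF positions (1-based) are converted to 0-based.
#'
#' @param path file path.
#' @param format "tsv" or "vcf".
#' @return integer matrix SNP x sample with a `snp_annot` attribute
#'   (data.frame `snp_id`, `chrom`, `pos` 0-based) when positions are known.
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- read_tsv_strict(path)
    if (names(df)[1] != "snp_id") {
      stop("genotype TSV must have 'snp_id' as its first column",
           call. = FALSE)
    }
    g <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(g) <- "integer"
    rownames(g) <- df$snp_id
    bad <- which(is.na(g) | !(g %in% c(0L, 1L, 2L)))
    if (length(bad) > 0) {
      stop("missing or non-{0,1,2} dosage at SNP '",
           rownames(g)[(bad[1] - 1) %% nrow(g) + 1], "'", call. = FALSE)
    }
    return(g)
  }
  read_genotypes_vcf(path)
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("reading VCF requires the VariantAnnotation package", call. = FALSE)
  }
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field", call. = FALSE)
  alt <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt)
  multi <- n_alt > 1
  if (any(multi)) {
    warning(sum(multi), " multi-allelic VCF record(s) skipped")
    gt <- gt[!multi, , drop = FALSE]
  }
  dosage_of <- function(x) {
    if (x %in% c(".", "./.", ".|.")) return(NA_integer_)
    alleles <- strsplit(x, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_integer_)
    sum(as.integer(alleles) > 0)
  }
  g <- apply(gt, c(1, 2), dosage_of)
  miss <- which(is.na(g), arr.ind = TRUE)
  if (nrow(miss) > 0) {
    stop("missing genotype at SNP '", rownames(g)[miss[1, 1]],
         "'; imputation is not performed", call. = FALSE)
  }
  storage.mode(g) <- "integer"
  rr <- SummarizedExperiment::rowRanges(vcf)[!multi]
  attr(g, "snp_annot") <- data.frame(
    snp_id = rownames(g),
    chrom = as.character(GenomeInfoDb::seqnames(rr)),
    pos = BiocGenerics::start(rr) - 1L,  # 1-based VCF -> 0-based internal
    stringsAsFactors = FALSE)
  g
}

#' @rdname read_genotypes
#' @param genotypes integer SNP x sample dosage matrix.
#' @export
write_genotypes <- function(genotypes, path) {
  df <- data.frame(snp_id = rownames(genotypes), genotypes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
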