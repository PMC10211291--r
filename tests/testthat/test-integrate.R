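# Integration filters: strict thresholds exactly as printed, hand-counted
# fixtures, and LD oracles.

mk_qtl <- function(study, snp, pos, cpg, p, chrom = "chrS",
                   type = "cpg") {
  data.frame(study_id = study, snp_id = snp, snp_chrom = chrom,
             snp_pos = pos, target_id = cpg, target_type = type, p = p,
             stringsAsFactors = FALSE)
}

cpg_annot3 <- data.frame(cpg_id = c("cgA", "cgB", "cgC"), chrom = "chrS",
                         pos = c(100000L, 200000L, 300000L),
                         stringsAsFactors = FALSE)

test_that("mQTL filter applies distance, p and replication rules strictly", {
  recs <- rbind(
    mk_qtl("st1", "rs1", 100000 + 5000, "cgA", 1e-15),   # pass, study 1
    mk_qtl("st3", "rs1", 100000 + 5000, "cgA", 1e-13),   # pass, study 3
    mk_qtl("st1", "rs2", 100000 + 15000, "cgA", 1e-15),  # too far
    mk_qtl("st1", "rs3", 100000 - 5000, "cgA", 1e-9),    # p too weak
    mk_qtl("st2", "rs3", 100000 - 5000, "cgA", 1e-9),
    mk_qtl("st1", "rs4", 100000 + 100, "cgA", 1e-20))    # single study
  out <- filter_mqtls(recs, cpg_annot3)
  expect_equal(nrow(out), 1L)
  expect_equal(out$snp_id, "rs1")
  expect_equal(out$n_studies, 2L)
  expect_equal(out$min_p, 1e-15)

  # boundary: distance exactly 10000 excluded (strict <)
  b1 <- rbind(mk_qtl("st1", "rs9", 110000, "cgA", 1e-15),
              mk_qtl("st2", "rs9", 110000, "cgA", 1e-15))
  expect_equal(nrow(filter_mqtls(b1, cpg_annot3)), 0L)
  # boundary: p exactly 2e-11 excluded
  b2 <- rbind(mk_qtl("st1", "rs9", 100100, "cgA", 2e-11),
              mk_qtl("st2", "rs9", 100100, "cgA", 2e-11))
  expect_equal(nrow(filter_mqtls(b2, cpg_annot3)), 0L)
  # pair passing in 2 of 4 studies kept
  b3 <- rbind(mk_qtl(c("st1", "st2", "st3", "st4"), "rs9", 100100, "cgA",
                     c(1e-15, 0.5, 1e-15, 0.5)))
  expect_equal(filter_mqtls(b3, cpg_annot3)$n_studies, 2L)
  # unknown CpG skipped and counted
  b4 <- mk_qtl("st1", "rs9", 100100, "cgUNKNOWN", 1e-15)
  out4 <- filter_mqtls(b4, cpg_annot3)
  expect_equal(attr(out4, "n_skipped"), 1L)
})

test_that("LD r2 matches hand-computed dosage correlations", {
  g <- rbind(a = c(0L, 0L, 1L, 1L, 2L, 2L),
             b = c(2L, 2L, 1L, 1L, 0L, 0L),
             c = c(0L, 1L, 0L, 1L, 0L, 1L),
             d = c(0L, 0L, 1L, 1L, 2L, 2L),
             e = rep(1L, 6))
  colnames(g) <- paste0("s", 1:6)
  expect_equal(ld_r2(g, "a", "d"), 1.0)           # identical vectors
  expect_equal(ld_r2(g, "a", "b"), 1.0)           # perfect anti-correlation
  expect_equal(ld_r2(g, "a", "c"), 0.0)           # orthogonal by hand
  expect_equal(ld_r2(g, "a", "c"), ld_r2(g, "c", "a"))  # symmetric
  expect_error(ld_r2(g, "a", "e"), "zero dosage variance")
  expect_error(ld_r2(g, "a", "zz"), "not genotyped")
})

test_that("GWAS filter enforces strict boundaries and deduplicates", {
  hits <- data.frame(
    snp_id = c("r1", "r2", "r3", "r4", "r1"),
    chrom = "chrS", pos = 1:5,
    trait = c("t1", "t1", "t1", "t1", "t1"),
    p = c(1e-9, 5e-8, 1e-9, 1e-12, 1e-10),
    n = c(5000, 5000, 1000, 20000, 5000), stringsAsFactors = FALSE)
  out <- filter_gwas(hits)
  # r2: p = 5e-8 exactly -> excluded; r3: n = 1000 exactly -> excluded;
  # r1 duplicated -> min p kept
  expect_setequal(out$snp_id, c("r1", "r4"))
  expect_equal(out$p[out$snp_id == "r1"], 1e-10)
})

test_that("GWAS linking requires identity or strict complete LD", {
  g <- rbind(p1 = c(0L, 0L, 1L, 1L, 2L, 2L),
             p2 = c(0L, 1L, 0L, 1L, 0L, 1L),
             g1 = c(0L, 0L, 1L, 1L, 2L, 2L),
             g2 = c(2L, 1L, 2L, 1L, 2L, 0L))
  colnames(g) <- paste0("s", 1:6)
  proxies <- data.frame(cpg_id = c("cgA", "cgB", "cgA"),
                        snp_id = c("p1", "p2", "g2"),
                        stringsAsFactors = FALSE)
  hits <- data.frame(snp_id = c("g1", "g2"), chrom = "chrS", pos = 1:2,
                     trait = c("lungX", "traitY"), p = c(1e-9, 1e-10),
                     n = c(5000, 5000), stringsAsFactors = FALSE)
  links <- link_gwas(proxies, hits, g,
                     trait_categories = c(lungX = "lung function"))
  # p1 -> g1 via r2 = 1; g2 is itself a GWAS SNP; p2 links to nothing
  expect_equal(nrow(links), 2L)
  expect_setequal(links$proxy_snp, c("p1", "g2"))
  expect_equal(links$r2[links$proxy_snp == "g2"], 1.0)
  expect_setequal(links$category, c("lung function", "other"))
  expect_false("p2" %in% links$proxy_snp)

  # boundary: r2 exactly at the threshold is not complete LD
  r2_p1g1 <- ld_r2(g, "p1", "g1")
  links2 <- link_gwas(proxies[1, , drop = FALSE], hits[1, , drop = FALSE],
                      g, r2_threshold = r2_p1g1)
  expect_equal(nrow(links2), 0L)
  # record order invariance
  links3 <- link_gwas(proxies[c(3, 1, 2), ], hits[2:1, ], g,
                      trait_categories = c(lungX = "lung function"))
  expect_equal(links3, links, ignore_attr = "n_skipped")
})

test_that("eQTM cis-window logic is half-open and strand-agnostic", {
  genes <- data.frame(gene_id = "g1", chrom = "chrS", start = 10000L,
                      end = 20000L, strand = "-", stringsAsFactors = FALSE)
  annot <- data.frame(cpg_id = c("cg_in", "cg_edge", "cg_out"),
                      chrom = "chrS", pos = c(5000L, 30000L, 30001L),
                      stringsAsFactors = FALSE)
  mk <- function(cpg, p) data.frame(
    study_id = "st1", snp_id = cpg, snp_chrom = "chrS",
    snp_pos = annot$pos[annot$cpg_id == cpg], target_id = "g1",
    target_type = "gene", p = p, stringsAsFactors = FALSE)
  # window is [0, 30000): 5000 in; exactly 30000 excluded; beyond excluded
  expect_equal(filter_eqtm(mk("cg_in", 1e-6), annot, genes)$cpg_id, "cg_in")
  expect_equal(nrow(filter_eqtm(mk("cg_edge", 1e-6), annot, genes)), 0L)
  expect_equal(nrow(filter_eqtm(mk("cg_out", 1e-6), annot, genes)), 0L)
  # p exactly 1e-5 excluded
  expect_equal(nrow(filter_eqtm(mk("cg_in", 1e-5), annot, genes)), 0L)
})

test_that("eQTL evidence requires SNP near CpG and CpG in gene window", {
  genes <- data.frame(gene_id = "g1", chrom = "chrS", start = 10000L,
                      end = 20000L, strand = "+", stringsAsFactors = FALSE)
  annot <- data.frame(cpg_id = c("cgA", "cgFar"), chrom = "chrS",
                      pos = c(15000L, 500000L), stringsAsFactors = FALSE)
  proxies <- data.frame(cpg_id = c("cgA", "cgA", "cgFar"),
                        snp_id = c("rsNear", "rsFar", "rsNear"),
                        stringsAsFactors = FALSE)
  recs <- rbind(
    mk_qtl("st1", "rsNear", 15000 + 9000, "g1", 1e-6, type = "gene"),
    mk_qtl("st1", "rsFar", 15000 + 11000, "g1", 1e-6, type = "gene"))
  out <- filter_eqtl(recs, proxies, annot, genes)
  # SNP 9 kb from CpG with CpG in window: kept; 11 kb: dropped;
  # cgFar outside the gene window: dropped regardless of SNP
  expect_equal(nrow(out), 1L)
  expect_equal(out$cpg_id, "cgA")
  expect_equal(out$snp_id, "rsNear")
})

test_that("filters are monotone in their thresholds", {
  set.seed(20)
  recs <- mk_qtl(sample(c("st1", "st2", "st3"), 60, TRUE),
                 sprintf("rs%02d", sample(10, 60, TRUE)),
                 sample(90000:110000, 60, TRUE), "cgA",
                 10^-runif(60, 5, 16))
  strict <- filter_mqtls(recs, cpg_annot3, p_max = 1e-12, dist_max = 5000)
  loose <- filter_mqtls(recs, cpg_annot3, p_max = 1e-10, dist_max = 10000)
  expect_true(all(paste(strict$cpg_id, strict$snp_id) %in%
                    paste(loose$cpg_id, loose$snp_id)))
})

test_that("multi-omics tally counts datasets and orders deterministically", {
  ev <- list(mqtl_a = c("cg1", "cg2", "cg3"),
             mqtl_b = c("cg1", "cg2"),
             eqtm = c("cg1", "cg2", "cg4"),
             eqtl = c("cg1", "cg5"),
             gwas_link = c("cg1", "cg2"))
  out <- multi_omics_tally(ev, min_layers = 4)
  expect_equal(out$cpg_id, c("cg1", "cg2"))
  expect_equal(out$n_omics_layers, c(5, 4))
  expect_equal(unname(unlist(out[1, names(ev)])), rep(1L, 5))
  out2 <- multi_omics_tally(ev, min_layers = 2)
  expect_equal(out2$cpg_id[1:2], c("cg1", "cg2"))
  expect_warning(out3 <- multi_omics_tally(ev, min_layers = 6),
                 "exceeds")
  expect_equal(nrow(out3), 0L)
})
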