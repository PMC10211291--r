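# Synthetic cohort generator: bookkeeping, determinism, and the analytic
# identities the simulated world must satisfy.

test_that("reference panel has the requested geometry and determinism", {
  p <- make_reference_panel(600, wb_celltypes(), 20, seed = 1)
  expect_equal(dim(p$profiles), c(600L, 6L))
  expect_equal(length(unlist(p$signature)), 120L)
  expect_false(anyDuplicated(unlist(p$signature)) > 0)
  expect_identical(p, make_reference_panel(600, wb_celltypes(), 20, seed = 1))
  expect_false(identical(
    p$profiles, make_reference_panel(600, wb_celltypes(), 20,
                                     seed = 2)$profiles))
  # positions sorted and unique
  expect_true(all(diff(p$annot$pos) > 0))
  expect_error(make_reference_panel(600, wb_celltypes(), 20),
               "seed")
  expect_error(make_reference_panel(600, c("A", "A"), 20, seed = 1),
               "duplicate")
  expect_error(make_reference_panel(50, wb_celltypes(), 20, seed = 1),
               "n_cpgs")
})

test_that("signature CpGs are separated by at least 0.5 from other types", {
  p <- make_reference_panel(600, wb_celltypes(), 20, seed = 3)
  for (ct in names(p$signature)) {
    own <- p$profiles[p$signature[[ct]], ct]
    other <- p$profiles[p$signature[[ct]],
                        setdiff(colnames(p$profiles), ct), drop = FALSE]
    sep <- apply(abs(own - other), 1, min)
    expect_gte(min(sep), 0.5)
  }
})

test_that("cohort generator produces the configured sizes and covariates", {
  co <- make_cohort(74, 67, seed = 2)
  expect_equal(nrow(co), 141L)
  expect_equal(sum(co$smoking), 67L)
  expect_equal(nrow(make_cohort(2, 2, seed = 0)), 4L)
  expect_error(make_cohort(1, 5, seed = 1), "at least 2")
  expect_identical(co, make_cohort(74, 67, seed = 2))

  # covariate means within 3 SE of configured targets at n = 1000
  big <- make_cohort(500, 500, covariates = list(age_mean = 50, age_sd = 10,
                                                 bmi_mean = 30, bmi_sd = 4),
                     seed = 5)
  expect_lt(abs(mean(big$age) - 50), 3 * 10 / sqrt(1000))
  expect_lt(abs(mean(big$bmi) - 30), 3 * 4 / sqrt(1000))
  expect_lt(abs(mean(big$sex == "F") - 0.5), 3 * 0.5 / sqrt(1000))
})

test_that("degenerate generator returns pure reference profiles", {
  p <- tiny_panel()
  co <- tiny_cohort(4, 4)
  sim <- simulate_methylomes(p, co, noise_sd = 0, purity = 1, seed = 7)
  for (ct in wb_celltypes()$name) {
    expect_equal(max(abs(sim$fractions[[ct]] -
                           p$profiles[, ct])), 0)
  }
})

test_that("whole blood is the exact proportion-weighted mixture at zero noise", {
  p <- tiny_panel()
  co <- tiny_cohort(5, 5)
  sim <- simulate_methylomes(p, co, noise_sd = 0, purity = 1, seed = 8)
  mix <- p$profiles %*% t(sim$truth$wb_proportions)
  ns <- co$smoking == 0
  expect_lt(max(abs(sim$fractions$WB[, ns] - mix[, ns])), 1e-12)
  expect_equal(unname(rowSums(sim$truth$wb_proportions)),
               rep(1, nrow(co)), tolerance = 1e-9)
})

test_that("injected direct effects are recovered by group-mean differencing", {
  p <- tiny_panel(seed = 21)
  co <- tiny_cohort(40, 40, seed = 22)
  # pick mid-methylation CpGs so the -0.10 delta is realized unclamped
  mid <- rownames(p$profiles)[abs(p$profiles[, "Bcell"] - 0.5) < 0.3][1:3]
  eff <- data.frame(cpg_id = mid, cell_type = "Bcell", delta = -0.10,
                    mechanism = "direct", stringsAsFactors = FALSE)
  sim <- simulate_methylomes(p, co, effects = eff, noise_sd = 0.05,
                             purity = 1, seed = 23, fractions = "Bcell")
  b <- sim$fractions$Bcell
  d <- rowMeans(b[mid, co$smoking == 1, drop = FALSE]) -
    rowMeans(b[mid, co$smoking == 0, drop = FALSE])
  # logit-scale noise 0.05 maps to < 0.01 beta-scale SD per CpG here
  mc_se <- 0.01 * sqrt(2 / 40)
  expect_lt(max(abs(d - (-0.10))), 3 * mc_se + 0.005)

  expect_error(
    simulate_methylomes(p, co, effects = data.frame(
      cpg_id = "nope", cell_type = "Bcell", delta = 0.1), seed = 1),
    "unknown CpG")
  expect_error(
    simulate_methylomes(p, co, effects = data.frame(
      cpg_id = mid[1], cell_type = "Tcell", delta = 0.1), seed = 1),
    "unknown cell type")
})

test_that("all simulated betas stay inside the clamp", {
  p <- tiny_panel()
  co <- tiny_cohort(5, 5)
  sim <- simulate_methylomes(p, co, noise_sd = 2, seed = 9)
  for (fr in names(sim$fractions)) {
    expect_true(all(sim$fractions[[fr]] >= 1e-6 &
                      sim$fractions[[fr]] <= 1 - 1e-6))
  }
})

test_that("subtype mode implements the naive-to-memory shift via proportions", {
  p <- tiny_panel(seed = 31)
  sp <- make_subtype_panel(p, seed = 32)
  co <- make_cohort(60, 60, seed = 33)
  bcfg <- list(naive_mean_ns = 0.600, naive_mean_sm = 0.528,
               memory_mean_ns = 0.313, memory_mean_sm = 0.360)
  sim <- simulate_methylomes(p, co, subtype_panel = sp, b_config = bcfg,
                             noise_sd = 0, seed = 34, fractions = "Bcell")
  sh <- sim$truth$b_subtype_shares
  sm <- co$smoking == 1
  d_naive <- mean(sh[sm, "NaiveB"]) - mean(sh[!sm, "NaiveB"])
  # Dirichlet concentration 200: group-mean SE ~ 0.45 pp
  expect_lt(abs(d_naive - (-0.072)), 3 * 0.0045)
  # B fraction equals the exact subtype mixture at zero noise
  mix <- sp$profiles %*% t(sh)
  expect_lt(max(abs(sim$fractions$Bcell - mix)), 1e-12)
})

test_that("genetics: LD targets, allele frequencies and determinism", {
  p <- tiny_panel()
  co <- make_cohort(250, 250, seed = 41)
  g1 <- simulate_genetics(co, p$annot, n_blocks = 4, snps_per_block = 3,
                          within_block_r2 = 1.0, seed = 42)
  # r2 = 1: duplicated dosage columns within each block
  expect_equal(g1$genotypes["rs_b01_01", ], g1$genotypes["rs_b01_02", ])
  expect_equal(ld_r2(g1$genotypes, "rs_b02_01", "rs_b02_03"), 1.0)

  g2 <- simulate_genetics(co, p$annot, n_blocks = 6, snps_per_block = 4,
                          maf_range = c(0.2, 0.4), within_block_r2 = 0.8,
                          seed = 43)
  # allele frequency within the configured range up to binomial SE
  af <- rowMeans(g2$genotypes) / 2
  se <- sqrt(0.4 * 0.6 / (2 * 500))
  expect_true(all(af > 0.2 - 4 * se & af < 0.4 + 4 * se))
  # within-block dosage r2 near the 0.8 target on average
  r2s <- sapply(1:6, function(b) ld_r2(g2$genotypes,
                                       sprintf("rs_b%02d_01", b),
                                       sprintf("rs_b%02d_02", b)))
  expect_lt(abs(mean(r2s) - 0.8), 0.1)
  expect_identical(g2, simulate_genetics(
    co, p$annot, n_blocks = 6, snps_per_block = 4,
    maf_range = c(0.2, 0.4), within_block_r2 = 0.8, seed = 43))
})

test_that("null mQTL slopes leave ~no pairs at the replication filter", {
  p <- tiny_panel()
  co <- tiny_cohort(70, 71, seed = 51)
  g <- simulate_genetics(co, p$annot, n_blocks = 6, snps_per_block = 3,
                         mqtl_specs = NULL, eqtl_specs = NULL,
                         eqtm_specs = NULL, seed = 52)
  pr <- filter_mqtls(g$mqtl_records, p$annot)
  expect_equal(nrow(pr), 0L)
})

test_that("injected QTL effects replicate across studies and pass filters", {
  p <- tiny_panel()
  co <- tiny_cohort(70, 71, seed = 61)
  g <- simulate_genetics(co, p$annot, n_blocks = 6, snps_per_block = 3,
                         seed = 62)
  pr <- filter_mqtls(g$mqtl_records, p$annot)
  expect_setequal(paste(pr$cpg_id, pr$snp_id),
                  paste(g$truth$mqtl$cpg_id, g$truth$mqtl$snp_id))
  expect_true(all(pr$n_studies >= 2))
})
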