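# EWAS: M transform, winsorization, robust fits, multiple testing,
# specificity and concordance.

test_that("M-value transform matches its closed form and inverts", {
  expect_equal(mvalue_transform(0.5), 0)
  expect_equal(mvalue_transform(0.8), 2)
  expect_equal(mvalue_transform(0), log2(1e-6 / (1 - 1e-6)))
  expect_equal(mvalue_transform(0), -19.93157, tolerance = 1e-5)
  b <- seq(0.01, 0.99, by = 0.01)
  expect_equal(mvalue_inverse(mvalue_transform(b)), b, tolerance = 1e-12)
  expect_true(all(diff(mvalue_transform(b)) > 0))
  expect_error(mvalue_transform(0.5, eps = 0.7))
})

test_that("winsorization clamps rows at type-7 quantiles", {
  m <- rbind(a = 0:9, b = rep(3, 10))
  w <- winsorize_rows(m, 0.10)
  expect_equal(unname(w["a", ]), pmin(pmax(0:9, 0.45), 8.55))
  expect_equal(unname(w["b", ]), rep(3, 10))      # constant row unchanged
  expect_equal(winsorize_rows(m, 0), m)           # fraction 0 is identity
})

test_that("Huber fit equals least squares on clean data", {
  # noise-free linear structure: coefficient recovered exactly
  set.seed(42)
  n <- 40
  sheet <- data.frame(subject_id = paste0("S", 1:n),
                      smoking = rep(0:1, n / 2),
                      age = rnorm(n, 40, 10), sex = sample(c("M", "F"), n, TRUE),
                      ancestry = sample(c("EUR", "AFR", "OTH"), n, TRUE),
                      bmi = rnorm(n, 27, 4), stringsAsFactors = FALSE)
  m <- 2 * sheet$smoking + 0.01 * sheet$age
  beta <- matrix(mvalue_inverse(rbind(m, m)), nrow = 2,
                 dimnames = list(c("cg1", "cg2"), sheet$subject_id))
  res <- fit_ewas(beta, sheet)
  expect_equal(res$coefficient, c(2, 2), tolerance = 1e-6)
  expect_true(all(res$converged))
  expect_equal(res$n_used, c(n, n))
})

test_that("winsorized and raw EWAS agree on rows without outliers", {
  set.seed(43)
  n <- 30
  sheet <- data.frame(subject_id = paste0("S", 1:n),
                      smoking = rep(0:1, n / 2), age = rnorm(n, 40, 5),
                      sex = sample(c("M", "F"), n, TRUE),
                      ancestry = sample(c("EUR", "AFR"), n, TRUE),
                      bmi = rnorm(n, 27, 4), stringsAsFactors = FALSE)
  m <- matrix(rnorm(5 * n, 0, 0.2), 5,
              dimnames = list(paste0("cg", 1:5), sheet$subject_id))
  # rows whose extremes tie at the clamp quantiles are left untouched:
  # repeated values put the 5% and 95% quantiles on the values themselves
  m[1, ] <- rep(c(-0.4, 0.4), length.out = n) + 0.3 * sheet$smoking
  m[2, ] <- rep(c(-0.2, 0, 0.2), length.out = n)
  mw <- winsorize_rows(m)
  untouched <- which(apply(mw == m, 1, all))
  expect_true(all(c(1, 2) %in% untouched))
  r1 <- fit_ewas(mvalue_inverse(m), sheet)
  r2 <- fit_ewas(mvalue_inverse(m), sheet, winsorize = TRUE)
  expect_equal(r1$p[untouched], r2$p[untouched], tolerance = 1e-6)
})

test_that("rank-deficient designs are rejected naming the aliased column", {
  n <- 20
  sheet <- data.frame(subject_id = paste0("S", 1:n),
                      smoking = rep(0:1, n / 2), age = 40, sex = "M",
                      ancestry = "EUR", bmi = 25, stringsAsFactors = FALSE)
  beta <- matrix(0.5, 2, n,
                 dimnames = list(c("cg1", "cg2"), sheet$subject_id))
  # age, sex, ancestry and bmi are all constant -> aliased with intercept
  expect_error(fit_ewas(beta, sheet), "rank deficient.*age")
})

test_that("null EWAS p values are calibrated and effects are detected", {
  p <- make_reference_panel(500, wb_celltypes(), 10, seed = 91)
  co <- make_cohort(65, 65, seed = 92)
  mid <- rownames(p$profiles)[abs(p$profiles[, "Gran"] - 0.5) < 0.25][1:5]
  eff <- data.frame(cpg_id = mid, cell_type = "Gran", delta = -0.10,
                    mechanism = "direct", stringsAsFactors = FALSE)
  sim <- simulate_methylomes(p, co, effects = eff, noise_sd = 0.1,
                             purity = 1, seed = 93, fractions = "Gran")
  res <- fit_ewas(sim$fractions$Gran, co)
  null_p <- res$p[!res$cpg_id %in% mid]
  expect_gt(mean(null_p < 0.05), 0.03)
  expect_lt(mean(null_p < 0.05), 0.07)
  hit <- res[res$cpg_id %in% mid, ]
  # beta-scale noise SD is ~<= 0.017 here, so 3 Monte-Carlo SE ~<= 0.01
  expect_lt(max(abs(hit$delta_meth - (-0.10))), 0.01)
  # far below the array-scale genome-wide threshold
  expect_true(all(hit$p < 1.2e-7))
})

test_that("multiple testing produces BH q values and Bonferroni flags", {
  res <- data.frame(cpg_id = paste0("cg", 1:4),
                    p = c(0.01, 0.02, 0.03, 0.04))
  out <- multiple_testing(res)
  expect_equal(out$q, rep(0.04, 4))
  # single test: q = p
  expect_equal(multiple_testing(data.frame(cpg_id = "cg1", p = 0.03))$q,
               0.03)
  # array-scale override reproduces the printed genome-wide threshold
  big <- multiple_testing(data.frame(cpg_id = "cg1", p = 1e-8),
                          n_tests = 420000)
  expect_equal(signif(attr(big, "bonferroni_threshold"), 2), 1.2e-7)
  expect_true(big$bonferroni)
  # nested thresholds: Bonferroni calls are a subset of FDR-5% calls
  set.seed(9)
  res2 <- multiple_testing(data.frame(cpg_id = paste0("c", 1:200),
                                      p = c(runif(20, 0, 1e-5), runif(180))))
  expect_true(all(res2$q[res2$bonferroni] < 0.05))
})

test_that("specificity calls match hand evaluation and a brute-force oracle", {
  p_mat <- rbind(
    cg1 = c(Bcell = 1e-12, Gran = 1e-3, Mono = 0.02, NK = 0.5,
            CD4T = 0.9, CD8T = 0.04),
    cg2 = c(Bcell = 1e-12, Gran = 1e-9, Mono = 0.5, NK = 0.5,
            CD4T = 0.5, CD8T = 0.5),
    cg3 = c(Bcell = 0.5, Gran = 0.5, Mono = 0.5, NK = 0.5,
            CD4T = 0.5, CD8T = 0.5))
  thr <- 1.2e-7
  sig <- p_mat < thr
  out <- classify_specificity(p_mat, sig)
  # cg1: significant only in B, and 1e-12 * 1e4 <= every other p
  expect_true(out$cell_type_specific[1])
  expect_true(out$highly_specific[1])
  expect_equal(out$best_cell_type[1], "Bcell")
  # cg2: two significant types, ratio only 1e3
  expect_false(out$cell_type_specific[2])
  expect_false(out$highly_specific[2])
  # cg3: all tied
  expect_false(out$highly_specific[3])
  expect_true(is.na(out$best_cell_type[3]))

  # property: agreement with a direct reimplementation on random tables
  brute <- function(p, sig, ratio = 1e4) {
    t(sapply(seq_len(nrow(p)), function(i) {
      b <- which.min(p[i, ])
      c(spec = sum(sig[i, ]) == 1,
        high = sum(p[i, ] == p[i, b]) == 1 &&
          all(p[i, b] * ratio <= p[i, -b]))
    }))
  }
  set.seed(10)
  for (k in c(2, 4, 6)) {
    pm <- matrix(10^-runif(20 * k, 0, 12), 20, k,
                 dimnames = list(paste0("cg", 1:20), paste0("T", 1:k)))
    sg <- pm < 1e-6
    mine <- classify_specificity(pm, sg)
    ref <- brute(pm, sg)
    expect_equal(mine$cell_type_specific, unname(ref[, "spec"]))
    expect_equal(mine$highly_specific, unname(ref[, "high"]))
  }
})

test_that("directional concordance counts majority signs", {
  d <- rbind(cg1 = c(-1, -1, -1, -1, 1, -1) / 100,
             cg2 = rep(0.01, 6),
             cg3 = c(1, 1, 1, -1, -1, -1) / 100,
             cg4 = c(0, 0.01, 0.01, -0.01, 0, 0))
  out <- directional_concordance(d)
  expect_equal(out$concordant_n, c(5L, 6L, 3L, 2L))
  expect_equal(out$majority_sign, c("-", "+", "±", "+"))
})
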