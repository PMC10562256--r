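test_that("genotype simulation is deterministic and respects the LD model", {
  g1 <- simulate_genotypes(40, 60, seed = 3)
  g2 <- simulate_genotypes(40, 60, seed = 3)
  expect_identical(g1$dosage, g2$dosage)
  expect_true(all(g1$dosage %in% 0:2))

  # independence: with ld_rho = 0 adjacent dosages are uncorrelated
  g0 <- simulate_genotypes(2000, 100, maf_range = c(0.1, 0.5),
                           ld_rho = 0, seed = 7)
  cors <- sapply(seq_len(99), function(j) {
    cor(g0$dosage[j, ], g0$dosage[j + 1, ])
  })
  expect_lt(mean(abs(cors)), 0.05)

  # strong LD raises adjacent correlation well above the null
  gl <- simulate_genotypes(2000, 100, maf_range = c(0.1, 0.5),
                           ld_block_size = 100, ld_rho = 0.9, seed = 7)
  cors_ld <- sapply(seq_len(99), function(j) {
    cor(gl$dosage[j, ], gl$dosage[j + 1, ])
  })
  expect_gt(mean(cors_ld), 0.5)
})

test_that("dosage means match the binomial sampling oracle at fixed MAF", {
  n <- 5000
  g <- simulate_genotypes(n, 40, maf_range = c(0.5, 0.5), seed = 9)
  # dosage ~ Binomial(2, 0.5): mean 1, SE of the per-variant mean
  se <- sqrt(2 * 0.5 * 0.5 / n)
  expect_true(all(abs(rowMeans(g$dosage) - 1) < 3 * se + 3 * se))
  expect_lt(abs(mean(g$dosage) - 1), 3 * se)
})

test_that("empirical MAF never falls below the configured bound by more than 3 SE", {
  g <- simulate_genotypes(500, 200, maf_range = c(0.1, 0.4), seed = 21)
  emp_f <- rowMeans(g$dosage) / 2
  emp_maf <- pmin(emp_f, 1 - emp_f)
  se <- sqrt(0.1 * 0.9 / (2 * 500))
  expect_true(all(emp_maf > 0.1 - 3 * se))
})

test_that("planted haQTL effects are recovered exactly in the noiseless limit", {
  cfg <- sim_config(n_individuals_per_tissue = c(t1 = 40),
                    n_variants = 200, n_ares = 10, n_genes = 5,
                    maf_range = c(0.2, 0.5),
                    noise_sd = 1e-9, covariate_count = 0,
                    frac_gare = 1, seed = 13)
  geno <- list(t1 = simulate_genotypes(40, 200, maf_range = c(0.2, 0.5),
                                       seed = 13))
  act <- simulate_activity(geno, cfg, seed = 99)
  tr <- act$truth$haqtl
  for (r in seq_len(nrow(tr))) {
    y <- act$activity$t1[tr$are_id[r], ]
    g <- geno$t1$dosage[tr$variant_id[r], ]
    slope <- coef(lm(y ~ g))[2]
    expect_lt(abs(unname(slope) - tr$beta[r]), 1e-6)
  }
})

test_that("sharing probability one propagates every effect with identical sign", {
  sm <- matrix(1, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  cfg <- sim_config(n_individuals_per_tissue = c(a = 20, b = 20),
                    n_variants = 200, n_ares = 30, n_genes = 5,
                    sharing_matrix = sm, frac_gare = 1, seed = 2)
  geno <- list(a = simulate_genotypes(20, 200, seed = 2),
               b = simulate_genotypes(20, 200, seed = 3))
  act <- simulate_activity(geno, cfg)
  tr <- act$truth$haqtl
  for (are in unique(tr$are_id)) {
    sub <- tr[tr$are_id == are, ]
    expect_setequal(sub$tissue, c("a", "b"))
    expect_length(unique(sign(sub$beta)), 1)
    expect_length(unique(sub$variant_id), 1)
  }
})

test_that("realized sharing matches the planted probability within binomial CI", {
  sm <- matrix(c(1, 0.6, 0.6, 1), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  shared <- 0L; total <- 0L
  for (sd in 1:4) {
    cfg <- sim_config(n_individuals_per_tissue = c(a = 4, b = 4),
                      n_variants = 2000, n_ares = 600, n_genes = 5,
                      sharing_matrix = sm, frac_gare = 1, seed = sd)
    geno <- list(a = simulate_genotypes(4, 2000, seed = sd),
                 b = simulate_genotypes(4, 2000, seed = sd + 100))
    act <- simulate_activity(geno, cfg)
    h <- act$truth$haqtl
    shared <- shared + sum(!h$primary)
    total <- total + sum(h$primary)
  }
  expect_gte(total, 500)
  half_ci <- 1.96 * sqrt(0.6 * 0.4 / total)
  expect_lt(abs(shared / total - 0.6), half_ci)
})

test_that("expression links follow frac_shared_causal and eQTL betas are recoverable", {
  mk <- function(frac, seed = 30) {
    cfg <- sim_config(n_individuals_per_tissue = c(t1 = 200),
                      n_variants = 400, n_ares = 20, n_genes = 20,
                      maf_range = c(0.2, 0.5),
                      frac_shared_causal = frac, frac_gare = 1,
                      noise_sd = 1, eqtl_effect_sd = 1, seed = seed)
    geno <- list(t1 = simulate_genotypes(200, 400,
                                         maf_range = c(0.2, 0.5),
                                         seed = seed))
    act <- simulate_activity(geno, cfg)
    list(expr = simulate_expression(geno, cfg, act$truth), geno = geno)
  }
  all_shared <- mk(1)
  expect_equal(nrow(all_shared$expr$truth$links), 20)
  none <- mk(0)
  expect_equal(nrow(none$expr$truth$links), 0)

  # OLS recovery of planted eQTL effects: per-gene estimate within 3 SE,
  # mean absolute error at the sampling-distribution scale
  ex <- all_shared$expr
  tr <- ex$truth$eqtl[ex$truth$eqtl$tissue == "t1", ]
  errs <- sapply(seq_len(nrow(tr)), function(r) {
    y <- ex$expression$t1[tr$gene_id[r], ]
    g <- all_shared$geno$t1$dosage[tr$variant_id[r], ]
    fit <- summary(lm(y ~ g))$coefficients
    expect_lt(abs(fit[2, 1] - tr$beta[r]), 3 * fit[2, 2] + 0.02)
    abs(fit[2, 1] - tr$beta[r])
  })
  expect_lt(mean(errs), 0.1)
})

test_that("fragment simulation inverts the activity formula in expectation", {
  ares <- data.frame(are_id = c("A1", "A2", "A3"), chrom = "chr1",
                     start = c(1000L, 3000L, 6000L),
                     end = c(1600L, 3500L, 7000L))
  act <- c(2, 0, 1.5)

  f0 <- simulate_fragments(act, ares, seed = 5)
  expect_identical(f0, simulate_fragments(act, ares, seed = 5))
  # zero-activity ARE receives no fragments
  expect_false(any(f0$start >= 3000 & f0$end <= 3500))

  # Poisson oracle: mean quantified activity over replicates within 3 SE
  reps <- 500
  qs <- sapply(seq_len(reps), function(i) {
    fr <- simulate_fragments(act, ares, mean_depth = 1,
                             seed = 1000 + i)
    quantify_activity(fr, ares, sample_ids = "s1")[, 1]
  })
  for (i in c(1, 3)) {
    len <- ares$end[i] - ares$start[i]
    eff <- min(200, len)
    lambda <- act[i] * len / eff
    se_mean <- sqrt(lambda / reps) * eff / len
    expect_lt(abs(mean(qs[i, ]) - act[i]), 3 * se_mean)
  }
  expect_error(simulate_fragments(act, ares, mean_depth = -1), "positive")
  expect_error(simulate_fragments(c(-1, 0, 0), ares), "non-negative")
})

test_that("GWAS simulation plants detectable causal signals deterministically", {
  cfg <- sim_config(n_individuals_per_tissue = c(t1 = 100),
                    n_variants = 300, n_ares = 10, n_genes = 5,
                    frac_gare = 1, seed = 4)
  geno <- list(t1 = simulate_genotypes(100, 300, seed = 4))
  act <- simulate_activity(geno, cfg)
  gw1 <- simulate_gwas(geno$t1, act$truth, shared_fraction = 1,
                       seed = 6, causal_z = 12)
  expect_identical(gw1, simulate_gwas(geno$t1, act$truth,
                                      shared_fraction = 1,
                                      seed = 6, causal_z = 12))
  causal <- attr(gw1, "gwas_causal")
  expect_true(length(causal) >= 1)
  expect_lt(min(gw1$p[gw1$variant %in% causal]), 5e-8)
  expect_error(simulate_gwas(geno$t1, act$truth, n_gwas = 1), ">= 2")
})

test_that("configuration bounds are enforced", {
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(frac_shared_causal = 1.5), "frac_shared_causal")
  expect_error(sim_config(n_individuals_per_tissue = c(a = 1)), "at least 2")
  bad_sm <- matrix(c(1, 0.2, 0.8, 1), 2, 2)
  expect_error(
    sim_config(n_individuals_per_tissue = c(a = 10, b = 10),
               sharing_matrix = bad_sm),
    "symmetric")
  cfg <- sim_config(n_individuals_per_tissue = c(a = 10, b = 10))
  expect_error(
    simulate_activity(list(a = simulate_genotypes(10, 100, seed = 1)), cfg),
    "missing for tissue")
})
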