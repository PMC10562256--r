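test_that("residualization matches a direct normal-equations solve", {
  withr::with_seed(101, {
    n <- 50
    X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, sprintf("c%d", 1:5)))
    Y <- matrix(rnorm(3 * n), 3, n, dimnames = list(sprintf("f%d", 1:3), NULL))
  })
  res <- residualize(Y, X)
  expect_equal(attr(res, "df_removed"), 5L)

  D <- cbind(1, X)
  for (i in 1:3) {
    # independent oracle: solve the normal equations directly
    beta <- solve(t(D) %*% D, t(D) %*% Y[i, ])
    oracle <- Y[i, ] - as.numeric(D %*% beta)
    expect_lt(max(abs(res[i, ] - oracle)), 1e-10)
    # residuals orthogonal to the design
    expect_lt(max(abs(t(D) %*% res[i, ])), 1e-8)
  }

  # covariate orthogonal to the phenotype: residual = centered phenotype
  y <- rep(c(-1, 1), 25)
  x_orth <- rep(c(1, 1, -1, -1), length.out = 50)   # orthogonal to y
  r1 <- residualize(matrix(y, 1), matrix(x_orth, ncol = 1))
  expect_equal(as.numeric(r1), y - mean(y), tolerance = 1e-12)

  # phenotype equal to a covariate: residual vanishes
  r2 <- residualize(matrix(X[, 1], 1), X)
  expect_lt(sqrt(sum(r2^2)), 1e-8)

  # collinear design is reported with the offending column
  X_bad <- cbind(X, c5_dup = X[, 5])
  expect_error(residualize(Y, X_bad), "collinear")

  # latent factors: removing all PCs of a low-rank matrix leaves noise
  withr::with_seed(5, {
    L <- matrix(rnorm(6 * 2), 6, 2) %*% matrix(rnorm(2 * 50), 2, 50)
  })
  r3 <- residualize(L, NULL, n_latent_factors = 2)
  expect_lt(max(abs(r3)), 1e-8)
})

test_that("nominal scan equals the closed-form simple-regression oracle", {
  g <- toy_genotypes(60, 40, seed = 15)
  center <- 20000
  withr::with_seed(16, y <- rnorm(60))
  nom <- nominal_scan(center, y, g, window_bp = 10000, maf_min = 0)
  expect_true(all(abs(nom$distance_to_center) <= 10000))
  for (r in seq_len(nrow(nom))) {
    x <- g$dosage[nom$variant_id[r], ]
    fit <- summary(lm(y ~ x))$coefficients
    expect_lt(abs(nom$beta[r] - fit[2, 1]), 1e-10)
    expect_lt(abs(nom$t_stat[r] - fit[2, 3]), 1e-10)
    expect_lt(abs(nom$p_nominal[r] - fit[2, 4]), 1e-10)
    expect_lt(abs(nom$se[r] - fit[2, 2]), 1e-10)
  }

  # p consistent with t and the residual degrees of freedom
  expect_equal(nom$p_nominal,
               2 * pt(-abs(nom$t_stat), 60 - 2), tolerance = 1e-8)

  # phenotype equal to a variant's dosage: beta 1, essentially zero p
  v <- "var0020"
  nom2 <- nominal_scan(center, as.numeric(g$dosage[v, ]), g,
                       window_bp = 10000, maf_min = 0)
  row <- nom2[nom2$variant_id == v, ]
  expect_equal(row$beta, 1, tolerance = 1e-10)
  expect_lt(row$p_nominal, 1e-12)
})

test_that("MAF and window filters are applied at their boundaries", {
  # construct dosages with known allele frequencies
  n <- 1000
  dos <- rbind(
    var_low  = rep(c(2, rep(0, 999 / 2.04)), length.out = n),  # placeholder
    var_pass = rep(0:2, length.out = n)
  )
  # exact MAF 0.049 and 0.05 via carrier counts
  dos["var_low", ] <- 0
  dos["var_low", seq_len(98)] <- 1     # 98/2000 = 0.049
  dos["var_pass", ] <- 0
  dos["var_pass", seq_len(100)] <- 1   # 100/2000 = 0.05
  g <- structure(list(
    dosage = dos,
    info = data.frame(variant_id = rownames(dos), chrom = "chr1",
                      pos = c(1000L, 2000L), maf = c(0.049, 0.05))
  ), class = "genotype_matrix")
  withr::with_seed(3, y <- rnorm(n))
  nom <- nominal_scan(1500, y, g, window_bp = 5000, maf_min = 0.05)
  expect_equal(nom$variant_id, "var_pass")

  # no variants in window is an empty result, not an error
  empty <- nominal_scan(1e9, y, g, window_bp = 1000)
  expect_equal(nrow(empty), 0)
})

test_that("empirical p behaves like the direct permutation estimate", {
  g <- toy_genotypes(80, 30, seed = 22)
  withr::with_seed(23, y <- rnorm(80))
  loc <- empirical_p(15000, y, g, n_permutations = 1000, seed = 4,
                     window_bp = 15000, maf_min = 0)
  expect_identical(
    loc$p_empirical,
    empirical_p(15000, y, g, n_permutations = 1000, seed = 4,
                window_bp = 15000, maf_min = 0)$p_empirical
  )
  # beta-approximated and direct estimates agree on a null locus
  expect_lt(abs(loc$p_empirical - loc$p_empirical_direct),
            0.05 + 2 * sqrt(loc$p_empirical_direct *
                              (1 - loc$p_empirical_direct) / 1000))

  expect_error(empirical_p(15000, rep(1, 80), g), "distinct")
  expect_error(empirical_p(15000, y, g, n_permutations = 50), ">= 100")
})

test_that("a single-variant locus gives near-uniform Beta shapes", {
  # one variant in the window: the minimum of one uniform p is uniform,
  # so the fitted shapes should be near (1, 1) and the empirical p near
  # the nominal p
  n <- 200
  withr::with_seed(31, {
    dos <- matrix(rbinom(n, 2, 0.4), 1, n,
                  dimnames = list("v1", sprintf("i%d", 1:n)))
    g <- structure(list(
      dosage = dos,
      info = data.frame(variant_id = "v1", chrom = "chr1", pos = 1000L,
                        maf = 0.4)
    ), class = "genotype_matrix")
    y <- rnorm(n)
  })
  loc <- empirical_p(1000, y, g, n_permutations = 2000, seed = 9,
                     window_bp = 5000, maf_min = 0)
  expect_lt(abs(loc$beta_shape1 - 1), 0.15)
  expect_lt(abs(loc$beta_shape2 - 1), 0.15)
  expect_lt(abs(loc$p_empirical - loc$p_nominal),
            0.2 * max(loc$p_nominal, 0.05))
})

test_that("gARE calling applies empirical and per-locus nominal thresholds", {
  # with shapes (1, 1) the nominal threshold equals the target itself
  expect_equal(locus_nominal_threshold(1, 1, 0.005), 0.005)

  loci <- data.frame(
    feature_id = c("A", "B"),
    lead_variant = c("v1", "v2"),
    beta = c(1, 1), se = c(0.1, 0.1), t_stat = c(10, 10),
    p_nominal = c(1e-6, 1e-6), distance_to_center = c(0L, 0L),
    n_variants_tested = c(3L, 3L),
    beta_shape1 = c(1, 1), beta_shape2 = c(1, 1),
    p_empirical = c(0.004, 0.006), p_empirical_direct = c(0.004, 0.006),
    nominal_threshold = c(0.005, 0.005), stringsAsFactors = FALSE
  )
  nominals <- list(
    A = data.frame(feature_id = "A", variant_id = c("v1", "v3", "v4"),
                   beta = c(1, 0.5, 0.2), se = 0.1, t_stat = c(10, 5, 2),
                   p_nominal = c(1e-6, 0.004, 0.2),
                   distance_to_center = c(0L, 10L, 20L), maf = 0.3,
                   stringsAsFactors = FALSE),
    B = data.frame(feature_id = "B", variant_id = "v2", beta = 1,
                   se = 0.1, t_stat = 10, p_nominal = 1e-6,
                   distance_to_center = 0L, maf = 0.3,
                   stringsAsFactors = FALSE)
  )
  scan <- structure(list(loci = loci, nominals = nominals, df_removed = 0L),
                    class = "qtl_scan")
  set_ <- call_gares(scan, 0.005)
  # empirical p 0.004 passes, 0.006 does not
  expect_equal(set_$features$feature_id, "A")
  # variants at p <= the locus threshold are haQTLs; the lead is included
  expect_setequal(set_$qtls$variant_id, c("v1", "v3"))
  expect_true("v1" %in% set_$qtls$variant_id)
})

test_that("discovery power increases with effect size and sample size", {
  discovery_rate <- function(beta, n, n_loci = 12, seed0 = 500) {
    hits <- 0
    for (i in seq_len(n_loci)) {
      g <- simulate_genotypes(n, 30, maf_range = c(0.2, 0.5),
                              seed = seed0 + i)
      withr::with_seed(seed0 + 1000 + i, {
        y <- beta * g$dosage[15, ] + rnorm(n)
      })
      loc <- empirical_p(15000, y, g, n_permutations = 200,
                         seed = seed0 + 2000 + i, window_bp = 15000)
      hits <- hits + (loc$p_empirical <= 0.005)
    }
    hits / n_loci
  }
  rates_beta <- c(discovery_rate(0.1, 80), discovery_rate(0.5, 80),
                  discovery_rate(1.2, 80))
  expect_true(all(diff(rates_beta) >= 0))
  expect_lt(rates_beta[1], rates_beta[3])

  rates_n <- c(discovery_rate(0.5, 30), discovery_rate(0.5, 80),
               discovery_rate(0.5, 200))
  expect_true(all(diff(rates_n) >= 0))
  expect_lt(rates_n[1], rates_n[3])
})
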