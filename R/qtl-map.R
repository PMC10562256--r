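#' Residualize phenotypes on covariates and latent factors
#'
#' Removes known covariates plus the top principal components of the
#' phenotype matrix (the standard stand-in for latent-factor methods) by
#' ordinary least squares, feature by feature, then re-centers. The
#' returned matrix carries the number of regressors removed in attribute
#' `df_removed` so downstream tests can adjust degrees of freedom.
#'
#' @param phenotype_matrix Feature x sample matrix.
#' @param covariates Sample x covariate matrix (or NULL).
#' @param n_latent_factors Number of phenotype principal components to
#'   remove (default 0).
#'
#' @return Residual matrix of the same shape, rows centered; attribute
#'   `df_removed` = number of non-intercept regressors removed.
#' @export
residualize <- function(phenotype_matrix, covariates = NULL,
                        n_latent_factors = 0) {
  n <- ncol(phenotype_matrix)
  design <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) {
      stop("covariates must have one row per sample", call. = FALSE)
    }
    design <- cbind(design, covariates)
  }
  if (n_latent_factors > 0) {
    pcs <- stats::prcomp(t(phenotype_matrix), center = TRUE,
                         scale. = FALSE)$x[, seq_len(n_latent_factors),
                                           drop = FALSE]
    colnames(pcs) <- sprintf("PC%d", seq_len(n_latent_factors))
    design <- cbind(design, pcs)
  }
  if (n <= ncol(design)) {
    stop("more regressors than samples", call. = FALSE)
  }
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    bad <- colnames(design)[qr_d$pivot[(qr_d$rank + 1):ncol(design)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  res <- t(qr.resid(qr_d, t(phenotype_matrix)))
  res <- res - rowMeans(res)   # re-center (numerically; residuals of an
                               # intercept model are already centered)
  dimnames(res) <- dimnames(phenotype_matrix)
  attr(res, "df_removed") <- ncol(design) - 1L
  res
}

# Vectorized simple regressions of a phenotype vector on each column of a
# dosage matrix (samples x variants). `df` is the residual degrees of
# freedom (n - 2 - covariates removed upstream).
simple_regressions <- function(y, X, df) {
  yc <- y - mean(y)
  Xc <- sweep(X, 2, colMeans(X))
  sxx <- colSums(Xc^2)
  syy <- sum(yc^2)
  sxy <- as.numeric(crossprod(Xc, yc))
  r <- sxy / sqrt(pmax(sxx * syy, 1e-300))
  r <- pmin(pmax(r, -1), 1)
  beta <- sxy / pmax(sxx, 1e-300)
  tstat <- r * sqrt(df) / sqrt(pmax(1 - r^2, 1e-300))
  se <- ifelse(abs(tstat) > 0, beta / tstat, sqrt(syy / sxx / df))
  p <- 2 * stats::pt(-abs(tstat), df)
  list(beta = beta, se = abs(se), t = tstat, p = p, r = r)
}

#' Nominal cis scan of one feature
#'
#' Simple linear regression of the (already residualized) phenotype on the
#' dosage of every variant within `window_bp` of the feature center that
#' passes the MAF filter. Degrees of freedom are reduced by the number of
#' covariates removed during residualization.
#'
#' @param feature_center Genomic position of the feature center (bp).
#' @param residual_phenotype Numeric vector across samples.
#' @param genotypes A `genotype_matrix` whose individuals match the
#'   phenotype order.
#' @param window_bp Cis window from the center (default 1e5).
#' @param maf_min Minimum minor allele frequency (default 0.05), computed
#'   from the dosages of the tested individuals.
#' @param df_removed Covariates removed upstream (default 0).
#' @param feature_id Feature label for the output.
#'
#' @return data.frame of class rows (feature_id, variant_id, beta, se,
#'   t_stat, p_nominal, distance_to_center, maf); zero rows if no variant
#'   passes.
#' @export
nominal_scan <- function(feature_center, residual_phenotype, genotypes,
                         window_bp = 1e5, maf_min = 0.05, df_removed = 0,
                         feature_id = "feature") {
  info <- genotypes$info
  dist <- info$pos - feature_center
  in_win <- abs(dist) <= window_bp
  if (!any(in_win)) return(empty_nominal())
  dos <- genotypes$dosage[in_win, , drop = FALSE]
  af <- rowMeans(dos) / 2
  maf <- pmin(af, 1 - af)
  pass <- maf >= maf_min
  if (!any(pass)) return(empty_nominal())
  dos <- dos[pass, , drop = FALSE]
  n <- length(residual_phenotype)
  df <- n - 2 - df_removed
  fit <- simple_regressions(residual_phenotype, t(dos), df)
  data.frame(
    feature_id = feature_id,
    variant_id = rownames(dos),
    beta = fit$beta, se = fit$se, t_stat = fit$t, p_nominal = fit$p,
    distance_to_center = dist[in_win][pass],
    maf = maf[pass],
    stringsAsFactors = FALSE
  )
}

empty_nominal <- function() {
  data.frame(feature_id = character(), variant_id = character(),
             beta = numeric(), se = numeric(), t_stat = numeric(),
             p_nominal = numeric(), distance_to_center = integer(),
             maf = numeric(), stringsAsFactors = FALSE)
}

# Maximum-likelihood Beta(a, b) fit with method-of-moments start; shapes
# clamped to [1e-3, 1e6].
fit_beta_mle <- function(x) {
  x <- pmin(pmax(x, 1e-300), 1 - 1e-16)
  m <- mean(x); v <- stats::var(x)
  if (v < 1e-12) v <- 1e-12
  common <- m * (1 - m) / v - 1
  start <- log(pmax(c(m * common, (1 - m) * common), 1e-3))
  nll <- function(ls) {
    a <- exp(ls[1]); b <- exp(ls[2])
    -sum(stats::dbeta(x, a, b, log = TRUE))
  }
  fit <- tryCatch(
    stats::optim(start, nll, method = "L-BFGS-B",
                 lower = log(1e-3), upper = log(1e6)),
    error = function(e) list(par = start)
  )
  shapes <- pmin(pmax(exp(fit$par), 1e-3), 1e6)
  c(shape1 = shapes[[1]], shape2 = shapes[[2]])
}

#' Per-locus nominal p-value threshold from fitted Beta shapes
#'
#' The nominal p-value corresponding to a target empirical p-value under
#' the locus's fitted Beta null of permutation minima; with shapes (1, 1)
#' (a single tested variant) the threshold equals the target itself.
#'
#' @param shape1,shape2 Fitted Beta shapes.
#' @param target Target empirical p level (default 0.005).
#' @return Nominal p-value threshold.
#' @export
locus_nominal_threshold <- function(shape1, shape2, target = 0.005) {
  stats::qbeta(target, shape1, shape2)
}

#' Permutation-based empirical p-value for one feature
#'
#' Permutes the phenotype across samples, records the minimum nominal
#' p-value per permutation, fits a Beta distribution to the minima by
#' maximum likelihood, and evaluates the Beta CDF at the observed lead
#' p-value. The direct permutation estimate (r + 1)/(n + 1) is reported
#' alongside. The per-locus nominal threshold is the Beta quantile at the
#' empirical target (default 0.005).
#'
#' @param feature_center,residual_phenotype,genotypes,window_bp,maf_min,df_removed,feature_id
#'   As in [nominal_scan()].
#' @param n_permutations Number of permutations (>= 100; default 1000).
#' @param seed Integer seed.
#' @param empirical_target Empirical p level defining the per-locus
#'   nominal threshold (default 0.005).
#'
#' @return One-row data.frame (feature_id, lead variant stats,
#'   n_variants_tested, beta_shape1, beta_shape2, p_empirical,
#'   p_empirical_direct, nominal_threshold), with the nominal scan in
#'   attribute `nominal`.
#' @export
empirical_p <- function(feature_center, residual_phenotype, genotypes,
                        n_permutations = 1000, seed = 1L, window_bp = 1e5,
                        maf_min = 0.05, df_removed = 0,
                        feature_id = "feature", empirical_target = 0.005) {
  if (n_permutations < 100) stop("need >= 100 permutations", call. = FALSE)
  if (length(unique(residual_phenotype)) < 2) {
    stop("phenotype has fewer than 2 distinct values", call. = FALSE)
  }
  nom <- nominal_scan(feature_center, residual_phenotype, genotypes,
                      window_bp, maf_min, df_removed, feature_id)
  if (nrow(nom) == 0) return(NULL)
  # lead: smallest p, then smallest |distance|, then variant id
  ord <- order(nom$p_nominal, abs(nom$distance_to_center), nom$variant_id)
  lead <- nom[ord[1], ]

  info <- genotypes$info
  in_win <- abs(info$pos - feature_center) <= window_bp
  dos <- genotypes$dosage[in_win, , drop = FALSE]
  dos <- dos[rownames(dos) %in% nom$variant_id, , drop = FALSE]
  n <- length(residual_phenotype)
  df <- n - 2 - df_removed

  Xc <- sweep(t(dos), 2, colMeans(t(dos)))        # samples x variants
  sxx <- colSums(Xc^2)
  perm_min_p <- with_seed(seed, {
    P <- matrix(0, n, n_permutations)
    for (j in seq_len(n_permutations)) {
      P[, j] <- residual_phenotype[sample.int(n)]
    }
    Pc <- sweep(P, 2, colMeans(P))
    num <- crossprod(Xc, Pc)                       # variants x perms
    r2 <- num^2 / outer(pmax(sxx, 1e-300), pmax(colSums(Pc^2), 1e-300))
    r2max <- apply(r2, 2, max)
    t2 <- r2max * df / pmax(1 - r2max, 1e-300)
    2 * stats::pt(-sqrt(t2), df)
  })
  shapes <- fit_beta_mle(perm_min_p)
  p_emp <- stats::pbeta(lead$p_nominal, shapes[1], shapes[2])
  p_dir <- (sum(perm_min_p <= lead$p_nominal) + 1) / (n_permutations + 1)
  out <- data.frame(
    feature_id = feature_id,
    lead_variant = lead$variant_id, beta = lead$beta, se = lead$se,
    t_stat = lead$t_stat, p_nominal = lead$p_nominal,
    distance_to_center = lead$distance_to_center,
    n_variants_tested = nrow(nom),
    beta_shape1 = unname(shapes[1]), beta_shape2 = unname(shapes[2]),
    p_empirical = p_emp, p_empirical_direct = p_dir,
    nominal_threshold = locus_nominal_threshold(shapes[1], shapes[2],
                                                empirical_target),
    stringsAsFactors = FALSE
  )
  attr(out, "nominal") <- nom
  out
}

#' Map cis QTLs for a matrix of features
#'
#' Residualizes the phenotype matrix, then runs the nominal scan and the
#' permutation pass for every feature. Reused unchanged for ARE activity
#' (haQTLs) and gene expression (eQTLs).
#'
#' @param phenotype_matrix Feature x sample matrix (raw; residualization
#'   happens inside).
#' @param genotypes A `genotype_matrix` (individuals must match columns).
#' @param feature_centers Named numeric vector: feature id -> center bp.
#' @param covariates Sample x covariate matrix or NULL.
#' @param n_latent_factors Phenotype PCs to remove (default 0).
#' @param window_bp,maf_min,n_permutations,empirical_target As above.
#' @param seed Integer seed; each feature gets an order-independent child
#'   seed.
#'
#' @return Object of class `qtl_scan`: list with `loci` (one row per
#'   feature), `nominals` (feature -> nominal data.frame), `df_removed`.
#' @export
map_qtls <- function(phenotype_matrix, genotypes, feature_centers,
                     covariates = NULL, n_latent_factors = 0,
                     window_bp = 1e5, maf_min = 0.05,
                     n_permutations = 1000, seed = 1L,
                     empirical_target = 0.005) {
  feats <- intersect(rownames(phenotype_matrix), names(feature_centers))
  if (length(feats) == 0) stop("no features with centers", call. = FALSE)
  res <- residualize(phenotype_matrix, covariates, n_latent_factors)
  dfr <- attr(res, "df_removed")
  loci <- list(); nominals <- list()
  for (i in seq_along(feats)) {
    f <- feats[i]
    row <- empirical_p(feature_centers[[f]], res[f, ], genotypes,
                       n_permutations = n_permutations,
                       seed = child_seed(seed, i),
                       window_bp = window_bp, maf_min = maf_min,
                       df_removed = dfr, feature_id = f,
                       empirical_target = empirical_target)
    if (!is.null(row)) {
      nominals[[f]] <- attr(row, "nominal")
      attr(row, "nominal") <- NULL
      loci[[f]] <- row
    }
  }
  loci_df <- if (length(loci)) {
    do.call(rbind, c(loci, list(make.row.names = FALSE)))
  } else {
    data.frame(feature_id = character(), lead_variant = character(),
               beta = numeric(), se = numeric(), t_stat = numeric(),
               p_nominal = numeric(), distance_to_center = integer(),
               n_variants_tested = integer(), beta_shape1 = numeric(),
               beta_shape2 = numeric(), p_empirical = numeric(),
               p_empirical_direct = numeric(), nominal_threshold = numeric(),
               stringsAsFactors = FALSE)
  }
  structure(
    list(loci = loci_df, nominals = nominals, df_removed = dfr),
    class = "qtl_scan"
  )
}

#' @export
print.qtl_scan <- function(x, ...) {
  cat(sprintf("qtl_scan: %d features tested (df adjustment %d)\n",
              nrow(x$loci), x$df_removed))
  if (nrow(x$loci)) {
    cat(sprintf("  median lead p %.3g; min empirical p %.3g\n",
                stats::median(x$loci$p_nominal), min(x$loci$p_empirical)))
  }
  invisible(x)
}

#' Call genetically influenced features and their QTL variants
#'
#' Features with empirical p at or below the threshold (default 0.005) are
#' genetically influenced (gAREs / eGenes); for each, the QTL variant list
#' contains every variant whose nominal p is at or below the locus-specific
#' nominal threshold (the Beta quantile of the empirical target).
#'
#' @param scan A `qtl_scan` from [map_qtls()].
#' @param empirical_threshold Empirical p cutoff (default 0.005).
#'
#' @return List of class `qtl_set`: `features` (locus rows of the called
#'   features), `qtls` (data.frame of per-variant hits).
#' @export
call_gares <- function(scan, empirical_threshold = 0.005) {
  loci <- scan$loci
  hit <- loci[loci$p_empirical <= empirical_threshold, , drop = FALSE]
  qtls <- list()
  for (f in hit$feature_id) {
    nom <- scan$nominals[[f]]
    thr <- hit$nominal_threshold[hit$feature_id == f]
    sel <- nom[nom$p_nominal <= thr, , drop = FALSE]
    if (nrow(sel)) qtls[[f]] <- sel
  }
  structure(
    list(features = hit,
         qtls = if (length(qtls)) do.call(rbind, c(qtls, list(make.row.names = FALSE))) else empty_nominal()),
    class = "qtl_set"
  )
}

#' @export
print.qtl_set <- function(x, ...) {
  cat(sprintf("qtl_set: %d genetically influenced features, %d QTL variants\n",
              nrow(x$features), nrow(x$qtls)))
  invisible(x)
}
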