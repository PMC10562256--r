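#' Configuration for a synthetic multitissue cohort
#'
#' Collects every knob of the synthetic generator: cohort layout, the LD
#' model, planted cis effect sizes, cross-tissue sharing probabilities and
#' confounding structure. The defaults describe a small two-tissue cohort
#' that exercises every downstream stage.
#'
#' @param n_individuals_per_tissue Named integer vector, tissue -> number of
#'   genotyped individuals (each tissue gets its own individuals).
#' @param n_variants Number of variants on the simulated chromosome.
#' @param n_ares Number of active regulatory elements (AREs).
#' @param n_genes Number of genes.
#' @param maf_range Length-2 numeric in (0, 0.5]: allele frequencies are
#'   drawn uniformly from this range.
#' @param ld_block_size Variants per LD block.
#' @param ld_rho AR(1) correlation of the latent haplotype field within a
#'   block, in [0, 1).
#' @param haqtl_effect_sd SD of planted haQTL effect sizes (0 = global null).
#' @param eqtl_effect_sd SD of planted eQTL effect sizes.
#' @param noise_sd SD of the Gaussian residual noise on activity/expression.
#' @param sharing_matrix Tissue x tissue matrix of probabilities that an
#'   effect planted in the row tissue is also planted (same sign) in the
#'   column tissue. Must be symmetric with unit diagonal.
#' @param frac_shared_causal Fraction of designated gene-ARE pairs whose
#'   eQTL reuses the ARE's causal variant (these become true links).
#' @param frac_gare Fraction of AREs that receive a planted haQTL.
#' @param covariate_count Number of simulated known covariates per tissue.
#' @param pos_step Spacing in bp between adjacent variants.
#' @param are_width Width in bp of each simulated ARE.
#' @param cis_window Window in bp around the ARE center from which its
#'   causal variant is drawn (matches the mapping window).
#' @param seed Integer seed; all generator randomness derives from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_individuals_per_tissue = c(tissueA = 60, tissueB = 60),
                       n_variants = 2000,
                       n_ares = 300,
                       n_genes = 100,
                       maf_range = c(0.05, 0.5),
                       ld_block_size = 20,
                       ld_rho = 0.6,
                       haqtl_effect_sd = 0.8,
                       eqtl_effect_sd = 0.8,
                       noise_sd = 1,
                       sharing_matrix = NULL,
                       frac_shared_causal = 0.5,
                       frac_gare = 0.5,
                       covariate_count = 2,
                       pos_step = 5000,
                       are_width = 600,
                       cis_window = 100000,
                       seed = 1L) {
  tissues <- names(n_individuals_per_tissue)
  if (is.null(tissues) || any(tissues == "")) {
    stop("`n_individuals_per_tissue` must be a named vector", call. = FALSE)
  }
  if (any(n_individuals_per_tissue < 2)) {
    stop("each tissue needs at least 2 individuals", call. = FALSE)
  }
  for (nm in c("n_variants", "n_ares", "n_genes", "ld_block_size")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 1) {
      stop(sprintf("`%s` must be a positive integer", nm), call. = FALSE)
    }
  }
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("`maf_range` must lie within (0, 0.5]", call. = FALSE)
  }
  stopifnot_scalar_number(ld_rho, "ld_rho", 0, 1 - 1e-12)
  stopifnot_scalar_number(haqtl_effect_sd, "haqtl_effect_sd", 0)
  stopifnot_scalar_number(eqtl_effect_sd, "eqtl_effect_sd", 0)
  stopifnot_scalar_number(noise_sd, "noise_sd", 1e-300)
  stopifnot_scalar_number(frac_shared_causal, "frac_shared_causal", 0, 1)
  stopifnot_scalar_number(frac_gare, "frac_gare", 0, 1)
  stopifnot_scalar_number(covariate_count, "covariate_count", 0)
  if (is.null(sharing_matrix)) {
    k <- length(tissues)
    sharing_matrix <- matrix(0.5, k, k, dimnames = list(tissues, tissues))
    diag(sharing_matrix) <- 1
  }
  sharing_matrix <- as.matrix(sharing_matrix)
  if (!identical(dim(sharing_matrix), c(length(tissues), length(tissues))) ||
      !isTRUE(all.equal(sharing_matrix, t(sharing_matrix))) ||
      any(abs(diag(sharing_matrix) - 1) > 1e-12) ||
      any(sharing_matrix < 0) || any(sharing_matrix > 1)) {
    stop("`sharing_matrix` must be tissue x tissue, symmetric, in [0,1], ",
         "with unit diagonal", call. = FALSE)
  }
  dimnames(sharing_matrix) <- list(tissues, tissues)
  structure(
    list(
      n_individuals_per_tissue = n_individuals_per_tissue,
      tissues = tissues,
      n_variants = as.integer(n_variants),
      n_ares = as.integer(n_ares),
      n_genes = as.integer(n_genes),
      maf_range = maf_range,
      ld_block_size = as.integer(ld_block_size),
      ld_rho = ld_rho,
      haqtl_effect_sd = haqtl_effect_sd,
      eqtl_effect_sd = eqtl_effect_sd,
      noise_sd = noise_sd,
      sharing_matrix = sharing_matrix,
      frac_shared_causal = frac_shared_causal,
      frac_gare = frac_gare,
      covariate_count = as.integer(covariate_count),
      pos_step = pos_step,
      are_width = are_width,
      cis_window = cis_window,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Simulate genotype dosages with blockwise LD
#'
#' Dosages in \{0, 1, 2\} are generated from two independent haplotypes per
#' individual. Each haplotype is a thresholded AR(1) Gaussian field
#' (correlation `ld_rho` between adjacent variants within a block, blocks
#' independent), so within-block dosage correlation decays geometrically
#' with distance -- a simple, controllable LD model adequate for cis-QTL and
#' colocalization testing.
#'
#' @param n_individuals Number of individuals (>= 2).
#' @param n_variants Number of variants.
#' @param maf_range Allele-frequency sampling range in (0, 0.5].
#' @param ld_block_size Variants per independent LD block.
#' @param ld_rho Within-block AR(1) correlation in [0, 1).
#' @param seed Integer seed.
#' @param chrom Chromosome label for the variant table.
#' @param pos_step Spacing in bp between adjacent variants.
#' @param mafs Optional numeric vector of allele frequencies (length
#'   `n_variants`), e.g. to share frequencies across tissue panels.
#'
#' @return A `genotype_matrix`: list with `dosage` (variants x individuals
#'   matrix) and `info` (data.frame: variant_id, chrom, pos, maf).
#' @export
simulate_genotypes <- function(n_individuals, n_variants,
                               maf_range = c(0.05, 0.5),
                               ld_block_size = 20, ld_rho = 0.6,
                               seed = 1L, chrom = "chr1", pos_step = 1000,
                               mafs = NULL) {
  if (n_individuals < 2) stop("`n_individuals` must be >= 2", call. = FALSE)
  if (n_variants < 1 || ld_block_size < 1) {
    stop("sizes must be positive", call. = FALSE)
  }
  if (maf_range[1] <= 0 || maf_range[2] > 0.5) {
    stop("`maf_range` must lie within (0, 0.5]", call. = FALSE)
  }
  with_seed(seed, {
    if (is.null(mafs)) {
      mafs <- stats::runif(n_variants, maf_range[1], maf_range[2])
    }
    thr <- stats::qnorm(mafs)
    hap <- function() {
      z <- matrix(stats::rnorm(n_individuals * n_variants),
                  n_individuals, n_variants)
      if (ld_rho > 0 && n_variants > 1) {
        w <- sqrt(1 - ld_rho^2)
        for (j in 2:n_variants) {
          if ((j - 1) %% ld_block_size != 0) {   # block boundary resets
            z[, j] <- ld_rho * z[, j - 1] + w * z[, j]
          }
        }
      }
      # allele carried when the latent value falls below the MAF quantile
      sweep(z, 2, thr, "<") * 1L
    }
    dosage <- t(hap() + hap())
    ids <- sprintf("var%04d", seq_len(n_variants))
    rownames(dosage) <- ids
    colnames(dosage) <- sprintf("ind%03d", seq_len(n_individuals))
    info <- data.frame(
      variant_id = ids, chrom = chrom,
      pos = as.integer(seq_len(n_variants) * pos_step),
      maf = pmin(mafs, 1 - mafs),
      stringsAsFactors = FALSE
    )
    structure(list(dosage = dosage, info = info), class = "genotype_matrix")
  })
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d variants x %d individuals\n",
              nrow(x$dosage), ncol(x$dosage)))
  cat(sprintf("  positions %d..%d on %s; mean MAF %.3f\n",
              min(x$info$pos), max(x$info$pos), x$info$chrom[1],
              mean(x$info$maf)))
  invisible(x)
}

# Evenly spaced ARE intervals over the variant span, each with a center.
make_are_table <- function(config, info) {
  lo <- min(info$pos); hi <- max(info$pos)
  centers <- round(seq(lo, hi, length.out = config$n_ares))
  half <- floor(config$are_width / 2)
  data.frame(
    are_id = sprintf("ARE%04d", seq_len(config$n_ares)),
    chrom = info$chrom[1],
    start = pmax(0L, as.integer(centers - half)),
    end = as.integer(centers + half),
    center = as.integer(centers),
    stringsAsFactors = FALSE
  )
}

#' Simulate ARE activity with planted cis effects
#'
#' Activity of each ARE is an additive linear model on the (implicitly
#' normalized) scale: baseline + planted causal-variant dosage effect +
#' covariate loadings + homoscedastic Gaussian noise. A fraction
#' `frac_gare` of AREs receives a causal variant drawn from its cis window;
#' the effect is planted in a primary tissue and propagated to each other
#' tissue with the probability given by `sharing_matrix`, always with the
#' same sign and magnitude. The first covariate acts as a cell-fraction-like
#' confounder loading in a common direction on all AREs.
#'
#' @param genotypes Named list, tissue -> `genotype_matrix`; tissues must
#'   match the config and share the same variant table.
#' @param config A `sim_config`.
#' @param seed Integer seed.
#'
#' @return List of class `sim_activity`: `activity` (tissue -> ARE x sample
#'   matrix), `ares` (interval table with centers), `covariates` (tissue ->
#'   sample x covariate matrix), `truth` (class `sim_truth`).
#' @export
simulate_activity <- function(genotypes, config, seed = config$seed) {
  tissues <- config$tissues
  if (!all(tissues %in% names(genotypes))) {
    stop("genotypes missing for tissue(s): ",
         paste(setdiff(tissues, names(genotypes)), collapse = ", "),
         call. = FALSE)
  }
  info <- genotypes[[tissues[1]]]$info
  ares <- make_are_table(config, info)
  with_seed(seed, {
    n_causal <- round(config$frac_gare * config$n_ares)
    causal_ares <- sort(sample.int(config$n_ares, n_causal))
    haqtl <- list()
    for (i in causal_ares) {
      in_win <- which(abs(info$pos - ares$center[i]) <= config$cis_window)
      v <- in_win[sample.int(length(in_win), 1L)]
      beta <- stats::rnorm(1, 0, config$haqtl_effect_sd)
      primary <- tissues[sample.int(length(tissues), 1L)]
      planted <- primary
      for (t2 in setdiff(tissues, primary)) {
        if (stats::runif(1) < config$sharing_matrix[primary, t2]) {
          planted <- c(planted, t2)
        }
      }
      for (tt in planted) {
        haqtl[[length(haqtl) + 1L]] <- data.frame(
          are_id = ares$are_id[i], tissue = tt,
          variant_id = info$variant_id[v], beta = beta,
          primary = tt == primary, stringsAsFactors = FALSE
        )
      }
    }
    haqtl <- if (length(haqtl)) do.call(rbind, haqtl) else
      data.frame(are_id = character(), tissue = character(),
                 variant_id = character(), beta = numeric(),
                 primary = logical(), stringsAsFactors = FALSE)

    # covariate loadings drawn once per cohort; first = confounder-like
    q <- config$covariate_count
    loadings <- NULL
    if (q > 0) {
      loadings <- matrix(stats::rnorm(config$n_ares * q, 0, 0.5),
                         config$n_ares, q)
      loadings[, 1] <- stats::rnorm(config$n_ares, 1, 0.3)
    }
    baseline <- stats::runif(config$n_ares, 1, 3)

    activity <- list(); covariates <- list()
    for (tt in tissues) {
      dos <- genotypes[[tt]]$dosage
      n <- ncol(dos)
      mat <- matrix(baseline, config$n_ares, n) +
        matrix(stats::rnorm(config$n_ares * n, 0, config$noise_sd),
               config$n_ares, n)
      if (q > 0) {
        cv <- matrix(stats::rnorm(n * q), n, q,
                     dimnames = list(colnames(dos),
                                     sprintf("cov%d", seq_len(q))))
        covariates[[tt]] <- cv
        mat <- mat + loadings %*% t(cv)
      }
      rows <- haqtl[haqtl$tissue == tt, , drop = FALSE]
      if (nrow(rows)) {
        ai <- match(rows$are_id, ares$are_id)
        vi <- match(rows$variant_id, rownames(dos))
        for (r in seq_len(nrow(rows))) {
          mat[ai[r], ] <- mat[ai[r], ] + rows$beta[r] * dos[vi[r], ]
        }
      }
      dimnames(mat) <- list(ares$are_id, colnames(dos))
      activity[[tt]] <- mat
    }

    # realized pairwise sharing among effects planted in the primary tissue
    prim <- haqtl[haqtl$primary, , drop = FALSE]
    k <- length(tissues)
    sharing_real <- matrix(NA_real_, k, k, dimnames = list(tissues, tissues))
    diag(sharing_real) <- 1
    for (a in tissues) for (b in setdiff(tissues, a)) {
      pa <- prim[prim$tissue == a, , drop = FALSE]
      if (nrow(pa)) {
        also <- paste(pa$are_id, b) %in%
          paste(haqtl$are_id, haqtl$tissue)[haqtl$tissue == b]
        sharing_real[a, b] <- mean(also)
      }
    }

    truth <- structure(
      list(haqtl = haqtl,
           eqtl = data.frame(gene_id = character(), tissue = character(),
                             variant_id = character(), beta = numeric(),
                             stringsAsFactors = FALSE),
           links = data.frame(are_id = character(), gene_id = character(),
                              stringsAsFactors = FALSE),
           sharing_planted = config$sharing_matrix,
           sharing_realized = sharing_real),
      class = "sim_truth"
    )
    structure(list(activity = activity, ares = ares,
                   covariates = covariates, truth = truth),
              class = "sim_activity")
  })
}

#' Simulate gene expression with planted eQTLs and shared causal variants
#'
#' Each gene receives a planted eQTL. Genes are paired round-robin with the
#' AREs that carry planted haQTLs; for a fraction `frac_shared_causal` of
#' those designated pairs the gene's causal variant is exactly the ARE's
#' causal variant (recorded as a true ARE-gene link), otherwise a distinct
#' variant from the gene's cis window is used.
#'
#' @param genotypes Named list, tissue -> `genotype_matrix`.
#' @param config A `sim_config`.
#' @param truth `sim_truth` from [simulate_activity()].
#' @param seed Integer seed.
#'
#' @return List of class `sim_expression`: `expression` (tissue -> gene x
#'   sample matrix), `genes` (data.frame: gene_id, chrom, tss), updated
#'   `truth` with `eqtl` and `links` filled in.
#' @export
simulate_expression <- function(genotypes, config, truth,
                                seed = config$seed + 1L) {
  stopifnot_scalar_number(config$frac_shared_causal, "frac_shared_causal", 0, 1)
  tissues <- config$tissues
  info <- genotypes[[tissues[1]]]$info
  ares <- make_are_table(config, info)
  with_seed(seed, {
    # TSS placed 5-40 kb from an ARE center so candidate windows are populated
    anchor <- rep_len(seq_len(config$n_ares), config$n_genes)
    offset <- sample(5000:40000, config$n_genes, replace = TRUE) *
      sample(c(-1, 1), config$n_genes, replace = TRUE)
    tss <- pmax(min(info$pos),
                pmin(max(info$pos), ares$center[anchor] + offset))
    genes <- data.frame(
      gene_id = sprintf("GENE%04d", seq_len(config$n_genes)),
      chrom = info$chrom[1], tss = as.integer(tss),
      stringsAsFactors = FALSE
    )

    prim <- truth$haqtl[truth$haqtl$primary, , drop = FALSE]
    eqtl <- list(); links <- list()
    if (nrow(prim)) {
      pair_are <- rep_len(seq_len(nrow(prim)), config$n_genes)
      n_shared <- round(config$frac_shared_causal * config$n_genes)
      shared <- rep(FALSE, config$n_genes)
      if (n_shared > 0) shared[sample.int(config$n_genes, n_shared)] <- TRUE
      for (g in seq_len(config$n_genes)) {
        row <- prim[pair_are[g], ]
        if (shared[g]) {
          v_id <- row$variant_id
          links[[length(links) + 1L]] <- data.frame(
            are_id = row$are_id, gene_id = genes$gene_id[g],
            stringsAsFactors = FALSE
          )
        } else {
          in_win <- which(abs(info$pos - genes$tss[g]) <= config$cis_window &
                            info$variant_id != row$variant_id)
          v_id <- info$variant_id[in_win[sample.int(length(in_win), 1L)]]
        }
        beta <- stats::rnorm(1, 0, config$eqtl_effect_sd)
        for (tt in tissues) {
          eqtl[[length(eqtl) + 1L]] <- data.frame(
            gene_id = genes$gene_id[g], tissue = tt,
            variant_id = v_id, beta = beta, stringsAsFactors = FALSE
          )
        }
      }
    }
    truth$eqtl <- if (length(eqtl)) do.call(rbind, eqtl) else truth$eqtl
    truth$links <- if (length(links)) unique(do.call(rbind, links)) else
      truth$links

    expr <- list()
    baseline <- stats::runif(config$n_genes, 1, 3)
    for (tt in tissues) {
      dos <- genotypes[[tt]]$dosage
      n <- ncol(dos)
      mat <- matrix(baseline, config$n_genes, n) +
        matrix(stats::rnorm(config$n_genes * n, 0, config$noise_sd),
               config$n_genes, n)
      rows <- truth$eqtl[truth$eqtl$tissue == tt, , drop = FALSE]
      if (nrow(rows)) {
        gi <- match(rows$gene_id, genes$gene_id)
        vi <- match(rows$variant_id, rownames(dos))
        for (r in seq_len(nrow(rows))) {
          mat[gi[r], ] <- mat[gi[r], ] + rows$beta[r] * dos[vi[r], ]
        }
      }
      dimnames(mat) <- list(genes$gene_id, colnames(dos))
      expr[[tt]] <- mat
    }
    structure(list(expression = expr, genes = genes, truth = truth),
              class = "sim_expression")
  })
}

#' Simulate fragment intervals consistent with a target activity profile
#'
#' Inverts the activity formula: per ARE the number of fragments is Poisson
#' with mean chosen so that the expected quantified activity
#' (sum of overlap lengths / ARE length) equals `mean_depth` times the
#' input activity. Fragments are placed uniformly, fully inside the ARE
#' (length capped at the ARE width for short AREs).
#'
#' @param activity_row Non-negative numeric vector, one value per ARE.
#' @param are_intervals Interval table (chrom, start, end), BED half-open.
#' @param mean_depth Global depth scalar (> 0).
#' @param fragment_length Fragment length in bp.
#' @param sample_id Sample label attached to each fragment.
#' @param seed Integer seed.
#'
#' @return data.frame (chrom, start, end, sample) of fragment intervals.
#' @export
simulate_fragments <- function(activity_row, are_intervals, mean_depth = 1,
                               fragment_length = 200, sample_id = "s1",
                               seed = 1L) {
  if (any(activity_row < 0)) stop("activities must be non-negative",
                                  call. = FALSE)
  if (mean_depth <= 0) stop("`mean_depth` must be positive", call. = FALSE)
  if (length(activity_row) != nrow(are_intervals)) {
    stop("one activity per ARE required", call. = FALSE)
  }
  with_seed(seed, {
    out <- list()
    for (i in seq_len(nrow(are_intervals))) {
      len <- are_intervals$end[i] - are_intervals$start[i]
      eff <- min(fragment_length, len)
      lambda <- mean_depth * activity_row[i] * len / eff
      cnt <- stats::rpois(1, lambda)
      if (cnt > 0) {
        starts <- are_intervals$start[i] +
          sample.int(len - eff + 1L, cnt, replace = TRUE) - 1L
        out[[length(out) + 1L]] <- data.frame(
          chrom = are_intervals$chrom[i], start = starts,
          end = starts + eff, sample = sample_id, stringsAsFactors = FALSE
        )
      }
    }
    if (length(out)) do.call(rbind, out) else
      data.frame(chrom = character(), start = integer(), end = integer(),
                 sample = character(), stringsAsFactors = FALSE)
  })
}

#' Simulate GWAS summary statistics with planted colocalization
#'
#' A configurable fraction of the planted haQTL causal variants is made
#' GWAS-causal with |z| = `causal_z`. Marginal effects at every variant are
#' propagated through the panel LD (sample covariance of dosages), then
#' perturbed by sampling noise at the standard-error scale
#' 1/sqrt(2 MAF (1-MAF) n), the standard value for a standardized trait.
#'
#' @param genotypes A `genotype_matrix` used as the LD panel.
#' @param truth `sim_truth` carrying planted haQTL causal variants.
#' @param shared_fraction Fraction of haQTL causal variants that are also
#'   GWAS-causal, in [0, 1].
#' @param n_gwas GWAS sample size (>= 2).
#' @param seed Integer seed.
#' @param causal_z Expected |z| of a GWAS-causal variant.
#' @param trait_type `"quantitative"` or `"case-control"` label.
#' @param min_spacing_bp Minimum distance between planted GWAS-causal
#'   variants (default 2e5, one cis-window diameter): GWAS loci are
#'   modeled as isolated association peaks, matching the
#'   single-causal-variant geometry colocalization assumes. Selection is
#'   greedy in random order, so fewer than the requested number may be
#'   planted on a crowded chromosome.
#'
#' @return data.frame (variant, chrom, pos, beta, se, p, n, trait_type),
#'   with the GWAS-causal variant ids in attribute `gwas_causal`.
#' @export
simulate_gwas <- function(genotypes, truth, shared_fraction = 0.5,
                          n_gwas = 50000, seed = 1L, causal_z = 8,
                          trait_type = "quantitative",
                          min_spacing_bp = 2e5) {
  if (n_gwas < 2) stop("`n_gwas` must be >= 2", call. = FALSE)
  stopifnot_scalar_number(shared_fraction, "shared_fraction", 0, 1)
  info <- genotypes$info
  dos <- genotypes$dosage
  with_seed(seed, {
    cands <- unique(truth$haqtl$variant_id)
    n_causal <- round(shared_fraction * length(cands))
    causal <- character()
    if (n_causal > 0) {
      pool <- sample(cands)          # greedy spacing-constrained selection
      kept_pos <- numeric()
      for (v in pool) {
        pos_v <- info$pos[match(v, info$variant_id)]
        if (!length(kept_pos) || min(abs(kept_pos - pos_v)) >= min_spacing_bp) {
          causal <- c(causal, v)
          kept_pos <- c(kept_pos, pos_v)
          if (length(causal) >= n_causal) break
        }
      }
    }
    f <- info$maf
    se <- 1 / sqrt(2 * f * (1 - f) * n_gwas)
    beta_marg <- numeric(nrow(info))
    if (length(causal)) {
      ci <- match(causal, info$variant_id)
      b_c <- causal_z * se[ci] * sample(c(-1, 1), length(ci), replace = TRUE)
      X <- t(dos)                              # individuals x variants
      Xc <- sweep(X, 2, colMeans(X))
      v <- colSums(Xc^2) / (nrow(X) - 1)
      covs <- crossprod(Xc, Xc[, ci, drop = FALSE]) / (nrow(X) - 1)
      beta_marg <- as.numeric(covs %*% b_c) / pmax(v, 1e-12)
    }
    beta_hat <- beta_marg + stats::rnorm(length(se), 0, se)
    z <- beta_hat / se
    data.frame(
      variant = info$variant_id, chrom = info$chrom, pos = info$pos,
      beta = beta_hat, se = se, p = 2 * stats::pnorm(-abs(z)),
      n = n_gwas, trait_type = trait_type, stringsAsFactors = FALSE
    ) -> out
    attr(out, "gwas_causal") <- causal
    out
  })
}

#' Generate a complete synthetic multitissue cohort
#'
#' One-call wrapper: per-tissue genotype panels sharing one variant table,
#' ARE activity with planted haQTLs, expression with planted eQTLs and
#' shared-causal links, and GWAS summary statistics.
#'
#' @param config A `sim_config`.
#' @param gwas_shared_fraction Fraction of haQTL causal variants that are
#'   GWAS-causal.
#' @return List of class `sim_cohort` with elements `config`, `genotypes`,
#'   `activity`, `ares`, `covariates`, `expression`, `genes`, `gwas`,
#'   `truth`.
#' @export
simulate_cohort <- function(config = sim_config(),
                            gwas_shared_fraction = 0.5) {
  tissues <- config$tissues
  mafs <- with_seed(child_seed(config$seed, 0), {
    stats::runif(config$n_variants, config$maf_range[1], config$maf_range[2])
  })
  genotypes <- list()
  for (i in seq_along(tissues)) {
    genotypes[[tissues[i]]] <- simulate_genotypes(
      n_individuals = config$n_individuals_per_tissue[[i]],
      n_variants = config$n_variants, maf_range = config$maf_range,
      ld_block_size = config$ld_block_size, ld_rho = config$ld_rho,
      seed = child_seed(config$seed, i), pos_step = config$pos_step,
      mafs = mafs
    )
    colnames(genotypes[[tissues[i]]]$dosage) <-
      sprintf("%s_ind%03d", tissues[i],
              seq_len(config$n_individuals_per_tissue[[i]]))
  }
  act <- simulate_activity(genotypes, config,
                           seed = child_seed(config$seed, 101))
  expr <- simulate_expression(genotypes, config, act$truth,
                              seed = child_seed(config$seed, 102))
  gwas <- simulate_gwas(genotypes[[tissues[1]]], expr$truth,
                        shared_fraction = gwas_shared_fraction,
                        seed = child_seed(config$seed, 103))
  structure(
    list(config = config, genotypes = genotypes, activity = act$activity,
         ares = act$ares, covariates = act$covariates,
         expression = expr$expression, genes = expr$genes, gwas = gwas,
         truth = expr$truth),
    class = "sim_cohort"
  )
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("sim_cohort\n")
  cat(sprintf("  tissues: %s\n", paste(x$config$tissues, collapse = ", ")))
  cat(sprintf("  %d variants, %d AREs, %d genes\n",
              x$config$n_variants, x$config$n_ares, x$config$n_genes))
  cat(sprintf("  planted haQTL records: %d; eQTLs: %d; true links: %d\n",
              nrow(x$truth$haqtl), nrow(x$truth$eqtl), nrow(x$truth$links)))
  invisible(x)
}
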