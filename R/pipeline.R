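#' Pipeline configuration
#'
#' A single declarative configuration for the end-to-end synthetic
#' pipeline: the cohort layout, every stage's parameters (all defaulting
#' to the study's thresholds) and the output directory. Can also be read
#' from a YAML file with [read_pipeline_config()].
#'
#' @param outdir Output directory (created if missing).
#' @param seed Global seed; every stage derives its own child seed.
#' @param sim `sim_config` for the synthetic cohort.
#' @param stages Character vector of stages to run, in order, from:
#'   simulate, quantify, cluster, qtl, sharing, coloc, glink.
#' @param binarize_cutoff Signal cutoff for module clustering (default 2).
#' @param n_modules Module count k for the synthetic cohort.
#' @param n_sample_clusters Sample clusters for group assignment.
#' @param activity_threshold Ubiquitous-score activity threshold (0.2).
#' @param window_bp,maf_min,n_permutations,empirical_threshold QTL stage
#'   parameters (defaults 1e5, 0.05, 1000, 0.005).
#' @param n_latent_factors Phenotype PCs removed during residualization.
#' @param p_share_threshold Replication p for haQTL sharing (0.02).
#' @param coloc_threshold,eqtl_missing_threshold Locus classification
#'   cutoffs (0.5, 0.1).
#' @param prior_sd,p1,p2,p12 Colocalization parameters.
#' @param mr_sig_threshold MR adjusted-p cutoff (0.2).
#' @param gwas_shared_fraction Fraction of haQTL causal variants that are
#'   GWAS-causal in the simulation.
#'
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir = tempfile("areqtl_run_"),
                            seed = 1L,
                            sim = sim_config(seed = seed),
                            stages = c("simulate", "quantify", "cluster",
                                       "qtl", "sharing", "coloc", "glink"),
                            binarize_cutoff = 2,
                            n_modules = 6,
                            n_sample_clusters = 3,
                            activity_threshold = 0.2,
                            window_bp = 1e5, maf_min = 0.05,
                            n_permutations = 200,
                            empirical_threshold = 0.005,
                            n_latent_factors = 2,
                            p_share_threshold = 0.02,
                            coloc_threshold = 0.5,
                            eqtl_missing_threshold = 0.1,
                            prior_sd = 0.15, p1 = 1e-4, p2 = 1e-4,
                            p12 = 1e-5,
                            mr_sig_threshold = 0.2,
                            gwas_shared_fraction = 0.5) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys override [pipeline_config()] defaults; keys under `sim`
#' override [sim_config()] defaults.
#'
#' @param path YAML file path.
#' @return Object of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_args <- raw$sim
  raw$sim <- NULL
  if (!is.null(sim_args$n_individuals_per_tissue)) {
    sim_args$n_individuals_per_tissue <-
      unlist(sim_args$n_individuals_per_tissue)
  }
  if (!is.null(sim_args$sharing_matrix)) {
    sim_args$sharing_matrix <- do.call(rbind, sim_args$sharing_matrix)
  }
  cfg <- do.call(pipeline_config, raw)
  if (length(sim_args)) {
    if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
    cfg$sim <- do.call(sim_config, sim_args)
  }
  cfg
}

#' Validate pipeline input files
#'
#' Checks standard-format inputs and collects (rather than fail-fasts)
#' every problem found: BED intervals with start < end, dosages within
#' [0, 2], p-values in (0, 1], and matrix/sample-id concordance between a
#' phenotype matrix and a dosage matrix.
#'
#' @param bed_paths Named character vector of BED files to check.
#' @param dosage_path Dosage TSV (optional).
#' @param phenotype_path Phenotype matrix TSV (optional); sample ids are
#'   checked against the dosage columns when both are given.
#' @param pvalue_paths Named vector of TSVs with a `p` column (optional).
#'
#' @return Character vector of error messages (empty when valid), each
#'   naming the file and offending entry.
#' @export
validate_inputs <- function(bed_paths = character(), dosage_path = NULL,
                            phenotype_path = NULL,
                            pvalue_paths = character()) {
  errors <- character()
  for (nm in names(bed_paths)) {
    df <- tryCatch(read_bed(bed_paths[[nm]]), error = function(e) NULL)
    if (is.null(df)) {
      errors <- c(errors, sprintf("%s: unreadable BED", bed_paths[[nm]]))
      next
    }
    bad <- which(df$start >= df$end | df$start < 0)
    for (b in bad) {
      errors <- c(errors, sprintf("%s line %d: invalid interval [%s, %s)",
                                  bed_paths[[nm]], b, df$start[b], df$end[b]))
    }
  }
  dos <- NULL
  if (!is.null(dosage_path)) {
    dos <- read_matrix_tsv(dosage_path)
    bad <- which(dos < 0 | dos > 2, arr.ind = TRUE)
    for (r in seq_len(min(nrow(bad), 50))) {
      errors <- c(errors, sprintf(
        "%s: dosage %.3g out of [0, 2] for variant %s, individual %s",
        dosage_path, dos[bad[r, 1], bad[r, 2]],
        rownames(dos)[bad[r, 1]], colnames(dos)[bad[r, 2]]))
    }
  }
  if (!is.null(phenotype_path)) {
    ph <- read_matrix_tsv(phenotype_path)
    if (!is.null(dos) && !setequal(colnames(ph), colnames(dos))) {
      errors <- c(errors, sprintf(
        "%s: sample ids do not match dosage columns (%d vs %d shared)",
        phenotype_path, ncol(ph), length(intersect(colnames(ph),
                                                   colnames(dos)))))
    }
  }
  for (nm in names(pvalue_paths)) {
    df <- utils::read.delim(pvalue_paths[[nm]], stringsAsFactors = FALSE)
    if (!"p" %in% names(df)) {
      errors <- c(errors, sprintf("%s: no `p` column", pvalue_paths[[nm]]))
      next
    }
    bad <- which(!(df$p > 0 & df$p <= 1))
    for (b in bad) {
      errors <- c(errors, sprintf("%s line %d: p-value %g outside (0, 1]",
                                  pvalue_paths[[nm]], b, df$p[b]))
    }
  }
  errors
}

stage_manifest <- function(manifest, stage, params, files) {
  hashes <- tools::md5sum(files)
  manifest[[stage]] <- list(parameters = params,
                            outputs = as.list(hashes),
                            status = "complete")
  manifest
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes, in order: cohort simulation; fragment-based quantification
#' and median-of-ratios normalization; module clustering and group
#' assignment; per-tissue haQTL and eQTL mapping; pairwise tissue-sharing
#' estimation and gARE type classification; GWAS-haQTL and GWAS-eQTL
#' colocalization with locus classification; gLink scoring with the
#' colocalized-gARE enrichment test. Each stage writes its outputs (TSV /
#' JSON) to the output directory before the next stage starts, and a run
#' manifest with parameter records and output hashes is written at the
#' end.
#'
#' @param config A `pipeline_config`.
#' @return The run manifest (invisibly also written to
#'   `manifest.json`), with stage results attached in attribute
#'   `results`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$outdir, ...)
  manifest <- list()
  results <- list()
  stages <- config$stages

  ## simulate -----------------------------------------------------------
  cohort <- simulate_cohort(config$sim, config$gwas_shared_fraction)
  results$cohort <- cohort
  if ("simulate" %in% stages) {
    files <- character()
    for (tt in config$sim$tissues) {
      f1 <- out(sprintf("genotypes_%s.tsv", tt))
      f2 <- out(sprintf("variants_%s.tsv", tt))
      write_dosage_tsv(cohort$genotypes[[tt]], f1, f2)
      f3 <- out(sprintf("activity_%s.tsv", tt))
      write_matrix_tsv(cohort$activity[[tt]], f3, "are_id")
      f4 <- out(sprintf("expression_%s.tsv", tt))
      write_matrix_tsv(cohort$expression[[tt]], f4, "gene_id")
      files <- c(files, f1, f2, f3, f4)
    }
    fa <- out("ares.bed"); write_bed(cohort$ares, fa)
    fg <- out("gwas.tsv")
    utils::write.table(cohort$gwas, fg, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    ft <- out("truth.json")
    jsonlite::write_json(
      list(haqtl = cohort$truth$haqtl, eqtl = cohort$truth$eqtl,
           links = cohort$truth$links), ft
    )
    manifest <- stage_manifest(manifest, "simulate",
                               list(seed = config$seed),
                               c(files, fa, fg, ft))
  }

  ## quantify / normalize ------------------------------------------------
  if ("quantify" %in% stages) {
    tt <- config$sim$tissues[1]
    act <- pmax(cohort$activity[[tt]], 0)
    samples <- colnames(act)
    frags <- do.call(rbind, lapply(seq_along(samples), function(si) {
      simulate_fragments(act[, si], cohort$ares, mean_depth = 1,
                         sample_id = samples[si],
                         seed = child_seed(config$seed, 200 + si))
    }))
    raw <- quantify_activity(frags, cohort$ares, sample_ids = samples)
    norm <- tryCatch(size_factor_normalize(raw), error = function(e) NULL)
    f1 <- out("activity_raw_quantified.tsv")
    write_matrix_tsv(raw, f1, "are_id")
    files <- f1
    if (!is.null(norm)) {
      f2 <- out("activity_normalized.tsv")
      write_matrix_tsv(norm$normalized, f2, "are_id")
      f3 <- out("size_factors.tsv")
      utils::write.table(
        data.frame(sample = names(norm$size_factors),
                   size_factor = norm$size_factors),
        f3, sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, f2, f3)
      results$quantified <- norm
    }
    manifest <- stage_manifest(manifest, "quantify",
                               list(tissue = tt, mean_depth = 1), files)
  }

  ## module clustering ----------------------------------------------------
  if ("cluster" %in% stages) {
    signal <- do.call(cbind, cohort$activity)
    bin <- binarize_signal(signal, config$binarize_cutoff)
    mods <- kcentroid_cluster(bin, k = config$n_modules,
                              seed = child_seed(config$seed, 300))
    mod_mean <- t(vapply(seq_len(config$n_modules), function(m) {
      rows <- which(mods$cluster == m)
      colMeans(signal[rows, , drop = FALSE])
    }, numeric(ncol(signal))))
    rownames(mod_mean) <- sprintf("module%03d", seq_len(config$n_modules))
    scl <- cluster_samples(mod_mean, config$n_sample_clusters)
    groups <- assign_groups(mod_mean, scl, config$activity_threshold)
    f1 <- out("are_modules.tsv")
    utils::write.table(
      data.frame(are_id = names(mods$cluster), module = mods$cluster),
      f1, sep = "\t", quote = FALSE, row.names = FALSE)
    f2 <- out("module_groups.tsv")
    utils::write.table(groups, f2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    f3 <- out("module_centroids.json")
    jsonlite::write_json(apply(mods$centroids, 1, identity,
                               simplify = FALSE), f3, digits = NA)
    results$modules <- list(assignment = mods, groups = groups,
                            sample_clusters = scl)
    manifest <- stage_manifest(
      manifest, "cluster",
      list(cutoff = config$binarize_cutoff, k = config$n_modules,
           n_sample_clusters = config$n_sample_clusters,
           activity_threshold = config$activity_threshold),
      c(f1, f2, f3))
  }

  ## QTL mapping ---------------------------------------------------------
  if (any(c("qtl", "sharing", "coloc", "glink") %in% stages)) {
    centers <- stats::setNames(cohort$ares$center, cohort$ares$are_id)
    tss <- stats::setNames(cohort$genes$tss, cohort$genes$gene_id)
    ha_scans <- list(); e_scans <- list(); ha_sets <- list()
    files <- character()
    for (ti in seq_along(config$sim$tissues)) {
      tt <- config$sim$tissues[ti]
      ha_scans[[tt]] <- map_qtls(
        cohort$activity[[tt]], cohort$genotypes[[tt]], centers,
        covariates = cohort$covariates[[tt]],
        n_latent_factors = config$n_latent_factors,
        window_bp = config$window_bp, maf_min = config$maf_min,
        n_permutations = config$n_permutations,
        seed = child_seed(config$seed, 400 + ti),
        empirical_target = config$empirical_threshold
      )
      ha_sets[[tt]] <- call_gares(ha_scans[[tt]],
                                  config$empirical_threshold)
      e_scans[[tt]] <- map_qtls(
        cohort$expression[[tt]], cohort$genotypes[[tt]], tss,
        covariates = cohort$covariates[[tt]],
        n_latent_factors = config$n_latent_factors,
        window_bp = config$window_bp, maf_min = config$maf_min,
        n_permutations = config$n_permutations,
        seed = child_seed(config$seed, 500 + ti),
        empirical_target = config$empirical_threshold
      )
      f1 <- out(sprintf("haqtl_loci_%s.tsv", tt))
      utils::write.table(ha_scans[[tt]]$loci, f1, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      f2 <- out(sprintf("eqtl_loci_%s.tsv", tt))
      utils::write.table(e_scans[[tt]]$loci, f2, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      files <- c(files, f1, f2)
    }
    results$haqtl <- ha_scans; results$haqtl_sets <- ha_sets
    results$eqtl <- e_scans
    if ("qtl" %in% stages) {
      manifest <- stage_manifest(
        manifest, "qtl",
        list(window_bp = config$window_bp, maf_min = config$maf_min,
             n_permutations = config$n_permutations,
             empirical_threshold = config$empirical_threshold,
             n_latent_factors = config$n_latent_factors),
        files)
    }
  }

  ## tissue sharing ------------------------------------------------------
  if ("sharing" %in% stages && length(config$sim$tissues) >= 2) {
    tissues <- config$sim$tissues
    presence <- matrix(TRUE, nrow(cohort$ares), length(tissues),
                       dimnames = list(cohort$ares$are_id, tissues))
    sharing_rows <- list(); files <- character()
    for (a in tissues) for (b in setdiff(tissues, a)) {
      pairs <- pair_leads(ha_sets[[a]], ha_scans[[b]]$nominals,
                          are_presence = presence,
                          discovery_tissue = a, replication_tissue = b)
      if (nrow(pairs) == 0) next
      est <- sharing_proportion(suppressWarnings(consistency_by_bin(pairs)))
      sharing_rows[[paste(a, b)]] <- data.frame(
        discovery = a, replication = b, n_pairs = nrow(pairs),
        sharing = est$sharing, sharing_raw = est$sharing_raw,
        stringsAsFactors = FALSE)
    }
    sharing_df <- do.call(rbind, sharing_rows)
    types <- classify_gare_types(
      ha_sets, presence,
      lapply(ha_scans, function(s) s$nominals),
      config$p_share_threshold
    )
    f1 <- out("tissue_sharing.tsv")
    utils::write.table(sharing_df, f1, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    f2 <- out("gare_types.tsv")
    utils::write.table(types, f2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    results$sharing <- sharing_df; results$gare_types <- types
    manifest <- stage_manifest(
      manifest, "sharing",
      list(p_share_threshold = config$p_share_threshold,
           bins = sharing_bins), c(f1, f2))
  }

  ## colocalization ------------------------------------------------------
  if (any(c("coloc", "glink") %in% stages)) {
    tt <- config$sim$tissues[1]
    gwas <- cohort$gwas
    coloc_rows <- list()
    gare_coloc <- logical()
    for (i in seq_len(nrow(ha_sets[[tt]]$features))) {
      f <- ha_sets[[tt]]$features$feature_id[i]
      hnom <- ha_scans[[tt]]$nominals[[f]]
      gsub <- gwas[match(hnom$variant_id, gwas$variant), , drop = FALSE]
      pp_h <- suppressWarnings(coloc_posteriors(
        wakefield_abf(gsub, config$prior_sd),
        wakefield_abf(hnom, config$prior_sd),
        config$p1, config$p2, config$p12))
      # eQTL coloc for genes whose cis window reaches this ARE
      e_pps <- list()
      for (g in names(e_scans[[tt]]$nominals)) {
        enom <- e_scans[[tt]]$nominals[[g]]
        if (length(intersect(enom$variant_id, hnom$variant_id)) >= 10) {
          gsub2 <- gwas[match(enom$variant_id, gwas$variant), , drop = FALSE]
          e_pps[[g]] <- suppressWarnings(coloc_posteriors(
            wakefield_abf(gsub2, config$prior_sd),
            wakefield_abf(enom, config$prior_sd),
            config$p1, config$p2, config$p12))
        }
      }
      cls <- classify_loci(pp_h, e_pps, config$coloc_threshold,
                           config$eqtl_missing_threshold, locus_id = f)
      coloc_rows[[f]] <- cls
      gare_coloc[f] <- cls$gwas_haqtl_pp4 >= config$coloc_threshold
    }
    coloc_df <- if (length(coloc_rows)) {
      do.call(rbind, c(coloc_rows, list(make.row.names = FALSE)))
    } else {
      data.frame(locus_id = character(), gwas_haqtl_pp4 = numeric(),
                 max_eqtl_pp4 = numeric(), label = character())
    }
    results$coloc <- coloc_df; results$gare_colocalized <- gare_coloc
    if ("coloc" %in% stages) {
      f1 <- out("coloc_classification.tsv")
      utils::write.table(coloc_df, f1, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      manifest <- stage_manifest(
        manifest, "coloc",
        list(coloc_threshold = config$coloc_threshold,
             eqtl_missing_threshold = config$eqtl_missing_threshold,
             prior_sd = config$prior_sd,
             priors = c(config$p1, config$p2, config$p12)), f1)
    }
  }

  ## gLink scores --------------------------------------------------------
  if ("glink" %in% stages) {
    tt <- config$sim$tissues[1]
    gares <- ha_sets[[tt]]$features
    gare_table <- merge(
      gares, cohort$ares[, c("are_id", "chrom", "start", "end")],
      by.x = "feature_id", by.y = "are_id")
    names(gare_table)[names(gare_table) == "feature_id"] <- "are_id"
    cands <- enumerate_candidates(gare_table, cohort$genes)
    # fine-mapped eQTLs in synthetic mode = planted causal eQTL variants
    info <- cohort$genotypes[[tt]]$info
    fm <- split(
      info$pos[match(cohort$truth$eqtl$variant_id, info$variant_id)],
      cohort$truth$eqtl$gene_id)
    enoms <- lapply(e_scans[[tt]]$nominals, function(df) {
      df$pos <- info$pos[match(df$variant_id, info$variant_id)]
      df
    })
    weights <- lapply(names(enoms), function(g) {
      rows <- cohort$truth$eqtl[cohort$truth$eqtl$gene_id == g &
                                  cohort$truth$eqtl$tissue == tt, ]
      stats::setNames(rows$beta, rows$variant_id)
    })
    names(weights) <- names(enoms)
    scores <- glink_scores(
      cands, gare_table, ha_scans[[tt]]$nominals, enoms, fm, weights,
      cohort$genotypes[[tt]]$dosage, cohort$activity[[tt]],
      prior_sd = config$prior_sd, p1 = config$p1, p2 = config$p2,
      p12 = config$p12)
    f1 <- out("glink_scores.tsv")
    utils::write.table(scores, f1, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- f1
    results$glink <- scores
    # enrichment of colocalized gAREs among linked gAREs
    if (length(results$gare_colocalized) > 1 &&
        any(results$gare_colocalized) && nrow(scores) > 0) {
      linked <- unique(scores$are_id[!is.na(scores$unified) &
                                       scores$unified >= 0.5])
      if (length(linked) > 0) {
        enr <- colocalized_gare_enrichment(
          linked, names(results$gare_colocalized),
          results$gare_colocalized)
        f2 <- out("enrichment.json")
        jsonlite::write_json(enr, f2, auto_unbox = TRUE, digits = NA)
        files <- c(files, f2)
        results$enrichment <- enr
      }
    }
    manifest <- stage_manifest(
      manifest, "glink",
      list(candidate_window = c(2000, 1e6),
           mr_sig_threshold = config$mr_sig_threshold), files)
  }

  fm <- out("manifest.json")
  jsonlite::write_json(manifest, fm, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  attr(manifest, "results") <- results
  invisible(manifest)
}
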