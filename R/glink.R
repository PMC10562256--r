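#' Enumerate candidate gARE-gene pairs by TSS distance
#'
#' Candidate pairs are genetically influenced AREs lying between 2 kb and
#' 1 Mb from a gene's TSS; the distance is the minimum over the ARE's
#' boundary points of |position - TSS|.
#'
#' @param gares Interval table of gAREs (are_id, chrom, start, end).
#' @param gene_tss_table data.frame (gene_id, chrom, tss).
#' @param min_distance,max_distance Window bounds in bp (defaults 2000 and
#'   1e6, both inclusive).
#'
#' @return data.frame (are_id, gene_id, tss_distance).
#' @export
enumerate_candidates <- function(gares, gene_tss_table,
                                 min_distance = 2000, max_distance = 1e6) {
  out <- list()
  for (g in seq_len(nrow(gene_tss_table))) {
    same <- gares$chrom == gene_tss_table$chrom[g]
    if (!any(same)) next
    sub <- gares[same, , drop = FALSE]
    d <- pmin(abs(sub$start - gene_tss_table$tss[g]),
              abs(sub$end - gene_tss_table$tss[g]))
    keep <- d >= min_distance & d <= max_distance
    if (any(keep)) {
      out[[length(out) + 1L]] <- data.frame(
        are_id = sub$are_id[keep], gene_id = gene_tss_table$gene_id[g],
        tss_distance = d[keep], stringsAsFactors = FALSE
      )
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(are_id = character(), gene_id = character(),
               tss_distance = numeric(), stringsAsFactors = FALSE)
}

#' Distance from a gARE to its gene's fine-mapped eQTLs
#'
#' Minimum distance from any fine-mapped eQTL position of the gene to the
#' gARE interval (0 if inside); Inf when the gene has none. The proximity
#' flag marks distances within the window (default 2 kb).
#'
#' @param are_start,are_end gARE interval, BED half-open.
#' @param fmeqtl_positions Positions of the gene's fine-mapped eQTLs
#'   (may be empty).
#' @param window Proximity window in bp (default 2000).
#'
#' @return List: `distance` (bp or Inf), `proximal` (logical).
#' @export
dist_to_fmeqtl <- function(are_start, are_end, fmeqtl_positions,
                           window = 2000) {
  if (length(fmeqtl_positions) == 0) {
    return(list(distance = Inf, proximal = FALSE))
  }
  d <- pmax(0, are_start - fmeqtl_positions,
            fmeqtl_positions - (are_end - 1L))
  dist <- min(d)
  list(distance = dist, proximal = dist <= window)
}

#' Most significant gARE-proximal eQTL p-value
#'
#' Minimum nominal eQTL p among the gene's variants within `window` bp of
#' the gARE interval; NA when no variant is in the window.
#'
#' @param are_start,are_end gARE interval, BED half-open.
#' @param gene_nominal_eqtls data.frame with columns `pos` and
#'   `p_nominal`.
#' @param window Window in bp (default 2000).
#'
#' @return Minimum p-value or NA.
#' @export
proximal_eqtl_p <- function(are_start, are_end, gene_nominal_eqtls,
                            window = 2000) {
  if (nrow(gene_nominal_eqtls) == 0) return(NA_real_)
  d <- pmax(0, are_start - gene_nominal_eqtls$pos,
            gene_nominal_eqtls$pos - (are_end - 1L))
  inw <- d <= window
  if (!any(inw)) return(NA_real_)
  min(gene_nominal_eqtls$p_nominal[inw])
}

#' Mendelian-randomization Wald ratio for gARE-gene pairs
#'
#' Uses each pair's instrument (the gARE's lead haQTL) to estimate the
#' causal effect of ARE activity on expression: the Wald ratio
#' beta_eQTL / beta_haQTL with first-order delta-method standard error
#' se_eQTL / |beta_haQTL| and a two-sided normal p-value.
#' Benjamini-Hochberg adjustment is applied across all valid pairs in the
#' batch; a pair is significant at adjusted p < 0.2.
#'
#' @param pairs data.frame with one row per pair and columns
#'   `beta_exposure`, `se_exposure` (haQTL), `beta_outcome`, `se_outcome`
#'   (eQTL at the same instrument).
#' @param sig_threshold Adjusted-p significance cutoff (default 0.2).
#'
#' @return data.frame (wald_ratio, se, p, p_adjusted, significant,
#'   invalid_instrument) aligned with `pairs`.
#' @export
mr_test <- function(pairs, sig_threshold = 0.2) {
  invalid <- abs(pairs$beta_exposure) < 1e-12
  ratio <- ifelse(invalid, NA_real_, pairs$beta_outcome / pairs$beta_exposure)
  se <- ifelse(invalid, NA_real_, pairs$se_outcome / abs(pairs$beta_exposure))
  p <- 2 * stats::pnorm(-abs(ratio / se))
  p_adj <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  p_adj[ok] <- stats::p.adjust(p[ok], method = "BH")
  data.frame(
    wald_ratio = ratio, se = se, p = p, p_adjusted = p_adj,
    significant = !is.na(p_adj) & p_adj < sig_threshold,
    invalid_instrument = invalid, stringsAsFactors = FALSE
  )
}

#' Inverse-variance-weighted MR over multiple instruments
#'
#' Combines per-instrument Wald ratios with weights 1/se^2; with a single
#' instrument this reduces to the Wald ratio itself.
#'
#' @param ratios Per-instrument Wald ratios.
#' @param ses Per-instrument delta-method standard errors.
#' @return List (estimate, se, p).
#' @export
mr_ivw <- function(ratios, ses) {
  w <- 1 / ses^2
  est <- sum(w * ratios) / sum(w)
  se <- sqrt(1 / sum(w))
  list(estimate = est, se = se, p = 2 * stats::pnorm(-abs(est / se)))
}

#' Correlation of gARE activity with genetically inferred expression
#'
#' The polygenic (genetically inferred) expression of a gene is the
#' weighted dosage sum over its independent eQTLs; the score is its
#' Pearson correlation with the gARE activity across individuals, with a
#' two-sided p-value from the t transform.
#'
#' @param dosage Variant x individual dosage matrix covering the weight
#'   variants.
#' @param eqtl_weights Named numeric vector, variant id -> effect size.
#' @param gare_activity Activity vector across the same individuals.
#'
#' @return List (r, p, pgs).
#' @export
expgs_correlation <- function(dosage, eqtl_weights, gare_activity) {
  if (length(eqtl_weights) == 0) stop("need >= 1 eQTL weight", call. = FALSE)
  vi <- match(names(eqtl_weights), rownames(dosage))
  if (any(is.na(vi))) {
    stop("weight variant(s) missing from dosage matrix: ",
         paste(names(eqtl_weights)[is.na(vi)], collapse = ", "),
         call. = FALSE)
  }
  pgs <- as.numeric(crossprod(dosage[vi, , drop = FALSE], eqtl_weights))
  if (stats::sd(pgs) == 0) {
    stop("polygenic score has zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(pgs, gare_activity)
  list(r = unname(ct$estimate), p = ct$p.value, pgs = pgs)
}

#' Unified gLink score by oriented percentile-rank aggregation
#'
#' Each component score is converted to a percentile rank across all
#' candidate pairs with the orientation "larger = stronger link"
#' (distances and p-values are inverted first); the unified score is the
#' mean of the available percentile ranks, ignoring missing components.
#'
#' @param score_table data.frame, one row per candidate pair, columns =
#'   component scores. Columns named in `invert` are treated as
#'   smaller-is-stronger.
#' @param invert Character vector of columns to invert (defaults to the
#'   distance and p-value components).
#'
#' @return data.frame (unified, n_components) aligned with `score_table`.
#' @export
unified_score <- function(score_table,
                          invert = c("gare_dist_to_fmeqtl",
                                     "gare_proximal_eqtl_p", "mr_p")) {
  n <- nrow(score_table)
  ranks <- matrix(NA_real_, n, ncol(score_table),
                  dimnames = list(NULL, names(score_table)))
  for (j in names(score_table)) {
    x <- score_table[[j]]
    if (j %in% invert) x <- -x
    ok <- !is.na(x) & (is.finite(x) | x == -Inf)   # -Inf: inverted Inf distance
    x[!is.na(x) & x == -Inf] <- -.Machine$double.xmax
    if (sum(ok) >= 2) {
      r <- rank(x[ok], ties.method = "average")
      ranks[ok, j] <- (r - 1) / (sum(ok) - 1)
    } else if (sum(ok) == 1) {
      ranks[ok, j] <- 1
    }
  }
  n_comp <- rowSums(!is.na(ranks))
  unified <- ifelse(n_comp > 0, rowMeans(ranks, na.rm = TRUE), NA_real_)
  data.frame(unified = unified, n_components = n_comp)
}

#' Enrichment of colocalized gAREs among linked gAREs
#'
#' One-sided two-sample proportion z-test (pooled variance, no continuity
#' correction) comparing the fraction of GWAS-haQTL-colocalized gAREs
#' among gAREs with a predicted gene link against the fraction among all
#' gAREs, with alternative "linked > background".
#'
#' @param linked_gares Character vector of gARE ids with a predicted link
#'   (subset of `all_gares`).
#' @param all_gares Character vector of all gARE ids.
#' @param colocalized_flags Named logical vector over `all_gares`.
#'
#' @return List (proportion_linked, proportion_background, z, p).
#' @export
colocalized_gare_enrichment <- function(linked_gares, all_gares,
                                        colocalized_flags) {
  if (length(linked_gares) == 0) stop("empty linked set", call. = FALSE)
  if (!all(linked_gares %in% all_gares)) {
    stop("linked set must be a subset of all gAREs", call. = FALSE)
  }
  coloc <- colocalized_flags[all_gares]
  p_all <- mean(coloc)
  p_link <- mean(colocalized_flags[linked_gares])
  n1 <- length(linked_gares); n2 <- length(all_gares)
  x1 <- sum(colocalized_flags[linked_gares]); x2 <- sum(coloc)
  pooled <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  z <- if (se > 0) (p_link - p_all) / se else 0
  list(proportion_linked = p_link, proportion_background = p_all,
       z = z, p = stats::pnorm(z, lower.tail = FALSE))
}

#' Area under the precision-recall curve
#'
#' Step-function AUPRC for a score ranking against binary labels; ties are
#' broken by score order after a stable sort. Pairs with missing scores
#' rank last. Used to benchmark link rankings against known true links.
#'
#' @param scores Numeric vector (larger = stronger prediction).
#' @param labels Logical vector of the same length.
#' @return AUPRC in [0, 1].
#' @export
auprc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("length mismatch", call. = FALSE)
  scores[is.na(scores)] <- -Inf
  ord <- order(scores, decreasing = TRUE)
  lab <- as.logical(labels)[ord]
  tp <- cumsum(lab)
  prec <- tp / seq_along(lab)
  rec <- tp / sum(lab)
  # integrate precision over recall steps (at each positive)
  sum(prec[lab]) / sum(lab) * max(rec)
}

#' Compute all gLink scores for candidate gARE-gene pairs
#'
#' Assembles, per candidate pair: distance to the gene's fine-mapped
#' eQTLs, the most significant gARE-proximal eQTL p, coloc PP4 and the
#' PP4/PP3 ratio (haQTL vs eQTL signals), the MR Wald ratio with
#' batch-adjusted p, the ExpPGS-activity correlation, and the unified
#' percentile-rank score.
#'
#' @param candidates data.frame from [enumerate_candidates()].
#' @param gare_table gARE interval table (are_id, start, end) with lead
#'   statistics columns `lead_variant`, `beta`, `se`.
#' @param haqtl_nominals Named list, ARE id -> nominal scan data.frame.
#' @param eqtl_nominals Named list, gene id -> nominal scan data.frame
#'   with a `pos` column.
#' @param fmeqtl_by_gene Named list, gene id -> positions of fine-mapped
#'   eQTLs.
#' @param eqtl_weights_by_gene Named list, gene id -> named effect-size
#'   vector for the polygenic expression score.
#' @param dosage Variant x individual dosage matrix.
#' @param activity ARE x individual activity matrix.
#' @param prior_sd,p1,p2,p12 Colocalization parameters.
#' @param pp_ratio_cap Cap for PP4/PP3 when PP3 underflows (default 1e6).
#'
#' @return data.frame with one row per candidate pair: the six component
#'   scores, `mr_p`, `mr_p_adjusted`, `unified`, `n_components`.
#' @export
glink_scores <- function(candidates, gare_table, haqtl_nominals,
                         eqtl_nominals, fmeqtl_by_gene,
                         eqtl_weights_by_gene, dosage, activity,
                         prior_sd = 0.15, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                         pp_ratio_cap = 1e6) {
  n <- nrow(candidates)
  out <- candidates
  if (n == 0) {
    for (cl in c("gare_dist_to_fmeqtl", "gare_proximal_eqtl_p",
                 "coloc_pp4", "coloc_pp4_pp3", "expgs_corr", "mr_effect",
                 "mr_p", "mr_p_adjusted", "unified")) {
      out[[cl]] <- numeric(0)
    }
    out$n_components <- integer(0)
    return(out)
  }
  out$gare_dist_to_fmeqtl <- Inf
  out$gare_proximal_eqtl_p <- NA_real_
  out$coloc_pp4 <- NA_real_
  out$coloc_pp4_pp3 <- NA_real_
  out$expgs_corr <- NA_real_
  mr_in <- data.frame(beta_exposure = rep(NA_real_, n), se_exposure = NA_real_,
                      beta_outcome = NA_real_, se_outcome = NA_real_)
  for (i in seq_len(n)) {
    a <- candidates$are_id[i]; g <- candidates$gene_id[i]
    gi <- match(a, gare_table$are_id)
    s <- gare_table$start[gi]; e <- gare_table$end[gi]
    fm <- dist_to_fmeqtl(s, e, fmeqtl_by_gene[[g]])
    out$gare_dist_to_fmeqtl[i] <- fm$distance
    enom <- eqtl_nominals[[g]]
    if (!is.null(enom)) {
      out$gare_proximal_eqtl_p[i] <- proximal_eqtl_p(s, e, enom)
    }
    hnom <- haqtl_nominals[[a]]
    if (!is.null(hnom) && !is.null(enom)) {
      pp <- tryCatch(suppressWarnings(coloc_posteriors(
        wakefield_abf(hnom, prior_sd),
        wakefield_abf(enom, prior_sd), p1, p2, p12
      )), error = function(e) NULL)
      if (!is.null(pp)) {
        out$coloc_pp4[i] <- pp[["PP4"]]
        out$coloc_pp4_pp3[i] <- min(pp[["PP4"]] / max(pp[["PP3"]], 1e-300),
                                    pp_ratio_cap)
      }
      # MR at the gARE's lead haQTL instrument
      lead <- gare_table$lead_variant[gi]
      j <- match(lead, enom$variant_id)
      if (!is.na(j)) {
        mr_in$beta_exposure[i] <- gare_table$beta[gi]
        mr_in$se_exposure[i] <- gare_table$se[gi]
        mr_in$beta_outcome[i] <- enom$beta[j]
        mr_in$se_outcome[i] <- enom$se[j]
      }
    }
    w <- eqtl_weights_by_gene[[g]]
    if (!is.null(w) && length(w) > 0 && a %in% rownames(activity)) {
      ec <- tryCatch(
        expgs_correlation(dosage, w, activity[a, ]),
        error = function(e) NULL
      )
      if (!is.null(ec)) out$expgs_corr[i] <- ec$r
    }
  }
  has_mr <- !is.na(mr_in$beta_exposure)
  out$mr_effect <- NA_real_; out$mr_p <- NA_real_
  out$mr_p_adjusted <- NA_real_
  if (any(has_mr)) {
    mr <- mr_test(mr_in[has_mr, , drop = FALSE])
    out$mr_effect[has_mr] <- mr$wald_ratio
    out$mr_p[has_mr] <- mr$p
    out$mr_p_adjusted[has_mr] <- mr$p_adjusted
  }
  comp <- out[, c("gare_dist_to_fmeqtl", "gare_proximal_eqtl_p",
                  "coloc_pp4", "coloc_pp4_pp3", "mr_p", "expgs_corr")]
  comp$expgs_corr <- abs(comp$expgs_corr)   # strength, not direction
  uni <- unified_score(comp)
  out$unified <- uni$unified
  out$n_components <- uni$n_components
  out
}
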