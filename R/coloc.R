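#' Wakefield approximate Bayes factors for one association signal
#'
#' For each variant, with V = se^2, W = prior_sd^2, z = beta/se and
#' shrinkage r = W/(V + W), the log approximate Bayes factor in favour of
#' association is 0.5 log(1 - r) + 0.5 z^2 r.
#'
#' @param assoc_stats data.frame with columns `variant` (or `variant_id`),
#'   `beta`, `se` (all se > 0); or `z` plus `se`.
#' @param prior_sd Prior standard deviation of the true effect
#'   (default 0.15, quantitative traits standardized to unit variance;
#'   use 0.2 on the log-odds scale for case-control).
#'
#' @return data.frame (variant, labf, r) of log ABFs.
#' @export
wakefield_abf <- function(assoc_stats, prior_sd = 0.15) {
  v_col <- intersect(c("variant", "variant_id"), names(assoc_stats))[1]
  if (is.na(v_col)) stop("no variant id column", call. = FALSE)
  if (!"se" %in% names(assoc_stats) || any(is.na(assoc_stats$se)) ||
      any(assoc_stats$se <= 0)) {
    stop("standard errors missing or non-positive", call. = FALSE)
  }
  z <- if ("z" %in% names(assoc_stats)) assoc_stats$z else
    assoc_stats$beta / assoc_stats$se
  V <- assoc_stats$se^2
  W <- prior_sd^2
  r <- W / (V + W)
  data.frame(
    variant = assoc_stats[[v_col]],
    labf = 0.5 * log(1 - r) + 0.5 * z^2 * r,
    r = r, stringsAsFactors = FALSE
  )
}

#' Colocalization posteriors under a single-causal-variant model
#'
#' Combines per-variant log ABFs of two traits over their shared variants
#' into posterior probabilities of the five hypotheses: H0 no association,
#' H1/H2 one trait only, H3 two distinct causal variants, H4 one shared
#' causal variant. All sums are taken in log space.
#'
#' @param abf1,abf2 data.frames from [wakefield_abf()]; variant lists are
#'   intersected (a warning is issued below 10 shared variants).
#' @param p1,p2 Prior probability a variant is causal for trait 1 / 2
#'   (default 1e-4).
#' @param p12 Prior probability a variant is causal for both
#'   (default 1e-5).
#'
#' @return Object of class `coloc_posterior`: named numeric PP0..PP4
#'   (sums to 1) with priors and variant count in attributes.
#' @export
coloc_posteriors <- function(abf1, abf2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  shared <- intersect(abf1$variant, abf2$variant)
  if (length(shared) == 0) stop("no shared variants", call. = FALSE)
  if (length(shared) < 10) {
    warning("only ", length(shared), " shared variants; posteriors may be ",
            "unstable")
  }
  l1 <- abf1$labf[match(shared, abf1$variant)]
  l2 <- abf2$labf[match(shared, abf2$variant)]
  s1 <- log_sum_exp(l1)
  s2 <- log_sum_exp(l2)
  s12 <- log_sum_exp(l1 + l2)
  # H3 sums ABF1_i * ABF2_j over i != j = (sum_i)(sum_j) - sum_i (both at i)
  h3 <- if (s1 + s2 > s12) log_diff_exp(s1 + s2, s12) else -Inf
  lh <- c(
    0,
    log(p1) + s1,
    log(p2) + s2,
    log(p1) + log(p2) + h3,
    log(p12) + s12
  )
  pp <- exp(lh - log_sum_exp(lh))
  names(pp) <- paste0("PP", 0:4)
  structure(pp, priors = c(p1 = p1, p2 = p2, p12 = p12),
            n_variants = length(shared), class = "coloc_posterior")
}

#' @export
print.coloc_posterior <- function(x, ...) {
  cat("coloc posteriors (", attr(x, "n_variants"), " shared variants):\n",
      sep = "")
  print(round(unclass(x)[1:5], 4))
  invisible(x)
}

#' Classify a locus from its colocalization posteriors
#'
#' A locus is colocalized when the GWAS-haQTL PP4 reaches 0.5. Among
#' colocalized loci, if no candidate gene's GWAS-eQTL PP4 reaches 0.1 the
#' locus is bulk-eQTL-missing, otherwise bulk-eQTL-capturing.
#'
#' @param gwas_haqtl_posterior `coloc_posterior` (or numeric PP0..PP4) for
#'   the GWAS-haQTL pair.
#' @param gwas_eqtl_posteriors Named list of posteriors, one per candidate
#'   gene (may be empty).
#' @param coloc_threshold GWAS-haQTL PP4 cutoff (default 0.5).
#' @param eqtl_missing_threshold GWAS-eQTL PP4 cutoff (default 0.1).
#' @param locus_id Locus label.
#'
#' @return data.frame (locus_id, gwas_haqtl_pp4, max_eqtl_pp4, label) with
#'   label in "colocalized+bulk-eQTL-missing",
#'   "colocalized+bulk-eQTL-capturing", "none".
#' @export
classify_loci <- function(gwas_haqtl_posterior, gwas_eqtl_posteriors = list(),
                          coloc_threshold = 0.5,
                          eqtl_missing_threshold = 0.1,
                          locus_id = "locus") {
  pp4 <- unname(gwas_haqtl_posterior[["PP4"]])
  eqtl_pp4 <- if (length(gwas_eqtl_posteriors)) {
    vapply(gwas_eqtl_posteriors, function(p) unname(p[["PP4"]]), numeric(1))
  } else numeric(0)
  max_e <- if (length(eqtl_pp4)) max(eqtl_pp4) else 0
  label <- if (pp4 >= coloc_threshold) {
    if (max_e < eqtl_missing_threshold) "colocalized+bulk-eQTL-missing"
    else "colocalized+bulk-eQTL-capturing"
  } else "none"
  data.frame(locus_id = locus_id, gwas_haqtl_pp4 = pp4,
             max_eqtl_pp4 = max_e, label = label, stringsAsFactors = FALSE)
}
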