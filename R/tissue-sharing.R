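#' Pair discovery lead haQTLs with replication-tissue statistics
#'
#' For each lead haQTL of a genetically influenced ARE in the discovery
#' tissue, attaches the nominal effect size and p-value of the same
#' variant at the same ARE in the replication tissue. Leads whose ARE is
#' absent from the replication tissue (per the cross-tissue presence
#' matrix) are excluded here; they are handled as ARE-specific in
#' [classify_gare_types()].
#'
#' @param discovery_set A `qtl_set` from the discovery tissue.
#' @param replication_nominals Named list, ARE id -> nominal scan
#'   data.frame in the replication tissue.
#' @param are_presence Optional logical matrix (ARE x tissue) restricting
#'   pairing to AREs present in `replication_tissue`.
#' @param discovery_tissue,replication_tissue Tissue labels.
#'
#' @return data.frame of paired leads (gare_id, variant_id,
#'   beta_discovery, p_discovery, beta_replication, p_replication,
#'   discovery_tissue, replication_tissue).
#' @export
pair_leads <- function(discovery_set, replication_nominals,
                       are_presence = NULL,
                       discovery_tissue = "discovery",
                       replication_tissue = "replication") {
  feats <- discovery_set$features
  out <- list()
  for (i in seq_len(nrow(feats))) {
    f <- feats$feature_id[i]
    if (!is.null(are_presence) &&
        (!f %in% rownames(are_presence) ||
         !isTRUE(are_presence[f, replication_tissue]))) next
    rep_nom <- replication_nominals[[f]]
    if (is.null(rep_nom)) next
    j <- match(feats$lead_variant[i], rep_nom$variant_id)
    if (is.na(j)) next
    out[[length(out) + 1L]] <- data.frame(
      gare_id = f, variant_id = feats$lead_variant[i],
      beta_discovery = feats$beta[i], p_discovery = feats$p_nominal[i],
      beta_replication = rep_nom$beta[j], p_replication = rep_nom$p_nominal[j],
      discovery_tissue = discovery_tissue,
      replication_tissue = replication_tissue,
      stringsAsFactors = FALSE
    )
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(gare_id = character(), variant_id = character(),
               beta_discovery = numeric(), p_discovery = numeric(),
               beta_replication = numeric(), p_replication = numeric(),
               discovery_tissue = character(),
               replication_tissue = character(), stringsAsFactors = FALSE)
}

# Replication p-value bin boundaries: strong (< 1e-5), medium [1e-5, 1e-3),
# weak [1e-3, 0.1), no-effect (>= 0.1).
sharing_bins <- c(1e-5, 1e-3, 0.1)
sharing_bin_labels <- c("strong", "medium", "weak", "no-effect")

#' Directionality consistency by replication-significance bin
#'
#' Pairs are grouped into four bins by replication-tissue nominal p-value;
#' within each bin the directionality consistency (DC) is the fraction of
#' pairs whose discovery and replication effects share a sign. Pairs with
#' a zero effect size are dropped with a warning (sign undefined).
#'
#' @param pairs data.frame from [pair_leads()].
#' @return data.frame of class `consistency_bins` (bin, count, perc, dc).
#' @export
consistency_by_bin <- function(pairs) {
  if (nrow(pairs) < 1) stop("need at least one pair", call. = FALSE)
  zero <- pairs$beta_discovery == 0 | pairs$beta_replication == 0
  if (any(zero)) {
    warning(sum(zero), " pair(s) with zero effect size dropped ",
            "(sign undefined)")
    pairs <- pairs[!zero, , drop = FALSE]
  }
  bin <- cut(pairs$p_replication, c(0, sharing_bins, 1),
             labels = sharing_bin_labels, right = FALSE,
             include.lowest = TRUE)
  same <- sign(pairs$beta_discovery) == sign(pairs$beta_replication)
  counts <- as.integer(table(bin))
  dc <- vapply(sharing_bin_labels, function(b) {
    idx <- bin == b
    if (any(idx)) mean(same[idx]) else NA_real_
  }, numeric(1))
  out <- data.frame(
    bin = sharing_bin_labels, count = counts,
    perc = counts / sum(counts), dc = unname(dc),
    stringsAsFactors = FALSE
  )
  class(out) <- c("consistency_bins", class(out))
  out
}

#' Tissue-sharing proportion from directionality consistency
#'
#' Sharing = sum over bins of Perc_i * (DC_i - (1 - DC_i)). A DC of 1
#' (perfect concordance) contributes its bin's full weight; a DC of 0.5
#' (random signs) contributes nothing. Empty bins contribute zero. The raw
#' signed value lies in [-1, 1]; the reported value is clamped to [0, 1].
#'
#' @param bins `consistency_bins` from [consistency_by_bin()].
#' @return List of class `sharing_estimate`: `sharing` (clamped),
#'   `sharing_raw`, `bins`.
#' @export
sharing_proportion <- function(bins) {
  if (abs(sum(bins$perc) - 1) > 1e-8) {
    stop("bin percentages must sum to 1", call. = FALSE)
  }
  contrib <- ifelse(is.na(bins$dc), 0, bins$perc * (2 * bins$dc - 1))
  raw <- sum(contrib)
  structure(list(sharing = min(max(raw, 0), 1), sharing_raw = raw,
                 bins = bins),
            class = "sharing_estimate")
}

#' @export
print.sharing_estimate <- function(x, ...) {
  cat(sprintf("tissue-sharing estimate: %.3f (raw %.3f)\n",
              x$sharing, x$sharing_raw))
  print.data.frame(x$bins, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Effect-size similarity between tissues within a bin
#'
#' Slope (with intercept) of the OLS regression of replication effect
#' sizes on discovery effect sizes, restricted to one replication bin.
#'
#' @param pairs data.frame from [pair_leads()].
#' @param bin One of `"strong"`, `"medium"`, `"weak"`, `"no-effect"`, or
#'   `"all"`.
#' @return Regression slope.
#' @export
effect_similarity <- function(pairs, bin = "all") {
  if (bin != "all") {
    b <- cut(pairs$p_replication, c(0, sharing_bins, 1),
             labels = sharing_bin_labels, right = FALSE,
             include.lowest = TRUE)
    pairs <- pairs[b == bin, , drop = FALSE]
  }
  if (nrow(pairs) < 3) stop("need >= 3 pairs in the bin", call. = FALSE)
  if (stats::var(pairs$beta_discovery) == 0) {
    stop("zero variance in discovery effect sizes", call. = FALSE)
  }
  unname(stats::coef(stats::lm(beta_replication ~ beta_discovery,
                               data = pairs))[2])
}

#' Simulate discovery/replication lead-haQTL pairs with known sharing
#'
#' Generates paired lead statistics under a planted sharing proportion:
#' a shared pair keeps the discovery effect in the replication tissue
#' (replication estimate centered on it, so sign agreement follows the
#' replication power at that effect size); a non-shared pair draws its
#' replication estimate from the null. Used to validate the
#' directionality-consistency sharing estimator.
#'
#' @param n_pairs Number of lead pairs.
#' @param sharing True sharing proportion in [0, 1].
#' @param beta_sd SD of discovery effect sizes (default 0.8).
#' @param rep_se Replication standard error (default 0.02, a
#'   well-powered replication cohort).
#' @param seed Integer seed.
#'
#' @return data.frame in the [pair_leads()] layout with attribute
#'   `shared` (logical ground truth per pair).
#' @export
simulate_lead_pairs <- function(n_pairs, sharing, beta_sd = 0.8,
                                rep_se = 0.02, seed = 1L) {
  stopifnot_scalar_number(sharing, "sharing", 0, 1)
  with_seed(seed, {
    b_disc <- stats::rnorm(n_pairs, 0, beta_sd)
    # exact planted proportion: round(s * n) shared pairs
    shared <- seq_len(n_pairs) %in%
      sample.int(n_pairs, round(sharing * n_pairs))
    mu <- ifelse(shared, b_disc, 0)
    b_rep <- stats::rnorm(n_pairs, mu, rep_se)
    z <- b_rep / rep_se
    out <- data.frame(
      gare_id = sprintf("ARE%05d", seq_len(n_pairs)),
      variant_id = sprintf("var%05d", seq_len(n_pairs)),
      beta_discovery = b_disc, p_discovery = 1e-6,
      beta_replication = b_rep,
      p_replication = 2 * stats::pnorm(-abs(z)),
      discovery_tissue = "discovery", replication_tissue = "replication",
      stringsAsFactors = FALSE
    )
    attr(out, "shared") <- shared
    out
  })
}

#' Classify genetically influenced AREs into sharing types
#'
#' For each gARE of a discovery tissue: type III (ARE-specific) if the ARE
#' is absent from every other tissue; type I (haQTL-shared) if the ARE is
#' present elsewhere and the lead haQTL replicates (nominal p <= the
#' replication threshold, default 0.02) in at least one other tissue;
#' type II (haQTL-specific) otherwise.
#'
#' @param gare_sets Named list, tissue -> `qtl_set`.
#' @param are_presence Logical matrix, ARE x tissue.
#' @param replication_p Function or list giving, for
#'   (gare_id, discovery tissue, other tissue), the replication nominal p
#'   of the lead variant; pass a named list tissue -> nominal list as in
#'   [pair_leads()].
#' @param p_share_threshold Replication p cutoff (default 0.02).
#'
#' @return data.frame (gare_id, tissue, label) with labels "I", "II",
#'   "III".
#' @export
classify_gare_types <- function(gare_sets, are_presence, replication_p,
                                p_share_threshold = 0.02) {
  tissues <- names(gare_sets)
  out <- list()
  for (tt in tissues) {
    feats <- gare_sets[[tt]]$features
    # replication tissues are all tissues in the presence matrix, not just
    # those with their own discovery set
    others <- setdiff(colnames(are_presence), tt)
    for (i in seq_len(nrow(feats))) {
      f <- feats$feature_id[i]
      present_elsewhere <- others[vapply(others, function(o) {
        f %in% rownames(are_presence) && isTRUE(are_presence[f, o])
      }, logical(1))]
      if (length(present_elsewhere) == 0) {
        label <- "III"
      } else {
        reps <- vapply(present_elsewhere, function(o) {
          nom <- replication_p[[o]][[f]]
          if (is.null(nom)) return(NA_real_)
          j <- match(feats$lead_variant[i], nom$variant_id)
          if (is.na(j)) NA_real_ else nom$p_nominal[j]
        }, numeric(1))
        label <- if (any(!is.na(reps) & reps <= p_share_threshold))
          "I" else "II"
      }
      out[[length(out) + 1L]] <- data.frame(
        gare_id = f, tissue = tt, label = label, stringsAsFactors = FALSE
      )
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(gare_id = character(), tissue = character(),
               label = character(), stringsAsFactors = FALSE)
}
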