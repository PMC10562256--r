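#' Filter candidate H3K27ac peaks into a tissue ARE set
#'
#' A peak is retained if it is significant (q-value <= `q_threshold`) and
#' present -- at least 1 bp of overlap between peak calls -- in at least two
#' Tier-1 samples, or if it overlaps a tissue-matched reference peak
#' (rescue ignores the q-value). Surviving peaks must additionally overlap
#' a promoter/enhancer chromatin-state interval by at least
#' `min_state_overlap` bp.
#'
#' @param per_sample_peaks Named list, sample id -> data.frame
#'   (chrom, start, end, q) of peak calls with q-values.
#' @param tier1_flags Named logical vector, sample id -> Tier-1 status.
#' @param reference_peaks Interval table (chrom, start, end) of reference
#'   peaks for the tissue, or NULL for none.
#' @param state_intervals Interval table of promoter/enhancer chromatin
#'   states.
#' @param q_threshold Peak significance cutoff (default 0.01).
#' @param min_state_overlap Minimum chromatin-state overlap in bp
#'   (default 50).
#'
#' @return data.frame of retained peaks (chrom, start, end, sample, q).
#' @export
filter_candidate_peaks <- function(per_sample_peaks, tier1_flags,
                                   reference_peaks = NULL, state_intervals,
                                   q_threshold = 0.01,
                                   min_state_overlap = 50) {
  samples <- names(per_sample_peaks)
  if (is.null(samples) || !all(samples %in% names(tier1_flags))) {
    stop("`tier1_flags` must cover every sample in `per_sample_peaks`",
         call. = FALSE)
  }
  peaks <- do.call(rbind, lapply(samples, function(s) {
    df <- per_sample_peaks[[s]]
    if (!"q" %in% names(df) || any(is.na(df$q))) {
      stop("peaks for sample ", s, " are missing q-values", call. = FALSE)
    }
    cbind(df[, c("chrom", "start", "end", "q")], sample = s)
  }))
  if (nrow(peaks) == 0) return(peaks)
  gr <- bed_to_granges(peaks)

  # Tier-1 support: >= 2 distinct Tier-1 samples whose peak calls overlap
  tier1_samples <- names(tier1_flags)[tier1_flags]
  t1 <- peaks$sample %in% tier1_samples
  support <- integer(nrow(peaks))
  if (any(t1)) {
    hits <- GenomicRanges::findOverlaps(gr, gr[t1])
    sup_sample <- peaks$sample[which(t1)][S4Vectors::subjectHits(hits)]
    support <- tabulate(
      S4Vectors::queryHits(hits)[!duplicated(
        paste(S4Vectors::queryHits(hits), sup_sample))],
      nbins = nrow(peaks)
    )
  }
  keep <- peaks$q <= q_threshold & support >= 2

  if (!is.null(reference_peaks) && nrow(reference_peaks) > 0) {
    ref_hit <- GenomicRanges::countOverlaps(gr, bed_to_granges(reference_peaks)) > 0
    keep <- keep | ref_hit
  }

  peaks <- peaks[keep, , drop = FALSE]
  if (nrow(peaks) == 0) return(peaks)

  # chromatin-state filter: total overlap with state intervals >= cutoff
  gr <- bed_to_granges(peaks)
  st <- GenomicRanges::reduce(bed_to_granges(state_intervals))
  ov <- GenomicRanges::findOverlaps(gr, st)
  widths <- IRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(gr)[S4Vectors::queryHits(ov)],
    GenomicRanges::ranges(st)[S4Vectors::subjectHits(ov)]
  ))
  tot <- numeric(nrow(peaks))
  if (length(ov)) {
    agg <- tapply(widths, S4Vectors::queryHits(ov), sum)
    tot[as.integer(names(agg))] <- agg
  }
  out <- peaks[tot >= min_state_overlap, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge per-tissue ARE sets into a reference set
#'
#' Overlapping or bookended intervals across tissues are merged into
#' maximal intervals; the presence matrix records which source tissues
#' contribute at least 1 bp to each merged ARE.
#'
#' @param per_tissue_are_sets Named list, tissue -> interval table
#'   (chrom, start, end).
#'
#' @return List with `ares` (data.frame: are_id, chrom, start, end) and
#'   `presence` (logical matrix, merged ARE x tissue).
#' @export
merge_reference_ares <- function(per_tissue_are_sets) {
  tissues <- names(per_tissue_are_sets)
  if (is.null(tissues)) stop("per-tissue sets must be named", call. = FALSE)
  all_bed <- do.call(rbind, lapply(unname(per_tissue_are_sets), function(d) {
    d[, c("chrom", "start", "end")]
  }))
  merged <- GenomicRanges::sort(GenomicRanges::reduce(bed_to_granges(all_bed)))
  presence <- vapply(per_tissue_are_sets, function(d) {
    g <- bed_to_granges(d)
    GenomeInfoDb::seqlevels(g) <- GenomeInfoDb::seqlevels(merged)
    GenomicRanges::countOverlaps(merged, g) > 0
  }, logical(length(merged)))
  presence <- matrix(presence, nrow = length(merged),
                     dimnames = list(NULL, tissues))
  bed <- granges_to_bed(merged)
  bed <- cbind(are_id = sprintf("mARE%05d", seq_len(nrow(bed))), bed,
               stringsAsFactors = FALSE)
  rownames(presence) <- bed$are_id
  list(ares = bed, presence = presence)
}

#' Quantify ARE activity from fragment coverage
#'
#' Activity of ARE i in sample k is the summed overlap length between
#' sample-k fragments and the ARE, divided by the ARE length.
#'
#' @param fragments data.frame (chrom, start, end, sample) of fragment
#'   intervals, BED half-open.
#' @param ares Interval table of AREs, non-overlapping; an `are_id` column
#'   is used for row names when present.
#' @param sample_ids Optional character vector fixing the column set and
#'   order (samples with no fragments get all-zero columns).
#'
#' @return Raw activity matrix, ARE x sample.
#' @export
quantify_activity <- function(fragments, ares, sample_ids = NULL) {
  if (nrow(ares) == 0) stop("empty ARE set", call. = FALSE)
  ids <- if ("are_id" %in% names(ares)) ares$are_id else
    sprintf("ARE%05d", seq_len(nrow(ares)))
  if (is.null(sample_ids)) sample_ids <- sort(unique(fragments$sample))
  mat <- matrix(0, nrow(ares), length(sample_ids),
                dimnames = list(ids, sample_ids))
  if (nrow(fragments) == 0) return(mat)
  gr_a <- bed_to_granges(ares)
  gr_f <- bed_to_granges(fragments)
  ov <- GenomicRanges::findOverlaps(gr_a, gr_f)
  if (length(ov)) {
    w <- IRanges::width(IRanges::pintersect(
      GenomicRanges::ranges(gr_a)[S4Vectors::queryHits(ov)],
      GenomicRanges::ranges(gr_f)[S4Vectors::subjectHits(ov)]
    ))
    si <- match(fragments$sample[S4Vectors::subjectHits(ov)], sample_ids)
    keep <- !is.na(si)
    idx <- cbind(S4Vectors::queryHits(ov)[keep], si[keep])
    len <- ares$end - ares$start
    for (r in seq_len(nrow(idx))) {
      mat[idx[r, 1], idx[r, 2]] <- mat[idx[r, 1], idx[r, 2]] + w[keep][r]
    }
    mat <- mat / len
  }
  mat
}

#' Median-of-ratios size-factor normalization
#'
#' For each sample, the size factor is the median over AREs (restricted to
#' AREs positive in every sample) of the ratio of the sample's value to the
#' ARE's geometric mean across samples; factors are rescaled to geometric
#' mean 1 and divided out.
#'
#' @param raw_matrix Raw activity matrix, ARE x sample, >= 2 samples.
#'
#' @return List with `normalized` (matrix) and `size_factors` (named
#'   vector, geometric mean 1).
#' @export
size_factor_normalize <- function(raw_matrix) {
  if (ncol(raw_matrix) < 2) stop("need >= 2 samples", call. = FALSE)
  pos <- rowSums(raw_matrix > 0) == ncol(raw_matrix)
  if (!any(pos)) {
    stop("no ARE has positive activity in every sample; add a pseudo-count ",
         "or filter AREs before normalizing", call. = FALSE)
  }
  sub <- raw_matrix[pos, , drop = FALSE]
  log_geo <- rowMeans(log(sub))
  factors <- apply(sub, 2, function(col) {
    exp(stats::median(log(col) - log_geo))
  })
  factors <- factors / exp(mean(log(factors)))
  normalized <- sweep(raw_matrix, 2, factors, "/")
  list(normalized = normalized, size_factors = factors)
}

#' GC-content correction by quantile-bin median equalization
#'
#' AREs are stratified into `n_bins` GC-content quantile bins; within each
#' bin every sample's values are rescaled so the sample's bin median equals
#' the cross-sample bin median, removing monotone GC artifacts. Off by
#' default in the pipeline.
#'
#' @param matrix_ Activity matrix, ARE x sample.
#' @param gc_per_are GC fraction in [0, 1] per ARE.
#' @param n_bins Number of GC quantile bins (default 10).
#'
#' @return Corrected activity matrix.
#' @export
gc_correct <- function(matrix_, gc_per_are, n_bins = 10) {
  if (any(gc_per_are < 0 | gc_per_are > 1)) {
    stop("GC content must lie in [0, 1]", call. = FALSE)
  }
  if (length(gc_per_are) != nrow(matrix_)) {
    stop("one GC value per ARE required", call. = FALSE)
  }
  qs <- unique(stats::quantile(gc_per_are, probs = seq(0, 1,
                                                       length.out = n_bins + 1)))
  if (length(qs) < 2) return(matrix_)   # constant GC: single bin, identity
  bins <- cut(gc_per_are, qs, include.lowest = TRUE)
  out <- matrix_
  for (b in levels(bins)) {
    rows <- which(bins == b)
    if (length(rows) == 0) next
    sample_med <- apply(matrix_[rows, , drop = FALSE], 2, stats::median)
    target <- stats::median(sample_med)
    scale <- ifelse(sample_med > 0, target / sample_med, 1)
    out[rows, ] <- sweep(matrix_[rows, , drop = FALSE], 2, scale, "*")
  }
  out
}
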