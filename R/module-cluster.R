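#' Binarize a signal matrix
#'
#' Entries at or above the cutoff become 1, all others 0. With -log10
#' p-value signal the conventional cutoff is 2 (p <= 0.01).
#'
#' @param signal_matrix Numeric matrix, ARE x epigenome/sample.
#' @param cutoff Threshold (default 2); the boundary value itself maps to 1.
#' @return Integer 0/1 matrix with the same dimnames.
#' @export
binarize_signal <- function(signal_matrix, cutoff = 2) {
  out <- (signal_matrix >= cutoff) * 1L
  dimnames(out) <- dimnames(signal_matrix)
  out
}

#' Jaccard distance between two binary vectors
#'
#' One minus the Jaccard index |u AND v| / |u OR v|; two all-zero vectors
#' are at distance 0.
#'
#' @param u,v Equal-length binary vectors.
#' @return Distance in [0, 1].
#' @export
jaccard_distance <- function(u, v) {
  if (length(u) != length(v)) stop("vectors differ in length", call. = FALSE)
  un <- sum(u | v)
  if (un == 0) return(0)
  1 - sum(u & v) / un
}

# Generalized Jaccard distance between binary rows and a real centroid
# matrix: 1 - sum(min) / sum(max), computed for all row/centroid pairs.
# For binary x and centroid c in [0,1]: min(x,c) = x*c elementwise when x
# is 0/1 and c >= 0?  No -- min(1,c)=c, min(0,c)=0 so sum(min) = x . c;
# max(1,c)=1, max(0,c)=c so sum(max) = sum(c) + sum(x) - x . c.
gen_jaccard_to_centroids <- function(bin, centroids) {
  dot <- bin %*% t(centroids)                   # n x k
  cs <- rowSums(centroids)
  rs <- rowSums(bin)
  denom <- outer(rs, cs, "+") - dot
  d <- 1 - ifelse(denom > 0, dot / denom, 1)    # empty/empty pair -> 0
  d[denom <= 0] <- 0
  d
}

#' Jaccard k-centroids clustering of a binary matrix
#'
#' Lloyd-style alternation: each row is assigned to the nearest centroid
#' under the generalized Jaccard distance (sum of elementwise minima over
#' sum of maxima; for binary points versus real-valued mean centroids),
#' then centroids are recomputed as cluster means. Assignment ties break to
#' the lowest cluster index. The best of `n_restarts` random restarts by
#' total within-cluster distance is kept; the objective is checked to be
#' non-increasing across iterations.
#'
#' @param binary_matrix 0/1 matrix, rows = AREs, columns = epigenomes.
#' @param k Number of modules, 1 <= k <= nrow.
#' @param n_restarts Random restarts (default 5).
#' @param seed Integer seed.
#' @param max_iter Iteration cap per restart.
#'
#' @return List of class `module_assignment`: `cluster` (named integer
#'   vector in 1..k), `centroids` (k x epigenome matrix), `objective`
#'   (total within-cluster distance), `iterations`.
#' @export
kcentroid_cluster <- function(binary_matrix, k, n_restarts = 5, seed = 1L,
                              max_iter = 100) {
  n <- nrow(binary_matrix)
  if (is.null(n) || n == 0) stop("empty matrix", call. = FALSE)
  if (k < 1 || k > n) stop("`k` must be in 1..nrow", call. = FALSE)
  bin <- (binary_matrix > 0) * 1
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      centroids <- bin[sample.int(n, k), , drop = FALSE]
      obj_prev <- Inf
      assign <- rep(1L, n)
      iters <- 0L
      trace <- numeric()
      repeat {
        iters <- iters + 1L
        d <- gen_jaccard_to_centroids(bin, centroids)
        assign_new <- max.col(-d, ties.method = "first")
        obj <- sum(d[cbind(seq_len(n), assign_new)])
        # stop at convergence or if the mean-centroid update failed to
        # improve the objective (keeps the recorded trace non-increasing)
        if (obj > obj_prev - 1e-12) {
          obj <- obj_prev
          break
        }
        assign <- assign_new
        trace <- c(trace, obj)
        obj_prev <- obj
        if (iters >= max_iter) break
        for (j in seq_len(k)) {
          rows <- which(assign == j)
          if (length(rows) > 0) {
            centroids[j, ] <- colMeans(bin[rows, , drop = FALSE])
          }
          # empty clusters keep their previous centroid
        }
      }
      if (is.null(best) || obj < best$objective) {
        best <- list(cluster = assign, centroids = centroids,
                     objective = obj, iterations = iters,
                     objective_trace = trace)
      }
    }
  })
  names(best$cluster) <- rownames(binary_matrix)
  rownames(best$centroids) <- sprintf("module%03d", seq_len(k))
  class(best) <- "module_assignment"
  best
}

#' @export
print.module_assignment <- function(x, ...) {
  cat(sprintf("module_assignment: %d AREs in %d modules (objective %.3f)\n",
              length(x$cluster), nrow(x$centroids), x$objective))
  invisible(x)
}

#' Ubiquitous score of a module
#'
#' Fraction of samples in which the module's mean ARE activity reaches the
#' activity threshold (default 0.2).
#'
#' @param module_mean_activity Per-sample mean activity of the module.
#' @param activity_threshold Threshold (default 0.2), boundary included.
#' @return Score in [0, 1].
#' @export
ubiquitous_score <- function(module_mean_activity, activity_threshold = 0.2) {
  mean(module_mean_activity >= activity_threshold)
}

#' Cluster reference samples by module-level signal
#'
#' Average-linkage hierarchical clustering with 1 - Pearson correlation as
#' the distance, cut into `n_clusters` clusters.
#'
#' @param module_mean_matrix Module x sample matrix of mean signals.
#' @param n_clusters Number of sample clusters (real-mode default 11).
#' @return Named integer vector of cluster labels per sample.
#' @export
cluster_samples <- function(module_mean_matrix, n_clusters = 11) {
  if (ncol(module_mean_matrix) < n_clusters) {
    stop("need at least `n_clusters` samples", call. = FALSE)
  }
  sds <- apply(module_mean_matrix, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant sample vector(s): correlation undefined for ",
         paste(colnames(module_mean_matrix)[sds == 0], collapse = ", "),
         call. = FALSE)
  }
  d <- stats::as.dist(1 - stats::cor(module_mean_matrix))
  stats::cutree(stats::hclust(d, method = "average"), k = n_clusters)
}

#' Assign modules to named groups
#'
#' Reproduces the group-assignment rules: modules with ubiquitous score
#' above 0.5 are broadly-active; scores in (0.1, 0.5] are multitissue;
#' modules with zero activity in every sample are newly-detected; every
#' other module is labelled by the sample cluster in which it shows its
#' strongest mean signal. Boundary scores fall to the lower category.
#'
#' @param module_mean_matrix Module x sample matrix of mean activities.
#' @param sample_clusters Named integer vector from [cluster_samples()].
#' @param activity_threshold Ubiquitous-score activity threshold
#'   (default 0.2).
#'
#' @return data.frame (module, ubiquitous_score, group,
#'   strongest_cluster).
#' @export
assign_groups <- function(module_mean_matrix, sample_clusters,
                          activity_threshold = 0.2) {
  mods <- rownames(module_mean_matrix)
  if (is.null(mods)) mods <- sprintf("module%03d", seq_len(nrow(module_mean_matrix)))
  scores <- apply(module_mean_matrix, 1, ubiquitous_score,
                  activity_threshold = activity_threshold)
  cl_ids <- sort(unique(sample_clusters))
  # mean module signal within each sample cluster
  cl_mean <- vapply(cl_ids, function(cl) {
    rowMeans(module_mean_matrix[, sample_clusters == cl, drop = FALSE])
  }, numeric(nrow(module_mean_matrix)))
  cl_mean <- matrix(cl_mean, nrow = nrow(module_mean_matrix))
  strongest <- cl_ids[max.col(cl_mean, ties.method = "first")]
  group <- character(length(mods))
  for (i in seq_along(mods)) {
    if (all(module_mean_matrix[i, ] == 0)) {
      group[i] <- "newly-detected"
    } else if (scores[i] > 0.5) {
      group[i] <- "broadly-active"
    } else if (scores[i] > 0.1) {
      group[i] <- "multitissue"
    } else {
      group[i] <- sprintf("sample-cluster-%d", strongest[i])
    }
  }
  data.frame(module = mods, ubiquitous_score = unname(scores),
             group = group, strongest_cluster = strongest,
             stringsAsFactors = FALSE)
}
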