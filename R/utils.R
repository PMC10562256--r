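# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stream index; keeps every
# stage's randomness reproducible and independent of processing order.
# Result stays below 2^31 - 1.
child_seed <- function(seed, index) {
  (as.double(seed) * 48271 + as.double(index) * 1299721) %% 2147483629
}

log_sum_exp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, stable in log space.
log_diff_exp <- function(a, b) {
  if (b > a) stop("log_diff_exp requires a >= b", call. = FALSE)
  if (b == -Inf) return(a)
  a + log1p(-exp(b - a))
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name,
                 format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}

# data.frame(chrom, start, end) in BED half-open coordinates -> GRanges.
bed_to_granges <- function(df) {
  if (!all(c("chrom", "start", "end") %in% names(df))) {
    stop("interval table needs columns chrom, start, end", call. = FALSE)
  }
  if (any(df$start < 0) || any(df$end <= df$start)) {
    stop("malformed intervals: need 0 <= start < end", call. = FALSE)
  }
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

granges_to_bed <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}
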