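test_that("activity quantification implements overlap-over-length exactly", {
  ares <- data.frame(are_id = c("A", "B"), chrom = "chr1",
                     start = c(100L, 400L), end = c(200L, 600L))
  frags <- data.frame(
    chrom = "chr1",
    start = c(150L, 380L, 470L),
    end = c(250L, 410L, 540L),
    sample = c("s1", "s2", "s2")
  )
  act <- quantify_activity(frags, ares, sample_ids = c("s1", "s2"))
  # one fragment overlapping 50 bp of the 100 bp ARE
  expect_equal(act["A", "s1"], 0.5)
  # fragments overlapping 10 bp and 70 bp of the 200 bp ARE
  expect_equal(act["B", "s2"], (10 + 70) / 200)
  expect_equal(act["B", "s1"], 0)
  expect_equal(act["A", "s2"], 0)

  # 30 + 70 over a 200 bp ARE
  ares2 <- data.frame(are_id = "C", chrom = "chr1", start = 0L, end = 200L)
  frags2 <- data.frame(chrom = "chr1", start = c(0L, 100L),
                       end = c(30L, 170L), sample = "s1")
  expect_equal(quantify_activity(frags2, ares2)["C", "s1"], 0.5)

  # no fragments for a sample -> all-zero column
  expect_true(all(quantify_activity(frags[0, ], ares,
                                    sample_ids = "s9") == 0))
  expect_error(quantify_activity(frags, ares[0, ]), "empty ARE set")
})

test_that("quantification is additive in fragment sets", {
  ares <- data.frame(are_id = sprintf("A%d", 1:5), chrom = "chr1",
                     start = seq(0L, 4000L, 1000L),
                     end = seq(500L, 4500L, 1000L))
  set.seed(41)
  mk <- function(n) {
    s <- sample.int(4500L, n)
    data.frame(chrom = "chr1", start = s, end = s + 200L,
               sample = sample(c("s1", "s2"), n, replace = TRUE))
  }
  f1 <- mk(30); f2 <- mk(20)
  ss <- c("s1", "s2")
  expect_equal(
    quantify_activity(rbind(f1, f2), ares, ss),
    quantify_activity(f1, ares, ss) + quantify_activity(f2, ares, ss)
  )
})

test_that("reference merging unions intervals and tracks tissue presence", {
  t1 <- data.frame(chrom = "chr1", start = c(100L, 500L), end = c(200L, 600L))
  t2 <- data.frame(chrom = "chr1", start = 150L, end = 250L)

  m <- merge_reference_ares(list(a = t1, b = t2))
  expect_equal(nrow(m$ares), 2)
  expect_equal(m$ares$start, c(100L, 500L))
  expect_equal(m$ares$end, c(250L, 600L))
  expect_equal(unname(m$presence[1, ]), c(TRUE, TRUE))
  expect_equal(unname(m$presence[2, ]), c(TRUE, FALSE))

  # identical sets: merged count equals either set, both present
  mi <- merge_reference_ares(list(a = t1, b = t1))
  expect_equal(nrow(mi$ares), nrow(t1))
  expect_true(all(mi$presence))

  # disjoint sets of sizes 3 and 4 -> merged size 7
  d1 <- data.frame(chrom = "chr1", start = c(0L, 1000L, 2000L),
                   end = c(100L, 1100L, 2100L))
  d2 <- data.frame(chrom = "chr2", start = c(0L, 1000L, 2000L, 3000L),
                   end = c(100L, 1100L, 2100L, 3100L))
  expect_equal(nrow(merge_reference_ares(list(a = d1, b = d2))$ares), 7)

  # idempotence: merging the merged set returns it unchanged
  m2 <- merge_reference_ares(list(merged = m$ares[, c("chrom", "start", "end")]))
  expect_equal(m2$ares[, c("chrom", "start", "end")],
               m$ares[, c("chrom", "start", "end")])

  expect_error(
    merge_reference_ares(list(a = data.frame(chrom = "chr1", start = 10L,
                                             end = 5L))),
    "malformed")
})

test_that("candidate-peak filtering applies the Tier-1, rescue and state rules", {
  state <- data.frame(chrom = "chr1", start = 0L, end = 10000L)
  pk <- function(start, end, q = 0.001) {
    data.frame(chrom = "chr1", start = start, end = end, q = q)
  }
  tier1 <- c(s1 = TRUE, s2 = TRUE, s3 = FALSE)

  # present in two Tier-1 samples -> kept; only one -> dropped
  kept <- filter_candidate_peaks(
    list(s1 = pk(100L, 300L), s2 = pk(250L, 400L), s3 = pk(5000L, 5200L)),
    tier1, NULL, state)
  expect_setequal(kept$sample, c("s1", "s2"))

  # Tier-1 failure rescued by reference overlap (q ignored for rescue)
  ref <- data.frame(chrom = "chr1", start = 5000L, end = 5100L)
  resc <- filter_candidate_peaks(
    list(s1 = pk(100L, 300L), s2 = pk(250L, 400L),
         s3 = pk(5000L, 5200L, q = 0.5)),
    tier1, ref, state)
  expect_true("s3" %in% resc$sample)

  # q above threshold without rescue -> dropped even with Tier-1 support
  bad_q <- filter_candidate_peaks(
    list(s1 = pk(100L, 300L, q = 0.02), s2 = pk(250L, 400L, q = 0.02)),
    tier1[1:2], NULL, state)
  expect_equal(nrow(bad_q), 0)

  # chromatin-state overlap boundary: exactly 50 bp kept, 49 bp dropped
  state50 <- data.frame(chrom = "chr1", start = 0L, end = 150L)
  at50 <- filter_candidate_peaks(
    list(s1 = pk(100L, 400L), s2 = pk(100L, 400L)),
    tier1[1:2], NULL, state50)
  expect_equal(nrow(at50), 2)
  state49 <- data.frame(chrom = "chr1", start = 0L, end = 149L)
  at49 <- filter_candidate_peaks(
    list(s1 = pk(100L, 400L), s2 = pk(100L, 400L)),
    tier1[1:2], NULL, state49)
  expect_equal(nrow(at49), 0)

  expect_error(
    filter_candidate_peaks(
      list(s1 = data.frame(chrom = "chr1", start = 1L, end = 2L)),
      tier1, NULL, state),
    "q-values")
})

test_that("size factors match median-of-ratios and the DESeq2 oracle", {
  # identical columns -> all factors 1
  m <- matrix(rep(c(1, 2, 3, 4), 3), 4, 3)
  sf <- size_factor_normalize(m)
  expect_equal(unname(sf$size_factors), rep(1, 3))

  # column B = 2 x column A -> factor ratio exactly 2
  m2 <- cbind(A = c(1, 2, 3), B = c(2, 4, 6))
  sf2 <- size_factor_normalize(m2)
  expect_equal(sf2$size_factors[["B"]] / sf2$size_factors[["A"]], 2)
  expect_equal(exp(mean(log(sf2$size_factors))), 1, tolerance = 1e-6)

  # random positive matrix: equality with two independent oracles
  set.seed(77)
  # odd row count so the median is a single order statistic and the
  # linear-space and log-space medians of ratios coincide exactly
  r <- matrix(rexp(201 * 10) + 0.1, 201, 10,
              dimnames = list(NULL, sprintf("s%d", 1:10)))
  sf3 <- size_factor_normalize(r)

  # brute-force median-of-ratios
  geo <- exp(rowMeans(log(r)))
  brute <- apply(r, 2, function(col) median(col / geo))
  brute <- brute / exp(mean(log(brute)))
  expect_equal(unname(sf3$size_factors), unname(brute), tolerance = 1e-10)

  # DESeq2 as an established independent implementation
  ds <- DESeq2::estimateSizeFactorsForMatrix(r)
  ds <- ds / exp(mean(log(ds)))
  expect_equal(unname(sf3$size_factors), unname(ds), tolerance = 1e-10)

  # normalization preserves within-sample rank order
  expect_equal(apply(sf3$normalized, 2, rank), apply(r, 2, rank))

  expect_error(size_factor_normalize(matrix(0, 3, 2)), "pseudo-count")
  expect_error(size_factor_normalize(matrix(1, 3, 1)), "2 samples")
})

test_that("GC correction removes planted monotone artifacts and little else", {
  set.seed(19)
  n <- 400
  gc <- runif(n, 0.3, 0.7)
  base <- matrix(rnorm(n * 6, 10, 1), n, 6,
                 dimnames = list(NULL, sprintf("s%d", 1:6)))

  # constant GC -> single bin -> identity
  expect_equal(gc_correct(base, rep(0.5, n)), base)

  # artifact multiplying one sample by (1 + gc)
  art <- base
  art[, 3] <- art[, 3] * (1 + gc)
  corr <- gc_correct(art, gc, n_bins = 10)
  bins <- cut(gc, quantile(gc, seq(0, 1, 0.1)), include.lowest = TRUE)
  for (b in levels(bins)) {
    rows <- bins == b
    med_s <- apply(corr[rows, ], 2, median)
    expect_true(all(abs(med_s - median(med_s)) / median(med_s) < 0.05))
  }

  # GC independent of activity -> small mean change
  null_corr <- gc_correct(base, gc, n_bins = 10)
  expect_lt(mean(abs(null_corr - base)) / mean(base), 0.05)

  expect_error(gc_correct(base, rep(1.2, n)), "\\[0, 1\\]")
})
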