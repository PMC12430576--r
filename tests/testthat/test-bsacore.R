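test_that("snp_index and delta follow their definitions and guard inputs", {
  expect_equal(snp_index(c(0L, 5L, 10L), c(10L, 10L, 10L)), c(0, 0.5, 1))
  expect_identical(snp_index(0L, 0L), NA_real_)        # zero depth is NA, not 0
  expect_identical(snp_index(NA_integer_, NA_integer_), NA_real_)
  expect_error(snp_index(11L, 10L), "exceed")
  expect_error(snp_index(-1L, 10L), "negative")
  expect_equal(delta_snp_index(c(0.9, 0.5), c(0.2, 0.5)), c(0.7, 0))
  expect_error(delta_snp_index(1.2, 0.5), "\\[0, 1\\]")
})

test_that("the three locus filters fire with fixed precedence", {
  tr <- make_track(index_hc1 = c(0.9, 0.3, 0.9, NA,  0.8),
                   index_hc2 = c(0.2, 0.2, 0.2, 0.2, 0.4),
                   depth_hc1 = c(10L, 10L, 4L,  NA,  12L),
                   depth_hc2 = c(12L, 9L,  11L, 10L, 6L))
  f <- filter_sites(tr)
  expect_identical(f$filter_status,
                   c("pass", "low_index_both", "low_depth", "missing_in_pool",
                     "pass"))
  expect_identical(sum(f$filter_status == "pass"), 2L)
  expect_identical(nrow(f), nrow(tr))                  # flagged, never removed
  # precedence: a site failing both index and depth reports low_index_both
  tr2 <- make_track(0.1, 0.2, 3L, 12L)
  expect_identical(filter_sites(tr2)$filter_status, "low_index_both")
  # an index below 0.5 in one pool only is signal, not a filter hit
  tr3 <- make_track(0.9, 0.1, 20L, 20L)
  expect_identical(filter_sites(tr3)$filter_status, "pass")
  # switchable groupings
  expect_identical(filter_sites(tr3, index_rule = "either")$filter_status,
                   "low_index_both")
  tr4 <- make_track(0.9, 0.6, 4L, 20L)
  expect_identical(filter_sites(tr4, depth_rule = "both")$filter_status, "pass")
})

test_that("window means equal direct subset means and tile from position 1", {
  tr <- make_track(index_hc1 = c(0.9, 0.8, 0.7, 0.6, 0.5),
                   index_hc2 = c(0.1, 0.2, 0.3, 0.2, 0.1),
                   depth_hc1 = c(10L, 12L, 14L, 16L, 18L),
                   depth_hc2 = c(10L, 10L, 10L, 10L, 10L),
                   pos = c(100, 300, 600, 1100, 1600))
  spec <- window_spec(window_size_bp = 1000, step_bp = 500, min_sites = 2)
  w <- window_scan(tr, spec)
  expect_identical(w$start, c(1, 501, 1001, 1501))
  expect_identical(w$end, c(1000, 1500, 1600, 1600))   # clipped at chrom end
  expect_identical(w$n_sites, c(3L, 2L, 2L, 1L))
  expect_identical(w$missing, c(FALSE, FALSE, FALSE, TRUE))
  # independent oracle: direct means over member sites
  for (i in seq_len(nrow(w))) {
    m <- tr$pos >= w$start[i] & tr$pos <= w$end[i]
    expect_equal(w$mean_delta[i], mean(tr$delta[m]))
    expect_equal(w$mean_index_hc1[i], mean(tr$index_hc1[m]))
    expect_equal(w$mean_depth_hc1[i], mean(tr$depth_hc1[m]))
  }
  # non-pass sites never enter a window mean
  tr2 <- tr
  tr2$filter_status[2] <- "low_depth"
  w2 <- window_scan(tr2, spec)
  expect_identical(w2$n_sites[1], 2L)
  expect_equal(w2$mean_delta[1], mean(tr$delta[c(1, 3)]))
})

test_that("null envelopes are deterministic, nested and collapse as confidence -> 0", {
  nm <- null_model(n_reps = 5000, seed = 7)
  t95 <- null_thresholds(30, 30, nm, confidence = 95)
  t99 <- null_thresholds(30, 30, nm, confidence = 99)
  expect_identical(null_thresholds(30, 30, nm, confidence = 95), t95)
  expect_gte(t99[["upper"]], t95[["upper"]])
  expect_lte(t99[["lower"]], t95[["lower"]])
  expect_gt(t95[["upper"]], 0)
  expect_lt(t95[["lower"]], 0)
  t0 <- null_thresholds(30, 30, nm, confidence = 0.1)
  expect_lt(t0[["upper"]] - t0[["lower"]], 0.1)        # shrinks to the median
  expect_error(null_thresholds(30, 30, nm, confidence = 100), "confidence")
  expect_error(null_thresholds(30, 30, nm, confidence = 0), "confidence")
})

test_that("the Monte-Carlo null matches the exact enumeration oracle", {
  nm <- null_model(n_reps = 10000, seed = 11)
  for (dp in list(c(5L, 5L), c(6L, 3L))) {
    ex <- null_delta_exact(dp[1], dp[2], nm$n_hc1, nm$n_hc2)
    expect_equal(sum(ex$prob), 1)
    expect_equal(sum(ex$delta * ex$prob), 0)           # null is centred
    set.seed(nm$seed)
    sim <- sim_null_delta(dp[1], dp[2], nm$n_hc1, nm$n_hc2, nm$n_reps)
    D <- max(abs(stats::ecdf(sim)(ex$delta + 1e-9) - ex$cdf))
    expect_lte(D, 0.02)
  }
  # at equal depth 5 the empirical 95% quantile sits on a stable lattice point
  ex55 <- null_delta_exact(5, 5, nm$n_hc1, nm$n_hc2)
  set.seed(nm$seed)
  sim55 <- sim_null_delta(5L, 5L, nm$n_hc1, nm$n_hc2, nm$n_reps)
  expect_identical(quantile_nearest_rank(sim55, 0.95),
                   exact_null_quantile(ex55, 0.95))
})

test_that("adjacent significant windows merge into one region", {
  w <- make_windows(start = c(1, 100001, 200001, 5000001),
                    end = c(1e6, 1.1e6, 1.2e6, 6e6),
                    mean_delta = c(0.4, 0.7, 0.5, 0.6))
  r <- call_regions(w, confidence = 99)
  expect_identical(nrow(r), 2L)
  expect_equal(r$start[1], 1, ignore_attr = TRUE)
  expect_equal(r$end[1], 1.2e6, ignore_attr = TRUE)
  expect_identical(r$n_windows[1], 3L)
  expect_equal(r$peak_start[1], 100001)                # window with max delta
  expect_equal(r$peak_delta[1], 0.7)
  expect_identical(r$region_id, c("region_01", "region_02"))
})

test_that("region span is end minus start", {
  w <- make_windows(start = 20600000, end = 22200000, mean_delta = 0.6)
  r <- call_regions(w, confidence = 99)
  expect_equal(r$span_bp, 1600000, ignore_attr = TRUE)
})

test_that("the merge gap separates distant windows", {
  w <- make_windows(start = c(1, 1100001), end = c(1e6, 2.1e6),
                    mean_delta = c(0.6, 0.6))
  expect_identical(nrow(call_regions(w, confidence = 99, gap_bp = 1e5)), 1L)
  expect_identical(nrow(call_regions(w, confidence = 99, gap_bp = 0)), 2L)
})

test_that("region calling is one-sided by default and respects missing windows", {
  w <- make_windows(start = c(1, 2000001), end = c(1e6, 3e6),
                    mean_delta = c(-0.7, 0.1))
  expect_identical(nrow(call_regions(w, confidence = 99)), 0L)
  expect_identical(nrow(call_regions(w, confidence = 99, tail = "both")), 1L)
  w2 <- make_windows(start = 1, end = 1e6, mean_delta = 0.7)
  w2$missing <- TRUE
  expect_identical(nrow(call_regions(w2, confidence = 99)), 0L)
  expect_error(call_regions(w2, confidence = 80), "80")
})

test_that("regions count their member pass-filter sites when given the track", {
  tr <- make_track(rep(0.9, 4), rep(0.1, 4), rep(20L, 4), rep(20L, 4),
                   pos = c(5e5, 9e5, 1.5e6, 5e6))
  tr$filter_status[2] <- "low_depth"
  w <- make_windows(start = 1, end = 1e6, mean_delta = 0.7)
  r <- call_regions(w, confidence = 99, track = tr)
  expect_identical(r$n_sites, 1L)
})

test_that("label permutation yields one global symmetric envelope", {
  tr <- make_track(stats::runif(200, 0.3, 0.9), stats::runif(200, 0.1, 0.7),
                   rep(20L, 200), rep(20L, 200),
                   pos = seq(1e5, by = 5e4, length.out = 200))
  w <- window_scan(tr, window_spec(1e6, 5e5, 5))
  nm <- null_model("label_permutation", n_reps = 200, seed = 3)
  wt <- attach_thresholds(w, nm, track = tr)
  expect_identical(length(unique(wt$ci99_high)), 1L)
  expect_lt(abs(wt$ci99_high[1] + wt$ci99_low[1]), 0.06)
  expect_error(attach_thresholds(w, nm), "track")
})
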