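test_that("windows tile marker ranks as enumerated by hand", {
  cfg <- scan_config() # 5-marker windows advancing by 2

  # 9 sites: windows over ranks (1-5), (3-7), (5-9) and nothing more
  w9 <- make_windows(index_tbl(rep(0.1, 9)), cfg)
  expect_equal(nrow(w9), 3L)
  expect_equal(w9$rank_start, c(1L, 3L, 5L))
  expect_equal(w9$rank_end, c(5L, 7L, 9L))
  expect_equal(w9$n_sites, c(5L, 5L, 5L))

  # 5 sites, all delta = 1 -> one full window with mean 1
  w5 <- make_windows(index_tbl(rep(1, 5)), cfg)
  expect_equal(nrow(w5), 1L)
  expect_equal(w5$mean_delta, 1)

  # a single site still yields a (partial) window
  w1 <- make_windows(index_tbl(0.4), cfg)
  expect_equal(w1$n_sites, 1L)
  expect_equal(w1$start, w1$end)

  # 10 sites: a trailing partial window covers the uncovered 10th site
  w10 <- make_windows(index_tbl(rep(0.1, 10)), cfg)
  expect_equal(w10$rank_end, c(5L, 7L, 9L, 10L))
  expect_equal(w10$n_sites[4], 4L)

  # window means are plain arithmetic means of member deltas
  d <- seq(0.1, 0.9, by = 0.1)
  wm <- make_windows(index_tbl(d), cfg)
  expect_equal(wm$mean_delta, c(mean(d[1:5]), mean(d[3:7]), mean(d[5:9])))

  expect_equal(nrow(make_windows(index_tbl(numeric(0)), cfg)), 0L)
})

test_that("LOESS smoothing preserves constant and linear signals", {
  cfg <- scan_config(loess_span = 0.5)

  wc <- smooth_loess(make_windows(index_tbl(rep(0.3, 40)), cfg), cfg)
  expect_lt(max(abs(wc$smoothed_delta - 0.3)), 1e-6)

  # regular spacing: window means of a linear signal are linear in midpoint
  d_lin <- seq(0, 1, length.out = 40)
  wl <- smooth_loess(make_windows(index_tbl(d_lin), cfg), cfg)
  expect_lt(max(abs(wl$smoothed_delta - wl$mean_delta)), 1e-6)

  # fewer than 3 windows: smoothed equals the raw mean
  w2 <- smooth_loess(make_windows(index_tbl(rep(0.2, 6)), cfg), cfg)
  expect_equal(nrow(w2), 2L)
  expect_equal(w2$smoothed_delta, w2$mean_delta)

  # smoothing never changes window count or order: 40 sites tile into 18
  # full windows (starts 1,3,...,35) plus one trailing window at rank 37
  expect_equal(wl$start, sort(wl$start))
  expect_equal(nrow(wl), 19L)
})

test_that("thresholds follow the fixed and interpolated-quantile rules", {
  grid <- tibble::tibble(smoothed_delta = seq(0, 0.999, by = 0.001))
  cfg_emp <- scan_config(threshold_mode = "empirical_tail", tail_fraction = 0.001)
  # oracle for the linear-interpolation quantile on an arithmetic grid:
  # h = (n-1)p = 999 * 0.999 = 998.001 -> x[999] + 0.001 * (x[1000]-x[999])
  expect_equal(compute_threshold(grid, cfg_emp), 0.998001)

  cfg_fix <- scan_config(threshold_mode = "fixed", fixed_threshold = 0.99)
  expect_equal(compute_threshold(grid, cfg_fix), 0.99)

  allc <- tibble::tibble(smoothed_delta = rep(0.42, 50))
  expect_equal(compute_threshold(allc, cfg_emp), 0.42)
})

test_that("marker-level region extraction merges, spans and flanks correctly", {
  cfg <- scan_config() # marker level, 500 kb merge gap, 50 kb flank

  # a lone significant site at scaffold position 780
  lone <- index_tbl(c(0.9, 0.1), pos = c(780L, 700000L), chrom = "Scaffold01")
  r <- extract_regions(lone, 0.5, cfg)
  expect_equal(r$start, -49220L)
  expect_equal(r$end, 50780L)
  expect_equal(r$length, 100001L)
  expect_equal(r$start_clamped, 1L)

  # two nearby significant sites span their exact interval (no flank)
  pair <- index_tbl(c(0.9, 0.85), pos = c(132175L, 132181L))
  r2 <- extract_regions(pair, 0.5, cfg)
  expect_equal(nrow(r2), 1L)
  expect_equal(r2$length, 7L)
  expect_equal(r2$n_sites, 2L)

  # sites farther apart than the merge gap stay separate regions
  far <- index_tbl(c(0.9, 0.9), pos = c(1e6, 2e6))
  expect_equal(nrow(extract_regions(far, 0.5, cfg)), 2L)

  # nothing above threshold -> empty region set
  expect_equal(nrow(extract_regions(index_tbl(rep(0.2, 10)), 0.5, cfg)), 0L)
})

test_that("window-level extraction merges overlapping significant windows", {
  cfg <- scan_config(extract_level = "window")
  d <- rep(0.9, 7) # 7 sites -> two windows, ranks (1-5) and (3-7)
  w <- make_windows(index_tbl(d), cfg)
  w$smoothed_delta <- w$mean_delta # exact control over significance
  r <- extract_regions(w, 0.5, cfg)
  expect_equal(nrow(r), 1L)
  expect_equal(r$n_sites, 7L)
  expect_equal(r$start, 1000L)
  expect_equal(r$end, 7000L)
})

test_that("raising the threshold never grows the significant spans", {
  set.seed(99)
  d <- c(rnorm(150, 0, 0.1), rnorm(30, 0.6, 0.1), rnorm(150, 0, 0.1))
  idx <- index_tbl(d)
  cfg <- scan_config()
  thresholds <- c(0.2, 0.3, 0.4, 0.5, 0.6)
  prev <- extract_regions(idx, thresholds[1], cfg)
  for (t in thresholds[-1]) {
    cur <- extract_regions(idx, t, cfg)
    # every unflanked span at the higher threshold lies inside one at the
    # lower threshold, and none appear from nowhere
    if (nrow(cur) > 0) {
      contained <- vapply(seq_len(nrow(cur)), function(i) {
        any(prev$chrom == cur$chrom[i] &
          prev$span_start <= cur$span_start[i] &
          prev$span_end >= cur$span_end[i])
      }, logical(1))
      expect_true(all(contained))
    }
    expect_lte(sum(cur$span_end - cur$span_start + 1),
               sum(prev$span_end - prev$span_start + 1))
    prev <- cur
  }
})

test_that("region lengths are untouched by clamping", {
  r <- regions("S1", c(-49220L, 100L), c(50780L, 200L))
  expect_equal(r$length, c(100001L, 101L))
  expect_equal(r$length, r$end - r$start + 1L) # raw span, not clamped span
  expect_equal(sum(r$length), sum(r$end - r$start + 1L))
  expect_equal(r$start_clamped, c(1L, 100L))
})

test_that("the composed scan runs on multi-chromosome input", {
  set.seed(5)
  idx <- dplyr::bind_rows(
    index_tbl(rnorm(60, 0, 0.05), chrom = "A01"),
    index_tbl(c(rnorm(25, 0, 0.05), rnorm(10, 0.65, 0.05), rnorm(25, 0, 0.05)),
      chrom = "A02"
    )
  )
  sc <- scan_deltas(idx, scan_config(), source = "snp")
  expect_equal(nrow(sc$windows), length(unique(sc$windows$start)) +
    sum(duplicated(sc$windows$start)))
  expect_true(all(sc$regions$source == "snp"))
  expect_true(all(sc$regions$chrom == "A02"))
})
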