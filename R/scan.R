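#' Genome-scan configuration
#'
#' Windowing is in marker rank, not base pairs: windows of `window_size`
#' consecutive markers advance by `step` markers (the classic QTL-seq
#' 5-SNP/2-SNP scheme). Smoothing is per-chromosome LOESS of the window
#' mean delta on the window midpoint. The significance threshold is either
#' a fixed delta value or the `(1 - tail_fraction)` genome-wide quantile of
#' the smoothed statistic (the empirical right-tail rule).
#'
#' @param window_size Markers per window.
#' @param step Markers the window advances by (`1 <= step <= window_size`).
#' @param loess_span LOESS span (fraction of a chromosome's windows in each
#'   local fit); the default 0.3 trades noise suppression against peak
#'   attenuation at typical window counts (see the package vignette).
#' @param threshold_mode `"empirical_tail"` (default) or `"fixed"`.
#' @param fixed_threshold Delta cutoff used when `threshold_mode = "fixed"`.
#' @param tail_fraction Right-tail mass for the empirical threshold
#'   (default 0.001, i.e. the top 0.1%).
#' @param flank_bp Half-width of the region reported around a lone
#'   significant site (default 50 kb each side, giving 100,001-bp regions).
#' @param extract_level What carries significance when regions are
#'   extracted: `"marker"` (default) compares each site's delta to the
#'   threshold — the convention that reproduces few-bp two-marker regions
#'   and 100,001-bp single-site regions — while `"window"` compares the
#'   smoothed window statistic.
#' @param merge_gap_bp Maximum gap (bp) between significant markers merged
#'   into one region when `extract_level = "marker"`.
#' @return A list of class `bsa_scan_config`.
#' @export
scan_config <- function(window_size = 5L,
                        step = 2L,
                        loess_span = 0.30,
                        threshold_mode = c("empirical_tail", "fixed"),
                        fixed_threshold = 0.99,
                        tail_fraction = 0.001,
                        flank_bp = 50000L,
                        extract_level = c("marker", "window"),
                        merge_gap_bp = 500000L) {
  stopifnot(
    window_size >= 1, step >= 1, step <= window_size,
    tail_fraction > 0, tail_fraction < 1,
    loess_span > 0, loess_span <= 1, flank_bp >= 0, merge_gap_bp >= 0
  )
  structure(
    list(
      window_size = as.integer(window_size), step = as.integer(step),
      loess_span = loess_span,
      threshold_mode = match.arg(threshold_mode),
      fixed_threshold = fixed_threshold, tail_fraction = tail_fraction,
      flank_bp = as.integer(flank_bp),
      extract_level = match.arg(extract_level),
      merge_gap_bp = as.integer(merge_gap_bp)
    ),
    class = "bsa_scan_config"
  )
}

#' Build sliding windows over per-site deltas
#'
#' Windows are laid out in marker rank per chromosome: ranks
#' `1..window_size`, `1+step..`, and so on; a trailing window with fewer
#' than `window_size` sites is emitted whenever sites would otherwise be
#' left uncovered (so scaffolds with few markers still produce a window).
#' `mean_delta` is the arithmetic mean of the member sites' deltas.
#'
#' @param index A per-site index tibble (see [compute_indices()]), sorted
#'   by position within chromosome.
#' @param config A [scan_config()] object.
#' @return A tibble of windows: `chrom`, `rank_start`, `rank_end`, `start`,
#'   `end`, `midpoint` (bp), `n_sites`, `mean_delta`.
#' @export
make_windows <- function(index, config = scan_config()) {
  w <- config$window_size
  s <- config$step
  per_chrom <- function(d) {
    d <- d[order(d$pos), , drop = FALSE]
    n <- nrow(d)
    starts <- seq.int(1L, n, by = s)
    ends <- pmin(starts + w - 1L, n)
    keep <- !duplicated(ends) # drop windows adding no uncovered site
    starts <- starts[keep]
    ends <- ends[keep]
    cs <- c(0, cumsum(d$delta))
    tibble(
      chrom = d$chrom[1],
      rank_start = starts, rank_end = ends,
      start = d$pos[starts], end = d$pos[ends],
      midpoint = (d$pos[starts] + d$pos[ends]) %/% 2L,
      n_sites = ends - starts + 1L,
      mean_delta = (cs[ends + 1L] - cs[starts]) / (ends - starts + 1L)
    )
  }
  if (nrow(index) == 0) {
    return(tibble(
      chrom = character(), rank_start = integer(), rank_end = integer(),
      start = integer(), end = integer(), midpoint = integer(),
      n_sites = integer(), mean_delta = numeric()
    ))
  }
  out <- bind_rows(lapply(split(index, index$chrom), per_chrom))
  arrange(out, .data$chrom, .data$start)
}

#' Smooth window deltas per chromosome by LOESS
#'
#' Fits a locally linear LOESS of `mean_delta` on `midpoint` separately for
#' each chromosome and evaluates it at the window midpoints. Chromosomes
#' with fewer than 3 windows keep their raw means. The effective span is
#' raised to cover at least 4 windows so small scaffolds remain fittable;
#' window count and order are never changed.
#'
#' @param windows Output of [make_windows()].
#' @param config A [scan_config()] object.
#' @return `windows` with a `smoothed_delta` column appended.
#' @export
smooth_loess <- function(windows, config = scan_config()) {
  per_chrom <- function(d) {
    n <- nrow(d)
    if (n < 3) {
      d$smoothed_delta <- d$mean_delta
      return(d)
    }
    span <- min(1, max(config$loess_span, 4 / n))
    fit <- loess(
      mean_delta ~ midpoint,
      data = d, span = span, degree = 1,
      control = loess.control(surface = "direct")
    )
    d$smoothed_delta <- as.numeric(predict(fit, newdata = d))
    d
  }
  if (nrow(windows) == 0) {
    windows$smoothed_delta <- numeric(0)
    return(windows)
  }
  out <- bind_rows(lapply(split(windows, windows$chrom), per_chrom))
  arrange(out, .data$chrom, .data$start)
}

#' Significance threshold for the smoothed delta
#'
#' In `"fixed"` mode returns `fixed_threshold` unchanged. In
#' `"empirical_tail"` mode returns the `(1 - tail_fraction)` quantile
#' (linear-interpolation definition, `stats::quantile` type 7) of the
#' genome-wide smoothed deltas.
#'
#' @param windows Smoothed windows (see [smooth_loess()]).
#' @param config A [scan_config()] object.
#' @return A single numeric threshold.
#' @export
compute_threshold <- function(windows, config = scan_config()) {
  if (config$threshold_mode == "fixed") {
    return(config$fixed_threshold)
  }
  stopifnot(nrow(windows) >= 1)
  quantile(windows$smoothed_delta,
    probs = 1 - config$tail_fraction,
    type = 7, names = FALSE, na.rm = TRUE
  )
}

#' Extract merged candidate regions from a thresholded scan
#'
#' Significance is strict (`statistic > threshold`). At the default
#' `extract_level = "marker"`, every site whose delta exceeds the threshold
#' is significant, and significant sites on one chromosome closer than
#' `merge_gap_bp` merge into one region spanning the outermost member
#' sites. At `extract_level = "window"`, windows whose smoothed delta
#' exceeds the threshold are significant and overlapping or bookended
#' significant windows merge. In both cases a region supported by a single
#' marker is widened to `site +/- flank_bp` — reproducing the 100,001-bp
#' single-site regions (including negative starts near scaffold edges)
#' that the 50-kb flank convention produces — while multi-site regions keep
#' the exact span of their member sites (two markers 7 bp apart give a
#' 7-bp region). Lengths are inclusive (`end - start + 1`).
#'
#' The columns `span_start`/`span_end` keep the unflanked span of the
#' significant sites; on that span, region extraction is monotone in the
#' threshold (raising it never grows coverage).
#'
#' @param x At marker level, a per-site index tibble (see
#'   [compute_indices()]); at window level, smoothed windows (see
#'   [smooth_loess()]).
#' @param threshold Numeric cutoff, usually from [compute_threshold()].
#' @param config A [scan_config()] object.
#' @param source Optional label (`"snp"`/`"indel"`) stored in the result.
#' @return A region tibble (see [regions()]) with extra columns `n_sites`,
#'   `span_start`, `span_end` and `peak_delta` (largest member statistic).
#' @export
extract_regions <- function(x, threshold, config = scan_config(),
                            source = NA_character_) {
  m <- if (config$extract_level == "marker") {
    sig_marker_spans(x, threshold, config)
  } else {
    sig_window_spans(x, threshold)
  }
  if (nrow(m) == 0) {
    out <- regions(character(), integer(), integer(), source = character())
    out$n_sites <- integer()
    out$span_start <- integer()
    out$span_end <- integer()
    out$peak_delta <- numeric()
    return(out)
  }
  m$span_start <- m$start
  m$span_end <- m$end
  lone <- m$n_sites == 1L
  if (any(lone)) {
    site <- m$start[lone] # start == end for a single-site region
    m$start[lone] <- site - config$flank_bp
    m$end[lone] <- site + config$flank_bp
    # flank expansion may create overlaps with a neighbouring region
    m <- merge_region_rows(m)
  }
  out <- regions(m$chrom, m$start, m$end, source = source)
  out$n_sites <- m$n_sites
  out$span_start <- m$span_start
  out$span_end <- m$span_end
  out$peak_delta <- m$peak_delta
  arrange(out, .data$chrom, .data$start)
}

# Cluster significant sites within merge_gap_bp on each chromosome.
sig_marker_spans <- function(index, threshold, config) {
  sig <- index[!is.na(index$delta) & index$delta > threshold, , drop = FALSE]
  if (nrow(sig) == 0) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(),
      n_sites = integer(), peak_delta = numeric()
    ))
  }
  per_chrom <- function(d) {
    d <- d[order(d$pos), , drop = FALSE]
    grp <- cumsum(c(TRUE, diff(d$pos) > config$merge_gap_bp))
    bind_rows(lapply(split(d, grp), function(g) {
      tibble(
        chrom = g$chrom[1], start = min(g$pos), end = max(g$pos),
        n_sites = nrow(g), peak_delta = max(g$delta)
      )
    }))
  }
  bind_rows(lapply(split(sig, sig$chrom), per_chrom))
}

# Merge overlapping/bookended significant windows; member sites counted by
# marker rank (windows on one chromosome share a rank scale).
sig_window_spans <- function(windows, threshold) {
  sig <- windows[!is.na(windows$smoothed_delta) &
    windows$smoothed_delta > threshold, , drop = FALSE]
  if (nrow(sig) == 0) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(),
      n_sites = integer(), peak_delta = numeric()
    ))
  }
  per_chrom <- function(d) {
    d <- d[order(d$start), , drop = FALSE]
    ce <- cummax(d$end)
    grp <- cumsum(c(TRUE, d$start[-1] > head(ce, -1) + 1))
    bind_rows(lapply(split(d, grp), function(g) {
      tibble(
        chrom = g$chrom[1],
        start = min(g$start), end = max(g$end),
        n_sites = max(g$rank_end) - min(g$rank_start) + 1L,
        peak_delta = max(g$smoothed_delta)
      )
    }))
  }
  bind_rows(lapply(split(sig, sig$chrom), per_chrom))
}

merge_region_rows <- function(m) {
  per_chrom <- function(d) {
    d <- d[order(d$start), , drop = FALSE]
    ce <- cummax(d$end)
    grp <- cumsum(c(TRUE, d$start[-1] > head(ce, -1) + 1))
    bind_rows(lapply(split(d, grp), function(g) {
      tibble(
        chrom = g$chrom[1], start = min(g$start), end = max(g$end),
        n_sites = sum(g$n_sites),
        span_start = min(g$span_start), span_end = max(g$span_end),
        peak_delta = max(g$peak_delta)
      )
    }))
  }
  bind_rows(lapply(split(m, m$chrom), per_chrom))
}

#' Run the whole genome scan on a per-site index table
#'
#' Convenience composition of [make_windows()], [smooth_loess()],
#' [compute_threshold()] and [extract_regions()]: the sliding-window
#' smoothed statistic sets the empirical threshold, and regions are then
#' extracted at `config$extract_level`.
#'
#' @inheritParams make_windows
#' @inheritParams extract_regions
#' @return A list with `windows` (smoothed), `threshold` and `regions`.
#' @export
scan_deltas <- function(index, config = scan_config(), source = NA_character_) {
  windows <- smooth_loess(make_windows(index, config), config)
  carrier <- if (config$extract_level == "marker") index else windows
  if (nrow(windows) == 0) {
    return(list(
      windows = windows, threshold = NA_real_,
      regions = extract_regions(carrier, Inf, config, source)
    ))
  }
  threshold <- compute_threshold(windows, config)
  list(
    windows = windows, threshold = threshold,
    regions = extract_regions(carrier, threshold, config, source)
  )
}
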