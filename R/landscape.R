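# Crossover landscapes: normalized distributions, sliding-window cM/Mb
# tracks, differential landscapes, hotspot usage and reduction.

TRACK_MODES <- c("NORMALIZED_FRACTION", "CM_PER_MB", "DIFFERENCE")

new_track <- function(start, end, value, mode, ...) {
  structure(tibble(start = start, end = end, value = value),
            mode = mode,
            class = c("xo_track", class(tibble())),
            ...)
}

#' @export
print.xo_track <- function(x, ...) {
  cat(sprintf("<xo_track> mode=%s, %d bins over [%g, %g)\n",
              attr(x, "mode"), nrow(x), min(x$start), max(x$end)))
  NextMethod()
}

track_mode <- function(track) attr(track, "mode")

# Bin index of 1-based point positions against half-open numeric bin
# edges [e_i, e_{i+1}); points use the continuous coordinate pos - 0.5.
bin_index <- function(midpoints, edges) {
  idx <- findInterval(point_coord(midpoints), edges)
  if (any(idx < 1L | idx >= length(edges))) {
    abort_input("crossover midpoints fall outside the binning range")
  }
  idx
}

resolve_midpoints <- function(calls) {
  calls <- ok_calls(calls)
  if (nrow(calls) == 0L) {
    abort_domain("no OK crossover calls: normalization is undefined")
  }
  calls$midpoint
}

#' Normalized crossover distribution
#'
#' Bins the midpoints of OK crossover calls and divides by the total
#' number of calls, so per-bin values are fractions of all mapped
#' crossovers in the interval and the track sums to exactly 1.  Calls
#' enter at their midpoint, not smeared over the breakpoint interval;
#' with `smear = TRUE` each call's mass is instead distributed
#' uniformly over its marker-bounded breakpoint interval.
#'
#' @param calls An `xo_map_result` or calls tibble; only `status ==
#'   "OK"` rows are used.
#' @param bins Either a numeric vector of increasing bin edges
#'   (0-based, half-open bins) or a [snp_map()], in which case the
#'   inter-marker intervals are the bins — the native resolution of
#'   breakpoint mapping.
#' @param smear Distribute each call over its breakpoint interval
#'   instead of its midpoint (default `FALSE`).
#'
#' @return An `xo_track` (columns `start`, `end`, `value`) with mode
#'   `NORMALIZED_FRACTION` and attribute `n_calls`.
#' @export
build_distribution <- function(calls, bins, smear = FALSE) {
  ok <- ok_calls(calls)
  if (nrow(ok) == 0L) {
    abort_domain("no OK crossover calls: normalization is undefined")
  }
  edges <- if (inherits(bins, "snp_map")) bins$pos else as.numeric(bins)
  if (length(edges) < 2L || is.unsorted(edges, strictly = TRUE)) {
    abort_input("`bins` must provide at least two strictly increasing edges")
  }
  n_bins <- length(edges) - 1L
  if (!smear) {
    idx <- bin_index(ok$midpoint, edges)
    value <- tabulate(idx, nbins = n_bins) / nrow(ok)
  } else {
    value <- numeric(n_bins)
    starts <- edges[-length(edges)]
    ends <- edges[-1L]
    for (i in seq_len(nrow(ok))) {
      a <- ok$left_pos[i]
      b <- ok$right_pos[i]
      if (is.na(a) || is.na(b) || b <= a) {
        abort_input("smear mode needs a positive-width breakpoint interval per call")
      }
      overlap <- pmax(0, pmin(ends, b) - pmax(starts, a))
      value <- value + overlap / (b - a)
    }
    value <- value / nrow(ok)
  }
  new_track(edges[-length(edges)], edges[-1L], value,
            mode = "NORMALIZED_FRACTION", n_calls = nrow(ok))
}

#' Sliding-window crossover frequency in cM/Mb
#'
#' Converts mapped crossover density into genetic-map units: the
#' interval's total map distance `interval_cm` is apportioned over
#' sliding windows by the fraction of OK crossover midpoints each
#' window contains, and divided by the window length in Mb.  Windows
#' advance by `step` on a grid anchored at the interval start and are
#' truncated at both interval edges (leading and trailing partial
#' windows are kept), so that when `window` is a multiple of `step`
#' every position is covered by exactly `window / step` windows and
#' the track integrates back to `interval_cm` exactly (see
#' [track_integral_cm()]).
#'
#' @inheritParams build_distribution
#' @param interval_cm Total genetic size of the interval in cM
#'   (typically from [estimate_rf()]).
#' @param span Numeric length-2, the interval's 0-based half-open
#'   limits; defaults to the map span when `calls` is an
#'   `xo_map_result`.
#' @param window Window width in bp (default 1000).
#' @param step Step between window starts in bp (default 100; must
#'   divide `window` for exact conservation).
#'
#' @return An `xo_track` with mode `CM_PER_MB` and attributes
#'   `interval_cm`, `window`, `step`, `span`, `n_calls`.
#' @export
moving_average_cm_per_mb <- function(calls, interval_cm, span = NULL,
                                     window = 1000, step = 100) {
  assert_scalar_number(interval_cm, "interval_cm", lower = 0)
  if (!is.numeric(window) || length(window) != 1L || window <= 0) {
    abort_input("`window` must be a positive width in bp")
  }
  if (!is.numeric(step) || length(step) != 1L || step <= 0) {
    abort_input("`step` must be a positive width in bp")
  }
  if (is.null(span) && inherits(calls, "xo_map_result")) {
    span <- attr(calls$snps, "span")
  }
  if (is.null(span) || length(span) != 2L || span[1] >= span[2]) {
    abort_input("`span` must be c(start, end) with start < end")
  }
  mids <- resolve_midpoints(calls)
  x <- point_coord(mids)
  if (any(x < span[1] | x >= span[2])) {
    abort_input("crossover midpoints fall outside the interval span")
  }
  n <- length(mids)
  # window grid: starts span[1] + k*step for k = -(window/step - 1) .. K,
  # truncated to the interval at both ends.
  k_min <- -(ceiling(window / step) - 1L)
  starts_full <- span[1] + step * seq(k_min, ceiling((span[2] - span[1]) / step))
  starts_full <- starts_full[starts_full < span[2] & starts_full + window > span[1]]
  w_start <- pmax(starts_full, span[1])
  w_end <- pmin(starts_full + window, span[2])
  counts <- vapply(seq_along(w_start), function(i) {
    sum(x >= w_start[i] & x < w_end[i])
  }, numeric(1))
  frac <- counts / n
  len_mb <- (w_end - w_start) / 1e6
  new_track(w_start, w_end, interval_cm * frac / len_mb,
            mode = "CM_PER_MB",
            interval_cm = interval_cm, window = window, step = step,
            span = span, n_calls = n)
}

#' Integrate a cM/Mb track back to centimorgans
#'
#' Because sliding windows overlap, each position is covered by
#' `window / step` windows; the conservation integral therefore
#' down-weights each window by `step / window`:
#' \deqn{\int = \frac{step}{window} \sum_w v_w \, \ell_w}
#' with \eqn{\ell_w} the (truncated) window length in Mb.  For tracks
#' built by [moving_average_cm_per_mb()] with `step` dividing
#' `window`, this returns the supplied `interval_cm` exactly.
#'
#' @param track An `xo_track` with mode `CM_PER_MB`.
#' @return The integrated map distance in cM.
#' @export
track_integral_cm <- function(track) {
  if (!identical(track_mode(track), "CM_PER_MB")) {
    abort_input("`track` must be a CM_PER_MB track")
  }
  step <- attr(track, "step")
  window <- attr(track, "window")
  sum(track$value * (track$end - track$start) / 1e6) * step / window
}

#' Differential crossover landscape
#'
#' Elementwise difference of two normalized crossover distributions
#' (sample minus control) over identical bins; because both inputs sum
#' to 1 the difference sums to 0, making redistribution (suppression
#' in one region, compensation elsewhere) directly readable.
#'
#' @param sample,control `xo_track`s with mode `NORMALIZED_FRACTION`
#'   on identical bin edges.
#' @return An `xo_track` with mode `DIFFERENCE`.
#' @export
differential_track <- function(sample, control) {
  for (tr in list(sample, control)) {
    if (!identical(track_mode(tr), "NORMALIZED_FRACTION")) {
      abort_input("both tracks must have mode NORMALIZED_FRACTION")
    }
  }
  if (nrow(sample) != nrow(control) ||
      !isTRUE(all.equal(sample$start, control$start)) ||
      !isTRUE(all.equal(sample$end, control$end))) {
    abort_input("sample and control tracks must share identical bin edges")
  }
  new_track(sample$start, sample$end, sample$value - control$value,
            mode = "DIFFERENCE")
}

#' Validate a hotspot annotation table
#'
#' @param hotspots Data frame with columns `name`, `start`, `end`
#'   (0-based half-open spans), non-overlapping.
#' @return The sorted, validated tibble.
#' @export
validate_hotspots <- function(hotspots) {
  hotspots <- as_tibble(hotspots)
  has_columns(hotspots, c("name", "start", "end"), "hotspot annotation")
  if (nrow(hotspots) > 0L) {
    if (any(hotspots$end <= hotspots$start)) {
      abort_input("hotspot spans must have start < end")
    }
    hotspots <- arrange(hotspots, .data$start)
    if (nrow(hotspots) > 1L &&
        any(hotspots$start[-1L] < hotspots$end[-nrow(hotspots)])) {
      abort_input("hotspot spans must not overlap")
    }
    if (anyDuplicated(hotspots$name)) abort_input("hotspot names must be unique")
  }
  hotspots
}

#' Hotspot usage: share of crossovers per hotspot
#'
#' The fraction of OK crossover midpoints falling within each
#' annotated hotspot span; everything else is `background`.  Shares
#' are non-negative and sum to 1 with the background, and are
#' invariant to the order of calls.
#'
#' @inheritParams build_distribution
#' @param hotspots Hotspot annotation (see [validate_hotspots()]), e.g.
#'   the Aro/Coco/Nala spans of a pericentromeric interval.  Spans are
#'   0-based half-open.
#'
#' @return A tibble (`hotspot`, `share`) with one row per hotspot plus
#'   a final `background` row, and attribute `n_calls`.
#' @export
hotspot_usage <- function(calls, hotspots) {
  mids <- resolve_midpoints(calls)
  hotspots <- validate_hotspots(hotspots)
  x <- point_coord(mids)
  share <- vapply(seq_len(nrow(hotspots)), function(i) {
    mean(x >= hotspots$start[i] & x < hotspots$end[i])
  }, numeric(1))
  usage <- tibble(
    hotspot = c(hotspots$name, "background"),
    share = c(share, 1 - sum(share))
  )
  attr(usage, "n_calls") <- length(mids)
  usage
}

#' Percent reduction of a hotspot's crossover share
#'
#' Compares the normalized crossover fraction within one hotspot span
#' between a sample and a control population:
#' \deqn{100 \times (1 - s_{sample} / s_{control})}
#' where `s` is the hotspot's share of all mapped crossovers (from
#' [hotspot_usage()]).  Negative values indicate enhancement.  This is
#' the share-based definition; it compares usage of the hotspot
#' relative to each population's own total, so it is insensitive to
#' overall map-distance changes.
#'
#' @param sample_usage,control_usage Usage tibbles from
#'   [hotspot_usage()].
#' @param hotspot Name of the hotspot to compare.
#' @return Percent reduction (scalar).
#' @export
hotspot_reduction <- function(sample_usage, control_usage, hotspot) {
  pick <- function(usage, what) {
    has_columns(usage, c("hotspot", "share"), "usage table")
    hit <- usage$share[usage$hotspot == hotspot]
    if (length(hit) != 1L) {
      abort_input(sprintf("hotspot '%s' not found in %s usage", hotspot, what))
    }
    hit
  }
  s <- pick(sample_usage, "sample")
  c0 <- pick(control_usage, "control")
  if (c0 == 0) {
    abort_domain(sprintf("control share for hotspot '%s' is zero; reduction undefined",
                         hotspot))
  }
  100 * (1 - s / c0)
}

# ---- I/O -------------------------------------------------------------------

#' Read hotspot annotations from BED
#'
#' Standard BED (0-based half-open) with the hotspot name in column 4,
#' parsed with `rtracklayer`.
#'
#' @param path Path to a BED file.
#' @return A validated hotspot tibble (`name`, `start`, `end`).
#' @export
read_hotspots_bed <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("file not found: %s", path))
  gr <- rtracklayer::import(path, format = "BED")
  validate_hotspots(tibble(
    name = if (!is.null(gr$name)) as.character(gr$name) else
      paste0("hotspot_", seq_along(gr)),
    start = as.numeric(GenomicRanges::start(gr) - 1),
    end = as.numeric(GenomicRanges::end(gr))
  ))
}

#' Write / read a landscape track as bedGraph
#'
#' Tracks are written as 4-column bedGraph (0-based half-open) via
#' `rtracklayer`; mode and window metadata are not preserved by the
#' format, so round trips recover coordinates and values only.
#'
#' @param track An `xo_track`.
#' @param path Output path (`.bedGraph`).
#' @param chrom Chromosome name for the output records.
#' @return `path` invisibly; `read_track_bedgraph()` returns a tibble
#'   (`start`, `end`, `value`).
#' @export
write_track_bedgraph <- function(track, path, chrom = "chr") {
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = round(track$start) + 1L,
                              end = round(track$end)),
    score = track$value
  )
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname write_track_bedgraph
#' @export
read_track_bedgraph <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("file not found: %s", path))
  gr <- rtracklayer::import(path, format = "bedGraph")
  tibble(start = as.numeric(GenomicRanges::start(gr) - 1),
         end = as.numeric(GenomicRanges::end(gr)),
         value = as.numeric(gr$score))
}

#' Write hotspot usage or reduction tables as TSV
#'
#' @param x A tibble (usage or any summary table).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_tsv <- function(x, path) {
  readr::write_tsv(as_tibble(x), path)
  invisible(path)
}
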