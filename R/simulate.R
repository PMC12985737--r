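# Synthetic-data generators with recorded ground truth.  Every
# generator is a pure function of (parameters, seed): a fixed seed
# reproduces the output exactly and the caller's RNG state is never
# disturbed.

#' Hotspot mixture model for crossover placement
#'
#' Crossover breakpoints concentrate in a few narrow hotspots over a
#' low background.  The model places a breakpoint by first choosing a
#' hotspot (or the background) by weight, then drawing a position
#' uniformly within the chosen region.  The background is uniform over
#' the *complement* of the hotspot spans, so each component's weight
#' is exactly the expected share of breakpoints inside its span —
#' which makes hotspot-usage and reduction statistics recoverable by
#' construction.
#'
#' @param interval_length Interval length in bp; the model lives on
#'   the 0-based half-open span `[0, interval_length)`.
#' @param hotspots Tibble with columns `name`, `start`, `end` (0-based
#'   half-open, non-overlapping, inside the interval) and `weight`.
#' @param background_weight Weight of the uniform background component;
#'   weights plus background must sum to 1.
#'
#' @return A list of class `hotspot_mixture`.
#' @export
hotspot_mixture <- function(interval_length, hotspots, background_weight) {
  assert_scalar_number(interval_length, "interval_length", lower = 1)
  hotspots <- validate_hotspots(hotspots[, c("name", "start", "end",
                                             "weight")])
  if (any(hotspots$start < 0) || any(hotspots$end > interval_length)) {
    abort_input("hotspot spans must lie within [0, interval_length)")
  }
  if (any(hotspots$weight < 0) || background_weight < 0) {
    abort_input("mixture weights must be non-negative")
  }
  total <- sum(hotspots$weight) + background_weight
  if (abs(total - 1) > 1e-9) {
    abort_input(sprintf("mixture weights must sum to 1 (got %.12f)", total))
  }
  structure(list(interval_length = interval_length,
                 hotspots = hotspots,
                 background_weight = background_weight),
            class = "hotspot_mixture")
}

#' @export
print.hotspot_mixture <- function(x, ...) {
  cat(sprintf("<hotspot_mixture> [0, %g) bp, %d hotspots, background %.3f\n",
              x$interval_length, nrow(x$hotspots), x$background_weight))
  print(x$hotspots)
  invisible(x)
}

# Maximal segments of the interval not covered by any hotspot.
background_segments <- function(model) {
  hs <- model$hotspots
  edges_start <- c(0, hs$end)
  edges_end <- c(hs$start, model$interval_length)
  seg <- tibble(start = edges_start, end = edges_end)
  seg[seg$end > seg$start, , drop = FALSE]
}

#' Default three-hotspot interval model
#'
#' A 40-kb pericentromeric interval with three interior hotspots — a
#' dominant central one flanked by two weaker ones — over a 10%
#' uniform background.  Mirrors the qualitative structure of a
#' reporter-flanked interval in which most crossovers concentrate in
#' three narrow regions; the exact spans and weights are the package's
#' reference simulation conditions, chosen once (spans aligned to
#' round coordinates, central hotspot carrying half of all crossovers).
#'
#' @param interval_length Interval length in bp (default 40000).
#' @return A [hotspot_mixture()].
#' @export
chp_like_mixture <- function(interval_length = 40000) {
  scale <- interval_length / 40000
  hotspot_mixture(
    interval_length,
    tibble(
      name = c("Aro", "Coco", "Nala"),
      start = c(4000, 16000, 30000) * scale,
      end = c(8000, 24000, 34000) * scale,
      weight = c(0.22, 0.50, 0.18)
    ),
    background_weight = 0.10
  )
}

#' Suppress one hotspot of a mixture by a known factor
#'
#' Returns a new mixture in which `hotspot`'s weight is reduced by
#' `reduction_pct` percent, the removed mass being redistributed
#' proportionally over the remaining components and background.  Used
#' to construct sample/control pairs with a built-in, exactly known
#' hotspot-share reduction for parameter-recovery tests.
#'
#' @param model A [hotspot_mixture()].
#' @param hotspot Name of the hotspot to suppress.
#' @param reduction_pct Percent reduction of the hotspot's weight
#'   (0-100).
#' @return A new `hotspot_mixture`.
#' @export
suppress_hotspot <- function(model, hotspot, reduction_pct) {
  stopifnot(inherits(model, "hotspot_mixture"))
  assert_scalar_number(reduction_pct, "reduction_pct", lower = 0, upper = 100)
  hs <- model$hotspots
  i <- which(hs$name == hotspot)
  if (length(i) != 1L) abort_input(sprintf("hotspot '%s' not in model", hotspot))
  removed <- hs$weight[i] * reduction_pct / 100
  hs$weight[i] <- hs$weight[i] - removed
  rest <- sum(hs$weight[-i]) + model$background_weight
  scale <- if (rest > 0) 1 + removed / rest else 1
  hs$weight[-i] <- hs$weight[-i] * scale
  hotspot_mixture(model$interval_length, hs,
                  model$background_weight * scale)
}

#' Expected bin masses under a hotspot mixture
#'
#' Analytic probability that a breakpoint falls in each half-open bin
#' `[e_i, e_{i+1})`: the reference density for convergence tests of
#' empirical crossover distributions.
#'
#' @param model A [hotspot_mixture()].
#' @param edges Increasing numeric bin edges within the interval.
#' @return Numeric vector of bin probabilities (sums to the fraction
#'   of the interval covered by the edges).
#' @export
mixture_bin_probs <- function(model, edges) {
  stopifnot(inherits(model, "hotspot_mixture"))
  if (length(edges) < 2L || is.unsorted(edges, strictly = TRUE)) {
    abort_input("`edges` must be strictly increasing with length >= 2")
  }
  starts <- edges[-length(edges)]
  ends <- edges[-1L]
  probs <- numeric(length(starts))
  hs <- model$hotspots
  for (i in seq_len(nrow(hs))) {
    overlap <- pmax(0, pmin(ends, hs$end[i]) - pmax(starts, hs$start[i]))
    probs <- probs + hs$weight[i] * overlap / (hs$end[i] - hs$start[i])
  }
  seg <- background_segments(model)
  seg_total <- sum(seg$end - seg$start)
  if (model$background_weight > 0 && seg_total > 0) {
    for (i in seq_len(nrow(seg))) {
      overlap <- pmax(0, pmin(ends, seg$end[i]) - pmax(starts, seg$start[i]))
      probs <- probs + model$background_weight * overlap / seg_total
    }
  }
  probs
}

#' Simulate fluorescent seed tallies
#'
#' Draws (green-only, red-only, other) seed counts multinomially from
#' the segregation-model class probabilities at a true
#' recombinant-gamete fraction, one draw per cross.
#'
#' @param r_true True recombinant-gamete fraction in \[0, 1\]
#'   (`r = cM / 100`).
#' @param n_total Seeds scored per cross.
#' @param n_crosses Number of independent crosses (default 1).
#' @param seed Optional integer seed for exact reproducibility.
#'
#' @return A seed-count tibble (`cross_id`, `n_green`, `n_red`,
#'   `n_total`) with attribute `truth` recording `r_true` and the
#'   seed.
#' @export
simulate_seed_counts <- function(r_true, n_total, n_crosses = 1, seed = NULL) {
  assert_scalar_number(r_true, "r_true", lower = 0, upper = 1)
  assert_scalar_number(n_total, "n_total", lower = 1)
  assert_scalar_number(n_crosses, "n_crosses", lower = 1)
  probs <- expected_seed_class_probs(r_true)
  p <- c(probs$p_green_only, probs$p_red_only, probs$p_other)
  counts <- with_seed_or_current(seed, rmultinom(n_crosses, size = n_total, prob = p))
  out <- tibble(
    cross_id = sprintf("sim_%03d", seq_len(n_crosses)),
    n_green = counts[1, ],
    n_red = counts[2, ],
    n_total = n_total
  )
  attr(out, "truth") <- list(r_true = r_true, cm_true = 100 * r_true,
                             seed = seed)
  out
}

#' Generate a synthetic SNP marker map
#'
#' Stands in for a curated high-fidelity Col/Ler marker list.
#' `uniform` spacing places markers evenly with the first and last at
#' the interval extremes; `random` draws positions uniformly without
#' replacement.  Alleles are drawn from \{A, C, G, T\} with the two
#' parental alleles always different.
#'
#' @param interval_length Interval length in bp.
#' @param n_markers Number of markers (at least 2, at most
#'   `interval_length`).
#' @param seed Optional integer seed.
#' @param spacing `"uniform"` or `"random"`.
#' @inheritParams snp_map
#' @return A [snp_map()] spanning `[0, interval_length)`.
#' @export
make_snp_map <- function(interval_length, n_markers, seed = NULL,
                         spacing = c("uniform", "random"),
                         interval_name = "sim_interval", chrom = "chr_sim") {
  spacing <- match.arg(spacing)
  assert_scalar_number(interval_length, "interval_length", lower = 2)
  assert_scalar_number(n_markers, "n_markers", lower = 2)
  if (n_markers > interval_length) {
    abort_input("`n_markers` cannot exceed `interval_length`")
  }
  with_seed_or_current(seed, {
    pos <- if (spacing == "uniform") {
      unique(round(seq(1, interval_length, length.out = n_markers)))
    } else {
      sort(sample.int(interval_length, n_markers))
    }
    col <- sample(c("A", "C", "G", "T"), length(pos), replace = TRUE)
    ler <- vapply(col, function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, character(1))
  })
  if (length(pos) != n_markers) {
    abort_input("uniform spacing produced duplicate positions; reduce `n_markers`")
  }
  snp_map(
    tibble(id = sprintf("m%04d", seq_along(pos)), pos = pos,
           col_allele = col, ler_allele = unname(ler)),
    interval_name = interval_name, chrom = chrom,
    span = c(0, interval_length)
  )
}

#' Simulate recombinant breakpoints from a hotspot mixture
#'
#' Each recombinant receives one true crossover breakpoint drawn from
#' the mixture (component by weight, then uniform within the
#' component's span) and an orientation drawn Bernoulli(0.5)
#' (`LER_TO_HET` = green-only seed geometry, `HET_TO_LER` = red-only).
#' With probability `p_double` a second, independent breakpoint is
#' added, producing a double-crossover chromatid that a single-
#' breakpoint caller must reject.
#'
#' @param n Number of recombinants.
#' @param model A [hotspot_mixture()].
#' @param seed Optional integer seed.
#' @param p_double Probability of a second breakpoint (default 0).
#'
#' @return A truth tibble (`recombinant_id`, `bp_1`, `bp_2`,
#'   `orientation`, `component`) with breakpoints as continuous
#'   coordinates in `[0, interval_length)`; attribute `truth` records
#'   the parameters.
#' @export
simulate_recombinants <- function(n, model, seed = NULL, p_double = 0) {
  stopifnot(inherits(model, "hotspot_mixture"))
  assert_scalar_number(n, "n", lower = 0)
  assert_scalar_number(p_double, "p_double", lower = 0, upper = 1)
  n <- as.integer(n)
  if (n == 0L) {
    out <- tibble(recombinant_id = character(), bp_1 = numeric(),
                  bp_2 = numeric(), orientation = character(),
                  component = character())
    attr(out, "truth") <- list(model = model, seed = seed, p_double = p_double)
    return(out)
  }
  hs <- model$hotspots
  seg <- background_segments(model)
  seg_len <- seg$end - seg$start
  draw_bp <- function(m) {
    comp <- sample.int(nrow(hs) + 1L, m, replace = TRUE,
                       prob = c(hs$weight, model$background_weight))
    bp <- numeric(m)
    for (i in seq_len(nrow(hs))) {
      sel <- comp == i
      bp[sel] <- runif(sum(sel), hs$start[i], hs$end[i])
    }
    bg <- comp == nrow(hs) + 1L
    if (any(bg)) {
      which_seg <- sample.int(nrow(seg), sum(bg), replace = TRUE,
                              prob = seg_len)
      bp[bg] <- seg$start[which_seg] + runif(sum(bg)) * seg_len[which_seg]
    }
    list(bp = bp, component = c(hs$name, "background")[comp])
  }
  out <- with_seed_or_current(seed, {
    first <- draw_bp(n)
    doubles <- runif(n) < p_double
    bp2 <- rep(NA_real_, n)
    if (any(doubles)) bp2[doubles] <- draw_bp(sum(doubles))$bp
    orientation <- sample(c("LER_TO_HET", "HET_TO_LER"), n, replace = TRUE)
    tibble(
      recombinant_id = sprintf("rec_%05d", seq_len(n)),
      bp_1 = ifelse(is.na(bp2), first$bp, pmin(first$bp, bp2)),
      bp_2 = ifelse(is.na(bp2), NA_real_, pmax(first$bp, bp2)),
      orientation = orientation,
      component = first$component
    )
  })
  attr(out, "truth") <- list(model = model, seed = seed, p_double = p_double)
  out
}

#' Simulate per-marker allele depths for recombinants
#'
#' Observes each recombinant's chromatid pair through finite
#' sequencing: on the HOM_LER side of the breakpoint the true Col-read
#' fraction is 0, on the HET side it is 0.5 (`LER_TO_HET` recombinants
#' start HOM_LER on the left and flip at each breakpoint).  Total
#' depth per marker is Poisson(`mean_depth`) — so MISSING handling is
#' exercised at low depth — and Col-supporting reads are
#' Binomial(depth, p(1-e) + (1-p)e) with symmetric per-base error `e`.
#'
#' @param truth A truth tibble from [simulate_recombinants()].
#' @param snps A [snp_map()].
#' @param mean_depth Mean sequencing depth per marker (default 1500,
#'   the scale of deep amplicon seed typing).
#' @param error_rate Symmetric allele-flip error per read, in
#'   \[0, 0.5) (default 0.002).
#' @param seed Optional integer seed.
#'
#' @return A long-format allele-depth tibble (`recombinant_id`,
#'   `marker_id`, `depth_col`, `depth_ler`).
#' @export
simulate_allele_depths <- function(truth, snps, mean_depth = 1500,
                                   error_rate = 0.002, seed = NULL) {
  stopifnot(inherits(snps, "snp_map"))
  has_columns(truth, c("recombinant_id", "bp_1", "orientation"), "truth table")
  assert_scalar_number(mean_depth, "mean_depth", lower = 1e-9)
  if (!is.numeric(error_rate) || length(error_rate) != 1L ||
      error_rate < 0 || error_rate >= 0.5) {
    abort_domain("`error_rate` must lie in [0, 0.5)")
  }
  n_rec <- nrow(truth)
  n_mark <- nrow(snps)
  if (n_rec == 0L || n_mark == 0L) {
    return(tibble(recombinant_id = character(), marker_id = character(),
                  depth_col = integer(), depth_ler = integer()))
  }
  x <- rep(point_coord(snps$pos), times = n_rec)
  rec <- rep(seq_len(n_rec), each = n_mark)
  bp1 <- truth$bp_1[rec]
  bp2 <- if ("bp_2" %in% names(truth)) truth$bp_2[rec] else rep(NA_real_, length(rec))
  crossings <- (x > bp1) + ifelse(is.na(bp2), 0L, x > bp2)
  starts_ler <- truth$orientation[rec] == "LER_TO_HET"
  is_het <- xor(!starts_ler, crossings %% 2 == 1)
  p_true <- ifelse(is_het, 0.5, 0)
  p_obs <- p_true * (1 - 2 * error_rate) + error_rate
  with_seed_or_current(seed, {
    depth <- rpois(length(x), mean_depth)
    dc <- rbinom(length(x), size = depth, prob = p_obs)
  })
  tibble(
    recombinant_id = truth$recombinant_id[rec],
    marker_id = rep(snps$id, times = n_rec),
    depth_col = as.integer(dc),
    depth_ler = as.integer(depth - dc)
  )
}

#' Deterministic crossover calls from simulated breakpoints
#'
#' Snaps each single-breakpoint recombinant to the flanking markers of
#' a map, producing the `OK` crossover call that an error-free,
#' saturating-depth mapping run would return: the breakpoint interval
#' is the inter-marker gap containing the true breakpoint.  Useful as
#' a noise-free reference when testing landscape statistics at scale.
#' Recombinants whose breakpoint falls outside the outermost markers
#' become `NO_TRANSITION`; double-crossover recombinants are rejected
#' with an error.
#'
#' @inheritParams simulate_allele_depths
#' @return A calls tibble in the layout of [call_crossover()].
#' @export
calls_from_breakpoints <- function(truth, snps) {
  stopifnot(inherits(snps, "snp_map"))
  has_columns(truth, c("recombinant_id", "bp_1", "orientation"), "truth table")
  if ("bp_2" %in% names(truth) && any(!is.na(truth$bp_2))) {
    abort_input("truth contains double-crossover recombinants; map them through allele depths instead")
  }
  coords <- point_coord(snps$pos)
  idx <- findInterval(truth$bp_1, coords)
  interior <- idx >= 1L & idx < nrow(snps)
  li <- ifelse(interior, idx, NA_integer_)
  ri <- li + 1L
  tibble(
    recombinant_id = truth$recombinant_id,
    status = ifelse(interior, "OK", "NO_TRANSITION"),
    orientation = ifelse(interior, truth$orientation, NA_character_),
    left_marker = snps$id[li],
    left_pos = snps$pos[li],
    right_marker = snps$id[ri],
    right_pos = snps$pos[ri],
    midpoint = floor((snps$pos[li] + snps$pos[ri]) / 2),
    n_informative = nrow(snps)
  )
}
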