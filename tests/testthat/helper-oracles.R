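# Independent oracles used across the suite.

# Brute-force seed-class probabilities: enumerate all 16 ordered pairs
# of F1 gametes (RG, neither, R-only, G-only) and classify each F2 seed
# by the union of the reporters its two gametes carry.  Kept deliberately
# naive and independent of expected_seed_class_probs().
enumerate_seed_class_probs <- function(r) {
  gametes <- data.frame(
    has_r = c(TRUE, FALSE, TRUE, FALSE),
    has_g = c(TRUE, FALSE, FALSE, TRUE),
    p = c((1 - r) / 2, (1 - r) / 2, r / 2, r / 2)
  )
  p_green <- 0
  p_red <- 0
  p_other <- 0
  for (i in 1:4) {
    for (j in 1:4) {
      pij <- gametes$p[i] * gametes$p[j]
      has_r <- gametes$has_r[i] || gametes$has_r[j]
      has_g <- gametes$has_g[i] || gametes$has_g[j]
      if (has_g && !has_r) {
        p_green <- p_green + pij
      } else if (has_r && !has_g) {
        p_red <- p_red + pij
      } else {
        p_other <- p_other + pij
      }
    }
  }
  c(p_green_only = p_green, p_red_only = p_red, p_other = p_other)
}

# Seed counts exactly matching the model expectation at fraction r.
expected_counts_at <- function(r, n_total) {
  p <- enumerate_seed_class_probs(r)
  data.frame(cross_id = sprintf("r=%g", r),
             n_green = n_total * p[["p_green_only"]],
             n_red = n_total * p[["p_red_only"]],
             n_total = n_total)
}

# A SNP map on an exact 400-bp grid aligned with round hotspot
# coordinates, so breakpoint snapping cannot leak mass across hotspot
# boundaries.
grid_snp_map <- function(interval_length = 40000, by = 400) {
  pos <- seq(by, interval_length, by = by)
  snp_map(
    tibble::tibble(id = sprintf("g%04d", seq_along(pos)), pos = pos,
                   col_allele = "A", ler_allele = "G"),
    interval_name = "grid", chrom = "chr_sim",
    span = c(0, interval_length)
  )
}

# TRUE when a true breakpoint coordinate lies inside the called
# breakpoint interval (between the flanking markers' point coordinates).
breakpoint_contained <- function(calls, truth) {
  b <- truth$bp_1[match(calls$recombinant_id, truth$recombinant_id)]
  b >= (calls$left_pos - 0.5) & b < (calls$right_pos - 0.5)
}

# Hand-built genotype track for caller unit tests.
toy_track <- function(calls, positions = NULL, id = "rec") {
  n <- length(calls)
  if (is.null(positions)) positions <- seq(100, by = 100, length.out = n)
  tibble::tibble(
    recombinant_id = id,
    marker_id = sprintf("m%02d", seq_len(n)),
    pos = positions,
    call = calls
  )
}
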