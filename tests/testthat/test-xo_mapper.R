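# Genotype calling, haplotype-block segmentation and breakpoint calls.

toy_map <- function(n = 10, by = 100) {
  snp_map(tibble::tibble(
    id = sprintf("m%02d", 1:n), pos = seq(by, by = by, length.out = n),
    col_allele = "A", ler_allele = "T"
  ), span = c(0, by * (n + 1)))
}

test_that("site genotypes follow the depth and fraction thresholds", {
  snps <- toy_map(6)
  depths <- tibble::tibble(
    recombinant_id = "r1",
    marker_id = sprintf("m%02d", 1:6),
    depth_col = c(0, 740, 1490, 550, 10, 330),
    depth_ler = c(1500, 760, 15, 950, 5, 1170)
  )
  track <- call_site_genotypes(depths, snps)
  expect_equal(track$call,
               c("HOM_LER", "HET", "HOM_COL", "HET", "MISSING", "MISSING"))
  # m04: 550/1500 = 0.367 is HET by default but falls in the ambiguous
  # gap under a tighter band; m06: 0.22 sits between hom_max and the band
  tight <- call_site_genotypes(depths, snps, het_band = c(0.4, 0.6))
  expect_equal(tight$call[4], "MISSING")
  expect_true(is.na(track$col_fraction[5]))
  expect_equal(track$col_fraction[1], 0)
})

test_that("genotype thresholds imply vanishing per-site miscall rates at depth", {
  # analytic binomial tails at fixed depth 1500, error 0.2%
  depth <- 1500
  e <- 0.002
  p_hom_miss <- 1 - pbinom(floor(0.15 * depth), depth, e)
  p_het_miss <- pbinom(ceiling(0.30 * depth) - 1, depth, 0.5) +
    (1 - pbinom(floor(0.70 * depth), depth, 0.5))
  expect_lt(p_hom_miss, 1e-6)
  expect_lt(p_het_miss, 1e-6)

  # and empirically: no miscalls over 5e4 simulated fixed-depth sites
  set.seed(5)
  hom <- rbinom(5e4, depth, e)
  het <- rbinom(5e4, depth, 0.5)
  expect_true(all(hom / depth <= 0.15))
  expect_true(all(het / depth >= 0.30 & het / depth <= 0.70))
})

test_that("a clean single transition is called with the right interval", {
  track <- toy_track(c("HOM_LER", "HOM_LER", "HET", "HET"))
  call <- call_crossover(track, min_flank = 2)
  expect_equal(call$status, "OK")
  expect_equal(call$left_pos, 200)
  expect_equal(call$right_pos, 300)
  expect_equal(call$midpoint, 250)
  expect_equal(call$orientation, "LER_TO_HET")

  rev <- call_crossover(toy_track(c("HET", "HET", "HOM_LER", "HOM_LER")))
  expect_equal(rev$orientation, "HET_TO_LER")
})

test_that("non-OK genotype patterns map to the right statuses", {
  expect_equal(call_crossover(toy_track(rep("HET", 5)))$status, "NO_TRANSITION")
  expect_equal(
    call_crossover(toy_track(c("HOM_LER", "HOM_LER", "HET", "HET",
                               "HOM_LER", "HOM_LER")))$status,
    "MULTIPLE_TRANSITIONS"
  )
  expect_equal(
    call_crossover(toy_track(c("HOM_LER", "HOM_LER", "HOM_COL", "HET")))$status,
    "UNEXPECTED_GENOTYPE"
  )
  expect_error(call_crossover(toy_track(c("HOM_LER", "MISSING", "MISSING"))),
               class = "xomapr_input_error")
})

test_that("isolated miscalls are absorbed by the flank requirement", {
  # one stray HET inside the HOM_LER block must not move the call
  track <- toy_track(c("HOM_LER", "HOM_LER", "HET", "HOM_LER", "HOM_LER",
                       "HET", "HET", "HET"))
  call <- call_crossover(track, min_flank = 2)
  expect_equal(call$status, "OK")
  expect_equal(c(call$left_pos, call$right_pos), c(500, 600))
  # with min_flank = 1 the stray marker creates extra boundaries
  expect_equal(call_crossover(track, min_flank = 1)$status,
               "MULTIPLE_TRANSITIONS")
})

test_that("MISSING markers widen the interval but never exclude the truth", {
  snps <- toy_map(12)
  truth <- tibble::tibble(recombinant_id = "r1", bp_1 = 550.3, bp_2 = NA_real_,
                          orientation = "LER_TO_HET")
  depths <- simulate_allele_depths(truth, snps, mean_depth = 2000,
                                   error_rate = 0, seed = 8)
  base <- call_crossover(
    call_site_genotypes(depths, snps), min_flank = 2
  )
  expect_equal(c(base$left_pos, base$right_pos), c(500, 600))
  # mask each marker in turn: the interval may widen by at most the
  # adjacent inter-marker gaps and must still contain the breakpoint
  for (m in snps$id) {
    masked <- depths
    masked$depth_col[masked$marker_id == m] <- 0
    masked$depth_ler[masked$marker_id == m] <- 0
    call <- call_crossover(call_site_genotypes(masked, snps), min_flank = 2)
    expect_equal(call$status, "OK")
    expect_gte(call$left_pos, 400)
    expect_lte(call$right_pos, 700)
    expect_true(breakpoint_contained(call, truth))
  }
})

test_that("orientation follows the reporter geometry of the selected seed", {
  snps <- toy_map(8)
  truth <- tibble::tibble(
    recombinant_id = c("green", "red"),
    bp_1 = c(420.7, 430.2), bp_2 = NA_real_,
    orientation = c("LER_TO_HET", "HET_TO_LER")
  )
  depths <- simulate_allele_depths(truth, snps, mean_depth = 1500,
                                   error_rate = 0.002, seed = 21)
  calls <- map_population(depths, snps)$calls
  expect_equal(calls$orientation[match("green", calls$recombinant_id)],
               "LER_TO_HET")
  expect_equal(calls$orientation[match("red", calls$recombinant_id)],
               "HET_TO_LER")
})

test_that("population mapping tallies statuses and isolates OK calls", {
  expect_equal(nrow(map_population(tibble::tibble(
    recombinant_id = character(), marker_id = character(),
    depth_col = numeric(), depth_ler = numeric()
  ), toy_map())$calls), 0)

  snps <- grid_snp_map()
  model <- chp_like_mixture()
  truth <- simulate_recombinants(80, model, seed = 31, p_double = 0.3)
  depths <- simulate_allele_depths(truth, snps, mean_depth = 1500,
                                   error_rate = 0.002, seed = 32)
  res <- map_population(depths, snps)
  doubles <- truth$recombinant_id[!is.na(truth$bp_2)]
  ok <- ok_calls(res)
  expect_gt(length(doubles), 0)
  expect_false(any(doubles %in% ok$recombinant_id))
  flagged <- res$calls[res$calls$recombinant_id %in% doubles, ]
  expect_true(all(flagged$status %in% c("MULTIPLE_TRANSITIONS",
                                        "NO_TRANSITION")))
  expect_equal(sum(res$tally), 80)
  expect_equal(unname(res$tally[["OK"]]), nrow(ok))
})

test_that("perfect data yields certain containment at marker resolution", {
  snps <- grid_snp_map(20000, by = 500)
  model <- hotspot_mixture(20000, tibble::tibble(
    name = "hs", start = 5000, end = 15000, weight = 0.9
  ), background_weight = 0.1)
  truth <- simulate_recombinants(150, model, seed = 41)
  depths <- simulate_allele_depths(truth, snps, mean_depth = 3000,
                                   error_rate = 0, seed = 42)
  res <- map_population(depths, snps)
  ok <- ok_calls(res)
  edge <- truth$bp_1 < 999.5 | truth$bp_1 >= 19499.5
  expect_equal(nrow(ok), sum(!edge))
  expect_true(all(breakpoint_contained(ok, truth)))
  expect_true(all(ok$right_pos - ok$left_pos == 500))
  expect_true(all(ok$midpoint > ok$left_pos & ok$midpoint < ok$right_pos))
})

test_that("candidate filtering retains exactly the concordant sites", {
  cand <- tibble::tibble(
    id = sprintf("c%02d", 1:10),
    pos = seq(100, 1000, by = 100),
    col_allele = "A", ler_allele = "C",
    n_concordant = c(100, 98, 50, 100, 95, 100, 100, 89, 100, 100),
    n_control = 100
  )
  kept <- filter_snp_candidates(cand, min_support = 0.9)
  expect_equal(nrow(kept), 8)
  expect_false(any(c("c03", "c08") %in% kept$id))
  expect_s3_class(kept, "snp_map")

  all_kept <- filter_snp_candidates(cand, min_support = 0.5)
  expect_equal(nrow(all_kept), 10)

  # generator-labelled truth: 5% of sites made discordant
  set.seed(7)
  n <- 200
  bad <- sort(sample(n, 10))
  cand2 <- tibble::tibble(
    id = sprintf("s%03d", 1:n), pos = seq_len(n) * 37,
    col_allele = "G", ler_allele = "T",
    n_concordant = ifelse(seq_len(n) %in% bad, 40, 99),
    n_control = 100
  )
  kept2 <- filter_snp_candidates(cand2, min_support = 0.9)
  expect_equal(setdiff(cand2$id, kept2$id), cand2$id[bad])

  expect_warning(
    filter_snp_candidates(cand2[bad, ], min_support = 0.9),
    "no candidate markers"
  )
})
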