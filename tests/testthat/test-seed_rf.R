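# Map-distance estimation from fluorescent seed segregation.

test_that("seed-class probabilities match the gamete-pair enumeration", {
  for (r in seq(0, 1, by = 0.05)) {
    oracle <- enumerate_seed_class_probs(r)
    got <- expected_seed_class_probs(r)
    expect_equal(got$p_green_only, oracle[["p_green_only"]], tolerance = 1e-14)
    expect_equal(got$p_red_only, oracle[["p_red_only"]], tolerance = 1e-14)
    expect_equal(got$p_other, oracle[["p_other"]], tolerance = 1e-14)
    expect_equal(got$p_green_only + got$p_red_only + got$p_other, 1)
    expect_identical(got$p_green_only, got$p_red_only)
  }
  expect_equal(expected_seed_class_probs(0)$p_green_only, 0)
  expect_equal(expected_seed_class_probs(0.01)$p_green_only, 0.004975)
  expect_equal(expected_seed_class_probs(1)$p_green_only, 0.25)
  expect_error(expected_seed_class_probs(1.2), class = "xomapr_domain_error")
  expect_error(expected_seed_class_probs(-0.1), class = "xomapr_domain_error")
})

test_that("estimate_rf inverts the segregation model exactly", {
  for (r in seq(0, 0.5, by = 0.01)) {
    counts <- expected_counts_at(r, n_total = 1e6)
    expect_equal(estimate_rf(counts)$cm, 100 * r, tolerance = 1e-12)
  }
})

test_that("estimate_rf handles boundary and example tallies", {
  expect_equal(estimate_rf(data.frame(
    cross_id = "none", n_green = 0, n_red = 0, n_total = 1000
  ))$cm, 0)
  expect_equal(estimate_rf(data.frame(
    cross_id = "edge", n_green = 250, n_red = 250, n_total = 1000
  ))$cm, 100)
  # independent route: numerically invert the class probabilities for
  # NG = NR = 10 of NT = 4000
  p_obs <- 20 / 4000 / 2
  r_star <- uniroot(function(r) (1 - (1 - r)^2) / 4 - p_obs,
                    c(0, 0.5), tol = 1e-12)$root
  got <- estimate_rf(data.frame(
    cross_id = "a", n_green = 10, n_red = 10, n_total = 4000
  ))$cm
  expect_equal(got, 100 * r_star, tolerance = 1e-8)
  expect_equal(got, 100 * (1 - sqrt(0.99)), tolerance = 1e-12)
})

test_that("estimate_rf rejects counts outside the model domain", {
  expect_error(
    estimate_rf(data.frame(cross_id = "x", n_green = 300, n_red = 300,
                           n_total = 1000)),
    class = "xomapr_domain_error"
  )
  expect_error(
    estimate_rf(data.frame(cross_id = "x", n_green = -1, n_red = 0,
                           n_total = 10)),
    class = "xomapr_input_error"
  )
  expect_error(
    estimate_rf(data.frame(cross_id = "x", n_green = 8, n_red = 8,
                           n_total = 10)),
    class = "xomapr_input_error"
  )
})

test_that("estimate is symmetric in NG/NR and strictly monotone in NG+NR", {
  a <- estimate_rf(data.frame(cross_id = "s", n_green = 7, n_red = 13,
                              n_total = 4000))$cm
  b <- estimate_rf(data.frame(cross_id = "s", n_green = 13, n_red = 7,
                              n_total = 4000))$cm
  expect_identical(a, b)
  nrec <- 0:200
  cms <- estimate_rf(data.frame(cross_id = as.character(nrec),
                                n_green = nrec, n_red = 0,
                                n_total = 4000))$cm
  expect_true(all(diff(cms) > 0))
})

test_that("per-cross and pooled aggregation are both reported", {
  counts <- data.frame(
    cross_id = c("c1", "c2", "c3"),
    n_green = c(5, 10, 20), n_red = c(6, 9, 18),
    n_total = c(3000, 5000, 8000)
  )
  s <- summarize_rf(counts)
  expect_equal(nrow(s$per_cross), 3)
  expect_equal(s$summary$mean_cm, mean(s$per_cross$cm))
  pooled <- estimate_rf(data.frame(cross_id = "p", n_green = 35, n_red = 33,
                                   n_total = 16000))$cm
  expect_equal(s$summary$pooled_cm, pooled)
})

test_that("bootstrap CIs are reproducible, bracketing, and degenerate-safe", {
  counts <- data.frame(cross_id = "a", n_green = 10, n_red = 10,
                       n_total = 4000)
  ci1 <- rf_bootstrap_ci(counts, n_boot = 2000, seed = 1)
  ci2 <- rf_bootstrap_ci(counts, n_boot = 2000, seed = 1)
  expect_identical(ci1, ci2)
  expect_lt(ci1$ci_low, ci1$cm)
  expect_gt(ci1$ci_high, ci1$cm)
  expect_true(ci1$ci_low >= 0)

  zero <- rf_bootstrap_ci(
    data.frame(cross_id = "z", n_green = 0, n_red = 0, n_total = 1000),
    n_boot = 500, seed = 3
  )
  expect_identical(zero$ci_low, 0)
  expect_identical(zero$cm, 0)
  expect_error(rf_bootstrap_ci(counts, n_boot = 10), class = "xomapr_input_error")
})

test_that("bootstrap does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(rf_bootstrap_ci(
    data.frame(cross_id = "a", n_green = 5, n_red = 5, n_total = 1000),
    n_boot = 200, seed = 7
  ))
  expect_identical(runif(1), before)
})

test_that("group comparisons behave like the named standard tests", {
  x <- c(0.30, 0.32, 0.34, 0.31, 0.33)
  expect_equal(compare_rf(x, x, method = "mannwhitney")$p_value, 1)

  y <- x + 10
  for (m in c("welch", "ttest", "mannwhitney")) {
    expect_lt(compare_rf(rep(x, 2), rep(y, 2), method = m)$p_value, 0.001)
  }

  set.seed(11)
  a <- rnorm(12, 0.33, 0.05)
  b <- rnorm(9, 0.52, 0.08)
  expect_equal(compare_rf(a, b, "welch")$p_value,
               t.test(a, b, var.equal = FALSE)$p.value)
  expect_equal(compare_rf(a, b, "ttest")$p_value,
               t.test(a, b, var.equal = TRUE)$p.value)
  expect_equal(compare_rf(a, b, "mannwhitney")$p_value,
               wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)

  expect_error(compare_rf(numeric(0), x), class = "xomapr_input_error")
  expect_error(compare_rf(1, 2, method = "welch"), class = "xomapr_input_error")
})

test_that("Welch comparison holds its nominal type-I error rate", {
  set.seed(42)
  reps <- 2000
  p <- replicate(reps, {
    compare_rf(rnorm(10), rnorm(10), method = "welch")$p_value
  })
  rate <- mean(p < 0.05)
  # 3 binomial SE around 0.05 at 2000 replicates
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("seed-count tables round-trip through TSV and CSV", {
  counts <- data.frame(cross_id = c("c1", "c2"), n_green = c(3, 4),
                       n_red = c(2, 5), n_total = c(1000, 1200))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(counts, tsv)
  expect_equal(as.data.frame(read_seed_counts(tsv)), counts)
  csv <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(counts, csv)
  expect_equal(as.data.frame(read_seed_counts(csv)), counts)
})
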