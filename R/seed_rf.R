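#' Expected seed-class probabilities under the reporter segregation model
#'
#' In an FTL/ESIL cross, one homolog carries linked dsRed (R) and eGFP
#' (G) seed-fluorescence reporters flanking the interval; the other
#' homolog carries neither.  F1 gametes occur with frequencies
#' RG: (1-r)/2, neither: (1-r)/2, R-only: r/2, G-only: r/2, where `r`
#' is the recombinant-gamete fraction for the interval.  An F2 seed's
#' fluorescence class is the union of the reporters carried by its two
#' gametes, so a seed is green-only when at least one gamete carries G
#' and neither carries R:
#'
#' \deqn{p_{green} = p_{red} = \frac{1 - (1 - r)^2}{4}}
#'
#' @param r Recombinant-gamete fraction(s) in \[0, 1\].
#'
#' @return A tibble with one row per element of `r` and columns `r`,
#'   `p_green_only`, `p_red_only`, `p_other` (both-color plus
#'   nonfluorescent seeds, never split further).  Rows sum to 1.
#'
#' @examples
#' expected_seed_class_probs(c(0, 0.01, 1))
#' @seealso [estimate_rf()], which inverts this model.
#' @export
expected_seed_class_probs <- function(r) {
  if (!is.numeric(r) || length(r) == 0L || anyNA(r)) {
    abort_domain("`r` must be numeric and non-missing")
  }
  if (any(r < 0 | r > 1)) {
    abort_domain("recombinant-gamete fraction `r` must lie in [0, 1]")
  }
  p_single <- (1 - (1 - r)^2) / 4
  tibble(
    r = r,
    p_green_only = p_single,
    p_red_only = p_single,
    p_other = 1 - 2 * p_single
  )
}

#' Estimate genetic map distance from fluorescent seed counts
#'
#' Inverts the two-gamete segregation model of
#' [expected_seed_class_probs()]: with `NG` green-only seeds, `NR`
#' red-only seeds, and `NT` seeds in total,
#'
#' \deqn{\mathrm{RF} = 100 \times \left(1 - \sqrt{1 - \frac{2(NG + NR)}{NT}}\right)}
#'
#' in centimorgans.  This is the exact inverse of the gamete model —
#' applied to the expected class counts at recombinant fraction `r` it
#' returns exactly `100 r` — and reduces to the familiar
#' `100 (NG + NR) / NT` for small `r`.  It returns 0 cM at zero
#' recombinant seeds and 100 cM at the model boundary
#' `NG + NR = NT / 2`.
#'
#' @param counts A data frame of seed tallies with columns `cross_id`,
#'   `n_green` (green-only seeds), `n_red` (red-only seeds), and
#'   `n_total` (all seeds scored).  Counts may be non-integer (e.g.
#'   expected counts); both-color and nonfluorescent seeds enter only
#'   through `n_total`.
#'
#' @return The input tibble with an added `cm` column (map distance in
#'   centimorgans, one value per cross).
#'
#' @examples
#' estimate_rf(data.frame(
#'   cross_id = "wt_1", n_green = 10, n_red = 10, n_total = 4000
#' ))
#' @export
estimate_rf <- function(counts) {
  counts <- validate_seed_counts(counts)
  x <- 2 * (counts$n_green + counts$n_red) / counts$n_total
  bad <- x > 1
  if (any(bad)) {
    abort_domain(sprintf(
      "impossible counts for the segregation model (2(NG+NR) > NT) in cross(es): %s",
      paste(counts$cross_id[bad], collapse = ", ")
    ))
  }
  counts$cm <- 100 * (1 - sqrt(1 - x))
  counts
}

#' Validate a seed-count table
#'
#' Checks the invariants of a seed tally: non-negative class counts,
#' `n_green + n_red <= n_total`, and `n_total > 0`.
#'
#' @inheritParams estimate_rf
#' @return The validated counts as a tibble (invisibly usable in
#'   pipelines).
#' @export
validate_seed_counts <- function(counts) {
  counts <- as_tibble(counts)
  has_columns(counts, c("cross_id", "n_green", "n_red", "n_total"),
              "seed-count table")
  if (nrow(counts) == 0L) abort_input("seed-count table has no rows")
  num <- c("n_green", "n_red", "n_total")
  for (col in num) {
    if (!is.numeric(counts[[col]]) || anyNA(counts[[col]])) {
      abort_input(sprintf("column `%s` must be numeric and non-missing", col))
    }
  }
  if (any(counts$n_green < 0) || any(counts$n_red < 0)) {
    abort_input("seed counts must be non-negative")
  }
  if (any(counts$n_total <= 0)) {
    abort_input("`n_total` must be positive")
  }
  if (any(counts$n_green + counts$n_red > counts$n_total)) {
    abort_input("`n_green + n_red` exceeds `n_total`")
  }
  counts
}

#' Summarise map distance across crosses
#'
#' Reports per-cross centimorgan estimates together with two
#' aggregates: the unweighted mean of per-cross estimates (matching
#' plots where each point is one cross and the center line is the
#' mean) and the pooled estimate obtained by summing counts over all
#' crosses before inverting the model.  The two differ only through
#' between-cross heterogeneity and unequal seed numbers.
#'
#' @inheritParams estimate_rf
#' @return A list with `per_cross` (tibble from [estimate_rf()]) and a
#'   one-row `summary` tibble with `n_crosses`, `mean_cm`, `pooled_cm`
#'   and `n_total`.
#' @export
summarize_rf <- function(counts) {
  per_cross <- estimate_rf(counts)
  pooled <- estimate_rf(tibble(
    cross_id = "pooled",
    n_green = sum(per_cross$n_green),
    n_red = sum(per_cross$n_red),
    n_total = sum(per_cross$n_total)
  ))
  list(
    per_cross = per_cross,
    summary = tibble(
      n_crosses = nrow(per_cross),
      mean_cm = mean(per_cross$cm),
      pooled_cm = pooled$cm,
      n_total = sum(per_cross$n_total)
    )
  )
}

#' Bootstrap confidence intervals for map-distance estimates
#'
#' Percentile bootstrap: for each cross the seed classes
#' (green-only, red-only, other) are resampled multinomially at the
#' observed total seed number, and the estimator is applied to every
#' resample.  Resamples that fall outside the model domain
#' (`2(NG+NR) > NT`, possible only near the 50 cM boundary) are
#' truncated to 100 cM.  With zero recombinant seeds the lower bound
#' collapses to 0 and the interval never fails.
#'
#' @inheritParams estimate_rf
#' @param n_boot Number of bootstrap resamples (default 2000; at
#'   least 100).
#' @param level Confidence level (default 0.95).
#' @param seed Optional integer seed; a fixed seed makes the interval
#'   reproducible.  The caller's RNG state is left untouched.
#'
#' @return The counts tibble with columns `cm`, `ci_low`, `ci_high`.
#'
#' @examples
#' rf_bootstrap_ci(
#'   data.frame(cross_id = "a", n_green = 10, n_red = 10, n_total = 4000),
#'   n_boot = 500, seed = 1
#' )
#' @export
rf_bootstrap_ci <- function(counts, n_boot = 2000, level = 0.95, seed = NULL) {
  counts <- estimate_rf(counts)
  assert_scalar_number(n_boot, "n_boot", lower = 100)
  assert_scalar_number(level, "level", lower = 0, upper = 1)
  alpha <- (1 - level) / 2
  with_seed_or_current(seed, {
    ci <- lapply(seq_len(nrow(counts)), function(i) {
      nt <- counts$n_total[i]
      probs <- c(counts$n_green[i], counts$n_red[i],
                 nt - counts$n_green[i] - counts$n_red[i]) / nt
      draws <- rmultinom(n_boot, size = nt, prob = probs)
      x <- pmin(2 * (draws[1, ] + draws[2, ]) / nt, 1)
      cms <- 100 * (1 - sqrt(1 - x))
      quantile(cms, probs = c(alpha, 1 - alpha), names = FALSE)
    })
    counts$ci_low <- vapply(ci, `[`, numeric(1), 1L)
    counts$ci_high <- vapply(ci, `[`, numeric(1), 2L)
  })
  counts
}

#' Compare per-cross map distances between two groups
#'
#' Two-sided comparison of centimorgan values between genotypes or
#' treatments, one value per cross.  `welch` is Welch's unequal-variance
#' t test, `ttest` the pooled-variance Student t test, and
#' `mannwhitney` the Mann-Whitney U (Wilcoxon rank-sum) test.  The
#' rank-sum test always uses the normal approximation with continuity
#' correction so that tied values (common with identical tallies) are
#' handled without warnings; identical groups give p = 1.
#'
#' @param group_a,group_b Numeric vectors of per-cross cM values.
#' @param method One of `"welch"`, `"mannwhitney"`, `"ttest"`.
#'
#' @return A one-row tibble with `method`, `statistic`, `p_value`,
#'   `n_a`, `n_b`.
#'
#' @examples
#' compare_rf(c(0.31, 0.35, 0.33), c(0.50, 0.55, 0.52), method = "welch")
#' @export
compare_rf <- function(group_a, group_b,
                       method = c("welch", "mannwhitney", "ttest")) {
  method <- match.arg(method)
  if (length(group_a) == 0L || length(group_b) == 0L) {
    abort_input("both groups must contain at least one value")
  }
  min_n <- if (method == "mannwhitney") 1L else 2L
  if (length(group_a) < min_n || length(group_b) < min_n) {
    abort_input(sprintf("method '%s' needs at least %d values per group",
                        method, min_n))
  }
  res <- switch(method,
    welch = t.test(group_a, group_b, var.equal = FALSE),
    ttest = t.test(group_a, group_b, var.equal = TRUE),
    mannwhitney = wilcox.test(group_a, group_b, exact = FALSE, correct = TRUE)
  )
  tibble(
    method = method,
    statistic = unname(res$statistic),
    p_value = res$p.value,
    n_a = length(group_a),
    n_b = length(group_b)
  )
}

#' Read a seed-count table
#'
#' Reads a delimited tally of seed classes per cross — the layout of a
#' raw seed-scoring sheet — with columns `cross_id`, `n_green`,
#' `n_red`, `n_total`.  The delimiter is chosen from the file
#' extension (`.csv` vs anything else = tab).
#'
#' @param path Path to a TSV/CSV file.
#' @return A validated seed-count tibble.
#' @export
read_seed_counts <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("file not found: %s", path))
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv
  } else {
    readr::read_tsv
  }
  validate_seed_counts(reader(path, show_col_types = FALSE, comment = "#"))
}
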