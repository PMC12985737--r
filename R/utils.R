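# Internal helpers shared across modules.

# Continuous coordinate of a 1-based base position: the point sits in
# the middle of the unit [pos - 1, pos).  All span/bin membership tests
# use this coordinate against 0-based half-open [start, end) intervals,
# so a position p lies in a BED span (start, end] iff start <= p - 0.5 < end.
point_coord <- function(pos) pos - 0.5

abort_domain <- function(msg) {
  abort(msg, class = "xomapr_domain_error")
}

abort_input <- function(msg) {
  abort(msg, class = "xomapr_input_error")
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state; with seed = NULL the current RNG stream is used.
with_seed_or_current <- function(seed, expr) {
  if (is.null(seed)) {
    force(expr)
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

# Deterministic per-stage seed derived from a master seed and a stage
# label; keeps every stochastic stage independently seeded while the
# user supplies a single integer.
stage_seed <- function(master_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master_seed) * 1009 + h) %% .Machine$integer.max)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort_input(sprintf("`%s` must be a single non-missing number", name))
  }
  if (x < lower || x > upper) {
    abort_input(sprintf("`%s` must be in [%s, %s], got %s", name, lower, upper, x))
  }
  invisible(x)
}

has_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort_input(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}
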