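# Crossover breakpoint calling from per-marker allele depths: the
# computational core of seed typing, downstream of read alignment.

GENOTYPE_LEVELS <- c("HOM_LER", "HET", "HOM_COL", "MISSING")
STATUS_LEVELS <- c("OK", "NO_TRANSITION", "MULTIPLE_TRANSITIONS",
                   "UNEXPECTED_GENOTYPE")

#' Call per-marker genotypes from allele depths
#'
#' Each marker of each recombinant is classified from the fraction of
#' reads supporting the Col allele.  Selected single-color seeds carry
#' one recombinant chromatid over a non-recombinant Ler homolog, so the
#' expected genotypes are HOM_LER (Col fraction near 0) on one side of
#' the breakpoint and HET (near 0.5) on the other; HOM_COL is still
#' called (near 1) so that contaminating or double-recombinant seeds
#' surface as QC failures downstream.
#'
#' Classification of the Col fraction `f` at total depth `d`:
#' `d < min_depth` gives MISSING; `f <= hom_max` HOM_LER; `f` inside
#' `het_band` HET; `f >= 1 - hom_max` HOM_COL; anything else (the gaps
#' between bands) is ambiguous and set to MISSING.  The defaults are
#' deliberately loose for ~1500x amplicon coverage and keep the caller
#' usable at far lower simulated depth.
#'
#' @param depths Long-format allele-depth table: columns
#'   `recombinant_id`, `marker_id`, `depth_col`, `depth_ler`.
#' @param snps The [snp_map()] the markers belong to; genotypes are
#'   returned in map order.
#' @param min_depth Minimum total depth for a call (default 20).
#' @param het_band Col-fraction interval called HET (default
#'   `c(0.30, 0.70)`).
#' @param hom_max Maximum Col fraction for HOM_LER, mirrored at
#'   `1 - hom_max` for HOM_COL (default 0.15).
#'
#' @return A tibble (`recombinant_id`, `marker_id`, `pos`, `depth_col`,
#'   `depth_ler`, `col_fraction`, `call`) sorted by recombinant and
#'   position, with class `genotype_track`.
#' @export
call_site_genotypes <- function(depths, snps, min_depth = 20,
                                het_band = c(0.30, 0.70), hom_max = 0.15) {
  depths <- as_tibble(depths)
  has_columns(depths, c("recombinant_id", "marker_id", "depth_col", "depth_ler"),
              "allele-depth table")
  stopifnot(inherits(snps, "snp_map"))
  assert_scalar_number(min_depth, "min_depth", lower = 1)
  assert_scalar_number(hom_max, "hom_max", lower = 0, upper = 0.5)
  if (length(het_band) != 2L || het_band[1] >= het_band[2]) {
    abort_input("`het_band` must be c(lo, hi) with lo < hi")
  }
  if (hom_max > het_band[1]) {
    abort_input("`hom_max` must not exceed the lower edge of `het_band`")
  }
  if (any(depths$depth_col < 0) || any(depths$depth_ler < 0)) {
    abort_input("allele depths must be non-negative")
  }
  unknown <- setdiff(depths$marker_id, snps$id)
  if (length(unknown) > 0L) {
    abort_input(sprintf("depth table contains marker(s) absent from the map: %s",
                        paste(utils::head(unknown, 5L), collapse = ", ")))
  }
  track <- left_join(depths,
                     tibble(marker_id = snps$id, pos = snps$pos),
                     by = "marker_id")
  total <- track$depth_col + track$depth_ler
  frac <- ifelse(total > 0, track$depth_col / total, NA_real_)
  track$col_fraction <- ifelse(total >= min_depth, frac, NA_real_)
  track$call <- case_when(
    total < min_depth ~ "MISSING",
    frac <= hom_max ~ "HOM_LER",
    frac >= 1 - hom_max ~ "HOM_COL",
    frac >= het_band[1] & frac <= het_band[2] ~ "HET",
    TRUE ~ "MISSING"
  )
  track <- arrange(track, .data$recombinant_id, .data$pos)
  class(track) <- c("genotype_track", class(track))
  track
}

#' Call a crossover breakpoint from one recombinant's genotype track
#'
#' Informative (non-MISSING) marker calls are segmented into maximal
#' runs of identical genotype (haplotype blocks).  A block boundary is
#' a candidate breakpoint when both flanking blocks contain at least
#' `min_flank` concordant markers — short blocks produced by isolated
#' miscalls therefore cannot create or destroy a call on their own.
#'
#' * exactly one HOM_LER/HET boundary: status `OK`; the breakpoint
#'   interval runs from the last marker of the left block to the first
#'   marker of the right block, with `midpoint = floor((left + right)/2)`;
#' * no boundary: `NO_TRANSITION` (also used when fewer than
#'   `min_flank` markers flank every boundary);
#' * more than one boundary: `MULTIPLE_TRANSITIONS` — the recombinant
#'   is rejected rather than arbitrated;
#' * any HOM_COL call among informative markers: `UNEXPECTED_GENOTYPE`
#'   (the single-chromatid seed model admits only HOM_LER and HET).
#'
#' Orientation is `LER_TO_HET` when the HOM_LER block is on the left
#' (the green-only seed geometry) and `HET_TO_LER` otherwise.
#'
#' @param track A `genotype_track` for a single recombinant (at least
#'   two informative markers).
#' @param min_flank Minimum markers supporting each side of a boundary
#'   (default 2).
#'
#' @return A one-row tibble: `recombinant_id`, `status`, `orientation`,
#'   `left_marker`, `left_pos`, `right_marker`, `right_pos`,
#'   `midpoint`, `n_informative`.  Interval fields are `NA` unless
#'   `status == "OK"`.
#' @export
call_crossover <- function(track, min_flank = 2) {
  track <- as_tibble(track)
  has_columns(track, c("recombinant_id", "marker_id", "pos", "call"),
              "genotype track")
  rid <- unique(track$recombinant_id)
  if (length(rid) != 1L) {
    abort_input("`track` must contain exactly one recombinant; see map_population()")
  }
  assert_scalar_number(min_flank, "min_flank", lower = 1)
  inf <- track[track$call != "MISSING", ]
  inf <- inf[order(inf$pos), ]
  if (nrow(inf) < 2L) {
    abort_input(sprintf("recombinant %s has fewer than 2 informative markers", rid))
  }
  empty_call <- function(status) {
    tibble(recombinant_id = rid, status = status,
           orientation = NA_character_,
           left_marker = NA_character_, left_pos = NA_real_,
           right_marker = NA_character_, right_pos = NA_real_,
           midpoint = NA_real_, n_informative = nrow(inf))
  }
  if (any(inf$call == "HOM_COL")) {
    return(empty_call("UNEXPECTED_GENOTYPE"))
  }
  runs <- rle(inf$call)
  ends <- cumsum(runs$lengths)
  n_runs <- length(runs$lengths)
  if (n_runs == 1L) return(empty_call("NO_TRANSITION"))
  boundary <- which(runs$lengths[-n_runs] >= min_flank &
                    runs$lengths[-1L] >= min_flank)
  if (length(boundary) == 0L) return(empty_call("NO_TRANSITION"))
  if (length(boundary) > 1L) return(empty_call("MULTIPLE_TRANSITIONS"))
  i <- boundary
  left_idx <- ends[i]
  right_idx <- left_idx + 1L
  orientation <- if (runs$values[i] == "HOM_LER") "LER_TO_HET" else "HET_TO_LER"
  tibble(
    recombinant_id = rid, status = "OK", orientation = orientation,
    left_marker = inf$marker_id[left_idx], left_pos = inf$pos[left_idx],
    right_marker = inf$marker_id[right_idx], right_pos = inf$pos[right_idx],
    midpoint = floor((inf$pos[left_idx] + inf$pos[right_idx]) / 2),
    n_informative = nrow(inf)
  )
}

#' Map a recombinant population to crossover calls
#'
#' Runs genotype calling and breakpoint calling over every recombinant
#' in an allele-depth table and tallies calls by status.  Recombinants
#' with fewer than two informative markers cannot exhibit a genotype
#' transition and are tallied as `NO_TRANSITION`.  Only `OK` calls
#' should feed landscape construction.
#'
#' @inheritParams call_site_genotypes
#' @inheritParams call_crossover
#'
#' @return A list of class `xo_map_result`: `calls` (one row per
#'   recombinant, as [call_crossover()]), `tally` (named integer vector
#'   over all four statuses), and `snps`.
#' @export
map_population <- function(depths, snps, min_depth = 20,
                           het_band = c(0.30, 0.70), hom_max = 0.15,
                           min_flank = 2) {
  depths <- as_tibble(depths)
  if (nrow(depths) == 0L) {
    calls <- tibble(
      recombinant_id = character(), status = character(),
      orientation = character(),
      left_marker = character(), left_pos = numeric(),
      right_marker = character(), right_pos = numeric(),
      midpoint = numeric(), n_informative = integer()
    )
  } else {
    tracks <- call_site_genotypes(depths, snps, min_depth = min_depth,
                                  het_band = het_band, hom_max = hom_max)
    pieces <- split(tracks, tracks$recombinant_id)
    calls <- bind_rows(lapply(pieces, function(tr) {
      tryCatch(call_crossover(tr, min_flank = min_flank),
               xomapr_input_error = function(e) {
                 tibble(recombinant_id = unique(tr$recombinant_id),
                        status = "NO_TRANSITION", orientation = NA_character_,
                        left_marker = NA_character_, left_pos = NA_real_,
                        right_marker = NA_character_, right_pos = NA_real_,
                        midpoint = NA_real_,
                        n_informative = sum(tr$call != "MISSING"))
               })
    }))
  }
  tally <- setNames(integer(length(STATUS_LEVELS)), STATUS_LEVELS)
  obs <- table(calls$status)
  tally[names(obs)] <- as.integer(obs)
  structure(list(calls = calls, tally = tally, snps = snps),
            class = "xo_map_result")
}

#' @export
print.xo_map_result <- function(x, ...) {
  cat(sprintf("<xo_map_result> %d recombinants over %s\n",
              nrow(x$calls), attr(x$snps, "interval_name")))
  print(x$tally)
  invisible(x)
}

#' Extract the OK crossover calls from a mapping result
#'
#' @param result An `xo_map_result` (or a calls tibble).
#' @return Tibble of calls with `status == "OK"`.
#' @export
ok_calls <- function(result) {
  calls <- if (inherits(result, "xo_map_result")) result$calls else as_tibble(result)
  calls[calls$status == "OK", , drop = FALSE]
}

# ---- I/O -------------------------------------------------------------------

#' Read a long-format allele-depth table
#'
#' TSV with columns `recombinant_id`, `marker_id`, `depth_col`,
#' `depth_ler` — the product of counting parental alleles in an
#' alignment pileup at the map's markers.
#'
#' @param path Path to the TSV file.
#' @return A tibble.
#' @export
read_allele_depths <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("file not found: %s", path))
  depths <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                            col_types = readr::cols(
                              recombinant_id = readr::col_character(),
                              marker_id = readr::col_character(),
                              depth_col = readr::col_double(),
                              depth_ler = readr::col_double()
                            ))
  has_columns(depths, c("recombinant_id", "marker_id", "depth_col", "depth_ler"),
              "allele-depth table")
  depths
}

#' Write an allele-depth table
#'
#' @param depths Long-format depth tibble.
#' @inheritParams read_allele_depths
#' @return `path`, invisibly.
#' @export
write_allele_depths <- function(depths, path) {
  readr::write_tsv(depths[, c("recombinant_id", "marker_id",
                              "depth_col", "depth_ler")], path)
  invisible(path)
}

#' Write / read crossover calls as BED-like TSV
#'
#' One row per recombinant with columns `chrom`, `start`, `end`
#' (0-based half-open: `start = left_pos`, `end = right_pos`, i.e. the
#' 1-based closed interval `[left_pos + 1, right_pos]` between the
#' flanking markers), `recombinant_id`, `orientation`, `status`,
#' `midpoint`.  Non-OK recombinants are retained with `.` in the
#' interval fields so that QC outcomes survive the round trip.
#'
#' @param result An `xo_map_result` or a calls tibble.
#' @param path Output path.
#' @param chrom Chromosome name; defaults to the map's when `result`
#'   is an `xo_map_result`.
#' @return `path` invisibly; `read_crossover_bed()` returns a calls
#'   tibble.
#' @export
write_crossover_bed <- function(result, path, chrom = NULL) {
  calls <- if (inherits(result, "xo_map_result")) result$calls else as_tibble(result)
  if (is.null(chrom)) {
    chrom <- if (inherits(result, "xo_map_result")) {
      attr(result$snps, "chrom")
    } else {
      "chr"
    }
  }
  fmt <- function(x) ifelse(is.na(x), ".", format(x, scientific = FALSE, trim = TRUE))
  lines <- sprintf("%s\t%s\t%s\t%s\t%s\t%s\t%s",
                   chrom, fmt(calls$left_pos), fmt(calls$right_pos),
                   calls$recombinant_id, fmt(calls$orientation),
                   calls$status, fmt(calls$midpoint))
  writeLines(c("#chrom\tstart\tend\trecombinant_id\torientation\tstatus\tmidpoint",
               lines), path)
  invisible(path)
}

#' @rdname write_crossover_bed
#' @export
read_crossover_bed <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("file not found: %s", path))
  raw <- readr::read_tsv(path, comment = "", show_col_types = FALSE,
                         col_names = c("chrom", "start", "end",
                                       "recombinant_id", "orientation",
                                       "status", "midpoint"),
                         col_types = "ccccccc", skip = 1L)
  num <- function(x) suppressWarnings(as.numeric(ifelse(x == ".", NA, x)))
  tibble(
    recombinant_id = raw$recombinant_id,
    status = raw$status,
    orientation = ifelse(raw$orientation == ".", NA_character_, raw$orientation),
    left_pos = num(raw$start),
    right_pos = num(raw$end),
    midpoint = num(raw$midpoint),
    chrom = raw$chrom
  )
}
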