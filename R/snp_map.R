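#' Construct a SNP marker map
#'
#' An ordered set of biallelic Col/Ler markers over a genomic interval:
#' the coordinate system every downstream genotype and breakpoint call
#' refers to.  Positions are 1-based base pairs; the interval `span` is
#' 0-based half-open, BED-style.
#'
#' @param markers Data frame with columns `id`, `pos` (1-based bp,
#'   strictly increasing), `col_allele`, `ler_allele` (single bases,
#'   unequal).
#' @param interval_name Name of the interval (e.g. `"ChP"`).
#' @param chrom Chromosome / contig name.
#' @param span Numeric length-2, 0-based half-open interval limits;
#'   defaults to `c(0, max(pos))`.
#'
#' @return A tibble of markers with class `snp_map` and attributes
#'   `interval_name`, `chrom`, `span`.
#' @export
snp_map <- function(markers, interval_name = "interval", chrom = "chr",
                    span = NULL) {
  markers <- as_tibble(markers)
  has_columns(markers, c("id", "pos", "col_allele", "ler_allele"), "marker table")
  markers <- markers[, c("id", "pos", "col_allele", "ler_allele")]
  markers$pos <- as.numeric(markers$pos)
  if (is.null(span)) span <- c(0, if (nrow(markers)) max(markers$pos) else 1)
  span <- as.numeric(span)
  if (length(span) != 2L || span[1] >= span[2]) {
    abort_input("`span` must be c(start, end) with start < end")
  }
  if (nrow(markers) > 0L) {
    if (is.unsorted(markers$pos, strictly = TRUE)) {
      abort_input("marker positions must be strictly increasing")
    }
    if (any(markers$pos <= span[1] | markers$pos > span[2])) {
      abort_input("marker positions must lie within the interval span")
    }
    bases <- c("A", "C", "G", "T")
    if (!all(markers$col_allele %in% bases) ||
        !all(markers$ler_allele %in% bases)) {
      abort_input("alleles must be single bases in {A, C, G, T}")
    }
    if (any(markers$col_allele == markers$ler_allele)) {
      abort_input("markers must be biallelic (col_allele != ler_allele)")
    }
    if (anyDuplicated(markers$id)) abort_input("marker ids must be unique")
  }
  structure(markers,
            interval_name = as.character(interval_name),
            chrom = as.character(chrom),
            span = span,
            class = c("snp_map", class(markers)))
}

#' @export
print.snp_map <- function(x, ...) {
  cat(sprintf("<snp_map> %s (%s:%g-%g), %d markers\n",
              attr(x, "interval_name"), attr(x, "chrom"),
              attr(x, "span")[1], attr(x, "span")[2], nrow(x)))
  NextMethod()
}

#' Filter candidate markers into a high-fidelity SNP map
#'
#' Builds a curated marker list from candidate sites scored against
#' homozygous parental controls: a site is kept when it is biallelic
#' and its observed allele agrees with the declared parental allele in
#' at least `min_support` of control observations.  Sites without
#' control observations are dropped.
#'
#' @param candidates Data frame sorted by position with columns `id`,
#'   `pos`, `col_allele`, `ler_allele`, `n_concordant` (control
#'   observations matching the declared allele), `n_control` (total
#'   control observations).
#' @param min_support Minimum concordance fraction (default 0.9).
#' @inheritParams snp_map
#'
#' @return A `snp_map` of the retained sites; an empty result raises a
#'   warning, not an error.
#' @export
filter_snp_candidates <- function(candidates, min_support = 0.9,
                                  interval_name = "interval", chrom = "chr",
                                  span = NULL) {
  candidates <- as_tibble(candidates)
  has_columns(candidates,
              c("id", "pos", "col_allele", "ler_allele",
                "n_concordant", "n_control"),
              "candidate table")
  assert_scalar_number(min_support, "min_support", lower = 0, upper = 1)
  if (is.unsorted(candidates$pos, strictly = TRUE)) {
    abort_input("candidates must be sorted by strictly increasing position")
  }
  keep <- candidates$n_control > 0 &
    candidates$n_concordant / pmax(candidates$n_control, 1) >= min_support &
    candidates$col_allele != candidates$ler_allele
  retained <- candidates[keep, c("id", "pos", "col_allele", "ler_allele")]
  if (nrow(retained) == 0L) {
    warn("no candidate markers passed filtering; returning an empty map")
  }
  snp_map(retained, interval_name = interval_name, chrom = chrom, span = span)
}

# ---- TSV dialect -----------------------------------------------------------

#' Read / write a SNP map as four-column TSV
#'
#' The TSV dialect has columns `id`, `pos`, `col_allele`, `ler_allele`
#' preceded by comment headers carrying the interval name, chromosome
#' and span, so that a write/read cycle reproduces the map exactly.
#'
#' @param snps A `snp_map`.
#' @param path File path.
#' @return `read_snp_map_tsv()` returns a `snp_map`;
#'   `write_snp_map_tsv()` returns `path` invisibly.
#' @export
write_snp_map_tsv <- function(snps, path) {
  stopifnot(inherits(snps, "snp_map"))
  span <- attr(snps, "span")
  header <- c(
    "# xomapr snp_map v1",
    sprintf("# interval_name=%s", attr(snps, "interval_name")),
    sprintf("# chrom=%s", attr(snps, "chrom")),
    sprintf("# span=%s,%s",
            format(span[1], scientific = FALSE),
            format(span[2], scientific = FALSE)),
    paste(c("id", "pos", "col_allele", "ler_allele"), collapse = "\t")
  )
  body <- sprintf("%s\t%s\t%s\t%s", snps$id,
                  format(snps$pos, scientific = FALSE, trim = TRUE),
                  snps$col_allele, snps$ler_allele)
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_snp_map_tsv
#' @export
read_snp_map_tsv <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("file not found: %s", path))
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  get_meta <- function(key) {
    hit <- grep(sprintf("^# %s=", key), meta, value = TRUE)
    if (length(hit) != 1L) abort_input(sprintf("missing '%s' header in %s", key, path))
    sub(sprintf("^# %s=", key), "", hit)
  }
  span <- as.numeric(strsplit(get_meta("span"), ",")[[1]])
  markers <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                             col_types = readr::cols(
                               id = readr::col_character(),
                               pos = readr::col_double(),
                               col_allele = readr::col_character(),
                               ler_allele = readr::col_character()
                             ))
  snp_map(markers, interval_name = get_meta("interval_name"),
          chrom = get_meta("chrom"), span = span)
}

# ---- VCF dialect -----------------------------------------------------------

#' Read / write a SNP map as VCF
#'
#' Markers are stored as biallelic SNP records with the Col allele as
#' REF and the Ler allele as ALT.  The interval name and span travel in
#' `##xomapr_*` meta lines and the chromosome in a `##contig` line, so
#' the map round-trips exactly.  Reading uses the `vcfR` parser and
#' keeps only biallelic single-base records.
#'
#' @inheritParams write_snp_map_tsv
#' @return `read_snp_map_vcf()` returns a `snp_map`;
#'   `write_snp_map_vcf()` returns `path` invisibly.
#' @export
write_snp_map_vcf <- function(snps, path) {
  stopifnot(inherits(snps, "snp_map"))
  span <- attr(snps, "span")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=xomapr",
    sprintf("##contig=<ID=%s,length=%s>", attr(snps, "chrom"),
            format(ceiling(span[2]), scientific = FALSE)),
    sprintf("##xomapr_interval_name=%s", attr(snps, "interval_name")),
    sprintf("##xomapr_span=%s,%s",
            format(span[1], scientific = FALSE),
            format(span[2], scientific = FALSE)),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
          collapse = "\t")
  )
  body <- sprintf("%s\t%s\t%s\t%s\t%s\t.\t.\t.",
                  attr(snps, "chrom"),
                  format(snps$pos, scientific = FALSE, trim = TRUE),
                  snps$id, snps$col_allele, snps$ler_allele)
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_snp_map_vcf
#' @export
read_snp_map_vcf <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("file not found: %s", path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  meta <- vcf@meta
  get_meta <- function(key, default) {
    hit <- grep(sprintf("^##%s=", key), meta, value = TRUE)
    if (length(hit) == 1L) sub(sprintf("^##%s=", key), "", hit) else default
  }
  keep <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L & !grepl(",", fix$ALT)
  fix <- fix[keep, , drop = FALSE]
  chrom <- get_meta("xomapr_chrom", unique(fix$CHROM)[1] %||% "chr")
  contig <- grep("^##contig=", meta, value = TRUE)
  if (length(contig) >= 1L) {
    chrom <- sub('.*ID=([^,>]+).*', "\\1", contig[1])
  }
  span_txt <- get_meta("xomapr_span", NA_character_)
  span <- if (!is.na(span_txt)) as.numeric(strsplit(span_txt, ",")[[1]]) else NULL
  snp_map(
    tibble(id = fix$ID, pos = as.numeric(fix$POS),
           col_allele = fix$REF, ler_allele = fix$ALT),
    interval_name = get_meta("xomapr_interval_name", "interval"),
    chrom = chrom, span = span
  )
}

#' Read a SNP map, dispatching on file extension
#'
#' `.vcf` files go through [read_snp_map_vcf()], anything else through
#' [read_snp_map_tsv()].
#'
#' @inheritParams read_snp_map_tsv
#' @return A `snp_map`.
#' @export
read_snp_map <- function(path) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    read_snp_map_vcf(path)
  } else {
    read_snp_map_tsv(path)
  }
}
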