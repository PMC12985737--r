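# End-to-end orchestration: seed scoring -> map distance; recombinant
# depths -> crossover calls -> landscapes / usage / differential.

pipeline_defaults <- function() {
  list(
    rf = list(n_boot = 2000, level = 0.95),
    map = list(min_depth = 20, het_band = c(0.30, 0.70), hom_max = 0.15,
               min_flank = 2),
    landscape = list(window = 1000, step = 100, interval_cm = NULL,
                     hotspots = NULL, control = NULL,
                     reduction_hotspot = NULL)
  )
}

#' Read and validate a pipeline run configuration
#'
#' YAML configuration with a mandatory top-level `seed` and
#' `out_prefix`, and optional `rf` (`counts` path, `n_boot`, `level`),
#' `map` (`snps`, `depths`, thresholds) and `landscape` (`window`,
#' `step`, `interval_cm`, `hotspots` BED, `control` crossover BED,
#' `reduction_hotspot`) sections.  Unset stage parameters resolve to
#' the package defaults; every stochastic stage derives its own seed
#' from the master seed and the stage name, so a configuration fully
#' determines a run.  Validation fails before any stage runs if the
#' seed is missing, an unknown key is present, or a referenced input
#' file does not exist.  Relative paths resolve against the
#' configuration file's directory.
#'
#' @param path Path to a YAML file.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("config not found: %s", path))
  validate_run_config(yaml::read_yaml(path), dir = dirname(normalizePath(path)))
}

#' @rdname read_run_config
#' @param config A configuration list (as parsed from YAML).
#' @param dir Directory against which relative paths resolve.
#' @export
validate_run_config <- function(config, dir = ".") {
  if (!is.list(config)) abort_input("config must be a mapping")
  known <- c("seed", "out_prefix", "rf", "map", "landscape")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0L) {
    abort_input(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  if (is.null(config$seed)) {
    abort_input("config validation: `seed` is required so that every run is reproducible")
  }
  assert_scalar_number(config$seed, "seed")
  if (is.null(config$out_prefix) || !is.character(config$out_prefix)) {
    abort_input("config validation: `out_prefix` (character) is required")
  }
  resolved <- pipeline_defaults()
  for (stage in c("rf", "map", "landscape")) {
    user <- config[[stage]]
    if (is.null(user)) next
    bad <- setdiff(names(user),
                   c(names(resolved[[stage]]),
                     c("counts", "snps", "depths")))
    if (length(bad) > 0L) {
      abort_input(sprintf("unknown key(s) in `%s`: %s", stage,
                          paste(bad, collapse = ", ")))
    }
    resolved[[stage]] <- modifyList(resolved[[stage]], user, keep.null = TRUE)
  }
  resolve_path <- function(p) {
    if (is.null(p)) return(NULL)
    if (!file.exists(p)) p <- file.path(dir, p)
    if (!file.exists(p)) {
      abort_input(sprintf("config validation: input file not found: %s", p))
    }
    normalizePath(p)
  }
  for (key in c("counts")) resolved$rf[[key]] <- resolve_path(config$rf[[key]])
  for (key in c("snps", "depths")) resolved$map[[key]] <- resolve_path(config$map[[key]])
  for (key in c("hotspots", "control")) {
    resolved$landscape[[key]] <- resolve_path(resolved$landscape[[key]])
  }
  structure(list(
    seed = as.integer(config$seed),
    out_prefix = config$out_prefix,
    rf = resolved$rf, map = resolved$map, landscape = resolved$landscape
  ), class = "run_config", dir = dir)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
          class = "xomapr_pipeline_error", parent = e)
  })
}

#' Run the crossover-analysis pipeline
#'
#' Executes the configured stages in order — map-distance estimation
#' from seed counts, crossover mapping from allele depths, landscape
#' and hotspot summaries — writing each product next to `out_prefix`
#' and finishing with a machine-readable manifest
#' (`<prefix>.manifest.json`) that records the package version, the
#' resolved value of every parameter, the derived per-stage seeds, and
#' an MD5 checksum of every output.  Re-running the same configuration
#' reproduces byte-identical outputs, hence identical checksums.
#'
#' Products (per configured stage): `<prefix>.rf.tsv` (per-cross cM
#' with bootstrap CIs), `<prefix>.xo.bed` (crossover calls),
#' `<prefix>.distribution.bedGraph` and `<prefix>.cm_per_mb.bedGraph`
#' (landscape tracks), `<prefix>.usage.tsv`, and — when a control
#' population is supplied — `<prefix>.diff.bedGraph` and
#' `<prefix>.reduction.tsv`.
#'
#' @param config A `run_config` from [read_run_config()], or a path to
#'   a YAML configuration.
#' @param quiet Suppress progress messages (default `FALSE`).
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  prefix <- config$out_prefix
  out_dir <- dirname(prefix)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  outputs <- character()
  manifest <- list(
    package = "xomapr",
    version = as.character(utils::packageVersion("xomapr")),
    seed = config$seed,
    stage_seeds = list(),
    parameters = list(rf = config$rf, map = config$map,
                      landscape = config$landscape),
    outputs = list()
  )
  interval_cm <- config$landscape$interval_cm
  chrom <- "chr"

  if (!is.null(config$rf$counts)) {
    say("stage rf: estimating map distance")
    rf_seed <- stage_seed(config$seed, "rf_bootstrap")
    manifest$stage_seeds$rf_bootstrap <- rf_seed
    rf_tab <- run_stage("rf", {
      counts <- read_seed_counts(config$rf$counts)
      rf_bootstrap_ci(counts, n_boot = config$rf$n_boot,
                      level = config$rf$level, seed = rf_seed)
    })
    path <- paste0(prefix, ".rf.tsv")
    readr::write_tsv(rf_tab, path)
    outputs <- c(outputs, path)
    if (is.null(interval_cm)) {
      interval_cm <- summarize_rf(rf_tab[, c("cross_id", "n_green", "n_red",
                                             "n_total")])$summary$pooled_cm
    }
  }

  result <- NULL
  if (!is.null(config$map$snps) && !is.null(config$map$depths)) {
    say("stage map: calling crossover breakpoints")
    result <- run_stage("map", {
      snps <- read_snp_map(config$map$snps)
      depths <- read_allele_depths(config$map$depths)
      map_population(depths, snps,
                     min_depth = config$map$min_depth,
                     het_band = config$map$het_band,
                     hom_max = config$map$hom_max,
                     min_flank = config$map$min_flank)
    })
    chrom <- attr(result$snps, "chrom")
    path <- paste0(prefix, ".xo.bed")
    write_crossover_bed(result, path)
    outputs <- c(outputs, path)
    say("stage map: %d/%d recombinants OK", result$tally[["OK"]],
        sum(result$tally))
  }

  if (!is.null(result)) {
    say("stage landscape: building tracks")
    ls_cfg <- config$landscape
    run_stage("landscape", {
      dist <- build_distribution(result, result$snps)
      path <- paste0(prefix, ".distribution.bedGraph")
      write_track_bedgraph(dist, path, chrom = chrom)
      outputs <- c(outputs, path)
      if (!is.null(interval_cm)) {
        cmmb <- moving_average_cm_per_mb(result, interval_cm,
                                         window = ls_cfg$window,
                                         step = ls_cfg$step)
        path <- paste0(prefix, ".cm_per_mb.bedGraph")
        write_track_bedgraph(cmmb, path, chrom = chrom)
        outputs <- c(outputs, path)
      }
      if (!is.null(ls_cfg$hotspots)) {
        hotspots <- read_hotspots_bed(ls_cfg$hotspots)
        usage <- hotspot_usage(result, hotspots)
        path <- paste0(prefix, ".usage.tsv")
        write_summary_tsv(usage, path)
        outputs <- c(outputs, path)
        if (!is.null(ls_cfg$control)) {
          control_calls <- read_crossover_bed(ls_cfg$control)
          ctrl_dist <- build_distribution(control_calls, result$snps)
          diff <- differential_track(dist, ctrl_dist)
          path <- paste0(prefix, ".diff.bedGraph")
          write_track_bedgraph(diff, path, chrom = chrom)
          outputs <- c(outputs, path)
          ctrl_usage <- hotspot_usage(control_calls, hotspots)
          reduce_names <- ls_cfg$reduction_hotspot %||% hotspots$name
          reduction <- tibble(
            hotspot = reduce_names,
            reduction_pct = vapply(reduce_names, function(h) {
              hotspot_reduction(usage, ctrl_usage, h)
            }, numeric(1))
          )
          path <- paste0(prefix, ".reduction.tsv")
          write_summary_tsv(reduction, path)
          outputs <- c(outputs, path)
        }
      }
    })
  }

  manifest$parameters$landscape$interval_cm <- interval_cm
  manifest$outputs <- lapply(setNames(outputs, basename(outputs)), function(p) {
    list(path = p, md5 = unname(tools::md5sum(p)))
  })
  manifest_path <- paste0(prefix, ".manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  say("pipeline complete: %d outputs in %.1f s", length(outputs),
      as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(manifest)
}
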