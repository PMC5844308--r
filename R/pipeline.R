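# End-to-end orchestration: simulate or load inputs, then run
# call -> partition -> enrichment -> distance -> chromosome scan ->
# divergence as configured, writing one TSV per stage plus a JSON
# manifest.

#' Run the full dispersion analysis pipeline
#'
#' The configuration is a named list (or a YAML file path) with either a
#' `simulation` block (arguments to [sim_config()]) or an `inputs` block
#' naming files (`chrom_sizes`, `gaps`, `gff3`, `elements` or
#' `hits` + `consensus_lengths`, optional `excluded` scaffold names,
#' optional `alignment` FASTA). Optional top-level settings:
#' `enrichment_reps` (default 1000), `distance_reps` (default 100),
#' `seed` (default 1), `bin_scheme` (`"tenths"`), stage toggles
#' `run_enrichment`, `run_distance`, `run_chromoscan`, `run_divergence`
#' (all `TRUE`).
#'
#' @param config Named list or path to a YAML file.
#' @param outdir Output directory (created if missing).
#' @param force Overwrite existing stage outputs (otherwise an error).
#' @param quiet Suppress progress messages.
#' @return Invisibly, the manifest list (also written to
#'   `manifest.json`): inputs, seed, package version, files written with
#'   row counts.
#' @export
run_pipeline <- function(config, outdir, force = FALSE, quiet = FALSE) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$simulation) && is.null(config$inputs)) {
    abort("config must contain a `simulation` or an `inputs` block")
  }
  if (!is.null(config$inputs)) {
    for (need in c("chrom_sizes", "gff3")) {
      if (is.null(config$inputs[[need]])) {
        abort(sprintf("config$inputs$%s is required", need))
      }
    }
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  say <- function(...) if (!quiet) inform(sprintf(...))
  files <- list()
  emit <- function(obj, name) {
    path <- file.path(outdir, name)
    if (file.exists(path) && !force) {
      abort(sprintf("%s exists; use force = TRUE to overwrite", path))
    }
    readr::write_tsv(as_tibble(obj), path, progress = FALSE)
    files[[name]] <<- nrow(as_tibble(obj))
    path
  }

  truth <- NULL
  if (!is.null(config$simulation)) {
    say("stage simulate")
    cfg <- do.call(sim_config, c(config$simulation, list(seed = seed)))
    genome <- sim_genome(cfg)
    annotation <- sim_annotation(cfg, genome)
    placed <- sim_repeats(cfg, genome, annotation)
    elements <- placed$elements
    truth <- placed$truth
    emit(truth, "truth.tsv")
  } else {
    inp <- config$inputs
    genome <- read_genome(inp$chrom_sizes, inp$gaps,
                          excluded = inp$excluded %||% character())
    annotation <- read_annotation(inp$gff3, genome)
    if (!is.null(inp$elements)) {
      elements <- read_elements_bed(inp$elements, genome)
    } else if (!is.null(inp$hits)) {
      say("stage call")
      lens <- readr::read_tsv(inp$consensus_lengths,
                              col_names = c("family", "length"),
                              col_types = "cd", progress = FALSE)
      hits <- read_hits(inp$hits, lens)
      hits <- filter_hits(hits)
      elements <- merge_hits_to_elements(hits, lens)
    } else {
      abort("config$inputs needs `elements` or `hits` + `consensus_lengths`")
    }
  }

  say("stage partition")
  partition <- build_partition(genome, annotation)
  elements <- categorize_elements(elements, partition)
  emit(elements, "elements.tsv")
  emit(summarize_partition(elements), "partition_summary.tsv")
  emit(multimer_census(elements), "multimer_census.tsv")

  if (config$run_enrichment %||% TRUE) {
    say("stage enrich")
    reps <- config$enrichment_reps %||% 1000
    enr <- enrichment_test(elements, partition, genome, annotation,
                           n_reps = reps, seed = seed)
    emit(tidy(enr), "enrichment.tsv")
  }
  if (config$run_distance %||% TRUE) {
    say("stage distance")
    reps <- config$distance_reps %||% 100
    intergenic <- elements[elements$category == "intergenic", , drop = FALSE]
    if (nrow(intergenic) > 0 && nrow(annotation$genes) > 0) {
      dp <- distance_null(intergenic, genome, annotation,
                          n_reps = reps, seed = seed)
      emit(glance(dp), "distance_test.tsv")
      emit(distance_density(dp), "distance_density.tsv")
    }
  }
  if (config$run_chromoscan %||% TRUE) {
    say("stage chromoscan")
    ct <- count_table(elements, annotation, genome)
    emit(ct, "count_table.tsv")
    if (nrow(ct) >= 3) {
      emit(regression_suite(ct), "regressions.tsv")
    } else {
      say("skipping regressions: fewer than 3 chromosomes")
    }
    scheme <- config$bin_scheme %||% "tenths"
    prof <- bin_profile(elements, genome, scheme = scheme)
    emit(prof, "bin_profiles.tsv")
    if (length(unique(elements$family)) >= 2) {
      emit(colocalization(prof), "colocalization.tsv")
    }
  }
  if ((config$run_divergence %||% TRUE) &&
      !is.null(config$inputs$alignment)) {
    say("stage diverge")
    block <- read_alignment(config$inputs$alignment)
    emit(tibble(n_rows = nrow(block),
                mean_divergence_pct = mean_pairwise_divergence(block)),
         "divergence.tsv")
  }

  manifest <- list(
    package = "disperscan",
    version = as.character(utils::packageVersion("disperscan")),
    seed = seed,
    config = config,
    files = files
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  say("pipeline complete: %d file(s) in %s", length(files) + 1L, outdir)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Log-distance density table for plotting distance profiles
#'
#' Kernel densities of `log10(distance + 1)` for the observed and pooled
#' null distances of a [distance_null()] result, evaluated on a common
#' grid — the table behind the classic observed-vs-null distance density
#' figure. Statistics always use raw distances; the transform is for the
#' plotting axis only.
#'
#' @param profile A `distance_profile`.
#' @param n_grid Grid size.
#' @return Tibble: `log10_distance`, `source`, `density`.
#' @export
distance_density <- function(profile, n_grid = 256) {
  lo <- log10(profile$observed + 1)
  ln <- log10(profile$null + 1)
  rng <- range(c(lo, ln))
  dob <- density(lo, from = rng[1], to = rng[2], n = n_grid)
  dnu <- density(ln, from = rng[1], to = rng[2], n = n_grid)
  bind_rows(
    tibble(log10_distance = dob$x, source = "observed", density = dob$y),
    tibble(log10_distance = dnu$x, source = "null", density = dnu$y)
  )
}
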