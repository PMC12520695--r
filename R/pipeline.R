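#' Read and validate a pipeline run configuration
#'
#' A run is described by a single YAML document validated up front, before
#' any work happens. Top-level keys:
#'
#' * `seed` (required): integer seed for every stochastic stage.
#' * `out_dir` (required): output directory.
#' * `simulate`: optional; `scenario: invivo|sortscreen` (plus optional
#'   overrides `n_genes`, `n_mice`) to generate library, counts and sample
#'   sheet in `out_dir`.
#' * `library`, `counts`, `samples`: input paths (required unless
#'   `simulate` provides them).
#' * `invivo`: optional; `min_lung_reads`, `pseudocount`, and a `triage`
#'   block (`interactome` path plus `top_n` or `min_fc`).
#' * `sortscreen`: optional; `alpha`, `n_permutations`, `direction`.
#'
#' @param path Path to the YAML config.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A configuration list (as parsed from YAML).
#' @export
validate_run_config <- function(cfg) {
  if (!is.list(cfg)) stop_config("config must be a mapping")
  for (key in c("seed", "out_dir")) {
    if (is.null(cfg[[key]])) stop_config("config is missing required key: ", key)
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L) {
    stop_config("seed must be a single integer")
  }
  if (is.null(cfg$simulate)) {
    for (key in c("library", "counts", "samples")) {
      if (is.null(cfg[[key]])) {
        stop_config("config needs `", key, "` (or a `simulate` block)")
      }
      if (!file.exists(cfg[[key]])) {
        stop_config("input file not found: ", cfg[[key]])
      }
    }
  } else if (!isTRUE(cfg$simulate$scenario %in% c("invivo", "sortscreen"))) {
    stop_config("simulate$scenario must be 'invivo' or 'sortscreen'")
  }
  if (!is.null(cfg$invivo$triage)) {
    tri <- cfg$invivo$triage
    if (is.null(tri$interactome)) stop_config("triage needs an interactome path")
    if (is.null(cfg$simulate) && !file.exists(tri$interactome)) {
      stop_config("interactome file not found: ", tri$interactome)
    }
    if (is.null(tri$top_n) == is.null(tri$min_fc)) {
      stop_config("triage needs exactly one of top_n or min_fc")
    }
  }
  structure(cfg, class = "run_config")
}

#' Run the configured pipeline stages
#'
#' Executes the stages implied by the configuration in dependency order:
#' simulate (or load) library/counts/samples, then the in vivo enrichment
#' ranking and triage if configured, then the sorting-screen RRA if
#' configured. Every output table gets a JSON provenance sidecar
#' (`<file>.provenance.json`) recording the package version, the full
#' configuration and the seed, so any table can be regenerated from its
#' sidecar alone. Log lines go to standard error; results never do.
#'
#' @param config A `run_config` (from [read_run_config()]) or a path to a
#'   YAML config.
#' @return Invisibly, a named character vector of produced files.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) config <- validate_run_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  produced <- character(0)
  log <- function(stage, ...) {
    message("[", stage, "] ", ...)
  }

  if (!is.null(config$simulate)) {
    log("simulate", "generating scenario '", config$simulate$scenario, "'")
    sim <- simulate_scenario(config$simulate, seed)
    manifest <- sim$manifest; counts <- sim$counts; sheet <- sim$sheet
    produced["library"] <- write_library_manifest(manifest, file.path(out_dir, "library.tsv"))
    produced["counts"] <- write_count_table(counts, file.path(out_dir, "counts.tsv"))
    produced["samples"] <- write_sample_sheet(sheet, file.path(out_dir, "samples.tsv"))
  } else {
    log("load", "reading inputs")
    manifest <- read_library_manifest(config$library)
    sheet <- read_sample_sheet(config$samples)
    counts <- read_count_table(config$counts, manifest, sheet)
  }

  if (!is.null(config$invivo) || any(sheet$role == "lung")) {
    iv <- config$invivo %||% list()
    icfg <- invivo_config(min_lung_reads = iv$min_lung_reads %||% 50L,
                          pseudocount = iv$pseudocount %||% 0.5)
    log("invivo", "ranking ", nrow(manifest), " guides over ",
        sum(sheet$role == "lung"), " lung sample(s)")
    res <- invivo_rank(counts, manifest, sheet, icfg)
    path <- file.path(out_dir, "ranking.tsv")
    utils::write.table(res$ranking, path, sep = "\t", quote = FALSE, row.names = FALSE)
    produced["ranking"] <- path
    dropped <- data.frame(guide_id = res$dropped, stringsAsFactors = FALSE)
    dpath <- file.path(out_dir, "dropped_guides.tsv")
    utils::write.table(dropped, dpath, sep = "\t", quote = FALSE, row.names = FALSE)
    produced["dropped"] <- dpath
    if (!is.null(iv$triage)) {
      log("triage", "intersecting with ", iv$triage$interactome)
      interactome <- read_protein_list(iv$triage$interactome)
      enriched <- select_enriched(res$ranking, top_n = iv$triage$top_n,
                                  min_avg_fold_change = iv$triage$min_fc)
      tri <- intersect_sets(enriched, interactome)
      tpath <- file.path(out_dir, "triage.json")
      jsonlite::write_json(
        list(overlap_genes = tri$overlap_genes,
             venn_counts = as.list(tri$venn_counts),
             n_union = tri$n_union, parameters = tri$parameters),
        tpath, auto_unbox = TRUE, pretty = TRUE, null = "null")
      produced["triage"] <- tpath
    }
  }

  if (!is.null(config$sortscreen) || all(c("sorted_high", "sorted_low") %in% sheet$role)) {
    ss <- config$sortscreen %||% list()
    scfg <- sortscreen_config(alpha = ss$alpha %||% 0.25,
                              n_permutations = ss$n_permutations %||% 10000L,
                              direction = ss$direction %||% "low",
                              seed = seed)
    log("sortscreen", "alpha-RRA at alpha=", scfg$alpha,
        ", ", scfg$n_permutations, " permutations")
    res <- sortscreen_rra(counts, manifest, sheet, scfg)
    path <- file.path(out_dir, "rra.tsv")
    utils::write.table(res$rra, path, sep = "\t", quote = FALSE, row.names = FALSE)
    produced["rra"] <- path
  }

  prov <- list(tool = "screenrank",
               version = as.character(utils::packageVersion("screenrank")),
               seed = seed,
               config = unclass(config))
  for (f in produced) {
    jsonlite::write_json(c(prov, list(file = basename(f))),
                         paste0(f, ".provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
  }
  log("done", length(produced), " output file(s) in ", out_dir)
  invisible(produced)
}

# Build a scenario dataset for run_pipeline's simulate block.
simulate_scenario <- function(sim, seed) {
  if (sim$scenario == "invivo") {
    sc <- invivo_scenario(seed = seed)
    if (!is.null(sim$n_genes)) sc$manifest_args$n_genes <- as.integer(sim$n_genes)
    if (!is.null(sim$n_mice)) sc$config$n_mice <- as.integer(sim$n_mice)
    manifest <- do.call(generate_library, sc$manifest_args)
    out <- simulate_invivo_screen(manifest, sc$config)
    list(manifest = manifest, counts = out$counts, sheet = out$sheet)
  } else {
    sc <- sortscreen_scenario(seed = seed)
    if (!is.null(sim$n_genes)) sc$manifest_args$n_genes <- as.integer(sim$n_genes)
    manifest <- do.call(generate_library, sc$manifest_args)
    out <- simulate_sorted_gates(manifest, sc$config)
    list(manifest = manifest, counts = out$counts, sheet = out$sheet)
  }
}
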