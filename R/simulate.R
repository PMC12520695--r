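#' Generate a synthetic sgRNA library manifest
#'
#' Synthetic gene symbols `GENE000001...` with `guides_per_gene` guides
#' each and random, distinct 20-nt protospacers. Deterministic for a given
#' seed. The default design mirrors a genome-wide activation library:
#' 23,430 genes x 3 guides = 70,290 sgRNAs.
#'
#' @param n_genes Number of genes (default 23430).
#' @param guides_per_gene Guides per gene (default 3).
#' @param seed RNG seed.
#' @return A manifest `data.frame` (`guide_id`, `gene`, `protospacer`).
#' @export
generate_library <- function(n_genes = 23430L, guides_per_gene = 3L, seed = 1L) {
  if (n_genes < 1 || guides_per_gene < 1) {
    stop_config("n_genes and guides_per_gene must be >= 1")
  }
  n <- as.integer(n_genes) * as.integer(guides_per_gene)
  with_seed(seed, {
    proto <- random_kmers(n, 20L)
    manifest <- data.frame(
      guide_id = sprintf("GENE%06d_sg%d", rep(seq_len(n_genes), each = guides_per_gene),
                         rep(seq_len(guides_per_gene), n_genes)),
      gene = sprintf("GENE%06d", rep(seq_len(n_genes), each = guides_per_gene)),
      protospacer = proto,
      stringsAsFactors = FALSE
    )
    validate_manifest(manifest)
    manifest
  })
}

# n distinct random k-mers over ACGT; redraw collisions.
random_kmers <- function(n, k) {
  draw <- function(m) {
    chars <- matrix(sample(c("A", "C", "G", "T"), m * k, replace = TRUE), m, k)
    do.call(paste0, as.data.frame(chars, stringsAsFactors = FALSE))
  }
  out <- draw(n)
  for (i in 1:50) {
    dup <- duplicated(out)
    if (!any(dup)) return(out)
    out[dup] <- draw(sum(dup))
  }
  stop_validation("could not generate distinct protospacers (sequence space exhausted)")
}

#' In vivo screen simulation configuration
#'
#' The generator emulates the statistical structure of an in vivo
#' metastasis screen: an overdispersed input library (log-normal per-guide
#' skew) sequenced by multinomial sampling; per-mouse lung colonization as
#' a severe clonal bottleneck (a few hundred founder clones drawn with
#' probability proportional to input abundance times a per-gene seeding
#' weight), independent log-normal clonal expansion, and multinomial
#' sequencing of the resulting lung library. Driver genes carry seeding
#' weight > 1.
#'
#' @param input_coverage_cells_per_guide Library representation of the
#'   baseline (default 500 cells/sgRNA).
#' @param input_depth_reads Sequencing depth of the input baseline;
#'   defaults to one read per cell
#'   (`input_coverage_cells_per_guide * n_guides`).
#' @param abundance_dispersion Log-normal sigma of per-guide library skew
#'   (default 0.5).
#' @param n_mice Number of transplanted mice (default 18).
#' @param metastasis_penetrance Probability a mouse develops lung
#'   metastasis (default 0.5, i.e. 9 of 18 expected).
#' @param clones_per_mouse Founder clones seeding each metastatic lung
#'   (default 200).
#' @param driver_genes Named numeric vector: seeding weight (> 1) per
#'   driver gene symbol; empty for a null screen.
#' @param expansion_noise_sigma Log-normal sigma of per-clone expansion
#'   (default 0.5).
#' @param lung_depth_reads Sequencing depth per lung sample (default 1e6).
#' @param seed RNG seed.
#' @return An `invivo_sim_config` list.
#' @export
invivo_sim_config <- function(input_coverage_cells_per_guide = 500L,
                              input_depth_reads = NULL,
                              abundance_dispersion = 0.5,
                              n_mice = 18L,
                              metastasis_penetrance = 0.5,
                              clones_per_mouse = 200L,
                              driver_genes = numeric(0),
                              expansion_noise_sigma = 0.5,
                              lung_depth_reads = 1e6,
                              seed = 1L) {
  if (metastasis_penetrance < 0 || metastasis_penetrance > 1) {
    stop_config("metastasis_penetrance must be in [0, 1]")
  }
  if (clones_per_mouse < 1) stop_config("clones_per_mouse must be >= 1")
  if (length(driver_genes) && (is.null(names(driver_genes)) || any(driver_genes <= 0))) {
    stop_config("driver_genes must be a named vector of positive weights")
  }
  structure(list(input_coverage_cells_per_guide = as.integer(input_coverage_cells_per_guide),
                 input_depth_reads = input_depth_reads,
                 abundance_dispersion = abundance_dispersion,
                 n_mice = as.integer(n_mice),
                 metastasis_penetrance = metastasis_penetrance,
                 clones_per_mouse = as.integer(clones_per_mouse),
                 driver_genes = driver_genes,
                 expansion_noise_sigma = expansion_noise_sigma,
                 lung_depth_reads = lung_depth_reads,
                 seed = as.integer(seed)),
            class = "invivo_sim_config")
}

#' Simulate the input baseline counts
#'
#' Per-guide abundance is log-normal(0, `abundance_dispersion`); reads are
#' a multinomial draw of `input_depth_reads` over those abundances, so the
#' column sum equals the configured depth exactly.
#'
#' @param manifest Library manifest.
#' @param config An [invivo_sim_config()].
#' @param sample_id Sample name for the column (default `"input"`).
#' @return List: `counts` (one-column integer matrix) and `abundance`
#'   (the latent per-guide abundances, needed by the lung simulator).
#' @export
simulate_input_counts <- function(manifest, config = invivo_sim_config(),
                                  sample_id = "input") {
  validate_manifest(manifest)
  n <- nrow(manifest)
  depth <- config$input_depth_reads %||%
    (config$input_coverage_cells_per_guide * n)
  with_seed(config$seed, {
    abundance <- if (config$abundance_dispersion > 0) {
      stats::rlnorm(n, 0, config$abundance_dispersion)
    } else rep(1, n)
    counts <- matrix(as.integer(stats::rmultinom(1, depth, abundance)),
                     ncol = 1, dimnames = list(manifest$guide_id, sample_id))
    list(counts = counts, abundance = abundance)
  })
}

#' Simulate bottlenecked lung-metastasis counts
#'
#' Each mouse develops metastasis with probability
#' `metastasis_penetrance`. A metastatic lung is founded by
#' `clones_per_mouse` clones drawn multinomially with probability
#' proportional to `abundance x driver weight`; each founded guide's final
#' mass is the sum of its founder clones' log-normal expansion factors;
#' lung reads are a multinomial draw of `lung_depth_reads` over those
#' masses. This produces the sparse, jackpotted lung libraries
#' characteristic of severe in vivo bottlenecks.
#'
#' @param abundance Latent per-guide input abundances (from
#'   [simulate_input_counts()]).
#' @param manifest Library manifest.
#' @param config An [invivo_sim_config()]. The RNG stream is offset from
#'   `config$seed` so that input and lung simulations are independent.
#' @return List: `counts` (guides x metastatic mice integer matrix; zero
#'   columns if no mouse seeds, with a warning), `sheet` (lung rows of a
#'   sample sheet), `metastatic` (logical per transplanted mouse).
#' @export
simulate_lung_metastasis <- function(abundance, manifest,
                                     config = invivo_sim_config()) {
  validate_manifest(manifest)
  n <- nrow(manifest)
  stopifnot(length(abundance) == n, all(abundance >= 0), sum(abundance) > 0)
  weight <- rep(1, n)
  if (length(config$driver_genes)) {
    hit <- match(manifest$gene, toupper(names(config$driver_genes)))
    weight[!is.na(hit)] <- config$driver_genes[hit[!is.na(hit)]]
  }
  seed_prob <- abundance * weight
  with_seed(config$seed + 1L, {
    metastatic <- stats::runif(config$n_mice) < config$metastasis_penetrance
    mice <- sprintf("mouse%02d", which(metastatic))
    counts <- matrix(0L, n, length(mice))
    dimnames(counts) <- list(manifest$guide_id,
                             if (length(mice)) paste0("lung_", mice) else NULL)
    for (j in seq_along(mice)) {
      founders <- as.vector(stats::rmultinom(1, config$clones_per_mouse, seed_prob))
      mass <- numeric(n)
      idx <- which(founders > 0)
      if (config$expansion_noise_sigma > 0) {
        for (i in idx) {
          mass[i] <- sum(stats::rlnorm(founders[i], 0, config$expansion_noise_sigma))
        }
      } else {
        mass[idx] <- founders[idx]
      }
      counts[, j] <- as.integer(stats::rmultinom(1, config$lung_depth_reads, mass))
    }
    if (!length(mice)) {
      warning("no metastatic mice drawn; returning empty lung set", call. = FALSE)
    }
    sheet <- data.frame(sample_id = colnames(counts) %||% character(0),
                        role = rep("lung", length(mice)),
                        mouse_id = mice, stringsAsFactors = FALSE)
    list(counts = counts, sheet = sheet, metastatic = metastatic)
  })
}

#' Simulate null lung columns by resampling the input distribution
#'
#' Sequencing-only null: each lung column is a multinomial draw from the
#' input abundance at the given depth, with no bottleneck and no driver
#' effects. Under this null the in vivo ranking's average fold changes
#' center at 1, which is the calibration check for the enrichment
#' statistic.
#'
#' @param abundance Latent per-guide input abundances.
#' @param manifest Library manifest.
#' @param n_mice Number of lung columns.
#' @param depth_reads Reads per lung column.
#' @param seed RNG seed.
#' @return List: `counts` (guides x mice) and `sheet` (lung sample rows).
#' @export
simulate_null_lungs <- function(abundance, manifest, n_mice = 8L,
                                depth_reads = 2e5, seed = 1L) {
  validate_manifest(manifest)
  n <- nrow(manifest)
  stopifnot(length(abundance) == n)
  with_seed(seed, {
    mice <- sprintf("mouse%02d", seq_len(n_mice))
    counts <- matrix(0L, n, n_mice,
                     dimnames = list(manifest$guide_id, paste0("lung_", mice)))
    for (j in seq_len(n_mice)) {
      counts[, j] <- as.integer(stats::rmultinom(1, depth_reads, abundance))
    }
    sheet <- data.frame(sample_id = colnames(counts), role = "lung",
                        mouse_id = mice, stringsAsFactors = FALSE)
    list(counts = counts, sheet = sheet)
  })
}

#' Simulate a full in vivo screen (input + lungs + sample sheet)
#'
#' Convenience wrapper combining [simulate_input_counts()] and
#' [simulate_lung_metastasis()] into a single count matrix and sample
#' sheet ready for [invivo_rank()].
#'
#' @param manifest Library manifest.
#' @param config An [invivo_sim_config()].
#' @return List: `counts`, `sheet`, `abundance`, `metastatic`.
#' @export
simulate_invivo_screen <- function(manifest, config = invivo_sim_config()) {
  input <- simulate_input_counts(manifest, config)
  lungs <- simulate_lung_metastasis(input$abundance, manifest, config)
  counts <- cbind(input$counts, lungs$counts)
  sheet <- rbind(
    data.frame(sample_id = colnames(input$counts), role = "input",
               mouse_id = NA_character_, stringsAsFactors = FALSE),
    lungs$sheet
  )
  list(counts = counts, sheet = sheet, abundance = input$abundance,
       metastatic = lungs$metastatic)
}

#' Scaled in vivo screen scenario
#'
#' The desk-scale default study condition exercised by the test suite:
#' 500 genes x 3 guides, 8 transplanted mice at full penetrance,
#' 200 founder clones per lung, 5 driver genes at seeding weight 20, and
#' 1e6 reads per sample. A full-scale variant (23,430 genes, 18 mice,
#' penetrance 0.5) is available via `scale = "full"` but is not exercised
#' by the tests.
#'
#' @param scale `"scaled"` (default) or `"full"`.
#' @param seed RNG seed.
#' @return List: `manifest_args` (for [generate_library()]), `config`
#'   (an [invivo_sim_config()]), `driver_genes` (symbols).
#' @export
invivo_scenario <- function(scale = c("scaled", "full"), seed = 1L) {
  scale <- match.arg(scale)
  if (scale == "scaled") {
    n_genes <- 500L; n_mice <- 8L; penetrance <- 1
  } else {
    n_genes <- 23430L; n_mice <- 18L; penetrance <- 0.5
  }
  drivers <- sprintf("GENE%06d", seq_len(5L))
  list(manifest_args = list(n_genes = n_genes, guides_per_gene = 3L, seed = seed),
       config = invivo_sim_config(n_mice = n_mice,
                                  metastasis_penetrance = penetrance,
                                  driver_genes = stats::setNames(rep(20, 5), drivers),
                                  seed = seed),
       driver_genes = drivers)
}

#' Sorted-gate screen simulation configuration
#'
#' Emulates a two-gate reporter-stability sort: each cell carries one
#' guide (uniform over the library); its reporter log-ratio is normal
#' around the per-gene effect; the top and bottom `gate_fraction` of cells
#' form the high and low gates; gate reads are multinomial over the gate's
#' cell composition. A negative effect destabilizes the reporter (shifts
#' cells toward the low gate), the signature of losing a stabilizer gene.
#'
#' @param n_cells Cells sorted (default 1e5, a desk-scale stand-in for
#'   the 2e7 cells of a full screen).
#' @param gate_fraction_high,gate_fraction_low Gate fractions in
#'   (0, 0.5] (default 0.05 each).
#' @param baseline_log_ratio_sigma Cell-to-cell reporter noise SD
#'   (default 1).
#' @param effect_genes Named numeric vector: log-ratio shift per gene for
#'   cells carrying that gene's guides (negative = destabilized).
#' @param reads_per_gate Sequencing depth per gate (default 1e6).
#' @param seed RNG seed.
#' @return A `sort_sim_config` list.
#' @export
sort_sim_config <- function(n_cells = 1e5, gate_fraction_high = 0.05,
                            gate_fraction_low = 0.05,
                            baseline_log_ratio_sigma = 1,
                            effect_genes = numeric(0),
                            reads_per_gate = 1e6, seed = 1L) {
  for (f in c(gate_fraction_high, gate_fraction_low)) {
    if (!(f > 0 && f <= 0.5)) stop_config("gate fractions must be in (0, 0.5]")
  }
  if (length(effect_genes) && is.null(names(effect_genes))) {
    stop_config("effect_genes must be named by gene symbol")
  }
  structure(list(n_cells = as.integer(n_cells),
                 gate_fraction_high = gate_fraction_high,
                 gate_fraction_low = gate_fraction_low,
                 baseline_log_ratio_sigma = baseline_log_ratio_sigma,
                 effect_genes = effect_genes,
                 reads_per_gate = reads_per_gate,
                 seed = as.integer(seed)),
            class = "sort_sim_config")
}

#' Simulate sorted-gate counts
#'
#' @param manifest Library manifest.
#' @param config A [sort_sim_config()].
#' @return List: `counts` (guides x `c(sorted_high, sorted_low)` integer
#'   matrix of sequencing reads), `cell_counts` (guides x gates matrix of
#'   sorted cells, the composition the reads are drawn from),
#'   `sheet` (gate sample rows), `gate_cells` (cells per gate,
#'   `floor(fraction * n_cells)` each).
#' @export
simulate_sorted_gates <- function(manifest, config = sort_sim_config()) {
  validate_manifest(manifest)
  n <- nrow(manifest)
  effect <- rep(0, n)
  if (length(config$effect_genes)) {
    hit <- match(manifest$gene, toupper(names(config$effect_genes)))
    effect[!is.na(hit)] <- config$effect_genes[hit[!is.na(hit)]]
  }
  with_seed(config$seed, {
    cell_guide <- sample.int(n, config$n_cells, replace = TRUE)
    log_ratio <- stats::rnorm(config$n_cells, effect[cell_guide],
                              config$baseline_log_ratio_sigma)
    n_hi <- floor(config$gate_fraction_high * config$n_cells)
    n_lo <- floor(config$gate_fraction_low * config$n_cells)
    ord <- order(log_ratio)
    lo_cells <- cell_guide[ord[seq_len(n_lo)]]
    hi_cells <- cell_guide[ord[seq.int(config$n_cells - n_hi + 1L, config$n_cells)]]
    comp_hi <- tabulate(hi_cells, nbins = n)
    comp_lo <- tabulate(lo_cells, nbins = n)
    counts <- cbind(
      sorted_high = as.integer(stats::rmultinom(1, config$reads_per_gate, comp_hi)),
      sorted_low = as.integer(stats::rmultinom(1, config$reads_per_gate, comp_lo))
    )
    rownames(counts) <- manifest$guide_id
    cell_counts <- cbind(sorted_high = comp_hi, sorted_low = comp_lo)
    rownames(cell_counts) <- manifest$guide_id
    sheet <- data.frame(sample_id = c("sorted_high", "sorted_low"),
                        role = c("sorted_high", "sorted_low"),
                        mouse_id = NA_character_, stringsAsFactors = FALSE)
    list(counts = counts, cell_counts = cell_counts, sheet = sheet,
         gate_cells = c(high = n_hi, low = n_lo))
  })
}

#' Scaled sorted-screen scenario
#'
#' Desk-scale default study condition for the reporter-stability screen:
#' a 500-gene x 3-guide kinase-style library, 1e5 sorted cells, 5%/5%
#' gates, and 5 stabilizer genes whose loss shifts the reporter log-ratio
#' by -2 SD.
#'
#' @param seed RNG seed.
#' @return List: `manifest_args`, `config` (a [sort_sim_config()]),
#'   `effect_genes` (symbols).
#' @export
sortscreen_scenario <- function(seed = 1L) {
  genes <- sprintf("GENE%06d", seq_len(5L))
  list(manifest_args = list(n_genes = 500L, guides_per_gene = 3L, seed = seed),
       config = sort_sim_config(effect_genes = stats::setNames(rep(-2, 5), genes),
                                seed = seed),
       effect_genes = genes)
}

#' Emit FASTQ files from a count matrix
#'
#' Writes, per sample, exactly `count` copies of
#' `constant_prefix + protospacer` reads in seeded shuffled order with
#' constant quality, so that [count_guides()] with
#' `quant_config(nchar(constant_prefix))` recovers the matrix exactly.
#' Paths ending in `.gz` are gzip-compressed.
#'
#' @param counts Integer guide-by-sample count matrix.
#' @param manifest Library manifest (rows must match `counts`).
#' @param dir Output directory (created if needed).
#' @param constant_prefix Constant bases prepended to each protospacer
#'   (default `"ACCG"`).
#' @param seed RNG seed for read shuffling.
#' @param gzip Compress output files (default `FALSE`).
#' @return Named character vector of FASTQ paths, one per sample.
#' @export
emit_fastq <- function(counts, manifest, dir, constant_prefix = "ACCG",
                       seed = 1L, gzip = FALSE) {
  assert_count_matrix(counts)
  validate_manifest(manifest)
  if (!identical(rownames(counts), manifest$guide_id)) {
    stop_validation("counts rows must match manifest guide order")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(ncol(counts))
  names(paths) <- colnames(counts)
  with_seed(seed, {
    for (j in seq_len(ncol(counts))) {
      sample_id <- colnames(counts)[j]
      path <- file.path(dir, paste0(sample_id, ".fastq", if (gzip) ".gz" else ""))
      seqs <- rep(paste0(constant_prefix, manifest$protospacer), counts[, j])
      if (length(seqs) > 1L) seqs <- seqs[sample.int(length(seqs))]
      con <- if (gzip) gzfile(path, "wb") else file(path, "wb")
      if (length(seqs)) {
        qual <- strrep("I", nchar(seqs[1]))
        writeLines(paste0("@", sample_id, ":", seq_along(seqs), "\n",
                          seqs, "\n+\n", qual),
                   con, sep = "\n")
      }
      close(con)
      paths[j] <- path
    }
  })
  paths
}
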