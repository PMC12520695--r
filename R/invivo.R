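#' In vivo enrichment ranking configuration
#'
#' Parameters of the lung-metastasis enrichment ranking. Guides with fewer
#' than `min_lung_reads` raw reads in a lung sample are excluded from that
#' mouse's analysis; counts are normalized to `normalization_scale` total
#' reads per sample (reads-per-million by default); fold changes add a
#' symmetric `pseudocount` (in normalized units) to numerator and
#' denominator so guides absent from the input baseline remain finite.
#'
#' `average_over` controls the cross-mouse denominator: `"all"` (default)
#' divides the summed per-mouse fold changes by the number of metastatic
#' mice, so a guide excluded in a mouse contributes nothing there; with
#' `"retained"` the mean runs only over mice in which the guide passed the
#' read floor. The all-mice denominator rewards reproducible enrichment
#' across animals and damps single-mouse clonal jackpots, which dominate a
#' retained-only average under a severe seeding bottleneck (see the
#' methods vignette).
#'
#' @param min_lung_reads Raw-read floor per lung sample (default 50).
#' @param normalization_scale Per-sample total after normalization
#'   (default `1e6`, i.e. reads-per-million).
#' @param pseudocount Symmetric pseudocount in normalized units
#'   (default 0.5).
#' @param averaging `"arithmetic"` (default) or `"geometric"` mean of
#'   per-mouse fold changes. Geometric averaging always runs over retained
#'   mice only (zeros would annihilate the product).
#' @param average_over `"all"` (default) or `"retained"`; see Details.
#' @return An `invivo_config` list.
#' @export
invivo_config <- function(min_lung_reads = 50L, normalization_scale = 1e6,
                          pseudocount = 0.5,
                          averaging = c("arithmetic", "geometric"),
                          average_over = c("all", "retained")) {
  averaging <- match.arg(averaging)
  average_over <- match.arg(average_over)
  if (min_lung_reads < 0) stop_config("min_lung_reads must be >= 0")
  if (normalization_scale <= 0) stop_config("normalization_scale must be positive")
  if (pseudocount < 0) stop_config("pseudocount must be non-negative")
  structure(list(min_lung_reads = as.integer(min_lung_reads),
                 normalization_scale = normalization_scale,
                 pseudocount = pseudocount,
                 averaging = averaging,
                 average_over = average_over),
            class = "invivo_config")
}

#' Low-coverage exclusion mask for lung samples
#'
#' A guide is retained in a lung sample iff its raw read count there is at
#' least `min_lung_reads`; the floor is applied per lung sample (per
#' mouse), matching the per-mouse structure of the fold-change step.
#'
#' @param counts Raw count matrix.
#' @param sheet Sample sheet; must contain at least one `lung` sample.
#' @param config An [invivo_config()].
#' @return Logical matrix (guides x lung samples), `TRUE` where retained.
#' @export
filter_low_coverage <- function(counts, sheet, config = invivo_config()) {
  assert_count_matrix(counts)
  validate_sample_sheet(sheet)
  lung <- sheet$sample_id[sheet$role == "lung"]
  if (!length(lung)) stop_validation("no lung samples in sample sheet")
  missing <- setdiff(lung, colnames(counts))
  if (length(missing)) {
    stop_validation("lung sample(s) missing from counts: ", paste(missing, collapse = ", "))
  }
  counts[, lung, drop = FALSE] >= config$min_lung_reads
}

#' Total-count normalization
#'
#' Scales each sample (column) so its total equals `scale`:
#' `value = raw * scale / column_sum`. Reads-per-million at the default
#' scale of `1e6`.
#'
#' @param counts Raw count matrix.
#' @param scale Positive total per column after normalization.
#' @return Numeric matrix of the same shape; each column sums to `scale`.
#' @export
normalize_total <- function(counts, scale = 1e6) {
  assert_count_matrix(counts)
  if (scale <= 0) stop_config("scale must be positive")
  sums <- colSums(counts)
  zero <- names(sums)[sums == 0]
  if (length(zero)) {
    stop_validation("cannot normalize zero-total sample(s): ", paste(zero, collapse = ", "))
  }
  sweep(counts, 2, sums / scale, "/")
}

#' Per-mouse fold change against the input baseline
#'
#' For every retained (guide, mouse) pair,
#' `fold_change = (lung_norm + pc) / (input_norm + pc)` on normalized
#' abundances; non-retained pairs carry `fold_change = NA`.
#'
#' @param normalized Normalized matrix from [normalize_total()].
#' @param sheet Sample sheet with exactly one `input` and >= 1 `lung`
#'   sample.
#' @param mask Retention mask from [filter_low_coverage()].
#' @param config An [invivo_config()].
#' @return Long `data.frame`: `guide_id`, `mouse_id`, `fold_change`,
#'   `retained`, one row per guide per lung sample.
#' @export
per_mouse_fold_change <- function(normalized, sheet, mask,
                                  config = invivo_config()) {
  validate_sample_sheet(sheet)
  input <- sheet$sample_id[sheet$role == "input"]
  if (length(input) != 1L) stop_validation("exactly one input sample is required")
  lung <- sheet[sheet$role == "lung", , drop = FALSE]
  if (!nrow(lung)) stop_validation("no lung samples in sample sheet")
  if (!all(colnames(mask) == lung$sample_id) || nrow(mask) != nrow(normalized)) {
    mask <- mask[rownames(normalized), lung$sample_id, drop = FALSE]
  }
  pc <- config$pseudocount
  base <- normalized[, input] + pc
  if (any(base <= 0)) {
    stop_validation("pseudocount must be positive when input abundances can be 0")
  }
  out <- vector("list", nrow(lung))
  for (i in seq_len(nrow(lung))) {
    fc <- (normalized[, lung$sample_id[i]] + pc) / base
    keep <- mask[, i]
    fc[!keep] <- NA_real_
    out[[i]] <- data.frame(guide_id = rownames(normalized),
                           mouse_id = lung$mouse_id[i],
                           fold_change = unname(fc),
                           retained = unname(keep),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Cross-mouse average fold change per guide
#'
#' Averages each guide's per-mouse fold changes into a single enrichment
#' value. Under the default configuration the arithmetic mean runs over
#' all metastatic mice (excluded pairs contribute 0); see
#' [invivo_config()] for the retained-only and geometric variants. Guides
#' retained in zero mice are dropped from the output and reported in the
#' `dropped` attribute.
#'
#' @param fcs Long fold-change `data.frame` from [per_mouse_fold_change()].
#' @param config An [invivo_config()].
#' @return `data.frame` with `guide_id`, `avg_fold_change`,
#'   `n_mice_retained`; attribute `dropped` lists guide ids retained
#'   nowhere.
#' @export
aggregate_across_mice <- function(fcs, config = invivo_config()) {
  stopifnot(all(c("guide_id", "mouse_id", "fold_change", "retained") %in% names(fcs)))
  n_mice <- length(unique(fcs$mouse_id))
  g <- factor(fcs$guide_id, levels = unique(fcs$guide_id))
  n_ret <- as.integer(tapply(fcs$retained, g, sum))
  if (config$averaging == "geometric") {
    avg <- as.numeric(tapply(seq_len(nrow(fcs)), g, function(i) {
      v <- fcs$fold_change[i][fcs$retained[i]]
      if (!length(v)) NA_real_ else exp(mean(log(v)))
    }))
  } else {
    tot <- as.numeric(tapply(ifelse(fcs$retained, fcs$fold_change, 0), g, sum))
    denom <- if (config$average_over == "all") n_mice else pmax(n_ret, 1L)
    avg <- tot / denom
  }
  res <- data.frame(guide_id = levels(g), avg_fold_change = avg,
                    n_mice_retained = n_ret, stringsAsFactors = FALSE)
  dropped <- res$guide_id[res$n_mice_retained == 0L]
  res <- res[res$n_mice_retained > 0L, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "dropped") <- dropped
  res
}

#' Best-guide-per-gene enrichment ranking
#'
#' For each gene, the most enriched surviving guide (highest average fold
#' change) represents the gene; genes are ranked by that value in
#' descending order (rank 1 = most enriched). Ties are broken by gene
#' symbol, ascending, for reproducibility; genes with no surviving guide
#' are omitted.
#'
#' @param per_guide Output of [aggregate_across_mice()].
#' @param manifest Library manifest mapping guides to genes.
#' @return `data.frame`: `gene`, `best_guide_id`, `avg_fold_change`,
#'   `n_mice_retained`, `rank`, sorted by descending `avg_fold_change`.
#' @export
gene_rank <- function(per_guide, manifest) {
  validate_manifest(manifest)
  idx <- match(per_guide$guide_id, manifest$guide_id)
  if (anyNA(idx)) {
    stop_validation("guide(s) without a manifest gene: ",
                    paste(utils::head(per_guide$guide_id[is.na(idx)], 5L), collapse = ", "))
  }
  gene <- manifest$gene[idx]
  # deterministic best guide: highest avg, then guide_id ascending on ties
  ord <- order(gene, -per_guide$avg_fold_change, per_guide$guide_id)
  pg <- per_guide[ord, , drop = FALSE]
  gg <- gene[ord]
  first <- !duplicated(gg)
  res <- data.frame(gene = gg[first],
                    best_guide_id = pg$guide_id[first],
                    avg_fold_change = pg$avg_fold_change[first],
                    n_mice_retained = pg$n_mice_retained[first],
                    stringsAsFactors = FALSE)
  res <- res[order(-res$avg_fold_change, res$gene), , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

#' Run the full in vivo enrichment ranking
#'
#' Convenience wrapper chaining [filter_low_coverage()],
#' [normalize_total()], [per_mouse_fold_change()],
#' [aggregate_across_mice()] and [gene_rank()].
#'
#' @param counts Raw guide-by-sample count matrix.
#' @param manifest Library manifest.
#' @param sheet Sample sheet with one `input` and >= 1 `lung` sample.
#' @param config An [invivo_config()].
#' @return List with `ranking` (gene-level results), `guide_avgs`
#'   (per-guide averages), `fold_changes` (long per-mouse table) and
#'   `dropped` (guides retained in no mouse).
#' @export
invivo_rank <- function(counts, manifest, sheet, config = invivo_config()) {
  assert_count_matrix(counts)
  validate_manifest(manifest)
  if (!identical(rownames(counts), manifest$guide_id)) {
    stop_validation("counts rows must match manifest guide order")
  }
  mask <- filter_low_coverage(counts, sheet, config)
  used <- sheet$sample_id[sheet$role %in% c("input", "lung")]
  normalized <- normalize_total(counts[, used, drop = FALSE],
                                config$normalization_scale)
  fcs <- per_mouse_fold_change(normalized, sheet, mask, config)
  per_guide <- aggregate_across_mice(fcs, config)
  list(ranking = gene_rank(per_guide, manifest),
       guide_avgs = per_guide,
       fold_changes = fcs,
       dropped = attr(per_guide, "dropped"))
}
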