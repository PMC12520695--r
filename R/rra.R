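#' Sorting-screen scoring configuration
#'
#' Parameters for the two-gate reporter-stability screen: cells are sorted
#' into high and low fluorescence-ratio gates; a guide enriched in the low
#' gate destabilizes the reporter when lost, implicating its gene as a
#' stabilizer. `direction = "low"` (default) therefore treats low-gate
#' enrichment as the hit direction; `"high"` flips it for destabilizer
#' screens.
#'
#' `alpha` is the top-rank fraction considered by alpha-RRA: only guides
#' whose normalized rank falls within the top `alpha` of all guides
#' contribute to a gene's aggregation score, which makes the statistic
#' robust to a gene's inert guides. `alpha = 1` is classical RRA.
#'
#' @param pseudocount Symmetric pseudocount on normalized counts
#'   (default 0.5).
#' @param direction `"low"` (default) or `"high"`: which gate's enrichment
#'   counts as a hit.
#' @param alpha Top-rank fraction in (0, 1] used by alpha-RRA
#'   (default 0.25).
#' @param n_permutations Permutations for the null (default 10000).
#' @param seed RNG seed for the permutation null (default 1).
#' @param normalization_scale Per-sample total after normalization
#'   (default `1e6`).
#' @return A `sortscreen_config` list.
#' @export
sortscreen_config <- function(pseudocount = 0.5, direction = c("low", "high"),
                              alpha = 0.25, n_permutations = 10000L,
                              seed = 1L, normalization_scale = 1e6) {
  direction <- match.arg(direction)
  if (!(alpha > 0 && alpha <= 1)) stop_config("alpha must be in (0, 1]")
  if (n_permutations < 1) stop_config("n_permutations must be >= 1")
  if (pseudocount < 0) stop_config("pseudocount must be non-negative")
  structure(list(pseudocount = pseudocount, direction = direction,
                 alpha = alpha, n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed),
                 normalization_scale = normalization_scale),
            class = "sortscreen_config")
}

#' Per-guide enrichment score between sort gates
#'
#' Computes, for each guide, the signed log2 ratio of its normalized
#' abundance in the hit gate over the other gate:
#' `score = log2((low_norm + pc) / (high_norm + pc))` for the default
#' stabilizer direction. Normalization is per-sample total-count
#' normalization ([normalize_total()]).
#'
#' @param counts Count matrix containing the two gate samples.
#' @param sheet Sample sheet with exactly one `sorted_high` and one
#'   `sorted_low` sample (replicates averaged upstream).
#' @param config A [sortscreen_config()].
#' @return `data.frame` with `guide_id` and `score`, in count-matrix row
#'   order.
#' @export
score_guides_sorted <- function(counts, sheet, config = sortscreen_config()) {
  assert_count_matrix(counts)
  validate_sample_sheet(sheet)
  hi <- sheet$sample_id[sheet$role == "sorted_high"]
  lo <- sheet$sample_id[sheet$role == "sorted_low"]
  if (length(hi) != 1L || length(lo) != 1L) {
    stop_validation("exactly one sorted_high and one sorted_low sample are required")
  }
  missing <- setdiff(c(hi, lo), colnames(counts))
  if (length(missing)) {
    stop_validation("gate sample(s) missing from counts: ", paste(missing, collapse = ", "))
  }
  norm <- normalize_total(counts[, c(hi, lo), drop = FALSE],
                          config$normalization_scale)
  pc <- config$pseudocount
  num <- if (config$direction == "low") norm[, lo] else norm[, hi]
  den <- if (config$direction == "low") norm[, hi] else norm[, lo]
  if (pc == 0 && any(den == 0)) {
    stop_validation("pseudocount must be positive when gate counts can be 0")
  }
  data.frame(guide_id = rownames(counts),
             score = unname(log2((num + pc) / (den + pc))),
             stringsAsFactors = FALSE)
}

# rho for one gene: sorted normalized ranks r (ascending), gene size n,
# top-fraction alpha. rho = min_k P(Beta(k, n - k + 1) <= r_(k)) over the
# selected k (r_(k) <= alpha); 1 when no guide is selected.
rra_rho <- function(r, alpha) {
  r <- sort(r)
  n <- length(r)
  k <- which(r <= alpha)
  if (!length(k)) return(1)
  min(stats::pbeta(r[k], k, n - k + 1))
}

# Vectorized rho over a matrix whose rows are draws of n ranks (unsorted).
rra_rho_matrix <- function(m, alpha) {
  n <- ncol(m)
  ms <- matrix(m[order(row(m), m)], nrow = nrow(m), byrow = TRUE) # row-wise sort
  rho <- rep(1, nrow(m))
  for (k in seq_len(n)) {
    p <- stats::pbeta(ms[, k], k, n - k + 1)
    sel <- ms[, k] <= alpha
    rho[sel] <- pmin(rho[sel], p[sel])
  }
  rho
}

#' Gene-level alpha robust rank aggregation with a permutation null
#'
#' Ranks guides by descending score, converts ranks to normalized ranks
#' `r = rank / n_guides` in (0, 1], and aggregates each gene's guide ranks
#' into a rho score: the minimum over its selected guides (those with
#' `r <= alpha`) of the Beta order-statistic probability
#' `P(U_(k) <= r_(k))` for `n` i.i.d. uniforms, where `n` is the gene's
#' guide count. Small rho means the gene's guides sit unexpectedly high in
#' the ranking. Genes with no selected guide score rho = 1.
#'
#' The null distribution of rho is obtained by permutation: for each gene
#' size, `n_permutations` draws of that many normalized ranks, sampled
#' without replacement from the observed rank pool (equivalent to
#' permuting the gene labels of the guides). The permutation p-value is
#' `(1 + #\{rho_null <= rho_obs\}) / (n_permutations + 1)`, so its floor is
#' `1/(n_permutations + 1)`; FDR is Benjamini-Hochberg across genes. Tied
#' guide scores receive average ranks before normalization.
#'
#' @param scores Per-guide score `data.frame` from [score_guides_sorted()]
#'   (columns `guide_id`, `score`).
#' @param manifest Library manifest mapping every guide to a gene.
#' @param config A [sortscreen_config()]; `alpha`, `n_permutations` and
#'   `seed` are used here.
#' @return `data.frame` sorted ascending by rho: `gene`, `rho`, `p_value`,
#'   `fdr`, `rank`, `n_guides`, `n_guides_selected`.
#' @export
alpha_rra <- function(scores, manifest, config = sortscreen_config()) {
  validate_manifest(manifest)
  stopifnot(all(c("guide_id", "score") %in% names(scores)))
  if (nrow(scores) < 2L) stop_validation("need at least 2 guides for rank aggregation")
  idx <- match(scores$guide_id, manifest$guide_id)
  if (anyNA(idx)) {
    stop_validation("guide(s) without a manifest gene: ",
                    paste(utils::head(scores$guide_id[is.na(idx)], 5L), collapse = ", "))
  }
  gene <- manifest$gene[idx]
  alpha <- config$alpha
  n_guides <- nrow(scores)
  # descending score -> rank 1 is the strongest hit; average ranks on ties
  r <- rank(-scores$score, ties.method = "average") / n_guides

  genes <- split(r, gene)
  rho_obs <- vapply(genes, rra_rho, numeric(1), alpha = alpha)
  n_sel <- vapply(genes, function(v) sum(v <= alpha), integer(1))
  sizes <- lengths(genes)

  nperm <- config$n_permutations
  p <- with_seed(config$seed, {
    pv <- numeric(length(genes))
    for (n in sort(unique(sizes))) {
      draws <- matrix(0, nperm, n)
      for (b in seq_len(nperm)) draws[b, ] <- r[sample.int(n_guides, n)]
      rho_null <- sort(rra_rho_matrix(draws, alpha))
      which_n <- sizes == n
      # #{null <= obs} via binary search on the sorted null
      cnt <- findInterval(rho_obs[which_n], rho_null)
      pv[which_n] <- (1 + cnt) / (nperm + 1)
    }
    pv
  })
  fdr <- benjamini_hochberg(p)
  res <- data.frame(gene = names(genes), rho = unname(rho_obs),
                    p_value = unname(p), fdr = unname(fdr),
                    n_guides = unname(sizes), n_guides_selected = unname(n_sel),
                    stringsAsFactors = FALSE)
  res <- res[order(res$rho, res$p_value, res$gene), , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res[, c("gene", "rho", "p_value", "fdr", "rank", "n_guides", "n_guides_selected")]
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment:
#' `q_(i) = min_(j >= i) p_(j) * m / j`, clipped at 1 and mapped back to
#' the input order. Thin validating front end over [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return FDR-adjusted values in input order.
#' @export
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03))
benjamini_hochberg <- function(p_values) {
  p <- as.numeric(p_values)
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p <= 0 | p > 1)) {
    stop_validation("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Run the full sorting-screen analysis
#'
#' Chains [score_guides_sorted()] and [alpha_rra()].
#'
#' @param counts Count matrix with the two gate samples.
#' @param manifest Library manifest.
#' @param sheet Sample sheet with the `sorted_high` / `sorted_low` roles.
#' @param config A [sortscreen_config()].
#' @return List with `rra` (gene-level results) and `guide_scores`.
#' @export
sortscreen_rra <- function(counts, manifest, sheet,
                           config = sortscreen_config()) {
  scores <- score_guides_sorted(counts, sheet, config)
  list(rra = alpha_rra(scores, manifest, config), guide_scores = scores)
}
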