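# Fixture builders and independent oracles shared across test files.

tiny_manifest <- function(n_genes = 3, guides_per_gene = 2, seed = 42) {
  generate_library(n_genes, guides_per_gene, seed = seed)
}

# Sample sheet with one input and n lung samples.
invivo_sheet <- function(n_mice) {
  rbind(
    data.frame(sample_id = "input", role = "input", mouse_id = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(sample_id = sprintf("lung_m%02d", seq_len(n_mice)), role = "lung",
               mouse_id = sprintf("m%02d", seq_len(n_mice)),
               stringsAsFactors = FALSE)
  )
}

gate_sheet <- function() {
  data.frame(sample_id = c("sorted_high", "sorted_low"),
             role = c("sorted_high", "sorted_low"),
             mouse_id = NA_character_, stringsAsFactors = FALSE)
}

random_counts <- function(manifest, sheet, lambda = 100, seed = 1) {
  n <- nrow(manifest)
  m <- length(sheet$sample_id)
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    counts <- matrix(rpois(n * m, lambda), n, m,
                     dimnames = list(manifest$guide_id, sheet$sample_id))
    storage.mode(counts) <- "integer"
    counts
  })
}

# Independent brute-force re-implementation of the in vivo ranking
# (explicit loops, no shared code with the package internals).
brute_force_invivo <- function(counts, manifest, sheet, min_reads = 50,
                               scale = 1e6, pc = 0.5,
                               average_over = "all") {
  input_id <- sheet$sample_id[sheet$role == "input"]
  lung <- sheet[sheet$role == "lung", , drop = FALSE]
  norm <- function(col) col / sum(col) * scale
  input_n <- norm(counts[, input_id])
  per_guide <- data.frame(guide_id = character(0), avg = numeric(0),
                          n_ret = integer(0))
  for (g in rownames(counts)) {
    fcs <- c()
    n_ret <- 0L
    for (i in seq_len(nrow(lung))) {
      raw <- counts[g, lung$sample_id[i]]
      if (raw >= min_reads) {
        lung_n <- norm(counts[, lung$sample_id[i]])[g]
        fcs <- c(fcs, (lung_n + pc) / (input_n[g] + pc))
        n_ret <- n_ret + 1L
      }
    }
    if (n_ret > 0L) {
      avg <- if (average_over == "all") sum(fcs) / nrow(lung) else mean(fcs)
      per_guide <- rbind(per_guide,
                         data.frame(guide_id = g, avg = avg, n_ret = n_ret))
    }
  }
  per_guide$gene <- manifest$gene[match(per_guide$guide_id, manifest$guide_id)]
  best <- do.call(rbind, lapply(split(per_guide, per_guide$gene), function(d) {
    d[order(-d$avg, d$guide_id), ][1, ]
  }))
  best <- best[order(-best$avg, best$gene), ]
  best$rank <- seq_len(nrow(best))
  rownames(best) <- NULL
  best
}

# Exhaustive permutation p-values for a tiny RRA instance: for each gene,
# enumerate every subset of its size from the observed normalized ranks.
exhaustive_rra_p <- function(r, gene, alpha) {
  rho_of <- function(v) {
    v <- sort(v); n <- length(v)
    k <- which(v <= alpha)
    if (!length(k)) return(1)
    min(pbeta(v[k], k, n - k + 1))
  }
  sapply(split(r, gene), function(rg) {
    obs <- rho_of(rg)
    subsets <- combn(r, length(rg))
    nulls <- apply(subsets, 2, rho_of)
    mean(nulls <= obs)
  })
}
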