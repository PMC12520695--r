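#' Select enriched genes from a ranking
#'
#' Applies an enrichment cutoff to a gene-level ranking — either the top
#' `top_n` genes or all genes with average fold change at or above
#' `min_avg_fold_change` — preserving rank order. Exactly one cutoff mode
#' must be supplied; the cutoff used is attached as attributes so
#' downstream overlap reports can record it.
#'
#' @param ranking Gene ranking `data.frame` from [gene_rank()].
#' @param top_n Integer cutoff: keep the first `top_n` genes.
#' @param min_avg_fold_change Numeric cutoff: keep genes with
#'   `avg_fold_change >= min_avg_fold_change`.
#' @return Character vector of gene symbols in rank order, with
#'   `cutoff_mode` / `cutoff_value` attributes.
#' @export
select_enriched <- function(ranking, top_n = NULL, min_avg_fold_change = NULL) {
  if (is.null(top_n) == is.null(min_avg_fold_change)) {
    stop_config("supply exactly one of top_n or min_avg_fold_change")
  }
  stopifnot(all(c("gene", "avg_fold_change", "rank") %in% names(ranking)))
  ranking <- ranking[order(ranking$rank), , drop = FALSE]
  if (!is.null(top_n)) {
    if (top_n < 1) stop_config("top_n must be >= 1")
    if (top_n > nrow(ranking)) {
      warning("top_n (", top_n, ") exceeds ranking size (", nrow(ranking),
              "); returning all genes", call. = FALSE)
      top_n <- nrow(ranking)
    }
    genes <- ranking$gene[seq_len(top_n)]
    mode <- "top_n"; value <- top_n
  } else {
    genes <- ranking$gene[ranking$avg_fold_change >= min_avg_fold_change]
    mode <- "min_avg_fold_change"; value <- min_avg_fold_change
  }
  structure(genes, cutoff_mode = mode, cutoff_value = value)
}

#' Intersect gene sets and compute Venn region counts
#'
#' Intersects an enriched-gene set with an interactome protein list (and
#' optionally a third set), producing the ordered overlap and the sizes of
#' the exclusive Venn regions. The overlap preserves the order of
#' `set_a` (screen-rank order when `set_a` comes from
#' [select_enriched()]).
#'
#' @param set_a First gene set (order preserved in the overlap).
#' @param set_b Second gene set.
#' @param set_c Optional third set.
#' @param names Labels for the sets in the Venn counts (length 2 or 3).
#' @return A `triage_result` list: `overlap_genes` (in `set_a` order,
#'   common to all supplied sets), `venn_counts` (named exclusive-region
#'   sizes), `n_union`, and `parameters` (cutoff metadata carried on
#'   `set_a`, if any).
#' @export
intersect_sets <- function(set_a, set_b, set_c = NULL,
                           names = c("screen", "interactome", "extra")) {
  a <- toupper(as.character(set_a)); a <- a[!duplicated(a)]
  b <- unique(toupper(as.character(set_b)))
  params <- list(cutoff_mode = attr(set_a, "cutoff_mode"),
                 cutoff_value = attr(set_a, "cutoff_value"))
  if (is.null(set_c)) {
    overlap <- a[a %in% b]
    venn <- c(length(setdiff(a, b)), length(setdiff(b, a)), length(overlap))
    names(venn) <- c(paste0(names[1], "_only"), paste0(names[2], "_only"),
                     paste(names[1], names[2], sep = "_and_"))
    n_union <- length(union(a, b))
  } else {
    cc <- unique(toupper(as.character(set_c)))
    overlap <- a[a %in% b & a %in% cc]
    u <- union(union(a, b), cc)
    ina <- u %in% a; inb <- u %in% b; inc <- u %in% cc
    venn <- c(sum(ina & !inb & !inc), sum(!ina & inb & !inc),
              sum(!ina & !inb & inc), sum(ina & inb & !inc),
              sum(ina & !inb & inc), sum(!ina & inb & inc),
              sum(ina & inb & inc))
    names(venn) <- c(paste0(names[1:3], "_only"),
                     paste(names[1], names[2], sep = "_and_"),
                     paste(names[1], names[3], sep = "_and_"),
                     paste(names[2], names[3], sep = "_and_"),
                     paste(names, collapse = "_and_"))
    n_union <- length(u)
  }
  structure(list(overlap_genes = overlap, venn_counts = venn,
                 n_union = n_union, parameters = params),
            class = "triage_result")
}

#' @export
print.triage_result <- function(x, ...) {
  cat("Triage overlap:", length(x$overlap_genes), "gene(s)\n")
  if (length(x$overlap_genes)) {
    cat(" ", paste(utils::head(x$overlap_genes, 20), collapse = ", "))
    if (length(x$overlap_genes) > 20) cat(", ...")
    cat("\n")
  }
  cat("Venn regions:\n")
  print(x$venn_counts)
  invisible(x)
}
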