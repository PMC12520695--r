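# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("screenrank_validation_error", "error")))
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("screenrank_config_error", "error")))
}

assert_count_matrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop_validation("counts must be a numeric matrix")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_validation("counts must have guide_id rownames and sample_id colnames")
  }
  if (anyNA(counts)) stop_validation("counts contain missing values")
  if (any(counts < 0)) stop_validation("counts contain negative entries")
  invisible(counts)
}
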