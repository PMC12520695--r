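#' Quantification configuration
#'
#' Amplicon reads carry the 20-nt protospacer behind a constant vector
#' portion. Extraction is configured either by a fixed prefix length (the
#' number of constant bases preceding the protospacer) or by an anchor
#' sequence located in the read, with the 20-mer taken immediately after
#' the anchor. Exactly one of the two modes is active.
#'
#' @param constant_prefix_length Non-negative integer; bases removed before
#'   the protospacer (fixed-prefix mode). Ignored when `anchor_sequence`
#'   is given.
#' @param anchor_sequence Optional string; when supplied, the protospacer
#'   is the 20 bases following the first occurrence of this anchor.
#' @param protospacer_length Protospacer length; 20 for these libraries.
#' @return A `quant_config` list.
#' @export
quant_config <- function(constant_prefix_length = 0L, anchor_sequence = NULL,
                         protospacer_length = 20L) {
  if (protospacer_length != 20L) {
    stop_config("protospacer_length must be 20 for these libraries")
  }
  if (is.null(anchor_sequence)) {
    if (!is.numeric(constant_prefix_length) || constant_prefix_length < 0) {
      stop_config("constant_prefix_length must be a non-negative integer")
    }
  } else {
    anchor_sequence <- toupper(anchor_sequence)
    if (!nzchar(anchor_sequence) || grepl("[^ACGTN]", anchor_sequence)) {
      stop_config("anchor_sequence must be a non-empty DNA string")
    }
  }
  structure(list(constant_prefix_length = as.integer(constant_prefix_length),
                 anchor_sequence = anchor_sequence,
                 protospacer_length = as.integer(protospacer_length)),
            class = "quant_config")
}

#' Extract the 20-nt protospacer candidate from a read
#'
#' Removes the constant portion of the read and returns the 20-base
#' candidate (uppercased), or `NA` when the read is too short or the anchor
#' is absent. Vectorized over reads.
#'
#' @param read_sequence Character vector of read sequences.
#' @param config A [quant_config()].
#' @return Character vector of 20-mers, `NA` where unextractable.
#' @export
#' @examples
#' cfg <- quant_config(constant_prefix_length = 4)
#' extract_protospacer(paste0("AAAA", strrep("ACGT", 5), "TTTT"), cfg)
extract_protospacer <- function(read_sequence, config) {
  stopifnot(inherits(config, "quant_config"))
  reads <- toupper(as.character(read_sequence))
  k <- config$protospacer_length
  if (is.null(config$anchor_sequence)) {
    start <- config$constant_prefix_length + 1L
    out <- substr(reads, start, start + k - 1L)
  } else {
    pos <- regexpr(config$anchor_sequence, reads, fixed = TRUE)
    start <- ifelse(pos > 0L, pos + nchar(config$anchor_sequence), NA_integer_)
    out <- substr(reads, start, start + k - 1L)
    out[is.na(start)] <- NA_character_
  }
  out[is.na(out) | nchar(out) < k] <- NA_character_
  out
}

#' Count sgRNAs in amplicon FASTQ files by exact protospacer match
#'
#' For each sample, every read's extracted 20-mer that exactly equals a
#' manifest protospacer increments that guide's count; all other reads are
#' counted as unmatched. Matching is exact and on the forward orientation
#' only (orientation is the library prep's responsibility); quality scores
#' are ignored.
#'
#' @param fastq_paths Named list (or named character vector): one FASTQ /
#'   FASTQ.gz path (or vector of paths) per sample; names are sample ids.
#' @param manifest Library manifest; protospacers must be unique.
#' @param config A [quant_config()].
#' @return A list with `counts` (integer guide-by-sample matrix in manifest
#'   order) and `report` (a `data.frame` per sample: `total_reads`,
#'   `matched_reads`, `unmatched_reads`, `mapping_rate`).
#' @export
count_guides <- function(fastq_paths, manifest, config = quant_config()) {
  validate_manifest(manifest)
  if (anyDuplicated(manifest$protospacer)) {
    stop_validation("manifest protospacers must be unique for exact-match counting")
  }
  if (is.character(fastq_paths)) fastq_paths <- as.list(fastq_paths)
  if (is.null(names(fastq_paths)) || any(!nzchar(names(fastq_paths)))) {
    stop_validation("fastq_paths must be named by sample_id")
  }
  samples <- names(fastq_paths)
  counts <- matrix(0L, nrow(manifest), length(samples),
                   dimnames = list(manifest$guide_id, samples))
  rep_rows <- vector("list", length(samples))
  for (j in seq_along(samples)) {
    seqs <- character(0)
    for (fp in fastq_paths[[j]]) {
      seqs <- c(seqs, read_fastq_sequences(fp))
    }
    total <- length(seqs)
    if (total) {
      proto <- extract_protospacer(seqs, config)
      hit <- match(proto, manifest$protospacer)
      tab <- tabulate(hit[!is.na(hit)], nbins = nrow(manifest))
      counts[, j] <- as.integer(tab)
    }
    matched <- sum(counts[, j])
    rep_rows[[j]] <- data.frame(
      sample_id = samples[j], total_reads = total, matched_reads = matched,
      unmatched_reads = total - matched,
      mapping_rate = if (total) matched / total else 0,
      stringsAsFactors = FALSE
    )
  }
  list(counts = counts, report = do.call(rbind, rep_rows))
}

# FASTQ sequences as a character vector; gz handled transparently.
read_fastq_sequences <- function(path) {
  if (!file.exists(path)) stop_validation("FASTQ not found: ", path)
  if (file.size(path) == 0L) return(character(0))
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e) {
      stop_validation("failed to parse FASTQ ", path, ": ", conditionMessage(e))
    }
  )
  as.character(seqs, use.names = FALSE)
}
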