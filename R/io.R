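#' Read an sgRNA library manifest
#'
#' A library manifest catalogs every guide in a pooled CRISPR library: a
#' unique guide identifier, the gene symbol it targets, and its 20-nt
#' protospacer. All downstream stages (quantification, ranking, rank
#' aggregation) key on this catalog.
#'
#' The canonical dialect is tab-delimited UTF-8 with a header containing the
#' columns `guide_id`, `gene` and `protospacer` (order-insensitive); lines
#' starting with `#` are ignored. Gene symbols are case-normalized to
#' uppercase so that screen genes and interactome protein lists intersect
#' reliably.
#'
#' @param path Path to the manifest file.
#' @param sep Field separator, `"\t"` (default) or `","`.
#' @return A `data.frame` with columns `guide_id`, `gene`, `protospacer`,
#'   one row per guide, in file row order.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("guide_id\tgene\tprotospacer",
#'              paste0("g1\tMLF2\t", strrep("ACGT", 5))), tf)
#' read_library_manifest(tf)
read_library_manifest <- function(path, sep = "\t") {
  df <- read_screen_table(path, sep)
  need <- c("guide_id", "gene", "protospacer")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop_validation("manifest is missing column(s): ", paste(missing, collapse = ", "))
  }
  manifest <- data.frame(
    guide_id = as.character(df$guide_id),
    gene = toupper(as.character(df$gene)),
    protospacer = toupper(as.character(df$protospacer)),
    stringsAsFactors = FALSE
  )
  validate_manifest(manifest)
  manifest
}

#' Validate a library manifest
#'
#' Enforces the manifest invariants: unique guide identifiers, non-empty
#' gene symbols, and protospacers that are exactly 20 characters over
#' `{A,C,G,T}`.
#'
#' @param manifest A manifest `data.frame` (see [read_library_manifest()]).
#' @return The manifest, invisibly, if valid; otherwise an error.
#' @export
validate_manifest <- function(manifest) {
  if (!is.data.frame(manifest) ||
      !all(c("guide_id", "gene", "protospacer") %in% names(manifest))) {
    stop_validation("manifest must be a data.frame with guide_id, gene, protospacer")
  }
  if (nrow(manifest) == 0L) stop_validation("manifest has no guides")
  dup <- manifest$guide_id[duplicated(manifest$guide_id)]
  if (length(dup)) {
    stop_validation("duplicate guide_id: ", paste(unique(dup), collapse = ", "))
  }
  if (any(!nzchar(manifest$gene))) stop_validation("manifest has empty gene symbols")
  bad <- which(nchar(manifest$protospacer) != 20L |
                 grepl("[^ACGT]", manifest$protospacer))
  if (length(bad)) {
    stop_validation("protospacer must be 20 nt over {A,C,G,T}; offending row(s): ",
                    paste(utils::head(bad, 5L), collapse = ", "))
  }
  invisible(manifest)
}

#' Write a library manifest to TSV
#'
#' @param manifest Manifest `data.frame`.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_library_manifest <- function(manifest, path, sep = "\t") {
  validate_manifest(manifest)
  utils::write.table(manifest[, c("guide_id", "gene", "protospacer")], path,
                     sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' The sample sheet assigns each sequenced sample a role in the screen:
#' `input` (the pre-selection baseline), `lung` (one per metastatic mouse,
#' with a `mouse_id`), or `sorted_high` / `sorted_low` (the two
#' fluorescence-ratio sort gates).
#'
#' @param path Path to a TSV with columns `sample_id`, `role` and optionally
#'   `mouse_id` (required for `lung` rows).
#' @param sep Field separator (default tab).
#' @return A `data.frame` with columns `sample_id`, `role`, `mouse_id`
#'   (`NA` where absent).
#' @export
read_sample_sheet <- function(path, sep = "\t") {
  df <- read_screen_table(path, sep)
  if (!all(c("sample_id", "role") %in% names(df))) {
    stop_validation("sample sheet needs columns sample_id and role")
  }
  sheet <- data.frame(
    sample_id = as.character(df$sample_id),
    role = as.character(df$role),
    mouse_id = if ("mouse_id" %in% names(df)) as.character(df$mouse_id) else NA_character_,
    stringsAsFactors = FALSE
  )
  sheet$mouse_id[!is.na(sheet$mouse_id) & !nzchar(sheet$mouse_id)] <- NA_character_
  validate_sample_sheet(sheet)
  sheet
}

#' Validate a sample sheet
#'
#' @param sheet Sample sheet `data.frame`.
#' @return The sheet, invisibly, if valid.
#' @export
validate_sample_sheet <- function(sheet) {
  roles <- c("input", "lung", "sorted_high", "sorted_low")
  if (!is.data.frame(sheet) || !all(c("sample_id", "role") %in% names(sheet))) {
    stop_validation("sample sheet must have sample_id and role columns")
  }
  if (anyDuplicated(sheet$sample_id)) {
    stop_validation("duplicate sample_id: ",
                    paste(unique(sheet$sample_id[duplicated(sheet$sample_id)]), collapse = ", "))
  }
  bad <- setdiff(sheet$role, roles)
  if (length(bad)) {
    stop_validation("unknown role(s): ", paste(bad, collapse = ", "),
                    " (expected ", paste(roles, collapse = "/"), ")")
  }
  if (sum(sheet$role == "input") > 1L) {
    stop_validation("at most one input sample is allowed per analysis")
  }
  lung <- sheet[sheet$role == "lung", , drop = FALSE]
  if (nrow(lung)) {
    if (anyNA(lung$mouse_id)) stop_validation("lung samples require a mouse_id")
    if (anyDuplicated(lung$mouse_id)) {
      stop_validation("mouse_id must be unique across lung samples")
    }
  }
  invisible(sheet)
}

#' Write a sample sheet to TSV
#'
#' @param sheet Sample sheet `data.frame`.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path, sep = "\t") {
  validate_sample_sheet(sheet)
  out <- sheet[, c("sample_id", "role", "mouse_id")]
  out$mouse_id[is.na(out$mouse_id)] <- ""
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a guide-by-sample count table
#'
#' Reads raw sgRNA read counts and aligns them to the manifest: rows are
#' reordered to manifest order, manifest guides absent from the file are
#' filled with zero (with a warning), and guides present in the file but
#' absent from the manifest are a hard error, surfacing library/count
#' mismatches rather than silently dropping reads.
#'
#' @param path Path to a TSV whose first column is `guide_id` and whose
#'   remaining columns are integer counts named by sample.
#' @param manifest Library manifest the counts must align to.
#' @param sheet Optional sample sheet; when given, every count column must
#'   be a known `sample_id`.
#' @param sep Field separator (default tab).
#' @return An integer matrix (guides x samples) with `guide_id` rownames in
#'   manifest order and `sample_id` colnames.
#' @export
read_count_table <- function(path, manifest, sheet = NULL, sep = "\t") {
  validate_manifest(manifest)
  df <- read_screen_table(path, sep, check.names = FALSE)
  if (names(df)[1] != "guide_id") {
    stop_validation("count table's first column must be guide_id")
  }
  ids <- as.character(df$guide_id)
  if (anyDuplicated(ids)) {
    stop_validation("duplicate guide_id in count table: ",
                    paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  unknown <- setdiff(ids, manifest$guide_id)
  if (length(unknown)) {
    stop_validation("count table has guide(s) absent from the manifest: ",
                    paste(utils::head(unknown, 5L), collapse = ", "))
  }
  samples <- names(df)[-1]
  if (!is.null(sheet)) {
    validate_sample_sheet(sheet)
    extra <- setdiff(samples, sheet$sample_id)
    if (length(extra)) {
      stop_validation("count column(s) not in sample sheet: ",
                      paste(extra, collapse = ", "))
    }
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals) || anyNA(vals)) {
    stop_validation("count table has non-numeric or missing cells")
  }
  bad <- which(vals < 0 | vals != floor(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop_validation("negative or non-integer count at guide ", ids[bad[1, 1]],
                    ", sample ", samples[bad[1, 2]])
  }
  counts <- matrix(0L, nrow(manifest), length(samples),
                   dimnames = list(manifest$guide_id, samples))
  counts[ids, ] <- as.integer(vals)
  missing <- setdiff(manifest$guide_id, ids)
  if (length(missing)) {
    warning(length(missing), " manifest guide(s) absent from count file; filled with 0",
            call. = FALSE)
  }
  counts
}

#' Write a count matrix to TSV
#'
#' @param counts Integer guide-by-sample matrix.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path, sep = "\t") {
  assert_count_matrix(counts)
  df <- data.frame(guide_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a protein / gene symbol list
#'
#' One symbol per line; blank lines and `#` comments are ignored; symbols
#' are uppercased and deduplicated so they intersect reliably with screen
#' gene symbols. This is the format used for interactome protein lists
#' (e.g. an IP-MS hit list) consumed by the triage stage.
#'
#' @param path Path to the list file.
#' @return A character vector of unique, uppercase symbols, in first-seen
#'   order.
#' @export
read_protein_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- unique(toupper(lines))
  if (!length(out)) stop_validation("protein list is empty after filtering")
  out
}

# Shared table reader: TSV/CSV, '#' comments, header required.
read_screen_table <- function(path, sep = "\t", check.names = TRUE) {
  if (!file.exists(path)) stop_validation("file not found: ", path)
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = check.names,
                    quote = "")
}
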