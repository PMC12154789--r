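#' Read a tag-by-sample count matrix with tag locations
#'
#' The counts file is a TSV whose first column is `tag_id` and whose remaining
#' columns are one per sample; the BED file carries the tag locations
#' (`chrom`, `start`, `end`, `tag_id`, `mapq`; 0-based half-open). Every
#' tag in the counts file must appear exactly once in the BED file. Row order
#' of the counts file is preserved.
#'
#' @param counts_path path to the counts TSV
#' @param bed_path path to the 5+ column BED file
#' @return a [tag_matrix()]
#' @export
read_tag_matrix <- function(counts_path, bed_path) {
  counts_df <- readr::read_tsv(counts_path, comment = "#", progress = FALSE,
                               show_col_types = FALSE,
                               col_types = readr::cols(
                                 tag_id = readr::col_character(),
                                 .default = readr::col_character()))
  if (!identical(names(counts_df)[1], "tag_id")) {
    abort("first column of the counts file must be 'tag_id'")
  }
  bed <- readr::read_tsv(bed_path, comment = "#",
                         col_names = c("chrom", "start", "end", "tag_id", "mapq"),
                         col_types = "ciici", progress = FALSE,
                         show_col_types = FALSE)
  samples <- names(counts_df)[-1]
  n_tags <- nrow(counts_df)
  if (n_tags == 0L) {
    counts <- matrix(0L, 0, length(samples),
                     dimnames = list(NULL, samples))
    loc <- bed[0, c("tag_id", "chrom", "start", "end", "mapq")]
    return(tag_matrix(counts, loc, samples))
  }
  missing <- setdiff(counts_df$tag_id, bed$tag_id)
  if (length(missing)) {
    abort(sprintf("tag ids absent from the BED file: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  # strict numeric parse: malformed or negative cells error with location
  counts <- matrix(0L, n_tags, length(samples),
                   dimnames = list(counts_df$tag_id, samples))
  for (j in seq_along(samples)) {
    raw <- counts_df[[j + 1L]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) | val < 0 | val != floor(val))
    if (length(bad)) {
      abort(sprintf(
        "counts file: non-negative integer expected at row %d, column '%s' (got '%s')",
        bad[1], samples[j], raw[bad[1]]))
    }
    counts[, j] <- as.integer(val)
  }
  loc <- bed[match(counts_df$tag_id, bed$tag_id),
             c("tag_id", "chrom", "start", "end", "mapq")]
  tag_matrix(counts, loc, samples)
}

MANIFEST_CLASSES <- c("control", "experimental", "blank")
STATUS_TOKENS <- c("positive", "negative", "unknown")

#' Read a sample manifest
#'
#' The manifest is a TSV with columns `sample_id`, `sample_class`
#' (control/experimental/blank), one column per CDH (`Ab10`, `K10L2`, `B`,
#' values positive/negative/unknown), `copy_class` (high/low/unknown) and
#' `ab10_type` (I/II/III/unknown). CDH columns that are absent are filled
#' with "unknown".
#'
#' @param path path to the manifest TSV
#' @param cdhs CDH column names expected (default `c("Ab10","K10L2","B")`)
#' @return a tibble, validated
#' @export
read_manifest <- function(path, cdhs = CDH_NAMES) {
  m <- readr::read_tsv(path, comment = "#", progress = FALSE,
                       show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("sample_id", "sample_class") %in% names(m))) {
    abort("manifest needs 'sample_id' and 'sample_class' columns")
  }
  for (cdh in cdhs) if (!cdh %in% names(m)) m[[cdh]] <- "unknown"
  if (!"copy_class" %in% names(m)) m$copy_class <- "unknown"
  if (!"ab10_type" %in% names(m)) m$ab10_type <- "unknown"
  m <- m[, c("sample_id", "sample_class", cdhs, "copy_class", "ab10_type")]
  validate_manifest(m, cdhs)
}

#' Validate a sample manifest
#'
#' Checks the invariants used throughout: unique sample ids, recognised
#' class/status tokens, blanks fully unknown, controls with at least one
#' known CDH status.
#'
#' @param manifest tibble as returned by [read_manifest()]
#' @param cdhs CDH column names
#' @return the manifest, invisibly validated (returned unchanged)
#' @export
validate_manifest <- function(manifest, cdhs = CDH_NAMES) {
  m <- tibble::as_tibble(manifest)
  if (anyDuplicated(m$sample_id)) {
    abort(sprintf("duplicated sample_id: '%s'",
                  m$sample_id[duplicated(m$sample_id)][1]))
  }
  bad <- setdiff(unique(m$sample_class), MANIFEST_CLASSES)
  if (length(bad)) {
    abort(sprintf("unrecognized sample_class token: '%s'", bad[1]))
  }
  for (cdh in cdhs) {
    bad <- setdiff(unique(m[[cdh]]), STATUS_TOKENS)
    if (length(bad)) {
      abort(sprintf("unrecognized %s status token: '%s'", cdh, bad[1]))
    }
  }
  if (!all(m$copy_class %in% c("high", "low", "unknown"))) {
    abort("copy_class must be high, low or unknown")
  }
  if (!all(m$ab10_type %in% c("I", "II", "III", "R", "unknown"))) {
    abort("ab10_type must be I, II, III, R or unknown")
  }
  blanks <- m$sample_class == "blank"
  if (any(blanks)) {
    known <- rowSums(as.matrix(m[blanks, cdhs, drop = FALSE] != "unknown")) > 0
    if (any(known)) {
      abort(sprintf("blank sample '%s' has a known CDH status",
                    m$sample_id[blanks][known][1]))
    }
  }
  ctrl <- m$sample_class == "control"
  if (any(ctrl)) {
    known <- rowSums(as.matrix(m[ctrl, cdhs, drop = FALSE] != "unknown")) > 0
    if (!all(known)) {
      abort(sprintf("control sample '%s' has no known CDH status",
                    m$sample_id[ctrl][!known][1]))
    }
  }
  m
}

#' Read and write bin definitions
#'
#' Bin definitions are TSVs with columns `chrom`, `start`, `end`, `label` and
#' optional `diagnostic_for`, `single_copy`, `type_specific`.
#'
#' @param path file path
#' @return a tibble of bin definitions
#' @export
read_bin_definitions <- function(path) {
  b <- readr::read_tsv(path, comment = "#", progress = FALSE,
                       show_col_types = FALSE,
                       col_types = readr::cols(
                         chrom = readr::col_character(),
                         start = readr::col_integer(),
                         end = readr::col_integer(),
                         label = readr::col_character(),
                         .default = readr::col_character()))
  if ("single_copy" %in% names(b)) b$single_copy <- b$single_copy == "TRUE"
  check_bins_nonoverlapping(b)
  b
}

#' @rdname read_bin_definitions
#' @param bins tibble of bin definitions
#' @export
write_bin_definitions <- function(bins, path) {
  readr::write_tsv(bins, path, na = "")
  invisible(path)
}

check_bins_nonoverlapping <- function(bins) {
  for (ch in unique(bins$chrom)) {
    b <- bins[bins$chrom == ch, ]
    b <- b[order(b$start), ]
    if (nrow(b) > 1 && any(b$start[-1] < b$end[-nrow(b)])) {
      abort(sprintf("overlapping bins on chromosome '%s'", ch))
    }
  }
  invisible(bins)
}

#' Write and read a call table
#'
#' The call table holds one row per (sample, CDH) with the consensus call,
#' the consensus fraction (majority-call count over rounds) and the number
#' of clustering rounds recorded. Writing then reading reproduces the table
#' exactly.
#'
#' @param calls tibble with `sample_id`, `cdh`, `call`, `consensus_fraction`,
#'   `n_rounds`
#' @param path file path
#' @export
write_call_table <- function(calls, path) {
  need <- c("sample_id", "cdh", "call", "consensus_fraction", "n_rounds")
  if (!all(need %in% names(calls))) {
    abort(paste0("call table must have columns: ", paste(need, collapse = ", ")))
  }
  readr::write_tsv(calls[, need], path, na = "NA")
  invisible(path)
}

#' @rdname write_call_table
#' @export
read_call_table <- function(path) {
  readr::read_tsv(path, comment = "#", progress = FALSE,
                  show_col_types = FALSE,
                  col_types = readr::cols(
                    sample_id = readr::col_character(),
                    cdh = readr::col_character(),
                    call = readr::col_character(),
                    consensus_fraction = readr::col_double(),
                    n_rounds = readr::col_integer()))
}

#' Write a tag matrix to counts TSV + BED
#'
#' @param tags a [tag_matrix()]
#' @param counts_path,bed_path output paths
#' @export
write_tag_matrix <- function(tags, counts_path, bed_path) {
  stopifnot(inherits(tags, "tag_matrix"))
  df <- tibble::as_tibble(tags$counts, rownames = "tag_id")
  readr::write_tsv(df, counts_path)
  bed <- tags$locations[, c("chrom", "start", "end", "tag_id", "mapq")]
  readr::write_tsv(bed, bed_path, col_names = FALSE)
  invisible(counts_path)
}

#' Write a sample manifest
#'
#' @param manifest manifest tibble
#' @param path output path
#' @export
write_manifest <- function(manifest, path) {
  readr::write_tsv(manifest, path)
  invisible(path)
}
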