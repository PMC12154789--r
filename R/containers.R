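#' Tag-by-sample count container
#'
#' A `tag_matrix` holds the per-tag read counts of a genotyping-by-sequencing
#' (GBS) experiment together with each tag's genomic location and BWA mapping
#' quality. Rows are tags, columns are samples. Counts are raw integers on
#' input; after [rpm_normalize()] they are reads-per-million depths and the
#' `normalized` flag is set.
#'
#' @param counts numeric matrix, tags x samples. Row names are taken as tag
#'   ids if `locations` lacks them.
#' @param locations data frame with columns `tag_id`, `chrom`, `start`, `end`,
#'   `mapq` (0-based half-open coordinates), one row per row of `counts`.
#' @param sample_ids character vector of column names; defaults to
#'   `colnames(counts)`.
#' @param normalized logical; `TRUE` once depths are reads-per-million.
#' @return An object of class `tag_matrix`.
#' @export
tag_matrix <- function(counts, locations, sample_ids = colnames(counts),
                       normalized = FALSE) {
  counts <- as.matrix(counts)
  locations <- tibble::as_tibble(locations)
  need <- c("tag_id", "chrom", "start", "end", "mapq")
  if (!all(need %in% names(locations))) {
    abort(paste0("`locations` must have columns: ", paste(need, collapse = ", ")))
  }
  if (nrow(counts) != nrow(locations)) {
    abort(sprintf("counts has %d rows but locations has %d", nrow(counts),
                  nrow(locations)))
  }
  if (anyDuplicated(locations$tag_id)) {
    dup <- locations$tag_id[duplicated(locations$tag_id)][1]
    abort(sprintf("duplicated tag_id: '%s'", dup))
  }
  if (any(locations$start >= locations$end)) {
    bad <- which(locations$start >= locations$end)[1]
    abort(sprintf("tag '%s' has start >= end", locations$tag_id[bad]))
  }
  if (any(locations$mapq < 0)) abort("mapping quality must be >= 0")
  if (is.null(sample_ids)) {
    abort("sample ids are required (column names of `counts`)")
  }
  if (ncol(counts) != length(sample_ids)) {
    abort("number of columns of counts must equal length of sample_ids")
  }
  if (any(counts < 0)) abort("counts must be non-negative")
  if (!normalized && any(counts != floor(counts))) {
    abort("raw counts must be integers; got fractional values")
  }
  dimnames(counts) <- list(locations$tag_id, sample_ids)
  structure(list(counts = counts, locations = locations,
                 sample_ids = sample_ids, normalized = normalized),
            class = "tag_matrix")
}

#' @export
print.tag_matrix <- function(x, ...) {
  cat(sprintf("<tag_matrix> %d tags x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              if (x$normalized) "reads-per-million" else "raw counts"))
  cat("chromosomes:", paste(unique(x$locations$chrom), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.tag_matrix <- function(x) dim(x$counts)

#' Subset a tag matrix by tag and/or sample
#'
#' @param x a [tag_matrix()]
#' @param tags logical/integer/character index over tags
#' @param samples logical/integer/character index over samples
#' @return a `tag_matrix`
#' @export
subset_tags <- function(x, tags = NULL, samples = NULL) {
  stopifnot(inherits(x, "tag_matrix"))
  counts <- x$counts
  loc <- x$locations
  if (!is.null(tags)) {
    counts <- counts[tags, , drop = FALSE]
    loc <- loc[match(rownames(counts), loc$tag_id), ]
  }
  if (!is.null(samples)) counts <- counts[, samples, drop = FALSE]
  tag_matrix(counts, loc, colnames(counts), normalized = x$normalized)
}

#' @rdname tag_matrix
#' @param x a `tag_matrix`
#' @param ... unused
#' @method tidy tag_matrix
#' @export
tidy.tag_matrix <- function(x, ...) {
  tibble::as_tibble(x$counts, rownames = "tag_id") |>
    tidyr::pivot_longer(-"tag_id", names_to = "sample_id", values_to = "depth") |>
    dplyr::left_join(x$locations, by = "tag_id")
}

#' Per-sample missingness of a tag matrix
#'
#' Missingness of a sample is the fraction of tags with zero depth in it.
#'
#' @param tags a [tag_matrix()]
#' @return tibble with `sample_id`, `missingness`
#' @export
sample_missingness <- function(tags) {
  stopifnot(inherits(tags, "tag_matrix"))
  tibble::tibble(sample_id = tags$sample_ids,
                 missingness = colMeans(tags$counts == 0))
}

#' Binned tag-index container
#'
#' A `bin_index` holds the tag index (`sqrt(c) + d`) of every bin in every
#' sample, where `c` is the number of tags with nonzero depth in the bin and
#' `d` the summed reads-per-million depth of those tags. Rows are bins,
#' columns are samples. `scaled = TRUE` marks a per-bin min/max scaled matrix.
#'
#' @param values numeric matrix bins x samples
#' @param bins data frame of bin definitions: `chrom`, `start`, `end`,
#'   `label`, and optionally `diagnostic_for` (CDH name or `NA`),
#'   `single_copy` (logical), `type_specific` (Ab10 type or `NA`).
#' @param scaled logical
#' @return an object of class `bin_index`
#' @export
bin_index <- function(values, bins, scaled = FALSE) {
  values <- as.matrix(values)
  bins <- tibble::as_tibble(bins)
  need <- c("chrom", "start", "end", "label")
  if (!all(need %in% names(bins))) {
    abort(paste0("`bins` must have columns: ", paste(need, collapse = ", ")))
  }
  if (!"diagnostic_for" %in% names(bins)) bins$diagnostic_for <- NA_character_
  if (!"single_copy" %in% names(bins)) bins$single_copy <- FALSE
  if (nrow(values) != nrow(bins)) abort("values rows must match bins rows")
  if (scaled && (any(values < -1e-9) || any(values > 1 + 1e-9))) {
    abort("scaled values must lie in [0, 1]")
  }
  if (!scaled && any(values < 0)) abort("unscaled tag index must be >= 0")
  rownames(values) <- bins$label
  structure(list(values = values, bins = bins, scaled = scaled),
            class = "bin_index")
}

#' @export
print.bin_index <- function(x, ...) {
  cat(sprintf("<bin_index> %d bins x %d samples (%s)\n", nrow(x$values),
              ncol(x$values), if (x$scaled) "min/max scaled" else "unscaled"))
  invisible(x)
}

#' @rdname bin_index
#' @param x a `bin_index`
#' @param ... unused
#' @method tidy bin_index
#' @export
tidy.bin_index <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "label") |>
    tidyr::pivot_longer(-"label", names_to = "sample_id",
                        values_to = "tag_index") |>
    dplyr::left_join(x$bins, by = "label")
}

#' Restrict a bin index to the diagnostic bins of one CDH
#'
#' @param index a [bin_index()]
#' @param cdh CDH name ("Ab10", "K10L2" or "B")
#' @return a `bin_index` containing only bins with `diagnostic_for == cdh`
#' @export
diagnostic_bins <- function(index, cdh) {
  stopifnot(inherits(index, "bin_index"))
  keep <- !is.na(index$bins$diagnostic_for) & index$bins$diagnostic_for == cdh
  if (!any(keep)) abort(sprintf("no diagnostic bins for '%s'", cdh))
  bin_index(index$values[keep, , drop = FALSE], index$bins[keep, ],
            scaled = index$scaled)
}

# samples-by-bins matrix for clustering / PCA / random forest
sample_matrix <- function(index) t(index$values)
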