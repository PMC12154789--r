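#' Reads-per-million normalisation
#'
#' Scales each sample's tag counts to reads per million, so per-sample
#' depths sum to 1e6 over all tags. Libraries of different size become
#' comparable; this is the first step of the tag-index pipeline.
#'
#' @param tags a [tag_matrix()] with raw counts
#' @return a [tag_matrix()] with `normalized = TRUE`
#' @export
rpm_normalize <- function(tags) {
  stopifnot(inherits(tags, "tag_matrix"))
  if (tags$normalized) return(tags)
  totals <- colSums(tags$counts)
  if (any(totals == 0)) {
    abort(sprintf("sample '%s' has zero total reads; remove it before normalising",
                  tags$sample_ids[totals == 0][1]))
  }
  depths <- sweep(tags$counts, 2, 1e6 / totals, `*`)
  tag_matrix(depths, tags$locations, tags$sample_ids, normalized = TRUE)
}

#' Blank-derived missingness cutoff
#'
#' Blank wells contain no genomic DNA, so their (very high) missingness
#' reflects pure sequencing background. The cutoff for real samples is the
#' minimum blank missingness minus a small offset; any sample more missing
#' than this is indistinguishable from background and is removed by
#' [filter_samples_and_tags()].
#'
#' @param tags a [tag_matrix()]
#' @param manifest sample manifest identifying blanks
#' @param offset subtracted from the minimum blank missingness
#'   (default 0.001)
#' @param cutoff optional explicit cutoff; returned unchanged (required
#'   when the dataset has no blanks)
#' @return a single number in \[0, 1\]
#' @export
blank_missingness_cutoff <- function(tags, manifest, offset = 0.001,
                                     cutoff = NULL) {
  if (!is.null(cutoff)) return(assert_scalar_number(cutoff, "cutoff", 0, 1))
  blanks <- manifest$sample_id[manifest$sample_class == "blank"]
  blanks <- intersect(blanks, tags$sample_ids)
  if (length(blanks) == 0) {
    abort(paste0("no blank samples present; supply an explicit `cutoff` ",
                 "for the missingness filter"))
  }
  miss <- sample_missingness(tags)
  min(miss$missingness[miss$sample_id %in% blanks]) - offset
}

#' Filter samples by missingness and tags by mapping quality
#'
#' Removes samples whose missingness exceeds the (blank-derived) cutoff,
#' then tags with BWA mapping quality below `min_mapq` (a tag at exactly
#' `min_mapq` is kept). Removal counts are reported.
#'
#' @param tags a [tag_matrix()]
#' @param cutoff missingness cutoff in \[0, 1\]
#' @param min_mapq minimum mapping quality retained (default 20)
#' @return the filtered [tag_matrix()]
#' @export
filter_samples_and_tags <- function(tags, cutoff, min_mapq = 20) {
  stopifnot(inherits(tags, "tag_matrix"))
  assert_scalar_number(cutoff, "cutoff", 0, 1)
  miss <- colMeans(tags$counts == 0)
  keep_s <- miss <= cutoff
  if (!any(keep_s)) abort("missingness filter removed every sample")
  keep_t <- tags$locations$mapq >= min_mapq
  sum(!keep_s) %theninform% "removed %d sample(s) above the missingness cutoff"
  sum(!keep_t) %theninform% "removed %d tag(s) below the mapping-quality threshold"
  subset_tags(tags, tags = keep_t, samples = keep_s)
}

# index of the bin (row of `bins`) containing each tag's start, NA if none
assign_tags_to_bins <- function(locations, bins) {
  check_bins_nonoverlapping(bins)
  out <- rep(NA_integer_, nrow(locations))
  for (ch in unique(bins$chrom)) {
    bi <- which(bins$chrom == ch)
    b <- bins[bi, ]
    o <- order(b$start)
    bi <- bi[o]; b <- b[o, ]
    ti <- which(locations$chrom == ch)
    if (!length(ti)) next
    k <- findInterval(locations$start[ti], b$start)
    inside <- k >= 1 & locations$start[ti] < b$end[pmax(k, 1)]
    out[ti[inside]] <- bi[k[inside]]
  }
  out
}

#' Binned tag index
#'
#' For every bin and sample computes the tag index `sqrt(c) + d`, where `c`
#' is the number of tags in the bin with nonzero depth in that sample and
#' `d` is the summed (reads-per-million) depth of those tags. Tags are
#' assigned to the bin containing their start coordinate; tags falling in
#' no bin are ignored.
#'
#' @param tags a normalised [tag_matrix()] (see [rpm_normalize()]); raw
#'   counts are accepted with a warning, in which case `d` sums raw counts
#' @param bins bin definitions (non-overlapping)
#' @param count_mode `"present"` (default) counts only tags with nonzero
#'   depth in the sample toward `c`; `"all"` counts every tag in the bin
#' @return an unscaled [bin_index()]
#' @export
bin_tag_index <- function(tags, bins, count_mode = c("present", "all")) {
  stopifnot(inherits(tags, "tag_matrix"))
  count_mode <- match.arg(count_mode)
  bins <- tibble::as_tibble(bins)
  if (!tags$normalized) {
    warn("tag matrix is not RPM-normalised; `d` will sum raw counts")
  }
  bin_of <- assign_tags_to_bins(tags$locations, bins)
  keep <- !is.na(bin_of)
  f <- factor(bin_of[keep], levels = seq_len(nrow(bins)))
  depths <- tags$counts[keep, , drop = FALSE]
  d <- rowsum(depths, f)                      # summed depth per bin
  cc <- if (count_mode == "present") {
    rowsum((depths > 0) + 0, f)               # tags observed in the sample
  } else {
    matrix(as.numeric(table(f)), nrow(bins), ncol(depths))
  }
  values <- sqrt(cc) + d
  colnames(values) <- tags$sample_ids
  bin_index(values, bins, scaled = FALSE)
}

#' Min/max scale a bin index across samples
#'
#' Each bin (row) is scaled independently to \[0, 1\] across samples, which
#' is what makes presence/absence contrast visible across samples in the
#' heat map and comparable for clustering. A constant row maps to all
#' zeros so downstream clustering never sees missing values.
#'
#' @param index an unscaled [bin_index()]
#' @return a scaled [bin_index()]
#' @export
minmax_scale <- function(index) {
  stopifnot(inherits(index, "bin_index"))
  if (index$scaled) abort("bin index is already scaled")
  v <- index$values
  rng <- apply(v, 1, range)
  span <- rng[2, ] - rng[1, ]
  scaled <- (v - rng[1, ]) / ifelse(span > 0, span, 1)
  scaled[span == 0, ] <- 0
  bin_index(scaled, index$bins, scaled = TRUE)
}

#' Build 1 Mb bins of single-copy gene sequence
#'
#' Walks single-copy gene intervals in coordinate order and emits a bin
#' boundary every `bin_size` of cumulative covered gene sequence -- bins
#' are 1 Mb of gene sequence, not of genomic coordinates, and may span
#' large genomic distances. A final partial bin is emitted only when it is
#' at least half full.
#'
#' @param gene_intervals tibble `chrom`, `start`, `end` of single-copy
#'   genes, non-overlapping within a chromosome
#' @param bin_size target cumulative gene sequence per bin (default 1e6)
#' @return a tibble of bin definitions with `single_copy = TRUE`
#' @export
single_copy_gene_bins <- function(gene_intervals, bin_size = 1e6) {
  g <- tibble::as_tibble(gene_intervals)
  check_bins_nonoverlapping(
    tibble::tibble(chrom = g$chrom, start = g$start, end = g$end,
                   label = as.character(seq_len(nrow(g)))))
  out <- list()
  for (ch in unique(g$chrom)) {
    gi <- g[g$chrom == ch, ]
    gi <- gi[order(gi$start), ]
    acc <- 0; bin_start <- NA_real_; k <- 0L
    for (i in seq_len(nrow(gi))) {
      s <- gi$start[i]; e <- gi$end[i]
      if (is.na(bin_start)) bin_start <- s
      while (acc + (e - s) >= bin_size) {
        cut <- s + (bin_size - acc)
        k <- k + 1L
        out[[length(out) + 1L]] <- tibble::tibble(
          chrom = ch, start = as.integer(bin_start), end = as.integer(cut),
          label = sprintf("%s_sc%02d", ch, k), gene_bp = bin_size)
        s <- cut; acc <- 0; bin_start <- if (s < e) s else NA_real_
      }
      if (s < e) { acc <- acc + (e - s) }
    }
    if (acc >= bin_size / 2 && !is.na(bin_start)) {
      k <- k + 1L
      out[[length(out) + 1L]] <- tibble::tibble(
        chrom = ch, start = as.integer(bin_start),
        end = as.integer(gi$end[nrow(gi)]),
        label = sprintf("%s_sc%02d", ch, k), gene_bp = acc)
    }
  }
  if (!length(out)) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), label = character(),
                          gene_bp = numeric(), diagnostic_for = character(),
                          single_copy = logical()))
  }
  res <- dplyr::bind_rows(out)
  res$diagnostic_for <- NA_character_
  res$single_copy <- TRUE
  res
}
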