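#' Pseudo copy number by single-copy-gene normalisation
#'
#' Divides each sample's mean unscaled tag index over a CDH's diagnostic
#' bins by its mean unscaled tag index over single-copy core-gene bins.
#' The ratio tracks relative dosage of the CDH; it is reported as a
#' continuous "pseudo" copy number, never rounded to integers.
#'
#' @param index unscaled [bin_index()] over the CDH diagnostic bins (a
#'   full index is accepted; diagnostic bins are selected via
#'   `diagnostic_for`)
#' @param sc_index unscaled [bin_index()] over the single-copy bins (a
#'   full index is accepted; bins with `single_copy = TRUE` are used)
#' @param cdh CDH name
#' @return tibble `sample_id`, `cdh`, `cdh_mean_index`,
#'   `single_copy_mean_index`, `pseudo_copy_number`, `flag`
#'   (`"unknown"` where the single-copy mean is zero)
#' @export
pseudo_copy_number <- function(index, sc_index, cdh) {
  stopifnot(inherits(index, "bin_index"), inherits(sc_index, "bin_index"))
  if (index$scaled || sc_index$scaled) {
    abort("pseudo copy number requires unscaled tag indices")
  }
  di <- diagnostic_bins(index, cdh)
  sc_rows <- sc_index$bins$single_copy
  scv <- if (any(sc_rows)) sc_index$values[sc_rows, , drop = FALSE]
         else sc_index$values
  samples <- intersect(colnames(di$values), colnames(scv))
  if (!length(samples)) abort("no shared samples between the two indices")
  cdh_mean <- colMeans(di$values[, samples, drop = FALSE])
  sc_mean <- colMeans(scv[, samples, drop = FALSE])
  ratio <- ifelse(sc_mean > 0, cdh_mean / sc_mean, NA_real_)
  tibble::tibble(sample_id = samples, cdh = cdh,
                 cdh_mean_index = unname(cdh_mean),
                 single_copy_mean_index = unname(sc_mean),
                 pseudo_copy_number = unname(ratio),
                 flag = unname(ifelse(sc_mean > 0, NA_character_, "unknown")))
}

#' Classify zygosity from control pseudo copy numbers
#'
#' For chromosome-10 CDHs, the hom/het threshold is the midpoint of the
#' mean pseudo copy number of known heterozygous (low copy class) and
#' homozygous (high copy class) controls; a sample at or above the
#' midpoint is called homozygous. With either control class missing,
#' zygosity is unknown.
#'
#' @param estimates tibble from [pseudo_copy_number()]
#' @param manifest sample manifest providing control copy classes
#' @param cdh CDH name (threshold is built from that CDH's controls)
#' @return `estimates` with added `zygosity` ("hom"/"het"/"unknown") and
#'   the threshold as attribute `"threshold"`
#' @export
classify_zygosity <- function(estimates, manifest, cdh = estimates$cdh[1]) {
  ctrl <- manifest[manifest$sample_class == "control" &
                     manifest[[cdh]] == "positive", ]
  pick <- function(cl) {
    ids <- ctrl$sample_id[ctrl$copy_class == cl]
    v <- estimates$pseudo_copy_number[estimates$sample_id %in% ids]
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  }
  het <- pick("low"); hom <- pick("high")
  if (is.na(het) || is.na(hom)) {
    estimates$zygosity <- "unknown"
    attr(estimates, "threshold") <- NA_real_
    return(estimates)
  }
  thr <- (het + hom) / 2
  estimates$zygosity <- dplyr::case_when(
    is.na(estimates$pseudo_copy_number) ~ "unknown",
    estimates$pseudo_copy_number >= thr ~ "hom",
    TRUE ~ "het")
  attr(estimates, "threshold") <- thr
  estimates
}
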