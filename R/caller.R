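# Control-anchored iterative k-means presence/absence calling.
#
# Every clustering round runs k-means (k = 2) on per-sample vectors of the
# min/max scaled tag index over a CDH's diagnostic bins. Clusters are named
# positive/negative from their control members only (80% purity rule);
# experimental samples inherit the label of their cluster; repeated rounds
# are tallied into a consensus call.

control_status <- function(manifest, cdh) {
  ctrl <- manifest[manifest$sample_class == "control", ]
  setNames(ctrl[[cdh]], ctrl$sample_id)
}

#' Automatic selection of diagnostic bins
#'
#' Flags bins whose mean scaled tag index differs between CDH-positive and
#' CDH-negative controls by at least `min_diff`, operationalising the
#' regions of stark contrast used for clustering.
#'
#' @param index scaled [bin_index()]
#' @param manifest sample manifest
#' @param cdh CDH name
#' @param min_diff minimum absolute difference of control-group means
#'   (default 0.5)
#' @return character vector of bin labels
#' @export
select_diagnostic_bins <- function(index, manifest, cdh, min_diff = 0.5) {
  stopifnot(inherits(index, "bin_index"), index$scaled)
  st <- control_status(manifest, cdh)
  pos <- intersect(names(st)[st == "positive"], colnames(index$values))
  neg <- intersect(names(st)[st == "negative"], colnames(index$values))
  if (!length(pos) || !length(neg)) {
    abort(sprintf("need positive and negative '%s' controls to select bins", cdh))
  }
  diff <- abs(rowMeans(index$values[, pos, drop = FALSE]) -
                rowMeans(index$values[, neg, drop = FALSE]))
  index$bins$label[diff >= min_diff]
}

#' Name k-means clusters from their control members
#'
#' A cluster is labelled positive (or negative) only when at least
#' `purity` of its control members share that status. A round in which
#' both clusters receive the same label, either cluster is unnamed, or a
#' cluster holds no controls, is invalid.
#'
#' @param assignments named integer vector, sample id -> cluster (1 or 2)
#' @param truth named character vector of control statuses
#'   ("positive"/"negative"); non-control samples are simply absent
#' @param purity minimum control purity to name a cluster (default 0.80)
#' @return list with `labels` (named character, "positive"/"negative"/
#'   "unnamed" per cluster) and `valid` (logical)
#' @export
name_clusters <- function(assignments, truth, purity = 0.80) {
  labels <- c(`1` = "unnamed", `2` = "unnamed")
  for (cl in c(1L, 2L)) {
    members <- names(assignments)[assignments == cl]
    ctrl <- members[members %in% names(truth)]
    if (!length(ctrl)) next     # zero controls: stays unnamed, round invalid
    frac_pos <- mean(truth[ctrl] == "positive")
    if (frac_pos >= purity) labels[cl] <- "positive"
    else if (1 - frac_pos >= purity) labels[cl] <- "negative"
  }
  valid <- !any(labels == "unnamed") && labels[1] != labels[2]
  list(labels = labels, valid = valid)
}

kmeans2 <- function(x) {
  tryCatch(kmeans(x, centers = 2, nstart = 10),
           error = function(e) NULL)
}

#' Validate controls by repeated subgroup k-means
#'
#' Splits the control panel (positive controls of one copy class plus all
#' negative controls) into random subgroups, clusters each with k-means
#' (k = 2), names clusters by control purity, and scores each control
#' against its known status. Repeated `n_reps` times with fresh random
#' splits; reports the fraction of repetitions each control was called
#' correctly. High and low copy-class controls are validated separately so
#' clustering reflects presence/absence rather than copy number; a copy
#' class too small to split is clustered as a single group.
#'
#' @param index scaled [bin_index()] (diagnostic bins are selected via
#'   `diagnostic_for`)
#' @param manifest sample manifest
#' @param cdh CDH name
#' @param copy_class "high" or "low"
#' @param n_subgroups number of random subgroups (default 3)
#' @param n_reps repetitions (default 100)
#' @param purity cluster-naming purity (default 0.80)
#' @param seed integer seed
#' @return tibble `sample_id`, `status`, `copy_class`, `accuracy`
#' @export
control_validation <- function(index, manifest, cdh, copy_class,
                               n_subgroups = 3, n_reps = 100,
                               purity = 0.80, seed = 1) {
  stopifnot(inherits(index, "bin_index"), index$scaled)
  x <- sample_matrix(diagnostic_bins(index, cdh))
  ctrl <- manifest[manifest$sample_class == "control", ]
  pos <- ctrl$sample_id[ctrl[[cdh]] == "positive" &
                          ctrl$copy_class == copy_class]
  neg <- ctrl$sample_id[ctrl[[cdh]] == "negative"]
  pos <- intersect(pos, rownames(x)); neg <- intersect(neg, rownames(x))
  if (length(pos) < 2 || length(neg) < 2) {
    abort(sprintf("need >= 2 positive (%s copy) and >= 2 negative '%s' controls",
                  copy_class, cdh))
  }
  ids <- c(pos, neg)
  truth <- setNames(rep(c("positive", "negative"), c(length(pos), length(neg))),
                    ids)
  # a copy class too small to guarantee 2 of each status per subgroup is
  # clustered as a single group
  k <- if (length(pos) < 2 * n_subgroups || length(neg) < 2 * n_subgroups)
    1L else n_subgroups
  set.seed(seed)
  correct <- setNames(numeric(length(ids)), ids)
  for (rep_i in seq_len(n_reps)) {
    grp <- sample(rep_len(seq_len(k), length(ids)))
    # merge any subgroup short of 2 controls of either status into the next
    repeat {
      tab_pos <- tabulate(grp[truth[ids] == "positive"], k)
      tab_neg <- tabulate(grp[truth[ids] == "negative"], k)
      bad <- which(tab_pos < 2 | tab_neg < 2)
      bad <- bad[tab_pos[bad] + tab_neg[bad] > 0]
      if (!length(bad) || length(unique(grp)) == 1L) break
      tgt <- if (bad[1] == max(grp)) bad[1] - 1L else bad[1] + 1L
      grp[grp == bad[1]] <- tgt
    }
    for (g in unique(grp)) {
      members <- ids[grp == g]
      km <- kmeans2(x[members, , drop = FALSE])
      if (is.null(km)) next     # degenerate subgroup: scored incorrect
      assignments <- setNames(km$cluster, members)
      nm <- name_clusters(assignments, truth, purity)
      if (!nm$valid) next
      called <- nm$labels[assignments]
      correct[members] <- correct[members] + (called == truth[members])
    }
  }
  tibble::tibble(sample_id = ids, status = unname(truth),
                 copy_class = copy_class, accuracy = unname(correct) / n_reps)
}

#' Validate high- and low-copy controls for one CDH
#'
#' Runs [control_validation()] for each copy class that has positive
#' controls and binds the results.
#'
#' @inheritParams control_validation
#' @param ... passed to [control_validation()]
#' @export
validate_controls <- function(index, manifest, cdh, ..., seed = 1) {
  ctrl <- manifest[manifest$sample_class == "control" &
                     manifest[[cdh]] == "positive", ]
  classes <- intersect(c("high", "low"), unique(ctrl$copy_class))
  if (!length(classes)) abort(sprintf("no positive '%s' controls", cdh))
  purrr::map_dfr(classes, function(cl) {
    control_validation(index, manifest, cdh, copy_class = cl, ...,
                       seed = derive_seed(seed, paste0(cdh, cl)))
  })
}

# One clustering round on a chunk of experimental samples. Draws roughly
# equal numbers of positive and negative controls, clusters controls +
# chunk, names clusters, and redraws controls until every control is
# correctly identified (up to retry_cap). Returns NULL when abandoned.
one_round <- function(x, pos_pool, neg_pool, chunk, truth, purity,
                      retry_cap) {
  n_draw <- min(length(pos_pool), length(neg_pool))
  for (try_i in seq_len(retry_cap)) {
    ctrls <- c(sample(pos_pool, n_draw), sample(neg_pool, n_draw))
    members <- c(ctrls, chunk)
    km <- kmeans2(x[members, , drop = FALSE])
    if (is.null(km)) next
    assignments <- setNames(km$cluster, members)
    nm <- name_clusters(assignments, truth, purity)
    if (!nm$valid) next
    called <- nm$labels[assignments[ctrls]]
    if (!all(called == truth[ctrls])) next
    return(list(calls = setNames(nm$labels[assignments[chunk]], chunk),
                n_controls = length(ctrls), retries = try_i - 1L))
  }
  NULL
}

#' One experimental clustering round
#'
#' Clusters a chunk of experimental samples together with a fresh random
#' draw of roughly equal positive/negative controls, and assigns each
#' experimental sample the label of its cluster. The chunk may hold at most
#' `spike_fraction` times the number of controls drawn. If any control
#' lands in the wrong cluster the round is redone with a fresh control
#' draw, up to `retry_cap` times.
#'
#' @param index scaled [bin_index()]
#' @param manifest sample manifest
#' @param cdh CDH name
#' @param exp_ids experimental sample ids to spike in
#' @param spike_fraction maximum experimental fraction of the control count
#'   (0.25 for chromosome-10 CDHs, 0.10 for the B chromosome)
#' @param copy_class which positive-control copy class anchors the round
#'   ("low" default; experimental carriers are mostly heterozygous)
#' @param purity cluster-naming purity
#' @param retry_cap redraw cap before the round is abandoned
#' @param seed optional seed
#' @return list with `calls` (named character or `NULL` if abandoned) and
#'   `valid`
#' @export
experimental_round <- function(index, manifest, cdh, exp_ids,
                               spike_fraction = 0.25, copy_class = "low",
                               purity = 0.80, retry_cap = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pools <- caller_pools(index, manifest, cdh, copy_class)
  n_controls <- 2 * min(length(pools$pos), length(pools$neg))
  cap <- max(1L, floor(spike_fraction * n_controls))
  if (length(exp_ids) > cap) {
    abort(sprintf("at most %d experimental samples allowed per round (%d controls, spike %.2f)",
                  cap, n_controls, spike_fraction))
  }
  r <- one_round(pools$x, pools$pos, pools$neg, exp_ids, pools$truth,
                 purity, retry_cap)
  if (is.null(r)) return(list(calls = NULL, valid = FALSE))
  list(calls = r$calls, valid = TRUE)
}

caller_pools <- function(index, manifest, cdh, copy_class) {
  x <- sample_matrix(diagnostic_bins(index, cdh))
  ctrl <- manifest[manifest$sample_class == "control", ]
  pos <- ctrl$sample_id[ctrl[[cdh]] == "positive" &
                          (copy_class == "any" | ctrl$copy_class == copy_class)]
  neg <- ctrl$sample_id[ctrl[[cdh]] == "negative"]
  pos <- intersect(pos, rownames(x)); neg <- intersect(neg, rownames(x))
  if (length(pos) < 2 || length(neg) < 2) {
    abort(sprintf("need >= 2 positive and >= 2 negative '%s' controls", cdh))
  }
  truth <- setNames(rep(c("positive", "negative"),
                        c(length(pos), length(neg))), c(pos, neg))
  list(x = x, pos = pos, neg = neg, truth = truth)
}

#' Consensus call from round tallies
#'
#' The final call is the majority class when its fraction of recorded
#' rounds reaches `threshold` (default 0.95); otherwise the sample is
#' ambiguous. A sample with zero recorded rounds is ambiguous and flagged.
#'
#' @param state tibble with `sample_id`, `positive`, `negative` round
#'   tallies
#' @param threshold consensus threshold (default 0.95)
#' @return call-table tibble: `sample_id`, `call`, `consensus_fraction`,
#'   `n_rounds`, `flag`
#' @export
consensus_call <- function(state, threshold = 0.95) {
  state$positive <- unname(state$positive)
  state$negative <- unname(state$negative)
  state$sample_id <- unname(state$sample_id)
  n <- state$positive + state$negative
  frac <- ifelse(n > 0, pmax(state$positive, state$negative) / n, NA_real_)
  majority <- ifelse(state$positive >= state$negative, "positive", "negative")
  call <- dplyr::case_when(
    n == 0 ~ "ambiguous",
    frac >= threshold ~ majority,
    TRUE ~ "ambiguous")
  tibble::tibble(sample_id = state$sample_id, call = call,
                 consensus_fraction = frac, n_rounds = as.integer(n),
                 flag = ifelse(n == 0, "no_calls", NA_character_))
}

#' Iterative consensus calling of one CDH
#'
#' Runs the full calling loop: in each of `rounds` passes every
#' experimental sample is spiked (in chunks no larger than
#' `spike_fraction` times the control count) into a k-means round anchored
#' by a fresh random control draw, and inherits its cluster's label.
#' Valid calls are tallied and summarised by [consensus_call()]. Chunks
#' whose round is abandoned (retry cap) record no call for that pass.
#'
#' @inheritParams experimental_round
#' @param rounds target number of recorded calls per sample (default 125)
#' @param consensus consensus threshold (default 0.95)
#' @param seed integer seed; fixes the whole run
#' @return call-table tibble with `cdh` column
#' @export
call_cdh <- function(index, manifest, cdh, exp_ids = NULL, rounds = 125,
                     consensus = 0.95, purity = 0.80, spike_fraction = 0.25,
                     copy_class = "low", retry_cap = 50, seed = 1) {
  stopifnot(inherits(index, "bin_index"), index$scaled)
  pools <- caller_pools(index, manifest, cdh, copy_class)
  if (is.null(exp_ids)) {
    exp_ids <- manifest$sample_id[manifest$sample_class == "experimental"]
    exp_ids <- intersect(exp_ids, rownames(pools$x))
  }
  if (!length(exp_ids)) {
    return(tibble::tibble(sample_id = character(), cdh = character(),
                          call = character(), consensus_fraction = double(),
                          n_rounds = integer(), flag = character()))
  }
  n_controls <- 2 * min(length(pools$pos), length(pools$neg))
  cap <- max(1L, floor(spike_fraction * n_controls))
  set.seed(seed)
  tally <- matrix(0L, length(exp_ids), 2,
                  dimnames = list(exp_ids, c("positive", "negative")))
  for (pass in seq_len(rounds)) {
    ord <- sample(exp_ids)
    chunks <- split(ord, ceiling(seq_along(ord) / cap))
    for (chunk in chunks) {
      r <- one_round(pools$x, pools$pos, pools$neg, chunk, pools$truth,
                     purity, retry_cap)
      if (is.null(r)) next      # abandoned: these samples miss this pass
      for (lab in c("positive", "negative")) {
        hit <- names(r$calls)[r$calls == lab]
        tally[hit, lab] <- tally[hit, lab] + 1L
      }
    }
  }
  state <- tibble::tibble(sample_id = rownames(tally),
                          positive = tally[, "positive"],
                          negative = tally[, "negative"])
  out <- consensus_call(state, consensus)
  tibble::add_column(out, cdh = cdh, .after = "sample_id")
}

#' Sequential chromosome-10 workflow
#'
#' The Ab10 pipeline cannot detect K10L2 and the K10L2 pipeline cannot
#' distinguish Ab10 from K10L2, so Ab10 is called first and only
#' Ab10-negative samples are assayed for K10L2. Ab10-positive samples get
#' a K10L2 call of "unknown"; Ab10-ambiguous samples are excluded from the
#' K10L2 stage by default.
#'
#' @param index_ab10,index_k10l2 scaled [bin_index()] objects carrying the
#'   Ab10 and K10L2 diagnostic bins (may be the same object)
#' @param manifest sample manifest
#' @param include_ambiguous run Ab10-ambiguous samples through the K10L2
#'   stage (default `FALSE`)
#' @param ... passed to [call_cdh()] (rounds, consensus, purity,
#'   spike_fraction, copy_class, retry_cap)
#' @param seed master seed; the two stages use derived sub-seeds
#' @return call-table tibble covering both CDHs
#' @export
chr10_workflow <- function(index_ab10, index_k10l2, manifest,
                           include_ambiguous = FALSE, ..., seed = 1) {
  ab10 <- call_cdh(index_ab10, manifest, "Ab10", ...,
                   seed = derive_seed(seed, "Ab10"))
  carry <- ab10$sample_id[ab10$call == "negative" |
                            (include_ambiguous & ab10$call == "ambiguous")]
  k10 <- call_cdh(index_k10l2, manifest, "K10L2", exp_ids = carry, ...,
                  seed = derive_seed(seed, "K10L2"))
  skipped <- setdiff(ab10$sample_id, carry)
  if (length(skipped)) {
    k10 <- dplyr::bind_rows(k10, tibble::tibble(
      sample_id = skipped, cdh = "K10L2", call = "unknown",
      consensus_fraction = NA_real_, n_rounds = 0L,
      flag = "not_assayed_ab10_stage"))
  }
  dplyr::bind_rows(ab10, k10) |> dplyr::arrange(.data$cdh, .data$sample_id)
}

#' Two-stage B chromosome workflow
#'
#' High-copy B samples can form their own k-means cluster and derail a
#' single-stage analysis, so calling proceeds in two stages: first with
#' high-copy controls to extract high-copy positives, then all samples not
#' called positive are re-assayed with low-copy controls. The final call
#' is positive if positive at either stage, otherwise the stage-2 result.
#'
#' @param index_b scaled [bin_index()] with the B diagnostic bins
#' @param manifest sample manifest
#' @param spike_fraction experimental fraction per round (default 0.10 for
#'   the B chromosome)
#' @param ... passed to [call_cdh()]
#' @param seed master seed
#' @return call-table tibble with a `stage` column
#' @export
b_two_stage_workflow <- function(index_b, manifest, spike_fraction = 0.10,
                                 ..., seed = 1) {
  s1 <- call_cdh(index_b, manifest, "B", spike_fraction = spike_fraction,
                 copy_class = "high", ..., seed = derive_seed(seed, "Bhigh"))
  s1$stage <- 1L
  redo <- s1$sample_id[s1$call != "positive"]
  s2 <- call_cdh(index_b, manifest, "B", exp_ids = redo,
                 spike_fraction = spike_fraction, copy_class = "low", ...,
                 seed = derive_seed(seed, "Blow"))
  s2$stage <- 2L
  dplyr::bind_rows(s1[s1$call == "positive", ], s2) |>
    dplyr::arrange(.data$sample_id)
}
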