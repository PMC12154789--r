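#' Train the random-forest Ab10 type classifier
#'
#' Fits a random forest to the scaled tag index of the Ab10 diagnostic
#' bins of typed control samples, using a stratified 70/30 split, and
#' reports holdout accuracy on the 30%.
#'
#' @param index scaled [bin_index()] (Ab10 diagnostic bins selected
#'   automatically)
#' @param manifest sample manifest; controls with `ab10_type` in I/II/III
#'   are used
#' @param train_frac training fraction (default 0.70)
#' @param ntree forest size (default 500)
#' @param seed integer seed
#' @return an object of class `ab10_typer`: list with `model`,
#'   `holdout` (tibble of holdout truth and calls), `holdout_accuracy`,
#'   `train_ids`, `test_ids`, `bins`
#' @export
train_typer <- function(index, manifest, train_frac = 0.70, ntree = 500,
                        seed = 1) {
  stopifnot(inherits(index, "bin_index"), index$scaled)
  x <- sample_matrix(diagnostic_bins(index, "Ab10"))
  ctrl <- manifest[manifest$sample_class == "control" &
                     manifest$ab10_type %in% c("I", "II", "III"), ]
  ids <- intersect(ctrl$sample_id, rownames(x))
  if (length(ids) < 6) abort("need at least 6 typed Ab10 controls")
  types <- setNames(ctrl$ab10_type[match(ids, ctrl$sample_id)], ids)
  set.seed(seed)
  train_ids <- unlist(lapply(split(ids, types[ids]), function(g) {
    sample(g, max(2L, round(train_frac * length(g))))
  }), use.names = FALSE)
  test_ids <- setdiff(ids, train_ids)
  if (length(unique(types[train_ids])) < length(unique(types[ids]))) {
    abort("a type is absent from the training split; re-stratify")
  }
  if (min(table(types[train_ids])) < 2) {
    abort("need >= 2 training samples of each type")
  }
  model <- randomForest::randomForest(
    x = x[train_ids, , drop = FALSE],
    y = factor(types[train_ids], levels = c("I", "II", "III")),
    ntree = ntree)
  holdout_calls <- if (length(test_ids)) {
    as.character(predict(model, x[test_ids, , drop = FALSE]))
  } else character()
  holdout <- tibble::tibble(sample_id = test_ids,
                            truth = unname(types[test_ids]),
                            call = holdout_calls)
  structure(list(model = model, holdout = holdout,
                 holdout_accuracy = if (nrow(holdout))
                   mean(holdout$call == holdout$truth) else NA_real_,
                 train_ids = train_ids, test_ids = test_ids,
                 bins = colnames(x)),
            class = "ab10_typer")
}

#' @export
print.ab10_typer <- function(x, ...) {
  cat(sprintf("<ab10_typer> %d trees, %d bins; holdout accuracy %.3f (%d samples)\n",
              x$model$ntree, length(x$bins), x$holdout_accuracy,
              nrow(x$holdout)))
  invisible(x)
}

#' @rdname train_typer
#' @param x an `ab10_typer`
#' @param ... unused
#' @method glance ab10_typer
#' @export
glance.ab10_typer <- function(x, ...) {
  tibble::tibble(n_train = length(x$train_ids), n_test = length(x$test_ids),
                 ntree = x$model$ntree, n_bins = length(x$bins),
                 holdout_accuracy = x$holdout_accuracy)
}

#' Call Ab10 types by forest vote
#'
#' A sample is assigned the type voted by the largest fraction of trees
#' when that fraction reaches `vote_threshold` (default 0.65, boundary
#' inclusive); otherwise the haplotype is classified ambiguous.
#'
#' @param typer an [train_typer()] result
#' @param index scaled [bin_index()] carrying the samples to type
#' @param sample_ids samples to type (default: all columns of `index`)
#' @param vote_threshold minimum vote fraction for a type call
#' @return tibble `sample_id`, `vote_I`, `vote_II`, `vote_III`, `top`,
#'   `call`
#' @export
call_types <- function(typer, index, sample_ids = NULL,
                       vote_threshold = 0.65) {
  stopifnot(inherits(typer, "ab10_typer"))
  x <- sample_matrix(diagnostic_bins(index, "Ab10"))
  if (!is.null(sample_ids)) x <- x[sample_ids, , drop = FALSE]
  x <- x[, typer$bins, drop = FALSE]
  votes <- predict(typer$model, x, type = "vote")   # fractions, rows sum to 1
  top_i <- max.col(votes, ties.method = "first")
  top_frac <- votes[cbind(seq_len(nrow(votes)), top_i)]
  top <- colnames(votes)[top_i]
  tibble::tibble(sample_id = rownames(x),
                 vote_I = unname(votes[, "I"]),
                 vote_II = unname(votes[, "II"]),
                 vote_III = unname(votes[, "III"]), top = top,
                 call = ifelse(top_frac >= vote_threshold, top, "ambiguous"))
}

#' PCA on top Gini-importance bins
#'
#' Ranks bins by the forest's mean decrease in Gini impurity, keeps the
#' `top_k` most important (in their original genomic order), and runs a
#' principal component analysis of the scaled tag index over those bins.
#'
#' @param typer an [train_typer()] result
#' @param index scaled [bin_index()]
#' @param top_k number of bins to keep (>= 2)
#' @param sample_ids samples to score (default all)
#' @return list with `scores` (tibble `sample_id`, `PC1`, ...) and
#'   `variance_explained` (numeric vector summing to 1)
#' @export
gini_pca <- function(typer, index, top_k = 25, sample_ids = NULL) {
  stopifnot(inherits(typer, "ab10_typer"))
  if (top_k < 2) abort("top_k must be >= 2")
  imp <- randomForest::importance(typer$model)[, "MeanDecreaseGini"]
  top_k <- min(top_k, length(imp))
  sel <- names(sort(imp, decreasing = TRUE))[seq_len(top_k)]
  x <- sample_matrix(diagnostic_bins(index, "Ab10"))
  if (!is.null(sample_ids)) x <- x[sample_ids, , drop = FALSE]
  x <- x[, typer$bins[typer$bins %in% sel], drop = FALSE]  # original order
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- tibble::as_tibble(pc$x) |>
    tibble::add_column(sample_id = rownames(x), .before = 1)
  list(scores = scores, variance_explained = var_frac)
}
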