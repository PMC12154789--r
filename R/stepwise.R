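# Stepwise GLM simplification and deviance partitioning across the three
# variable classes (population structure, genetic loci, environment).

# Wald test of a whole model term (multi-df for factors); aliased
# coefficients are ignored.
wald_term_p <- function(fit, var) {
  labs <- attr(stats::terms(fit), "term.labels")
  asgn <- attr(stats::model.matrix(fit), "assign")
  cols <- which(asgn == which(labs == var))
  b <- coef(fit)[cols]
  keep <- !is.na(b)
  if (!any(keep)) return(1)
  b <- b[keep]; cols <- cols[keep]
  v <- vcov(fit)[cols, cols, drop = FALSE]
  w <- tryCatch(drop(t(b) %*% solve(v, b)), error = function(e) 0)
  pchisq(w, df = length(b), lower.tail = FALSE)
}

term_p_values <- function(fit, vars, test) {
  if (test == "wald") {
    vapply(vars, function(v) wald_term_p(fit, v), 0)
  } else {
    d1 <- stats::drop1(fit, test = "Chisq")
    p <- d1[["Pr(>Chi)"]]
    setNames(p[match(vars, rownames(d1))], vars)
  }
}

deviance_explained <- function(fit) {
  if (fit$null.deviance <= 0) return(0)
  (fit$null.deviance - fit$deviance) / fit$null.deviance
}

#' Stepwise GLM simplification over variable classes
#'
#' Starting from the full model over all supplied variables, repeatedly
#' drops the single worst term (largest p-value above `alpha`), refits,
#' and stops when every remaining term is significant at `alpha`. Ties are
#' broken deterministically: largest p first, then canonical (sorted) name
#' order -- so the result does not depend on the order in which variables
#' are supplied (see [check_order_invariance()]). Only complete cases are
#' used so the null model is identical across refits.
#'
#' @param data data frame holding the response and all variables
#' @param response name of the response column (0/1 for binomial)
#' @param classes named list of character vectors assigning each variable
#'   to a class, e.g. `list(structure = ..., genetic = ...,
#'   environment = ...)`
#' @param family `"binomial"` (logit) or `"gaussian"`
#' @param alpha retention threshold (default 0.01)
#' @param test `"wald"` (default) or `"lrt"` for term p-values
#' @return an object of class `cdh_glm`: the final [stats::glm] fit plus
#'   the surviving terms per class, the drop history, and the deviance
#'   explained
#' @export
stepwise_glm <- function(data, response, classes,
                         family = c("binomial", "gaussian"), alpha = 0.01,
                         test = c("wald", "lrt")) {
  family <- match.arg(family); test <- match.arg(test)
  vars <- unlist(classes, use.names = FALSE)
  if (anyDuplicated(vars)) abort("a variable appears in more than one class")
  missing_vars <- setdiff(c(response, vars), names(data))
  if (length(missing_vars)) {
    abort(paste0("variables absent from `data`: ",
                 paste(missing_vars, collapse = ", ")))
  }
  df <- tibble::as_tibble(data)[, c(response, vars)]
  df <- df[complete.cases(df), ]
  fam <- if (family == "binomial") binomial() else gaussian()
  fit_with <- function(v) {
    fml <- stats::reformulate(if (length(v)) v else "1", response = response)
    fit <- glm(fml, data = df, family = fam)
    if (!fit$converged) {
      abort(paste0("GLM did not converge with terms: ",
                   paste(v, collapse = ", ")))
    }
    fit
  }
  current <- sort(vars)     # canonical order makes tie-breaks deterministic
  history <- tibble::tibble(step = integer(), dropped = character(),
                            p = double())
  fit <- fit_with(current)
  step_i <- 0L
  while (length(current)) {
    p <- term_p_values(fit, current, test)
    bad <- p[p > alpha]
    if (!length(bad)) break
    worst <- names(bad)[order(-bad, names(bad))][1]
    step_i <- step_i + 1L
    history <- dplyr::add_row(history, step = step_i, dropped = worst,
                              p = unname(bad[worst]))
    current <- setdiff(current, worst)
    fit <- fit_with(current)
  }
  final_p <- if (length(current)) term_p_values(fit, current, test) else
    setNames(numeric(), character())
  var_class <- setNames(rep(names(classes), lengths(classes)),
                        unlist(classes, use.names = FALSE))
  structure(list(
    fit = fit,
    terms = tibble::tibble(variable = current,
                           class = unname(var_class[current]),
                           p = unname(final_p)),
    classes = lapply(classes, intersect, current),
    input_classes = classes,
    history = history,
    data = df, response = response, family = family, alpha = alpha,
    test = test,
    deviance_explained = deviance_explained(fit)),
    class = "cdh_glm")
}

#' @export
print.cdh_glm <- function(x, ...) {
  cat(sprintf("<cdh_glm> %s model of '%s': %d surviving terms, %.1f%% deviance explained\n",
              x$family, x$response, nrow(x$terms),
              100 * x$deviance_explained))
  invisible(x)
}

#' @rdname stepwise_glm
#' @param x a `cdh_glm`
#' @param ... unused
#' @method tidy cdh_glm
#' @export
tidy.cdh_glm <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  labs <- attr(stats::terms(x$fit), "term.labels")
  asgn <- attr(stats::model.matrix(x$fit), "assign")
  keep <- !is.na(coef(x$fit))
  var_class <- setNames(x$terms$class, x$terms$variable)
  variable <- c("(Intercept)", labs)[asgn[keep] + 1]
  tibble::tibble(term = rownames(cf),
                 variable = variable,
                 class = dplyr::coalesce(var_class[variable], NA_character_),
                 estimate = cf[, 1], std.error = cf[, 2],
                 statistic = cf[, 3], p.value = cf[, 4])
}

#' @rdname stepwise_glm
#' @method glance cdh_glm
#' @export
glance.cdh_glm <- function(x, ...) {
  tibble::tibble(family = x$family,
                 nobs = nrow(x$data),
                 n_terms = nrow(x$terms),
                 null_deviance = x$fit$null.deviance,
                 residual_deviance = x$fit$deviance,
                 deviance_explained = x$deviance_explained,
                 aic = x$fit$aic)
}

#' Check robustness of the stepwise result to variable order
#'
#' Re-runs [stepwise_glm()] under random permutations of the variable
#' order and reports whether the final term set is identical each time.
#'
#' @param object a [stepwise_glm()] result
#' @param n_perm number of permutations (default 10)
#' @param seed integer seed
#' @return `TRUE` (invisibly) if all permutations agree; otherwise a
#'   warning is raised and `FALSE` returned
#' @export
check_order_invariance <- function(object, n_perm = 10, seed = 1) {
  stopifnot(inherits(object, "cdh_glm"))
  base <- sort(object$terms$variable)
  set.seed(seed)
  classes0 <- object$input_classes
  vars <- unlist(classes0, use.names = FALSE)
  ok <- TRUE
  for (i in seq_len(n_perm)) {
    perm <- sample(vars)
    classes_p <- lapply(classes0, function(v) perm[perm %in% v])
    refit <- stepwise_glm(object$data, object$response, classes_p,
                          family = object$family, alpha = object$alpha,
                          test = object$test)
    if (!identical(sort(refit$terms$variable), base)) ok <- FALSE
  }
  if (!ok) warn("stepwise result depends on variable order")
  invisible(ok)
}

#' Partition deviance across variable classes
#'
#' Fits one sub-model per class containing only that class's surviving
#' terms, on exactly the complete-case sample set of the full model, and
#' reports the deviance explained by each alongside the full model. The
#' partitions are not expected to sum to the full model: variable classes
#' share variation.
#'
#' @param object a [stepwise_glm()] result
#' @return tibble `class`, `n_terms`, `deviance_explained` (final row is
#'   the full model)
#' @export
deviance_partition <- function(object) {
  stopifnot(inherits(object, "cdh_glm"))
  fam <- if (object$family == "binomial") binomial() else gaussian()
  rows <- purrr::map_dfr(names(object$classes), function(cl) {
    v <- object$classes[[cl]]
    de <- if (!length(v)) 0 else {
      fml <- stats::reformulate(v, response = object$response)
      deviance_explained(glm(fml, data = object$data, family = fam))
    }
    tibble::tibble(class = cl, n_terms = length(v), deviance_explained = de)
  })
  dplyr::add_row(rows, class = "full", n_terms = nrow(object$terms),
                 deviance_explained = object$deviance_explained)
}
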