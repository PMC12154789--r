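#' Hard-filter a genotype matrix
#'
#' Applies the SNP filters in the order used throughout: individual calls
#' with read depth <= 3 or >= 20 or genotype quality <= 60 are set
#' missing; SNPs on the exclusion list (precomputed homology / transposable
#' element screen) are dropped; SNPs with minor-allele frequency below
#' `maf_min` or missingness above `snp_missing_max` are dropped; finally
#' samples with more than `sample_missing_max` missing calls are dropped.
#' Minor-allele frequencies are recomputed after call masking.
#'
#' @param geno a `cdh_genotypes` list (see
#'   [simulate_association_dataset()]) with `dosage`, `depth`, `gq`,
#'   `snp_info`
#' @param depth_min,depth_max exclusive bounds on retained call depth
#' @param gq_min exclusive lower bound on retained genotype quality
#' @param maf_min minimum minor-allele frequency (default 0.05)
#' @param snp_missing_max maximum per-SNP missingness (default 0.75)
#' @param sample_missing_max maximum per-sample missingness (default 0.10)
#' @param exclude character vector of SNP ids to drop verbatim
#' @return the filtered `cdh_genotypes`; the `snp_info` tibble gains a
#'   recomputed `maf` column, and attribute `"filter_log"` records removal
#'   counts
#' @export
filter_genotypes <- function(geno, depth_min = 3, depth_max = 20,
                             gq_min = 60, maf_min = 0.05,
                             snp_missing_max = 0.75,
                             sample_missing_max = 0.10,
                             exclude = character()) {
  d <- geno$dosage
  mask <- geno$depth <= depth_min | geno$depth >= depth_max |
    geno$gq <= gq_min
  d[mask] <- NA_integer_
  keep_snp <- !colnames(d) %in% exclude
  af <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  miss <- colMeans(is.na(d))
  maf[is.nan(maf)] <- 0
  keep_snp <- keep_snp & maf >= maf_min & miss <= snp_missing_max
  d <- d[, keep_snp, drop = FALSE]
  keep_sample <- rowMeans(is.na(d)) <= sample_missing_max
  d <- d[keep_sample, , drop = FALSE]
  if (nrow(d) == 0 || ncol(d) == 0) {
    abort("genotype filtering removed everything; relax the thresholds")
  }
  af <- colMeans(d, na.rm = TRUE) / 2
  snp_info <- geno$snp_info[match(colnames(d), geno$snp_info$snp), ]
  snp_info$maf <- pmin(af, 1 - af)
  out <- geno
  out$dosage <- d
  out$depth <- geno$depth[keep_sample, keep_snp, drop = FALSE]
  out$gq <- geno$gq[keep_sample, keep_snp, drop = FALSE]
  out$snp_info <- snp_info
  out$sample_ids <- rownames(d)
  if (!is.null(out$phenotype)) out$phenotype <- out$phenotype[rownames(d)]
  if (!is.null(out$env)) {
    out$env <- out$env[match(rownames(d), out$env$sample_id), ]
  }
  attr(out, "filter_log") <- tibble::tibble(
    masked_calls = sum(mask),
    snps_dropped = sum(!keep_snp),
    samples_dropped = sum(!keep_sample))
  out
}

#' Population-structure principal components
#'
#' PCA on centred dosages (missing calls mean-imputed for the PCA only).
#'
#' @param geno a `cdh_genotypes` or a samples-by-SNPs dosage matrix
#' @param k number of components returned (default 10; `k = 0` yields an
#'   empty covariate set)
#' @return list with `scores` (tibble `sample_id`, `PC1..PCk`) and
#'   `variance_explained`
#' @export
structure_pcs <- function(geno, k = 10) {
  d <- if (inherits(geno, "cdh_genotypes")) geno$dosage else as.matrix(geno)
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d))
    d[idx] <- mu[(idx - 1) %/% nrow(d) + 1]
  }
  if (k == 0) {
    return(list(scores = tibble::tibble(sample_id = rownames(d)),
                variance_explained = numeric()))
  }
  pc <- prcomp(d, center = TRUE, scale. = FALSE)
  if (k > ncol(pc$x)) {
    abort(sprintf("k = %d exceeds the rank of the genotype matrix (%d)",
                  k, ncol(pc$x)))
  }
  scores <- tibble::as_tibble(pc$x[, seq_len(k), drop = FALSE]) |>
    tibble::add_column(sample_id = rownames(d), .before = 1)
  list(scores = scores,
       variance_explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)])
}

#' Per-SNP association scan with principal-component covariates
#'
#' Fits `phenotype ~ dosage + PC1..PCk` per SNP -- logistic regression for
#' presence/absence phenotypes, linear regression for (log) copy number --
#' and reports the Wald test on the dosage term. Monomorphic SNPs are
#' skipped with a flag; non-converged or separated fits are flagged, not
#' silently dropped.
#'
#' @param geno a `cdh_genotypes` or dosage matrix
#' @param phenotype numeric vector named by sample (0/1 for binomial)
#' @param pcs covariate tibble from [structure_pcs()]`$scores` (or `NULL`
#'   for an unadjusted scan)
#' @param family `"binomial"` (logit) or `"gaussian"`
#' @param threshold genome-wide significance threshold (default 5e-8)
#' @return tibble `snp`, `chrom`, `pos`, `beta`, `se`, `p`, `significant`,
#'   `flag`
#' @export
gwas <- function(geno, phenotype, pcs = NULL,
                 family = c("binomial", "gaussian"), threshold = 5e-8) {
  family <- match.arg(family)
  d <- if (inherits(geno, "cdh_genotypes")) geno$dosage else as.matrix(geno)
  info <- if (inherits(geno, "cdh_genotypes")) geno$snp_info else
    tibble::tibble(snp = colnames(d), chrom = NA_character_, pos = NA_integer_)
  if (is.null(names(phenotype))) {
    if (length(phenotype) != nrow(d)) abort("phenotype/genotype sample mismatch")
    names(phenotype) <- rownames(d)
  }
  if (!all(rownames(d) %in% names(phenotype))) {
    abort("phenotype/genotype sample mismatch")
  }
  y <- phenotype[rownames(d)]
  covar <- NULL
  if (!is.null(pcs) && ncol(pcs) > 1) {
    if (!all(rownames(d) %in% pcs$sample_id)) {
      abort("covariate/genotype sample mismatch")
    }
    covar <- as.matrix(pcs[match(rownames(d), pcs$sample_id), -1, drop = FALSE])
  }
  fam <- if (family == "binomial") binomial() else gaussian()
  res <- purrr::map_dfr(seq_len(ncol(d)), function(j) {
    g <- d[, j]
    ok <- !is.na(g) & !is.na(y)
    out <- tibble::tibble(snp = colnames(d)[j], beta = NA_real_,
                          se = NA_real_, p = NA_real_,
                          significant = FALSE, flag = NA_character_)
    if (length(unique(g[ok])) < 2) {
      out$flag <- "monomorphic"
      return(out)
    }
    xmat <- cbind(`(Intercept)` = 1, dosage = g,
                  if (!is.null(covar)) covar)
    fit <- suppressWarnings(
      glm.fit(xmat[ok, , drop = FALSE], y[ok], family = fam))
    cf <- fit$coefficients
    if (fit$rank < ncol(xmat)) {
      out$flag <- "rank_deficient"
      return(out)
    }
    # Wald se from the unscaled covariance of the IRLS working model,
    # honouring the QR column pivot as summary.glm does
    p1 <- seq_len(fit$rank)
    cov_un <- chol2inv(fit$qr$qr[p1, p1, drop = FALSE])
    disp <- if (family == "gaussian")
      sum(fit$weights * fit$residuals^2) / fit$df.residual else 1
    se_all <- rep(NA_real_, ncol(xmat))
    se_all[fit$qr$pivot[p1]] <- sqrt(diag(cov_un) * disp)
    se <- se_all[2]
    beta <- unname(cf[2])
    z <- beta / se
    out$beta <- beta; out$se <- se
    out$p <- 2 * pnorm(-abs(z))
    out$significant <- !is.na(out$p) && out$p < threshold
    if (!fit$converged) out$flag <- "not_converged"
    else if (family == "binomial" && abs(beta) > 15) out$flag <- "separated"
    out
  })
  dplyr::left_join(res, info[, intersect(c("snp", "chrom", "pos"), names(info))],
                   by = "snp") |>
    dplyr::relocate("chrom", "pos", .after = "snp")
}

#' Screen multi-allelic sites and collapse to additive coding
#'
#' Multi-allelic sites are first tested as factors (each alternate allele
#' a level) against the phenotype with the structure covariates; when no
#' minor alternate allele is individually significant at `alpha`, calls
#' carrying it are set missing and the remaining alternate allele is coded
#' additively.
#'
#' @param calls character matrix of per-sample allele pairs (e.g. "A/T"),
#'   samples x sites
#' @param ref,alts named lists/vectors: reference allele and alternate
#'   alleles per site
#' @param phenotype 0/1 vector named by sample
#' @param pcs structure covariates (tibble with `sample_id`)
#' @param alpha significance level for keeping a minor allele as a factor
#'   level (default 0.01)
#' @return list with `dosage` (additive matrix over the major alternate
#'   allele) and `report` (per-site tibble of minor-allele p-values and the
#'   action taken)
#' @export
collapse_multiallelic <- function(calls, ref, alts, phenotype, pcs = NULL,
                                  alpha = 0.01) {
  samples <- rownames(calls)
  y <- phenotype[samples]
  covar <- if (!is.null(pcs))
    as.matrix(pcs[match(samples, pcs$sample_id), -1, drop = FALSE]) else NULL
  dosage <- matrix(NA_integer_, nrow(calls), ncol(calls),
                   dimnames = dimnames(calls))
  report <- purrr::map_dfr(seq_len(ncol(calls)), function(j) {
    site <- colnames(calls)[j]
    al <- strsplit(calls[, j], "/", fixed = TRUE)
    a1 <- vapply(al, `[`, "", 1); a2 <- vapply(al, `[`, "", 2)
    alt_j <- alts[[site]]
    cnt <- vapply(alt_j, function(a) sum(a1 == a) + sum(a2 == a), 0)
    major_alt <- alt_j[which.max(cnt)]
    minors <- setdiff(alt_j, major_alt)
    minor_p <- NA_real_
    if (length(minors)) {
      gfac <- factor(paste(pmin(a1, a2), pmax(a1, a2), sep = "/"))
      df <- data.frame(y = y, g = gfac)
      if (!is.null(covar)) df <- cbind(df, covar)
      fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
      cf <- summary(fit)$coefficients
      rows <- grepl(paste(minors, collapse = "|"), rownames(cf))
      minor_p <- if (any(rows)) min(cf[rows, 4]) else NA_real_
    }
    keep_minor <- !is.na(minor_p) && minor_p <= alpha
    if (!keep_minor) {
      has_minor <- a1 %in% minors | a2 %in% minors
      dos <- (a1 == major_alt) + (a2 == major_alt)
      dos[has_minor] <- NA_integer_
      dosage[, j] <<- as.integer(dos)
    }
    tibble::tibble(site = site, major_alt = major_alt,
                   n_minor_alleles = length(minors), minor_p = minor_p,
                   action = if (keep_minor) "kept_as_factor"
                            else "collapsed_additive")
  })
  list(dosage = dosage, report = report)
}

#' Flag collinear covariate pairs
#'
#' All pairs of numeric covariates with absolute Pearson correlation above
#' `threshold` are flagged. Flags are advisory: the user decides which
#' variable to drop. Constant variables (correlation undefined) are
#' flagged separately.
#'
#' @param variables data frame of numeric covariates
#' @param threshold absolute correlation threshold (default 0.70)
#' @return tibble `var1`, `var2`, `r`, `flag`
#' @export
collinearity_screen <- function(variables, threshold = 0.70) {
  v <- dplyr::select(tibble::as_tibble(variables), dplyr::where(is.numeric))
  out <- tibble::tibble(var1 = character(), var2 = character(),
                        r = double(), flag = character())
  const <- names(v)[vapply(v, function(x) sd(x, na.rm = TRUE) == 0, TRUE)]
  for (cv in const) {
    out <- dplyr::add_row(out, var1 = cv, var2 = NA_character_,
                          r = NA_real_, flag = "constant")
  }
  keep <- setdiff(names(v), const)
  if (length(keep) >= 2) {
    cm <- cor(v[keep], use = "pairwise.complete.obs")
    idx <- which(upper.tri(cm) & abs(cm) > threshold, arr.ind = TRUE)
    if (nrow(idx)) {
      out <- dplyr::bind_rows(out, tibble::tibble(
        var1 = rownames(cm)[idx[, 1]], var2 = colnames(cm)[idx[, 2]],
        r = cm[idx], flag = "collinear"))
    }
  }
  out
}
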