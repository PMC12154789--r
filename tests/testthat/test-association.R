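mk_geno <- function(dosage, depth = NULL, gq = NULL) {
  n <- nrow(dosage); m <- ncol(dosage)
  if (is.null(rownames(dosage))) rownames(dosage) <- sprintf("i%02d", 1:n)
  if (is.null(colnames(dosage))) colnames(dosage) <- sprintf("s%02d", 1:m)
  structure(list(
    dosage = dosage,
    depth = depth %||% matrix(10L, n, m, dimnames = dimnames(dosage)),
    gq = gq %||% matrix(90L, n, m, dimnames = dimnames(dosage)),
    snp_info = tibble::tibble(snp = colnames(dosage), chrom = "chr1",
                              pos = seq_len(m)),
    sample_ids = rownames(dosage)), class = "cdh_genotypes")
}

test_that("genotype filters honour the depth/GQ/MAF/missingness boundaries", {
  set.seed(1)
  dosage <- matrix(rbinom(40 * 30, 2, 0.4), 40, 30)
  g <- mk_geno(dosage)
  # depth boundaries are strict: 3 and 20 masked, 4 and 19 kept
  g$depth[1, 1] <- 3L; g$depth[2, 1] <- 4L
  g$depth[3, 1] <- 19L; g$depth[4, 1] <- 20L
  g$gq[5, 1] <- 60L; g$gq[6, 1] <- 61L
  f <- filter_genotypes(g)
  expect_true(is.na(f$dosage[1, 1]))
  expect_false(is.na(f$dosage[2, 1]))
  expect_false(is.na(f$dosage[3, 1]))
  expect_true(is.na(f$dosage[4, 1]))
  expect_true(is.na(f$dosage[5, 1]))
  expect_false(is.na(f$dosage[6, 1]))

  # MAF 0.04 dropped at the 0.05 rule
  g2 <- mk_geno(cbind(dosage,
                      rare = c(rep(1L, 3), rep(0L, 37)),  # MAF 0.0375
                      ok = c(rep(1L, 5), rep(0L, 35))))   # MAF 0.0625
  f2 <- filter_genotypes(g2)
  expect_false("rare" %in% colnames(f2$dosage))
  expect_true("ok" %in% colnames(f2$dosage))
  expect_equal(unname(f2$snp_info$maf[f2$snp_info$snp == "ok"]), 0.0625)

  # SNP missingness > 0.75 dropped; sample missingness > 0.10 dropped
  g3 <- mk_geno(dosage)
  g3$depth[1:31, 2] <- 0L                      # SNP s02: 77.5% missing
  g3$depth[7, 3:7] <- 0L                       # sample i07: 5/30 calls missing
  f3 <- filter_genotypes(g3)
  expect_false("s02" %in% colnames(f3$dosage))
  expect_false("i07" %in% rownames(f3$dosage))

  # explicit exclusion list applied verbatim
  f4 <- filter_genotypes(g, exclude = "s03")
  expect_false("s03" %in% colnames(f4$dosage))
  expect_error(filter_genotypes(g, maf_min = 0.9), "removed everything")
})

test_that("structure PCs recover simulated populations and are equivariant", {
  sim <- simulate_association_dataset(300, 150, k_pops = 3, fst = 0.3,
                                      seed = 6)
  pcs <- structure_pcs(sim, k = 4)
  pop <- max.col(sim$admixture)
  pc1 <- pcs$scores$PC1
  between <- var(tapply(pc1, pop, mean))
  within <- mean(tapply(pc1, pop, var))
  expect_gt(between / within, 1)

  # permuting samples permutes scores identically
  perm <- sample(nrow(sim$dosage))
  pcs_perm <- structure_pcs(sim$dosage[perm, ], k = 4)
  expect_equal(pcs_perm$scores$PC1,
               pcs$scores$PC1[perm], tolerance = 1e-8)

  expect_equal(ncol(structure_pcs(sim, k = 0)$scores), 1L)
  expect_error(structure_pcs(sim$dosage[1:5, 1:3], k = 10), "rank")
})

test_that("the GLM engine matches a textbook IRLS oracle to 6 decimals", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(0, 1, 0, 1, 1)
  df <- data.frame(y = y, x = x)
  fit <- stepwise_glm(df, "y", list(genetic = "x"), family = "binomial",
                      alpha = 1)

  # hand-rolled iteratively reweighted least squares, logit link
  X <- cbind(1, x)
  beta <- c(0, 0)
  for (i in 1:50) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    beta <- solve(t(X) %*% (w * X), t(X) %*% (w * z))
  }
  expect_equal(unname(coef(fit$fit)), unname(drop(beta)), tolerance = 1e-6)

  # gaussian branch against the least-squares closed form
  y2 <- c(1.2, 2.1, 2.9, 4.3, 4.8)
  fit2 <- stepwise_glm(data.frame(y = y2, x = x), "y",
                       list(genetic = "x"), family = "gaussian", alpha = 1)
  beta2 <- solve(t(X) %*% X, t(X) %*% y2)
  expect_equal(unname(coef(fit2$fit)), unname(drop(beta2)), tolerance = 1e-6)
})

test_that("the association scan flags monomorphic SNPs and checks samples", {
  sim <- simulate_association_dataset(200, 10, k_pops = 1, seed = 2)
  sim$dosage[, 1] <- 1L
  scan <- gwas(sim, sim$phenotype, pcs = NULL, family = "binomial")
  expect_equal(scan$flag[1], "monomorphic")
  expect_true(is.na(scan$p[1]))
  expect_true(all(!is.na(scan$p[-1])))
  expect_error(gwas(sim, sim$phenotype[1:10]), "mismatch")
})

test_that("a planted large-effect SNP is detected through PC adjustment", {
  sim <- simulate_association_dataset(
    1000, 50, k_pops = 3,
    causal_snps = tibble::tibble(snp = 5, or = 3, maf = 0.3), seed = 17)
  pcs <- structure_pcs(sim, k = 10)
  scan <- gwas(sim, sim$phenotype, pcs$scores, family = "binomial")
  expect_lt(scan$p[5], 5e-8)
  expect_true(scan$significant[5])
  # oracle: direct logistic fit reproduces the reported p-value
  X <- as.matrix(pcs$scores[, -1])
  oracle <- summary(glm(sim$phenotype ~ sim$dosage[, 5] + X,
                        family = binomial()))$coefficients[2, 4]
  expect_equal(unname(scan$p[5]), unname(oracle), tolerance = 1e-9)
})

test_that("stepwise simplification drops noise and is order-invariant", {
  set.seed(11)
  n <- 400
  df <- tibble::tibble(
    x1 = rnorm(n), x2 = rnorm(n), noise = rnorm(n),
    env1 = rnorm(n))
  eta <- -0.3 + 1.2 * df$x1 - 0.9 * df$x2 + 0.8 * df$env1
  df$y <- rbinom(n, 1, plogis(eta))
  classes <- list(structure = character(),
                  genetic = c("x1", "x2", "noise"),
                  environment = "env1")
  fit <- stepwise_glm(df, "y", classes, family = "binomial")
  expect_setequal(fit$terms$variable, c("x1", "x2", "env1"))
  expect_equal(fit$history$dropped, "noise")
  expect_true(check_order_invariance(fit, n_perm = 10, seed = 1))

  # all-significant model is a fixed point
  fit2 <- stepwise_glm(df, "y", list(genetic = c("x1", "x2")),
                       family = "binomial")
  expect_equal(nrow(fit2$history), 0L)

  # pure-noise response simplifies to the intercept with zero deviance
  df$y0 <- rbinom(n, 1, 0.5)
  fit3 <- stepwise_glm(df, "y0", classes, family = "binomial",
                       alpha = 1e-6)
  expect_equal(nrow(fit3$terms), 0L)
  expect_equal(fit3$deviance_explained, 0)

  td <- tidy(fit)
  expect_true(all(c("term", "class", "estimate", "p.value") %in% names(td)))
  expect_equal(glance(fit)$n_terms, 3L)
})

test_that("collinearity screening flags by absolute correlation", {
  set.seed(5)
  v <- tibble::tibble(a = rnorm(500), b = rnorm(500))
  v$dup <- v$a
  v$neg <- -v$b
  v$const <- 1
  out <- collinearity_screen(v)
  pairs <- paste(out$var1, out$var2)
  expect_true("a dup" %in% pairs)
  expect_true("b neg" %in% pairs)
  expect_equal(out$flag[out$var1 == "const"], "constant")
  clean <- collinearity_screen(v[, c("a", "b")])
  expect_equal(nrow(clean), 0L)
})

test_that("deviance partitions reflect shared and orthogonal variation", {
  set.seed(7)
  n <- 500
  df <- tibble::tibble(g = rnorm(n), e = rnorm(n))
  df$y <- rbinom(n, 1, plogis(1.0 * df$g + 1.0 * df$e))
  fit <- stepwise_glm(df, "y", list(genetic = "g", environment = "e"),
                      family = "binomial")
  part <- deviance_partition(fit)
  full <- part$deviance_explained[part$class == "full"]
  parts <- part$deviance_explained[part$class != "full"]
  expect_true(all(parts >= 0 & parts <= 1))
  # orthogonal predictors: partitions approximately sum to the full model
  expect_lt(abs(sum(parts) - full), 0.15 * full)

  # fully collinear classes: each partition alone matches the full model
  df2 <- tibble::tibble(g = df$g, gdup = df$g + rnorm(n, sd = 1e-3),
                        y = df$y)
  fit2 <- stepwise_glm(df2, "y", list(genetic = "g", environment = "gdup"),
                       family = "binomial", alpha = 1)
  part2 <- deviance_partition(fit2)
  full2 <- part2$deviance_explained[part2$class == "full"]
  parts2 <- part2$deviance_explained[part2$class != "full"]
  expect_true(all(abs(parts2 - full2) < 0.02))
  expect_gt(sum(parts2), full2)

  # null response: all partitions near zero
  df$y0 <- rbinom(n, 1, 0.5)
  fit3 <- stepwise_glm(df, "y0", list(genetic = "g", environment = "e"),
                       family = "binomial", alpha = 1)
  part3 <- deviance_partition(fit3)
  expect_true(all(part3$deviance_explained < 0.02))
})

test_that("non-significant minor alleles are collapsed to additive coding", {
  set.seed(9)
  n <- 120
  a1 <- sample(c("A", "T"), n, TRUE, prob = c(0.6, 0.4))
  a2 <- sample(c("A", "T"), n, TRUE, prob = c(0.6, 0.4))
  a1[1:6] <- "C"   # rare, non-causal third allele
  calls <- matrix(paste(a1, a2, sep = "/"), ncol = 1,
                  dimnames = list(sprintf("i%03d", 1:n), "site1"))
  y <- setNames(rbinom(n, 1, 0.4), rownames(calls))
  res <- collapse_multiallelic(calls, ref = list(site1 = "A"),
                               alts = list(site1 = c("T", "C")),
                               phenotype = y)
  expect_equal(res$report$action, "collapsed_additive")
  expect_true(all(is.na(res$dosage[1:6, 1])))
  expected <- (a1 == "T") + (a2 == "T")
  expect_equal(unname(res$dosage[7:n, 1]), expected[7:n])
})
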