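test_that("RPM normalisation rescales each sample to one million reads", {
  loc <- tibble::tibble(tag_id = paste0("t", 1:3), chrom = "chr1",
                        start = c(0L, 100L, 200L), end = c(64L, 164L, 264L),
                        mapq = 60L)
  counts <- matrix(c(5L, 0L,
                     99995L, 10L,
                     0L, 90L), nrow = 3, byrow = TRUE,
                   dimnames = list(loc$tag_id, c("a", "b")))
  tm <- tag_matrix(counts, loc)
  norm <- rpm_normalize(tm)
  expect_equal(norm$counts["t1", "a"], 50)        # 5 x 1e6 / 1e5
  expect_equal(norm$counts["t1", "b"], 0)
  expect_equal(unname(colSums(norm$counts)), c(1e6, 1e6))
  zero <- tag_matrix(matrix(c(1L, 0L), 1,
                            dimnames = list("t1", c("ok", "empty"))),
                     loc[1, ])
  expect_error(rpm_normalize(zero), "empty")
})

test_that("the blank missingness cutoff is min(blank) minus the offset", {
  loc <- tibble::tibble(tag_id = sprintf("t%03d", 1:100), chrom = "chr1",
                        start = seq(0L, by = 100L, length.out = 100),
                        end = seq(64L, by = 100L, length.out = 100),
                        mapq = 60L)
  mk <- function(missingness) {
    n0 <- round(100 * missingness)
    c(rep(0L, n0), rep(3L, 100 - n0))
  }
  counts <- cbind(b1 = mk(0.95), b2 = mk(0.98), s1 = mk(0.10))
  rownames(counts) <- loc$tag_id
  tm <- tag_matrix(counts, loc)
  manifest <- tibble::tibble(
    sample_id = c("b1", "b2", "s1"),
    sample_class = c("blank", "blank", "experimental"),
    Ab10 = "unknown", K10L2 = "unknown", B = "unknown",
    copy_class = "unknown", ab10_type = "unknown")
  expect_equal(blank_missingness_cutoff(tm, manifest), 0.949)
  one_blank <- manifest[manifest$sample_id != "b2", ]
  tm1 <- subset_tags(tm, samples = c("b1", "s1"))
  tm1$counts[, "b1"] <- mk(0.50)
  expect_equal(blank_missingness_cutoff(tm1, one_blank), 0.499)
  no_blank <- manifest[3, ]
  tm2 <- subset_tags(tm, samples = "s1")
  expect_equal(blank_missingness_cutoff(tm2, no_blank, cutoff = 0.9), 0.9)
  expect_error(blank_missingness_cutoff(tm2, no_blank), "cutoff")
})

test_that("sample and tag filters honour the boundary conventions", {
  tm <- tiny_tags()   # s2 missingness 0.5; t2 has mapq 19, t4 mapq 20
  filtered <- suppressMessages(filter_samples_and_tags(tm, cutoff = 0.49))
  expect_false("s2" %in% filtered$sample_ids)
  expect_false("t2" %in% filtered$locations$tag_id)   # mapq 19 removed
  expect_true("t4" %in% filtered$locations$tag_id)    # mapq 20 kept
  untouched <- filter_samples_and_tags(tm, cutoff = 1, min_mapq = 0)
  expect_equal(untouched$counts, tm$counts)
  expect_error(suppressMessages(filter_samples_and_tags(tm, cutoff = 0)),
               "every sample")
})

test_that("bin_tag_index computes sqrt(c) + d and matches a per-tag oracle", {
  loc <- tibble::tibble(tag_id = paste0("t", 1:6), chrom = "chr1",
                        start = c(0L, 10L, 20L, 30L, 1000100L, 1000200L),
                        end = c(64L, 74L, 84L, 94L, 1000164L, 1000264L),
                        mapq = 60L)
  depths <- matrix(c(2.5, 0,
                     2.5, 0,
                     2.5, 0,
                     2.5, 0,
                     3,   0,
                     4,   0), nrow = 6, byrow = TRUE,
                   dimnames = list(loc$tag_id, c("a", "b")))
  tm <- tag_matrix(depths, loc, normalized = TRUE)
  bins <- tibble::tibble(chrom = "chr1", start = c(0L, 1000000L),
                         end = c(1000000L, 2000000L), label = c("b1", "b2"))
  idx <- bin_tag_index(tm, bins)
  expect_equal(idx$values["b1", "a"], sqrt(4) + 10)   # c=4, d=10 -> 12
  expect_equal(idx$values["b2", "a"], sqrt(2) + 7)
  expect_equal(unname(idx$values[, "b"]), c(0, 0))    # no expressed tags

  # brute-force oracle on random data
  set.seed(1)
  n <- 50
  loc2 <- tibble::tibble(tag_id = sprintf("r%02d", 1:n), chrom = "chr1",
                         start = sort(sample.int(5e6, n)), mapq = 60L)
  loc2$end <- loc2$start + 64L
  d2 <- matrix(round(runif(n * 3) * 10) * rbinom(n * 3, 1, 0.6), n, 3,
               dimnames = list(loc2$tag_id, c("x", "y", "z")))
  tm2 <- tag_matrix(d2, loc2, normalized = TRUE)
  bins2 <- tibble::tibble(chrom = "chr1",
                          start = as.integer((0:4) * 1e6),
                          end = as.integer((1:5) * 1e6),
                          label = paste0("w", 1:5))
  idx2 <- bin_tag_index(tm2, bins2)
  oracle <- matrix(0, 5, 3)
  for (i in seq_len(n)) {
    b <- loc2$start[i] %/% 1e6 + 1
    for (j in 1:3) if (d2[i, j] > 0) oracle[b, j] <- oracle[b, j] + d2[i, j]
  }
  cc <- matrix(0, 5, 3)
  for (i in seq_len(n)) {
    b <- loc2$start[i] %/% 1e6 + 1
    for (j in 1:3) cc[b, j] <- cc[b, j] + (d2[i, j] > 0)
  }
  expect_equal(unname(idx2$values), sqrt(cc) + oracle)

  # additive consistency: c and d accumulated at half-bin granularity and
  # recombined reproduce the 1 Mb index exactly (sqrt applied only at the
  # final granularity)
  c_half <- matrix(0, 10, 3); d_half <- matrix(0, 10, 3)
  for (i in seq_len(n)) {
    h <- loc2$start[i] %/% 5e5 + 1
    for (j in 1:3) if (d2[i, j] > 0) {
      c_half[h, j] <- c_half[h, j] + 1
      d_half[h, j] <- d_half[h, j] + d2[i, j]
    }
  }
  pair <- rep(1:5, each = 2)
  c_comb <- rowsum(c_half, pair); d_comb <- rowsum(d_half, pair)
  expect_equal(unname(idx2$values), unname(sqrt(c_comb) + d_comb))

  expect_error(
    bin_tag_index(tm2, dplyr::mutate(bins2, start = start - c(0L, rep(1e5L, 4)))),
    "overlap")
})

test_that("min/max scaling is per bin with a zero rule for constant rows", {
  bins <- tibble::tibble(chrom = "c", start = c(0L, 1000000L),
                         end = c(1000000L, 2000000L), label = c("b1", "b2"))
  idx <- bin_index(rbind(c(2, 6, 10), c(5, 5, 5)), bins)
  sc <- minmax_scale(idx)
  expect_equal(unname(sc$values[1, ]), c(0, 0.5, 1))
  expect_equal(unname(sc$values[2, ]), c(0, 0, 0))
  single <- minmax_scale(bin_index(matrix(c(3, 8), 2), bins))
  expect_equal(unname(single$values[, 1]), c(0, 0))
  expect_true(all(sc$values >= 0 & sc$values <= 1))
})

test_that("single-copy gene bins accumulate gene sequence, not coordinates", {
  genes <- tibble::tibble(chrom = "chr1",
                          start = as.integer(seq(0, 9) * 1e6),
                          end = as.integer(seq(0, 9) * 1e6 + 2e5))
  bins <- single_copy_gene_bins(genes)
  expect_equal(nrow(bins), 2L)
  expect_equal(bins$gene_bp, c(1e6, 1e6))
  expect_true(all(bins$single_copy))
  # spans large genomic distance: first bin covers five genes
  expect_equal(bins$end[1], genes$end[5])

  none <- single_copy_gene_bins(tibble::tibble(chrom = "chr1", start = 0L,
                                               end = 100000L))
  expect_equal(nrow(none), 0L)

  genes2 <- tibble::tibble(chrom = "chr1",
                           start = as.integer(seq(0, 7) * 1e6),
                           end = as.integer(seq(0, 7) * 1e6 + 2e5))
  bins2 <- single_copy_gene_bins(genes2)   # 1.6 Mb total
  expect_equal(nrow(bins2), 2L)
  expect_equal(bins2$gene_bp[2], 0.6e6)

  expect_error(single_copy_gene_bins(tibble::tibble(
    chrom = "chr1", start = c(0L, 100L), end = c(200L, 300L))), "overlap")
})

test_that("the tag-index pipeline is invariant to sample order", {
  s <- shared_sim()
  perm <- sample(ncol(s$ds$tags$counts))
  permuted <- subset_tags(s$ds$tags, samples = perm)
  norm <- rpm_normalize(permuted)
  filt <- suppressMessages(filter_samples_and_tags(
    norm, blank_missingness_cutoff(norm, s$ds$manifest)))
  idx <- bin_tag_index(filt, s$ds$bins)
  common <- intersect(colnames(idx$values), colnames(s$idx$values))
  expect_equal(idx$values[, common], s$idx$values[, common])
})
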