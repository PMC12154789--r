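test_that("clusters are named by control purity at the 80% rule", {
  truth <- setNames(rep(c("positive", "negative"), c(10, 10)),
                    paste0("c", 1:20))
  # 9/1 positive in cluster 1, 1/9 in cluster 2 -> named and valid
  a <- setNames(c(rep(1L, 9), 2L, 1L, rep(2L, 9)), paste0("c", 1:20))
  nm <- name_clusters(a, truth)
  expect_true(nm$valid)
  expect_equal(unname(nm$labels), c("positive", "negative"))

  # 7/3 split -> purity 0.7 -> unnamed, round invalid
  b <- setNames(c(rep(1L, 7), rep(2L, 3), rep(1L, 3), rep(2L, 7)),
                paste0("c", 1:20))
  expect_false(name_clusters(b, truth)$valid)

  # both clusters >= 80% positive -> contradiction, invalid
  truth2 <- setNames(rep("positive", 10), paste0("p", 1:10))
  cc <- setNames(rep(c(1L, 2L), each = 5), paste0("p", 1:10))
  expect_false(name_clusters(cc, truth2)$valid)

  # a cluster with zero controls leaves the round invalid
  d <- setNames(c(rep(1L, 20), 2L), c(paste0("c", 1:20), "exp1"))
  expect_false(name_clusters(d, truth)$valid)

  # experimental members never influence the labels
  e_with <- setNames(c(a, rep(2L, 30)), c(names(a), paste0("e", 1:30)))
  expect_equal(name_clusters(e_with, truth)$labels, nm$labels)
})

test_that("consensus calls require 95% agreement across rounds", {
  state <- tibble::tibble(
    sample_id = c("a", "b", "c", "d"),
    positive = c(120L, 118L, 0L, 0L),
    negative = c(5L, 7L, 125L, 0L))
  out <- consensus_call(state)
  expect_equal(out$call, c("positive", "ambiguous", "negative", "ambiguous"))
  expect_equal(out$consensus_fraction[1], 0.96)
  expect_equal(out$consensus_fraction[2], 118 / 125)
  expect_equal(out$n_rounds, c(125L, 125L, 125L, 0L))
  expect_equal(out$flag[4], "no_calls")
})

test_that("experimental rounds cap the spike at the configured fraction", {
  s <- shared_sim()
  # 10 low-copy positive + 20 negative controls -> 20 drawn, cap = 5
  expect_error(
    experimental_round(s$scaled, s$ds$manifest, "Ab10",
                       exp_ids = sprintf("exp_%03d", 1:11),
                       spike_fraction = 0.25, seed = 1),
    "at most 5")
  r <- experimental_round(s$scaled, s$ds$manifest, "Ab10",
                          exp_ids = intersect(sprintf("exp_%03d", 1:5),
                                              colnames(s$scaled$values)),
                          spike_fraction = 0.25, seed = 1)
  expect_true(r$valid)
  expect_true(all(r$calls %in% c("positive", "negative")))
})

test_that("control validation is deterministic and collapses without signal", {
  s <- shared_sim()
  a <- control_validation(s$scaled, s$ds$manifest, "Ab10", "low",
                          n_reps = 20, seed = 9)
  b <- control_validation(s$scaled, s$ds$manifest, "Ab10", "low",
                          n_reps = 20, seed = 9)
  expect_identical(a, b)
  expect_true(all(a$accuracy == 1))

  # no dosage contrast: accuracy collapses toward chance
  null_cfg <- sim_config(dosage_effect = 1.001, background_rate = 1,
                         n_experimental = 0, seed = 13)
  null_ds <- simulate_tag_dataset(null_cfg)
  norm <- rpm_normalize(null_ds$tags)
  filt <- suppressMessages(filter_samples_and_tags(
    norm, blank_missingness_cutoff(norm, null_ds$manifest)))
  null_sc <- minmax_scale(bin_tag_index(filt, null_ds$bins))
  null_acc <- control_validation(null_sc, null_ds$manifest, "Ab10", "low",
                                 n_reps = 20, seed = 9)
  expect_lt(mean(null_acc$accuracy), 0.9)
})

test_that("the chromosome-10 workflow is sequential", {
  s <- shared_sim()
  calls <- shared_calls()$chr10
  truth <- s$ds$truth
  ab10 <- calls[calls$cdh == "Ab10", ]
  k10 <- calls[calls$cdh == "K10L2", ]
  tt <- truth[match(ab10$sample_id, truth$sample_id), ]
  # Ab10 carriers are called positive and never assayed for K10L2
  ab10_carriers <- ab10$sample_id[tt$ab10_copies > 0]
  expect_true(all(ab10$call[tt$ab10_copies > 0] == "positive"))
  expect_true(all(k10$call[k10$sample_id %in% ab10_carriers] == "unknown"))
  # K10L2 carriers come out Ab10-negative, K10L2-positive
  tk <- truth[match(k10$sample_id, truth$sample_id), ]
  k10_carriers <- k10$sample_id[tk$k10l2_copies > 0]
  expect_true(all(ab10$call[ab10$sample_id %in% k10_carriers] == "negative"))
  expect_true(all(k10$call[tk$k10l2_copies > 0] == "positive"))
  expect_true(all(k10$call[tk$k10l2_copies == 0 & tk$ab10_copies == 0] ==
                    "negative"))
  expect_true(all(ab10$n_rounds == 25L))
})

test_that("the two-stage B workflow recovers high and low copy carriers", {
  s <- shared_sim()
  b <- shared_calls()$b
  tt <- s$ds$truth[match(b$sample_id, s$ds$truth$sample_id), ]
  expect_true(all(b$call[tt$b_copies > 0] == "positive"))
  expect_true(all(b$call[tt$b_copies == 0] == "negative"))
  # every sample appears exactly once in the final table
  expect_equal(anyDuplicated(b$sample_id), 0L)
})

test_that("calling is reproducible under a fixed seed", {
  s <- shared_sim()
  exp_ids <- intersect(s$ds$manifest$sample_id[
    s$ds$manifest$sample_class == "experimental"],
    colnames(s$scaled$values))[1:8]
  a <- call_cdh(s$scaled, s$ds$manifest, "Ab10", exp_ids = exp_ids,
                rounds = 10, seed = 123)
  b <- call_cdh(s$scaled, s$ds$manifest, "Ab10", exp_ids = exp_ids,
                rounds = 10, seed = 123)
  expect_identical(a, b)
})
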