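# Fixtures are built in code; the heavier simulated dataset is memoised so
# the suite pays for it once.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a tiny deterministic tag matrix: 4 tags x 3 samples
tiny_tags <- function() {
  loc <- tibble::tibble(
    tag_id = paste0("t", 1:4),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(0L, 100L, 1500000L, 10L),
    end = c(64L, 164L, 1500064L, 74L),
    mapq = c(60L, 19L, 60L, 20L))
  counts <- matrix(c(5L, 0L, 2L,
                     1L, 1L, 0L,
                     0L, 3L, 4L,
                     2L, 0L, 0L),
                   nrow = 4, byrow = TRUE,
                   dimnames = list(loc$tag_id, c("s1", "s2", "s3")))
  tag_matrix(counts, loc)
}

tiny_manifest <- function() {
  tibble::tibble(
    sample_id = c("s1", "s2", "s3"),
    sample_class = c("control", "control", "blank"),
    Ab10 = c("positive", "negative", "unknown"),
    K10L2 = c("negative", "negative", "unknown"),
    B = c("negative", "negative", "unknown"),
    copy_class = c("low", "unknown", "unknown"),
    ab10_type = c("I", "unknown", "unknown"))
}

# the shared well-separated simulated study: tag dataset, unscaled and
# scaled bin indices (post filtering)
shared_sim <- function() {
  memo("shared_sim", {
    cfg <- sim_config(seed = 42)
    ds <- simulate_tag_dataset(cfg)
    norm <- rpm_normalize(ds$tags)
    cutoff <- blank_missingness_cutoff(norm, ds$manifest)
    filt <- suppressMessages(filter_samples_and_tags(norm, cutoff))
    idx <- bin_tag_index(filt, ds$bins)
    list(cfg = cfg, ds = ds, idx = idx, scaled = minmax_scale(idx))
  })
}

# consensus calls of the shared study at a reduced round count (the
# calling loop is exercised at full depth in the acceptance suite)
shared_calls <- function() {
  memo("shared_calls", {
    s <- shared_sim()
    chr10 <- chr10_workflow(s$scaled, s$scaled, s$ds$manifest,
                            rounds = 25, seed = 7)
    b <- b_two_stage_workflow(s$scaled, s$ds$manifest, rounds = 25, seed = 7)
    list(chr10 = chr10, b = b)
  })
}

expect_tsv_roundtrip <- function(write_fn, read_fn, x) {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fn(x, path)
  expect_equal(as.data.frame(read_fn(path)), as.data.frame(x))
}
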