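# Internal helpers shared across modules.

# Derive a stage-specific seed from a master seed so stages are independently
# reproducible. Kept below 2^31 - 1.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647L)
}

`%theninform%` <- function(n, msg) {
  if (n > 0) inform(sprintf(msg, n))
  invisible(n)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}

# Write a tibble to TSV with a provenance comment header; `read_prov_tsv()`
# skips it. Used by the pipeline stage writers.
write_prov_tsv <- function(x, path, seed = NULL, config_hash = NULL) {
  hdr <- sprintf("# cdhscan seed=%s config=%s",
                 seed %||% "NA", config_hash %||% "NA")
  body <- sub("\n$", "", readr::format_tsv(x, na = ""))
  writeLines(c(hdr, body), path)
  invisible(path)
}

read_prov_tsv <- function(path, col_types = NULL) {
  readr::read_tsv(path, comment = "#", col_types = col_types %||% readr::cols(),
                  progress = FALSE, show_col_types = FALSE)
}
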