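#' Assemble a full-run configuration
#'
#' Collects every threshold of the pipeline in one declarative object with
#' the standard defaults: 1 Mb bins, mapping quality 20, blank-missingness
#' offset 0.001, 80% cluster-naming purity, experimental spike fractions
#' 0.25 (chromosome 10) and 0.10 (B), 125 rounds, 95% consensus, 70%
#' random-forest training fraction, 65% vote threshold, genome-wide
#' significance 5e-8, stepwise alpha 0.01 and collinearity threshold 0.70.
#' The configuration (including the master seed) is serialised into the
#' output directory, and every output file header records its hash.
#'
#' @param sim a [sim_config()] describing the synthetic dataset to run on,
#'   or `NULL` when `input` paths are given
#' @param input optional named list of paths: `counts`, `bed`, `manifest`,
#'   `bins`
#' @param seed master seed; each stage derives its own sub-seed from it
#' @param min_mapq,blank_offset,purity,spike_chr10,spike_b,rounds,
#'   consensus,train_frac,vote_threshold,gwas_threshold,alpha,
#'   collinearity,retry_cap pipeline thresholds (see above)
#' @param association run the association stage on a simulated
#'   genotype/environment dataset (logical)
#' @param assoc named list of arguments for
#'   [simulate_association_dataset()] used when `association = TRUE`
#' @return an object of class `run_config`
#' @export
run_config <- function(sim = sim_config(), input = NULL, seed = 1,
                       min_mapq = 20, blank_offset = 0.001, purity = 0.80,
                       spike_chr10 = 0.25, spike_b = 0.10, rounds = 125,
                       consensus = 0.95, train_frac = 0.70,
                       vote_threshold = 0.65, gwas_threshold = 5e-8,
                       alpha = 0.01, collinearity = 0.70, retry_cap = 50,
                       association = FALSE,
                       assoc = list(n = 600, n_snps = 300, k_pops = 3)) {
  if (is.null(sim) && is.null(input)) {
    abort("either `sim` or `input` paths must be supplied")
  }
  structure(list(sim = sim, input = input, seed = as.integer(seed),
                 min_mapq = min_mapq, blank_offset = blank_offset,
                 purity = purity, spike_chr10 = spike_chr10,
                 spike_b = spike_b, rounds = rounds, consensus = consensus,
                 train_frac = train_frac, vote_threshold = vote_threshold,
                 gwas_threshold = gwas_threshold, alpha = alpha,
                 collinearity = collinearity, retry_cap = retry_cap,
                 association = association, assoc = assoc),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)), parent = e)
  })
}

#' Run the end-to-end pipeline
#'
#' Executes tag-index computation, the sequential chromosome-10 and
#' two-stage B calling workflows, pseudo-copy-number estimation with
#' zygosity, Ab10 typing of called positives, and (optionally) the
#' association stage, writing every stage's tables into `out_dir`.
#' Re-running with the same configuration and seed reproduces every
#' output byte for byte.
#'
#' @param config a [run_config()]
#' @param out_dir output directory (created if missing)
#' @return invisibly, a list with the in-memory stage results and the
#'   paths written
#' @export
run_full <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- substr(rlang::hash(unclass(config)), 1, 12)
  wr <- function(x, name) {
    write_prov_tsv(x, file.path(out_dir, name), seed = config$seed,
                   config_hash = hash)
  }
  paths <- character()

  ds <- stage("input", {
    if (!is.null(config$sim)) {
      sim <- config$sim
      sim$seed <- derive_seed(config$seed, "simulate")
      simulate_tag_dataset(sim)
    } else {
      list(tags = read_tag_matrix(config$input$counts, config$input$bed),
           manifest = read_manifest(config$input$manifest),
           truth = NULL,
           bins = read_bin_definitions(config$input$bins))
    }
  })

  idx <- stage("tagindex", {
    norm <- rpm_normalize(ds$tags)
    cutoff <- blank_missingness_cutoff(norm, ds$manifest,
                                       offset = config$blank_offset)
    filtered <- filter_samples_and_tags(norm, cutoff,
                                        min_mapq = config$min_mapq)
    unscaled <- bin_tag_index(filtered, ds$bins)
    scaled <- minmax_scale(unscaled)
    wr(tibble::as_tibble(unscaled$values, rownames = "label"),
       "bin_index_unscaled.tsv")
    wr(tibble::as_tibble(scaled$values, rownames = "label"),
       "bin_index_scaled.tsv")
    list(unscaled = unscaled, scaled = scaled, cutoff = cutoff)
  })

  calls <- stage("call", {
    chr10 <- chr10_workflow(idx$scaled, idx$scaled, ds$manifest,
                            rounds = config$rounds,
                            consensus = config$consensus,
                            purity = config$purity,
                            spike_fraction = config$spike_chr10,
                            retry_cap = config$retry_cap,
                            seed = derive_seed(config$seed, "chr10"))
    b <- b_two_stage_workflow(idx$scaled, ds$manifest,
                              spike_fraction = config$spike_b,
                              rounds = config$rounds,
                              consensus = config$consensus,
                              purity = config$purity,
                              retry_cap = config$retry_cap,
                              seed = derive_seed(config$seed, "bchrom"))
    all_calls <- dplyr::bind_rows(chr10, b[, names(chr10)])
    wr(all_calls, "calls.tsv")
    all_calls
  })

  cn <- stage("copynumber", {
    ests <- purrr::map_dfr(CDH_NAMES, function(cdh) {
      e <- pseudo_copy_number(idx$unscaled, idx$unscaled, cdh)
      if (cdh != "B") e <- classify_zygosity(e, ds$manifest, cdh)
      else e$zygosity <- "unknown"
      e
    })
    wr(ests, "copy_number.tsv")
    ests
  })

  typing <- stage("type", {
    typer <- train_typer(idx$scaled, ds$manifest,
                         train_frac = config$train_frac,
                         seed = derive_seed(config$seed, "typer"))
    ab10_pos <- calls$sample_id[calls$cdh == "Ab10" &
                                  calls$call == "positive"]
    types <- if (length(ab10_pos)) {
      call_types(typer, idx$scaled, sample_ids = ab10_pos,
                 vote_threshold = config$vote_threshold)
    } else tibble::tibble()
    if (nrow(types)) wr(types, "ab10_types.tsv")
    list(typer = typer, types = types)
  })

  assoc <- NULL
  if (isTRUE(config$association)) {
    assoc <- stage("association", {
      args <- config$assoc
      args$seed <- derive_seed(config$seed, "assoc")
      geno <- do.call(simulate_association_dataset, args)
      pcs <- structure_pcs(geno, k = min(10, nrow(geno$dosage) - 1))
      scan <- gwas(geno, geno$phenotype, pcs$scores,
                   family = "binomial", threshold = config$gwas_threshold)
      wr(scan, "gwas.tsv")
      list(geno = geno, pcs = pcs, scan = scan)
    })
  }

  cfg_path <- file.path(out_dir, "config.json")
  stage("provenance", {
    writeLines(config_to_json(config, hash), cfg_path)
  })
  invisible(list(dataset = ds, index = idx, calls = calls,
                 copy_number = cn, typing = typing, association = assoc,
                 out_dir = out_dir))
}

config_to_json <- function(config, hash) {
  x <- unclass(config)
  x$sim <- if (!is.null(x$sim)) unclass(x$sim) else NULL
  if (!is.null(x$sim)) {
    x$sim$genome <- as.list(x$sim$genome)
    x$sim$regions <- NULL          # bins are written alongside, not inline
  }
  x$config_hash <- hash
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                     null = "null")
  } else {
    paste(utils::capture.output(utils::str(x)), collapse = "\n")
  }
}
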