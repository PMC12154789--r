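#' Default simulated genome and bin layout
#'
#' The simulated reference mimics a concatenated mapping target: the Ab10
#' haplotype (20 Mb, of which the distal 12 Mb are Ab10-diagnostic and the
#' proximal 8 Mb are shared with normal chromosome 10), the K10L2 haplotype
#' (12 Mb, distal 8 Mb diagnostic), the uniquely mappable portion of the B
#' chromosome (6 Mb, all diagnostic -- the B is mostly repeats, so its
#' unique tag space is small), and a 1000 Mb single-copy backbone standing
#' in for the rest of the genome and used for copy-number normalisation.
#' The backbone dwarfs the diagnostic regions on purpose: reads-per-million
#' normalisation is compositional, and only when diagnostic regions are a
#' small share of the tag space (as in the real genome) does carrying one
#' CDH leave the scaled signal of another usable.
#' Because the Ab10 haplotype contains sequence closely
#' related to K10L2, simulated Ab10 carriers also produce signal in the
#' K10L2 diagnostic bins -- the property that forces the sequential
#' chromosome-10 workflow. Within the Ab10 diagnostic region the last six
#' bins are type-specific (two bins each for cytological types I, II, III).
#'
#' @return a list with `genome` (tibble chrom/length) and `regions`
#'   (tibble of 1 Mb bin definitions)
#' @export
default_sim_regions <- function() {
  genome <- tibble::tibble(
    chrom = c("Ab10", "K10L2", "B", "core"),
    length = c(20e6, 12e6, 6e6, 1000e6))
  mk <- function(chrom, n) {
    tibble::tibble(chrom = chrom,
                   start = as.integer((seq_len(n) - 1) * 1e6),
                   end = as.integer(seq_len(n) * 1e6),
                   label = sprintf("%s_bin%02d", chrom, seq_len(n)))
  }
  ab10 <- mk("Ab10", 20)
  ab10$diagnostic_for <- c(rep(NA_character_, 8), rep("Ab10", 12))
  ab10$type_specific <- c(rep(NA_character_, 14),
                          "I", "I", "II", "II", "III", "III")
  k10 <- mk("K10L2", 12)
  k10$diagnostic_for <- c(rep(NA_character_, 4), rep("K10L2", 8))
  k10$type_specific <- NA_character_
  b <- mk("B", 6)
  b$diagnostic_for <- "B"
  b$type_specific <- NA_character_
  core <- mk("core", 1000)
  core$diagnostic_for <- NA_character_
  core$type_specific <- NA_character_
  regions <- dplyr::bind_rows(ab10, k10, b, core)
  regions$single_copy <- regions$chrom == "core"
  list(genome = genome, regions = regions)
}

#' Simulation configuration
#'
#' Assembles and validates the configuration of the tag-count simulator.
#' Counts are negative binomial (GBS depth is overdispersed) with a
#' log-normal per-sample library-size factor. Tags in a CDH's diagnostic
#' bins have their mean multiplied by `dosage_effect * copy_number` in
#' carriers and reduced to a small mis-mapping floor (`background_rate`)
#' in non-carriers. Blank wells draw from a sparse low-count contaminant
#' model so that their missingness exceeds every real sample.
#'
#' @param n_controls_pos positive controls per CDH (split evenly between
#'   high and low copy classes)
#' @param n_controls_neg shared CDH-negative controls
#' @param n_experimental experimental (unknown-status) samples
#' @param n_blanks blank wells (no genomic DNA)
#' @param genome,regions genome table and bin definitions; defaults from
#'   [default_sim_regions()]
#' @param tag_density expected GBS tags per Mb (the paper's data fix no
#'   value; the default is arbitrary and configurable)
#' @param baseline_mean expected reads per tag at one genomic copy
#' @param dispersion negative-binomial overdispersion (variance
#'   `mu + dispersion * mu^2`)
#' @param dosage_effect multiplicative count factor per CDH copy (> 1)
#' @param libsize_sigma log-normal sd of the per-sample library factor
#' @param missing_rate probability a tag drops out of a sample
#' @param background_rate mean multiplier of diagnostic tags in
#'   non-carriers (mis-mapping noise floor)
#' @param blank_tag_prob probability a tag shows any contaminant reads in
#'   a blank
#' @param prevalence named vector of carrier probabilities among
#'   experimental samples
#' @param hom_frac fraction of experimental chromosome-10 carriers that are
#'   homozygous
#' @param b_copy_max maximum simulated B chromosome copy number
#' @param b_copy_dist carrier B copy-number distribution: `"pois"`
#'   (1 + Poisson(2), the typical 1-3 copy landrace regime) or
#'   `"uniform"` (uniform on 1..`b_copy_max`, for dosage-recovery studies)
#' @param recombinant_frac fraction of experimental Ab10 carriers given a
#'   mixed (type I + type II) signature, emulating natural recombinants
#' @param seed integer; fully determines the output
#' @return an object of class `sim_config`
#' @export
sim_config <- function(n_controls_pos = 20, n_controls_neg = 20,
                       n_experimental = 30, n_blanks = 2,
                       genome = NULL, regions = NULL,
                       tag_density = 50,
                       baseline_mean = 20, dispersion = 0.3,
                       dosage_effect = 10, libsize_sigma = 0.3,
                       missing_rate = 0.05, background_rate = 0.02,
                       blank_tag_prob = 0.01,
                       prevalence = c(Ab10 = 0.15, K10L2 = 0.15, B = 0.2),
                       hom_frac = 0.25, b_copy_max = 14,
                       b_copy_dist = c("pois", "uniform"),
                       recombinant_frac = 0.3, seed = 1) {
  b_copy_dist <- match.arg(b_copy_dist)
  if (is.null(genome) || is.null(regions)) {
    def <- default_sim_regions()
    genome <- genome %||% def$genome
    regions <- regions %||% def$regions
  }
  assert_scalar_number(dosage_effect, "dosage_effect", lower = 1 + 1e-9)
  for (nm in c("missing_rate", "background_rate", "blank_tag_prob",
               "hom_frac", "recombinant_frac")) {
    assert_scalar_number(get(nm), nm, lower = 0, upper = 1)
  }
  if (any(prevalence < 0) || any(prevalence > 1)) {
    abort("prevalence values must be in [0, 1]")
  }
  chrom_len <- setNames(genome$length, genome$chrom)
  if (!all(regions$chrom %in% genome$chrom)) {
    abort("bin definitions reference chromosomes absent from the genome")
  }
  if (any(regions$end > chrom_len[regions$chrom])) {
    abort("bin definitions extend beyond chromosome ends")
  }
  check_bins_nonoverlapping(regions)
  structure(list(
    n_controls_pos = n_controls_pos, n_controls_neg = n_controls_neg,
    n_experimental = n_experimental, n_blanks = n_blanks,
    genome = genome, regions = tibble::as_tibble(regions),
    tag_density = tag_density, baseline_mean = baseline_mean,
    dispersion = dispersion, dosage_effect = dosage_effect,
    libsize_sigma = libsize_sigma, missing_rate = missing_rate,
    background_rate = background_rate, blank_tag_prob = blank_tag_prob,
    prevalence = prevalence, hom_frac = hom_frac, b_copy_max = b_copy_max,
    b_copy_dist = b_copy_dist,
    recombinant_frac = recombinant_frac, seed = as.integer(seed)),
    class = "sim_config")
}

# Per-sample truth table: copies of each CDH plus Ab10 type.
simulate_truth <- function(config) {
  pos <- purrr::map_dfr(CDH_NAMES, function(cdh) {
    n <- config$n_controls_pos
    if (n == 0) return(tibble::tibble())
    n_high <- ceiling(n / 2)
    copy_class <- c(rep("high", n_high), rep("low", n - n_high))
    copies <- if (cdh == "B") ifelse(copy_class == "high", 8L, 1L) else
      ifelse(copy_class == "high", 2L, 1L)
    tt <- tibble::tibble(
      sample_id = sprintf("ctrl_%s_pos_%02d", tolower(cdh), seq_len(n)),
      sample_class = "control",
      ab10_copies = if (cdh == "Ab10") copies else 0L,
      k10l2_copies = if (cdh == "K10L2") copies else 0L,
      b_copies = if (cdh == "B") copies else 0L,
      copy_class = copy_class,
      ab10_type = if (cdh == "Ab10")
        rep(c("I", "II", "III"), length.out = n) else "unknown")
    tt
  })
  neg <- tibble::tibble(
    sample_id = sprintf("ctrl_neg_%02d", seq_len(config$n_controls_neg)),
    sample_class = "control", ab10_copies = 0L, k10l2_copies = 0L,
    b_copies = 0L, copy_class = "unknown", ab10_type = "unknown")
  n_exp <- config$n_experimental
  exp <- tibble::tibble(
    sample_id = sprintf("exp_%03d", seq_len(n_exp)),
    sample_class = rep("experimental", n_exp),
    ab10_copies = 0L, k10l2_copies = 0L, b_copies = 0L,
    copy_class = "unknown", ab10_type = "unknown")
  if (n_exp > 0) {
    # chromosome 10 carries Ab10 or K10L2, not both (one pair of homologs;
    # carriers are mostly heterozygous)
    chr10 <- runif(n_exp)
    p_ab <- config$prevalence[["Ab10"]]; p_k <- config$prevalence[["K10L2"]]
    ncopy <- ifelse(runif(n_exp) < config$hom_frac, 2L, 1L)
    exp$ab10_copies <- ifelse(chr10 < p_ab, ncopy, 0L)
    exp$k10l2_copies <- ifelse(chr10 >= p_ab & chr10 < p_ab + p_k, ncopy, 0L)
    b_carrier <- runif(n_exp) < config$prevalence[["B"]]
    b_copies <- if (identical(config$b_copy_dist, "uniform")) {
      sample.int(config$b_copy_max, n_exp, replace = TRUE)
    } else {
      1L + rpois(n_exp, 2)
    }
    exp$b_copies <- ifelse(b_carrier, pmin(b_copies, config$b_copy_max), 0L)
    is_ab <- exp$ab10_copies > 0
    exp$ab10_type[is_ab] <- ifelse(
      runif(sum(is_ab)) < config$recombinant_frac, "R",
      sample(c("I", "II", "III"), sum(is_ab), replace = TRUE))
  }
  blank <- tibble::tibble(
    sample_id = sprintf("blank_%02d", seq_len(config$n_blanks)),
    sample_class = "blank", ab10_copies = 0L, k10l2_copies = 0L,
    b_copies = 0L, copy_class = "unknown", ab10_type = "unknown")
  dplyr::bind_rows(pos, neg, exp, blank)
}

truth_to_manifest <- function(truth) {
  status <- function(copies, known) {
    dplyr::case_when(!known ~ "unknown", copies > 0 ~ "positive",
                     TRUE ~ "negative")
  }
  known <- truth$sample_class == "control"
  # the K10L2 assay cannot distinguish Ab10 from K10L2, so Ab10-positive
  # controls are unusable as K10L2-negative controls
  k10_known <- known & truth$ab10_copies == 0
  tibble::tibble(
    sample_id = truth$sample_id,
    sample_class = truth$sample_class,
    Ab10 = status(truth$ab10_copies, known),
    K10L2 = status(truth$k10l2_copies, k10_known),
    B = status(truth$b_copies, known),
    copy_class = ifelse(known, truth$copy_class, "unknown"),
    ab10_type = ifelse(known, truth$ab10_type, "unknown"))
}

#' Simulate a GBS tag dataset with known CDH truth
#'
#' Generates a [tag_matrix()], a validated sample manifest and the hidden
#' truth table under the count model described in [sim_config()]. The same
#' seed always yields the identical dataset.
#'
#' @param config a [sim_config()]
#' @return a list with elements `tags` ([tag_matrix()]), `manifest`
#'   (tibble), `truth` (tibble, includes experimental samples' hidden
#'   status) and `bins` (bin definitions used)
#' @export
simulate_tag_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  regions <- config$regions

  # tag positions: uniform per chromosome at the configured density
  tags <- purrr::map_dfr(seq_len(nrow(config$genome)), function(i) {
    ch <- config$genome$chrom[i]; len <- config$genome$length[i]
    n <- max(1L, as.integer(round(len / 1e6 * config$tag_density)))
    start <- sort(sample.int(as.integer(len - 64L), n))
    tibble::tibble(chrom = ch, start = start, end = start + 64L)
  })
  tags$tag_id <- sprintf("t%05d", seq_len(nrow(tags)))
  # most tags map cleanly; a minority at low mapping quality exercises the
  # mapq filter downstream
  tags$mapq <- ifelse(runif(nrow(tags)) < 0.10,
                      sample(0:19, nrow(tags), replace = TRUE), 60L)

  truth <- simulate_truth(config)
  manifest <- validate_manifest(truth_to_manifest(truth))
  n_tags <- nrow(tags); n_samp <- nrow(truth)

  # map each tag to its bin's annotation
  bin_of <- assign_tags_to_bins(tags, regions)
  diag_cdh <- regions$diagnostic_for[bin_of]
  type_of <- if ("type_specific" %in% names(regions))
    regions$type_specific[bin_of] else rep(NA_character_, n_tags)
  diag_cdh[is.na(bin_of)] <- NA_character_

  # dosage multiplier per tag x sample
  mult <- matrix(1, n_tags, n_samp)
  copies <- cbind(Ab10 = truth$ab10_copies,
                  K10L2 = truth$k10l2_copies + truth$ab10_copies,
                  B = truth$b_copies)
  for (cdh in CDH_NAMES) {
    sel <- !is.na(diag_cdh) & diag_cdh == cdh
    if (!any(sel)) next
    cp <- copies[, cdh]
    m <- ifelse(cp > 0, config$dosage_effect * cp, config$background_rate)
    mult[sel, ] <- rep(m, each = sum(sel))
  }
  # Ab10 type-specific bins: signal only when the sample's type matches
  # (recombinants "R" combine type I and II signatures)
  has_type <- !is.na(type_of)
  if (any(has_type)) {
    for (ty in c("I", "II", "III")) {
      sel <- has_type & type_of == ty
      if (!any(sel)) next
      match_ty <- truth$ab10_type == ty |
        (truth$ab10_type == "R" & ty %in% c("I", "II"))
      off <- truth$ab10_copies > 0 & !match_ty
      if (any(off)) {
        mult[sel, off] <- config$background_rate
      }
    }
  }

  lib <- exp(rnorm(n_samp, 0, config$libsize_sigma))
  mu <- config$baseline_mean * mult * rep(lib, each = n_tags)
  counts <- matrix(rnbinom(n_tags * n_samp, mu = mu,
                           size = 1 / config$dispersion),
                   n_tags, n_samp)
  counts[matrix(runif(n_tags * n_samp) < config$missing_rate,
                n_tags, n_samp)] <- 0L
  blanks <- truth$sample_class == "blank"
  if (any(blanks)) {
    for (j in which(blanks)) {
      hit <- rbinom(n_tags, 1, config$blank_tag_prob)
      counts[, j] <- hit * (1L + rpois(n_tags, 1))
    }
  }
  storage.mode(counts) <- "integer"
  colnames(counts) <- truth$sample_id
  tm <- tag_matrix(counts, tags[, c("tag_id", "chrom", "start", "end", "mapq")],
                   truth$sample_id)
  list(tags = tm, manifest = manifest, truth = truth, bins = regions)
}

#' Simulate a structured genotype/environment/phenotype dataset
#'
#' Genotypes are drawn from a k-population admixture model: ancestral allele
#' frequencies diverge across populations by a Balding-Nichols model with
#' divergence `fst`, individual admixture proportions are Dirichlet, and
#' dosages are binomial in the individual-specific frequency. Environment
#' variables are generated with a stated correlation to the admixture
#' proportions, and a binary phenotype is drawn from a logistic model over
#' the causal SNPs and environment variables.
#'
#' @param n number of individuals
#' @param n_snps number of biallelic SNPs
#' @param k_pops number of source populations (>= 1)
#' @param causal_snps tibble with columns `snp` (index), `or` (odds ratio
#'   per minor allele, > 0) and optionally `maf` (target minor-allele
#'   frequency of that SNP)
#' @param causal_env tibble with columns `var` (environment variable name)
#'   and `beta` (logistic coefficient)
#' @param fst Balding-Nichols divergence among populations
#' @param n_env number of environment variables (`env1`, `env2`, ...)
#' @param env_corr share of environment variance explained by admixture
#' @param prevalence approximate phenotype prevalence
#' @param seed integer seed; fully determines the output
#' @return a list of class `cdh_genotypes` with `dosage` (n x n_snps),
#'   `depth`, `gq` (same shape), `snp_info`, `env` (tibble), `phenotype`
#'   (0/1 vector named by sample), `admixture` (n x k matrix)
#' @export
simulate_association_dataset <- function(n, n_snps, k_pops = 3,
                                         causal_snps = NULL,
                                         causal_env = NULL,
                                         fst = 0.15, n_env = 3,
                                         env_corr = 0.6,
                                         prevalence = 0.3, seed = 1) {
  if (!is.null(causal_snps)) {
    if (any(causal_snps$or <= 0)) abort("odds ratios must be > 0")
    if (nrow(causal_snps) > n_snps) abort("more causal SNPs than SNPs")
  }
  if (k_pops < 1) abort("k_pops must be >= 1")
  set.seed(as.integer(seed))
  p_anc <- runif(n_snps, 0.1, 0.9)
  if (fst > 0 && k_pops > 1) {
    a <- p_anc * (1 - fst) / fst
    b <- (1 - p_anc) * (1 - fst) / fst
    pops <- matrix(stats::rbeta(k_pops * n_snps, rep(a, each = k_pops),
                                rep(b, each = k_pops)), k_pops, n_snps)
  } else {
    pops <- matrix(rep(p_anc, each = k_pops), k_pops, n_snps)
  }
  if (!is.null(causal_snps) && "maf" %in% names(causal_snps)) {
    for (i in seq_len(nrow(causal_snps))) {
      if (!is.na(causal_snps$maf[i])) {
        # undifferentiated causal SNP at the requested frequency
        pops[, causal_snps$snp[i]] <- causal_snps$maf[i]
      }
    }
  }
  q <- matrix(rgamma(n * k_pops, shape = 0.8), n, k_pops)
  q <- q / rowSums(q)
  freq <- q %*% pops
  dosage <- matrix(rbinom(n * n_snps, 2, freq), n, n_snps)
  sample_ids <- sprintf("ind_%04d", seq_len(n))
  snp_ids <- sprintf("snp%05d", seq_len(n_snps))
  dimnames(dosage) <- list(sample_ids, snp_ids)
  depth <- matrix(rnbinom(n * n_snps, mu = 10, size = 5), n, n_snps,
                  dimnames = dimnames(dosage))
  gq <- matrix(pmin(99L, pmax(0L, as.integer(round(rnorm(n * n_snps, 85, 12))))),
               n, n_snps, dimnames = dimnames(dosage))
  snp_info <- tibble::tibble(
    snp = snp_ids,
    chrom = paste0("chr", rep_len(1:10, n_snps)),
    pos = as.integer(seq(1e5, 2e8, length.out = n_snps)),
    ref = "A", alt = "T")
  env <- matrix(0, n, n_env,
                dimnames = list(sample_ids, paste0("env", seq_len(n_env))))
  for (j in seq_len(n_env)) {
    w <- rnorm(k_pops)
    struct <- as.numeric(q %*% w)
    struct <- if (sd(struct) > 0) scale(struct)[, 1] else rep(0, n)
    env[, j] <- sqrt(env_corr) * struct + sqrt(1 - env_corr) * rnorm(n)
  }
  eta <- rep(qlogis(prevalence), n)
  if (!is.null(causal_snps)) {
    for (i in seq_len(nrow(causal_snps))) {
      g <- dosage[, causal_snps$snp[i]]
      eta <- eta + log(causal_snps$or[i]) * (g - mean(g))
    }
  }
  if (!is.null(causal_env)) {
    for (i in seq_len(nrow(causal_env))) {
      e <- env[, causal_env$var[i]]
      eta <- eta + causal_env$beta[i] * (e - mean(e))
    }
  }
  phenotype <- setNames(rbinom(n, 1, plogis(eta)), sample_ids)
  structure(list(dosage = dosage, depth = depth, gq = gq,
                 snp_info = snp_info,
                 env = tibble::as_tibble(env) |>
                   tibble::add_column(sample_id = sample_ids, .before = 1),
                 phenotype = phenotype, admixture = q,
                 sample_ids = sample_ids),
            class = "cdh_genotypes")
}

#' @export
print.cdh_genotypes <- function(x, ...) {
  cat(sprintf("<cdh_genotypes> %d samples x %d SNPs\n",
              nrow(x$dosage), ncol(x$dosage)))
  invisible(x)
}
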