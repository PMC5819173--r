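#' Simulation configuration for paired mouse/human expression data
#'
#' Bundles and validates the parameters of the synthetic-data generator.
#' The generator plants sex-differential expression in a mouse count matrix
#' and a human count matrix whose per-gene female-minus-male direction
#' agrees with the mouse direction at a controlled rate, so the
#' cross-species concordance machinery can be validated against known
#' ground truth.
#'
#' Sex-differential ("DE") genes carry a log2 fold change of
#' `effect_log2fc` in both species; the human sign matches the mouse sign
#' with probability `concordance_rate`. All remaining genes carry a small
#' sub-threshold shift of `background_log2fc` in both species whose signs
#' agree with probability `background_concordance`; this is what gives the
#' resampling null its non-trivial "chance concordance" base rate. Setting
#' `background_log2fc = 0` removes the background signal entirely
#' (a global null for the non-DE genes).
#'
#' @param n_genes number of genes simulated in each species.
#' @param samples_per_sex_mouse,samples_per_sex_human samples per sex
#'   (>= 2) in each species.
#' @param frac_sex_de fraction of genes planted as sex-differential.
#' @param effect_log2fc absolute log2 fold change (female vs male) planted
#'   in DE genes.
#' @param background_log2fc absolute log2 fold change planted in non-DE
#'   genes (0 disables the background effect).
#' @param nb_dispersion negative-binomial dispersion shared across genes
#'   (variance = mu + dispersion * mu^2).
#' @param baseline_log_mean_range range (natural log of expected counts)
#'   from which per-gene baseline means are drawn log-uniformly.
#' @param concordance_rate probability that a DE gene's human sign matches
#'   its mouse sign.
#' @param background_concordance sign-match probability for non-DE genes.
#' @param corr_block_size genes per correlation block (1 = independent
#'   genes).
#' @param corr_rho target within-block correlation of log counts.
#' @param frac_unmapped fraction of genes left out of the orthology map.
#' @param seed integer seed; identical configurations reproduce
#'   bit-identical datasets.
#'
#' @return A validated list of class `sim_config`.
#' @seealso [generate_paired_expression()]
#' @export
sim_config <- function(n_genes = 2400,
                       samples_per_sex_mouse = 8,
                       samples_per_sex_human = 20,
                       frac_sex_de = 0.25,
                       effect_log2fc = 1.5,
                       background_log2fc = 0.7,
                       nb_dispersion = 0.05,
                       baseline_log_mean_range = log(c(50, 5000)),
                       concordance_rate = 0.49,
                       background_concordance = 0.28,
                       corr_block_size = 1,
                       corr_rho = 0,
                       frac_unmapped = 0,
                       seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes", min = 1L)
  samples_per_sex_mouse <- check_count(samples_per_sex_mouse,
                                       "samples_per_sex_mouse", min = 2L)
  samples_per_sex_human <- check_count(samples_per_sex_human,
                                       "samples_per_sex_human", min = 2L)
  check_fraction(frac_sex_de, "frac_sex_de")
  check_fraction(concordance_rate, "concordance_rate")
  check_fraction(background_concordance, "background_concordance")
  check_fraction(frac_unmapped, "frac_unmapped")
  check_positive(effect_log2fc, "effect_log2fc")
  if (!is.numeric(background_log2fc) || length(background_log2fc) != 1L ||
      is.na(background_log2fc) || background_log2fc < 0) {
    stop_field("background_log2fc", "must be a single number >= 0")
  }
  check_positive(nb_dispersion, "nb_dispersion")
  if (!is.numeric(baseline_log_mean_range) ||
      length(baseline_log_mean_range) != 2L ||
      any(!is.finite(baseline_log_mean_range)) ||
      baseline_log_mean_range[1] > baseline_log_mean_range[2]) {
    stop_field("baseline_log_mean_range",
               "must be an increasing pair of finite reals")
  }
  corr_block_size <- check_count(corr_block_size, "corr_block_size", min = 1L)
  if (!is.numeric(corr_rho) || length(corr_rho) != 1L || is.na(corr_rho) ||
      corr_rho < 0 || corr_rho >= 1) {
    stop_field("corr_rho", "must be a single number in [0, 1)")
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_field("seed", "must be a single finite integer")
  }
  structure(
    list(n_genes = n_genes,
         samples_per_sex_mouse = samples_per_sex_mouse,
         samples_per_sex_human = samples_per_sex_human,
         frac_sex_de = frac_sex_de,
         effect_log2fc = effect_log2fc,
         background_log2fc = background_log2fc,
         nb_dispersion = nb_dispersion,
         baseline_log_mean_range = baseline_log_mean_range,
         concordance_rate = concordance_rate,
         background_concordance = background_concordance,
         corr_block_size = corr_block_size,
         corr_rho = corr_rho,
         frac_unmapped = frac_unmapped,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Construct an expression dataset
#'
#' A thin validated container for a gene-by-sample count matrix with
#' per-sample sex labels and a species tag.
#'
#' @param counts non-negative integer matrix, genes in rows; must carry
#'   row and column names.
#' @param sex character vector of per-sample labels, `"F"` or `"M"`, with
#'   at least two samples of each.
#' @param species species label, e.g. `"mouse"` or `"human"`.
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `counts`, `sex`, `species`, `gene_ids`, `sample_ids`.
#' @export
expression_dataset <- function(counts, sex, species) {
  if (!is.matrix(counts) || is.null(rownames(counts)) ||
      is.null(colnames(counts))) {
    stop_field("counts", "must be a matrix with gene row names and sample column names")
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    stop_field("counts", "gene and sample ids must be unique")
  }
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop_field("counts", "entries must be finite non-negative integers")
  }
  sex <- as.character(sex)
  if (length(sex) != ncol(counts) || !all(sex %in% c("F", "M"))) {
    stop_field("sex", "must be one 'F'/'M' label per sample")
  }
  if (sum(sex == "F") < 2L || sum(sex == "M") < 2L) {
    stop_field("sex", "need at least 2 samples of each sex")
  }
  if (!is.character(species) || length(species) != 1L) {
    stop_field("species", "must be a single label")
  }
  structure(
    list(counts = counts, sex = sex, species = species,
         gene_ids = rownames(counts), sample_ids = colnames(counts)),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d genes x %d samples (%s; %d F / %d M)\n",
              nrow(x$counts), ncol(x$counts), x$species,
              sum(x$sex == "F"), sum(x$sex == "M")))
  invisible(x)
}

#' Construct a one-to-one orthology map
#'
#' Pairs whose mouse or human identifier occurs more than once are dropped
#' (all offending pairs, not just the later ones), so the surviving map is
#' strictly one-to-one.
#'
#' @param mouse_gene,human_gene equal-length identifier vectors.
#' @return A data.frame of class `orthology_map` with columns
#'   `mouse_gene`, `human_gene`; the number of pairs dropped is stored in
#'   attribute `n_dropped`.
#' @export
orthology_map <- function(mouse_gene, human_gene) {
  if (length(mouse_gene) != length(human_gene)) {
    stop_field("pairs", "mouse_gene and human_gene must have equal length")
  }
  mouse_gene <- as.character(mouse_gene)
  human_gene <- as.character(human_gene)
  dup <- mouse_gene %in% mouse_gene[duplicated(mouse_gene)] |
    human_gene %in% human_gene[duplicated(human_gene)]
  out <- data.frame(mouse_gene = mouse_gene[!dup],
                    human_gene = human_gene[!dup],
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- sum(dup)
  class(out) <- c("orthology_map", "data.frame")
  out
}

# Per-sample negative-binomial count matrix for one species.
# mu_base: per-gene baseline means; sign/eff: planted female shift.
simulate_species_counts <- function(mu_base, sign, eff_log2fc, n_per_sex,
                                    dispersion, corr_block_size, corr_rho,
                                    species) {
  n_genes <- length(mu_base)
  n_samples <- 2L * n_per_sex
  sex <- rep(c("F", "M"), each = n_per_sex)
  # female group mean multiplied by 2^(sign * effect)
  mu <- matrix(mu_base, n_genes, n_samples)
  shift <- 2^(sign * eff_log2fc)
  mu[, sex == "F"] <- mu[, sex == "F"] * shift
  if (corr_block_size > 1L && corr_rho > 0) {
    # Shared per-sample lognormal latent factor within each gene block.
    # Its log-variance s2 is set from the target correlation of log
    # counts, using the NB dispersion as the squared biological CV:
    # rho ~ s2 / (s2 + dispersion).
    s2 <- corr_rho / (1 - corr_rho) * dispersion
    block <- ceiling(seq_len(n_genes) / corr_block_size)
    z <- matrix(rnorm(max(block) * n_samples, sd = sqrt(s2)),
                max(block), n_samples)
    mu <- mu * exp(z[block, , drop = FALSE] - s2 / 2)
  }
  counts <- matrix(rnbinom(n_genes * n_samples, mu = mu, size = 1 / dispersion),
                   n_genes, n_samples)
  storage.mode(counts) <- "integer"
  prefix <- substr(species, 1L, 1L)
  rownames(counts) <- sprintf("%sgene%05d", prefix, seq_len(n_genes))
  colnames(counts) <- sprintf("%s_%s%02d", species, sex,
                              c(seq_len(n_per_sex), seq_len(n_per_sex)))
  expression_dataset(counts, sex, species)
}

#' Generate paired mouse/human datasets with planted sex effects
#'
#' Draws negative-binomial count matrices for two species. DE genes carry
#' a `effect_log2fc` female-vs-male shift whose human direction matches the
#' mouse direction with probability `concordance_rate`; the remaining genes
#' carry a `background_log2fc` shift with match probability
#' `background_concordance` (or no shift at all when
#' `background_log2fc = 0`). Baseline means are drawn log-uniformly over
#' `baseline_log_mean_range`, independently per species. With
#' `corr_block_size > 1` a shared per-sample lognormal factor induces
#' positive gene-gene correlation within consecutive blocks.
#'
#' @param config a [sim_config()] object.
#' @return A list of class `paired_expression` with elements `mouse` and
#'   `human` ([expression_dataset()]), `map` ([orthology_map()]) and
#'   `truth` (class `synthetic_truth`: `de_flags`, `mouse_sign`,
#'   `human_sign`, `planted_concordance` — the realized sign-match
#'   fraction among DE genes — and `seed`).
#' @export
generate_paired_expression <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop_field("config", "must be a sim_config object")
  }
  with_seed(config$seed, {
    n <- config$n_genes
    n_de <- round(config$frac_sex_de * n)
    de_flags <- rep(FALSE, n)
    if (n_de > 0) de_flags[sample.int(n, n_de)] <- TRUE

    mouse_sign <- integer(n)
    if (config$background_log2fc > 0) {
      mouse_sign <- sample(c(-1L, 1L), n, replace = TRUE)
    } else if (n_de > 0) {
      mouse_sign[de_flags] <- sample(c(-1L, 1L), n_de, replace = TRUE)
    }
    match_prob <- ifelse(de_flags, config$concordance_rate,
                         config$background_concordance)
    agree <- rbinom(n, 1L, match_prob) == 1L
    human_sign <- ifelse(mouse_sign == 0L, 0L,
                         ifelse(agree, mouse_sign, -mouse_sign))

    eff <- ifelse(de_flags, config$effect_log2fc, config$background_log2fc)
    r <- config$baseline_log_mean_range
    mu_mouse <- exp(runif(n, r[1], r[2]))
    mu_human <- exp(runif(n, r[1], r[2]))

    mouse <- simulate_species_counts(mu_mouse, mouse_sign, eff,
                                     config$samples_per_sex_mouse,
                                     config$nb_dispersion,
                                     config$corr_block_size, config$corr_rho,
                                     "mouse")
    human <- simulate_species_counts(mu_human, human_sign, eff,
                                     config$samples_per_sex_human,
                                     config$nb_dispersion,
                                     config$corr_block_size, config$corr_rho,
                                     "human")

    keep <- rep(TRUE, n)
    n_drop <- round(config$frac_unmapped * n)
    if (n_drop > 0) keep[sample.int(n, n_drop)] <- FALSE
    map <- orthology_map(mouse$gene_ids[keep], human$gene_ids[keep])

    truth <- structure(
      list(de_flags = stats::setNames(de_flags, mouse$gene_ids),
           mouse_sign = stats::setNames(mouse_sign, mouse$gene_ids),
           human_sign = stats::setNames(human_sign, human$gene_ids),
           planted_concordance = if (n_de > 0) {
             mean(human_sign[de_flags] == mouse_sign[de_flags])
           } else {
             NA_real_
           },
           seed = config$seed),
      class = "synthetic_truth"
    )
    structure(list(mouse = mouse, human = human, map = map, truth = truth,
                   config = config),
              class = "paired_expression")
  })
}

#' Simulate a limiting-dilution assay table
#'
#' Positive-well counts at each dose are binomial with per-well success
#' probability `1 - (1 - true_frequency)^dose`: a well is positive when at
#' least one of its `dose` cells is clonogenic.
#'
#' @param true_frequency clonogenic fraction per cell, in \[0, 1\].
#' @param doses cells plated per well at each dilution (defaults to the
#'   3000/600/120/24/5/1 serial dilution).
#' @param wells_per_dose replicate wells per dose (default 14).
#' @param seed integer seed.
#' @param group optional group label attached to the design.
#' @return An [ld_design()] object.
#' @export
generate_ld_assay <- function(true_frequency,
                              doses = c(3000, 600, 120, 24, 5, 1),
                              wells_per_dose = 14,
                              seed = 1L,
                              group = NULL) {
  check_fraction(true_frequency, "true_frequency")
  if (!is.numeric(doses) || length(doses) < 1L || any(doses <= 0) ||
      any(doses != round(doses))) {
    stop_field("doses", "must be positive integers")
  }
  wells_per_dose <- check_count(wells_per_dose, "wells_per_dose", min = 1L)
  with_seed(seed, {
    p_pos <- 1 - (1 - true_frequency)^doses
    positive <- rbinom(length(doses), wells_per_dose, p_pos)
    ld_design(dose = doses, wells = rep(wells_per_dose, length(doses)),
              positive = positive, group = group)
  })
}
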