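# Cross-species sign-concordance statistic and its resampling null:
# the observed fraction of ortholog pairs whose female-minus-male
# directions agree is calibrated against concordance fractions of many
# random gene sets, summarized by a fitted normal and an empirical tail
# probability.

#' Per-gene sex direction map
#'
#' Sign of mean(F) - mean(M) per gene; genes with an exactly zero
#' difference are excluded and recorded with a reason.
#'
#' @param logcpm matrix of (log) expression values, genes x samples.
#' @param sex per-sample `"F"`/`"M"` labels, >= 2 of each.
#' @return An object of class `direction_map`: list with `sign` (named
#'   vector of -1/+1) and `excluded` (data.frame of gene, reason).
#' @export
sex_direction <- function(logcpm, sex) {
  sex <- as.character(sex)
  if (length(sex) != ncol(logcpm) || !all(sex %in% c("F", "M"))) {
    stop_field("sex", "must be one 'F'/'M' label per column")
  }
  if (sum(sex == "F") < 2L || sum(sex == "M") < 2L) {
    stop_field("sex", "need at least 2 samples per sex")
  }
  diff <- rowMeans(logcpm[, sex == "F", drop = FALSE]) -
    rowMeans(logcpm[, sex == "M", drop = FALSE])
  zero <- diff == 0
  structure(
    list(sign = stats::setNames(as.integer(sign(diff[!zero])),
                                rownames(logcpm)[!zero]),
         excluded = data.frame(
           gene = rownames(logcpm)[zero],
           reason = rep("zero-difference", sum(zero)),
           stringsAsFactors = FALSE)),
    class = "direction_map"
  )
}

# A direction_map built from a DE table's fold-change signs.
direction_from_de <- function(de_table) {
  zero <- de_table$direction == 0L
  structure(
    list(sign = stats::setNames(de_table$direction[!zero],
                                de_table$gene[!zero]),
         excluded = data.frame(gene = de_table$gene[zero],
                               reason = rep("zero-difference", sum(zero)),
                               stringsAsFactors = FALSE)),
    class = "direction_map"
  )
}

#' Map mouse genes to human orthologs
#'
#' @param genes mouse gene ids to map.
#' @param map an [orthology_map()]; must be strictly one-to-one.
#' @return List with `pairs` (data.frame `mouse_gene`, `human_gene` for the
#'   mappable genes, input order preserved) and `n_unmapped`.
#' @export
map_orthologs <- function(genes, map) {
  if (anyDuplicated(map$mouse_gene) || anyDuplicated(map$human_gene)) {
    stop("orthology map is not one-to-one after filtering", call. = FALSE)
  }
  idx <- match(genes, map$mouse_gene)
  found <- !is.na(idx)
  list(pairs = data.frame(mouse_gene = genes[found],
                          human_gene = map$human_gene[idx[found]],
                          stringsAsFactors = FALSE),
       n_unmapped = sum(!found))
}

#' Cross-species concordance fraction
#'
#' Fraction of ortholog pairs whose mouse and human directions agree,
#' among pairs with a defined sign on both sides.
#'
#' @param mouse_dirs,human_dirs `direction_map` objects.
#' @param pairs data.frame with columns `mouse_gene`, `human_gene`.
#' @return List with `fraction`, `n_used` and `concordant` (named logical
#'   vector over the usable pairs, names = mouse gene ids).
#' @export
concordance_fraction <- function(mouse_dirs, human_dirs, pairs) {
  ms <- mouse_dirs$sign[pairs$mouse_gene]
  hs <- human_dirs$sign[pairs$human_gene]
  ok <- !is.na(ms) & !is.na(hs)
  if (!any(ok)) {
    stop("no ortholog pairs with defined directions on both sides",
         call. = FALSE)
  }
  conc <- stats::setNames(ms[ok] == hs[ok], pairs$mouse_gene[ok])
  list(fraction = mean(conc), n_used = sum(ok), concordant = conc)
}

#' Resampling null distribution of the concordance fraction
#'
#' Repeatedly draws `set_size` distinct genes uniformly without
#' replacement from the universe and records the concordance fraction of
#' each set; draws are independent across resamples from a single seeded
#' generator. A normal distribution is fitted to the null values by
#' moments (the maximum-likelihood fit).
#'
#' @param universe logical vector: per-gene concordance indicators for the
#'   whole resampling universe (e.g. the `concordant` element of
#'   [concordance_fraction()]).
#' @param set_size genes per resampled set (default 500).
#' @param n_resamples number of sets (default 100000).
#' @param seed integer seed.
#' @return An object of class `null_distribution`: list with `values`,
#'   `set_size`, `n_resamples`, `seed`, `mu_hat`, `sigma_hat`.
#' @export
resample_null <- function(universe, set_size = 500, n_resamples = 100000,
                          seed = 1L) {
  if (!is.logical(universe) || any(is.na(universe))) {
    stop_field("universe", "must be a logical vector of concordance indicators")
  }
  set_size <- check_count(set_size, "set_size", min = 1L)
  n_resamples <- check_count(n_resamples, "n_resamples", min = 1L)
  n_universe <- length(universe)
  if (n_universe < set_size) {
    stop_field("set_size", sprintf(
      "universe has %d genes, smaller than set_size = %d",
      n_universe, set_size))
  }
  values <- with_seed(seed, {
    vapply(seq_len(n_resamples), function(i) {
      sum(universe[sample.int(n_universe, set_size)])
    }, 0) / set_size
  })
  mu <- mean(values)
  sigma <- sqrt(mean((values - mu)^2))
  structure(
    list(values = values, set_size = set_size, n_resamples = n_resamples,
         seed = as.integer(seed), mu_hat = mu, sigma_hat = sigma),
    class = "null_distribution"
  )
}

#' Tail probability of an observed concordance under the resampling null
#'
#' `z = (observed - mu_hat) / sigma_hat`; `p_normal` is the upper tail of
#' the fitted normal at the observed value; `p_empirical` is the add-one
#' corrected exceedance fraction `(1 + #\{null >= observed\}) /
#' (n_resamples + 1)`. Both are one-sided (enrichment of concordance).
#'
#' @param null a [resample_null()] object.
#' @param observed observed concordance fraction.
#' @return List with `z`, `p_normal`, `p_empirical`, `mu_hat`,
#'   `sigma_hat`, and `degenerate` (TRUE when `sigma_hat = 0`, in which
#'   case `p_normal` is `NA`).
#' @export
tail_probability <- function(null, observed) {
  if (!inherits(null, "null_distribution")) {
    stop_field("null", "must come from resample_null()")
  }
  check_fraction(observed, "observed")
  degenerate <- null$sigma_hat == 0
  z <- if (degenerate) NA_real_ else (observed - null$mu_hat) / null$sigma_hat
  p_normal <- if (degenerate) NA_real_ else stats::pnorm(z, lower.tail = FALSE)
  p_empirical <- (1 + sum(null$values >= observed)) / (null$n_resamples + 1)
  list(z = z, p_normal = p_normal, p_empirical = p_empirical,
       mu_hat = null$mu_hat, sigma_hat = null$sigma_hat,
       degenerate = degenerate)
}

#' End-to-end cross-species concordance analysis
#'
#' Runs the full pipeline on a pair of count datasets: filter unexpressed
#' genes, TMM-normalize and log-CPM both species, moderated-t sex test and
#' FDR/fold-change selection on the mouse side, sign of the mean
#' difference on the human side, observed concordance over the selected
#' ortholog-mapped genes, resampling null, and tail probabilities.
#'
#' @param mouse,human [expression_dataset()] objects.
#' @param map an [orthology_map()] pairing mouse and human gene ids.
#' @param q_max,min_fold mouse DE selection thresholds (see [select_de()]).
#' @param d0 moderation prior degrees of freedom (see [sex_de_test()]).
#' @param set_size resampled set size; `NULL` (default) matches the
#'   observed set size so the null calibrates the observed statistic
#'   exactly; pass `500` for the classic fixed size.
#' @param n_resamples number of null sets (default 100000).
#' @param universe `"all"` (default): resample from all expressed,
#'   ortholog-mapped genes with defined directions; `"de"`: resample from
#'   the selected DE genes only.
#' @param seed integer seed for the resampling.
#' @return An object of class `concordance_result`: list with
#'   `observed_fraction`, `n_genes_used`, `null` (the
#'   [resample_null()] object), `z`, `p_normal`, `p_empirical`, `de`
#'   (the [select_de()] summary), `n_unmapped` and a `config` echo.
#' @export
run_concordance <- function(mouse, human, map,
                            q_max = 0.05, min_fold = 2, d0 = 4,
                            set_size = NULL, n_resamples = 100000,
                            universe = c("all", "de"), seed = 1L) {
  universe <- match.arg(universe)
  mouse <- filter_unexpressed(mouse)
  human <- filter_unexpressed(human)

  mouse_lcpm <- log_cpm(mouse, tmm_factors(mouse))
  human_lcpm <- log_cpm(human, tmm_factors(human))

  de_table <- sex_de_test(mouse_lcpm, mouse$sex, d0 = d0)
  de_sel <- select_de(de_table, q_max = q_max, min_fold = min_fold)
  if (de_sel$n_selected == 0L) {
    stop("concordance stage: no genes pass the DE selection", call. = FALSE)
  }

  mouse_dirs <- direction_from_de(de_table)
  human_dirs <- sex_direction(human_lcpm, human$sex)

  mapped_all <- map_orthologs(de_table$gene, map)
  conc_all <- concordance_fraction(mouse_dirs, human_dirs, mapped_all$pairs)

  sel_in <- names(conc_all$concordant) %in% de_sel$genes
  if (!any(sel_in)) {
    stop("concordance stage: no selected DE genes have mapped directions",
         call. = FALSE)
  }
  observed <- mean(conc_all$concordant[sel_in])
  n_used <- sum(sel_in)

  null_universe <- if (universe == "all") {
    conc_all$concordant
  } else {
    conc_all$concordant[sel_in]
  }
  if (is.null(set_size)) set_size <- min(n_used, length(null_universe))
  null <- resample_null(null_universe, set_size = set_size,
                        n_resamples = n_resamples, seed = seed)
  tail <- tail_probability(null, observed)

  structure(
    list(observed_fraction = observed,
         n_genes_used = n_used,
         null = null,
         z = tail$z,
         p_normal = tail$p_normal,
         p_empirical = tail$p_empirical,
         de = de_sel,
         n_unmapped = mapped_all$n_unmapped,
         config = list(q_max = q_max, min_fold = min_fold, d0 = d0,
                       set_size = set_size, n_resamples = n_resamples,
                       universe = universe, seed = as.integer(seed))),
    class = "concordance_result"
  )
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf(
    paste0("concordance_result: observed %.1f%% over %d genes\n",
           "  null: mu = %.3f, sigma = %.4f (%d sets of %d from universe '%s')\n",
           "  z = %.2f, p_normal = %.3g, p_empirical = %.3g\n"),
    100 * x$observed_fraction, x$n_genes_used,
    x$null$mu_hat, x$null$sigma_hat, x$null$n_resamples, x$null$set_size,
    x$config$universe, x$z, x$p_normal, x$p_empirical))
  invisible(x)
}
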