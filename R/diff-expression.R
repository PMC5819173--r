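# Differential-expression stage: expression filtering, TMM-style scale
# factors, log-CPM, moderated t statistics, BH adjustment and
# FDR/fold-change selection. Written as a self-contained, auditable
# equivalent of the usual TMM + moderated linear-model pipeline; see the
# methods vignette for where it deliberately differs.

counts_of <- function(x) {
  if (inherits(x, "expression_dataset")) x$counts else x
}

#' Drop genes with zero counts in every sample
#'
#' @param x an [expression_dataset()] or a counts matrix.
#' @return The same type of object with all-zero gene rows removed, order
#'   preserved. Errors if nothing would remain.
#' @export
filter_unexpressed <- function(x) {
  counts <- counts_of(x)
  keep <- rowSums(counts > 0) > 0
  if (!any(keep)) {
    stop("all genes are unexpressed in every sample", call. = FALSE)
  }
  if (inherits(x, "expression_dataset")) {
    expression_dataset(counts[keep, , drop = FALSE], x$sex, x$species)
  } else {
    counts[keep, , drop = FALSE]
  }
}

#' Trimmed-mean-of-M-values normalization factors
#'
#' Per-sample scale factors computed from doubly trimmed, precision-weighted
#' mean log2 ratios (M-values) of relative abundances against a reference
#' sample. The reference is the sample whose upper-quartile/library-size
#' ratio is closest to the mean of those ratios. Genes with a zero count in
#' either sample are excluded pairwise; the `trim_m` extreme fractions of
#' M and the `trim_a` extremes of average abundance (A) are trimmed; the
#' surviving M-values are averaged with weights inversely proportional to
#' their delta-method variance on the relative-abundance scale, so factors
#' depend only on sample proportions and are exactly invariant to scaling
#' any sample's counts. Factors are rescaled to geometric mean 1.
#'
#' @param x an [expression_dataset()] or counts matrix (>= 2 samples).
#' @param trim_m fraction of M-values trimmed from each tail (default 0.30).
#' @param trim_a fraction of A-values trimmed from each tail (default 0.05).
#' @return An object of class `norm_factors`: list with `factors`
#'   (geometric mean 1) and `lib_sizes`.
#' @export
tmm_factors <- function(x, trim_m = 0.30, trim_a = 0.05) {
  counts <- counts_of(x)
  if (ncol(counts) < 2L) stop_field("x", "need at least 2 samples")
  lib <- colSums(counts)
  if (any(lib <= 0)) stop_field("x", "every sample needs a positive library size")

  # reference: upper-quartile/library ratio closest to the mean ratio
  uq_ratio <- apply(counts, 2L, stats::quantile, probs = 0.75) / lib
  ref <- which.min(abs(uq_ratio - mean(uq_ratio)))
  p_ref <- counts[, ref] / lib[ref]

  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    p_obs <- counts[, j] / lib[j]
    keep <- p_obs > 0 & p_ref > 0
    if (!any(keep)) {
      stop(sprintf("normalization failed: sample '%s' shares no expressed genes with the reference",
                   colnames(counts)[j]), call. = FALSE)
    }
    po <- p_obs[keep]
    pr <- p_ref[keep]
    m <- log2(po / pr)
    a <- 0.5 * log2(po * pr)
    if (max(abs(m)) < 1e-6) return(1)
    n <- length(m)
    lo_m <- floor(n * trim_m) + 1
    hi_m <- n + 1 - lo_m
    lo_a <- floor(n * trim_a) + 1
    hi_a <- n + 1 - lo_a
    rm_ <- rank(m)
    ra_ <- rank(a)
    sel <- rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a
    if (!any(sel)) return(1)
    w <- 1 / ((1 - po) / po + (1 - pr) / pr)
    2^(sum(w[sel] * m[sel]) / sum(w[sel]))
  }, 0)

  f <- f / exp(mean(log(f)))
  structure(list(factors = f, lib_sizes = lib), class = "norm_factors")
}

#' Log2 counts per million
#'
#' `log2((count + prior) / (effective library + 2 * prior) * 1e6)` with the
#' effective library `lib * factor` and the prior count scaled in
#' proportion to the effective library relative to one million, so the
#' transform is exactly invariant to rescaling a sample's counts. At an
#' effective library of 1e6 the prior equals `prior_count` verbatim.
#'
#' @param x an [expression_dataset()] or counts matrix.
#' @param factors a `norm_factors` object from [tmm_factors()]; defaults
#'   to unit factors.
#' @param prior_count prior count at a one-million effective library
#'   (default 0.5).
#' @return Real matrix of log2-CPM values, same dimnames as the counts.
#' @export
log_cpm <- function(x, factors = NULL, prior_count = 0.5) {
  counts <- counts_of(x)
  check_positive(prior_count, "prior_count")
  if (is.null(factors)) {
    factors <- structure(list(factors = rep(1, ncol(counts)),
                              lib_sizes = colSums(counts)),
                         class = "norm_factors")
  }
  if (length(factors$factors) != ncol(counts)) {
    stop_field("factors", "must provide one factor per sample")
  }
  eff <- factors$lib_sizes * factors$factors
  if (any(eff <= 0)) stop_field("factors", "effective library sizes must be positive")
  prior <- prior_count * eff / 1e6
  out <- log2(sweep(counts, 2L, prior, "+") / rep(eff + 2 * prior,
                                                  each = nrow(counts)) * 1e6)
  dimnames(out) <- dimnames(counts)
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q(i) = min over j >= i of m * p(j) / j` on the
#' sorted p-values, mapped back to input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1)) {
    stop_field("p", "must be numeric values in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Moderated t test for sex-differential expression
#'
#' Per gene: log2 fold change = mean(F) - mean(M) of log-CPM values; the
#' pooled two-group variance is shrunk toward the across-gene mean
#' variance with `d0` prior degrees of freedom,
#' `s2_mod = (d0 * s2_bar + d * s2) / (d0 + d)`, and the t statistic is
#' referred to a t distribution with `d0 + d` degrees of freedom
#' (`d = nF + nM - 2`). With `d0 = 0` this is the ordinary pooled
#' two-sample t test.
#'
#' @param logcpm matrix of log2-CPM values (genes x samples).
#' @param sex per-sample labels, `"F"`/`"M"`, >= 2 of each.
#' @param d0 prior degrees of freedom for variance moderation (default 4).
#' @return A data.frame of class `de_table` with columns `gene`,
#'   `log2fc_FvsM`, `t`, `df`, `p`, `q`, `direction` (sign of the fold
#'   change: -1, 0, +1) and `mean_logcpm`.
#' @export
sex_de_test <- function(logcpm, sex, d0 = 4) {
  sex <- as.character(sex)
  if (length(sex) != ncol(logcpm) || !all(sex %in% c("F", "M"))) {
    stop_field("sex", "must be one 'F'/'M' label per column")
  }
  nF <- sum(sex == "F")
  nM <- sum(sex == "M")
  if (nF < 2L || nM < 2L) {
    stop_field("sex", "need at least 2 samples per sex")
  }
  if (!is.numeric(d0) || length(d0) != 1L || is.na(d0) || d0 < 0) {
    stop_field("d0", "must be a single number >= 0")
  }
  xF <- logcpm[, sex == "F", drop = FALSE]
  xM <- logcpm[, sex == "M", drop = FALSE]
  fc <- rowMeans(xF) - rowMeans(xM)
  d <- nF + nM - 2L
  s2 <- ((nF - 1L) * row_vars(xF) + (nM - 1L) * row_vars(xM)) / d
  s2_mod <- (d0 * mean(s2) + d * s2) / (d0 + d)
  se <- sqrt(s2_mod * (1 / nF + 1 / nM))
  tval <- ifelse(se > 0, fc / se, ifelse(fc == 0, 0, sign(fc) * Inf))
  p <- 2 * stats::pt(-abs(tval), df = d0 + d)
  out <- data.frame(
    gene = rownames(logcpm),
    log2fc_FvsM = fc,
    t = tval,
    df = d0 + d,
    p = p,
    q = bh_adjust(p),
    direction = as.integer(sign(fc)),
    mean_logcpm = rowMeans(logcpm),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  class(out) <- c("de_table", "data.frame")
  out
}

#' Select differentially expressed genes
#'
#' Keeps genes with `q <= q_max` and `|log2fc| >= log2(min_fold)` (both
#' thresholds inclusive).
#'
#' @param table a `de_table` from [sex_de_test()].
#' @param q_max FDR threshold (default 0.05).
#' @param min_fold minimum fold change (default 2, i.e. |log2fc| >= 1).
#' @return An object of class `de_selection`: list with `genes`,
#'   `directions` (named sign vector), `n_selected`, `n_tested`, `q_max`,
#'   `min_fold`.
#' @export
select_de <- function(table, q_max = 0.05, min_fold = 2) {
  check_fraction(q_max, "q_max")
  if (!is.numeric(min_fold) || length(min_fold) != 1L || min_fold < 1) {
    stop_field("min_fold", "must be a single number >= 1")
  }
  sel <- table$q <= q_max & abs(table$log2fc_FvsM) >= log2(min_fold)
  structure(
    list(genes = table$gene[sel],
         directions = stats::setNames(table$direction[sel], table$gene[sel]),
         n_selected = sum(sel),
         n_tested = nrow(table),
         q_max = q_max,
         min_fold = min_fold),
    class = "de_selection"
  )
}

#' @export
print.de_selection <- function(x, ...) {
  cat(sprintf("de_selection: %d of %d genes at q <= %g and fold >= %g\n",
              x$n_selected, x$n_tested, x$q_max, x$min_fold))
  invisible(x)
}
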