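test_that("all-zero gene rows are removed and everything else kept in order", {
  m <- make_counts(5, 4, seed = 1)
  m[3, ] <- 0L
  out <- filter_unexpressed(m)
  expect_equal(rownames(out), rownames(m)[-3])
  m2 <- make_counts(5, 4, seed = 2) + 1L
  expect_identical(filter_unexpressed(m2), m2)
  m3 <- m2
  m3[, ] <- 0L
  m3[2, 3] <- 1L  # a single count anywhere keeps the gene
  expect_equal(rownames(filter_unexpressed(m3)), rownames(m3)[2])
  expect_error(filter_unexpressed(m3 * 0L), "unexpressed")
})

test_that("TMM factors are unity for proportional columns", {
  m <- make_counts(50, 1, seed = 3) + 1L
  same <- cbind(s1 = m[, 1], s2 = m[, 1], s3 = m[, 1])
  rownames(same) <- rownames(m)
  expect_equal(tmm_factors(same)$factors, rep(1, 3))
  tripled <- cbind(s1 = m[, 1], s2 = 3L * m[, 1])
  rownames(tripled) <- rownames(m)
  expect_equal(tmm_factors(tripled)$factors, c(1, 1))
})

test_that("TMM factors match an independent step-by-step computation", {
  counts <- matrix(c(10, 100, 1000, 50, 500,
                     20, 220, 1800, 110, 900,
                     15, 130,  900,  45, 700), nrow = 5,
                   dimnames = list(paste0("g", 1:5), paste0("s", 1:3)))
  # frozen from a spreadsheet-style walk through the definition:
  # reference = sample 1 (upper-quartile/library ratio closest to mean),
  # double trim of M (0.30) and A (0.05) tails, precision-weighted mean
  # of surviving M-values, factors rescaled to geometric mean 1
  expect_equal(tmm_factors(counts)$factors,
               c(0.8996836922, 0.9793278224, 1.1349639277),
               tolerance = 1e-6)
  expect_equal(prod(tmm_factors(counts)$factors)^(1/3), 1, tolerance = 1e-9)
})

test_that("TMM factors stay close to edgeR's on generic count data", {
  skip_if_not_installed("edgeR")
  m <- make_counts(800, 6, seed = 4)
  mine <- tmm_factors(m)$factors
  ed <- edgeR::calcNormFactors(edgeR::DGEList(m))$samples$norm.factors
  # small systematic difference expected: weights here are depth-free
  expect_lt(max(abs(mine - ed)), 0.02)
})

test_that("log-CPM matches its defining formula at a one-million library", {
  m <- matrix(c(0L, 1000000L - 0L,
                5L, 999995L), nrow = 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  lc <- log_cpm(m)
  expect_equal(lc["g1", "s1"], log2(0.5 / (1e6 + 1) * 1e6), tolerance = 1e-12)
  # CPM of exactly 1 with a vanishing prior tends to log2(1) = 0
  m2 <- matrix(c(1L, 999999L), 2, 1,
               dimnames = list(c("g1", "g2"), "s1"))
  lc2 <- log_cpm(cbind(m2, m2), prior_count = 1e-9)
  expect_equal(lc2["g1", 1], 0, tolerance = 1e-6)
})

test_that("TMM and log-CPM are invariant to rescaling one sample's counts", {
  m <- make_counts(400, 5, seed = 6) + 1L
  f1 <- tmm_factors(m)
  l1 <- log_cpm(m, f1)
  m2 <- m
  m2[, 3] <- 7L * m2[, 3]
  f2 <- tmm_factors(m2)
  l2 <- log_cpm(m2, f2)
  expect_lt(max(abs(l1 - l2)), 1e-9)
})

test_that("moderated t reduces to the ordinary pooled t when d0 = 0", {
  x <- make_counts(40, 8, seed = 7)
  lx <- log2(x + 1)
  sex <- rep(c("F", "M"), each = 4)
  tab <- sex_de_test(lx, sex, d0 = 0)
  for (g in c(1, 17, 40)) {
    tt <- t.test(lx[g, sex == "F"], lx[g, sex == "M"], var.equal = TRUE)
    expect_equal(tab$t[g], unname(tt$statistic), tolerance = 1e-9)
    expect_equal(tab$p[g], tt$p.value, tolerance = 1e-9)
  }
})

test_that("a gene with identical values gives zero fold change and p = 1", {
  lx <- rbind(g1 = rep(3.7, 8), g2 = c(1, 2, 3, 4, 2, 3, 4, 5))
  colnames(lx) <- paste0("s", 1:8)
  tab <- sex_de_test(lx, rep(c("F", "M"), each = 4))
  expect_equal(tab$log2fc_FvsM[1], 0)
  expect_equal(tab$direction[1], 0L)
  expect_equal(tab$p[1], 1)
  expect_error(sex_de_test(lx, c("F", rep("M", 7))), "2 samples per sex")
})

test_that("planted signs are recovered in nearly all detected DE genes", {
  cfg <- sim_config(n_genes = 1500, samples_per_sex_mouse = 8,
                    samples_per_sex_human = 2, frac_sex_de = 0.2,
                    effect_log2fc = 2, background_log2fc = 0, seed = 31)
  b <- generate_paired_expression(cfg)
  lc <- log_cpm(b$mouse, tmm_factors(b$mouse))
  tab <- sex_de_test(lc, b$mouse$sex)
  sel <- select_de(tab)
  truth_sign <- b$truth$mouse_sign[sel$genes]
  expect_gte(mean(sel$directions == truth_sign), 0.99)
})

test_that("BH adjustment equals the brute-force step-up rule", {
  expect_equal(bh_adjust(c(0.005, 0.02, 0.1)), c(0.015, 0.03, 0.1))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.2, 1.3)), "\\[0, 1\\]")
  set.seed(11)
  all_perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  for (n in 1:6) {
    p <- round(runif(n), 3)
    p[1] <- min(p[1], 0.999)  # include ties occasionally via rounding
    for (ord in all_perms(seq_len(n))) {
      expect_equal(bh_adjust(p[ord]), bh_brute_force(p[ord]), tolerance = 1e-12)
    }
  }
})

test_that("selection applies both FDR and fold-change thresholds inclusively", {
  tab <- data.frame(
    gene = paste0("g", 1:6),
    log2fc_FvsM = c(0.9, -1.2, 2.5, 1.1, -0.2, 1.4),
    t = 0, df = 10,
    p = c(0.001, 0.01, 0.001, 0.2, 0.001, 0.004),
    q = c(0.04, 0.05, 0.002, 0.3, 0.01, 0.049),
    direction = c(1L, -1L, 1L, 1L, -1L, 1L),
    mean_logcpm = 5
  )
  class(tab) <- c("de_table", "data.frame")
  sel <- select_de(tab, q_max = 0.05, min_fold = 2)
  # g1 fails the fold filter despite q = 0.04; g2 sits exactly on q = 0.05
  # and is included ("less than or equal"); g4 fails q; g5 fails fold
  expect_setequal(sel$genes, c("g2", "g3", "g6"))
  expect_equal(sel$n_tested, 6L)
  expect_equal(unname(sel$directions[sel$genes == "g2"]), -1L)
})
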