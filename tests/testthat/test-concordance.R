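test_that("sex direction is the sign of the mean F - M difference", {
  lx <- rbind(g1 = c(4, 6, 1, 3), g2 = c(1, 3, 4, 6), g3 = c(2, 4, 2, 4))
  colnames(lx) <- paste0("s", 1:4)
  dm <- sex_direction(lx, c("F", "F", "M", "M"))
  expect_equal(unname(dm$sign[c("g1", "g2")]), c(1L, -1L))
  expect_false("g3" %in% names(dm$sign))
  expect_equal(dm$excluded$gene, "g3")
  expect_equal(dm$excluded$reason, "zero-difference")
  expect_error(sex_direction(lx, c("F", "M", "M", "M")), "2 samples per sex")
})

test_that("planted human directions are recovered from simulated counts", {
  cfg <- sim_config(n_genes = 800, samples_per_sex_mouse = 2,
                    samples_per_sex_human = 20, frac_sex_de = 1,
                    effect_log2fc = 1, seed = 13)
  b <- generate_paired_expression(cfg)
  lc <- log_cpm(b$human, tmm_factors(b$human))
  dm <- sex_direction(lc, b$human$sex)
  truth <- b$truth$human_sign[names(dm$sign)]
  expect_gte(mean(dm$sign == truth), 0.99)
})

test_that("concordance fraction counts matching signs over usable pairs", {
  md <- structure(list(sign = c(m1 = 1L, m2 = 1L, m3 = -1L, m4 = -1L),
                       excluded = NULL), class = "direction_map")
  hd <- structure(list(sign = c(h1 = 1L, h2 = -1L, h3 = -1L, h4 = 1L),
                       excluded = NULL), class = "direction_map")
  pairs <- data.frame(mouse_gene = paste0("m", 1:4),
                      human_gene = paste0("h", 1:4))
  res <- concordance_fraction(md, hd, pairs)
  expect_equal(res$fraction, 0.5)
  expect_equal(res$n_used, 4L)
  hd2 <- structure(list(sign = c(h1 = 1L, h2 = 1L, h3 = -1L, h4 = -1L)),
                   class = "direction_map")
  expect_equal(concordance_fraction(md, hd2, pairs)$fraction, 1)
  # a pair with an undefined human sign is dropped, not counted
  hd3 <- structure(list(sign = c(h1 = 1L, h3 = -1L)), class = "direction_map")
  expect_equal(concordance_fraction(md, hd3, pairs)$n_used, 2L)
  hd4 <- structure(list(sign = c(x = 1L)), class = "direction_map")
  expect_error(concordance_fraction(md, hd4, pairs), "no ortholog pairs")
})

test_that("independent random signs give ~50% concordance on 500 genes", {
  fr <- vapply(1:40, function(s) {
    u <- make_concordance_universe(500, 0.5, seed = 600 + s)
    mean(u)
  }, 0)
  expect_true(all(abs(fr - 0.5) < 4 * sqrt(0.25 / 500)))
  expect_lt(abs(mean(fr) - 0.5), 3 * sqrt(0.25 / 500 / 40))
})

test_that("degenerate and exhaustive resampling nulls behave as forced", {
  u <- rep(TRUE, 60)
  null <- resample_null(u, set_size = 10, n_resamples = 50, seed = 1)
  expect_true(all(null$values == 1))
  expect_equal(null$sigma_hat, 0)
  u2 <- make_concordance_universe(80, 0.4, seed = 2)
  null2 <- resample_null(u2, set_size = 80, n_resamples = 30, seed = 3)
  expect_true(all(null2$values == mean(u2)))
  expect_error(resample_null(u2, set_size = 81), "smaller than set_size")
})

test_that("resampling null moments match binomial theory", {
  u <- make_concordance_universe(20000, 0.28, seed = 41)
  null <- resample_null(u, set_size = 500, n_resamples = 10000, seed = 42)
  se_mu <- sqrt(0.28 * 0.72 * (1 / 20000 + 1 / (500 * 10000)))
  expect_lt(abs(null$mu_hat - 0.28), 3 * se_mu)
  expect_lt(abs(null$sigma_hat - sqrt(0.28 * 0.72 / 500)),
            0.1 * sqrt(0.28 * 0.72 / 500))
})

test_that("resampling is seeded, reproducible and exchangeable over gene order", {
  u <- make_concordance_universe(3000, 0.3, seed = 50)
  n1 <- resample_null(u, set_size = 300, n_resamples = 2000, seed = 7)
  n2 <- resample_null(u, set_size = 300, n_resamples = 2000, seed = 7)
  expect_identical(n1$values, n2$values)
  # permuting the universe changes individual draws but not the moments
  # beyond Monte Carlo error
  set.seed(99)
  n3 <- resample_null(u[sample(length(u))], set_size = 300,
                      n_resamples = 2000, seed = 7)
  mc_se <- n1$sigma_hat / sqrt(2000)
  expect_lt(abs(n1$mu_hat - n3$mu_hat), 5 * mc_se)
  expect_lt(abs(n1$sigma_hat - n3$sigma_hat) / n1$sigma_hat, 0.1)
})

test_that("normal tail probabilities follow the fitted null", {
  u <- make_concordance_universe(5000, 0.3, seed = 60)
  null <- resample_null(u, set_size = 400, n_resamples = 5000, seed = 61)
  expect_equal(tail_probability(null, null$mu_hat)$p_normal, 0.5)
  expect_equal(tail_probability(null, null$mu_hat + 1.959964 * null$sigma_hat)$p_normal,
               0.025, tolerance = 1e-4)
  expect_equal(tail_probability(null, null$mu_hat + 4.7534 * null$sigma_hat)$p_normal,
               1e-6, tolerance = 0.01 * 1e-6 / 1e-6)
  # monotone decreasing in the observed fraction
  obs <- null$mu_hat + seq(-2, 3, by = 0.25) * null$sigma_hat
  pv <- vapply(obs, function(o) tail_probability(null, min(max(o, 0), 1))$p_normal, 0)
  expect_true(all(diff(pv) < 0))
  # degenerate null: empirical tail still defined, normal flagged
  dn <- resample_null(rep(TRUE, 30), set_size = 5, n_resamples = 20, seed = 1)
  tp <- tail_probability(dn, 0.9)
  expect_true(tp$degenerate)
  expect_true(is.na(tp$p_normal))
  expect_equal(tp$p_empirical, (1 + 20) / 21)
})

test_that("empirical and normal tails agree within the null's bulk", {
  u <- make_concordance_universe(6000, 0.3, seed = 70)
  null <- resample_null(u, set_size = 500, n_resamples = 20000, seed = 71)
  for (kk in c(0, 1, 1.5, 2)) {
    tp <- tail_probability(null, null$mu_hat + kk * null$sigma_hat)
    expect_lt(abs(tp$p_empirical - tp$p_normal) / tp$p_normal, 0.2)
  }
})

test_that("the end-to-end concordance run is deterministic given a seed", {
  cfg <- sim_config(n_genes = 600, frac_sex_de = 0.3, seed = 81)
  b <- generate_paired_expression(cfg)
  r1 <- run_concordance(b$mouse, b$human, b$map, n_resamples = 500, seed = 9)
  r2 <- run_concordance(b$mouse, b$human, b$map, n_resamples = 500, seed = 9)
  expect_identical(r1, r2)
  expect_equal(r1$p_empirical,
               (1 + sum(r1$null$values >= r1$observed_fraction)) /
                 (r1$null$n_resamples + 1))
  # universe = "de" resamples from the selected genes only
  r3 <- run_concordance(b$mouse, b$human, b$map, n_resamples = 500,
                        set_size = 100, universe = "de", seed = 9)
  expect_equal(length(r3$null$values), 500L)
  expect_lte(r3$null$set_size, r3$n_genes_used)
})

test_that("unmapped genes are excluded and counted in the pipeline", {
  cfg <- sim_config(n_genes = 500, frac_sex_de = 0.3, frac_unmapped = 0.2,
                    seed = 83)
  b <- generate_paired_expression(cfg)
  expect_equal(nrow(b$map), 400L)
  r <- run_concordance(b$mouse, b$human, b$map, n_resamples = 200, seed = 1)
  expect_gte(r$n_unmapped, 90L)  # ~20% of the expressed genes
})
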