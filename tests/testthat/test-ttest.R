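# Two-condition fold-change analysis against textbook t-test oracles.

test_that("qpcr_ttest matches the hand-computed pooled t-test", {
  withr::with_seed(31, {
    for (k in 1:20) {
      n <- sample(3:8, 1)
      fc <- exp(rnorm(1))
      d <- simulate_ttest(n_rep = n, true_fc = c(g = fc),
                          noise_sd = runif(1, 0.1, 0.5))
      w <- qpcrquant:::ttest_wdct(d, qpcr_meta(d))
      tr <- w$wdct[w$condition == "treatment"]
      co <- w$wdct[w$condition == "control"]
      res <- qpcr_ttest(d, var_equal = TRUE, p_adjust = "none")
      orc <- oracle_pooled_ttest(tr, co)
      expect_equal(res$statistic, orc$statistic, tolerance = 1e-10)
      expect_equal(res$df, orc$df)
      expect_equal(res$p_value, orc$p, tolerance = 1e-10)
      expect_equal(res$se_log2, orc$se, tolerance = 1e-10)
      expect_equal(res$fc, 2^(-(mean(tr) - mean(co))), tolerance = 1e-12)
      # CI back-transforms the t-interval on the difference
      tcrit <- qt(0.975, orc$df)
      expect_equal(res$lcl, 2^(-(mean(tr) - mean(co) + tcrit * orc$se)),
                   tolerance = 1e-10)
    }
  })
})

test_that("the Welch option matches the Welch-Satterthwaite oracle", {
  withr::with_seed(32, {
    a <- rnorm(5, 0, 1)
    b <- rnorm(5, 1, 10)
    res <- welch_ttest(a, b)
    orc <- oracle_welch_ttest(a, b)
    expect_equal(res$statistic, orc$statistic, tolerance = 1e-10)
    expect_equal(res$df, orc$df, tolerance = 1e-10)
    expect_equal(res$p_value, orc$p, tolerance = 1e-10)
  })
  # variances 1 vs 100 with n = 5 each cripple the df well below 8
  withr::with_seed(33, {
    a <- scale(rnorm(5))[, 1]           # sd exactly 1
    b <- scale(rnorm(5))[, 1] * 10      # sd exactly 10
    expect_lt(welch_ttest(a, b)$df, 8)
  })
  # identical groups: t = 0, p = 1
  x <- c(1, 2, 3, 4)
  res0 <- welch_ttest(x, x)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  expect_error(welch_ttest(1, c(1, 2)), "at least 2")
})

test_that("symmetric data give FC 1 and p 1; direction is sane", {
  # same wdct per replicate in both conditions, varying across replicates
  d <- tibble::tibble(
    condition = rep(c("control", "treatment"), each = 6),
    gene = rep(rep(c("g", "ref"), each = 3), 2),
    e = 2,
    ct = c(30.0, 30.4, 29.6, 25, 25, 25, 30.0, 30.4, 29.6, 25, 25, 25)
  )
  res <- qpcr_ttest(qpcr_table(d, "ttest"))
  expect_equal(res$fc, 1)
  expect_equal(res$p_value, 1)
  expect_equal(res$sig, "")
  # lowering treatment target Ct (more transcript) must push FC above 1
  d_up <- d
  d_up$ct[7:9] <- d_up$ct[7:9] - 2
  expect_gt(qpcr_ttest(qpcr_table(d_up, "ttest"))$fc, 1)
})

test_that("paired and unpaired tests agree on FC, differ in se/df", {
  d <- simulate_ttest(n_rep = 6, true_fc = c(g = 3), noise_sd = 0.3,
                      seed = 34)
  up <- qpcr_ttest(d, paired = FALSE)
  pa <- qpcr_ttest(d, paired = TRUE)
  expect_equal(up$fc, pa$fc, tolerance = 1e-12)
  expect_equal(pa$df, up$df / 2)
  expect_false(isTRUE(all.equal(up$se_log2, pa$se_log2)))
  # paired oracle
  w <- qpcrquant:::ttest_wdct(d, qpcr_meta(d))
  orc <- oracle_paired_ttest(w$wdct[w$condition == "treatment"],
                             w$wdct[w$condition == "control"])
  expect_equal(pa$p_value, orc$p, tolerance = 1e-10)
})

test_that("degenerate inputs error with the gene named", {
  d <- simulate_ttest(n_rep = 3, true_fc = c(gBad = 4), noise_sd = 0,
                      seed = 35)
  expect_error(qpcr_ttest(d), "gBad")
  expect_error(qpcr_ttest(d, paired = TRUE), "gBad")
})

test_that("multi-gene results are BH-adjusted and marked from adjusted p", {
  d <- simulate_ttest(n_rep = 4,
                      true_fc = c(g1 = 6, g2 = 1.05, g3 = 0.2),
                      noise_sd = 0.25, seed = 36)
  res <- qpcr_ttest(d, p_adjust = "BH")
  expect_equal(res$p_adj, oracle_bh(res$p_value), tolerance = 1e-12)
  expect_true(all(res$p_adj >= res$p_value))
  expect_equal(res$sig, qpcrquant:::sig_marks(res$p_adj))
  raw <- qpcr_ttest(d, p_adjust = "none")
  expect_equal(raw$p_adj, raw$p_value)
  expect_equal(raw$sig, qpcrquant:::sig_marks(raw$p_value))
})

test_that("two reference genes are combined through the two-ref wdct", {
  base <- simulate_ttest(n_rep = 4, true_fc = c(g = 3), noise_sd = 0.2,
                         seed = 37)
  # duplicate the reference gene under a second name: the averaged two-ref
  # weighting must reproduce the single-ref result exactly
  base_df <- tibble::as_tibble(base)
  ref2 <- dplyr::mutate(base_df[base_df$gene == "ref", ], gene = "ref2")
  d2 <- qpcr_table(dplyr::bind_rows(base_df, ref2), "ttest", n_ref = 2)
  expect_equal(qpcr_ttest(d2)$fc, qpcr_ttest(base)$fc, tolerance = 1e-12)
})
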