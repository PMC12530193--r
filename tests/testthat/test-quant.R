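# Core arithmetic: weighted delta-Ct, RE/FC, and the lognormal
# back-transformations.

test_that("wdct matches hand-computed values and reduces to delta-Ct at E = 2", {
  expect_equal(wdct(2, 25, 2, 20), 5)
  expect_equal(wdct(1.9, 25, 2, 20), log2(1.9) * 25 - 20)
  expect_equal(wdct(1.9, 25, 2, 20), 3.1500, tolerance = 1e-4)
  # two reference genes: mean of the weighted reference terms
  expect_equal(wdct(2, 25, 2, 20, 2, 22), 4)
})

test_that("wdct rejects invalid efficiencies and non-finite CTs", {
  expect_error(wdct(1, 25, 2, 20), "target_e")
  expect_error(wdct(2, 25, 0.9, 20), "ref_e")
  expect_error(wdct(2, Inf, 2, 20), "finite")
  expect_error(wdct(2, 25, 2, 20, ref2_e = 2), "ref2_ct")
})

test_that("wdct is strictly increasing in target CT", {
  ct <- seq(18, 30, by = 0.5)
  w <- wdct(1.9, ct, 2, 20)
  expect_true(all(diff(w) > 0))
})

test_that("relative expression and fold change follow the 2^-x definitions", {
  expect_equal(relative_expression(0), 1)
  expect_equal(relative_expression(1), 0.5)
  expect_equal(relative_expression(-2), 4)
  expect_equal(fold_change(3, 5), 4)
  expect_equal(fold_change(5, 5), 1)
  expect_equal(fold_change(5, 3), 0.25)
  expect_equal(livak_fc(3, 5), 4)
  expect_equal(livak_fc(0, 0), 1)
  # RE strictly decreasing in mean wdct
  expect_true(all(diff(relative_expression(seq(-3, 3, 0.25))) < 0))
})

test_that("fold change is anti-symmetric and consistent with RE ratios", {
  withr::with_seed(11, {
    for (k in 1:20) {
      tr <- rnorm(1); co <- rnorm(1)
      expect_equal(fold_change(tr, co) * fold_change(co, tr), 1)
      expect_equal(fold_change(tr, co),
                   relative_expression(tr) / relative_expression(co))
    }
  })
})

test_that("SE back-transform reproduces the published anchor values", {
  b1 <- se_backtransform(4.0185, 0.2193)
  expect_equal(b1$lower_se, 3.4518, tolerance = 1e-4)
  expect_equal(b1$upper_se, 4.6782, tolerance = 1e-4)
  b2 <- se_backtransform(2.1987, 0.4388)
  expect_equal(b2$lower_se, 1.6221, tolerance = 1e-4)
  expect_equal(b2$upper_se, 2.9803, tolerance = 1e-4)
})

test_that("SE bounds are multiplicatively symmetric and collapse at se = 0", {
  withr::with_seed(12, {
    center <- exp(rnorm(25)); se <- abs(rnorm(25))
    b <- se_backtransform(center, se)
    expect_true(all(b$lower_se <= center & center <= b$upper_se))
    expect_equal(b$upper_se / center, center / b$lower_se)
  })
  expect_equal(se_backtransform(3.3, 0),
               tibble::tibble(lower_se = 3.3, upper_se = 3.3))
  expect_error(se_backtransform(-1, 0.1), "positive")
  expect_error(se_backtransform(2, -0.1), "non-negative")
})

test_that("confidence limits use the t quantile and collapse correctly", {
  ci <- ci_backtransform(4, 0.25, df = 4)
  expect_equal(ci$lcl, 2^(2 - qt(0.975, 4) * 0.25))
  expect_equal(ci$ucl, 2^(2 + qt(0.975, 4) * 0.25))
  # large df approaches the normal multiplier 1.95996
  ci_inf <- ci_backtransform(2, 0.3, df = 1e9)
  expect_equal(log2(ci_inf$ucl) - 1, 1.959964 * 0.3, tolerance = 1e-4)
  expect_equal(ci_backtransform(5, 0, df = 3),
               tibble::tibble(lcl = 5, ucl = 5))
  # FC = 1 gives an interval symmetric about 1 on the log scale
  ci1 <- ci_backtransform(1, 0.4, df = 6)
  expect_equal(ci1$lcl * ci1$ucl, 1)
  expect_error(ci_backtransform(2, 0.1, df = 0.5), "df")
})

test_that("p-value adjustment validates input and matches BH semantics", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(adjust_pvalues(0.04), 0.04)
  expect_equal(adjust_pvalues(c(0.2, 0.8), method = "none"), c(0.2, 0.8))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})
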