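# The generators realize the lognormal model the statistics assume; with
# all randomness switched off every estimator must invert them exactly.

test_that("generation is deterministic under a fixed seed", {
  a <- simulate_qpcr(list(f = c("c", "t")), n_rep = 4, true_re = c(1, 2),
                     noise_sd = 0.3, rep_sd = 0.2, seed = 42)
  b <- simulate_qpcr(list(f = c("c", "t")), n_rep = 4, true_re = c(1, 2),
                     noise_sd = 0.3, rep_sd = 0.2, seed = 42)
  expect_identical(as.data.frame(a), as.data.frame(b))
  d1 <- simulate_dilution(c(g = 1.9), noise_sd = 0.1, seed = 9)
  d2 <- simulate_dilution(c(g = 1.9), noise_sd = 0.1, seed = 9)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
})

test_that("noiseless generation inverts exactly through RE and FC", {
  d <- simulate_qpcr(list(f = c("c", "t")), n_rep = 3, true_re = c(1, 0.5),
                     noise_sd = 0, seed = 1)
  w <- add_wdct(d)
  re_t <- relative_expression(mean(w$wdct[w$f == "t"]))
  expect_equal(re_t, 0.5, tolerance = 1e-12)
  d2 <- simulate_qpcr(list(f = c("Co", "Tr")), n_rep = 3, true_re = c(1, 4),
                      noise_sd = 0, e_target = 1.9, e_ref = 2.1, seed = 2)
  w2 <- add_wdct(d2)
  expect_equal(fold_change(mean(w2$wdct[w2$f == "Tr"]),
                           mean(w2$wdct[w2$f == "Co"])),
               4, tolerance = 1e-12)
})

test_that("noiseless ttest-layout generation carries the exact fold change", {
  d <- simulate_ttest(n_rep = 3, true_fc = c(gA = 1, gB = 4), noise_sd = 0,
                      seed = 3)
  w <- qpcrquant:::ttest_wdct(d, qpcr_meta(d))
  for (g in c("gA", "gB")) {
    fc <- fold_change(mean(w$wdct[w$gene == g & w$condition == "treatment"]),
                      mean(w$wdct[w$gene == g & w$condition == "control"]))
    expect_equal(fc, c(gA = 1, gB = 4)[[g]], tolerance = 1e-12)
  }
  expect_equal(nlevels(d$gene), 3) # 2 targets + 1 reference, reference last
  expect_equal(levels(d$gene)[3], "ref")
  expect_error(simulate_ttest(n_rep = 1, true_fc = 2), ">= 2")
})

test_that("estimated FC lands near truth at large n with noise", {
  d <- simulate_ttest(n_rep = 100, true_fc = c(g = 4), noise_sd = 0.2,
                      seed = 4)
  res <- qpcr_ttest(d)
  # se of log2 FC ~ noise_sd * sqrt(2/n) ~ 0.028; [3.5, 4.5] is > 5 se wide
  expect_gt(res$fc, 3.5)
  expect_lt(res$fc, 4.5)
})

test_that("dilution series follow the standard-curve model", {
  d <- simulate_dilution(c(g = 2), dilutions = c(1, 0.1, 0.01),
                         ct_at_dilution1 = 20, noise_sd = 0)
  expect_equal(diff(d$g), rep(log2(10), 2), tolerance = 1e-10)
  expect_equal(d$g[1], 20)
  expect_error(simulate_dilution(c(g = 0.9)), "> 1")
  expect_error(simulate_dilution(2, dilutions = c(1, 0.1)), "3 distinct")
})

test_that("generated wdct mean and SD converge to the generator settings", {
  d <- simulate_qpcr(list(f = c("a", "b")), n_rep = 4000,
                     true_re = c(1, 8), noise_sd = 0.4, seed = 5)
  w <- add_wdct(d)
  expect_equal(mean(w$wdct[w$f == "b"]), -3, tolerance = 0.05)
  expect_equal(sd(w$wdct[w$f == "b"]), 0.4, tolerance = 0.05)
})

test_that("degenerate generator settings are rejected", {
  expect_error(simulate_qpcr(list(f = c("a", "b")), true_re = c(1, -2)),
               "positive")
  expect_error(simulate_qpcr(list(f = c("a", "b")), n_rep = 0), "n_rep")
  expect_error(simulate_qpcr(list(c("a", "b"))), "named")
})
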