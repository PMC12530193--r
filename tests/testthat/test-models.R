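# ANOVA/ANCOVA fold change with a calibrator, relative-expression analysis,
# repeated measures and marginal-means comparisons.

sim1 <- function(noise = 0.15, seed = 41, n_rep = 3) {
  simulate_qpcr(list(treatment = c("L1", "L2", "L3")), n_rep = n_rep,
                true_re = c(1, 2, 8), noise_sd = noise, seed = seed)
}

test_that("model structure follows the analysis type", {
  d <- simulate_qpcr(list(f1 = c("a", "b"), f2 = c("x", "y", "z")),
                     n_rep = 3, true_re = 1, noise_sd = 0.2, seed = 42)
  fit_anova <- suppressWarnings(fit_wdct_model(d, main_factor = "f1"))
  expect_true(any(grepl("f1:f2", tidy(fit_anova)$term)))
  fit_ancova <- suppressWarnings(
    fit_wdct_model(d, main_factor = "f1", analysis_type = "ancova"))
  expect_false(any(grepl(":", tidy(fit_ancova)$term)))
  expect_equal(fit_ancova$analysis_type, "ancova")
  g <- glance(fit_ancova)
  expect_equal(g$nobs, nrow(d))
  expect_error(fit_wdct_model(d, main_factor = "nope"), "main_factor")
})

test_that("single-factor ANOVA table has the factor effect and residuals", {
  fit <- suppressWarnings(fit_wdct_model(sim1()))
  tab <- tidy(fit)
  expect_true("treatment" %in% tab$term)
  expect_equal(tab$df[tab$term == "treatment"], 2)
  # noiseless data with distinct level means: p effectively zero
  fit0 <- suppressWarnings(fit_wdct_model(sim1(noise = 0)))
  expect_lt(tidy(fit0)$p.value[1], 1e-12)
})

test_that("fold changes vs the calibrator are exact on noiseless data", {
  res <- suppressWarnings(qpcr_anova_fc(sim1(noise = 0), calibrator = "L1"))
  expect_equal(res$contrast, c("L1", "L2 vs L1", "L3 vs L1"))
  expect_equal(res$fc, c(1, 2, 8), tolerance = 1e-12)
  expect_equal(res$p_value[1], 1)
  expect_true(is.na(res$lcl[1]))
  # a different calibrator rescales the fold changes accordingly
  res2 <- suppressWarnings(qpcr_anova_fc(sim1(noise = 0), calibrator = "L2"))
  expect_equal(res2$fc[res2$contrast == "L3 vs L2"], 4, tolerance = 1e-12)
  expect_error(suppressWarnings(qpcr_anova_fc(sim1(), calibrator = "L9")),
               "Calibrator")
})

test_that("two-level one-factor ANOVA FC equals the pooled t-test", {
  d <- simulate_qpcr(list(cond = c("Co", "Tr")), n_rep = 5,
                     true_re = c(1, 3), noise_sd = 0.3, seed = 43)
  afc <- suppressWarnings(qpcr_anova_fc(d, calibrator = "Co"))
  w <- add_wdct(d)
  orc <- oracle_pooled_ttest(w$wdct[w$cond == "Tr"], w$wdct[w$cond == "Co"])
  row <- afc[afc$contrast == "Tr vs Co", ]
  expect_equal(row$fc, 2^(-orc$statistic * orc$se), tolerance = 1e-10)
  expect_equal(row$p_value, orc$p, tolerance = 1e-10)
  expect_equal(row$se_log2, orc$se, tolerance = 1e-10)
  expect_equal(row$df, orc$df)
})

test_that("RE table is consistent with FC contrasts and sorted by RE", {
  d <- sim1(noise = 0.2, seed = 44)
  re <- suppressWarnings(qpcr_anova_re(d))
  expect_true(all(diff(re$re) <= 0))
  fit <- attr(re, "fit")
  fc <- suppressWarnings(qpcr_anova_fc(fit, calibrator = "L1"))
  re_l2 <- re$re[re$treatment == "L2"]
  re_l1 <- re$re[re$treatment == "L1"]
  expect_equal(re_l2 / re_l1, fc$fc[fc$contrast == "L2 vs L1"],
               tolerance = 1e-10)
  # noiseless identical conditions share a single letter
  d_eq <- simulate_qpcr(list(f = c("a", "b", "c")), n_rep = 3, true_re = 1,
                        noise_sd = 0.05, seed = 45)
  re_eq <- suppressWarnings(qpcr_anova_re(d_eq))
  expect_equal(unique(re_eq$letters), "a")
})

test_that("a 2x3 design yields six RE rows and respects empty-cell errors", {
  d <- simulate_qpcr(list(f1 = c("a", "b"), f2 = c("x", "y", "z")),
                     n_rep = 2, true_re = 1, noise_sd = 0.2, seed = 46)
  re <- suppressWarnings(qpcr_anova_re(d))
  expect_equal(nrow(re), 6)
  d_miss <- tibble::as_tibble(d)
  d_miss <- d_miss[!(d_miss$f1 == "b" & d_miss$f2 == "z"), ]
  x <- qpcr_table(d_miss, "anova")
  expect_error(suppressWarnings(qpcr_anova_re(x)), "b:z")
})

test_that("letters reflect the pairwise comparisons they summarize", {
  d <- sim1(noise = 0.1, seed = 47, n_rep = 4)
  re <- suppressWarnings(qpcr_anova_re(d))
  prs <- attr(re, "pairwise")
  expect_equal(nrow(prs), 3)
  # rebuild the p matrix independently and check the sharing property
  lbl <- as.character(re$treatment)
  pm <- matrix(1, 3, 3, dimnames = list(c("L1", "L2", "L3"),
                                        c("L1", "L2", "L3")))
  splits <- strsplit(gsub("[()]", "", prs$contrast), " - ")
  for (k in seq_len(nrow(prs))) {
    pm[splits[[k]][1], splits[[k]][2]] <- prs$p.value[k]
    pm[splits[[k]][2], splits[[k]][1]] <- prs$p.value[k]
  }
  expect_true(cld_consistent(re$letters, pm[lbl, lbl], 0.05))
})

test_that("ANCOVA with a null covariate reproduces the ANOVA fold change", {
  d <- simulate_qpcr(list(cov = c("u", "v"), treatment = c("L1", "L2")),
                     n_rep = 3, true_re = c(1, 4, 1, 4), noise_sd = 0,
                     seed = 48)
  fc_anova <- suppressWarnings(
    qpcr_anova_fc(d, main_factor = "treatment", analysis_type = "anova"))
  fc_ancova <- suppressWarnings(
    qpcr_anova_fc(d, main_factor = "treatment", analysis_type = "ancova"))
  expect_equal(fc_ancova$fc[2], fc_anova$fc[2], tolerance = 1e-10)
  expect_equal(fc_ancova$fc[2], 4, tolerance = 1e-10)
})

test_that("significant interactions with the main factor raise a warning", {
  # strong crossing interaction: effect of treatment reverses with geno
  d <- simulate_qpcr(list(geno = c("g1", "g2"), treatment = c("c", "t")),
                     n_rep = 4, true_re = c(1, 4, 4, 1), noise_sd = 0.1,
                     seed = 49)
  w <- capture_warnings(qpcr_anova_fc(d, main_factor = "treatment"))
  expect_true(any(grepl("Interaction", w)))
  # no interaction warning when the factors act additively
  d_add <- simulate_qpcr(list(geno = c("g1", "g2"), treatment = c("c", "t")),
                         n_rep = 4, true_re = c(1, 4, 2, 8), noise_sd = 0.1,
                         seed = 53)
  w_add <- capture_warnings(qpcr_anova_fc(d_add, main_factor = "treatment"))
  expect_false(any(grepl("Interaction", w_add)))
})

test_that("repeated measures recover exact fold changes with id offsets", {
  d <- simulate_repeated(6, c(time2 = 4, time3 = 0.5), noise_sd = 0,
                         id_sd = 0.8, seed = 50)
  res <- suppressWarnings(qpcr_repeated(d))
  expect_equal(res$contrast[1], "time1")
  expect_equal(res$fc, c(1, 4, 0.5), tolerance = 1e-9)
  # id-specific offsets are real here; the mixed model must absorb them
  fit <- attr(res, "fit")
  expect_true(fit$is_mixed)
})

test_that("marginal means comparisons cover effects and slices", {
  d <- simulate_qpcr(list(f1 = c("a", "b"), f2 = c("x", "y", "z")),
                     n_rep = 3, true_re = c(1, 2, 1, 1, 2, 1),
                     noise_sd = 0.15, seed = 51)
  fit <- suppressWarnings(fit_wdct_model(d, main_factor = "f2"))
  main <- qpcr_means(fit, "f2")
  expect_equal(nrow(main), 3) # C(3,2)
  expect_equal(main$p_adj, oracle_bh(main$p_value), tolerance = 1e-12)
  sliced <- qpcr_means(fit, "f2", by = "f1")
  expect_equal(nrow(sliced), 6) # 2 slices x 3 contrasts
  expect_equal(sort(unique(as.character(sliced$f1))), c("a", "b"))
  expect_error(qpcr_means(fit, "f9"), "not in the model")
})

test_that("balanced-design marginal means equal raw cell-mean averages", {
  d <- simulate_qpcr(list(f1 = c("a", "b"), f2 = c("x", "y")),
                     n_rep = 3, true_re = c(1, 2, 4, 8), noise_sd = 0.2,
                     seed = 52)
  fit <- suppressWarnings(fit_wdct_model(d, main_factor = "f1"))
  em <- attr(qpcr_means(fit, "f1"), "emmeans")
  w <- add_wdct(d)
  cell_means <- tapply(w$wdct, list(w$f1, w$f2), mean)
  expect_equal(sort(em$emmean), sort(unname(rowMeans(cell_means))),
               tolerance = 1e-10)
})
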