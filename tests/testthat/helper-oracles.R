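# Independent textbook/brute-force oracles used to check the package's
# statistics. These deliberately re-derive everything from first principles
# and never call the code paths they verify.

# pooled-variance two-sample t-test
oracle_pooled_ttest <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t <- (mean(a) - mean(b)) / se
  df <- na + nb - 2
  list(statistic = t, df = df, p = 2 * pt(-abs(t), df), se = se)
}

# Welch t-test with Welch-Satterthwaite degrees of freedom
oracle_welch_ttest <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(statistic = t, df = df, p = 2 * pt(-abs(t), df))
}

# paired t-test
oracle_paired_ttest <- function(a, b) {
  d <- a - b
  se <- sd(d) / sqrt(length(d))
  t <- mean(d) / se
  df <- length(d) - 1
  list(statistic = t, df = df, p = 2 * pt(-abs(t), df), se = se)
}

# Benjamini-Hochberg step-up with explicit monotonicity enforcement
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# Pfaffl efficiency-corrected ratio, straight from its published form:
# E_target^-(mean CT_Tr - mean CT_Co)_target / E_ref^-(mean CT_Tr - mean CT_Co)_ref
oracle_pfaffl <- function(e_target, ct_target_tr, ct_target_co,
                          e_ref, ct_ref_tr, ct_ref_co) {
  e_target^(-(mean(ct_target_tr) - mean(ct_target_co))) /
    e_ref^(-(mean(ct_ref_tr) - mean(ct_ref_co)))
}

# the defining property of a compact letter display, checked pair by pair
cld_consistent <- function(letters_vec, p_matrix, alpha) {
  n <- length(letters_vec)
  sets <- strsplit(letters_vec, "")
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      share <- length(intersect(sets[[i]], sets[[j]])) > 0
      if (share != (p_matrix[i, j] >= alpha)) return(FALSE)
    }
  }
  TRUE
}

# random symmetric p-value matrix with unit diagonal
random_p_matrix <- function(n, labels = letters[seq_len(n)]) {
  m <- matrix(1, n, n, dimnames = list(labels, labels))
  ps <- runif(n * (n - 1) / 2)
  m[lower.tri(m)] <- ps
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  m
}
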