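# Synthetic qPCR data with known ground truth. The generative model is the
# one under which the package's statistics are valid: weighted delta-Ct
# values are normal on the log2 scale (equivalently RE/FC are lognormal),
# so every generator draws wdct = -log2(true RE) + random effects + noise
# and then solves the target Ct from the wdct definition.

with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Simulate a factorial qPCR experiment
#'
#' Draws per-observation weighted delta-Ct values
#' `wdct = -log2(true_re) + block effect + replicate effect + N(0, noise_sd)`
#' for every design cell and biological replicate, then emits reference Ct
#' values around `baseline_ref_ct` and solves the target Ct from the wdct
#' definition, so that the generated table analysed with this package
#' recovers `true_re` (exactly, when all randomness is switched off).
#'
#' Block and replicate effects are normal on the log2 scale, shared by all
#' observations of the same block / replicate ID, which is exactly the
#' random-intercept structure the model-based analyses assume. By default the
#' reference gene is perfectly stable (`ref_ct_jitter = 0`) so the ground
#' truth lives entirely in the target gene.
#'
#' @param design Named list of factors and their level names, e.g.
#'   `list(treatment = c("L1", "L2", "L3"))`; 1-3 factors.
#' @param n_rep Biological replicates per design cell (>= 1).
#' @param true_re True relative expression per design cell: a single value,
#'   or a vector in cell order (levels of the first factor varying slowest),
#'   optionally named by the cell labels (levels joined with `":"`).
#' @param e_target,e_ref Amplification efficiencies (amplification-factor
#'   scale, in (1, 2.5]).
#' @param baseline_ref_ct Mean reference-gene Ct (cycles).
#' @param noise_sd Residual SD of wdct (log2 units).
#' @param n_block Number of blocks (0 = no block column). With blocks, each
#'   block contains `n_rep` replicates of every cell.
#' @param block_sd,rep_sd SDs of the normal block / biological-replicate
#'   random intercepts (log2 units).
#' @param ref_ct_jitter SD of per-observation noise on the reference Ct
#'   (cycles); default 0 (perfectly stable reference).
#' @param seed Optional integer seed; the global RNG state is restored
#'   afterwards.
#' @return A validated `qpcr_tbl` in the anova layout.
#' @examples
#' simulate_qpcr(list(treatment = c("L1", "L2")), n_rep = 3,
#'               true_re = c(1, 4), noise_sd = 0.2, seed = 1)
#' @export
simulate_qpcr <- function(design, n_rep = 3, true_re = 1,
                          e_target = 2, e_ref = 2, baseline_ref_ct = 25,
                          noise_sd = 0.25, n_block = 0, block_sd = 0,
                          rep_sd = 0, ref_ct_jitter = 0, seed = NULL) {
  if (!is.list(design) || !length(design) || length(design) > 3 ||
      is.null(names(design))) {
    abort("`design` must be a named list of 1-3 factors.")
  }
  if (n_rep < 1) abort("`n_rep` must be >= 1.")
  if (any(true_re <= 0)) abort("`true_re` must be positive.")
  if (noise_sd < 0 || block_sd < 0 || rep_sd < 0 || ref_ct_jitter < 0) {
    abort("Standard deviations must be non-negative.")
  }

  cells <- rev(expand.grid(rev(design), stringsAsFactors = FALSE,
                           KEEP.OUT.ATTRS = FALSE))
  cell_labels <- do.call(paste, c(cells, sep = ":"))
  re <- resolve_true_re(true_re, cell_labels)

  blocks <- if (n_block > 0) paste0("b", seq_len(n_block)) else NA_character_
  grid <- tidyr::expand_grid(
    cell = seq_len(nrow(cells)),
    block = blocks,
    rep = paste0("r", seq_len(n_rep))
  )

  with_seed_maybe(seed, {
    block_eff <- if (n_block > 0) setNames(rnorm(n_block, 0, block_sd), blocks) else NULL
    rep_ids <- unique(if (n_block > 0) paste(grid$block, grid$rep) else grid$rep)
    rep_eff <- setNames(rnorm(length(rep_ids), 0, rep_sd), rep_ids)
    rep_key <- if (n_block > 0) paste(grid$block, grid$rep) else grid$rep
    wdct_val <- unname(
      -log2(re[grid$cell]) +
        (if (n_block > 0) block_eff[grid$block] else 0) +
        rep_eff[rep_key] +
        rnorm(nrow(grid), 0, noise_sd)
    )
    ref_ct <- baseline_ref_ct + rnorm(nrow(grid), 0, ref_ct_jitter)
    target_ct <- (wdct_val + log2(e_ref) * ref_ct) / log2(e_target)

    out <- dplyr::bind_cols(
      cells[grid$cell, , drop = FALSE],
      if (n_block > 0) tibble(block = grid$block),
      tibble(rep = grid$rep, target_e = e_target, target_ct = target_ct,
             ref1_e = e_ref, ref1_ct = ref_ct)
    )
    qpcr_table(as_tibble(out), "anova", n_ref = 1, block = n_block > 0,
               tech_rep = FALSE)
  })
}

resolve_true_re <- function(true_re, cell_labels) {
  n <- length(cell_labels)
  if (length(true_re) == 1) return(rep(true_re, n))
  if (!is.null(names(true_re))) {
    missing_cells <- setdiff(cell_labels, names(true_re))
    if (length(missing_cells)) {
      abort(paste0("`true_re` is missing cells: ",
                   paste(missing_cells, collapse = ", ")))
    }
    return(unname(true_re[cell_labels]))
  }
  if (length(true_re) != n) {
    abort(sprintf("`true_re` must have length 1 or %d (one per design cell).", n))
  }
  true_re
}

#' Simulate a two-condition multi-gene experiment (t-test layout)
#'
#' Generates the 4-column t-test layout: control condition first, target
#' genes followed by one reference gene, rows within each (condition, gene)
#' cell ordered by biological replicate so that the positional replicate
#' pairing used by [qpcr_ttest()] holds by construction. The control-condition
#' relative expression of every target is 1; the treatment condition shifts
#' the target's wdct by `-log2(true_fc)` plus normal noise.
#'
#' @param n_rep Biological replicates per condition (>= 2).
#' @param true_fc True fold change (treatment vs control) per target gene;
#'   names become gene labels (unnamed values are labelled `gene1`, ...).
#' @param noise_sd Residual SD of wdct (log2 units), applied in both
#'   conditions.
#' @param e Amplification efficiency used for every gene.
#' @param baseline_ref_ct Reference-gene Ct (cycles), held fixed.
#' @param seed Optional integer seed.
#' @return A validated `qpcr_tbl` in the ttest layout (reference gene
#'   `"ref"` last).
#' @examples
#' simulate_ttest(n_rep = 4, true_fc = c(myb = 4), noise_sd = 0.3, seed = 1)
#' @export
simulate_ttest <- function(n_rep, true_fc = 2, noise_sd = 0.25, e = 2,
                           baseline_ref_ct = 25, seed = NULL) {
  if (n_rep < 2) abort("`n_rep` must be >= 2 (a t-test needs at least two replicates).")
  if (any(true_fc <= 0)) abort("`true_fc` must be positive.")
  genes <- names(true_fc) %||% paste0("gene", seq_along(true_fc))
  if (is.null(names(true_fc))) names(true_fc) <- genes

  grid <- tidyr::expand_grid(
    condition = c("control", "treatment"),
    gene = c(genes, "ref"),
    rep = seq_len(n_rep)
  )
  with_seed_maybe(seed, {
    is_ref <- grid$gene == "ref"
    true_wdct <- ifelse(
      is_ref, NA_real_,
      ifelse(grid$condition == "treatment", -log2(true_fc[grid$gene]), 0)
    )
    wdct_val <- true_wdct + rnorm(nrow(grid), 0, noise_sd)
    ct <- ifelse(
      is_ref, baseline_ref_ct,
      (wdct_val + log2(e) * baseline_ref_ct) / log2(e)
    )
    qpcr_table(tibble(condition = grid$condition, gene = grid$gene,
                      e = e, ct = ct),
               "ttest", n_ref = 1)
  })
}

#' Simulate a dilution series for efficiency estimation
#'
#' Standard-curve model: `Ct = ct_at_dilution1 - log10(dilution) /
#' log10(E_true) + N(0, noise_sd)`, one Ct column per gene. With `E = 2`
#' the Ct increases by `log2(10) = 3.3219` cycles per 10-fold dilution.
#'
#' @param e_true True amplification efficiency per gene (> 1); names become
#'   gene column labels.
#' @param dilutions Positive dilution factors (>= 3 distinct values).
#' @param ct_at_dilution1 Ct at dilution 1 (recycled across genes).
#' @param noise_sd SD of Ct noise (cycles).
#' @param n_rep Replicate measurements per dilution.
#' @param seed Optional integer seed.
#' @return A validated `qpcr_tbl` in the efficiency layout.
#' @examples
#' simulate_dilution(c(geneA = 2), dilutions = c(1, 0.1, 0.01))
#' @export
simulate_dilution <- function(e_true, dilutions = c(1, 0.1, 0.01),
                              ct_at_dilution1 = 20, noise_sd = 0,
                              n_rep = 1, seed = NULL) {
  if (any(e_true <= 1)) abort("`e_true` must be > 1 on the amplification-factor scale.")
  if (any(dilutions <= 0) || length(unique(dilutions)) < 3) {
    abort("`dilutions` must be positive with at least 3 distinct values.")
  }
  genes <- names(e_true) %||% paste0("gene", seq_along(e_true))
  ct1 <- rep_len(ct_at_dilution1, length(e_true))
  dil <- rep(dilutions, each = n_rep)
  with_seed_maybe(seed, {
    ct_cols <- purrr::map2(e_true, ct1, function(e, c0) {
      c0 - log10(dil) / log10(e) + rnorm(length(dil), 0, noise_sd)
    })
    names(ct_cols) <- genes
    qpcr_table(dplyr::bind_cols(tibble(dilution = dil), tibble::as_tibble(ct_cols)),
               "efficiency")
  })
}
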