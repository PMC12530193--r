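# Data model and IO. Input tables follow the positional column-arrangement
# conventions of standard qPCR analysis layouts; columns are mapped by
# position, renamed to canonical names, and validated. An explicit name
# mapping can override the positional convention.

QPCR_LAYOUTS <- c("anova", "ancova", "ttest", "repeated", "efficiency")

#' Validate and canonicalize a qPCR data frame
#'
#' Maps the columns of a long-format qPCR table to canonical names according
#' to the positional layout convention, validates values, and attaches layout
#' metadata. All analysis functions in the package expect tables produced by
#' this function or by [read_qpcr()] / the `simulate_*()` generators.
#'
#' Expected column arrangements (positional):
#' \describe{
#'   \item{anova / ancova}{`factor1 [- factor2 [- factor3]] [- block] - rep
#'     [- tech_rep] - targetE - targetCt - ref1E - ref1Ct [- ref2E - ref2Ct]`}
#'   \item{ttest}{`condition - gene - E - Ct`, with the control level of
#'     `condition` first and the reference gene level(s) last.}
#'   \item{repeated}{`id [- treatment] - time - targetE - targetCt - ref1E -
#'     ref1Ct [- ref2E - ref2Ct]`; each id is one physical individual
#'     measured at every time point.}
#'   \item{efficiency}{`dilution` followed by one Ct column per gene (gene
#'     names taken from the header).}
#' }
#'
#' The number of reference genes, and the presence of block / technical
#' replicate / treatment columns, are inferred from the column count, the
#' column names (names matching `block` or `tech` are recognised), and the
#' value ranges (efficiency columns lie in (1, 2.5]); each can be forced via
#' the corresponding argument.
#'
#' @param data A data frame in one of the supported arrangements.
#' @param layout One of `"anova"`, `"ancova"`, `"ttest"`, `"repeated"`,
#'   `"efficiency"`.
#' @param n_ref Number of reference genes (1 or 2). For the ttest layout,
#'   the number of trailing gene levels flagged as references (default 1).
#' @param block,tech_rep,treatment Logical, force presence/absence of the
#'   optional columns; `NULL` (default) infers from names and column count.
#' @param col_map Optional named character vector mapping canonical names
#'   (e.g. `c(target_ct = "myCt")`) onto columns of `data`, overriding the
#'   positional convention for those columns.
#' @return A tibble with canonical column names, class `qpcr_tbl`, carrying
#'   layout metadata attributes.
#' @examples
#' d <- data.frame(
#'   treat = rep(c("ctrl", "drought"), each = 3), rep = rep(1:3, 2),
#'   targetE = 2, targetCt = c(30, 30.2, 29.8, 28, 28.3, 27.9),
#'   refE = 2, refCt = 25
#' )
#' qpcr_table(d, "anova")
#' @export
qpcr_table <- function(data, layout = c("anova", "ancova", "ttest",
                                        "repeated", "efficiency"),
                       n_ref = NULL, block = NULL, tech_rep = NULL,
                       treatment = NULL, col_map = NULL) {
  layout <- match.arg(layout)
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  data <- as_tibble(data)
  if (!is.null(col_map)) {
    missing_cols <- setdiff(unname(col_map), names(data))
    if (length(missing_cols)) {
      abort(paste0("`col_map` names columns absent from `data`: ",
                   paste(missing_cols, collapse = ", ")))
    }
  }
  switch(layout,
    ttest      = validate_ttest_layout(data, n_ref %||% 1L),
    efficiency = validate_efficiency_layout(data),
    repeated   = validate_repeated_layout(data, n_ref, treatment),
    validate_factorial_layout(data, layout, n_ref, block, tech_rep, col_map)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

new_qpcr_tbl <- function(data, layout, meta) {
  structure(
    data,
    class = c("qpcr_tbl", class(as_tibble(data))),
    qpcr_layout = layout,
    qpcr_meta = meta
  )
}

#' Layout metadata of a qPCR table
#'
#' @param x A `qpcr_tbl` created by [qpcr_table()] or [read_qpcr()].
#' @return A list with the layout tag plus, depending on layout, the factor
#'   column names, block/rep/tech-rep columns, and number of reference genes.
#' @export
qpcr_meta <- function(x) {
  if (!inherits(x, "qpcr_tbl")) abort("`x` is not a qpcr_tbl.")
  c(list(layout = attr(x, "qpcr_layout")), attr(x, "qpcr_meta"))
}

#' @export
print.qpcr_tbl <- function(x, ...) {
  m <- qpcr_meta(x)
  cat("<qpcr_tbl> layout:", m$layout)
  if (!is.null(m$factor_cols)) {
    cat(" | factors:", paste(m$factor_cols, collapse = ", "))
  }
  if (isTRUE(m$block)) cat(" | block")
  if (!is.null(m$n_ref)) cat(" | reference genes:", m$n_ref)
  cat("\n")
  print(as_tibble(x), ...)
  invisible(x)
}

# -- value checks ------------------------------------------------------------

looks_like_efficiency <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x > 1 & x <= 2.5)
}

check_numeric_col <- function(data, col, what) {
  x <- data[[col]]
  if (!is.numeric(x)) {
    bad <- which(is.na(suppressWarnings(as.numeric(as.character(x)))))[1]
    abort(sprintf("Column `%s` (%s) is not numeric (first offending row: %s).",
                  col, what, bad %||% NA))
  }
  if (anyNA(x) || !all(is.finite(x))) {
    abort(sprintf("Column `%s` (%s) contains missing or non-finite values (row %d). Missing values are not supported; remove or re-measure them.",
                  col, what, which(!is.finite(x))[1]))
  }
  invisible(x)
}

check_ct_col <- function(data, col) {
  x <- check_numeric_col(data, col, "Ct")
  if (any(x <= 0)) {
    abort(sprintf("Column `%s`: Ct values must be > 0 (row %d).",
                  col, which(x <= 0)[1]))
  }
  invisible(x)
}

check_e_col <- function(data, col) {
  x <- check_numeric_col(data, col, "efficiency")
  if (any(x <= 1 | x > 2.5)) {
    abort(sprintf("Column `%s`: amplification efficiencies must lie in (1, 2.5] on the amplification-factor scale (row %d).",
                  col, which(x <= 1 | x > 2.5)[1]))
  }
  if (any(x < 1.6 | x > 2.2)) {
    warn(sprintf("Column `%s`: efficiencies outside [1.6, 2.2] look unusual; check the amplification-factor scale.", col))
  }
  invisible(x)
}

# -- factorial (anova/ancova) layout ----------------------------------------

validate_factorial_layout <- function(data, layout, n_ref, block, tech_rep,
                                      col_map = NULL) {
  nc <- ncol(data)
  nms <- names(data)

  # number of reference genes: forced, or inferred from whether the column
  # six-from-the-end has efficiency-like values (then the trailing E/Ct block
  # spans six columns)
  if (is.null(n_ref)) {
    n_ref <- if (nc >= 9 && looks_like_efficiency(data[[nc - 5]])) 2L else 1L
  }
  n_ref <- as.integer(n_ref)
  if (!n_ref %in% 1:2) abort("`n_ref` must be 1 or 2.")
  n_meas <- 2L * (1L + n_ref)
  lead <- nc - n_meas
  lead_nms <- nms[seq_len(max(lead, 0))]

  if (is.null(block)) block <- any(grepl("block", lead_nms, ignore.case = TRUE))
  if (is.null(tech_rep)) tech_rep <- any(grepl("tech", lead_nms, ignore.case = TRUE))
  n_fac <- lead - 1L - as.integer(block) - as.integer(tech_rep)
  if (n_fac < 1 || n_fac > 3) {
    abort(paste0(
      "Unexpected number of columns (", nc, ") for the ", layout, " layout. ",
      "Expected: factor1 [- factor2 [- factor3]] ",
      if (isTRUE(block)) "- block " else "[- block] ",
      "- rep ", if (isTRUE(tech_rep)) "- tech_rep " else "",
      "- targetE - targetCt - ref1E - ref1Ct",
      if (n_ref == 2) " - ref2E - ref2Ct" else "", "."
    ))
  }

  # keep the user's factor names when they are usable; measurement columns
  # always get canonical names
  fac_names <- nms[seq_len(n_fac)]
  usable <- !is.na(fac_names) & fac_names == make.names(fac_names) &
    !duplicated(fac_names) &
    !fac_names %in% c("block", "rep", "tech_rep", "target_e", "target_ct",
                      "ref1_e", "ref1_ct", "ref2_e", "ref2_ct")
  fac_names[!usable] <- paste0("factor", seq_len(n_fac))[!usable]
  canonical <- c(
    fac_names,
    if (block) "block", "rep", if (tech_rep) "tech_rep",
    "target_e", "target_ct", "ref1_e", "ref1_ct",
    if (n_ref == 2) c("ref2_e", "ref2_ct")
  )
  data <- apply_col_map(data, canonical, col_map)
  names(data) <- canonical

  e_cols <- grep("_e$", canonical, value = TRUE)
  ct_cols <- grep("_ct$", canonical, value = TRUE)
  purrr::walk(e_cols, ~ check_e_col(data, .x))
  purrr::walk(ct_cols, ~ check_ct_col(data, .x))

  fac_cols <- fac_names
  # a leading column whose values look like efficiencies indicates a permuted
  # arrangement (measurement columns must come last)
  for (col in fac_cols) {
    if (looks_like_efficiency(data[[col]])) {
      abort(sprintf("Column `%s` is positioned as a factor but holds efficiency-like values; columns must be arranged factors - [block] - rep - [tech_rep] - E/Ct.", col))
    }
  }
  data <- dplyr::mutate(
    data,
    dplyr::across(dplyr::all_of(c(fac_cols, if (block) "block")),
                  ~ factor(.x, levels = unique(.x))),
    rep = factor(.data$rep, levels = unique(.data$rep))
  )

  key_cols <- c(fac_cols, if (block) "block", "rep", if (tech_rep) "tech_rep")
  dup <- duplicated(data[key_cols])
  if (any(dup)) {
    abort(sprintf("Duplicated observation key (%s) at row %d.",
                  paste(key_cols, collapse = ", "), which(dup)[1]))
  }

  new_qpcr_tbl(data, layout, list(
    factor_cols = fac_cols, block = block, rep_col = "rep",
    tech_rep = tech_rep, n_ref = n_ref
  ))
}

apply_col_map <- function(data, canonical, col_map) {
  if (is.null(col_map)) return(data)
  unknown <- setdiff(names(col_map), canonical)
  if (length(unknown)) {
    abort(paste0("`col_map` refers to unknown canonical columns: ",
                 paste(unknown, collapse = ", "),
                 ". Valid names: ", paste(canonical, collapse = ", ")))
  }
  # start from the positional order, then substitute the explicitly mapped
  # columns in place
  out <- data
  for (canon in names(col_map)) {
    pos <- match(canon, canonical)
    out[[pos]] <- data[[col_map[[canon]]]]
  }
  out
}

# -- ttest layout ------------------------------------------------------------

validate_ttest_layout <- function(data, n_ref) {
  if (ncol(data) != 4) {
    abort("The ttest layout needs exactly 4 columns: condition (control level first) - gene (reference gene(s) last) - efficiency - Ct.")
  }
  names(data) <- c("condition", "gene", "e", "ct")
  check_e_col(data, "e")
  check_ct_col(data, "ct")
  data <- dplyr::mutate(
    data,
    condition = factor(.data$condition, levels = unique(.data$condition)),
    gene = factor(.data$gene, levels = unique(.data$gene))
  )
  if (nlevels(data$condition) != 2) {
    abort(sprintf("The ttest layout needs exactly two condition levels; found %d.",
                  nlevels(data$condition)))
  }
  n_gene <- nlevels(data$gene)
  n_ref <- as.integer(n_ref)
  if (!n_ref %in% 1:2 || n_gene - n_ref < 1) {
    abort("Need at least one target gene and 1-2 reference genes (the last gene level(s)).")
  }
  counts <- dplyr::count(data, .data$condition, .data$gene)
  if (dplyr::n_distinct(counts$n) != 1) {
    abort("Unequal observation counts per (condition, gene) cell; replicate pairing requires balanced cells.")
  }
  new_qpcr_tbl(data, "ttest", list(
    n_ref = n_ref,
    control = levels(data$condition)[1],
    ref_genes = tail(levels(data$gene), n_ref),
    target_genes = head(levels(data$gene), n_gene - n_ref),
    n_rep = counts$n[1]
  ))
}

# -- repeated-measures layout ------------------------------------------------

validate_repeated_layout <- function(data, n_ref, treatment) {
  nc <- ncol(data)
  if (is.null(n_ref)) {
    n_ref <- if (nc >= 9 && looks_like_efficiency(data[[nc - 5]])) 2L else 1L
  }
  n_ref <- as.integer(n_ref)
  n_meas <- 2L * (1L + n_ref)
  lead <- nc - n_meas
  if (is.null(treatment)) treatment <- lead == 3L
  n_expected <- 2L + as.integer(treatment)
  if (lead != n_expected) {
    abort(paste0("Unexpected number of columns (", nc, ") for the repeated layout. Expected: id [- treatment] - time - targetE - targetCt - ref1E - ref1Ct [- ref2E - ref2Ct]."))
  }
  canonical <- c("id", if (treatment) "treatment", "time",
                 "target_e", "target_ct", "ref1_e", "ref1_ct",
                 if (n_ref == 2) c("ref2_e", "ref2_ct"))
  names(data) <- canonical
  purrr::walk(grep("_e$", canonical, value = TRUE), ~ check_e_col(data, .x))
  purrr::walk(grep("_ct$", canonical, value = TRUE), ~ check_ct_col(data, .x))
  data <- dplyr::mutate(
    data,
    id = factor(.data$id, levels = unique(.data$id)),
    time = factor(.data$time, levels = unique(.data$time)),
    dplyr::across(dplyr::any_of("treatment"), ~ factor(.x, levels = unique(.x)))
  )
  dup <- duplicated(data[c("id", "time")])
  if (any(dup)) {
    abort(sprintf("Each id must appear once per time point (duplicate at row %d).", which(dup)[1]))
  }
  per_id <- table(data$id)
  if (all(per_id == 1)) {
    abort("Every id is observed at a single time point; this is not a repeated-measures design.")
  }
  if (any(per_id == 1)) {
    warn(sprintf("%d id(s) observed at a single time point only.", sum(per_id == 1)))
  }
  new_qpcr_tbl(data, "repeated", list(
    n_ref = n_ref, treatment = treatment,
    factor_cols = c(if (treatment) "treatment", "time"), id_col = "id"
  ))
}

# -- efficiency (dilution-series) layout ------------------------------------

validate_efficiency_layout <- function(data) {
  if (ncol(data) < 2) {
    abort("The efficiency layout needs a dilution column followed by at least one gene Ct column.")
  }
  gene_names <- names(data)[-1]
  names(data)[1] <- "dilution"
  check_numeric_col(data, "dilution", "dilution")
  purrr::walk(gene_names, ~ check_ct_col(data, .x))
  new_qpcr_tbl(data, "efficiency", list(genes = gene_names))
}

# -- reading / writing -------------------------------------------------------

detect_delim <- function(path) {
  header <- readLines(path, n = 1)
  counts <- vapply(c("," = ",", "\t" = "\t", ";" = ";"),
                   function(d) lengths(regmatches(header, gregexpr(d, header, fixed = TRUE))),
                   integer(1))
  if (all(counts == 0)) abort("Could not detect a delimiter (comma, tab or semicolon) in the header row.")
  names(counts)[which.max(counts)]
}

#' Read a qPCR table from a delimited text file
#'
#' Reads a CSV/TSV (delimiter auto-detected among comma, tab and semicolon),
#' then validates it with [qpcr_table()]. The file must have a header row;
#' columns are interpreted positionally according to `layout`.
#'
#' @param path Path to a delimited text file with a header row.
#' @inheritParams qpcr_table
#' @param ... Passed on to [qpcr_table()] (`n_ref`, `block`, `tech_rep`,
#'   `treatment`, `col_map`).
#' @return A validated `qpcr_tbl`.
#' @export
read_qpcr <- function(path, layout = c("anova", "ancova", "ttest",
                                       "repeated", "efficiency"), ...) {
  layout <- match.arg(layout)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readr::read_delim(path, delim = detect_delim(path),
                           show_col_types = FALSE, progress = FALSE,
                           trim_ws = TRUE)
  qpcr_table(raw, layout, ...)
}

#' Write a qPCR table back to CSV
#'
#' Writes the canonical long-format table at full numeric precision, so that
#' `read_qpcr()` on the written file round-trips the values.
#'
#' @param data A `qpcr_tbl` or plain data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_qpcr <- function(data, path) {
  readr::write_csv(as_tibble(data), path)
  invisible(path)
}

#' Average technical replicates
#'
#' Collapses technical replicates by replacing every numeric E/Ct column
#' with its arithmetic mean (on the Ct scale) within each group, dropping
#' the technical-replicate column. The result has one row per distinct
#' grouping key and is revalidated, so it can flow straight into the
#' analysis functions.
#'
#' @param data A `qpcr_tbl` containing a technical-replicate column, or any
#'   data frame whose non-grouping numeric columns should be averaged.
#' @param groups Character vector of grouping column names. Defaults to all
#'   factor/block/rep columns of a `qpcr_tbl`.
#' @return A `qpcr_tbl` (or tibble) with one row per group.
#' @examples
#' d <- data.frame(
#'   f = rep("a", 4), rep = c(1, 1, 2, 2), tech = c(1, 2, 1, 2),
#'   targetE = 2, targetCt = c(20, 21, 22, 23), refE = 2, refCt = 15
#' )
#' x <- qpcr_table(d, "anova", tech_rep = TRUE)
#' mean_technical_reps(x)
#' @export
mean_technical_reps <- function(data, groups = NULL) {
  is_qpcr <- inherits(data, "qpcr_tbl")
  if (is_qpcr) {
    m <- qpcr_meta(data)
    if (is.null(groups)) {
      groups <- c(m$factor_cols, if (isTRUE(m$block)) "block",
                  m$rep_col %||% character())
    }
  }
  missing_groups <- setdiff(groups, names(data))
  if (is.null(groups) || length(missing_groups)) {
    abort(paste0("Grouping column(s) not found: ",
                 paste(missing_groups %||% "none given", collapse = ", ")))
  }
  value_cols <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                        c(groups, "tech_rep"))
  out <- data |>
    as_tibble() |>
    dplyr::mutate(dplyr::across(dplyr::all_of(groups), ~.x)) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(value_cols), mean),
                     .by = dplyr::all_of(groups))
  if (is_qpcr && isTRUE(qpcr_meta(data)$tech_rep)) {
    m <- qpcr_meta(data)
    qpcr_table(out, attr(data, "qpcr_layout"), n_ref = m$n_ref,
               block = m$block, tech_rep = FALSE)
  } else {
    out
  }
}

# -- result writing (publication table shapes) ------------------------------

fmt4 <- function(x) {
  ifelse(is.na(x), "", formatC(x, digits = 4, format = "f"))
}

#' Write an analysis result table to CSV
#'
#' Writes fold-change, relative-expression or efficiency results in the
#' conventional publication column order, numbers formatted to 4 decimal
#' places. Fold-change tables carry `Gene` (t-test results) or `Contrast`
#' (ANOVA results) as the label column; an adjusted-p column is appended
#' when a multiplicity adjustment other than `"none"` was applied.
#'
#' @param result A `qpcr_fc`, `qpcr_re` or `qpcr_efficiency` result object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_qpcr_results <- function(result, path) {
  if (is.null(result) || !nrow(result)) abort("`result` is empty; nothing to write.")
  out <- if (inherits(result, "qpcr_fc")) {
    format_fc_results(result)
  } else if (inherits(result, "qpcr_re")) {
    format_re_results(result)
  } else if (inherits(result, "qpcr_efficiency")) {
    tibble(
      Gene = result$gene, Slope = fmt4(result$slope),
      Intercept = fmt4(result$intercept), R2 = fmt4(result$r_squared),
      E = fmt4(result$efficiency),
      `Efficiency %` = fmt4(result$percent_efficiency)
    )
  } else {
    abort("`result` must be a qpcr_fc, qpcr_re or qpcr_efficiency object.")
  }
  readr::write_csv(out, path)
  invisible(path)
}

format_fc_results <- function(result) {
  label_col <- if ("gene" %in% names(result)) "Gene" else "Contrast"
  out <- tibble(
    !!label_col := result[[if (label_col == "Gene") "gene" else "contrast"]],
    FC = fmt4(result$fc), LCL = fmt4(result$lcl), UCL = fmt4(result$ucl),
    `p value` = fmt4(result$p_value), se = fmt4(result$se_log2),
    Lower.se = fmt4(result$lower_se), Upper.se = fmt4(result$upper_se)
  )
  if (label_col == "Contrast") {
    out <- out |>
      dplyr::mutate(sig = result$sig) |>
      dplyr::relocate("sig", .after = "p value")
  }
  p_adjust <- attr(result, "p_adjust") %||% "none"
  if (!identical(p_adjust, "none") && "p_adj" %in% names(result) &&
      nrow(result) > 1) {
    out$`p adj` <- fmt4(result$p_adj)
  }
  out
}

format_re_results <- function(result) {
  fac_cols <- attr(result, "factor_cols") %||% character()
  out <- result[fac_cols]
  names(out) <- tools::toTitleCase(names(out))
  dplyr::bind_cols(out, tibble(
    RE = fmt4(result$re), LCL = fmt4(result$lcl), UCL = fmt4(result$ucl),
    se = fmt4(result$se_log2), Lower.se = fmt4(result$lower_se),
    Upper.se = fmt4(result$upper_se), Letters = result$letters
  ))
}
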