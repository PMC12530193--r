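# Compact letter display by the insert-and-absorb algorithm: start with one
# letter column containing every group; for each significantly different
# pair split any column containing both; absorb columns that became subsets
# of others. Two groups share a letter if and only if their pairwise p-value
# is >= alpha.

#' Compact letter display from a pairwise p-value matrix
#'
#' Assigns letter codes summarizing all pairwise comparisons: two groups
#' share at least one letter exactly when their pairwise p-value is >=
#' `alpha` (i.e. groups sharing no letter differ significantly). Letters are
#' assigned `"a"`, `"b"`, ... in the order groups appear in the matrix, so
#' sorting the matrix rows (e.g. by descending relative expression) before
#' the call yields the conventional presentation where the largest mean is
#' `"a"`.
#'
#' @param p_matrix Symmetric numeric matrix of pairwise p-values; row/column
#'   names are used as group labels (diagonal ignored).
#' @param alpha Significance threshold.
#' @return A character vector of letter strings, one per group, named by the
#'   group labels when present.
#' @examples
#' p <- matrix(c(1, .001, .001, .001, 1, .9, .001, .9, 1), 3, 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' compact_letter_display(p) # "a"  "b"  "b"
#' @export
compact_letter_display <- function(p_matrix, alpha = 0.05) {
  if (!is.matrix(p_matrix) || nrow(p_matrix) != ncol(p_matrix)) {
    abort("`p_matrix` must be a square matrix.")
  }
  if (!isTRUE(all.equal(p_matrix, t(p_matrix), tolerance = 1e-12,
                        check.attributes = FALSE))) {
    abort("`p_matrix` must be symmetric.")
  }
  n <- nrow(p_matrix)
  labels <- rownames(p_matrix) %||% as.character(seq_len(n))
  if (n == 1) return(setNames("a", labels))

  columns <- list(seq_len(n))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (is.na(p_matrix[i, j]) || p_matrix[i, j] >= alpha) next
      hit <- vapply(columns, function(s) i %in% s && j %in% s, logical(1))
      if (!any(hit)) next
      split_cols <- unlist(lapply(columns[hit], function(s) {
        list(setdiff(s, i), setdiff(s, j))
      }), recursive = FALSE)
      columns <- absorb_columns(c(columns[!hit], split_cols))
    }
  }
  columns <- columns[lengths(columns) > 0]
  # order letters by the first group each column contains
  columns <- columns[order(vapply(columns, min, integer(1)))]
  letter_pool <- make_letter_pool(length(columns))
  out <- vapply(seq_len(n), function(g) {
    paste(letter_pool[vapply(columns, function(s) g %in% s, logical(1))],
          collapse = "")
  }, character(1))
  setNames(out, labels)
}

absorb_columns <- function(columns) {
  columns <- unique(lapply(columns, sort))
  keep <- rep(TRUE, length(columns))
  for (a in seq_along(columns)) {
    for (b in seq_along(columns)) {
      if (a != b && keep[a] &&
          all(columns[[a]] %in% columns[[b]]) &&
          (length(columns[[a]]) < length(columns[[b]]) || a > b)) {
        keep[a] <- FALSE
        break
      }
    }
  }
  columns[keep]
}

make_letter_pool <- function(k) {
  if (k <= 26) return(letters[seq_len(k)])
  c(letters, as.vector(outer(letters, letters, paste0)))[seq_len(k)]
}
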